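#' Spanning tree over a labeled channel set
#'
#' The unit of all network metrics: an acyclic connected subgraph holding
#' every channel, with positive edge weights (WPLI strengths). The
#' constructor validates the tree property (N - 1 edges, no cycles, hence
#' connected).
#'
#' @param labels Node names.
#' @param edges Data frame with columns `a`, `b`, `weight`.
#' @return Object of class `"mst_tree"` with `labels`, `edges`, `N`, `M`.
#' @export
spanning_tree <- function(labels, edges) {
  labels <- as.character(labels)
  edges <- as.data.frame(edges)
  if (!all(c("a", "b", "weight") %in% names(edges))) {
    stop("edges need columns a, b, weight", call. = FALSE)
  }
  n <- length(labels)
  if (nrow(edges) != n - 1) {
    stop("a spanning tree over ", n, " nodes needs ", n - 1, " edges",
         call. = FALSE)
  }
  if (any(edges$weight <= 0)) {
    stop("tree edge weights must be positive", call. = FALSE)
  }
  miss <- setdiff(unique(c(edges$a, edges$b)), labels)
  if (length(miss)) {
    stop("edges reference unknown nodes: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(edges))) {
    ra <- find(match(edges$a[k], labels))
    rb <- find(match(edges$b[k], labels))
    if (ra == rb) stop("edges contain a cycle", call. = FALSE)
    parent[ra] <- rb
  }
  structure(
    list(labels = labels, edges = edges, N = n, M = nrow(edges)),
    class = "mst_tree"
  )
}

#' @export
print.mst_tree <- function(x, ...) {
  cat("<mst_tree> ", x$N, " nodes, ", x$M, " edges, total weight ",
      signif(sum(x$edges$weight), 4), "\n", sep = "")
  invisible(x)
}

#' Maximum-weight spanning tree of a connectivity matrix
#'
#' Because WPLI edge weights encode synchronization strength (inverse
#' distance), the informative backbone is the spanning tree of maximum
#' total weight — the "minimum spanning tree" after weight inversion.
#' Kruskal's algorithm on edges sorted by descending weight, ties broken
#' lexicographically on the label pair, so the result is deterministic.
#'
#' @param conn `"mst_connectivity"` (or symmetric labeled matrix). Only
#'   strictly positive entries count as edges.
#' @return `"mst_tree"`.
#' @export
mst <- function(conn) {
  if (inherits(conn, "mst_connectivity")) {
    m <- conn$values
  } else {
    m <- as.matrix(conn)
  }
  labels <- rownames(m)
  n <- length(labels)
  ii <- which(upper.tri(m) & m > 0, arr.ind = TRUE)
  ed <- data.frame(a = labels[ii[, 1]], b = labels[ii[, 2]],
                   weight = m[ii])
  ord <- order(-ed$weight, ed$a, ed$b)
  ed <- ed[ord, , drop = FALSE]
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  keep <- logical(nrow(ed))
  taken <- 0L
  for (k in seq_len(nrow(ed))) {
    ra <- find(match(ed$a[k], labels))
    rb <- find(match(ed$b[k], labels))
    if (ra != rb) {
      parent[ra] <- rb
      keep[k] <- TRUE
      taken <- taken + 1L
      if (taken == n - 1L) break
    }
  }
  if (taken < n - 1L) {
    roots <- vapply(seq_len(n), find, integer(1))
    comps <- split(labels, roots)
    stop("graph is disconnected; components: ",
         paste(vapply(comps, paste, "", collapse = ","), collapse = " | "),
         call. = FALSE)
  }
  ed <- ed[keep, , drop = FALSE]
  rownames(ed) <- NULL
  spanning_tree(labels, ed)
}

# label -> adjacency index list
tree_adjacency <- function(tree) {
  adj <- vector("list", tree$N)
  ia <- match(tree$edges$a, tree$labels)
  ib <- match(tree$edges$b, tree$labels)
  for (k in seq_along(ia)) {
    adj[[ia[k]]] <- c(adj[[ia[k]]], ib[k])
    adj[[ib[k]]] <- c(adj[[ib[k]]], ia[k])
  }
  adj
}

#' Node degree
#'
#' Number of tree edges incident on each node; degree-1 nodes are leaves,
#' high-degree nodes are hubs.
#'
#' @param tree `"mst_tree"`.
#' @return Named integer vector.
#' @export
node_degree <- function(tree) {
  tab <- table(factor(c(tree$edges$a, tree$edges$b), levels = tree$labels))
  out <- as.integer(tab)
  names(out) <- tree$labels
  out
}

#' Normalized betweenness centrality on a tree
#'
#' Fraction of ordered pairs (h, j), h != j, both different from i, whose
#' (unique) tree path passes through node i, normalized by
#' (N - 1)(N - 2). On a tree this equals the product-sum of the component
#' sizes created by removing i. Leaves score 0; a star center scores 1.
#'
#' @param tree `"mst_tree"` with at least 3 nodes.
#' @return Named numeric vector in \[0, 1\].
#' @export
node_betweenness <- function(tree) {
  n <- tree$N
  if (n < 3) {
    stop("betweenness undefined for fewer than 3 nodes", call. = FALSE)
  }
  adj <- tree_adjacency(tree)
  out <- numeric(n)
  for (i in seq_len(n)) {
    sizes <- integer(0)
    visited <- logical(n)
    visited[i] <- TRUE
    for (nb in adj[[i]]) {
      if (visited[nb]) next
      # BFS of the component hanging off neighbour nb with i removed
      queue <- nb
      visited[nb] <- TRUE
      sz <- 0L
      while (length(queue)) {
        v <- queue[1]
        queue <- queue[-1]
        sz <- sz + 1L
        for (w in adj[[v]]) {
          if (!visited[w]) {
            visited[w] <- TRUE
            queue <- c(queue, w)
          }
        }
      }
      sizes <- c(sizes, sz)
    }
    out[i] <- (sum(sizes)^2 - sum(sizes^2)) / ((n - 1) * (n - 2))
  }
  names(out) <- tree$labels
  out
}

#' @rdname node_degree
#' @return `node_metrics` returns a data frame with columns `node`,
#'   `degree`, `betweenness`.
#' @export
node_metrics <- function(tree) {
  data.frame(node = tree$labels, degree = node_degree(tree),
             betweenness = node_betweenness(tree), row.names = NULL)
}

# hop eccentricities by BFS; trees are small so this is O(N^2)
tree_hop_diameter <- function(tree) {
  adj <- tree_adjacency(tree)
  n <- tree$N
  best <- 0L
  for (s in seq_len(n)) {
    dist <- rep(NA_integer_, n)
    dist[s] <- 0L
    queue <- s
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      for (w in adj[[v]]) {
        if (is.na(dist[w])) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
      }
    }
    best <- max(best, max(dist))
  }
  best
}

#' Tree-level network metrics
#'
#' * `tree_diameter`: longest hop distance between any two nodes divided by
#'   the edge count M; 1 for a path, 2/M for a star. High values mean long
#'   communication routes.
#' * `leaf_fraction`: number of degree-1 nodes over M; 1 for a star
#'   (maximally centralized), 2/M for a path.
#' * `tree_hierarchy`: L / (2 M C_Bmax), balancing integration against hub
#'   overload; tends to 0 for a line and 0.5 for a star.
#' * `global_fc`: sum of tree edge weights — overall synchronization
#'   strength retained by the backbone.
#'
#' @param tree `"mst_tree"` (N >= 3 where noted).
#' @return Scalar; `tree_metrics` returns a one-row data frame with
#'   `diameter`, `leaf_fraction`, `tree_hierarchy`, `betweenness_max`,
#'   `global_fc`.
#' @export
tree_diameter <- function(tree) {
  tree_hop_diameter(tree) / tree$M
}

#' @rdname tree_diameter
#' @export
leaf_fraction <- function(tree) {
  if (tree$N < 3) {
    stop("leaf fraction undefined for fewer than 3 nodes", call. = FALSE)
  }
  sum(node_degree(tree) == 1) / tree$M
}

#' @rdname tree_diameter
#' @export
tree_hierarchy <- function(tree) {
  if (tree$N < 3) {
    stop("tree hierarchy undefined for fewer than 3 nodes", call. = FALSE)
  }
  cb_max <- max(node_betweenness(tree))
  if (cb_max <= 0) stop("internal error: zero maximum betweenness")
  leaves <- sum(node_degree(tree) == 1)
  leaves / (2 * tree$M * cb_max)
}

#' @rdname tree_diameter
#' @export
global_fc <- function(tree) {
  sum(tree$edges$weight)
}

#' @rdname tree_diameter
#' @export
tree_metrics <- function(tree) {
  data.frame(
    diameter = tree_diameter(tree),
    leaf_fraction = leaf_fraction(tree),
    tree_hierarchy = tree_hierarchy(tree),
    betweenness_max = max(node_betweenness(tree)),
    global_fc = global_fc(tree)
  )
}

edge_keys <- function(tree) {
  paste(pmin(tree$edges$a, tree$edges$b), pmax(tree$edges$a, tree$edges$b),
        sep = "|")
}

#' Graph edit distance between labeled trees
#'
#' With a fixed, label-matched node set and unit edge insertion/deletion
#' costs (no node operations, no substitutions), the minimum edit cost is
#' the size of the symmetric difference of the edge sets: each differing
#' edge contributes its deletion plus its replacement's insertion.
#' `count_swaps_once = TRUE` counts a delete+insert swap as a single
#' operation (halving the distance) for sensitivity analysis.
#'
#' @param t1,t2 `"mst_tree"` objects over identical node sets.
#' @param count_swaps_once Logical, default FALSE.
#' @return Nonnegative numeric distance.
#' @export
graph_edit_distance <- function(t1, t2, count_swaps_once = FALSE) {
  if (!setequal(t1$labels, t2$labels)) {
    stop("trees must share the same labeled node set", call. = FALSE)
  }
  e1 <- edge_keys(t1)
  e2 <- edge_keys(t2)
  d <- length(setdiff(e1, e2)) + length(setdiff(e2, e1))
  if (count_swaps_once) d / 2 else d
}

#' Group-averaged network
#'
#' Element-wise arithmetic mean of the subjects' connectivity matrices,
#' then the maximum-weight spanning tree of the average — the
#' group-specific backbone. Averaging before tree construction discards
#' individual variability, so group trees are descriptive; formal edgewise
#' inference should use [nbs()].
#'
#' @param conns List of `"mst_connectivity"` with matched labels and band.
#' @return `"mst_tree"`.
#' @export
group_network <- function(conns) {
  if (!length(conns)) stop("need at least one matrix", call. = FALSE)
  labs <- conns[[1]]$labels
  for (cn in conns) {
    if (!identical(cn$labels, labs)) {
      stop("connectivity matrices must share channel labels", call. = FALSE)
    }
  }
  avg <- Reduce(`+`, lapply(conns, `[[`, "values")) / length(conns)
  mst(connectivity_from_matrix(avg, conns[[1]]$band))
}

#' Summaries of pairwise graph edit distances
#'
#' `within_session`: mean and SD of the edit distance over all unordered
#' pairs of trees (between-subject dissimilarity of one session).
#' `between_sessions`: per-subject paired distance between `trees` and
#' `trees_b` (same subject order), then mean and SD across subjects.
#'
#' @param trees List of `"mst_tree"`.
#' @param mode `"within_session"` or `"between_sessions"`.
#' @param trees_b Second list, required for `between_sessions`, matched by
#'   position to `trees`.
#' @param count_swaps_once Passed to [graph_edit_distance()].
#' @return List with `mean`, `sd`, `n`, `distances`.
#' @export
pairwise_ged_summary <- function(trees,
                                 mode = c("within_session",
                                          "between_sessions"),
                                 trees_b = NULL,
                                 count_swaps_once = FALSE) {
  mode <- match.arg(mode)
  if (mode == "within_session") {
    if (length(trees) < 2) {
      stop("within-session summary needs at least two trees", call. = FALSE)
    }
    pairs <- utils::combn(length(trees), 2)
    d <- apply(pairs, 2, function(p) {
      graph_edit_distance(trees[[p[1]]], trees[[p[2]]], count_swaps_once)
    })
  } else {
    if (is.null(trees_b) || length(trees_b) != length(trees)) {
      stop("between-sessions summary needs trees_b matched to trees",
           call. = FALSE)
    }
    if (length(trees) < 1) stop("need at least one pair", call. = FALSE)
    d <- mapply(function(x, y) graph_edit_distance(x, y, count_swaps_once),
                trees, trees_b)
  }
  list(mean = mean(d), sd = stats::sd(d), n = length(d), distances = d)
}

as_igraph_tree <- function(tree) {
  igraph::graph_from_data_frame(
    tree$edges[, c("a", "b", "weight")],
    directed = FALSE,
    vertices = data.frame(name = tree$labels)
  )
}

#' Serialize a spanning tree
#'
#' Writes `<stem>.edges.tsv` (node_a, node_b, weight) and
#' `<stem>.graphml`.
#'
#' @param tree `"mst_tree"`.
#' @param stem Output path stem.
#' @export
write_tree <- function(tree, stem) {
  utils::write.table(tree$edges, paste0(stem, ".edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  igraph::write_graph(as_igraph_tree(tree), paste0(stem, ".graphml"),
                      format = "graphml")
  invisible(stem)
}

#' @rdname write_tree
#' @param labels Node label set of the serialized tree (isolated nodes
#'   cannot be recovered from the edge list alone; defaults to the nodes
#'   appearing in edges).
#' @export
read_tree <- function(stem, labels = NULL) {
  ed <- utils::read.table(paste0(stem, ".edges.tsv"), header = TRUE,
                          sep = "\t")
  if (is.null(labels)) labels <- unique(c(ed$a, ed$b))
  spanning_tree(labels, ed)
}
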