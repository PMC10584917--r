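#' Network-based statistics for paired connectivity comparisons
#'
#' Edgewise paired t-tests between two matched stacks of connectivity
#' matrices; edges with |t| above the threshold are kept and grouped into
#' connected components. Family-wise error over components is controlled by
#' permutation: subject difference matrices are sign-flipped (the paired
#' exchangeability null), the maximal component statistic is recorded per
#' permutation, and each observed component's p-value is the proportion of
#' null maxima at least as large. With up to 12 subjects all 2^n sign
#' patterns are enumerated (the identity included); otherwise `n_perm`
#' random patterns are drawn under `seed`.
#'
#' @param conns_a,conns_b Either lists of `"mst_connectivity"` or 3-d
#'   arrays (channels x channels x subjects), matched by subject.
#' @param t_threshold Edgewise |t| threshold (default 2).
#' @param n_perm Random permutations when enumeration is infeasible.
#' @param alpha Significance level reported in the result (default 0.05).
#' @param statistic Component statistic: `"extent"` (edge count, default)
#'   or `"intensity"` (sum of |t| over the component's edges).
#' @param seed Integer seed for the random permutations.
#' @return Object of class `"mst_nbs"`: `components` (list of data frames
#'   with columns `a`, `b`, `t`), `p` (per-component FWER p-values),
#'   `t_threshold`, `n_perm` (effective count), `statistic`, `alpha`,
#'   `labels`.
#' @export
nbs <- function(conns_a, conns_b, t_threshold = 2, n_perm = 5000,
                alpha = 0.05, statistic = c("extent", "intensity"),
                seed = NULL) {
  statistic <- match.arg(statistic)
  a <- conn_stack(conns_a)
  b <- conn_stack(conns_b)
  if (!identical(dim(a), dim(b)) ||
      !identical(dimnames(a)[[1]], dimnames(b)[[1]])) {
    stop("the two connectivity stacks must match in channels and subjects",
         call. = FALSE)
  }
  nsub <- dim(a)[3]
  if (nsub < 2) stop("need at least 2 subjects", call. = FALSE)
  if (n_perm < 100) {
    warning("fewer than 100 permutations gives a very coarse p-value")
  }
  labels <- dimnames(a)[[1]]
  nch <- length(labels)
  ut <- which(upper.tri(matrix(0, nch, nch)))
  edge_nodes <- arrayInd(ut, c(nch, nch))
  # subjects x edges matrix of paired differences
  d <- t(apply(a - b, 3, function(m) m[ut]))
  d <- matrix(d, nrow = nsub)

  if (nsub <= 12) {
    bits <- as.matrix(expand.grid(rep(list(c(1, -1)), nsub)))
    signs <- unname(bits)
  } else {
    if (!is.null(seed)) set.seed(seed)
    signs <- matrix(sample(c(1, -1), n_perm * nsub, replace = TRUE),
                    n_perm, nsub)
    signs[1, ] <- 1   # include the identity so p >= 1/n_perm
  }
  nperm_eff <- nrow(signs)

  ssq <- colSums(d^2)
  tmat <- perm_tstats(signs, d, ssq)
  t_obs <- perm_tstats(matrix(1, 1, nsub), d, ssq)[1, ]

  sup_obs <- which(abs(t_obs) > t_threshold)
  comps_idx <- edge_components(sup_obs, edge_nodes, nch)
  comp_stat <- function(edges, tv) {
    if (statistic == "extent") length(edges) else sum(abs(tv[edges]))
  }
  null_max <- apply(tmat, 1, function(tv) {
    sup <- which(abs(tv) > t_threshold)
    if (!length(sup)) return(0)
    cs <- edge_components(sup, edge_nodes, nch)
    max(vapply(cs, comp_stat, numeric(1), tv = tv))
  })
  comps <- lapply(comps_idx, function(edges) {
    data.frame(a = labels[edge_nodes[edges, 1]],
               b = labels[edge_nodes[edges, 2]],
               t = t_obs[edges])
  })
  p <- vapply(comps_idx, function(edges) {
    mean(null_max >= comp_stat(edges, t_obs))
  }, numeric(1))
  structure(
    list(components = comps, p = p, t_threshold = t_threshold,
         n_perm = nperm_eff, statistic = statistic, alpha = alpha,
         labels = labels),
    class = "mst_nbs"
  )
}

#' @export
print.mst_nbs <- function(x, ...) {
  cat("<mst_nbs> ", length(x$components), " suprathreshold component(s), ",
      x$n_perm, " permutations, |t| > ", x$t_threshold, "\n", sep = "")
  for (i in seq_along(x$components)) {
    cat(sprintf("  component %d: %d edge(s), p = %.4g\n", i,
                nrow(x$components[[i]]), x$p[i]))
  }
  invisible(x)
}

conn_stack <- function(x) {
  if (is.array(x) && length(dim(x)) == 3) return(x)
  if (is.list(x) && all(vapply(x, inherits, TRUE, "mst_connectivity"))) {
    labs <- x[[1]]$labels
    arr <- simplify2array(lapply(x, `[[`, "values"))
    dimnames(arr) <- list(labs, labs, NULL)
    return(arr)
  }
  stop("expected a channels x channels x subjects array or a list of ",
       "connectivity matrices", call. = FALSE)
}

# vectorized paired t statistics for all sign-flip patterns at once:
# sign flips leave sum(d^2) untouched, so only the mean varies.
perm_tstats <- function(signs, d, ssq) {
  n <- ncol(signs)
  mu <- (signs %*% d) / n
  v <- sweep(-n * mu^2, 2, ssq, `+`) / (n - 1)
  v[v < 0] <- 0
  tt <- mu / sqrt(v / n)
  tt[is.nan(tt)] <- 0      # zero mean, zero variance
  tt
}

# connected components of a suprathreshold edge set via union-find;
# returns a list of integer vectors of edge indices
edge_components <- function(edge_idx, edge_nodes, nch) {
  if (!length(edge_idx)) return(list())
  parent <- seq_len(nch)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (e in edge_idx) {
    ra <- find(edge_nodes[e, 1])
    rb <- find(edge_nodes[e, 2])
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(edge_nodes[edge_idx, 1], find, integer(1))
  unname(split(edge_idx, roots))
}

#' Wilcoxon signed-rank test for matched samples
#'
#' Two-sided test on paired differences. Zero differences are dropped (the
#' common convention). With 14 or fewer informative pairs the null
#' distribution of the signed-rank statistic is enumerated exactly over all
#' sign assignments using midranks, which stays exact under ties; with no
#' ties and up to 25 pairs the exact signed-rank distribution is used;
#' otherwise the tie-corrected normal approximation applies.
#'
#' @param a,b Matched numeric vectors (per-subject values under the two
#'   conditions).
#' @return List of class `"htest"` with `statistic` (V, sum of positive
#'   ranks), `p.value`, `method`, and `n` (informative pairs).
#' @export
wilcoxon_signed_rank <- function(a, b) {
  if (length(a) != length(b)) {
    stop("paired samples must have equal length", call. = FALSE)
  }
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    stop("degenerate sample: all paired differences are zero",
         call. = FALSE)
  }
  if (n < 2) {
    stop("degenerate sample: fewer than 2 non-zero differences",
         call. = FALSE)
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  mu <- sum(r) / 2
  ties <- anyDuplicated(r) > 0
  if (n <= 14) {
    method <- "exact signed-rank (full sign enumeration, midranks)"
    grid <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    vnull <- as.vector(grid %*% r)
    p <- mean(abs(vnull - mu) >= abs(v - mu) - 1e-9)
  } else if (!ties && n <= 25) {
    method <- "exact signed-rank"
    p <- stats::wilcox.test(d, exact = TRUE)$p.value
  } else {
    method <- "normal approximation with tie correction"
    p <- stats::wilcox.test(d, exact = FALSE, correct = TRUE)$p.value
  }
  structure(
    list(statistic = c(V = v), p.value = min(p, 1), n = n,
         method = paste("Wilcoxon signed-rank test:", method),
         data.name = "paired differences"),
    class = "htest"
  )
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up adjustment of a family of p-values; hypotheses with adjusted
#' p-value at or below `alpha` are rejected. Never rejects more hypotheses
#' than uncorrected testing at the same level.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @param alpha FDR level (default 0.05).
#' @return Data frame with columns `p`, `p_adj`, `reject`.
#' @export
fdr_correct <- function(pvals, alpha = 0.05) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p_adj <- stats::p.adjust(pvals, method = "BH")
  data.frame(p = pvals, p_adj = p_adj, reject = p_adj <= alpha)
}
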