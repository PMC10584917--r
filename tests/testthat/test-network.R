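test_that("maximum-weight tree picks the strongest edges", {
  m <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  m["A", "B"] <- m["B", "A"] <- 0.9
  m["A", "C"] <- m["C", "A"] <- 0.5
  m["B", "C"] <- m["C", "B"] <- 0.8
  tr <- mst(m)
  expect_setequal(paste(tr$edges$a, tr$edges$b), c("A B", "B C"))
  expect_equal(global_fc(tr), 1.7)
})

test_that("an input that is already a tree is returned unchanged", {
  m <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  m["a", "b"] <- m["b", "a"] <- 0.5
  m["b", "c"] <- m["c", "b"] <- 0.4
  m["c", "d"] <- m["d", "c"] <- 0.3
  tr <- mst(m)
  expect_equal(tr$M, 3)
  expect_equal(sort(tr$edges$weight), c(0.3, 0.4, 0.5))
})

test_that("16-channel matrices give 15-edge trees; disconnection errors", {
  set.seed(1)
  m <- matrix(runif(256, 0.01, 1), 16, 16)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dimnames(m) <- list(default_montage()$labels, default_montage()$labels)
  expect_equal(mst(m)$M, 15)
  m2 <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  m2["a", "b"] <- m2["b", "a"] <- 0.5
  m2["c", "d"] <- m2["d", "c"] <- 0.5
  expect_error(mst(m2), "disconnected")
})

test_that("mst matches exhaustive spanning-tree enumeration on 5-node graphs", {
  labs <- letters[1:5]
  for (s in 1:100) {
    set.seed(s)
    m <- matrix(runif(25, 0.05, 1), 5, 5, dimnames = list(labs, labs))
    m <- (m + t(m)) / 2
    diag(m) <- 0
    expect_equal(global_fc(mst(m)), bf_best_tree_weight(m), tolerance = 1e-12)
  }
})

test_that("degrees count incident edges and sum to twice the edge count", {
  labs <- default_montage()$labels
  st <- star_tree(labs)
  k <- node_degree(st)
  expect_equal(unname(k[1]), 15)
  expect_true(all(k[-1] == 1))
  pt <- path_tree(labs)
  kp <- node_degree(pt)
  expect_equal(unname(kp[c(1, 16)]), c(1, 1))
  expect_true(all(kp[2:15] == 2))
  for (s in 1:5) {
    tr <- random_tree(sample(3:12, 1), s)
    expect_equal(sum(node_degree(tr)), 2 * tr$M)
  }
})

test_that("betweenness is exact on canonical topologies", {
  labs <- default_montage()$labels
  cb <- node_betweenness(star_tree(labs))
  expect_equal(unname(cb[1]), 1)
  expect_true(all(cb[-1] == 0))
  p4 <- path_tree(c("a", "b", "c", "d"))
  expect_equal(unname(node_betweenness(p4)["b"]), 2 / 3)
  p16 <- path_tree(labs)
  expect_equal(max(node_betweenness(p16)), 112 / 210)
  expect_error(node_betweenness(path_tree(c("a", "b"))), "fewer than 3")
})

test_that("betweenness agrees with the path-enumeration oracle on random trees", {
  for (s in 1:12) {
    tr <- random_tree(sample(3:8, 1), 100 + s)
    expect_equal(node_betweenness(tr), bf_betweenness(tr),
                 tolerance = 1e-12)
  }
})

test_that("diameter and leaf fraction follow their definitions", {
  labs <- default_montage()$labels
  expect_equal(tree_diameter(path_tree(labs)), 1)
  expect_equal(tree_diameter(star_tree(labs)), 2 / 15)
  expect_equal(tree_diameter(path_tree(c("a", "b", "c"))), 1)
  expect_equal(leaf_fraction(star_tree(labs)), 1)
  expect_equal(leaf_fraction(path_tree(labs)), 2 / 15)
  expect_equal(leaf_fraction(path_tree(c("a", "b", "c"))), 1)
})

test_that("tree hierarchy separates star and line topologies", {
  labs <- default_montage()$labels
  expect_equal(tree_hierarchy(star_tree(labs)), 0.5)
  expect_equal(tree_hierarchy(star_tree(letters[1:5])), 0.5)
  expect_equal(tree_hierarchy(path_tree(labs)), 0.125)
  th <- vapply(c(4, 8, 16, 64),
               function(n) tree_hierarchy(path_tree(sprintf("n%03d", 1:n))),
               numeric(1))
  expect_true(all(diff(th) < 0))
  # 0.5 marks the star, not a universal ceiling: a double star (two hubs
  # splitting the leaves) exceeds it because no single node carries all
  # paths while the leaf count stays maximal
  labs10 <- sprintf("d%02d", 1:10)
  dbl <- spanning_tree(labs10, data.frame(
    a = c("d01", rep("d01", 4), rep("d02", 4)),
    b = c("d02", labs10[3:6], labs10[7:10]),
    weight = 1
  ))
  expect_gt(tree_hierarchy(dbl), 0.5)
  # positive and bounded by 1 on arbitrary random trees
  for (s in 1:20) {
    tr <- random_tree(sample(3:16, 1), 200 + s)
    expect_gt(tree_hierarchy(tr), 0)
    expect_lte(tree_hierarchy(tr), 1)
  }
})

test_that("global FC sums tree weights linearly", {
  tr <- spanning_tree(c("a", "b", "c"),
                      data.frame(a = c("a", "b"), b = c("b", "c"),
                                 weight = c(0.5, 0.3)))
  expect_equal(global_fc(tr), 0.8)
  tr2 <- tr
  tr2$edges$weight <- tr$edges$weight * 0.5
  expect_equal(global_fc(tr2), 0.4)
})

test_that("graph edit distance is the edge symmetric difference", {
  labs <- letters[1:4]
  p <- path_tree(labs)                       # a-b-c-d
  expect_equal(graph_edit_distance(p, p), 0)
  q <- spanning_tree(labs, data.frame(a = c("a", "b", "b"),
                                      b = c("b", "c", "d"), weight = 1))
  expect_equal(graph_edit_distance(p, q), 2)
  expect_equal(graph_edit_distance(p, q, count_swaps_once = TRUE), 1)
  # disjoint edge sets: a path in consecutive order vs a stride-2 reorder
  labs16 <- default_montage()$labels
  p1 <- path_tree(labs16)
  p2 <- path_tree(labs16[c(seq(1, 15, by = 2), seq(2, 16, by = 2))])
  expect_equal(graph_edit_distance(p1, p2), 30)
  expect_error(graph_edit_distance(p, path_tree(letters[5:8])), "node set")
})

test_that("graph edit distance satisfies the metric axioms on random trees", {
  for (s in 1:30) {
    t1 <- random_tree(8, 300 + s)
    t2 <- random_tree(8, 400 + s)
    t3 <- random_tree(8, 500 + s)
    expect_equal(graph_edit_distance(t1, t1), 0)
    expect_equal(graph_edit_distance(t1, t2), graph_edit_distance(t2, t1))
    expect_lte(graph_edit_distance(t1, t3),
               graph_edit_distance(t1, t2) + graph_edit_distance(t2, t3))
  }
})

test_that("group networks average matrices before tree construction", {
  set.seed(9)
  labs <- letters[1:5]
  mk <- function() {
    m <- matrix(runif(25, 0.05, 1), 5, 5, dimnames = list(labs, labs))
    m <- (m + t(m)) / 2
    diag(m) <- 0
    connectivity_from_matrix(m)
  }
  c1 <- mk()
  expect_equal(group_network(list(c1))$edges, mst(c1)$edges)
  expect_equal(group_network(list(c1, c1, c1))$edges, mst(c1)$edges)
  c2 <- mk()
  avg <- (c1$values + c2$values) / 2
  gt <- group_network(list(c1, c2))
  expect_equal(global_fc(gt), bf_best_tree_weight(avg), tolerance = 1e-12)
})

test_that("pairwise edit-distance summaries cover both comparison designs", {
  labs <- letters[1:4]
  p <- path_tree(labs)
  q <- spanning_tree(labs, data.frame(a = c("a", "b", "b"),
                                      b = c("b", "c", "d"), weight = 1))
  same <- pairwise_ged_summary(list(p, p, p), "within_session")
  expect_equal(same$mean, 0)
  expect_equal(same$sd, 0)
  bs <- pairwise_ged_summary(list(p, p), "between_sessions",
                             trees_b = list(q, q))
  expect_equal(bs$mean, 2)
  # within-session invariance to ordering
  w1 <- pairwise_ged_summary(list(p, q, p), "within_session")
  w2 <- pairwise_ged_summary(list(q, p, p), "within_session")
  expect_equal(sort(w1$distances), sort(w2$distances))
  expect_error(pairwise_ged_summary(list(p), "within_session"), "two trees")
})

test_that("trees serialize to edge lists and GraphML and round-trip", {
  tr <- random_tree(8, 77)
  stem <- tempfile()
  write_tree(tr, stem)
  expect_true(file.exists(paste0(stem, ".graphml")))
  tr2 <- read_tree(stem, labels = tr$labels)
  expect_equal(graph_edit_distance(tr, tr2), 0)
  expect_equal(sort(tr2$edges$weight), sort(tr$edges$weight))
})
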