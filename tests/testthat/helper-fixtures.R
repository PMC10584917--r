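# Shared fixtures: all built in code at test time.

two_channel_montage <- function(labels = c("C3", "C4")) {
  montage_spec(labels, stats::setNames(rep("parietal", 2), labels))
}

# Two-channel epoch set of sinusoids with a constant phase lag, built
# directly (independently of the cohort generator).
lagged_epochs <- function(n_epochs, freq = 10, lag = pi / 4, fs = 128,
                          dur = 2, noise_sd = 0, strength = 1,
                          common_gain = 0, seed = 1) {
  set.seed(seed)
  n <- fs * dur
  tt <- (0:(n - 1)) / fs
  dat <- array(0, c(n_epochs, 2, n))
  for (e in seq_len(n_epochs)) {
    th <- stats::runif(1, 0, 2 * pi)
    th2 <- stats::runif(1, 0, 2 * pi)
    x <- sin(2 * pi * freq * tt + th)
    y <- strength * sin(2 * pi * freq * tt + th - lag) +
      (1 - strength) * sin(2 * pi * freq * tt + th2)
    if (common_gain > 0) {
      thc <- stats::runif(1, 0, 2 * pi)
      src <- common_gain * sin(2 * pi * freq * tt + thc)
      x <- x + src
      y <- y + src
    }
    if (noise_sd > 0) {
      x <- x + stats::rnorm(n, 0, noise_sd)
      y <- y + stats::rnorm(n, 0, noise_sd)
    }
    dat[e, 1, ] <- x
    dat[e, 2, ] <- y
  }
  epoch_set(dat, fs, c("C3", "C4"), rep("left", n_epochs))
}

# analytic-signal instantaneous phase via FFT (positive frequencies doubled)
analytic_phase <- function(x) {
  n <- length(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  Arg(stats::fft(stats::fft(x) * h, inverse = TRUE) / n)
}

star_tree <- function(labels, weight = 1) {
  spanning_tree(labels, data.frame(a = labels[1], b = labels[-1],
                                   weight = weight))
}

path_tree <- function(labels, weight = 1) {
  n <- length(labels)
  spanning_tree(labels, data.frame(a = labels[-n], b = labels[-1],
                                   weight = weight))
}

# random labeled tree by uniform random attachment
random_tree <- function(n, seed) {
  set.seed(seed)
  labels <- sprintf("n%02d", seq_len(n))
  a <- labels[vapply(2:n, function(i) sample.int(i - 1, 1), integer(1))]
  spanning_tree(labels, data.frame(a = a, b = labels[-1],
                                   weight = stats::runif(n - 1, 0.1, 1)))
}

# brute-force betweenness oracle: enumerate the unique path of every
# ordered pair and count pass-throughs
bf_betweenness <- function(tree) {
  g <- igraph::graph_from_data_frame(tree$edges[, c("a", "b")],
                                     directed = FALSE,
                                     vertices = tree$labels)
  n <- tree$N
  counts <- stats::setNames(numeric(n), tree$labels)
  for (h in seq_len(n)) {
    for (j in seq_len(n)) {
      if (h == j) next
      p <- igraph::shortest_paths(g, from = tree$labels[h],
                                  to = tree$labels[j])$vpath[[1]]
      inner <- setdiff(names(p), tree$labels[c(h, j)])
      counts[inner] <- counts[inner] + 1
    }
  }
  counts / ((n - 1) * (n - 2))
}

# exhaustive maximum-weight spanning tree total weight by enumerating all
# (n-1)-edge subsets of the complete graph
bf_best_tree_weight <- function(m) {
  labels <- rownames(m)
  n <- nrow(m)
  ut <- which(upper.tri(m), arr.ind = TRUE)
  best <- -Inf
  for (comb in utils::combn(nrow(ut), n - 1, simplify = FALSE)) {
    sel <- ut[comb, , drop = FALSE]
    w <- m[sel]
    if (any(w <= 0)) next
    g <- igraph::graph_from_data_frame(
      data.frame(a = labels[sel[, 1]], b = labels[sel[, 2]]),
      directed = FALSE, vertices = labels
    )
    if (igraph::is_connected(g)) best <- max(best, sum(w))
  }
  best
}

# symmetric null connectivity stacks for NBS simulations: per-subject
# baseline plus independent condition noise, so paired differences are
# exchangeable under sign flips
null_conn_stack <- function(n_sub = 10, nch = 16, sd = 0.05) {
  labs <- sprintf("ch%02d", seq_len(nch))
  mk <- function(base) {
    m <- base + matrix(stats::rnorm(nch * nch, 0, sd), nch, nch)
    m <- (m + t(m)) / 2
    diag(m) <- 0
    m
  }
  a <- array(0, c(nch, nch, n_sub), dimnames = list(labs, labs, NULL))
  b <- a
  for (s in seq_len(n_sub)) {
    base <- matrix(stats::runif(nch * nch, 0.1, 0.5), nch, nch)
    base <- (base + t(base)) / 2
    a[, , s] <- mk(base)
    b[, , s] <- mk(base)
  }
  list(a = a, b = b)
}
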