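# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's vectorized code paths: naive double loops over
# contingency cells, exhaustive enumeration over partitions and boundary
# subsets.

# plug-in mutual information (bits) by naive double loop over a count table
naive_mi <- function(tab) {
  n <- sum(tab)
  px <- rowSums(tab) / n
  py <- colSums(tab) / n
  out <- 0
  for (a in seq_len(nrow(tab))) {
    for (b in seq_len(ncol(tab))) {
      p <- tab[a, b] / n
      if (p > 0) out <- out + p * log2(p / (px[a] * py[b]))
    }
  }
  as.numeric(out)
}

# joint entropy (bits) by naive double loop
naive_h <- function(tab) {
  n <- sum(tab)
  out <- 0
  for (a in seq_len(nrow(tab))) {
    for (b in seq_len(ncol(tab))) {
      p <- tab[a, b] / n
      if (p > 0) out <- out - p * log2(p)
    }
  }
  as.numeric(out)
}

# expand a count table into two aligned code vectors
codes_from_table <- function(tab) {
  x <- integer(0); y <- integer(0)
  for (a in seq_len(nrow(tab))) {
    for (b in seq_len(ncol(tab))) {
      k <- tab[a, b]
      x <- c(x, rep(a, k)); y <- c(y, rep(b, k))
    }
  }
  list(x = x, y = y)
}

# all partitions of 1..n into exactly k non-empty blocks (restricted growth)
set_partitions <- function(n, k) {
  out <- list()
  rec <- function(i, assign, used) {
    if (i > n) {
      if (used == k) out[[length(out) + 1L]] <<- assign
      return(invisible())
    }
    for (b in seq_len(min(used + 1L, k))) {
      rec(i + 1L, c(assign, b), max(used, b))
    }
  }
  rec(1L, integer(0), 0L)
  out
}

# SR of a partition: per block, the maximal multiple redundancy
partition_sr <- function(R, assign) {
  sum(vapply(unique(assign), function(b) {
    members <- which(assign == b)
    max(vapply(members, function(i)
      sum(R[i, setdiff(members, i)]), numeric(1)))
  }, numeric(1)))
}

# exhaustive class-dependent discretization: try every subset of candidate
# midpoints of size 1..(max_intervals-1), scoring R = I/H by the naive
# oracles on the resulting interval x class table
exhaustive_ocdd_r <- function(values, class_codes, max_intervals) {
  v <- sort(unique(values))
  mids <- (v[-length(v)] + v[-1]) / 2
  best <- 0
  for (q in 2:max_intervals) {
    nb <- q - 1L
    if (nb > length(mids)) break
    sets <- utils::combn(length(mids), nb)
    for (j in seq_len(ncol(sets))) {
      cuts <- mids[sets[, j]]
      codes <- findInterval(values, cuts) + 1L
      tab <- table(codes, class_codes)
      h <- naive_h(tab)
      r <- if (h > 0) naive_mi(tab) / h else 0
      if (r > best) best <- r
    }
  }
  best
}

# small mixed-mode fixture with planted dependence between x1 and x2
toy_table <- function(n = 60, seed = 42) {
  set.seed(seed)
  x1 <- stats::runif(n)
  x2 <- x1 + stats::rnorm(n, sd = 0.05)
  x3 <- stats::runif(n)
  cat1 <- ifelse(x1 > 0.5, "hi", "lo")
  mixed_mode_table(data.frame(x1 = x1, x2 = x2, x3 = x3, cat1 = cat1,
                              stringsAsFactors = FALSE))
}

# block-structured redundancy matrix: perfect within-block, zero across
block_R <- function(sizes) {
  N <- sum(sizes)
  R <- matrix(0, N, N)
  start <- 1L
  for (s in sizes) {
    idx <- start:(start + s - 1L)
    R[idx, idx] <- 1
    start <- start + s
  }
  diag(R) <- 1
  rownames(R) <- colnames(R) <- paste0("G", seq_len(N))
  R
}
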