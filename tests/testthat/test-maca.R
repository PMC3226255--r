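test_that("k = 1 needs no assignment and picks the globally best mode", {
  set.seed(3)
  M <- matrix(stats::runif(36, 0, 0.5), 6, 6)
  R <- (M + t(M)) / 2; diag(R) <- 1
  rownames(R) <- colnames(R) <- paste0("G", 1:6)
  cl <- kmodes_cluster(R, 1, seed = 1)
  expect_equal(cl$k, 1L)
  expect_equal(sort(cl$clusters[[1]]), 1:6)
  mr_all <- sapply(1:6, function(i) sum(R[i, -i]))
  expect_equal(cl$modes, which.max(mr_all))
  expect_equal(cl$sr, max(mr_all))
})

test_that("perfect block structure is recovered exactly at k = 2", {
  R <- block_R(c(3, 4))
  cl <- kmodes_cluster(R, 2, seed = 5)
  parts <- lapply(cl$clusters, sort)
  expect_true(any(vapply(parts, identical, logical(1), 1:3)))
  expect_true(any(vapply(parts, identical, logical(1), 4:7)))
  # ties on MR within a block resolve to the lowest attribute index
  expect_setequal(cl$modes, c(1L, 4L))
})

test_that("k-modes with restarts attains the exhaustive-partition SR optimum", {
  set.seed(17)
  for (rep in 1:4) {
    N <- sample(5:7, 1)
    M <- matrix(stats::runif(N * N, 0, 0.6), N, N)
    R <- (M + t(M)) / 2; diag(R) <- 1
    rownames(R) <- colnames(R) <- paste0("G", seq_len(N))
    for (k in 2:3) {
      best_oracle <- max(vapply(set_partitions(N, k), function(a)
        partition_sr(R, a), numeric(1)))
      found <- max(vapply(1:30, function(s)
        kmodes_cluster(R, k, seed = s)$sr, numeric(1)))
      expect_equal(found, best_oracle, tolerance = 1e-10)
    }
  }
})

test_that("returned SR dominates every iterate of the run", {
  set.seed(23)
  M <- matrix(stats::runif(100, 0, 0.5), 10, 10)
  R <- (M + t(M)) / 2; diag(R) <- 1
  for (s in 1:5) {
    cl <- kmodes_cluster(R, 3, seed = s)
    expect_true(all(cl$sr >= cl$sr_trace - 1e-12))
  }
})

test_that("clustering invariants hold: disjoint, exhaustive, mode maximal", {
  set.seed(29)
  M <- matrix(stats::runif(81, 0, 0.7), 9, 9)
  R <- (M + t(M)) / 2; diag(R) <- 1
  cl <- kmodes_cluster(R, 3, seed = 2)
  all_members <- sort(unlist(cl$clusters))
  expect_equal(all_members, 1:9)             # disjoint and exhaustive
  for (r in seq_len(cl$k)) {
    members <- cl$clusters[[r]]
    expect_true(cl$modes[r] %in% members)
    mr <- vapply(members, function(i) multiple_redundancy(R, i, members),
                 numeric(1))
    expect_equal(multiple_redundancy(R, cl$modes[r], members), max(mr))
  }
  expect_equal(cl$sr, sum(cl$per_cluster_mr))
})

test_that("SR model selection finds the planted number of blocks", {
  R <- block_R(c(3, 3, 4))
  cl <- select_k(R, 2, 5, restarts = 10, seed = 1)
  expect_equal(cl$k, 3L)
  parts <- lapply(cl$clusters, sort)
  expect_true(any(vapply(parts, identical, logical(1), 1:3)))
  expect_true(any(vapply(parts, identical, logical(1), 4:6)))
  expect_true(any(vapply(parts, identical, logical(1), 7:10)))
  # oracle: no 3-block partition beats the planted one
  oracle <- max(vapply(set_partitions(10, 3), function(a)
    partition_sr(R, a), numeric(1)))
  expect_equal(cl$sr, oracle, tolerance = 1e-10)
})

test_that("SR ties between k resolve toward the smaller k", {
  R <- diag(2); rownames(R) <- colnames(R) <- c("a", "b")  # R(1,2) = 0
  cl <- select_k(R, 1, 2, restarts = 3, seed = 1)
  expect_equal(cl$k, 1L)
  expect_equal(cl$sr, 0)
})

test_that("attribute order only relabels the partition", {
  set.seed(41)
  M <- matrix(stats::runif(64, 0, 0.6), 8, 8)
  R <- (M + t(M)) / 2; diag(R) <- 1
  rownames(R) <- colnames(R) <- paste0("G", 1:8)
  perm <- sample(8)
  Rp <- R[perm, perm]
  best <- max(vapply(1:20, function(s) kmodes_cluster(R, 2, seed = s)$sr,
                     numeric(1)))
  best_p <- max(vapply(1:20, function(s) kmodes_cluster(Rp, 2, seed = s)$sr,
                       numeric(1)))
  expect_equal(best, best_p, tolerance = 1e-10)
})
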