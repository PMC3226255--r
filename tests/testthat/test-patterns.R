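test_that("adjusted residual handles null, boundary and degenerate cases", {
  # o = e exactly
  expect_equal(adjusted_residual(50, c(0.5, 0.5), 200), 0)
  # degenerate: an always-true event has zero variance
  d <- adjusted_residual(100, c(1, 1), 100)
  expect_equal(as.numeric(d), 0)
  expect_true(isTRUE(attr(d, "degenerate")))
  expect_error(adjusted_residual(10, c(0.5, 0), 20), "probabilities")
  expect_error(adjusted_residual(30, c(0.5, 0.5), 20), "exceeds")
})

test_that("order-2 residuals equal the classical two-way adjusted residuals", {
  set.seed(101)
  tables <- c(
    list(matrix(c(40, 10, 10, 40), 2, 2)),
    replicate(12, {
      nr <- sample(2:4, 1); nc <- sample(2:4, 1)
      matrix(rpois(nr * nc, 8) + 1, nr, nc)
    }, simplify = FALSE))
  for (tab in tables) {
    n <- sum(tab)
    std <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))$stdres
    for (a in seq_len(nrow(tab))) {
      for (b in seq_len(ncol(tab))) {
        d <- adjusted_residual(tab[a, b],
                               c(rowSums(tab)[a] / n, colSums(tab)[b] / n),
                               n)
        expect_equal(as.numeric(d), std[a, b], tolerance = 1e-10)
      }
    }
  }
})

test_that("a planted deterministic pair dominates the order-2 patterns", {
  set.seed(7)
  n <- 400
  a <- sample(c("p", "q"), n, replace = TRUE)
  b <- a                                    # forced label equality
  cc <- sample(c("u", "v"), n, replace = TRUE)
  ev <- data.frame(a = a, b = ifelse(b == "p", "P", "Q"), cc = cc,
                   stringsAsFactors = FALSE)
  pats <- discover_patterns(ev, max_order = 2)
  expect_gt(nrow(pats), 0)
  top <- pats$events[[1]]
  expect_setequal(names(top), c("a", "b"))
  expect_true(all(abs(pats$residual) <= abs(pats$residual[1])))
})

test_that("type-I error of the significance screen is near nominal", {
  set.seed(211)
  n <- 400
  n_sig <- 0; n_eval <- 0
  for (rep in 1:200) {
    ev <- data.frame(
      a = sample(c("x", "y", "z"), n, replace = TRUE),
      b = sample(c("x", "y", "z"), n, replace = TRUE),
      stringsAsFactors = FALSE)
    pats <- discover_patterns(ev, max_order = 2, d_threshold = 1.96)
    n_sig <- n_sig + nrow(pats)
    n_eval <- n_eval + length(unique(ev$a)) * length(unique(ev$b))
  }
  rate <- n_sig / n_eval
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.08)
})

test_that("support is anti-monotone and sorting is by |d| then events", {
  set.seed(303)
  n <- 500
  a <- sample(c("x", "y"), n, replace = TRUE)
  b <- ifelse(stats::runif(n) < 0.8, a, sample(c("x", "y"), n, replace = TRUE))
  cc <- ifelse(stats::runif(n) < 0.8, a, sample(c("x", "y"), n, replace = TRUE))
  ev <- data.frame(a = a, b = b, cc = cc, stringsAsFactors = FALSE)
  pats <- discover_patterns(ev, max_order = 3)
  expect_true(all(diff(abs(pats$residual)) <= 1e-12))
  # every order-3 pattern's count is bounded by any order-2 sub-pattern's
  key2 <- list()
  for (i in which(pats$order == 2))
    key2[[paste(sort(paste0(names(pats$events[[i]]), "=", pats$events[[i]])),
                collapse = "|")]] <- pats$observed[i]
  for (i in which(pats$order == 3)) {
    ev3 <- pats$events[[i]]
    for (drop in seq_along(ev3)) {
      sub <- ev3[-drop]
      k <- paste(sort(paste0(names(sub), "=", sub)), collapse = "|")
      if (!is.null(key2[[k]])) expect_lte(pats$observed[i], key2[[k]])
    }
  }
})

test_that("duplicate patterns across clusters merge keeping the best residual", {
  p1 <- data.frame(event_string = "a=x & b=y", order = 2L, observed = 30L,
                   expected = 10, residual = 3.1, sign = 1L,
                   source_cluster = 1L, stringsAsFactors = FALSE)
  p1$events <- list(c(a = "x", b = "y"))
  p2 <- p1; p2$residual <- 2.4; p2$source_cluster <- 2L
  p3 <- p1; p3$event_string <- "a=x & c=z"; p3$events <- list(c(a = "x", c = "z"))
  p3$residual <- 2.0; p3$source_cluster <- 2L

  merged <- merge_patterns(list(p1, rbind(p2, p3)))
  expect_equal(nrow(merged), 2L)
  dup <- merged[merged$event_string == "a=x & b=y", ]
  expect_equal(dup$residual, 3.1)
  expect_equal(dup$provenance[[1]], c(1L, 2L))
  expect_true("a=x & c=z" %in% merged$event_string)

  # disjoint sets concatenate unchanged
  merged2 <- merge_patterns(list(p1, p3))
  expect_equal(nrow(merged2), 2L)
})

test_that("independent attributes yield no patterns; dependence yields them", {
  set.seed(99)
  n <- 600
  dep_a <- sample(c("x", "y"), n, replace = TRUE)
  ev <- data.frame(a = dep_a, b = dep_a, stringsAsFactors = FALSE)
  expect_gt(nrow(discover_patterns(ev, max_order = 2)), 0)
})
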