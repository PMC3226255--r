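test_that("interval schemes cover the line totally and disjointly", {
  sch <- interval_scheme("g", c(0.3, 0.6), c("L", "N", "H"))
  x <- c(-1, 0, 0.29999, 0.3, 0.5, 0.6, 0.9, 10)
  labs <- apply_scheme(sch, x)
  expect_equal(labs, c("L", "L", "L", "N", "N", "H", "H", "H"))
  codes <- apply_scheme(sch, x, codes = TRUE)
  expect_equal(as.integer(codes), c(1L, 1L, 1L, 2L, 2L, 3L, 3L, 3L))
  expect_error(interval_scheme("g", c(0.5, 0.4), c("a", "b", "c")),
               "increasing")
  expect_error(interval_scheme("g", 0.5, c("a", "b", "c")), "one label")
})

test_that("mode discretization is the equal-frequency tertile partition", {
  sch <- discretize_mode(1:9, 3)
  expect_equal(sch$labels, c("L", "N", "H"))
  expect_equal(sch$cuts, c(3.5, 6.5))
  expect_equal(as.vector(table(apply_scheme(sch, 1:9))), c(3L, 3L, 3L))

  set.seed(8)
  u <- stats::runif(1800)
  sch_u <- discretize_mode(u, 3)
  p <- table(apply_scheme(sch_u, u)) / 1800
  expect_equal(-sum(p * log2(p)), log2(3), tolerance = 1e-3)

  expect_error(discretize_mode(rep(1, 10), 3), "distinct")
})

test_that("ties at a tertile boundary collapse into the lower interval", {
  x <- c(rep(1, 5), 2, 3, 4, 5)         # tie spanning the first tertile
  sch <- discretize_mode(x, 3)
  labs <- apply_scheme(sch, x)
  expect_equal(length(unique(labs[x == 1])), 1L)
  expect_equal(unique(labs[x == 1]), "L")
})

test_that("class-separable values get a single cut with R = 1", {
  values <- 1:10
  cls <- ifelse(values < 5, 1L, 2L)
  sch <- ocdd(values, cls, max_intervals = 3)
  expect_equal(length(sch$cuts), 1L)
  expect_gte(sch$cuts, 4)
  expect_lte(sch$cuts, 5)
  expect_equal(attr(sch, "r"), 1, tolerance = 1e-12)
})

test_that("the boundary search equals exhaustive enumeration on small inputs", {
  set.seed(19)
  for (rep in 1:8) {
    nd <- sample(6:12, 1)
    vals <- sample(sort(stats::runif(nd)), 40, replace = TRUE)
    cls <- sample(1:3, 40, replace = TRUE)
    # half the cases: class correlated with value
    if (rep %% 2 == 0) cls <- findInterval(vals, c(0.3, 0.7)) + 1L
    for (mi in 2:3) {
      sch <- ocdd(vals, cls, max_intervals = mi)
      expect_equal(attr(sch, "r"), exhaustive_ocdd_r(vals, cls, mi),
                   tolerance = 1e-10)
    }
  }
})

test_that("permuted class labels give no spuriously strong discretization", {
  set.seed(37)
  vals <- stats::runif(300)
  cls <- sample(rep(1:3, each = 100))      # independent of vals
  r_obs <- attr(ocdd(vals, cls, max_intervals = 3), "r")
  null_r <- replicate(100, {
    attr(ocdd(vals, sample(cls), max_intervals = 3), "r")
  })
  expect_lt(r_obs, quantile(null_r, 0.95) + 0.02)
})

test_that("degenerate inputs pass through as a single interval", {
  sch <- ocdd(rep(2.5, 20), rep(1:2, 10))
  expect_equal(length(sch$cuts), 0L)
  expect_equal(sch$labels, "I1")
})

test_that("tau gates fuzzy cluster membership for event tables", {
  tab <- toy_table(n = 120, seed = 55)
  R <- redundancy_matrix(tab)
  cl <- kmodes_cluster(R, 2, seed = 3)
  mu <- fuzzy_memberships(R, cl, f = 1.5)

  full <- build_cluster_event_tables(tab, cl, mu, tau = 0)
  for (et in full)
    expect_equal(length(et$member_attributes), n_attributes(tab))

  # just above the largest cross-membership the tables reduce to the
  # crisp clusters exactly
  crisp_tau <- max(apply(mu$mu, 1, function(r) sort(r, decreasing = TRUE)[2])) +
    1e-6
  crisp <- build_cluster_event_tables(tab, cl, mu, tau = crisp_tau)
  for (r in seq_along(crisp))
    expect_setequal(crisp[[r]]$member_attributes, cl$clusters[[r]])

  expect_error(build_cluster_event_tables(tab, cl, mu, tau = 1.1),
               "mode")
})

test_that("event tables are complete: every sample, one label per member", {
  tab <- toy_table(n = 120, seed = 56)
  R <- redundancy_matrix(tab)
  cl <- kmodes_cluster(R, 2, seed = 3)
  mu <- fuzzy_memberships(R, cl, f = 1.5)
  ets <- build_cluster_event_tables(tab, cl, mu, tau = 0.003)
  for (et in ets) {
    expect_equal(nrow(et$events), n_samples(tab))
    expect_false(anyNA(et$events))
    mode_name <- tab$attribute_names[et$mode]
    if (tab$attribute_kinds[[et$mode]] == "continuous")
      expect_setequal(unique(et$events[[mode_name]]), c("L", "N", "H"))
    # continuous members all carry a scheme; labels map 1:1 through it
    for (nmm in names(et$schemes)) {
      sch <- et$schemes[[nmm]]
      expect_equal(apply_scheme(sch, tab$values[[nmm]]), et$events[[nmm]])
    }
  }
})
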