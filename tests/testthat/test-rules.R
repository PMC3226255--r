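toy_events_labels <- function(n = 100, seed = 71, p_match = 0.85) {
  set.seed(seed)
  cls <- rep(c("c1", "c2"), each = n / 2)
  g1 <- ifelse(stats::runif(n) < p_match, ifelse(cls == "c1", "L", "H"),
               sample(c("L", "H"), n, replace = TRUE))
  g2 <- ifelse(stats::runif(n) < p_match, ifelse(cls == "c1", "X", "Y"),
               sample(c("X", "Y"), n, replace = TRUE))
  list(events = data.frame(g1 = g1, g2 = g2, stringsAsFactors = FALSE),
       labels = cls)
}

test_that("weight of evidence is zero without evidence, exact when exclusive", {
  ev <- data.frame(g = rep(c("a", "b"), each = 50), stringsAsFactors = FALSE)
  cls <- rep(c("c1", "c2"), times = 50)      # class independent of g
  expect_equal(weight_of_evidence(c(g = "a"), "c1", ev, cls), 0)

  # antecedent in 10 of 50 class-c samples, 0 of 50 others
  ev2 <- data.frame(g = c(rep("a", 10), rep("b", 40), rep("b", 50)),
                    stringsAsFactors = FALSE)
  cls2 <- rep(c("c", "d"), each = 50)
  expect_equal(weight_of_evidence(c(g = "a"), "c", ev2, cls2),
               log2((11 / 52) / (1 / 52)), tolerance = 1e-12)
  expect_error(weight_of_evidence(c(g = "a"), "zz", ev2, cls2), "absent")
})

test_that("two-class weights of evidence are antisymmetric unsmoothed", {
  x <- toy_events_labels()
  for (lab in c("L", "H")) {
    w1 <- weight_of_evidence(c(g1 = lab), "c1", x$events, x$labels,
                             smooth = FALSE)
    w2 <- weight_of_evidence(c(g1 = lab), "c2", x$events, x$labels,
                             smooth = FALSE)
    expect_equal(w1, -w2, tolerance = 1e-12)
  }
})

test_that("mined rules are class-discriminative with sensible confidences", {
  x <- toy_events_labels()
  rules <- mine_rules(x$events, x$labels, max_order = 3L)
  expect_gt(nrow(rules), 0)
  expect_true(all(rules$confidence >= 0 & rules$confidence <= 1))
  expect_true(all(rules$support >= 1))
  expect_true(all(is.finite(rules$wofe)))
  top <- rules[1, ]
  expect_gt(top$confidence, 0.7)
})

test_that("classification follows the summed evidence and its tie rules", {
  rules <- data.frame(
    antecedent_string = c("g1=L", "g2=X"),
    consequent = c("c1", "c2"),
    order = c(2L, 2L), wofe = c(3.0, 1.0),
    support = c(10L, 10L), confidence = c(0.9, 0.8),
    residual = c(3, 2), source_cluster = c(1L, 1L),
    stringsAsFactors = FALSE)
  rules$antecedent <- list(c(g1 = "L"), c(g2 = "X"))
  priors <- c(c1 = 0.5, c2 = 0.5)

  res <- classify_sample(c(g1 = "L", g2 = "Y"), rules, priors)
  expect_equal(res$class, "c1")
  expect_false(res$no_match)

  both <- classify_sample(c(g1 = "L", g2 = "X"), rules, priors)
  expect_equal(both$class, "c1")            # 3.0 beats 1.0
  expect_equal(unname(both$evidence[c("c1", "c2")]), c(3, 1))

  none <- classify_sample(c(g1 = "H", g2 = "Y"), rules,
                          c(c1 = 0.3, c2 = 0.7))
  expect_true(none$no_match)
  expect_equal(none$class, "c2")            # majority fallback

  # a zero-weight rule never changes the outcome
  zero <- rules[1, ]; zero$wofe <- 0; zero$consequent <- "c2"
  zero$antecedent <- list(c(g1 = "L"))
  res2 <- classify_sample(c(g1 = "L", g2 = "X"), rbind(rules, zero), priors)
  expect_equal(res2$class, both$class)
  expect_equal(res2$evidence, both$evidence)
})

test_that("nested antecedents are not double-counted per class", {
  rules <- data.frame(
    antecedent_string = c("g1=L & g2=X", "g1=L"),
    consequent = c("c1", "c1"),
    order = c(3L, 2L), wofe = c(2.0, 1.5),
    support = c(5L, 10L), confidence = c(0.9, 0.8),
    residual = c(3, 2.5), source_cluster = c(1L, 1L),
    stringsAsFactors = FALSE)
  rules$antecedent <- list(c(g1 = "L", g2 = "X"), c(g1 = "L"))
  res <- classify_sample(c(g1 = "L", g2 = "X"), rules,
                         c(c1 = 0.5, c2 = 0.5))
  # only the higher-order rule counts: 2.0, not 3.5
  expect_equal(unname(res$evidence["c1"]), 2.0)
})

test_that("leave-one-out classification beats the majority baseline", {
  x <- toy_events_labels(n = 60, seed = 73, p_match = 0.9)
  res <- classify_loo(x$events, x$labels, max_order = 3L)
  expect_gt(res$accuracy, res$majority_baseline + 0.2)
})
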