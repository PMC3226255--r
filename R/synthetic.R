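#' Configuration for the benchmark mixed-mode generator
#'
#' @param class_sizes five class sizes (defaults 500, 300, 300, 400, 300).
#' @param noise_fraction fraction of tuples whose attribute values are
#'   replaced by fully random draws (default 0.25).
#' @param seed RNG seed.
#' @return a `generator_config` list.
#' @export
generator_config <- function(class_sizes = c(500L, 300L, 300L, 400L, 300L),
                             noise_fraction = 0.25, seed = 1L) {
  if (length(class_sizes) != 5L || any(class_sizes < 1L))
    stop("class_sizes must be five positive counts")
  if (noise_fraction < 0 || noise_fraction >= 1)
    stop("noise_fraction must lie in [0, 1)")
  structure(list(class_sizes = as.integer(class_sizes),
                 noise_fraction = noise_fraction, seed = as.integer(seed)),
            class = "generator_config")
}

# class imposition: each class fixes A1 and a sub-range of A13; A6 follows
# its A1/A13-conditional rule. The five classes are distinguishable by
# (A1, A13) and consistent with every deterministic attribute rule.
class_imposition <- function() {
  data.frame(
    class = paste0("C", 1:5),
    a1 = c("T", "T", "T", "F", "F"),
    a13_lo = c(0.0, 0.2, 0.4, 0.7, 0.0),
    a13_hi = c(0.2, 0.4, 0.7, 1.0, 0.5),
    stringsAsFactors = FALSE)
}

runif_range <- function(n, lo, hi) stats::runif(n, lo, hi)

#' Generate the benchmark mixed-mode dataset
#'
#' Twenty attributes with planted three-cluster structure: A1, A2 are
#' binary symbols in \{T, F\}; A3, A4, A5 are ternary symbols in
#' \{X, Y, Z\}; A6..A20 are continuous on \[0, 1\]. Five classes are
#' imposed through (A1, A13) ranges (with A6 following its conditional
#' rule), and every remaining attribute is drawn from the conditional
#' rules:
#' \itemize{
#'   \item A2 = "T" iff A13 < 0.2;
#'   \item A3 = X/Y/Z by A13 thresholds 0.2, 0.4;
#'   \item A4 = X/Y/Z by A6 thresholds 0.3, 0.6;
#'   \item A5 = Y/Z/X by A6 thresholds 0.2, 0.4;
#'   \item A6 ~ U\[0, 0.7\] if A1 = T and A13 < 0.5, U(0.3, 0.8\] if
#'     A1 = T and A13 >= 0.5, else U\[0, 1\];
#'   \item A7 ~ U\[0, 0.5\] if A1 = T else U(0.5, 1\];
#'   \item A8..A12 ~ U\[0, 0.5\] if A1 = F else U(0.5, 1\];
#'   \item A14..A17 track A13's band (below 0.3 / 0.3–0.6 / above 0.6);
#'   \item A18..A20 occupy the rotated band (0.3–0.6 / 0.6–1 / 0–0.3).
#' }
#' Finally `floor(noise_fraction * n)` tuples, chosen without replacement,
#' have all 20 attribute values replaced by uniform draws over each
#' attribute's domain; their class labels are kept (noise corrupts
#' features, not labels).
#'
#' @param config a [generator_config()].
#' @return a [mixed_mode_table()] with class labels and attributes
#'   `noise_idx` (indices of noise-replaced tuples) and `config`.
#' @export
generate_synthetic <- function(config = generator_config()) {
  set.seed(config$seed)
  imp <- class_imposition()
  n <- sum(config$class_sizes)
  cls <- rep(imp$class, times = config$class_sizes)
  row <- match(cls, imp$class)

  A1 <- imp$a1[row]
  A13 <- runif_range(n, imp$a13_lo[row], imp$a13_hi[row])
  A6 <- numeric(n)
  t_lo <- A1 == "T" & A13 < 0.5
  t_hi <- A1 == "T" & A13 >= 0.5
  other <- A1 == "F"
  A6[t_lo] <- runif_range(sum(t_lo), 0, 0.7)
  A6[t_hi] <- runif_range(sum(t_hi), 0.3, 0.8)
  A6[other] <- runif_range(sum(other), 0, 1)

  A2 <- ifelse(A13 < 0.2, "T", "F")
  A3 <- ifelse(A13 < 0.2, "X", ifelse(A13 < 0.4, "Y", "Z"))
  A4 <- ifelse(A6 < 0.3, "X", ifelse(A6 < 0.6, "Y", "Z"))
  A5 <- ifelse(A6 < 0.2, "Y", ifelse(A6 < 0.4, "Z", "X"))
  A7 <- ifelse(A1 == "T", runif_range(n, 0, 0.5), runif_range(n, 0.5, 1))

  cols <- list(A1 = A1, A2 = A2, A3 = A3, A4 = A4, A5 = A5,
               A6 = A6, A7 = A7)
  for (j in 8:12) {
    cols[[paste0("A", j)]] <-
      ifelse(A1 == "F", runif_range(n, 0, 0.5), runif_range(n, 0.5, 1))
  }
  cols$A13 <- A13
  band <- function(lo1, hi1, lo2, hi2, lo3, hi3) {
    ifelse(A13 < 0.3, runif_range(n, lo1, hi1),
           ifelse(A13 < 0.6, runif_range(n, lo2, hi2),
                  runif_range(n, lo3, hi3)))
  }
  for (j in 14:17) cols[[paste0("A", j)]] <- band(0, 0.3, 0.3, 0.6, 0.6, 1)
  for (j in 18:20) cols[[paste0("A", j)]] <- band(0.3, 0.6, 0.6, 1, 0, 0.3)

  values <- as.data.frame(cols, stringsAsFactors = FALSE)

  n_noise <- floor(config$noise_fraction * n)
  noise_idx <- sort(sample.int(n, n_noise))
  if (n_noise > 0L) {
    values$A1[noise_idx] <- sample(c("T", "F"), n_noise, replace = TRUE)
    values$A2[noise_idx] <- sample(c("T", "F"), n_noise, replace = TRUE)
    for (a in c("A3", "A4", "A5"))
      values[[a]][noise_idx] <- sample(c("X", "Y", "Z"), n_noise,
                                       replace = TRUE)
    for (j in 6:20)
      values[[paste0("A", j)]][noise_idx] <- stats::runif(n_noise)
  }

  tab <- mixed_mode_table(values, class_labels = cls)
  attr(tab, "noise_idx") <- noise_idx
  attr(tab, "config") <- config
  tab
}

#' Structural diagnostics of a generated dataset
#'
#' Reports per-class counts, the empirical noise fraction, and the number
#' of conditional-rule violations among non-noise tuples (the generator's
#' deterministic rules must hold exactly there).
#'
#' @param table a table from [generate_synthetic()] (or any table with the
#'   same attribute layout; then `noise_idx` can be supplied).
#' @param noise_idx indices of noise tuples; defaults to the attribute
#'   stored by the generator.
#' @return list with `class_counts`, `n_noise`, `noise_fraction`,
#'   `violations` (total count) and `violations_by_rule`.
#' @export
validate_structure <- function(table, noise_idx = attr(table, "noise_idx")) {
  v <- table$values
  n <- nrow(v)
  clean <- setdiff(seq_len(n), noise_idx)
  cv <- v[clean, , drop = FALSE]
  in_range <- function(x, lo, hi) x >= lo & x <= hi
  checks <- list(
    A2 = cv$A2 == ifelse(cv$A13 < 0.2, "T", "F"),
    A3 = cv$A3 == ifelse(cv$A13 < 0.2, "X", ifelse(cv$A13 < 0.4, "Y", "Z")),
    A4 = cv$A4 == ifelse(cv$A6 < 0.3, "X", ifelse(cv$A6 < 0.6, "Y", "Z")),
    A5 = cv$A5 == ifelse(cv$A6 < 0.2, "Y", ifelse(cv$A6 < 0.4, "Z", "X")),
    A6 = ifelse(cv$A1 == "T" & cv$A13 < 0.5, in_range(cv$A6, 0, 0.7),
                ifelse(cv$A1 == "T", in_range(cv$A6, 0.3, 0.8),
                       in_range(cv$A6, 0, 1))),
    A7 = ifelse(cv$A1 == "T", in_range(cv$A7, 0, 0.5),
                in_range(cv$A7, 0.5, 1)))
  for (j in 8:12) {
    a <- paste0("A", j)
    checks[[a]] <- ifelse(cv$A1 == "F", in_range(cv[[a]], 0, 0.5),
                          in_range(cv[[a]], 0.5, 1))
  }
  for (j in 14:17) {
    a <- paste0("A", j)
    checks[[a]] <- ifelse(cv$A13 < 0.3, in_range(cv[[a]], 0, 0.3),
                          ifelse(cv$A13 < 0.6, in_range(cv[[a]], 0.3, 0.6),
                                 in_range(cv[[a]], 0.6, 1)))
  }
  for (j in 18:20) {
    a <- paste0("A", j)
    checks[[a]] <- ifelse(cv$A13 < 0.3, in_range(cv[[a]], 0.3, 0.6),
                          ifelse(cv$A13 < 0.6, in_range(cv[[a]], 0.6, 1),
                                 in_range(cv[[a]], 0, 0.3)))
  }
  by_rule <- vapply(checks, function(ok) sum(!ok), integer(1))
  list(class_counts = base::table(table$class_labels),
       n_noise = length(noise_idx),
       noise_fraction = length(noise_idx) / n,
       violations = sum(by_rule),
       violations_by_rule = by_rule)
}
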