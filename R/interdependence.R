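#' Number of bins for contingency-table density estimation
#'
#' Continuous attributes are compared through an m-by-m contingency table.
#' The bin count is chosen so that a table of that size still averages at
#' least `alpha` data points per cell: m = max(2, floor(sqrt(n / alpha))).
#' `alpha` is a small rule-of-thumb integer (2 or 3 in practice).
#'
#' @param sample_size number of samples n.
#' @param alpha minimum average points per contingency cell.
#' @return integer bin count m >= 2.
#' @export
choose_bin_count <- function(sample_size, alpha = 3L) {
  stopifnot(length(sample_size) == 1L, length(alpha) == 1L)
  if (alpha < 1L) stop("alpha must be a positive integer")
  if (alpha > sample_size) stop("alpha exceeds the sample size")
  max(2L, as.integer(floor(sqrt(sample_size / alpha))))
}

#' Equal-frequency binning of a continuous attribute
#'
#' Assigns each value an integer code in 1..m by quantile (equal-frequency)
#' binning. Tied values always share a code (ties go to the lower bin), so
#' the mapping is deterministic; with heavy ties, bins left empty are
#' compacted away and `m` collapses to the number of occupied bins.
#'
#' @param values finite numeric vector.
#' @param m requested number of bins.
#' @return integer vector of codes in 1..m' with attribute `m` (occupied
#'   bin count, m' <= m).
#' @export
bin_continuous <- function(values, m) {
  if (!all(is.finite(values))) stop("values must be finite")
  if (m < 1L) stop("m must be >= 1")
  n <- length(values)
  if (m > n) stop("more bins than values")
  r <- rank(values, ties.method = "min")    # ties share the lower rank
  codes <- as.integer(floor((r - 1) * m / n)) + 1L
  occ <- sort(unique(codes))
  codes <- match(codes, occ)                # compact empty bins
  attr(codes, "m") <- length(occ)
  codes
}

#' Integer codes for a categorical attribute
#'
#' @param values character vector.
#' @return integer codes 1..m with attribute `m` (alphabet size).
#' @export
encode_categorical <- function(values) {
  lv <- sort(unique(as.character(values)))
  codes <- match(as.character(values), lv)
  attr(codes, "m") <- length(lv)
  attr(codes, "levels") <- lv
  codes
}

#' Mutual information of two discrete code vectors (bits)
#'
#' Plug-in estimate from the joint contingency table,
#' I = sum p(a,b) log2( p(a,b) / (p(a) p(b)) ); empty cells contribute 0.
#'
#' @param x,y equal-length integer code vectors.
#' @return mutual information in bits (non-negative up to rounding).
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y)) stop("code vectors differ in length")
  tab <- table(x, y)
  n <- sum(tab)
  p <- tab / n
  px <- rowSums(p)
  py <- colSums(p)
  pe <- outer(px, py)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / pe[nz]))
}

#' Joint entropy of two discrete code vectors (bits)
#'
#' H = -sum p(a,b) log2 p(a,b) over the joint contingency table.
#'
#' @param x,y equal-length integer code vectors.
#' @return joint entropy in bits.
#' @export
joint_entropy <- function(x, y) {
  if (length(x) != length(y)) stop("code vectors differ in length")
  tab <- table(x, y)
  p <- tab / sum(tab)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Interdependence redundancy between two coded attributes
#'
#' R = I / H, mutual information normalized by joint entropy: a symmetric
#' similarity in [0, 1] insensitive to the number of attribute states.
#' Returns 0 when the joint entropy is 0 (both attributes constant).
#'
#' @param x,y equal-length integer code vectors.
#' @return redundancy in [0, 1].
#' @export
redundancy_codes <- function(x, y) {
  h <- joint_entropy(x, y)
  if (h <= 0) return(0)
  r <- mutual_information(x, y) / h
  min(max(r, 0), 1)  # clamp fp noise at the boundaries
}

# Bin every attribute of a table once, globally: continuous attributes with
# choose_bin_count()/bin_continuous(), categorical with their native symbols.
attribute_codes <- function(table, alpha = 3L) {
  n <- n_samples(table)
  m_cont <- choose_bin_count(n, alpha)
  lapply(seq_len(n_attributes(table)), function(j) {
    if (table$attribute_kinds[[j]] == "continuous")
      bin_continuous(table$values[[j]], min(m_cont, n))
    else
      encode_categorical(table$values[[j]])
  })
}

#' Pairwise interdependence redundancy matrix
#'
#' Computes R between every pair of attributes of a mixed-mode table.
#' Each continuous attribute is quantile-binned once, globally, into
#' m = max(2, floor(sqrt(n/alpha))) bins; categorical attributes keep their
#' native symbols. The matrix is computed once and all clustering operates
#' on it.
#'
#' @param table a [mixed_mode_table()].
#' @param alpha minimum average points per contingency cell (default 3).
#' @return object of class `redundancy_matrix`: the symmetric N x N matrix
#'   with attributes `alpha` and `bin_count`.
#' @export
redundancy_matrix <- function(table, alpha = 3L) {
  codes <- attribute_codes(table, alpha)
  N <- length(codes)
  R <- diag(0, N)
  for (i in seq_len(N)) {
    for (j in i:N) {
      R[i, j] <- R[j, i] <- redundancy_codes(codes[[i]], codes[[j]])
    }
  }
  dimnames(R) <- list(table$attribute_names, table$attribute_names)
  structure(R, alpha = alpha,
            bin_count = choose_bin_count(n_samples(table), alpha),
            class = c("redundancy_matrix", "matrix", "array"))
}

#' Redundancy between two attributes of a table
#'
#' Single-pair convenience wrapper over the same binning used by
#' [redundancy_matrix()].
#'
#' @param table a [mixed_mode_table()].
#' @param i,j attribute indices or names.
#' @param alpha minimum average points per contingency cell.
#' @return redundancy in [0, 1].
#' @export
redundancy <- function(table, i, j, alpha = 3L) {
  idx <- function(a) if (is.character(a)) match(a, table$attribute_names) else a
  codes <- attribute_codes(table, alpha)
  redundancy_codes(codes[[idx(i)]], codes[[idx(j)]])
}

#' Multiple interdependence redundancy of an attribute within a cluster
#'
#' MR(G_i) = sum of R(G_i : G_j) over the other members j of the cluster;
#' 0 for a singleton. The cluster member maximizing MR is the cluster's
#' mode (its most representative attribute).
#'
#' @param R a `redundancy_matrix` (or plain symmetric matrix).
#' @param i attribute index.
#' @param cluster integer vector of attribute indices containing `i`.
#' @return MR value (non-negative real).
#' @export
multiple_redundancy <- function(R, i, cluster) {
  if (!i %in% cluster) stop("attribute is not a member of the cluster")
  others <- setdiff(cluster, i)
  if (length(others) == 0L) return(0)
  sum(R[i, others])
}
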