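#' Interval scheme for a continuous attribute
#'
#' Ordered cut-points mapping a continuous attribute to labelled intervals
#' (primary events). Intervals are half-open `[c_j, c_{j+1})` with the
#' first interval open below and the last closed above, so every observed
#' value maps to exactly one interval.
#'
#' @param attribute attribute identifier.
#' @param cuts strictly increasing numeric cut-points (possibly empty).
#' @param labels one label per interval (`length(cuts) + 1`).
#' @return object of class `interval_scheme`.
#' @export
interval_scheme <- function(attribute, cuts, labels) {
  cuts <- as.numeric(cuts)
  if (length(cuts) > 1L && any(diff(cuts) <= 0))
    stop("cut-points must be strictly increasing")
  if (length(labels) != length(cuts) + 1L)
    stop("need exactly one label per interval")
  structure(list(attribute = attribute, cuts = cuts,
                 labels = as.character(labels)),
            class = "interval_scheme")
}

#' @export
print.interval_scheme <- function(x, ...) {
  bounds <- c(-Inf, x$cuts, Inf)
  for (j in seq_along(x$labels))
    cat(sprintf("  %s: [%g, %g)\n", x$labels[j], bounds[j], bounds[j + 1]))
  invisible(x)
}

#' Map values through an interval scheme
#'
#' @param scheme an [interval_scheme()].
#' @param values numeric vector.
#' @param codes return integer interval indices instead of labels.
#' @return character labels (or integer codes) of length `length(values)`.
#' @export
apply_scheme <- function(scheme, values, codes = FALSE) {
  idx <- findInterval(values, scheme$cuts) + 1L
  if (codes) {
    attr(idx, "m") <- length(scheme$labels)
    return(idx)
  }
  scheme$labels[idx]
}

#' Entropy-maximizing discretization of a cluster mode
#'
#' The mode (representative attribute) of each cluster is discretized
#' without reference to any other variable; absent other information the
#' maximum-entropy partition of an empirical distribution is the
#' equal-frequency one. Three intervals are labelled "L", "N", "H"
#' (lowly / normally / highly expressed); other counts get generic labels
#' I1..In. Cut-points sit halfway between the adjacent boundary values, and
#' ties never straddle a cut (the lower interval absorbs them).
#'
#' @param values finite numeric vector.
#' @param n_intervals number of intervals (default 3).
#' @param attribute identifier stored in the scheme.
#' @return an [interval_scheme()].
#' @export
discretize_mode <- function(values, n_intervals = 3L, attribute = "mode") {
  if (!all(is.finite(values))) stop("values must be finite")
  n_distinct <- length(unique(values))
  if (n_intervals < 2L) stop("need at least 2 intervals")
  if (n_intervals > n_distinct)
    stop("more intervals than distinct values")
  codes <- bin_continuous(values, n_intervals)
  m <- attr(codes, "m")
  cuts <- vapply(seq_len(m - 1L), function(j) {
    (max(values[codes == j]) + min(values[codes == j + 1L])) / 2
  }, numeric(1))
  labels <- if (m == 3L) c("L", "N", "H") else paste0("I", seq_len(m))
  interval_scheme(attribute, cuts, labels)
}

# Per-segment contributions to mutual information and joint entropy with a
# fixed class variable. `cum` is a (B+1) x K matrix of cumulative class
# counts at each candidate boundary (row 1 = zero counts, row B+1 = totals).
# Returns i and h matrices where [a, b] holds the contribution of the
# segment between boundary a-1 and boundary b-1 (0 = start sentinel).
segment_stats <- function(cum, n, class_p) {
  B1 <- nrow(cum)
  K <- ncol(cum)
  i_mat <- matrix(0, B1, B1)
  h_mat <- matrix(0, B1, B1)
  for (a in seq_len(B1 - 1L)) {
    seg <- sweep(cum[(a + 1L):B1, , drop = FALSE], 2L, cum[a, ])  # counts
    p <- seg / n
    nb <- rowSums(p)
    lp <- ifelse(p > 0, log2(p), 0)
    h <- -rowSums(p * lp)
    pe <- outer(nb, class_p)
    ii <- rowSums(ifelse(p > 0, p * (lp - log2(pmax(pe, .Machine$double.xmin))), 0))
    i_mat[a, (a + 1L):B1] <- ii
    h_mat[a, (a + 1L):B1] <- h
  }
  list(i = i_mat, h = h_mat)
}

#' Class-dependent optimal discretization of a continuous attribute
#'
#' Chooses interval boundaries for a continuous attribute that maximize its
#' interdependence redundancy R = I/H with a given discrete class variable
#' — here, the discretized mode of the attribute's fuzzy cluster. Candidate
#' boundaries are the midpoints between consecutive distinct sorted values;
#' for every interval count q in 2..`max_intervals` the boundary subset
#' maximizing R is found by exact search over candidate subsets (segment
#' statistics are precomputed from cumulative class counts, so each subset
#' is scored in O(q)). The scheme with globally maximal R is returned, ties
#' resolved toward fewer intervals.
#'
#' When an attribute has more than `max_candidates` candidate midpoints the
#' candidate set is thinned to an equal-frequency-spaced subset of that
#' size; the oracle regime (few distinct values) always keeps all midpoints.
#'
#' @param values finite numeric vector.
#' @param class_codes integer codes of the driving class variable (same
#'   length).
#' @param max_intervals largest interval count searched (default 3).
#' @param max_candidates cap on candidate boundaries (default 200).
#' @param attribute identifier stored in the scheme.
#' @return an [interval_scheme()] with attributes `r` (achieved redundancy)
#'   and `r_by_q` (best R per interval count).
#' @export
ocdd <- function(values, class_codes, max_intervals = 3L,
                 max_candidates = 200L, attribute = "attr") {
  if (length(values) != length(class_codes))
    stop("values and class_codes differ in length")
  if (max_intervals < 2L) stop("max_intervals must be >= 2")
  v_sorted <- sort(unique(values))
  if (length(v_sorted) < 2L) {
    sch <- interval_scheme(attribute, numeric(0), "I1")
    attr(sch, "r") <- 0
    return(sch)
  }
  n <- length(values)
  K <- max(class_codes)
  # candidate boundaries: midpoints between consecutive distinct values
  mids <- (v_sorted[-length(v_sorted)] + v_sorted[-1L]) / 2
  if (length(mids) > max_candidates) {
    keep <- unique(round(seq(1L, length(mids), length.out = max_candidates)))
    mids <- mids[keep]
  }
  B <- length(mids)
  # cumulative class counts below each boundary (+ sentinels)
  ord <- order(values)
  vs <- values[ord]
  cs <- class_codes[ord]
  cum <- matrix(0, B + 2L, K)
  pos <- findInterval(mids, vs)            # samples strictly below each mid
  for (c in seq_len(K)) {
    cum_c <- cumsum(cs == c)
    cum[2:(B + 1L), c] <- cum_c[pos]
    cum[B + 2L, c] <- cum_c[n]
  }
  class_p <- cum[B + 2L, ] / n
  st <- segment_stats(cum, n, class_p)
  E <- B + 2L                              # end sentinel row

  best <- NULL
  r_by_q <- stats::setNames(rep(NA_real_, max_intervals - 1L),
                            paste0("q", 2:max_intervals))
  for (q in 2:max_intervals) {
    nb <- q - 1L                           # boundaries to choose
    if (nb > B) break
    if (choose(B, nb) > 5e6)
      stop("candidate search too large; lower max_candidates or max_intervals")
    combos <- utils::combn(B, nb)          # nb x ncomb, boundary indices
    rows <- rbind(1L, combos + 1L)         # segment start rows (sentinel 1)
    ends <- rbind(combos + 1L, E)          # segment end rows
    idx <- cbind(as.vector(rows), as.vector(ends))
    I_tot <- colSums(matrix(st$i[idx], nrow = q))
    H_tot <- colSums(matrix(st$h[idx], nrow = q))
    r_all <- ifelse(H_tot > 0, I_tot / H_tot, 0)
    j <- which.max(r_all)
    r_by_q[q - 1L] <- r_all[j]
    if (is.null(best) || r_all[j] > best$r + 1e-12)
      best <- list(r = r_all[j], cuts = mids[combos[, j]])
  }
  labels <- paste0("I", seq_len(length(best$cuts) + 1L))
  sch <- interval_scheme(attribute, best$cuts, labels)
  attr(sch, "r") <- best$r
  attr(sch, "r_by_q") <- r_by_q
  sch
}

#' Build per-cluster event tables from a fuzzified clustering
#'
#' For each fuzzy attribute cluster: members are the attributes whose
#' membership in the cluster is at least `tau`; a continuous mode is
#' discretized into 3 equal-frequency states (L/N/H); every other
#' continuous member is discretized by [ocdd()] against the mode's discrete
#' codes; categorical members (including a categorical mode) pass through
#' with their native symbols. Because memberships overlap, an attribute can
#' appear — and be discretized differently — in several cluster tables;
#' that multiplicity is what lets patterns span crisp cluster boundaries.
#'
#' @param table a [mixed_mode_table()].
#' @param clustering an `attribute_clustering`.
#' @param membership a [fuzzy_memberships()] result.
#' @param tau membership inclusion threshold (default 0.003).
#' @param max_intervals interval cap passed to [ocdd()].
#' @param max_candidates candidate-boundary cap passed to [ocdd()].
#' @return list of `cluster_events` objects, one per cluster, each with
#'   `cluster_id`, `member_attributes`, `mode`, `schemes`, `events`
#'   (data.frame of labels), `membership_weight`.
#' @export
build_cluster_event_tables <- function(table, clustering, membership,
                                       tau = 0.003, max_intervals = 3L,
                                       max_candidates = 200L) {
  mu <- membership$mu
  nm <- table$attribute_names
  out <- vector("list", clustering$k)
  for (r in seq_len(clustering$k)) {
    members <- which(mu[, r] >= tau)
    mode_idx <- clustering$modes[r]
    if (!mode_idx %in% members)
      stop("inclusion threshold tau excludes cluster ", r, "'s own mode")
    # mode first, then remaining members by descending membership
    rest <- setdiff(members, mode_idx)
    members <- c(mode_idx, rest[order(mu[rest, r], decreasing = TRUE)])

    if (table$attribute_kinds[[mode_idx]] == "continuous") {
      mode_scheme <- discretize_mode(table$values[[mode_idx]], 3L,
                                     attribute = nm[mode_idx])
      mode_codes <- apply_scheme(mode_scheme, table$values[[mode_idx]],
                                 codes = TRUE)
    } else {
      mode_scheme <- NULL
      mode_codes <- encode_categorical(table$values[[mode_idx]])
    }

    schemes <- list()
    events <- list()
    for (i in members) {
      if (table$attribute_kinds[[i]] == "categorical") {
        events[[nm[i]]] <- table$values[[i]]
      } else if (i == mode_idx) {
        schemes[[nm[i]]] <- mode_scheme
        events[[nm[i]]] <- apply_scheme(mode_scheme, table$values[[i]])
      } else {
        sch <- ocdd(table$values[[i]], mode_codes,
                    max_intervals = max_intervals,
                    max_candidates = max_candidates, attribute = nm[i])
        schemes[[nm[i]]] <- sch
        events[[nm[i]]] <- apply_scheme(sch, table$values[[i]])
      }
    }
    out[[r]] <- structure(
      list(cluster_id = r,
           member_attributes = members,
           mode = mode_idx,
           schemes = schemes,
           events = as.data.frame(events, check.names = FALSE,
                                  stringsAsFactors = FALSE),
           membership_weight = mu[members, r]),
      class = "cluster_events")
  }
  out
}

#' @export
print.cluster_events <- function(x, ...) {
  cat(sprintf("cluster_events: cluster %d, %d members, %d samples\n",
              x$cluster_id, length(x$member_attributes), nrow(x$events)))
  invisible(x)
}
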