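#' Adjusted residual of an event conjunction
#'
#' Tests the observed co-occurrence count of a set of primary events
#' against the independence assumption. With per-event marginal
#' probabilities p_1..p_q and n samples, the expected count is
#' e = n * prod(p_i), the variance v = e * prod(1 - p_i), and
#' d = (o - e) / sqrt(v), asymptotically standard normal under
#' independence. For two events this is exactly the classical adjusted
#' (Haberman) residual of a two-way contingency-table cell.
#'
#' @param observed observed co-occurrence count o.
#' @param marginal_probs per-event marginal probabilities, each in (0, 1].
#' @param n sample size.
#' @return the adjusted residual; 0 (with attribute `degenerate = TRUE`)
#'   when the variance vanishes because some p_i = 1.
#' @export
adjusted_residual <- function(observed, marginal_probs, n) {
  if (any(marginal_probs <= 0) || any(marginal_probs > 1))
    stop("marginal probabilities must lie in (0, 1]")
  if (observed > n) stop("observed count exceeds the sample size")
  e <- n * prod(marginal_probs)
  v <- e * prod(1 - marginal_probs)
  if (v <= 0) {
    d <- 0
    attr(d, "degenerate") <- TRUE
    return(d)
  }
  (observed - e) / sqrt(v)
}

# internal: residual pieces for a candidate given marginal probs and o
residual_parts <- function(o, probs, n) {
  e <- n * prod(probs)
  v <- e * prod(1 - probs)
  d <- if (v > 0) (o - e) / sqrt(v) else 0
  list(e = e, v = v, d = d)
}

#' Discover statistically significant high-order event patterns
#'
#' Level-wise search over conjunctions of primary events drawn from
#' distinct attributes of one cluster event table. A candidate is scored
#' only when its independence expectation reaches `min_expected` (residual
#' validity); it is retained when |d| >= `d_threshold`. Growth prunes
#' extensions that cannot reach significance: an extension's observed count
#' never exceeds its parent's, so a parent whose most optimistic residual
#' (o at its ceiling) falls below threshold is not extended. Significantly
#' under-represented conjunctions (d <= -threshold) are recorded with
#' `sign = -1` but are not grown further and are excluded from rule mining
#' downstream.
#'
#' @param event_table a `cluster_events` from
#'   [build_cluster_event_tables()], or a plain data.frame of label
#'   columns.
#' @param min_order smallest pattern order (default 2).
#' @param max_order largest pattern order (default 4; clipped to the number
#'   of attributes with a warning).
#' @param d_threshold significance threshold on |d| (default 1.96, the
#'   two-sided 95% normal point).
#' @param min_expected minimum expected count for a candidate to be scored
#'   (default 3).
#' @return data.frame of patterns sorted by |d| descending (ties by the
#'   lexicographic event string): columns `events` (list of named label
#'   vectors), `event_string`, `order`, `observed`, `expected`, `residual`,
#'   `sign`, `source_cluster`.
#' @export
discover_patterns <- function(event_table, min_order = 2L, max_order = 4L,
                              d_threshold = 1.96, min_expected = 3) {
  if (inherits(event_table, "cluster_events")) {
    events <- event_table$events
    cluster_id <- event_table$cluster_id
  } else {
    events <- as.data.frame(event_table, stringsAsFactors = FALSE)
    cluster_id <- NA_integer_
  }
  if (min_order < 2L) stop("min_order must be >= 2")
  if (d_threshold <= 0) stop("d_threshold must be positive")
  n <- nrow(events)
  A <- ncol(events)
  if (max_order > A) {
    warning("max_order exceeds the number of attributes; clipping to ", A)
    max_order <- A
  }
  attr_names <- names(events)

  # primary events: one indicator column per (attribute, label); events of
  # constant attributes (p = 1) are degenerate (zero variance) and dropped
  prim_attr <- integer(0)
  prim_lab <- character(0)
  cols <- list()
  for (j in seq_len(A)) {
    for (lab in sort(unique(events[[j]]))) {
      ind <- as.numeric(events[[j]] == lab)
      if (mean(ind) >= 1) next
      cols[[length(cols) + 1L]] <- ind
      prim_attr <- c(prim_attr, j)
      prim_lab <- c(prim_lab, lab)
    }
  }
  if (length(cols) == 0L) return(pattern_frame(list()))
  Pmat <- do.call(cbind, cols)               # n x P indicator matrix
  p_marg <- colMeans(Pmat)
  P <- ncol(Pmat)

  results <- list()
  # frontier: event-index rows (q x F), indicators (n x F), observed counts,
  # running products of p and (1 - p)
  frontier <- list(ev = matrix(seq_len(P), nrow = 1L), Fmat = Pmat,
                   o = colSums(Pmat), pprod = p_marg, qprod = 1 - p_marg,
                   last = prim_attr)

  for (ord in 2:max_order) {
    F <- length(frontier$o)
    # candidate grid: frontier f extended by primary p of a later attribute
    allowed <- outer(frontier$last, prim_attr, `<`)
    e_mat <- n * outer(frontier$pprod, p_marg)
    v_mat <- e_mat * outer(frontier$qprod, 1 - p_marg)
    # prune: o is capped by the parent's count, under-representation by -e,
    # so a candidate with both bounds inside the threshold cannot be
    # significant at any observed count
    d_ub <- (outer(frontier$o, rep(1, P)) - e_mat) / sqrt(v_mat)
    d_lb <- e_mat / sqrt(v_mat)
    eval_mask <- allowed & e_mat >= min_expected &
      (d_ub >= d_threshold | d_lb >= d_threshold)
    if (!any(eval_mask)) break
    counts <- crossprod(frontier$Fmat, Pmat)  # F x P co-occurrence counts
    stopifnot(all(counts <= frontier$o + 1e-9))  # anti-monotone support
    d_mat <- (counts - e_mat) / sqrt(v_mat)

    sig <- eval_mask & abs(d_mat) >= d_threshold
    if (ord >= min_order && any(sig)) {
      hit <- which(sig, arr.ind = TRUE)
      for (h in seq_len(nrow(hit))) {
        f <- hit[h, 1L]; p <- hit[h, 2L]
        ev_idx <- c(frontier$ev[, f], p)
        labs <- stats::setNames(prim_lab[ev_idx],
                                attr_names[prim_attr[ev_idx]])
        results[[length(results) + 1L]] <- list(
          events = labs, order = ord, observed = counts[f, p],
          expected = e_mat[f, p], residual = d_mat[f, p],
          sign = if (d_mat[f, p] >= 0) 1L else -1L,
          source_cluster = cluster_id)
      }
    }
    if (ord == max_order) break
    # grow positively associated / not-yet-significant candidates only;
    # significantly under-represented conjunctions are reported, not mined
    grow <- eval_mask & (d_mat >= 0 | abs(d_mat) < d_threshold)
    sel <- which(grow, arr.ind = TRUE)
    if (nrow(sel) == 0L) break
    f_idx <- sel[, 1L]; p_idx <- sel[, 2L]
    frontier <- list(
      ev = rbind(frontier$ev[, f_idx, drop = FALSE], p_idx),
      Fmat = frontier$Fmat[, f_idx, drop = FALSE] *
        Pmat[, p_idx, drop = FALSE],
      o = counts[sel],
      pprod = frontier$pprod[f_idx] * p_marg[p_idx],
      qprod = frontier$qprod[f_idx] * (1 - p_marg[p_idx]),
      last = prim_attr[p_idx])
  }

  pattern_frame(results)
}

# internal: assemble and sort a pattern data.frame
pattern_frame <- function(results) {
  if (length(results) == 0L) {
    return(data.frame(event_string = character(0), order = integer(0),
                      observed = integer(0), expected = numeric(0),
                      residual = numeric(0), sign = integer(0),
                      source_cluster = integer(0)))
  }
  ev_str <- vapply(results, function(p)
    paste(paste0(names(p$events), "=", p$events), collapse = " & "),
    character(1))
  df <- data.frame(
    event_string = ev_str,
    order = vapply(results, `[[`, integer(1), "order"),
    observed = vapply(results, function(p) as.integer(p$observed), integer(1)),
    expected = vapply(results, `[[`, numeric(1), "expected"),
    residual = vapply(results, `[[`, numeric(1), "residual"),
    sign = vapply(results, `[[`, integer(1), "sign"),
    source_cluster = vapply(results, function(p)
      as.integer(p$source_cluster), integer(1)),
    stringsAsFactors = FALSE)
  df$events <- lapply(results, `[[`, "events")
  ord <- order(-abs(df$residual), df$event_string)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Merge pattern lists discovered in different fuzzy clusters
#'
#' Fuzzified clusters overlap, so the same event-set can be rediscovered in
#' several cluster tables (possibly with different interval labels from
#' per-cluster discretization). Patterns whose event sets are identical are
#' collapsed to the instance with maximal |d|, retaining the provenance of
#' all source clusters; same attributes with different labels stay
#' distinct.
#'
#' @param per_cluster list of pattern data.frames from
#'   [discover_patterns()].
#' @return one merged pattern data.frame sorted by |d| descending, with a
#'   `provenance` list column of contributing cluster ids.
#' @export
merge_patterns <- function(per_cluster) {
  all_df <- do.call(rbind, lapply(per_cluster, function(df) {
    df$provenance <- as.list(df$source_cluster)
    df
  }))
  if (is.null(all_df) || nrow(all_df) == 0L) {
    out <- pattern_frame(list())
    out$provenance <- list()
    return(out)
  }
  key <- vapply(all_df$events, function(ev)
    paste(sort(paste0(names(ev), "=", ev)), collapse = "|"), character(1))
  groups <- split(seq_along(key), key)
  keep <- vapply(groups, function(rows)
    rows[which.max(abs(all_df$residual[rows]))], integer(1))
  prov <- all_df$provenance
  out <- all_df[keep, , drop = FALSE]
  out$provenance <- unname(lapply(groups, function(rows)
    sort(unique(unlist(prov[rows])))))
  ord <- order(-abs(out$residual), out$event_string)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-class confidences of patterns against held-out labels
#'
#' Post-hoc annotation only: for each pattern, the fraction of matching
#' samples carrying each class label.
#'
#' @param patterns a pattern data.frame.
#' @param events the event data.frame the patterns were mined from.
#' @param class_labels per-sample labels.
#' @return the pattern data.frame with one `conf_<class>` column per class.
#' @export
pattern_confidences <- function(patterns, events, class_labels) {
  stopifnot(length(class_labels) == nrow(events))
  classes <- sort(unique(class_labels))
  for (cl in classes) patterns[[paste0("conf_", cl)]] <- NA_real_
  for (i in seq_len(nrow(patterns))) {
    ev <- patterns$events[[i]]
    match_ind <- Reduce(`&`, lapply(names(ev), function(a)
      events[[a]] == ev[[a]]))
    if (sum(match_ind) == 0) next
    for (cl in classes)
      patterns[[paste0("conf_", cl)]][i] <-
        mean(class_labels[match_ind] == cl)
  }
  patterns
}
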