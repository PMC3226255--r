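#' Weight of evidence of an event set for a class
#'
#' WofE = log2[ P(antecedent | class = c) / P(antecedent | class != c) ],
#' Laplace-smoothed (+1 on each matching count, +number-of-classes on each
#' class total) so the measure stays finite when an antecedent never
#' occurs outside (or inside) the class. Positive values support class c.
#'
#' @param antecedent named character vector of (attribute = label) events.
#' @param class_value the class symbol the evidence is weighed for.
#' @param events data.frame of per-sample event labels.
#' @param class_labels per-sample class labels.
#' @param smooth apply Laplace smoothing (default TRUE); without it the
#'   measure is infinite when the antecedent is exclusive to one side.
#' @return the weight of evidence (bits).
#' @export
weight_of_evidence <- function(antecedent, class_value, events, class_labels,
                               smooth = TRUE) {
  stopifnot(length(class_labels) == nrow(events))
  if (!class_value %in% class_labels)
    stop("class '", class_value, "' absent from the data")
  k_classes <- length(unique(class_labels))
  match_ind <- Reduce(`&`, lapply(names(antecedent), function(a)
    events[[a]] == antecedent[[a]]))
  in_c <- class_labels == class_value
  add_n <- if (smooth) 1 else 0
  add_d <- if (smooth) k_classes else 0
  p_given_c <- (sum(match_ind & in_c) + add_n) / (sum(in_c) + add_d)
  p_given_not <- (sum(match_ind & !in_c) + add_n) / (sum(!in_c) + add_d)
  log2(p_given_c / p_given_not)
}

#' Mine weight-of-evidence classification rules
#'
#' Appends the (held-out) class attribute as one more event column to each
#' cluster event table and mines patterns that include exactly one class
#' event; each such pattern becomes a rule `antecedent => class` retained
#' when the class-conditioned association is significant and positive
#' (|d| >= `d_threshold`, d > 0). The rule is scored by its weight of
#' evidence, support (antecedent matches) and confidence (fraction of
#' matches in the consequent class). Class labels play no part in any
#' earlier stage; this is post-hoc evaluation of a label-free
#' discretization.
#'
#' @param event_tables list of `cluster_events` (or data.frames).
#' @param class_labels per-sample labels.
#' @param d_threshold significance threshold (default 1.96).
#' @param min_expected minimum expected count (default 3).
#' @param max_order maximum rule order including the class event
#'   (default 4).
#' @return data.frame of rules sorted by WofE descending: `antecedent`
#'   (list column), `antecedent_string`, `consequent`, `order`, `wofe`,
#'   `support`, `confidence`, `residual`, `source_cluster`.
#' @export
mine_rules <- function(event_tables, class_labels, d_threshold = 1.96,
                       min_expected = 3, max_order = 4L) {
  if (inherits(event_tables, "cluster_events") || is.data.frame(event_tables))
    event_tables <- list(event_tables)
  class_col <- ".class"
  per_cluster <- lapply(event_tables, function(tab) {
    ev <- if (inherits(tab, "cluster_events")) tab$events else tab
    cid <- if (inherits(tab, "cluster_events")) tab$cluster_id else NA_integer_
    stopifnot(length(class_labels) == nrow(ev))
    ev2 <- ev
    ev2[[class_col]] <- as.character(class_labels)
    pats <- discover_patterns(ev2, min_order = 2L, max_order = max_order,
                              d_threshold = d_threshold,
                              min_expected = min_expected)
    if (nrow(pats) == 0L) return(NULL)
    has_class <- vapply(pats$events, function(e) class_col %in% names(e),
                        logical(1))
    pats <- pats[has_class & pats$sign > 0, , drop = FALSE]
    if (nrow(pats) == 0L) return(NULL)
    rows <- list()
    antecedents <- list()
    for (i in seq_len(nrow(pats))) {
      ev_set <- pats$events[[i]]
      consequent <- unname(ev_set[[class_col]])
      antecedent <- ev_set[names(ev_set) != class_col]
      if (length(antecedent) < 1L) next
      match_ind <- Reduce(`&`, lapply(names(antecedent), function(a)
        ev[[a]] == antecedent[[a]]))
      support <- sum(match_ind)
      if (support < 1L) next
      rows[[length(rows) + 1L]] <- data.frame(
        antecedent_string = paste(paste0(names(antecedent), "=", antecedent),
                                  collapse = " & "),
        consequent = consequent,
        order = length(antecedent) + 1L,
        wofe = weight_of_evidence(antecedent, consequent, ev, class_labels),
        support = support,
        confidence = mean(class_labels[match_ind] == consequent),
        residual = pats$residual[i],
        source_cluster = cid,
        stringsAsFactors = FALSE)
      antecedents[[length(antecedents) + 1L]] <- antecedent
    }
    if (length(rows) == 0L) return(NULL)
    out <- do.call(rbind, rows)
    out$antecedent <- antecedents
    out
  })
  per_cluster <- per_cluster[!vapply(per_cluster, is.null, logical(1))]
  if (length(per_cluster) == 0L) {
    return(data.frame(antecedent_string = character(0),
                      consequent = character(0), order = integer(0),
                      wofe = numeric(0), support = integer(0),
                      confidence = numeric(0), residual = numeric(0),
                      source_cluster = integer(0)))
  }
  rules <- do.call(rbind, per_cluster)
  # collapse duplicate (antecedent, consequent) pairs across clusters
  key <- paste(vapply(rules$antecedent, function(a)
    paste(sort(paste0(names(a), "=", a)), collapse = "|"), character(1)),
    rules$consequent, sep = " => ")
  keep <- !duplicated(key)
  rules <- rules[keep, , drop = FALSE]
  rules <- rules[order(-rules$wofe, rules$antecedent_string), , drop = FALSE]
  rownames(rules) <- NULL
  rules
}

#' Classify a sample by summed weight of evidence
#'
#' Each class accumulates the WofE of the rules the sample matches.
#' Higher-order rules are counted first and a matched rule whose
#' antecedent is a subset of an already-counted rule for the same class is
#' skipped, so nested rules are not double-counted. The class with maximal
#' total evidence wins; ties go to the class with the larger prior, and a
#' sample matching no rule falls back to the majority class with a
#' `no_match` flag.
#'
#' @param sample_events named character vector (or single-row data.frame)
#'   of the sample's event labels.
#' @param rules rule data.frame from [mine_rules()].
#' @param class_priors named numeric vector of class priors (used for tie
#'   breaks and the no-match fallback).
#' @return list with `class`, `evidence` (named per-class totals),
#'   `no_match`.
#' @export
classify_sample <- function(sample_events, rules, class_priors) {
  if (is.data.frame(sample_events)) {
    stopifnot(nrow(sample_events) == 1L)
    sample_events <- stats::setNames(
      vapply(sample_events, as.character, character(1)), names(sample_events))
  }
  if (nrow(rules) == 0L) stop("rules must be non-empty")
  classes <- names(sort(class_priors, decreasing = TRUE))
  evidence <- stats::setNames(rep(0, length(classes)), classes)
  matched <- vapply(seq_len(nrow(rules)), function(i) {
    a <- rules$antecedent[[i]]
    all(names(a) %in% names(sample_events)) &&
      all(sample_events[names(a)] == unlist(a))
  }, logical(1))
  any_match <- any(matched)
  idx <- which(matched)
  idx <- idx[order(-rules$order[idx], -abs(rules$wofe[idx]))]
  counted <- list()
  for (i in idx) {
    cl <- rules$consequent[i]
    a_key <- paste0(names(rules$antecedent[[i]]), "=", rules$antecedent[[i]])
    prior <- counted[[cl]]
    if (!is.null(prior) &&
        any(vapply(prior, function(p) all(a_key %in% p), logical(1))))
      next                                   # nested within a counted rule
    evidence[cl] <- evidence[cl] + rules$wofe[i]
    counted[[cl]] <- c(prior, list(a_key))
  }
  if (!any_match) {
    return(list(class = classes[1L], evidence = evidence, no_match = TRUE))
  }
  # which.max on the prior-sorted vector breaks ties toward larger prior
  list(class = names(evidence)[which.max(evidence)],
       evidence = evidence, no_match = FALSE)
}

#' Classify every sample of an event-table set by summed weight of evidence
#'
#' Batch counterpart of [classify_sample()]: each rule's antecedent is
#' matched against the event table of the cluster it was mined from (the
#' same attribute may be discretized differently per fuzzy cluster), a
#' matched rule is suppressed when a matched same-class rule with a strict
#' superset antecedent exists (transitively equivalent to the sequential
#' subset-skipping of [classify_sample()]), and each sample takes the class
#' with maximal summed evidence — ties toward the larger prior, no-match
#' samples fall back to the majority class.
#'
#' @param event_tables list of `cluster_events` or data.frames, indexed by
#'   the rules' `source_cluster`; a single frame serves rules with no
#'   cluster provenance.
#' @param rules rule data.frame from [mine_rules()].
#' @param class_priors named numeric vector of class priors.
#' @return list with `class` (n predictions), `evidence` (n x classes
#'   matrix), `no_match` (logical n).
#' @export
classify_events <- function(event_tables, rules, class_priors) {
  if (inherits(event_tables, "cluster_events") || is.data.frame(event_tables))
    event_tables <- list(event_tables)
  evs <- lapply(event_tables, function(t)
    if (inherits(t, "cluster_events")) t$events else t)
  n <- nrow(evs[[1L]])
  if (nrow(rules) == 0L) stop("rules must be non-empty")
  nr <- nrow(rules)
  matched <- matrix(FALSE, n, nr)
  for (i in seq_len(nr)) {
    a <- rules$antecedent[[i]]
    src <- rules$source_cluster[i]
    ev <- if (is.na(src)) evs[[1L]] else evs[[src]]
    matched[, i] <- Reduce(`&`, lapply(names(a), function(at)
      ev[[at]] == a[[at]]))
  }
  keys <- lapply(rules$antecedent, function(a) paste0(names(a), "=", a))
  classes <- names(sort(class_priors, decreasing = TRUE))
  evidence <- matrix(0, n, length(classes),
                     dimnames = list(NULL, classes))
  for (cl in classes) {
    in_cl <- which(rules$consequent == cl)
    for (i in in_cl) {
      dominators <- in_cl[vapply(in_cl, function(j)
        j != i && length(keys[[j]]) > length(keys[[i]]) &&
          all(keys[[i]] %in% keys[[j]]), logical(1))]
      active <- matched[, i]
      if (length(dominators) > 0L)
        active <- active & !apply(matched[, dominators, drop = FALSE], 1L, any)
      evidence[, cl] <- evidence[, cl] + rules$wofe[i] * active
    }
  }
  no_match <- rowSums(matched) == 0L
  pred <- classes[apply(evidence, 1L, which.max)]  # ties -> larger prior
  pred[no_match] <- classes[1L]
  list(class = pred, evidence = evidence, no_match = no_match)
}

#' Leave-one-out classification accuracy over an event table set
#'
#' For each held-out sample, rules are re-mined from the remaining samples
#' (the discretization itself is fixed and label-free) and the sample is
#' classified by summed weight of evidence.
#'
#' @param event_tables list of `cluster_events` (or data.frames).
#' @param class_labels per-sample labels.
#' @param ... passed to [mine_rules()].
#' @return list with `accuracy`, `predicted`, `majority_baseline`.
#' @export
classify_loo <- function(event_tables, class_labels, ...) {
  if (inherits(event_tables, "cluster_events") || is.data.frame(event_tables))
    event_tables <- list(event_tables)
  evs <- lapply(event_tables, function(t)
    if (inherits(t, "cluster_events")) t$events else t)
  n <- nrow(evs[[1L]])
  joint <- do.call(cbind, lapply(seq_along(evs), function(r) {
    e <- evs[[r]]
    names(e) <- paste0("c", r, ".", names(e))
    e
  }))
  predicted <- character(n)
  for (s in seq_len(n)) {
    train_tabs <- lapply(seq_along(evs), function(r) {
      e <- evs[[r]][-s, , drop = FALSE]
      names(e) <- paste0("c", r, ".", names(evs[[r]]))
      e
    })
    rules <- mine_rules(train_tabs, class_labels[-s], ...)
    priors <- table(class_labels[-s]) / (n - 1)
    if (nrow(rules) == 0L) {
      predicted[s] <- names(which.max(priors))
    } else {
      predicted[s] <- classify_sample(joint[s, , drop = FALSE], rules,
                                      c(priors))$class
    }
  }
  list(accuracy = mean(predicted == class_labels),
       predicted = predicted,
       majority_baseline = max(table(class_labels)) / n)
}
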