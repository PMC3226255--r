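#' k-modes attribute clustering on a redundancy matrix
#'
#' Clusters attributes (not samples) with a k-modes analogue of k-means in
#' which the interdependence redundancy R plays the role of (negative)
#' distance and each cluster is represented by its mode — the member with
#' maximal multiple interdependence redundancy MR within the cluster —
#' instead of a centroid. Iterates assignment (each attribute joins the
#' cluster whose mode it is most redundant with) and mode update until the
#' assignment is stable.
#'
#' Ties are broken deterministically: assignment ties on R go to the lowest
#' cluster index, mode-update ties on MR to the lowest attribute index.
#' Should a cluster empty out, its mode is re-seeded with the attribute
#' whose best redundancy to the current modes is lowest.
#'
#' @param R a [redundancy_matrix()] (or symmetric matrix in [0,1]).
#' @param k number of clusters.
#' @param seed RNG seed for the initial draw of k distinct modes.
#' @param max_iter iteration cap (default 100).
#' @param init_modes optional integer vector of k starting modes,
#'   overriding the seeded draw.
#' @return an `attribute_clustering`: list with `clusters` (list of integer
#'   index vectors), `modes`, `k`, `sr`, `per_cluster_mr`.
#' @export
kmodes_cluster <- function(R, k, seed = 1L, max_iter = 100L, init_modes = NULL) {
  N <- nrow(R)
  if (k < 1L || k > N) stop("k must lie in 1..N")
  if (is.null(init_modes)) {
    set.seed(seed)
    modes <- sample.int(N, k)
  } else {
    stopifnot(length(init_modes) == k, !anyDuplicated(init_modes))
    modes <- as.integer(init_modes)
  }

  assign_to_modes <- function(modes) {
    sim <- unname(R[, modes, drop = FALSE])    # N x k
    assignment <- apply(sim, 1L, which.max)    # which.max: first max -> lowest cluster
    assignment[modes] <- seq_len(k)            # a mode anchors its own cluster
    # repair empty clusters: re-seed with the attribute least served by any mode
    repeat {
      empty <- setdiff(seq_len(k), unique(assignment))
      if (length(empty) == 0L) break
      best_r <- apply(R[, modes, drop = FALSE], 1L, max)
      candidates <- setdiff(order(best_r), modes)
      newmode <- candidates[1L]
      modes[empty[1L]] <- newmode
      sim <- unname(R[, modes, drop = FALSE])
      assignment <- apply(sim, 1L, which.max)
      assignment[modes] <- seq_len(k)
    }
    list(assignment = assignment, modes = modes)
  }

  snapshot <- function(assignment, modes) {
    clusters <- lapply(seq_len(k), function(r) which(assignment == r))
    per_mr <- vapply(seq_len(k), function(r)
      multiple_redundancy(R, modes[r], clusters[[r]]), numeric(1))
    list(clusters = clusters, modes = modes, per_mr = per_mr, sr = sum(per_mr))
  }

  assignment <- rep(0L, N)
  best <- NULL
  sr_trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    a <- assign_to_modes(modes)
    modes <- a$modes
    converged <- identical(a$assignment, assignment)
    assignment <- a$assignment
    # mode update: member with maximal MR; which.max ties -> lowest index
    for (r in seq_len(k)) {
      members <- which(assignment == r)
      mr <- vapply(members, function(i) multiple_redundancy(R, i, members),
                   numeric(1))
      modes[r] <- members[which.max(mr)]
    }
    snap <- snapshot(assignment, modes)
    sr_trace <- c(sr_trace, snap$sr)
    if (is.null(best) || snap$sr > best$sr + 1e-12) best <- snap
    if (converged) break
  }
  structure(
    list(clusters = best$clusters, modes = best$modes, k = k,
         sr = best$sr, per_cluster_mr = best$per_mr,
         attribute_names = rownames(R), sr_trace = sr_trace),
    class = "attribute_clustering")
}

#' @export
print.attribute_clustering <- function(x, ...) {
  cat(sprintf("attribute_clustering: k = %d, SR = %.4f\n", x$k, x$sr))
  nm <- x$attribute_names
  if (is.null(nm)) nm <- as.character(seq_len(sum(lengths(x$clusters))))
  for (r in seq_len(x$k)) {
    cat(sprintf("  [%d] mode %s (MR = %.4f): %s\n", r, nm[x$modes[r]],
                x$per_cluster_mr[r],
                paste(nm[x$clusters[[r]]], collapse = ", ")))
  }
  invisible(x)
}

#' Select the number of attribute clusters by SR maximization
#'
#' SR is the sum, over clusters, of the mode's MR; it is the model-selection
#' objective over k. For each k in `k_min..k_max`, `restarts` seeded
#' k-modes runs are performed and the best-SR clustering kept; the
#' clustering with globally maximal SR is returned. SR ties (within 1e-12)
#' resolve toward smaller k (parsimony).
#'
#' @param R a [redundancy_matrix()].
#' @param k_min,k_max search range (defaults 2..min(N-1, 10)).
#' @param restarts seeded restarts per k (default 10).
#' @param seed base RNG seed; run j of a given k uses a seed derived
#'   deterministically from it.
#' @param max_iter per-run iteration cap.
#' @return the best `attribute_clustering` (with an `sr_by_k` attribute
#'   giving the best SR found at each k).
#' @export
select_k <- function(R, k_min = 2L, k_max = min(nrow(R) - 1L, 10L),
                     restarts = 10L, seed = 1L, max_iter = 100L) {
  N <- nrow(R)
  if (k_min < 1L || k_max > N || k_min > k_max) stop("invalid k range")
  best <- NULL
  sr_by_k <- stats::setNames(numeric(0), character(0))
  for (k in k_min:k_max) {
    best_k <- NULL
    for (j in seq_len(restarts)) {
      run_seed <- (seed * 1000L + k * 100L + j) %% .Machine$integer.max
      cl <- kmodes_cluster(R, k, seed = run_seed, max_iter = max_iter)
      if (is.null(best_k) || cl$sr > best_k$sr + 1e-12) best_k <- cl
    }
    sr_by_k[as.character(k)] <- best_k$sr
    if (is.null(best) || best_k$sr > best$sr + 1e-12) best <- best_k
  }
  attr(best, "sr_by_k") <- sr_by_k
  best
}
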