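#' Fuzzy membership of every attribute in every attribute cluster
#'
#' Converts a crisp attribute clustering into degrees of membership: each
#' attribute's membership in cluster r is the fractional share of its
#' (sharpened) redundancy with cluster r's mode among all k modes,
#'
#'   mu_r(G_i) = R(G_i : G^r)^(1/(f-1)) / sum_c R(G_i : G^c)^(1/(f-1)).
#'
#' The fuzzification parameter f > 1 controls sharpness: f = 2 normalizes
#' the redundancies linearly so they sum to 1; as f approaches 1 the
#' attribute's nearest mode takes all the weight; as f grows the rows tend
#' to uniform 1/k. Rows always sum to 1 (the stability property of fuzzy
#' membership assignments); an attribute with zero redundancy to every mode
#' falls back to the uniform row 1/k.
#'
#' @param R a [redundancy_matrix()].
#' @param clustering an `attribute_clustering` from [kmodes_cluster()] or
#'   [select_k()].
#' @param f fuzzification parameter, real > 1 (default 1.5).
#' @return object of class `fuzzy_membership`: list with `mu` (N x k
#'   row-stochastic matrix), `f`, `clustering`.
#' @export
fuzzy_memberships <- function(R, clustering, f = 1.5) {
  if (f <= 1) stop("fuzzification parameter f must exceed 1")
  modes <- clustering$modes
  k <- clustering$k
  sim <- R[, modes, drop = FALSE]            # N x k redundancy to each mode
  mx <- apply(sim, 1L, max)
  scaled <- sim / ifelse(mx > 0, mx, 1)      # row-rescale: stable for f ~ 1
  w <- scaled ^ (1 / (f - 1))
  rs <- rowSums(w)
  zero <- mx <= 0
  w[zero, ] <- 1 / k
  rs[zero] <- 1
  mu <- w / rs
  dimnames(mu) <- list(rownames(R), paste0("AC", seq_len(k)))
  structure(list(mu = mu, f = f, clustering = clustering),
            class = "fuzzy_membership")
}

#' @export
print.fuzzy_membership <- function(x, ...) {
  cat(sprintf("fuzzy_membership: %d attributes x %d clusters, f = %g\n",
              nrow(x$mu), ncol(x$mu), x$f))
  print(round(x$mu, 4))
  invisible(x)
}
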