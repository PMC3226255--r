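#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end run. Defaults follow the
#' package's standard analysis settings: contingency cells average at
#' least `alpha = 3` points, the cluster count is searched over
#' `k_min..k_max` with `restarts` seeded starts each, memberships use
#' fuzzification `f = 1.5`, cluster tables admit attributes with
#' membership at least `tau = 0.003`, non-mode attributes get up to
#' `max_intervals = 3` intervals, and patterns are screened at
#' `d_threshold = 1.96` with `min_expected = 3`.
#'
#' @param alpha,k_min,k_max,restarts,f,tau,max_intervals,d_threshold,min_expected,max_order,seed
#'   stage parameters (see the stage functions).
#' @param class_column optional class-column name, used only for post-hoc
#'   rule mining.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(alpha = 3L, k_min = 2L, k_max = 6L,
                            restarts = 10L, f = 1.5, tau = 0.003,
                            max_intervals = 3L, d_threshold = 1.96,
                            min_expected = 3, max_order = 4L, seed = 1L,
                            class_column = NULL) {
  cfg <- list(alpha = alpha, k_min = k_min, k_max = k_max,
              restarts = restarts, f = f, tau = tau,
              max_intervals = max_intervals, d_threshold = d_threshold,
              min_expected = min_expected, max_order = max_order,
              seed = seed, class_column = class_column)
  stopifnot(cfg$alpha >= 1, cfg$k_min >= 1, cfg$k_max >= cfg$k_min,
            cfg$restarts >= 1, cfg$f > 1, cfg$tau >= 0, cfg$tau <= 1,
            cfg$max_intervals >= 2, cfg$d_threshold > 0)
  structure(cfg, class = "pipeline_config")
}

#' Run the full unsupervised pattern-discovery pipeline
#'
#' Chains redundancy matrix, cluster-count selection, fuzzification,
#' per-cluster discretization and pattern discovery; when the table
#' carries class labels (and `config$class_column` is not disabled via
#' `use_labels = FALSE`), weight-of-evidence rules are additionally mined
#' post hoc. Class labels are stripped before every unsupervised stage.
#'
#' @param table a [mixed_mode_table()].
#' @param config a [pipeline_config()].
#' @param use_labels mine rules when labels are present (default TRUE).
#' @return a `pipeline_result` list: `redundancy`, `clustering`,
#'   `membership`, `event_tables`, `patterns` (merged), `rules` (or NULL),
#'   `config`.
#' @export
run_pipeline <- function(table, config = pipeline_config(),
                         use_labels = TRUE) {
  labels <- table$class_labels
  unsup <- strip_class(table)

  R <- redundancy_matrix(unsup, alpha = config$alpha)
  clustering <- select_k(R, k_min = config$k_min,
                         k_max = min(config$k_max, nrow(R) - 1L),
                         restarts = config$restarts, seed = config$seed)
  membership <- fuzzy_memberships(R, clustering, f = config$f)
  event_tables <- build_cluster_event_tables(
    unsup, clustering, membership, tau = config$tau,
    max_intervals = config$max_intervals)
  per_cluster <- lapply(event_tables, discover_patterns,
                        min_order = 2L, max_order = config$max_order,
                        d_threshold = config$d_threshold,
                        min_expected = config$min_expected)
  patterns <- merge_patterns(per_cluster)

  rules <- NULL
  if (use_labels && !is.null(labels)) {
    rules <- mine_rules(event_tables, labels,
                        d_threshold = config$d_threshold,
                        min_expected = config$min_expected,
                        max_order = config$max_order)
  }
  structure(list(redundancy = R, clustering = clustering,
                 membership = membership, event_tables = event_tables,
                 patterns = patterns, rules = rules, config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("== attribute clusters ==\n")
  print(x$clustering)
  cat("\n== fuzzy memberships (f =", x$membership$f, ") ==\n")
  print(round(x$membership$mu, 4))
  cat("\n== top patterns ==\n")
  top <- utils::head(x$patterns, 10L)
  if (nrow(top) > 0) {
    for (i in seq_len(nrow(top)))
      cat(sprintf("  d = %6.2f  o = %4d  %s\n", top$residual[i],
                  top$observed[i], top$event_string[i]))
  } else cat("  (none)\n")
  if (!is.null(x$rules)) {
    cat("\n== top rules ==\n")
    top <- utils::head(x$rules, 10L)
    for (i in seq_len(nrow(top)))
      cat(sprintf("  WofE = %6.3f  conf = %.2f  if {%s} then {%s}\n",
                  top$wofe[i], top$confidence[i],
                  top$antecedent_string[i], top$consequent[i]))
  }
  invisible(x)
}

#' Export pipeline artifacts as JSON
#'
#' Writes clustering, membership matrix, interval schemes, patterns and
#' rules (when present) under an output directory as versioned JSON files.
#'
#' @param result a `pipeline_result`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
export_artifacts <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  w <- function(x, name) {
    p <- file.path(dir, name)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <<- c(paths, p)
  }
  cl <- result$clustering
  w(list(schema = "fuzzpat/clustering/1", k = cl$k, sr = cl$sr,
         modes = cl$attribute_names[cl$modes],
         per_cluster_mr = cl$per_cluster_mr,
         clusters = lapply(cl$clusters, function(ix) cl$attribute_names[ix])),
    "clustering.json")
  w(list(schema = "fuzzpat/membership/1", f = result$membership$f,
         attributes = rownames(result$membership$mu),
         mu = unname(apply(result$membership$mu, 1L, as.list, simplify = FALSE))),
    "membership.json")
  schemes <- lapply(result$event_tables, function(t)
    lapply(t$schemes, function(s)
      list(attribute = s$attribute, cuts = s$cuts, labels = s$labels)))
  w(list(schema = "fuzzpat/schemes/1", clusters = schemes), "schemes.json")
  pat <- result$patterns
  w(list(schema = "fuzzpat/patterns/1",
         patterns = lapply(seq_len(nrow(pat)), function(i)
           list(events = as.list(pat$events[[i]]), order = pat$order[i],
                observed = pat$observed[i], expected = pat$expected[i],
                residual = pat$residual[i],
                provenance = pat$provenance[[i]]))),
    "patterns.json")
  if (!is.null(result$rules)) {
    ru <- result$rules
    w(list(schema = "fuzzpat/rules/1",
           rules = lapply(seq_len(nrow(ru)), function(i)
             list(antecedent = as.list(ru$antecedent[[i]]),
                  consequent = ru$consequent[i], wofe = ru$wofe[i],
                  support = ru$support[i], confidence = ru$confidence[i]))),
      "rules.json")
  }
  invisible(paths)
}
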