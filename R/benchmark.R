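#' Truth set of known planted or reference fusions
#'
#' @param gene_a,gene_b Gene symbol vectors (one true pair per element).
#' @param label Description of the truth set.
#' @return A `truth_set` object (data.frame of pairs plus label).
#' @export
truth_set <- function(gene_a, gene_b, label = "truth") {
  if (length(gene_a) == 0) {
    stop("truth set must be non-empty for sensitivity to be defined",
         call. = FALSE)
  }
  key <- pair_key(gene_a, gene_b)
  keep <- !duplicated(key)
  structure(list(pairs = data.frame(gene_a = pmin(gene_a, gene_b)[keep],
                                    gene_b = pmax(gene_a, gene_b)[keep],
                                    pair = key[keep],
                                    stringsAsFactors = FALSE),
                 label = label),
            class = "truth_set")
}

#' Load a truth set from a two-column TSV
#'
#' @param path Tab-delimited file with columns gene_a, gene_b.
#' @param label Description.
#' @return A [truth_set()].
#' @export
load_truth_set <- function(path, label = basename(path)) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  truth_set(df[[1]], df[[2]], label = label)
}

#' Sensitivity/precision arithmetic from raw counts
#'
#' Sensitivity is the fraction of possible true fusions identified;
#' precision is the fraction of identified fusions that are true. Both are
#' reported as percentages rounded to one decimal, matching the convention
#' of benchmark tables. With zero identified fusions precision is
#' undefined and reported as 0 with `precision_defined = FALSE`.
#'
#' Counts may be fractional: benchmarks averaged over replicate runs
#' (e.g. duplicate library preparations) yield means such as 15.5.
#'
#' @param n_total_identified Total fusions identified.
#' @param n_true_identified True fusions identified.
#' @param n_possible Number of possible true fusions (> 0).
#' @return A `benchmark_result` list: the three counts plus `sensitivity`
#'   and `precision` in percent and `precision_defined`.
#' @export
benchmark_result <- function(n_total_identified, n_true_identified,
                             n_possible) {
  stopifnot(n_possible > 0, n_true_identified >= 0,
            n_total_identified >= 0)
  precision_defined <- n_total_identified > 0
  structure(list(
    n_total_identified = n_total_identified,
    n_true_identified = n_true_identified,
    n_possible = n_possible,
    sensitivity = round(100 * n_true_identified / n_possible, 1),
    precision = if (precision_defined) {
      round(100 * n_true_identified / n_total_identified, 1)
    } else {
      0
    },
    precision_defined = precision_defined
  ), class = "benchmark_result")
}

#' Score identified consensus records against a truth set
#'
#' Matching is by unordered gene pair after harmonization; breakpoint
#' agreement is not required (counts are per fusion, not per isoform).
#'
#' @param identified Consensus record data.frame (e.g. the filtered
#'   channel of a pipeline run).
#' @param truth A [truth_set()].
#' @return A [benchmark_result()].
#' @export
score_against_truth <- function(identified, truth) {
  if (!inherits(truth, "truth_set")) stop("truth must be a truth_set",
                                          call. = FALSE)
  n_total <- nrow(identified)
  n_true <- sum(unique(identified$pair) %in% truth$pairs$pair)
  benchmark_result(n_total, n_true, nrow(truth$pairs))
}

#' Consensus-threshold ablation sweep
#'
#' Runs the overlap + filter + rescue cascade over a grid of
#' configurations — each consensus threshold crossed with filtering
#' off/on and known-list rescue off/on — and scores each configuration
#' against the truth set. Mirrors the standard ablation used to choose the
#' 3-caller consensus: filtering raises precision at some cost to
#' sensitivity, and known-list rescue restores sensitivity.
#'
#' @param calls_by_caller Named list of harmonized unified call
#'   data.frames.
#' @param store A [cohort_store()].
#' @param known A `known_fusion_list`.
#' @param truth A [truth_set()].
#' @param thresholds Integer vector of `min_callers` values (default 2:3).
#' @param cfg Base [filter_config()]; its consensus threshold is
#'   overridden per row.
#' @return data.frame: one row per configuration with columns
#'   min_callers, filter, known_list, n_total, n_true, sensitivity,
#'   precision.
#' @export
consensus_sweep <- function(calls_by_caller, store, known, truth,
                            thresholds = c(2L, 3L),
                            cfg = filter_config()) {
  records <- overlap_calls(calls_by_caller)
  grid <- expand.grid(min_callers = thresholds,
                      filter = c(FALSE, TRUE),
                      known_list = c(FALSE, TRUE),
                      stringsAsFactors = FALSE)
  # "filter off, known list on" is not a pipeline configuration.
  grid <- grid[!(grid$known_list & !grid$filter), , drop = FALSE]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    th <- grid$min_callers[i]
    cfg_i <- filter_config(
      min_callers = th,
      readthrough_max_distance = cfg$readthrough_max_distance,
      max_cohort_frequency = cfg$max_cohort_frequency,
      min_reads = cfg$min_reads,
      known_list_min_callers = min(cfg$known_list_min_callers, th)
    )
    kept <- if (grid$filter[i]) {
      apply_filters(records, store,
                    if (grid$known_list[i]) known else NULL,
                    cfg_i)$kept
    } else {
      records[records$caller_count >= th, , drop = FALSE]
    }
    res <- score_against_truth(kept, truth)
    data.frame(min_callers = th, filter = grid$filter[i],
               known_list = grid$known_list[i],
               n_total = res$n_total_identified,
               n_true = res$n_true_identified,
               sensitivity = res$sensitivity,
               precision = res$precision,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$min_callers, out$filter, out$known_list), ]
}
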