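#' Filtering configuration
#'
#' Thresholds for consensus filtering. Defaults follow the optimized
#' pipeline configuration: at least 3 supporting callers, read-through
#' removal below 200,000 bases, cohort-frequency removal above 10%, and a
#' minimum of 4 supporting reads from at least one caller. Known-list
#' fusions are rescued down to 2 supporting callers.
#'
#' All comparison directions are strict, mirroring the rule statements:
#' distance strictly below `readthrough_max_distance` is filtered,
#' frequency strictly above `max_cohort_frequency` is filtered (exactly
#' 10% is retained), and a record is low-evidence only when every caller
#' supplies strictly fewer than `min_reads` reads.
#'
#' @param min_callers Minimum distinct callers for consensus (default 3).
#' @param readthrough_max_distance Breakpoint distance in bases below which
#'   a same-chromosome, same-strand event is treated as a read-through
#'   transcript (default 200000).
#' @param max_cohort_frequency Cohort detection frequency above which a
#'   pair is treated as a recurrent artifact (default 0.10).
#' @param min_reads Minimum supporting reads required from at least one
#'   caller (default 4).
#' @param known_list_min_callers Minimum callers for a known-list rescue
#'   (default 2); must not exceed `min_callers`.
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_callers = 3L,
                          readthrough_max_distance = 200000L,
                          max_cohort_frequency = 0.10,
                          min_reads = 4L,
                          known_list_min_callers = 2L) {
  stopifnot(min_callers >= 1, readthrough_max_distance > 0,
            max_cohort_frequency > 0, min_reads >= 1,
            known_list_min_callers >= 1)
  if (known_list_min_callers > min_callers) {
    stop("known_list_min_callers must not exceed min_callers",
         call. = FALSE)
  }
  structure(list(min_callers = as.integer(min_callers),
                 readthrough_max_distance =
                   as.integer(readthrough_max_distance),
                 max_cohort_frequency = max_cohort_frequency,
                 min_reads = as.integer(min_reads),
                 known_list_min_callers =
                   as.integer(known_list_min_callers)),
            class = "filter_config")
}

#' Read-through transcript test
#'
#' A consensus record looks like a read-through (conjoined) transcript when
#' its reconciled best breakpoints lie on the same chromosome and the same
#' known strand, strictly fewer than `readthrough_max_distance` bases
#' apart. An unknown strand on either side never triggers the filter: the
#' same-strand condition cannot be asserted.
#'
#' @param records Consensus record data.frame (breakpoints reconciled).
#' @param cfg A [filter_config()].
#' @return Logical vector, `TRUE` where the record is a read-through.
#' @export
is_readthrough <- function(records, cfg = filter_config()) {
  if (nrow(records) == 0) return(logical(0))
  same_chrom <- records$chrom5 == records$chrom3
  known_strand <- records$strand5 %in% c("+", "-") &
    records$strand3 %in% c("+", "-")
  same_strand <- known_strand & records$strand5 == records$strand3
  dist <- abs(records$pos5 - records$pos3)
  same_chrom & same_strand & dist < cfg$readthrough_max_distance
}

#' Recurrent cohort-artifact test
#'
#' `TRUE` where the gene pair's detection frequency in the cohort store is
#' strictly greater than `max_cohort_frequency`. Pairs absent from the
#' store have frequency 0.
#'
#' @param records Consensus record data.frame.
#' @param store A [cohort_store()].
#' @param cfg A [filter_config()].
#' @return Logical vector.
#' @export
is_high_frequency <- function(records, store, cfg = filter_config()) {
  if (nrow(records) == 0) return(logical(0))
  freq <- cohort_frequency(store, records$gene_a, records$gene_b)
  freq > cfg$max_cohort_frequency
}

#' Low read-evidence test
#'
#' `TRUE` where no contributing caller supplies at least `min_reads`
#' supporting reads, i.e. the maximum read count over supporting calls is
#' strictly below the threshold. One caller with sufficient reads retains
#' the record.
#'
#' @param records Consensus record data.frame.
#' @param cfg A [filter_config()].
#' @return Logical vector.
#' @export
is_low_evidence <- function(records, cfg = filter_config()) {
  if (nrow(records) == 0) return(logical(0))
  records$max_reads < cfg$min_reads
}

#' Apply consensus and knowledge-based filters with known-list rescue
#'
#' A record is kept when it reaches the consensus threshold and passes all
#' three knowledge-based filters, or when its exact unordered pair is on
#' the known fusion list and at least `known_list_min_callers` callers
#' support it — rescue overrides the read-through, frequency and evidence
#' filters as well as the consensus threshold. Every removal carries its
#' reasons; kept and removed records partition the input.
#'
#' @param records Prioritized consensus record data.frame.
#' @param store A [cohort_store()] (or `NULL` for an empty store).
#' @param known A [load_known_list()] object (or `NULL` for no rescue).
#' @param cfg A [filter_config()].
#' @return List with elements `kept` (records retained, input order),
#'   `removed` (records filtered out) and `decisions` (audit data.frame:
#'   pair, caller_count, kept, reasons, rescued_by_known_list).
#' @export
apply_filters <- function(records, store = NULL, known = NULL,
                          cfg = filter_config()) {
  if (is.null(store)) store <- cohort_store()
  if (nrow(records) == 0) {
    return(list(kept = records, removed = records,
                decisions = data.frame(pair = character(),
                                       caller_count = integer(),
                                       kept = logical(),
                                       reasons = character(),
                                       rescued_by_known_list = logical(),
                                       stringsAsFactors = FALSE)))
  }
  below <- records$caller_count < cfg$min_callers
  rt <- is_readthrough(records, cfg)
  hf <- is_high_frequency(records, store, cfg)
  le <- is_low_evidence(records, cfg)
  on_list <- if (is.null(known)) {
    rep(FALSE, nrow(records))
  } else {
    records$pair %in% known$pairs$pair
  }
  rescued <- on_list & records$caller_count >= cfg$known_list_min_callers
  clean <- !below & !rt & !hf & !le
  keep <- clean | rescued
  reasons <- mapply(function(b, r, h, l) {
    paste(c("below-consensus", "read-through", "high-frequency",
            "low-evidence")[c(b, r, h, l)], collapse = ";")
  }, below, rt, hf, le)
  decisions <- data.frame(
    pair = records$pair,
    caller_count = records$caller_count,
    kept = keep,
    reasons = unname(reasons),
    rescued_by_known_list = keep & !clean & rescued,
    stringsAsFactors = FALSE
  )
  list(kept = records[keep, , drop = FALSE],
       removed = records[!keep, , drop = FALSE],
       decisions = decisions)
}
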