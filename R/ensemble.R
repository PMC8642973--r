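#' Unordered gene-pair key
#'
#' Order-independent key for a fusion's two gene partners:
#' `pair_key("MET", "RBPMS") == pair_key("RBPMS", "MET")`. Reciprocal
#' fusions and discordant donor/acceptor assignments across callers
#' therefore collapse to one key. Self-fusions (both partners identical)
#' are permitted.
#'
#' @param a,b Gene symbol vectors.
#' @return Character vector of keys.
#' @export
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' Overlap harmonized calls from several callers on unordered gene pairs
#'
#' Pools the calls of all callers and groups them by unordered gene pair,
#' producing exactly one consensus record per distinct pair. A caller
#' contributing several isoform calls for the same pair contributes all of
#' them to the record but counts once towards `caller_count`; reciprocal
#' orientations merge into one record with both observed directions
#' recorded. Output is independent of the order of callers and of rows
#' within each caller's file.
#'
#' @param calls_by_caller Named list mapping caller name to its unified
#'   call data.frame. Duplicate caller names are a configuration error.
#' @return A consensus record data.frame, one row per gene pair, with a
#'   `calls` list-column holding the supporting calls, reconciled best
#'   breakpoints (see [reconcile_breakpoints()]) and priority ordering
#'   applied (see [prioritize_records()]).
#' @export
overlap_calls <- function(calls_by_caller) {
  if (is.null(names(calls_by_caller)) ||
      anyDuplicated(names(calls_by_caller))) {
    stop("calls_by_caller must be a named list with unique caller names",
         call. = FALSE)
  }
  for (cl in names(calls_by_caller)) {
    if (nrow(calls_by_caller[[cl]]) > 0) {
      calls_by_caller[[cl]]$caller <- cl
    }
  }
  pooled <- do.call(rbind, unname(calls_by_caller))
  if (is.null(pooled) || nrow(pooled) == 0) {
    return(empty_records())
  }
  # Canonical row order so that grouping is permutation-invariant.
  pooled <- pooled[order(pooled$caller, pooled$gene5, pooled$gene3,
                         pooled$chrom5, pooled$pos5, pooled$chrom3,
                         pooled$pos3, pooled$reads), , drop = FALSE]
  key <- pair_key(pooled$gene5, pooled$gene3)
  groups <- split(seq_len(nrow(pooled)), key)
  rows <- lapply(names(groups), function(k) {
    g <- pooled[groups[[k]], , drop = FALSE]
    rownames(g) <- NULL
    genes <- strsplit(k, "|", fixed = TRUE)[[1]]
    if (length(genes) == 1) genes <- c(genes, genes)
    data.frame(
      pair = k,
      gene_a = genes[1], gene_b = genes[2],
      caller_count = length(unique(g$caller)),
      callers = paste(sort(unique(g$caller)), collapse = ","),
      n_calls = nrow(g),
      max_reads = max(g$reads),
      orientations = paste(sort(unique(paste0(g$gene5, ">", g$gene3))),
                           collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  records <- do.call(rbind, rows)
  records$calls <- I(lapply(names(groups), function(k) {
    g <- pooled[groups[[k]], , drop = FALSE]
    rownames(g) <- NULL
    g
  }))
  records <- reconcile_breakpoints(records)
  prioritize_records(records)
}

empty_records <- function() {
  df <- data.frame(
    pair = character(), gene_a = character(), gene_b = character(),
    caller_count = integer(), callers = character(), n_calls = integer(),
    max_reads = integer(), orientations = character(),
    stringsAsFactors = FALSE
  )
  df$calls <- I(list())
  df$best_gene5 <- character()
  df$best_gene3 <- character()
  df$chrom5 <- character(); df$pos5 <- integer(); df$strand5 <- character()
  df$chrom3 <- character(); df$pos3 <- integer(); df$strand3 <- character()
  df
}

#' Reconcile discordant breakpoints within consensus records
#'
#' When different callers report different breakpoints for the same gene
#' pair, the breakpoint pair of the supporting call with the most reads is
#' promoted to the record's best breakpoints. Ties on reads are broken by
#' the breakpoint tuple supported by the most distinct callers, then by the
#' lexicographically smallest `(chrom5, pos5, chrom3, pos3)` tuple, so the
#' choice is deterministic. All candidate breakpoints remain available in
#' the `calls` list-column.
#'
#' @param records Consensus record data.frame from [overlap_calls()].
#' @return `records` with `best_gene5`, `best_gene3`, `chrom5`, `pos5`,
#'   `strand5`, `chrom3`, `pos3`, `strand3` set from the winning call.
#' @export
reconcile_breakpoints <- function(records) {
  if (nrow(records) == 0) return(empty_records())
  best <- lapply(records$calls, function(g) {
    bp <- paste(g$chrom5, g$pos5, g$chrom3, g$pos3)
    support <- vapply(bp, function(b) {
      length(unique(g$caller[bp == b]))
    }, integer(1))
    tied <- g$reads == max(g$reads)
    cand <- which(tied)
    cand <- cand[support[cand] == max(support[cand])]
    cand <- cand[order(g$chrom5[cand], g$pos5[cand], g$chrom3[cand],
                       g$pos3[cand])]
    g[cand[1], , drop = FALSE]
  })
  best <- do.call(rbind, best)
  records$best_gene5 <- best$gene5
  records$best_gene3 <- best$gene3
  records$chrom5 <- best$chrom5
  records$pos5 <- best$pos5
  records$strand5 <- best$strand5
  records$chrom3 <- best$chrom3
  records$pos3 <- best$pos3
  records$strand3 <- best$strand3
  records
}

#' Prioritize consensus records
#'
#' Stable sort: descending by the number of contributing callers, then
#' descending by the maximum supporting read count, then by gene-pair key
#' so fully tied records have a reproducible order.
#'
#' @param records Consensus record data.frame.
#' @return Reordered records.
#' @export
prioritize_records <- function(records) {
  if (nrow(records) == 0) return(records)
  ord <- order(-records$caller_count, -records$max_reads, records$pair)
  out <- records[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
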