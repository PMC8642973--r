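#' Pipeline configuration
#'
#' Bundles everything one end-to-end run needs: the per-caller input files
#' (any subset of the supported callers), the knowledge resources, the
#' filter thresholds, and the output location. The pipeline is
#' customizable: any subset of callers may be supplied, provided the
#' consensus threshold does not exceed the number of callers.
#'
#' @param caller_files Named character vector mapping caller name to its
#'   native output file; at least one.
#' @param known_list A `known_fusion_list`, a path to one, or `NULL`.
#' @param alias_table An `alias_table`, a path to one, or `NULL` to use
#'   the bundled snapshot.
#' @param freq_store A `cohort_store`, a path to a saved store, or `NULL`
#'   for an empty store.
#' @param cfg A [filter_config()].
#' @param outdir Output directory for reports, or `NULL` to skip writing.
#' @param sample_id Sample identifier used in logs and when registering
#'   the sample in the frequency store.
#' @param register Logical: register this sample's >= 2-caller unfiltered
#'   consensus in the frequency store after the run (artifact filtering
#'   must see artifacts, so registration is pre-filter by default).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(caller_files,
                            known_list = NULL,
                            alias_table = NULL,
                            freq_store = NULL,
                            cfg = filter_config(),
                            outdir = NULL,
                            sample_id = "sample",
                            register = FALSE) {
  if (length(caller_files) < 1 || is.null(names(caller_files))) {
    stop("caller_files must be a named vector with at least one file",
         call. = FALSE)
  }
  if (cfg$min_callers > length(caller_files)) {
    stop("min_callers (", cfg$min_callers, ") exceeds the number of ",
         "provided callers (", length(caller_files), ")", call. = FALSE)
  }
  structure(list(caller_files = caller_files, known_list = known_list,
                 alias_table = alias_table, freq_store = freq_store,
                 cfg = cfg, outdir = outdir, sample_id = sample_id,
                 register = register),
            class = "pipeline_config")
}

resolve_known <- function(x) {
  if (is.null(x)) return(NULL)
  if (inherits(x, "known_fusion_list")) return(x)
  load_known_list(x)
}

resolve_alias <- function(x) {
  if (inherits(x, "alias_table")) return(x)
  load_alias_table(x)
}

resolve_store <- function(x) {
  if (is.null(x)) return(cohort_store())
  if (inherits(x, "cohort_store")) return(x)
  if (file.exists(x)) return(load_cohort_store(x))
  cohort_store()
}

#' Run the full ensemble fusion-detection pipeline
#'
#' Executes parse -> harmonize -> overlap -> reconcile -> prioritize ->
#' filter/rescue -> annotate, and optionally writes the four report
#' channels (see [write_report()]). A caller file that fails to parse is
#' skipped with a warning and the run continues on the remaining callers,
#' so one failed upstream tool never voids a sample. Because the run is a
#' pure function of the supplied caller files, re-running as more callers
#' finish ("incremental mode") gives exactly the result of a batch run on
#' the same file set.
#'
#' @param config A [pipeline_config()].
#' @return An `ensemble_report` list: `filtered` (kept, prioritized,
#'   annotated records), `unfiltered` (all consensus records, annotated),
#'   `singletons` (single-caller known-list channel), `audit` (filter
#'   decisions), `store` (the possibly updated cohort store), and
#'   `counts` (per-stage tallies).
#' @export
run_pipeline <- function(config) {
  alias <- resolve_alias(config$alias_table)
  known <- resolve_known(config$known_list)
  store <- resolve_store(config$freq_store)
  cfg <- config$cfg

  calls_by_caller <- list()
  n_parsed <- 0L
  for (cl in names(config$caller_files)) {
    calls <- tryCatch(
      parse_caller_output(config$caller_files[[cl]], cl),
      error = function(e) {
        warning("caller '", cl, "' skipped: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    if (!is.null(calls)) {
      calls_by_caller[[cl]] <- harmonize_calls(calls, alias)
      n_parsed <- n_parsed + nrow(calls)
    }
  }
  if (length(calls_by_caller) == 0) {
    stop("no caller file could be parsed", call. = FALSE)
  }

  records <- overlap_calls(calls_by_caller)
  filt <- apply_filters(records, store, known, cfg)
  singles <- if (is.null(known)) {
    records[0, , drop = FALSE]
  } else {
    extract_singletons(records, known)
  }
  annotate <- function(x) {
    x$cohort_frequency <- if (nrow(x) > 0) {
      cohort_frequency(store, x$pair)
    } else {
      numeric(0)
    }
    if (!is.null(known)) x <- annotate_known(x, known)
    x
  }
  filtered <- annotate(filt$kept)
  unfiltered <- annotate(records)
  singles <- annotate(singles)

  if (isTRUE(config$register)) {
    consensus2 <- records$pair[records$caller_count >= 2L]
    store <- register_sample(store, config$sample_id, consensus2)
  }

  report <- structure(list(
    filtered = filtered, unfiltered = unfiltered, singletons = singles,
    audit = filt$decisions, store = store,
    counts = c(callers = length(calls_by_caller), parsed = n_parsed,
               consensus = nrow(records), kept = nrow(filtered),
               removed = nrow(filt$removed),
               rescued = sum(filt$decisions$rescued_by_known_list),
               singletons = nrow(singles))
  ), class = "ensemble_report")
  message(sprintf(
    "[%s] callers=%d parsed=%d consensus=%d kept=%d removed=%d rescued=%d singletons=%d",
    config$sample_id, report$counts[["callers"]],
    report$counts[["parsed"]], report$counts[["consensus"]],
    report$counts[["kept"]], report$counts[["removed"]],
    report$counts[["rescued"]], report$counts[["singletons"]]))
  if (!is.null(config$outdir)) {
    write_report(report, config$outdir)
  }
  report
}

report_columns <- function() {
  c("pair", "gene_a", "gene_b", "best_gene5", "best_gene3", "chrom5",
    "pos5", "strand5", "chrom3", "pos3", "strand3",
    "breakpoint_distance", "caller_count", "callers", "n_calls",
    "max_reads", "per_caller_reads", "orientations", "junction_seq",
    "frame", "cohort_frequency", "known_pair", "gene_a_known_partner",
    "gene_a_score", "gene_a_type", "gene_b_known_partner",
    "gene_b_score", "gene_b_type")
}

# Flatten a record data.frame (with calls list-column) to the documented
# report schema.
flatten_records <- function(records) {
  n <- nrow(records)
  out <- data.frame(matrix(nrow = n, ncol = 0))
  base <- setdiff(report_columns(),
                  c("breakpoint_distance", "per_caller_reads",
                    "junction_seq", "frame"))
  for (col in base) {
    out[[col]] <- if (col %in% names(records)) {
      records[[col]]
    } else if (n > 0) {
      NA
    } else {
      logical(0)
    }
  }
  out$breakpoint_distance <- ifelse(
    records$chrom5 == records$chrom3,
    abs(records$pos5 - records$pos3), NA_integer_)
  per_caller <- vapply(records$calls, function(g) {
    agg <- tapply(g$reads, g$caller, max)
    paste(paste0(names(agg), ":", agg), collapse = ",")
  }, character(1))
  out$per_caller_reads <- per_caller
  best <- lapply(seq_len(n), function(i) {
    g <- records$calls[[i]]
    hit <- g$chrom5 == records$chrom5[i] & g$pos5 == records$pos5[i] &
      g$chrom3 == records$chrom3[i] & g$pos3 == records$pos3[i]
    g[which(hit)[1], , drop = FALSE]
  })
  out$junction_seq <- vapply(best, function(b) {
    if (is.null(b) || is.na(b$junction_seq)) NA_character_
    else b$junction_seq
  }, character(1))
  out$frame <- vapply(best, function(b) b$frame, character(1))
  out[, report_columns()]
}

#' Write the four report channels as tab-delimited files
#'
#' Writes `filtered.tsv`, `unfiltered.tsv`, `singletons.tsv` (all in the
#' fixed documented schema of [report_columns()]) and `audit.tsv` (one
#' row per consensus record with its filter decision and reasons) into
#' `outdir`. Byte-stable for identical inputs.
#'
#' @param report An `ensemble_report` from [run_pipeline()].
#' @param outdir Output directory (created if needed).
#' @return Named vector of the four file paths.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(filtered = file.path(outdir, "filtered.tsv"),
             unfiltered = file.path(outdir, "unfiltered.tsv"),
             singletons = file.path(outdir, "singletons.tsv"),
             audit = file.path(outdir, "audit.tsv"))
  for (ch in c("filtered", "unfiltered", "singletons")) {
    flat <- flatten_records(report[[ch]])
    flat$channel <- if (nrow(flat) > 0) ch else character(0)
    utils::write.table(flat, paths[[ch]], sep = "\t", quote = FALSE,
                       na = "", row.names = FALSE)
  }
  utils::write.table(report$audit, paths[["audit"]], sep = "\t",
                     quote = FALSE, na = "", row.names = FALSE)
  invisible(paths)
}
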