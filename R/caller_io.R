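#' Supported fusion callers
#'
#' The seven fusion-calling algorithms whose native tab-delimited output
#' dialects are understood by [parse_caller_output()].
#'
#' @return Character vector of caller identifiers.
#' @export
#' @examples
#' callers()
callers <- function() {
  c("arriba", "cicero", "fusionmap", "fusioncatcher", "jaffa",
    "mapsplice", "starfusion")
}

#' Canonical unified-call column order
#' @keywords internal
unified_columns <- function() {
  c("caller", "gene5", "gene3", "chrom5", "pos5", "strand5",
    "chrom3", "pos3", "strand3", "reads", "split_reads",
    "spanning_pairs", "junction_seq", "frame")
}

#' Caller output dialect definitions
#'
#' Loads the declarative per-caller dialect configuration that maps each
#' tool's native column layout onto the unified fusion-call model. Dialects
#' are shipped as editable JSON data rather than hard-coded adapters; a
#' custom file with the same schema may be supplied to support other caller
#' versions.
#'
#' @param path Path to a dialect JSON file. Defaults to the bundled config.
#' @return Named list of dialect definitions, one per caller.
#' @export
caller_dialects <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "dialects.json", package = "fusemble",
                        mustWork = TRUE)
  }
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}

# Pull one unified field out of the native table according to an extraction
# rule: a column name plus an optional split separator and part index.
extract_field <- function(df, rule) {
  x <- as.character(df[[rule$column]])
  if (!is.null(rule$sep)) {
    parts <- strsplit(x, rule$sep, fixed = TRUE)
    idx <- rule$index
    x <- vapply(parts, function(p) {
      if (length(p) >= idx) p[[idx]] else NA_character_
    }, character(1))
  }
  if (!is.null(rule$map)) {
    m <- unlist(rule$map)
    x <- ifelse(x %in% names(m), unname(m[x]), "unknown")
  }
  x
}

# Single chromosome namespace: no "chr" prefix, mitochondrial as "MT".
normalize_chrom <- function(x) {
  x <- sub("^chr", "", x)
  x[x == "M"] <- "MT"
  x
}

normalize_strand <- function(x) {
  x[!(x %in% c("+", "-"))] <- "."
  x
}

empty_calls <- function() {
  data.frame(
    caller = character(), gene5 = character(), gene3 = character(),
    chrom5 = character(), pos5 = integer(), strand5 = character(),
    chrom3 = character(), pos3 = integer(), strand3 = character(),
    reads = integer(), split_reads = integer(), spanning_pairs = integer(),
    junction_seq = character(), frame = character(),
    stringsAsFactors = FALSE
  )
}

#' Parse one fusion caller's native output file
#'
#' Reads a caller's tab-delimited prediction file and converts every row to
#' the unified fusion-call model: gene symbols as reported, 1-based
#' breakpoint coordinates in a normalized chromosome namespace (no "chr"
#' prefix, mitochondrial "MT"), strands as "+", "-" or "." (unknown), and a
#' single `reads` evidence count. When a dialect distinguishes split reads
#' from spanning pairs, `reads` is their sum; when it reports one count,
#' that count is used as-is.
#'
#' Rows whose gene fields cannot be parsed (empty or missing symbols) or
#' whose coordinates are not positive integers are dropped with a warning
#' reporting how many were discarded. A file with a valid header and zero
#' data rows yields an empty call set: a caller may legitimately report no
#' fusions.
#'
#' @param path Path to the caller's output file.
#' @param caller One of [callers()].
#' @param dialects Dialect set from [caller_dialects()].
#' @return A data.frame of unified calls (columns of [unified_columns()]).
#' @export
parse_caller_output <- function(path, caller, dialects = caller_dialects()) {
  if (!caller %in% names(dialects)) {
    stop("unknown caller '", caller, "'; configured dialects: ",
         paste(names(dialects), collapse = ", "), call. = FALSE)
  }
  if (!file.exists(path)) {
    stop("caller file does not exist: ", path, call. = FALSE)
  }
  d <- dialects[[caller]]
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "", check.names = FALSE,
                          colClasses = "character",
                          stringsAsFactors = FALSE)
  if (isTRUE(d$strip_leading_hash) && ncol(df) > 0) {
    names(df)[1] <- sub("^#", "", names(df)[1])
  }
  needed <- unique(vapply(d$fields, function(r) r$column, character(1)))
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    stop("file ", path, " does not match the '", caller,
         "' dialect; missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0) return(empty_calls())

  f <- d$fields
  out <- data.frame(
    caller = rep(caller, nrow(df)),
    gene5 = extract_field(df, f$gene5),
    gene3 = extract_field(df, f$gene3),
    chrom5 = normalize_chrom(extract_field(df, f$chrom5)),
    pos5 = suppressWarnings(as.integer(extract_field(df, f$pos5))),
    strand5 = normalize_strand(extract_field(df, f$strand5)),
    chrom3 = normalize_chrom(extract_field(df, f$chrom3)),
    pos3 = suppressWarnings(as.integer(extract_field(df, f$pos3))),
    strand3 = normalize_strand(extract_field(df, f$strand3)),
    stringsAsFactors = FALSE
  )
  if (!is.null(f$split_reads) && !is.null(f$spanning_pairs)) {
    out$split_reads <- suppressWarnings(
      as.integer(extract_field(df, f$split_reads)))
    out$spanning_pairs <- suppressWarnings(
      as.integer(extract_field(df, f$spanning_pairs)))
    out$reads <- out$split_reads + out$spanning_pairs
  } else {
    out$reads <- suppressWarnings(as.integer(extract_field(df, f$reads)))
    out$split_reads <- NA_integer_
    out$spanning_pairs <- NA_integer_
  }
  out$junction_seq <- if (!is.null(f$junction_seq)) {
    x <- extract_field(df, f$junction_seq)
    ifelse(is.na(x) | x == "" | x == ".", NA_character_, x)
  } else {
    NA_character_
  }
  out$frame <- if (!is.null(f$frame)) {
    extract_field(df, f$frame)
  } else {
    "unknown"
  }
  if (d$coordinate_convention == "0-based") {
    out$pos5 <- out$pos5 + 1L
    out$pos3 <- out$pos3 + 1L
  }

  bad_gene <- is.na(out$gene5) | is.na(out$gene3) |
    out$gene5 == "" | out$gene3 == ""
  bad_pos <- is.na(out$pos5) | is.na(out$pos3) |
    out$pos5 < 1L | out$pos3 < 1L
  drop <- bad_gene | bad_pos
  if (any(drop)) {
    warning(sum(drop), " row(s) in ", basename(path),
            " dropped (unparseable gene or coordinate fields)",
            call. = FALSE)
    out <- out[!drop, , drop = FALSE]
  }
  out$reads[is.na(out$reads)] <- 0L
  rownames(out) <- NULL
  out[, unified_columns()]
}

#' Write unified fusion calls to the canonical tab-delimited format
#'
#' One row per call, fixed column order, absent optional fields serialized
#' as empty strings. [read_unified_calls()] restores an identical call set.
#'
#' @param calls Unified call data.frame.
#' @param path Output path.
#' @export
write_unified_calls <- function(calls, path) {
  calls <- calls[, unified_columns(), drop = FALSE]
  utils::write.table(calls, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read calls from the canonical unified format
#'
#' @param path Path written by [write_unified_calls()].
#' @return Unified call data.frame.
#' @export
read_unified_calls <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0) return(empty_calls())
  for (col in c("pos5", "pos3", "reads", "split_reads", "spanning_pairs")) {
    df[[col]] <- suppressWarnings(as.integer(df[[col]]))
  }
  df$junction_seq[!is.na(df$junction_seq) & df$junction_seq == ""] <-
    NA_character_
  rownames(df) <- NULL
  df[, unified_columns()]
}
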