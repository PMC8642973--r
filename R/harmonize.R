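#' Load a gene-symbol alias table
#'
#' The table maps reported gene symbols (which may be outdated aliases from
#' whichever reference a caller was built against) to approved HGNC symbols,
#' with the cytogenetic band of each approved symbol. Format: tab-delimited
#' with columns `approved_symbol`, `alias`, `cytoband` (one alias per row;
#' an identity row per approved symbol is conventional but not required —
#' approved symbols are taken from the `approved_symbol` column).
#'
#' A small snapshot sufficient for the bundled fixtures ships with the
#' package; supply a full HGNC-derived table for production use.
#'
#' @param path Path to the alias TSV. Defaults to the bundled snapshot.
#' @return An `alias_table` object.
#' @export
load_alias_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "alias_table.tsv", package = "fusemble",
                        mustWork = TRUE)
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  need <- c("approved_symbol", "alias", "cytoband")
  if (!all(need %in% names(df))) {
    stop("alias table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  approved <- unique(df[, c("approved_symbol", "cytoband")])
  approved <- approved[!duplicated(approved$approved_symbol), ]
  alias_map <- split(df[, c("approved_symbol", "cytoband")], df$alias)
  structure(
    list(approved = stats::setNames(approved$cytoband,
                                    approved$approved_symbol),
         alias_map = alias_map),
    class = "alias_table"
  )
}

# Chromosome component of a cytoband string ("7q31.2" -> "7").
band_chrom <- function(band) {
  sub("^([0-9XY]+|MT).*$", "\\1", band)
}

# Arm component ("7q31.2" -> "q"); NA when absent.
band_arm <- function(band) {
  arm <- substr(sub("^([0-9XY]+|MT)", "", band), 1, 1)
  ifelse(arm %in% c("p", "q"), arm, NA_character_)
}

#' Normalize one gene symbol to its approved HGNC symbol
#'
#' Approved symbols pass through unchanged. A symbol that is an alias of
#' exactly one approved symbol converts to it. When an alias matches
#' several approved symbols, the breakpoint locus disambiguates: the
#' candidate whose cytoband lies on the locus chromosome (and arm, when
#' both are known) wins. If no candidate — or more than one — matches, or
#' no locus is available, the symbol passes through unchanged with status
#' `"unresolved"`; symbols are never dropped.
#'
#' @param symbol Reported gene symbol.
#' @param locus Optional breakpoint locus: a chromosome name, or a list
#'   with elements `chrom` and optionally `band`.
#' @param table An [load_alias_table()] object.
#' @return List with elements `symbol` (the normalized symbol) and `status`
#'   (one of `"approved"`, `"alias"`, `"band-resolved"`, `"unresolved"`).
#' @export
normalize_symbol <- function(symbol, locus = NULL, table) {
  if (symbol %in% names(table$approved)) {
    return(list(symbol = symbol, status = "approved"))
  }
  cand <- table$alias_map[[symbol]]
  if (is.null(cand) || nrow(cand) == 0) {
    return(list(symbol = symbol, status = "unresolved"))
  }
  cand <- cand[!duplicated(cand$approved_symbol), , drop = FALSE]
  if (nrow(cand) == 1) {
    return(list(symbol = cand$approved_symbol, status = "alias"))
  }
  if (!is.null(locus)) {
    chrom <- if (is.list(locus)) locus$chrom else locus
    arm <- if (is.list(locus) && !is.null(locus$band)) {
      band_arm(paste0(chrom, locus$band))
    } else {
      NA_character_
    }
    hit <- band_chrom(cand$cytoband) == chrom
    if (!is.na(arm)) {
      cand_arm <- band_arm(cand$cytoband)
      hit <- hit & (is.na(cand_arm) | cand_arm == arm)
    }
    if (sum(hit) == 1) {
      return(list(symbol = cand$approved_symbol[hit],
                  status = "band-resolved"))
    }
  }
  list(symbol = symbol, status = "unresolved")
}

#' Harmonize all gene symbols in a call set
#'
#' Applies [normalize_symbol()] to the 5' and 3' gene of every call, using
#' the call's own breakpoint chromosome as the disambiguating locus. All
#' other fields are untouched; the number of calls never changes.
#' Harmonization is idempotent. Unresolved symbols are reported once as a
#' warning naming the symbols.
#'
#' @param calls Unified call data.frame.
#' @param table An [load_alias_table()] object.
#' @return The call data.frame with harmonized `gene5`/`gene3`.
#' @export
harmonize_calls <- function(calls, table) {
  if (nrow(calls) == 0) return(calls)
  resolve <- function(symbols, chroms) {
    key <- paste(symbols, chroms)
    uniq <- !duplicated(key)
    res <- mapply(function(s, ch) normalize_symbol(s, ch, table),
                  symbols[uniq], chroms[uniq], SIMPLIFY = FALSE)
    names(res) <- key[uniq]
    out <- vapply(res, `[[`, character(1), "symbol")[key]
    status <- vapply(res, `[[`, character(1), "status")[key]
    list(symbol = unname(out), status = unname(status))
  }
  r5 <- resolve(calls$gene5, calls$chrom5)
  r3 <- resolve(calls$gene3, calls$chrom3)
  unres <- unique(c(calls$gene5[r5$status == "unresolved"],
                    calls$gene3[r3$status == "unresolved"]))
  if (length(unres) > 0) {
    warning("unresolved gene symbols pass through unchanged: ",
            paste(sort(unres), collapse = ", "), call. = FALSE)
  }
  calls$gene5 <- r5$symbol
  calls$gene3 <- r3$symbol
  calls
}
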