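#' Load the known-fusion list
#'
#' Reads a curated list of unordered gene-symbol pairs with established
#' oncogenic relevance (tab-delimited, columns `gene_a`, `gene_b`), used
#' both to rescue filtered consensus calls and to score gene partners.
#' Pairs are deduplicated under order swap. For every gene the partner
#' frequency `f` — the number of list pairs containing it — is computed,
#' along with the maximum `f_max` and the set of common partners
#' (`f >= 3`), each carrying a pathogenic frequency score and a gene-type
#' descriptor.
#'
#' @param path Path to the pair TSV. Defaults to the bundled seed list.
#' @param gene_types Optional named character vector mapping gene symbol to
#'   a free-text type descriptor; defaults to the bundled gene annotation.
#' @param score_method Passed to [pathogenic_frequency_score()].
#' @return A `known_fusion_list` object with elements `pairs` (data.frame
#'   gene_a, gene_b, pair), `partner_frequency` (named integer), `f_max`,
#'   and `common_partners` (data.frame gene, f, frequency_score,
#'   gene_type).
#' @export
load_known_list <- function(path = NULL, gene_types = NULL,
                            score_method = c("ratio", "reciprocal")) {
  score_method <- match.arg(score_method)
  if (is.null(path)) {
    path <- system.file("extdata", "known_fusions.tsv",
                        package = "fusemble", mustWork = TRUE)
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) {
    stop("known fusion list must have two gene columns", call. = FALSE)
  }
  bad <- which(is.na(df[[1]]) | is.na(df[[2]]) |
                 df[[1]] == "" | df[[2]] == "")
  if (length(bad) > 0) {
    stop("malformed known-list row(s) at line(s): ",
         paste(bad + 1, collapse = ", "), call. = FALSE)
  }
  known_fusion_list(df[[1]], df[[2]], gene_types = gene_types,
                    score_method = score_method)
}

#' Construct a known-fusion list from gene pair vectors
#'
#' @param gene_a,gene_b Gene symbol vectors (one pair per element).
#' @param gene_types,score_method See [load_known_list()].
#' @return A `known_fusion_list` object.
#' @export
known_fusion_list <- function(gene_a, gene_b, gene_types = NULL,
                              score_method = c("ratio", "reciprocal")) {
  score_method <- match.arg(score_method)
  if (is.null(gene_types)) gene_types <- bundled_gene_types()
  key <- pair_key(gene_a, gene_b)
  keep <- !duplicated(key)
  pairs <- data.frame(gene_a = pmin(gene_a, gene_b)[keep],
                      gene_b = pmax(gene_a, gene_b)[keep],
                      pair = key[keep], stringsAsFactors = FALSE)
  f <- table(c(pairs$gene_a, pairs$gene_b))
  partner_frequency <- stats::setNames(as.integer(f), names(f))
  f_max <- if (length(partner_frequency) > 0) {
    max(partner_frequency)
  } else {
    0L
  }
  common <- partner_frequency[partner_frequency >= 3L]
  common_partners <- data.frame(
    gene = names(common),
    f = unname(common),
    frequency_score = pathogenic_frequency_score(unname(common), f_max,
                                                 method = score_method),
    gene_type = ifelse(names(common) %in% names(gene_types),
                       unname(gene_types[names(common)]), "unknown"),
    stringsAsFactors = FALSE
  )
  structure(list(pairs = pairs, partner_frequency = partner_frequency,
                 f_max = f_max, common_partners = common_partners,
                 score_method = score_method),
            class = "known_fusion_list")
}

bundled_gene_types <- function() {
  path <- system.file("extdata", "mock_gene_annotation.tsv",
                      package = "fusemble", mustWork = TRUE)
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(ann$gene_type, ann$symbol)
}

#' Gene Partner Predicted Pathogenicity Score
#'
#' Scores a gene by how often it appears as a partner on the known-fusion
#' list. The score ranges from 10 (the most frequent partner, `f = f_max`)
#' down to 1 (least frequent, but present at least 3 times); genes seen
#' fewer than 3 times are not scored (`NA`).
#'
#' The default mapping is `clamp(round(10 * f / f_max), 1, 10)` for
#' `f >= 3`, which is monotone in `f` and meets both published endpoints.
#' `method = "reciprocal"` instead applies the literal published formula
#' `10 / (f_max - f)`, retained for comparison only: it is undefined at
#' `f = f_max` (returned as 10) and is not integer-valued or bounded in
#' between.
#'
#' @param f Partner frequency (count of list pairs containing the gene).
#' @param f_max Maximum partner frequency on the list; `f <= f_max`.
#' @param method `"ratio"` (default) or `"reciprocal"`.
#' @return Numeric vector of scores; `NA` where `f < 3`.
#' @export
pathogenic_frequency_score <- function(f, f_max,
                                       method = c("ratio", "reciprocal")) {
  method <- match.arg(method)
  if (any(f > f_max)) stop("f must not exceed f_max", call. = FALSE)
  if (any(f < 0)) stop("f must be non-negative", call. = FALSE)
  out <- rep(NA_real_, length(f))
  eligible <- f >= 3
  if (method == "ratio") {
    out[eligible] <- pmin(10, pmax(1, round(10 * f[eligible] / f_max)))
  } else {
    out[eligible] <- ifelse(f[eligible] == f_max, 10,
                            10 / (f_max - f[eligible]))
  }
  out
}

#' Annotate consensus records with known-partner information
#'
#' Adds, for each record: whether the exact unordered pair is on the known
#' list (`known_pair`), and per-gene partner annotations — known-partner
#' designation (partner frequency at least 3), pathogenic frequency score,
#' and gene-type descriptor. Record order and evidence fields are never
#' altered.
#'
#' @param records Consensus record data.frame.
#' @param known A `known_fusion_list`.
#' @return `records` with annotation columns `known_pair`,
#'   `gene_a_known_partner`, `gene_a_score`, `gene_a_type`, and the
#'   `gene_b_*` equivalents.
#' @export
annotate_known <- function(records, known) {
  cp <- known$common_partners
  lookup <- function(genes, col, default) {
    i <- match(genes, cp$gene)
    out <- cp[[col]][i]
    out[is.na(i)] <- default
    out
  }
  records$known_pair <- records$pair %in% known$pairs$pair
  for (side in c("gene_a", "gene_b")) {
    g <- records[[side]]
    records[[paste0(side, "_known_partner")]] <- g %in% cp$gene
    records[[paste0(side, "_score")]] <-
      if (nrow(records) > 0) lookup(g, "frequency_score", NA_real_)
      else numeric(0)
    records[[paste0(side, "_type")]] <-
      if (nrow(records) > 0) lookup(g, "gene_type", NA_character_)
      else character(0)
  }
  records
}

#' Extract the singleton channel
#'
#' Known-list fusions supported by a single caller are too weakly supported
#' for the main output (even rescue requires two callers) but are emitted
#' on a supplementary channel for manual review, so that a pathogenic
#' fusion seen by one caller with minimal evidence is never silently lost.
#'
#' @param records The full (unfiltered) consensus record set.
#' @param known A `known_fusion_list`.
#' @return The records with `caller_count == 1` whose pair is on the list.
#' @export
extract_singletons <- function(records, known) {
  keep <- records$caller_count == 1L & records$pair %in% known$pairs$pair
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
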