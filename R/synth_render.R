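# Renderers that write planted unified calls back out in each caller's
# native dialect. These are the synthesis-side mirrors of the dialect
# parsers; round-tripping through parse_caller_output() is covered by the
# test suite. Some dialects deliberately exercise parser normalization:
# mapsplice uses 0-based coordinates and "chr"-prefixed joint chromosome
# strings, jaffa and starfusion use "chr" prefixes.

or_dot <- function(x) ifelse(is.na(x) | x == "", ".", x)

render_arriba <- function(m) {
  split <- ifelse(is.na(m$split_reads), m$reads, m$split_reads)
  span <- ifelse(is.na(m$spanning_pairs), 0L, m$spanning_pairs)
  df <- data.frame(
    gene1 = m$gene5, gene2 = m$gene3,
    s1 = paste0(m$strand5, "/", m$strand5),
    s2 = paste0(m$strand3, "/", m$strand3),
    breakpoint1 = paste0(m$chrom5, ":", m$pos5),
    breakpoint2 = paste0(m$chrom3, ":", m$pos3),
    split_reads = split, discordant_mates = span,
    reading_frame = ifelse(m$frame == "unknown", ".", m$frame),
    fusion_transcript = or_dot(m$junction_seq),
    stringsAsFactors = FALSE
  )
  names(df) <- c("#gene1", "gene2", "strand1(gene/fusion)",
                 "strand2(gene/fusion)", "breakpoint1", "breakpoint2",
                 "split_reads", "discordant_mates", "reading_frame",
                 "fusion_transcript")
  df
}

render_cicero <- function(m) {
  data.frame(
    geneA = m$gene5, chrA = m$chrom5, posA = m$pos5, ortA = m$strand5,
    geneB = m$gene3, chrB = m$chrom3, posB = m$pos3, ortB = m$strand3,
    readsA = m$reads, contig = or_dot(m$junction_seq),
    stringsAsFactors = FALSE, check.names = FALSE
  )
}

render_fusionmap <- function(m) {
  data.frame(
    FusionID = sprintf("FUS_%05d", seq_len(nrow(m))),
    KnownGene1 = m$gene5, Chromosome1 = m$chrom5, Position1 = m$pos5,
    KnownGene2 = m$gene3, Chromosome2 = m$chrom3, Position2 = m$pos3,
    Strand = paste0(m$strand5, m$strand3),
    SeedCount = m$reads,
    stringsAsFactors = FALSE
  )
}

render_fusioncatcher <- function(m) {
  split <- ifelse(is.na(m$split_reads), m$reads, m$split_reads)
  span <- ifelse(is.na(m$spanning_pairs), 0L, m$spanning_pairs)
  df <- data.frame(
    g1 = m$gene5, g2 = m$gene3,
    p1 = paste(m$chrom5, m$pos5, m$strand5, sep = ":"),
    p2 = paste(m$chrom3, m$pos3, m$strand3, sep = ":"),
    Spanning_pairs = span, Spanning_unique_reads = split,
    Predicted_effect = m$frame,
    stringsAsFactors = FALSE
  )
  names(df) <- c("Gene_1_symbol(5end_fusion_partner)",
                 "Gene_2_symbol(3end_fusion_partner)",
                 "Fusion_point_for_gene_1(5end_fusion_partner)",
                 "Fusion_point_for_gene_2(3end_fusion_partner)",
                 "Spanning_pairs", "Spanning_unique_reads",
                 "Predicted_effect")
  df
}

render_jaffa <- function(m) {
  split <- ifelse(is.na(m$split_reads), m$reads, m$split_reads)
  span <- ifelse(is.na(m$spanning_pairs), 0L, m$spanning_pairs)
  df <- data.frame(
    genes = paste0(m$gene5, ":", m$gene3),
    chrom1 = paste0("chr", m$chrom5), base1 = m$pos5,
    strand1 = m$strand5,
    chrom2 = paste0("chr", m$chrom3), base2 = m$pos3,
    strand2 = m$strand3,
    sp = span, sr = split,
    inFrame = ifelse(m$frame == "in-frame", "TRUE",
                     ifelse(m$frame == "out-of-frame", "FALSE", "NA")),
    classification = rep("HighConfidence", nrow(m)),
    stringsAsFactors = FALSE
  )
  names(df) <- c("fusion genes", "chrom1", "base1", "strand1", "chrom2",
                 "base2", "strand2", "spanning pairs", "spanning reads",
                 "inFrame", "classification")
  df
}

render_mapsplice <- function(m) {
  data.frame(
    chrom = paste0("chr", m$chrom5, "~chr", m$chrom3),
    doner_end = m$pos5 - 1L, acceptor_start = m$pos3 - 1L,
    coverage = m$reads,
    strand = paste0(m$strand5, m$strand3),
    annotated_gene_donor = m$gene5,
    annotated_gene_acceptor = m$gene3,
    stringsAsFactors = FALSE
  )
}

render_starfusion <- function(m) {
  split <- ifelse(is.na(m$split_reads), m$reads, m$split_reads)
  span <- ifelse(is.na(m$spanning_pairs), 0L, m$spanning_pairs)
  df <- data.frame(
    FusionName = paste0(m$gene5, "--", m$gene3),
    JunctionReadCount = split, SpanningFragCount = span,
    LeftBreakpoint = paste(paste0("chr", m$chrom5), m$pos5, m$strand5,
                           sep = ":"),
    RightBreakpoint = paste(paste0("chr", m$chrom3), m$pos3, m$strand3,
                            sep = ":"),
    stringsAsFactors = FALSE
  )
  names(df)[1] <- "#FusionName"
  df
}

dialect_renderers <- function() {
  list(arriba = render_arriba, cicero = render_cicero,
       fusionmap = render_fusionmap, fusioncatcher = render_fusioncatcher,
       jaffa = render_jaffa, mapsplice = render_mapsplice,
       starfusion = render_starfusion)
}

#' Write planted calls as native per-caller dialect files
#'
#' @param manifest Manifest data.frame (unified columns plus `category`).
#' @param caller_set Callers to write (one file each; a caller with no
#'   rows gets a header-only file).
#' @param dir Output directory.
#' @return Named character vector of file paths.
#' @keywords internal
write_caller_files <- function(manifest, caller_set, dir) {
  renderers <- dialect_renderers()
  unknown <- setdiff(caller_set, names(renderers))
  if (length(unknown) > 0) {
    stop("no dialect renderer for caller(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  paths <- stats::setNames(
    file.path(dir, paste0(caller_set, ".tsv")), caller_set)
  for (cl in caller_set) {
    m <- manifest[manifest$caller == cl, , drop = FALSE]
    df <- if (nrow(m) == 0) {
      # paste() treats zero-length inputs as "", so render a placeholder
      # row and truncate to get a header-only frame
      template <- data.frame(
        category = "x", caller = cl, gene5 = "G1", gene3 = "G2",
        chrom5 = "1", pos5 = 1L, strand5 = "+", chrom3 = "2", pos3 = 1L,
        strand3 = "+", reads = 1L, split_reads = 1L,
        spanning_pairs = 0L, junction_seq = NA_character_,
        frame = "unknown", stringsAsFactors = FALSE)
      renderers[[cl]](template)[0, , drop = FALSE]
    } else {
      renderers[[cl]](m)
    }
    utils::write.table(df, paths[[cl]], sep = "\t", quote = FALSE,
                       na = "", row.names = FALSE, col.names = TRUE)
  }
  paths
}
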