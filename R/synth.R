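#' Load the bundled gene annotation
#'
#' A small synthetic stand-in for a genome annotation: approximate
#' coordinates, strand, cytogenetic band and a type descriptor for ~50
#' genes recurrently involved in oncogenic fusions, plus deterministic
#' filler genes (`SYN*`) laid out so that each autosome carries a
#' same-strand neighbouring pair less than 200 kb apart (read-through
#' material) and several well-separated genes (false-positive material).
#' Distances and bands are therefore well-defined without any genome
#' download. Not a real reference; coordinates are approximate.
#'
#' @param path Optional path to an alternative annotation TSV with columns
#'   symbol, chrom, start, end, strand, band, gene_type.
#' @return data.frame of gene records.
#' @export
load_gene_annotation <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "mock_gene_annotation.tsv",
                        package = "fusemble", mustWork = TRUE)
  }
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(chrom = "character"))
}

#' Specification of a synthetic per-caller fixture
#'
#' Declares the planted content of a synthetic multi-caller dataset: true
#' fusions (optionally drawn from the known-fusion list), read-through
#' artifacts (same-strand neighbours under 200 kb), recurrent cohort
#' artifacts (pre-registered above 10% detection frequency), low-evidence
#' decoys (multi-caller but every read count below 4), single-caller
#' known-list fusions (singleton-channel material), and per-caller unique
#' false positives with a skewed low read distribution.
#'
#' Default counts emulate a reference-standard experiment: 14 true fusions
#' all on the known list, a caller-count distribution skewed towards
#' full 7-caller consensus, a 22-sample cohort in the frequency store with
#' recurrent pairs observed in 7 of 22 samples (31.8%), and per-caller
#' false-positive burdens shaped like the relative burdens of the seven
#' real callers (CICERO and JAFFA noisiest), scaled down ~10x for desk-
#' scale runtimes.
#'
#' @param seed Integer random seed; the same spec and seed yield a
#'   byte-identical fixture.
#' @param n_true Number of planted true fusions.
#' @param true_caller_counts Named weight vector over caller counts
#'   `"3"`..`"7"` from which each true fusion's support is drawn.
#' @param n_readthrough,n_recurrent,n_low_evidence,n_singleton_known
#'   Counts of the artifact categories.
#' @param per_caller_fp Named integer vector: unique false positives per
#'   caller; its names define which callers are simulated.
#' @param known_list_fraction Fraction of true fusions taken from the
#'   known list (the first `n` list pairs, in list order, so the planted
#'   truth is stable across seeds); the rest are random filler pairs.
#' @param cohort_size,recurrent_in Frequency-store cohort size and the
#'   number of samples in which each recurrent pair is observed.
#' @param recurrent_truth Pair keys among the planted truth that are also
#'   pre-registered as recurrent (emulating a true fusion sitting at
#'   artificially high cohort frequency, e.g. from one caller's systematic
#'   false calls); only applied when the pair is actually planted.
#' @param read_mean Mean supporting reads for true and artifact calls.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 7L,
                         n_true = 14L,
                         true_caller_counts = c("3" = 0.04, "4" = 0.06,
                                                "5" = 0.064, "6" = 0.194,
                                                "7" = 0.642),
                         n_readthrough = 3L,
                         n_recurrent = 3L,
                         n_low_evidence = 2L,
                         n_singleton_known = 1L,
                         per_caller_fp = c(arriba = 10L, cicero = 130L,
                                           fusionmap = 14L,
                                           fusioncatcher = 60L,
                                           jaffa = 90L, mapsplice = 8L,
                                           starfusion = 15L),
                         known_list_fraction = 1,
                         cohort_size = 22L,
                         recurrent_in = 7L,
                         recurrent_truth = "ALK|EML4",
                         read_mean = 30) {
  stopifnot(n_true >= 0, n_readthrough >= 0, n_recurrent >= 0,
            n_low_evidence >= 0, n_singleton_known >= 0,
            known_list_fraction >= 0, known_list_fraction <= 1,
            cohort_size >= 1, recurrent_in >= 0,
            recurrent_in <= cohort_size, all(per_caller_fp >= 0))
  if (is.null(names(per_caller_fp))) {
    stop("per_caller_fp must be named by caller", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), n_true = as.integer(n_true),
                 true_caller_counts = true_caller_counts,
                 n_readthrough = as.integer(n_readthrough),
                 n_recurrent = as.integer(n_recurrent),
                 n_low_evidence = as.integer(n_low_evidence),
                 n_singleton_known = as.integer(n_singleton_known),
                 per_caller_fp = per_caller_fp,
                 known_list_fraction = known_list_fraction,
                 cohort_size = as.integer(cohort_size),
                 recurrent_in = as.integer(recurrent_in),
                 recurrent_truth = recurrent_truth,
                 read_mean = read_mean),
            class = "fixture_spec")
}

# Run expr with a private, seeded RNG state, restoring the caller's state.
with_fixture_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

random_position <- function(ann, symbol) {
  g <- ann[ann$symbol == symbol, ]
  as.integer(sample(seq(g$start, g$end), 1))
}

gene_field <- function(ann, symbol, field) {
  ann[[field]][match(symbol, ann$symbol)]
}

# One planted call row in the unified schema plus provenance columns.
planted_row <- function(category, caller, gene5, gene3, pos5, pos3, ann,
                        reads, dual = NA) {
  if (is.na(dual)) dual <- caller %in% c("arriba", "fusioncatcher",
                                         "jaffa", "starfusion")
  if (dual) {
    split <- as.integer(ceiling(reads * 0.6))
    span <- as.integer(reads - split)
  } else {
    split <- NA_integer_
    span <- NA_integer_
  }
  data.frame(
    category = category, caller = caller,
    gene5 = gene5, gene3 = gene3,
    chrom5 = gene_field(ann, gene5, "chrom"),
    pos5 = as.integer(pos5),
    strand5 = gene_field(ann, gene5, "strand"),
    chrom3 = gene_field(ann, gene3, "chrom"),
    pos3 = as.integer(pos3),
    strand3 = gene_field(ann, gene3, "strand"),
    reads = as.integer(reads), split_reads = split,
    spanning_pairs = span,
    junction_seq = paste(sample(c("A", "C", "G", "T"), 20,
                                replace = TRUE), collapse = ""),
    frame = sample(c("in-frame", "out-of-frame", "unknown"), 1,
                   prob = c(0.5, 0.3, 0.2)),
    stringsAsFactors = FALSE
  )
}

# Sample n unique cross-chromosome filler-gene pairs not already used.
sample_filler_pairs <- function(n, ann, used) {
  filler <- ann$symbol[startsWith(ann$symbol, "SYN")]
  out <- character(0)
  pairs <- list()
  while (length(pairs) < n) {
    g <- sample(filler, 2)
    if (gene_field(ann, g[1], "chrom") == gene_field(ann, g[2], "chrom")) {
      next
    }
    k <- pair_key(g[1], g[2])
    if (k %in% used || k %in% out) next
    out <- c(out, k)
    pairs[[length(pairs) + 1]] <- g
  }
  pairs
}

# Build the full planted-call manifest and companion objects in memory.
build_fixture <- function(spec, known, ann) {
  caller_set <- names(spec$per_caller_fp)
  n_known <- round(spec$n_true * spec$known_list_fraction)
  if (n_known > 0 && nrow(known$pairs) == 0) {
    stop("known_list_fraction > 0 requires a non-empty known list",
         call. = FALSE)
  }
  if (n_known > nrow(known$pairs)) {
    stop("known list has too few pairs for the requested truth",
         call. = FALSE)
  }
  rows <- list()
  used <- character(0)

  # --- true fusions -------------------------------------------------------
  truth_pairs <- list()
  if (n_known > 0) {
    for (i in seq_len(n_known)) {
      truth_pairs[[i]] <- c(known$pairs$gene_a[i], known$pairs$gene_b[i])
    }
  }
  if (spec$n_true > n_known) {
    extra <- sample_filler_pairs(spec$n_true - n_known, ann, used)
    truth_pairs <- c(truth_pairs, extra)
  }
  used <- c(used, vapply(truth_pairs,
                         function(g) pair_key(g[1], g[2]), character(1)))
  counts_avail <- intersect(as.integer(names(spec$true_caller_counts)),
                            seq_len(length(caller_set)))
  for (g in truth_pairs) {
    w <- spec$true_caller_counts[as.character(counts_avail)]
    k <- counts_avail[sample.int(length(counts_avail), 1, prob = w)]
    support <- sample(caller_set, k)
    pos5 <- random_position(ann, g[1])
    pos3 <- random_position(ann, g[2])
    reads <- stats::rpois(k, spec$read_mean)
    reads[1] <- max(reads[1], 5L)  # at least one caller with >= 4 reads
    for (j in seq_len(k)) {
      # discordant breakpoints for part of the support, to exercise
      # breakpoint reconciliation
      jit <- if (j > 2) sample(-2:2, 2, replace = TRUE) else c(0L, 0L)
      rows[[length(rows) + 1]] <-
        planted_row("true", support[j], g[1], g[2],
                    pos5 + jit[1], pos3 + jit[2], ann, max(reads[j], 1L))
    }
  }
  truth <- if (length(truth_pairs) > 0) {
    truth_set(vapply(truth_pairs, `[`, character(1), 1),
              vapply(truth_pairs, `[`, character(1), 2),
              label = "planted truth")
  } else {
    # negative control: an empty truth (sensitivity is undefined, but the
    # planted-pair set is still well-defined)
    structure(list(pairs = data.frame(gene_a = character(),
                                      gene_b = character(),
                                      pair = character(),
                                      stringsAsFactors = FALSE),
                   label = "planted truth (empty)"),
              class = "truth_set")
  }

  # --- read-through artifacts: SYNA/SYNB neighbours, < 200 kb apart ------
  rt_chroms <- sample(1:22, spec$n_readthrough)
  for (c in rt_chroms) {
    g5 <- paste0("SYNA", c); g3 <- paste0("SYNB", c)
    used <- c(used, pair_key(g5, g3))
    support <- sample(caller_set, min(sample(3:5, 1), length(caller_set)))
    pos5 <- random_position(ann, g5)
    pos3 <- random_position(ann, g3)
    for (cl in support) {
      rows[[length(rows) + 1]] <-
        planted_row("readthrough", cl, g5, g3, pos5, pos3, ann,
                    stats::rpois(1, spec$read_mean) + 4L)
    }
  }

  # --- recurrent cohort artifacts ----------------------------------------
  rec_pairs <- sample_filler_pairs(spec$n_recurrent, ann, used)
  rec_keys <- vapply(rec_pairs, function(g) pair_key(g[1], g[2]),
                     character(1))
  used <- c(used, rec_keys)
  for (g in rec_pairs) {
    support <- sample(caller_set, min(sample(3:5, 1), length(caller_set)))
    pos5 <- random_position(ann, g[1])
    pos3 <- random_position(ann, g[2])
    for (cl in support) {
      rows[[length(rows) + 1]] <-
        planted_row("recurrent", cl, g[1], g[2], pos5, pos3, ann,
                    stats::rpois(1, spec$read_mean) + 4L)
    }
  }

  # --- low-evidence decoys: enough callers, every read count < 4 ---------
  le_pairs <- sample_filler_pairs(spec$n_low_evidence, ann, used)
  used <- c(used, vapply(le_pairs, function(g) pair_key(g[1], g[2]),
                         character(1)))
  for (g in le_pairs) {
    support <- sample(caller_set, min(3L, length(caller_set)))
    pos5 <- random_position(ann, g[1])
    pos3 <- random_position(ann, g[2])
    for (cl in support) {
      rows[[length(rows) + 1]] <-
        planted_row("low_evidence", cl, g[1], g[2], pos5, pos3, ann,
                    sample(1:3, 1))
    }
  }

  # --- single-caller known-list fusions (singleton channel) --------------
  single_candidates <- known$pairs[!(known$pairs$pair %in% used), ,
                                   drop = FALSE]
  n_single <- min(spec$n_singleton_known, nrow(single_candidates))
  if (n_single > 0) {
    for (i in seq_len(n_single)) {
      g5 <- single_candidates$gene_a[i]
      g3 <- single_candidates$gene_b[i]
      used <- c(used, single_candidates$pair[i])
      cl <- if ("jaffa" %in% caller_set) "jaffa" else caller_set[1]
      rows[[length(rows) + 1]] <-
        planted_row("singleton_known", cl, g5, g3,
                    random_position(ann, g5), random_position(ann, g3),
                    ann, 1L)
    }
  }

  # --- per-caller unique false positives ---------------------------------
  for (cl in names(spec$per_caller_fp)) {
    n_fp <- spec$per_caller_fp[[cl]]
    if (n_fp == 0) next
    fp_pairs <- sample_filler_pairs(n_fp, ann, used)
    used <- c(used, vapply(fp_pairs, function(g) pair_key(g[1], g[2]),
                           character(1)))
    for (g in fp_pairs) {
      rows[[length(rows) + 1]] <-
        planted_row("false_positive", cl, g[1], g[2],
                    random_position(ann, g[1]),
                    random_position(ann, g[2]), ann,
                    stats::rgeom(1, 0.5) + 1L)
    }
  }

  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL

  # --- frequency store: cohort with the recurrent pairs at high frequency
  store <- cohort_store(samples = sprintf("COHORT%02d",
                                          seq_len(spec$cohort_size)))
  hot <- c(rec_keys, intersect(spec$recurrent_truth, truth$pairs$pair))
  for (k in hot) {
    store$observations[[k]] <-
      sprintf("COHORT%02d", seq_len(spec$recurrent_in))
  }
  list(manifest = manifest, truth = truth, store = store, known = known)
}

#' Generate a deterministic synthetic multi-caller fixture
#'
#' Materializes a [fixture_spec()] as one native-dialect output file per
#' caller, together with the planted truth set, a pre-populated cohort
#' frequency store, the known-fusion list used, and a manifest attributing
#' every written row to its planted category. The same spec and seed
#' produce byte-identical files.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @param known A `known_fusion_list` (default: bundled seed list).
#' @param annotation Gene annotation (default: bundled).
#' @return A `fixture_bundle` list: `caller_files` (named paths), `truth`,
#'   `store`, `known`, `manifest`, `spec`.
#' @export
generate_fixture <- function(spec, dir,
                             known = load_known_list(),
                             annotation = load_gene_annotation()) {
  bundle <- with_fixture_seed(spec$seed,
                              build_fixture(spec, known, annotation))
  bundle$spec <- spec
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  bundle$caller_files <- write_caller_files(bundle$manifest,
                                            names(spec$per_caller_fp), dir)
  utils::write.table(bundle$manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  save_cohort_store(bundle$store, file.path(dir, "cohort_store.json"))
  class(bundle) <- "fixture_bundle"
  bundle
}

#' Dilution series of a fixture
#'
#' Emulates serial dilution of a reference standard: at dilution factor
#' `d` every true fusion's read counts are scaled by `d` (rounded down,
#' per evidence class where the caller distinguishes split reads from
#' spanning pairs) and a call is dropped from a caller once its scaled
#' reads reach 0. Artifact and false-positive rows are left at full
#' strength, as their origin is not the diluted analyte. Recovery of true
#' fusions is monotone non-increasing in dilution.
#'
#' @param spec A [fixture_spec()].
#' @param dilution_factors Numeric vector of factors in (0, 1].
#' @param dir Parent output directory; one subdirectory per factor.
#' @param known,annotation As in [generate_fixture()].
#' @return List of `fixture_bundle`s, one per factor.
#' @export
dilution_series <- function(spec, dilution_factors, dir,
                            known = load_known_list(),
                            annotation = load_gene_annotation()) {
  stopifnot(all(dilution_factors > 0), all(dilution_factors <= 1))
  base <- with_fixture_seed(spec$seed,
                            build_fixture(spec, known, annotation))
  lapply(seq_along(dilution_factors), function(i) {
    d <- dilution_factors[i]
    bundle <- base
    bundle$spec <- spec
    m <- bundle$manifest
    tr <- m$category == "true"
    dual <- tr & !is.na(m$split_reads)
    m$split_reads[dual] <- as.integer(floor(m$split_reads[dual] * d))
    m$spanning_pairs[dual] <-
      as.integer(floor(m$spanning_pairs[dual] * d))
    m$reads[dual] <- m$split_reads[dual] + m$spanning_pairs[dual]
    single <- tr & is.na(m$split_reads)
    m$reads[single] <- as.integer(floor(m$reads[single] * d))
    m <- m[!(tr & m$reads == 0L), , drop = FALSE]
    rownames(m) <- NULL
    bundle$manifest <- m
    sub <- file.path(dir, sprintf("dilution_%03d", i))
    dir.create(sub, recursive = TRUE, showWarnings = FALSE)
    bundle$caller_files <-
      write_caller_files(m, names(spec$per_caller_fp), sub)
    class(bundle) <- "fixture_bundle"
    bundle
  })
}
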