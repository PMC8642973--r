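# Shared test helpers: a unified-call constructor, a brute-force overlap
# oracle, and an independent rule evaluator that predicts the kept set of
# a fixture straight from its manifest. The oracles deliberately avoid the
# package's grouping and filtering code paths.

make_call <- function(caller = "arriba", gene5 = "AAA", gene3 = "BBB",
                      chrom5 = "1", pos5 = 1000L, strand5 = "+",
                      chrom3 = "2", pos3 = 2000L, strand3 = "+",
                      reads = 10L, split_reads = NA_integer_,
                      spanning_pairs = NA_integer_,
                      junction_seq = NA_character_, frame = "unknown") {
  data.frame(caller = caller, gene5 = gene5, gene3 = gene3,
             chrom5 = chrom5, pos5 = as.integer(pos5), strand5 = strand5,
             chrom3 = chrom3, pos3 = as.integer(pos3), strand3 = strand3,
             reads = as.integer(reads),
             split_reads = as.integer(split_reads),
             spanning_pairs = as.integer(spanning_pairs),
             junction_seq = junction_seq, frame = frame,
             stringsAsFactors = FALSE)
}

# Brute-force all-pairs grouping: two calls belong together iff their
# unordered gene sets are equal. Implemented by linear scan against group
# representatives, no keying.
oracle_overlap <- function(calls_by_caller) {
  pooled <- do.call(rbind, unname(calls_by_caller))
  groups <- list()
  for (i in seq_len(nrow(pooled))) {
    g5 <- pooled$gene5[i]; g3 <- pooled$gene3[i]
    placed <- FALSE
    for (j in seq_along(groups)) {
      rep_row <- groups[[j]][1, ]
      if (setequal(c(g5, g3), c(rep_row$gene5, rep_row$gene3))) {
        groups[[j]] <- rbind(groups[[j]], pooled[i, ])
        placed <- TRUE
        break
      }
    }
    if (!placed) groups[[length(groups) + 1]] <- pooled[i, ]
  }
  out <- lapply(groups, function(g) {
    genes <- sort(unique(c(g$gene5, g$gene3)))
    if (length(genes) == 1) genes <- c(genes, genes)
    data.frame(pair = paste(genes[1], genes[2], sep = "|"),
               caller_count = length(unique(g$caller)),
               n_calls = nrow(g),
               max_reads = max(g$reads),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out[order(out$pair), ]
}

# Independent rule evaluator: expected kept pair set from a fixture
# manifest, the frequency store internals and the known list, by literal
# application of the consensus/filter/rescue rules.
oracle_expected_kept <- function(manifest, store, known,
                                 min_callers = 3, min_reads = 4,
                                 max_freq = 0.10, rt_dist = 200000,
                                 known_min = 2) {
  key <- paste(pmin(manifest$gene5, manifest$gene3),
               pmax(manifest$gene5, manifest$gene3), sep = "|")
  kept <- character(0)
  for (k in unique(key)) {
    g <- manifest[key == k, ]
    n_callers <- length(unique(g$caller))
    best <- g[which.max(g$reads), ]
    rt <- best$chrom5 == best$chrom3 &&
      best$strand5 %in% c("+", "-") && best$strand5 == best$strand3 &&
      abs(best$pos5 - best$pos3) < rt_dist
    freq <- if (length(store$samples) > 0) {
      length(store$observations[[k]]) / length(store$samples)
    } else 0
    clean <- n_callers >= min_callers && !rt && freq <= max_freq &&
      max(g$reads) >= min_reads
    rescued <- k %in% known$pairs$pair && n_callers >= known_min
    if (clean || rescued) kept <- c(kept, k)
  }
  sort(kept)
}

# Tiny random call sets for property tests.
random_calls_by_caller <- function(n_callers = 3, max_calls = 10,
                                   gene_pool = LETTERS[1:8]) {
  cls <- sample(callers(), n_callers)
  out <- lapply(cls, function(cl) {
    n <- sample(0:max_calls, 1)
    if (n == 0) return(make_call(caller = cl)[0, ])
    do.call(rbind, lapply(seq_len(n), function(i) {
      g <- sample(gene_pool, 2)
      make_call(caller = cl, gene5 = g[1], gene3 = g[2],
                chrom5 = sample(c("1", "2", "7"), 1),
                pos5 = sample(1e6, 1),
                chrom3 = sample(c("1", "2", "7"), 1),
                pos3 = sample(1e6, 1),
                reads = sample(0:50, 1))
    }))
  })
  names(out) <- cls
  out
}

seraseq_spec <- function(seed = 7L, ...) fixture_spec(seed = seed, ...)
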