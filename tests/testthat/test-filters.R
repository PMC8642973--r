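# Build a one-row consensus record data.frame with chosen best breakpoints.
rec_row <- function(gene_a = "AAA", gene_b = "BBB", caller_count = 3L,
                    max_reads = 20L, chrom5 = "1", pos5 = 1e6L,
                    strand5 = "+", chrom3 = "2", pos3 = 2e6L,
                    strand3 = "+", per_caller_reads = max_reads) {
  calls <- do.call(rbind, lapply(seq_len(caller_count), function(i) {
    make_call(caller = callers()[i], gene5 = gene_a, gene3 = gene_b,
              chrom5 = chrom5, pos5 = pos5, strand5 = strand5,
              chrom3 = chrom3, pos3 = pos3, strand3 = strand3,
              reads = as.integer(rep_len(per_caller_reads,
                                         caller_count)[i]))
  }))
  overlap_calls(split(calls, calls$caller))
}

test_that("read-through detection follows the distance/strand/chrom rule", {
  cfg <- filter_config()
  # same chromosome and strand, 150 kb apart: read-through
  r <- rec_row(chrom5 = "1", pos5 = 1000000L, chrom3 = "1",
               pos3 = 1150000L, strand5 = "+", strand3 = "+")
  expect_true(is_readthrough(r, cfg))
  # 225 kb apart at the same locus: retained (a genuine intrachromosomal
  # deletion, not a neighbouring-gene transcript)
  r <- rec_row(gene_a = "BCAN", gene_b = "NTRK1", chrom5 = "1",
               pos5 = 156650000L, chrom3 = "1", pos3 = 156875000L,
               strand5 = "+", strand3 = "+")
  expect_false(is_readthrough(r, cfg))
  # interchromosomal: never a read-through
  r <- rec_row(gene_a = "RBPMS", gene_b = "MET", chrom5 = "8",
               chrom3 = "7", strand5 = "+", strand3 = "+")
  expect_false(is_readthrough(r, cfg))
  # opposite strands, or unknown strand, cannot be read-through
  r <- rec_row(chrom5 = "1", pos5 = 1e6L, chrom3 = "1", pos3 = 1.1e6L,
               strand5 = "+", strand3 = "-")
  expect_false(is_readthrough(r, cfg))
  r <- rec_row(chrom5 = "1", pos5 = 1e6L, chrom3 = "1", pos3 = 1.1e6L,
               strand5 = ".", strand3 = ".")
  expect_false(is_readthrough(r, cfg))
  # overlapping genes, distance 0, same strand: filtered
  r <- rec_row(chrom5 = "1", pos5 = 1e6L, chrom3 = "1", pos3 = 1e6L)
  expect_true(is_readthrough(r, cfg))
})

test_that("cohort-frequency filter is strictly greater-than", {
  cfg <- filter_config()
  store <- cohort_store()
  for (i in 1:22) {
    pairs <- if (i <= 7) c("ALK|EML4", "AAA|BBB") else "AAA|BBB"
    store <- register_sample(store, paste0("S", i), pairs)
  }
  r_alk <- rec_row(gene_a = "ALK", gene_b = "EML4")
  expect_equal(cohort_frequency(store, "ALK", "EML4"), 7 / 22)
  expect_equal(round(100 * cohort_frequency(store, "ALK", "EML4"), 1),
               31.8)
  expect_true(is_high_frequency(r_alk, store, cfg))
  # below threshold, and absent-from-store pairs, are retained
  expect_false(is_high_frequency(rec_row(gene_a = "X", gene_b = "Y"),
                                 store, cfg))
  # exactly 10%: retained (strict inequality)
  store10 <- cohort_store()
  for (i in 1:10) {
    store10 <- register_sample(store10, paste0("S", i),
                               if (i == 1) "PPP|QQQ" else character(0))
  }
  expect_equal(cohort_frequency(store10, "PPP", "QQQ"), 0.10)
  expect_false(is_high_frequency(rec_row(gene_a = "PPP", gene_b = "QQQ"),
                                 store10, cfg))
})

test_that("low-evidence filter needs one caller at or above min_reads", {
  cfg <- filter_config()
  expect_true(is_low_evidence(rec_row(per_caller_reads = c(3L, 2L, 1L)),
                              cfg))
  expect_false(is_low_evidence(rec_row(per_caller_reads = c(4L, 1L, 1L)),
                               cfg))
  expect_true(is_low_evidence(rec_row(caller_count = 1L,
                                      per_caller_reads = 0L), cfg))
})

test_that("rescue keeps known-list fusions that fail filters", {
  cfg <- filter_config()
  known <- known_fusion_list(c("KIAA1549", "ALK"), c("BRAF", "EML4"),
                             gene_types = c())
  store <- cohort_store()
  for (i in 1:22) {
    store <- register_sample(store, paste0("S", i),
                             if (i <= 7) "ALK|EML4" else character(0))
  }
  recs <- rbind(
    # known pair, 3 callers, every caller < 4 reads: rescued
    rec_row(gene_a = "KIAA1549", gene_b = "BRAF", caller_count = 3L,
            chrom5 = "7", pos5 = 138900000L, chrom3 = "7",
            pos3 = 140800000L, strand5 = "-", strand3 = "-",
            per_caller_reads = c(2L, 1L, 3L)),
    # known pair at 31.8% cohort frequency, 4 callers: rescued
    rec_row(gene_a = "EML4", gene_b = "ALK", caller_count = 4L,
            chrom5 = "2", chrom3 = "2", pos5 = 42200000L,
            pos3 = 29500000L, strand5 = "+", strand3 = "-"),
    # unlisted pair with plenty of reads but only 2 callers: removed
    rec_row(gene_a = "UUU", gene_b = "VVV", caller_count = 2L,
            per_caller_reads = 50L)
  )
  out <- apply_filters(recs, store, known, cfg)
  expect_setequal(out$kept$pair, c("BRAF|KIAA1549", "ALK|EML4"))
  dec <- out$decisions
  expect_true(all(dec$rescued_by_known_list[dec$pair %in%
                                              c("BRAF|KIAA1549",
                                                "ALK|EML4")]))
  expect_equal(dec$reasons[dec$pair == "BRAF|KIAA1549"], "low-evidence")
  expect_equal(dec$reasons[dec$pair == "ALK|EML4"], "high-frequency")
  expect_equal(dec$reasons[dec$pair == "UUU|VVV"], "below-consensus")
  expect_false(dec$kept[dec$pair == "UUU|VVV"])
})

test_that("kept and removed partition the input", {
  withr::with_seed(11, {
    cbc <- random_calls_by_caller(n_callers = 5, max_calls = 15)
  })
  recs <- overlap_calls(cbc)
  out <- apply_filters(recs, cohort_store(), NULL, filter_config())
  expect_equal(nrow(out$kept) + nrow(out$removed), nrow(recs))
  expect_length(intersect(out$kept$pair, out$removed$pair), 0)
  expect_equal(nrow(out$decisions), nrow(recs))
  # with no known list, everything kept has >= 3 callers
  expect_true(all(out$kept$caller_count >= 3))
})

test_that("filters are monotone in their thresholds", {
  withr::with_seed(23, {
    cbc <- random_calls_by_caller(n_callers = 5, max_calls = 20,
                                  gene_pool = LETTERS[1:6])
  })
  recs <- overlap_calls(cbc)
  store <- cohort_store()
  n_kept <- function(cfg) nrow(apply_filters(recs, store, NULL, cfg)$kept)
  base <- filter_config(min_callers = 2, min_reads = 2,
                        known_list_min_callers = 2)
  stricter_reads <- filter_config(min_callers = 2, min_reads = 10,
                                  known_list_min_callers = 2)
  stricter_callers <- filter_config(min_callers = 4, min_reads = 2,
                                    known_list_min_callers = 2)
  expect_lte(n_kept(stricter_reads), n_kept(base))
  expect_lte(n_kept(stricter_callers), n_kept(base))
})

test_that("the three boolean filters commute", {
  # kept set must equal filtering by each test independently, in any order
  withr::with_seed(31, {
    cbc <- random_calls_by_caller(n_callers = 4, max_calls = 15)
  })
  recs <- overlap_calls(cbc)
  cfg <- filter_config()
  store <- cohort_store()
  masks <- list(!is_readthrough(recs, cfg),
                !is_high_frequency(recs, store, cfg),
                !is_low_evidence(recs, cfg),
                recs$caller_count >= cfg$min_callers)
  for (perm in list(c(1, 2, 3, 4), c(4, 3, 2, 1), c(2, 4, 1, 3))) {
    keep <- rep(TRUE, nrow(recs))
    for (i in perm) keep <- keep & masks[[i]]
    expect_equal(recs$pair[keep],
                 apply_filters(recs, store, NULL, cfg)$kept$pair)
  }
})
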