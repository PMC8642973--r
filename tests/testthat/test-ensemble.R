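test_that("overlap groups unordered pairs across callers", {
  # all seven callers report the same fusion: one record, count 7
  calls7 <- lapply(stats::setNames(nm = callers()), function(cl) {
    make_call(caller = cl, gene5 = "RBPMS", gene3 = "MET", chrom5 = "8",
              chrom3 = "7", reads = 10L)
  })
  rec <- overlap_calls(calls7)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$caller_count, 7L)

  # five of seven support, the others report something else
  calls5 <- calls7
  calls5$mapsplice <- make_call(caller = "mapsplice", gene5 = "AAA",
                                gene3 = "BBB")
  calls5$fusionmap <- make_call(caller = "fusionmap", gene5 = "CCC",
                                gene3 = "DDD")
  rec <- overlap_calls(calls5)
  expect_equal(rec$caller_count[rec$pair == "MET|RBPMS"], 5L)
  expect_equal(nrow(rec), 3)
})

test_that("reciprocal orientations merge into one record", {
  calls <- list(
    arriba = make_call(caller = "arriba", gene5 = "AAA", gene3 = "BBB"),
    jaffa = make_call(caller = "jaffa", gene5 = "BBB", gene3 = "AAA")
  )
  rec <- overlap_calls(calls)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$caller_count, 2L)
  expect_equal(rec$orientations, "AAA>BBB,BBB>AAA")
})

test_that("a caller's multiple isoform calls count once", {
  calls <- list(
    cicero = rbind(
      make_call(caller = "cicero", gene5 = "AAA", gene3 = "BBB",
                pos5 = 100L, reads = 9L),
      make_call(caller = "cicero", gene5 = "AAA", gene3 = "BBB",
                pos5 = 900L, reads = 3L)
    ),
    jaffa = make_call(caller = "jaffa", gene5 = "AAA", gene3 = "BBB",
                      reads = 2L)
  )
  rec <- overlap_calls(calls)
  expect_equal(rec$caller_count, 2L)
  expect_equal(rec$n_calls, 3L)
  expect_equal(rec$max_reads, 9L)
})

test_that("breakpoint reconciliation prefers reads, callers, then order", {
  # 20 reads beats 5
  calls <- list(
    arriba = make_call(caller = "arriba", pos5 = 111L, pos3 = 222L,
                       reads = 20L),
    jaffa = make_call(caller = "jaffa", pos5 = 888L, pos3 = 999L,
                      reads = 5L)
  )
  rec <- overlap_calls(calls)
  expect_equal(rec$pos5, 111L)
  expect_equal(rec$pos3, 222L)

  # read tie: the breakpoint supported by more callers wins
  calls <- list(
    arriba = make_call(caller = "arriba", pos5 = 111L, reads = 10L),
    jaffa = make_call(caller = "jaffa", pos5 = 888L, reads = 10L),
    cicero = make_call(caller = "cicero", pos5 = 888L, reads = 1L)
  )
  rec <- overlap_calls(calls)
  expect_equal(rec$pos5, 888L)

  # full tie: lexicographically smallest (chrom5, pos5, chrom3, pos3)
  calls <- list(
    arriba = make_call(caller = "arriba", pos5 = 500L, reads = 10L),
    jaffa = make_call(caller = "jaffa", pos5 = 120L, reads = 10L)
  )
  rec <- overlap_calls(calls)
  expect_equal(rec$pos5, 120L)
  # single supporting call: its breakpoints
  rec <- overlap_calls(list(cicero = make_call(caller = "cicero",
                                               pos5 = 77L)))
  expect_equal(rec$pos5, 77L)
  expect_equal(rec$best_gene5, "AAA")
})

test_that("prioritization sorts by callers, reads, then pair key", {
  by_caller <- list(
    arriba = rbind(
      make_call(caller = "arriba", gene5 = "G7", gene3 = "H7"),
      make_call(caller = "arriba", gene5 = "LOW", gene3 = "READS",
                reads = 4L),
      make_call(caller = "arriba", gene5 = "HIGH", gene3 = "READS",
                reads = 40L)),
    jaffa = rbind(
      make_call(caller = "jaffa", gene5 = "G7", gene3 = "H7"),
      make_call(caller = "jaffa", gene5 = "READS", gene3 = "LOW",
                reads = 2L),
      make_call(caller = "jaffa", gene5 = "HIGH", gene3 = "READS",
                reads = 1L)),
    cicero = make_call(caller = "cicero", gene5 = "G7", gene3 = "H7")
  )
  rec <- overlap_calls(by_caller)
  expect_equal(rec$pair, c("G7|H7", "HIGH|READS", "LOW|READS"))
  expect_equal(rec$caller_count, c(3L, 2L, 2L))
  expect_equal(rec$max_reads, c(10L, 40L, 4L))
})

test_that("overlap is invariant to caller and row permutations", {
  withr::with_seed(99, {
    base <- random_calls_by_caller(n_callers = 4, max_calls = 12)
  })
  ref <- overlap_calls(base)
  for (s in 1:5) {
    withr::with_seed(s, {
      shuffled <- base[sample(names(base))]
      shuffled <- lapply(shuffled, function(df) {
        df[sample(nrow(df)), , drop = FALSE]
      })
    })
    got <- overlap_calls(shuffled)
    expect_equal(got$pair, ref$pair)
    expect_equal(got$pos5, ref$pos5)
    expect_equal(got$pos3, ref$pos3)
    expect_equal(got$callers, ref$callers)
  }
})

test_that("overlap matches the brute-force oracle on random instances", {
  for (s in 1:10) {
    withr::with_seed(s, {
      cbc <- random_calls_by_caller(n_callers = sample(2:5, 1),
                                    max_calls = 6)
    })
    if (sum(vapply(cbc, nrow, integer(1))) == 0) next
    got <- overlap_calls(cbc)
    got <- got[order(got$pair), ]
    want <- oracle_overlap(cbc)
    expect_equal(got$pair, want$pair)
    expect_equal(got$caller_count, want$caller_count)
    expect_equal(got$n_calls, want$n_calls)
    expect_equal(got$max_reads, want$max_reads)
    # conservation: every input call lands in exactly one record
    expect_equal(sum(got$n_calls),
                 sum(vapply(cbc, nrow, integer(1))))
  }
})

test_that("self-fusions and duplicate caller names are handled", {
  rec <- overlap_calls(list(
    cicero = make_call(caller = "cicero", gene5 = "AAA", gene3 = "AAA")))
  expect_equal(rec$pair, "AAA|AAA")
  bad <- list(make_call(), make_call())
  names(bad) <- c("arriba", "arriba")
  expect_error(overlap_calls(bad), "unique caller names")
})
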