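test_that("arriba dialect parses breakpoints, strands and read sums", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    paste("#gene1", "gene2", "strand1(gene/fusion)", "strand2(gene/fusion)",
          "breakpoint1", "breakpoint2", "split_reads", "discordant_mates",
          "reading_frame", "fusion_transcript", sep = "\t"),
    paste("RBPMS", "MET", "+/+", "+/+", "8:30500000", "7:116700000",
          "12", "8", "in-frame", "ACGTACGT", sep = "\t")
  ), path)
  calls <- parse_caller_output(path, "arriba")
  expect_equal(nrow(calls), 1)
  expect_equal(calls$gene5, "RBPMS")
  expect_equal(calls$gene3, "MET")
  expect_equal(calls$chrom5, "8")
  expect_equal(calls$pos5, 30500000L)
  expect_equal(calls$reads, 20L)  # 12 split + 8 spanning
  expect_equal(calls$split_reads, 12L)
  expect_equal(calls$spanning_pairs, 8L)
  expect_equal(calls$frame, "in-frame")
})

test_that("single-column pair encoding parses to the same gene fields", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    paste("#FusionName", "JunctionReadCount", "SpanningFragCount",
          "LeftBreakpoint", "RightBreakpoint", sep = "\t"),
    paste("RBPMS--MET", "12", "8", "chr8:30500000:+", "chr7:116700000:+",
          sep = "\t")
  ), path)
  calls <- parse_caller_output(path, "starfusion")
  expect_equal(calls$gene5, "RBPMS")
  expect_equal(calls$gene3, "MET")
  expect_equal(calls$chrom5, "8")  # chr prefix stripped
  expect_equal(calls$reads, 20L)
})

test_that("zero-fusion files parse to empty call sets without error", {
  dialects <- caller_dialects()
  dir <- withr::local_tempdir()
  manifest <- make_call()[0, ]
  paths <- fusemble:::write_caller_files(cbind(category = character(0),
                                               manifest),
                                         callers(), dir)
  for (cl in callers()) {
    calls <- parse_caller_output(paths[[cl]], cl, dialects)
    expect_equal(nrow(calls), 0, info = cl)
  }
})

test_that("every dialect round-trips the same underlying fusion", {
  dir <- withr::local_tempdir()
  base <- make_call(gene5 = "TPM3", gene3 = "NTRK1", chrom5 = "1",
                    pos5 = 154170000L, strand5 = "-", chrom3 = "1",
                    pos3 = 156850000L, strand3 = "+", reads = 20L,
                    split_reads = 12L, spanning_pairs = 8L,
                    junction_seq = "ACGTACGTACGT", frame = "in-frame")
  parsed <- lapply(callers(), function(cl) {
    m <- base
    m$caller <- cl
    # single-count dialects carry one evidence number
    if (cl %in% c("cicero", "fusionmap", "mapsplice")) {
      m$split_reads <- NA_integer_
      m$spanning_pairs <- NA_integer_
    }
    paths <- fusemble:::write_caller_files(cbind(category = "x", m),
                                           cl, dir)
    parse_caller_output(paths[[cl]], cl)
  })
  names(parsed) <- callers()
  # identical modulo caller identity and dialect-dependent optional fields
  for (cl in callers()) {
    p <- parsed[[cl]]
    expect_equal(p$gene5, "TPM3", info = cl)
    expect_equal(p$gene3, "NTRK1", info = cl)
    expect_equal(p$chrom5, "1", info = cl)
    expect_equal(p$pos5, 154170000L, info = cl)  # incl. 0-based mapsplice
    expect_equal(p$pos3, 156850000L, info = cl)
    expect_equal(p$strand5, "-", info = cl)
    expect_equal(p$strand3, "+", info = cl)
    expect_equal(p$reads, 20L, info = cl)
    expect_equal(p$caller, cl, info = cl)
  }
  # dual-evidence dialects preserve the split/spanning breakdown
  for (cl in c("arriba", "fusioncatcher", "jaffa", "starfusion")) {
    expect_equal(parsed[[cl]]$split_reads, 12L, info = cl)
    expect_equal(parsed[[cl]]$spanning_pairs, 8L, info = cl)
  }
})

test_that("unknown caller and header mismatches are clear errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("a\tb\n1\t2", path)
  expect_error(parse_caller_output(path, "nosuchcaller"), "unknown caller")
  expect_error(parse_caller_output(path, "cicero"), "missing columns")
  expect_error(parse_caller_output(path, "cicero"), "geneA")
  expect_error(parse_caller_output("/nonexistent/file.tsv", "cicero"),
               "does not exist")
})

test_that("rows with unparseable gene fields are dropped and counted", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    paste("geneA", "chrA", "posA", "ortA", "geneB", "chrB", "posB",
          "ortB", "readsA", "contig", sep = "\t"),
    paste("AAA", "1", "100", "+", "BBB", "2", "200", "-", "7", ".",
          sep = "\t"),
    paste("", "1", "100", "+", "CCC", "2", "200", "-", "7", ".",
          sep = "\t"),
    paste("DDD", "1", "0", "+", "EEE", "2", "200", "-", "7", ".",
          sep = "\t")
  ), path)
  expect_warning(calls <- parse_caller_output(path, "cicero"),
                 "2 row\\(s\\)")
  expect_equal(nrow(calls), 1)
  expect_equal(calls$gene5, "AAA")
})

test_that("unified format round-trips field-wise, including absent fields", {
  path <- withr::local_tempfile(fileext = ".tsv")
  calls <- rbind(
    make_call(reads = 5L),
    make_call(caller = "jaffa", gene5 = "X", gene3 = "Y", reads = 20L,
              split_reads = 15L, spanning_pairs = 5L,
              junction_seq = "AACCGGTT", frame = "in-frame"),
    make_call(caller = "cicero", gene5 = "P", gene3 = "Q", strand5 = ".",
              reads = 0L)
  )
  write_unified_calls(calls, path)
  back <- read_unified_calls(path)
  expect_equal(back, calls)

  write_unified_calls(calls[0, ], path)
  expect_equal(nrow(read_unified_calls(path)), 0)
  expect_equal(readLines(path), paste(fusemble:::unified_columns(),
                                      collapse = "\t"))
})
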