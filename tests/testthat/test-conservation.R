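test_that("12-column alignment tables parse and validate", {
  f <- withr::local_tempfile()
  writeLines(c(
    "q1\ts1\t98.5\t500\t6\t1\t1\t500\t1000\t1499\t1e-100\t900",
    "q2 s1 90.0 300 10 0 11 310 2000 1501 1e-50 400"), f)
  aln <- parse_alignment_table(f)
  expect_equal(aln$qstart[1], 1L)
  expect_equal(aln$qend[1], 500L)
  expect_equal(aln$orientation, c("+", "-"))
  expect_equal(aln$percent_identity[1], 98.5)

  writeLines("q1 s1 98.5 500 6 1 1 500 1000 1499 1e-100", f)
  expect_error(parse_alignment_table(f), "11 columns")

  # round trip through the writer
  writeLines(c(
    "q1\ts1\t98.5\t500\t6\t1\t1\t500\t1000\t1499\t1e-100\t900"), f)
  aln <- parse_alignment_table(f)
  f2 <- withr::local_tempfile()
  write_alignment_table(aln, f2)
  expect_equal(parse_alignment_table(f2), aln)
})

test_that("one-sample t-test matches the closed form and t.test", {
  r <- one_sample_t(c(0.1, 0.2, 0.3, 0.4, 0.5), 0.3)
  expect_equal(r$t_stat, 0)
  expect_equal(r$p_two_sided, 1)

  r <- one_sample_t(c(0.1, 0.2, 0.3, 0.4, 0.5), 0)
  expect_equal(r$t_stat, 4.2426, tolerance = 1e-4)
  expect_equal(r$df, 4L)
  expect_equal(r$p_two_sided, 0.01324, tolerance = 1e-3)

  expect_error(one_sample_t(rep(0.5, 5), 0.9), "degenerate")
  z <- one_sample_t(rep(0.5, 5), 0.5)
  expect_equal(z$t_stat, 0)
  expect_equal(z$p_two_sided, 1)

  # cross-check against stats::t.test on random cases
  withr::with_seed(1, {
    for (i in 1:50) {
      x <- runif(sample(3:10, 1))
      mu <- runif(1)
      mine <- one_sample_t(x, mu)
      ref <- stats::t.test(x, mu = mu)
      expect_equal(mine$t_stat, unname(ref$statistic), tolerance = 1e-12)
      expect_equal(mine$p_two_sided, ref$p.value, tolerance = 1e-12)
    }
  })

  td <- generics::tidy(one_sample_t(c(0.1, 0.2, 0.3), 0.1, category = "no_change"))
  expect_equal(td$category, "no_change")
  expect_equal(td$control_3, 0.3)
})

test_that("zero-edit orthologs classify as fully conserved", {
  p <- builtin_presets()$xan
  sim <- simulate_survey(survey_params(n_repeats = 24, genome_length = 80000,
                                       seed = 21), p)
  hits <- scan_repeats(sim$genome, p)
  ort <- simulate_ortholog(sim$genome, sim$orfs, sim$truth, seed = 2)
  regs <- build_query_regions(sim$orfs, hits)
  regs <- regs[regs$contains_repeat, ]
  calls <- classify_conservation(regs, hits, ort$alignments,
                                 ort$subject_genome, p)
  expect_true(all(calls$region_class == "no_change"))
  expect_true(all(calls$repeat_status == "conserved"))
})

test_that("planted edits are recovered at the default thresholds", {
  p <- builtin_presets()$xan
  sim <- simulate_survey(survey_params(n_repeats = 24, genome_length = 80000,
                                       seed = 22), p)
  hits <- scan_repeats(sim$genome, p)
  regs <- build_query_regions(sim$orfs, hits)
  regs <- regs[regs$contains_repeat, ]

  ort <- simulate_ortholog(sim$genome, sim$orfs, sim$truth,
                           edit_rates = c(insertion = 1),
                           sizes = list(insertion = c(500L, 500L),
                                        deletion = c(50L, 200L)),
                           seed = 3)
  calls <- classify_conservation(regs, hits, ort$alignments,
                                 ort$subject_genome, p)
  expect_true(all(calls$region_class == "insertion"))
  expect_true(all(calls$repeat_status == "conserved"))

  ort <- simulate_ortholog(sim$genome, sim$orfs, sim$truth,
                           edit_rates = c(flanking_loss = 1), seed = 4)
  calls <- classify_conservation(regs, hits, ort$alignments,
                                 ort$subject_genome, p)
  expect_true(all(calls$region_class == "flanking_change"))

  ort <- simulate_ortholog(sim$genome, sim$orfs, sim$truth,
                           edit_rates = c(locus_loss = 1), seed = 5)
  calls <- classify_conservation(regs, hits, ort$alignments,
                                 ort$subject_genome, p)
  expect_true(all(calls$region_class == "no_homology"))
  expect_true(all(calls$repeat_status == "no_alignment"))

  # same seed gives identical output
  o1 <- simulate_ortholog(sim$genome, sim$orfs, sim$truth,
                          edit_rates = c(insertion = 0.5), seed = 6)
  o2 <- simulate_ortholog(sim$genome, sim$orfs, sim$truth,
                          edit_rates = c(insertion = 0.5), seed = 6)
  expect_identical(o1$subject_genome$sequence, o2$subject_genome$sequence)
  expect_identical(o1$alignments, o2$alignments)
})

test_that("a mutated subject locus is called absent_or_mutated", {
  p <- builtin_presets()$xan
  # query region: two ORFs around an intergenic repeat
  left <- paste(rep("ATGCCA", 50), collapse = "")
  right <- paste(rep("TTGCAC", 50), collapse = "")
  array <- strrep("GGGAATC", 4)
  qseq <- paste0(left, "AAGGTT", array, "CCATTA", right)
  genome <- genome_record("q", qseq)
  orfs <- tibble::tibble(
    genome_id = "q", start = c(0L, nchar(left) + 12L + 28L),
    end = c(nchar(left), nchar(qseq)), strand = c("+", "+"),
    locus_tag = c("L", "R"), product = "")
  hits <- scan_repeats(genome, p)
  expect_equal(nrow(hits), 1)
  regs <- build_query_regions(orfs, hits)
  expect_true(regs$contains_repeat)
  # subject: same locus but every seed mutated (G->T in each unit)
  sseq <- gsub("GGGAATC", "GTGAATC", qseq, fixed = TRUE)
  subject <- genome_record("s", sseq)
  aln <- tibble::tibble(
    query_id = regs$region_id, subject_id = "s", percent_identity = 96,
    aln_length = nchar(qseq), mismatches = 4L, gap_opens = 0L,
    qstart = 1L, qend = nchar(qseq), sstart = 1L, send = nchar(sseq),
    evalue = 0, bitscore = 1000, orientation = "+")
  expect_equal(
    classify_repeat_presence(regs, hits, aln, subject, p), "absent_or_mutated")
  # identical subject is conserved
  expect_equal(
    classify_repeat_presence(regs, hits, aln, genome_record("s", qseq), p),
    "conserved")
  # no alignment over the repeat
  aln2 <- dplyr::mutate(aln, qend = 100L, send = 100L)
  expect_equal(
    classify_repeat_presence(regs, hits, aln2, subject, p), "no_alignment")
})

test_that("control sets are seeded, repeat-free and orientation-matched", {
  p <- builtin_presets()$xan
  sim <- simulate_survey(survey_params(n_repeats = 30, genome_length = 150000,
                                       seed = 31), p)
  hits <- scan_repeats(sim$genome, p)
  regs <- build_query_regions(sim$orfs, hits)
  rep_regs <- regs[regs$contains_repeat, ]
  n_free <- sum(!regs$contains_repeat)
  pool_size <- min(n_free, 30L)
  sets <- build_control_sets(sim$orfs, rep_regs, hits,
                             pool_size = pool_size, set_size = 20L,
                             designs = c("random", "position_matched",
                                         "orientation_matched"),
                             seed = 99)
  sets2 <- build_control_sets(sim$orfs, rep_regs, hits,
                              pool_size = pool_size, set_size = 20L,
                              designs = c("random", "position_matched",
                                          "orientation_matched"),
                              seed = 99)
  expect_identical(sets, sets2)
  for (s in sets) {
    expect_equal(nrow(s), 20)
    expect_true(all(!s$contains_repeat))
  }
  orient <- function(r) ifelse(r$left_strand == r$right_strand, "aligned",
                               ifelse(r$left_strand == "+", "convergent",
                                      "divergent"))
  target <- table(factor(orient(rep_regs),
                         levels = c("aligned", "convergent", "divergent")))
  target_n <- g4repeats:::largest_remainder(
    as.numeric(target) / sum(target), 20L)
  got <- table(factor(orient(sets$control_3),
                      levels = c("aligned", "convergent", "divergent")))
  expect_equal(as.integer(got), target_n)

  expect_error(
    build_control_sets(sim$orfs, rep_regs, hits, pool_size = 10000L),
    "pool too small")
})

test_that("category-wise conservation tests produce the expected table", {
  p <- builtin_presets()$xan
  sim <- simulate_survey(survey_params(n_repeats = 24, genome_length = 80000,
                                       seed = 41), p)
  hits <- scan_repeats(sim$genome, p)
  regs <- build_query_regions(sim$orfs, hits)
  rep_regs <- regs[regs$contains_repeat, ]
  ort <- simulate_ortholog(sim$genome, sim$orfs, sim$truth, seed = 7)
  rep_calls <- classify_conservation(rep_regs, hits, ort$alignments,
                                     ort$subject_genome, p)
  ctrl_regs <- regs[!regs$contains_repeat, ][1:10, ]
  ctrl_calls <- lapply(1:5, function(k) {
    ort_c <- simulate_ortholog(sim$genome, sim$orfs, sim$truth,
                               regions = ctrl_regs,
                               edit_rates = c(insertion = 0.5), seed = 8 + k)
    classify_conservation(ctrl_regs, hits, ort_c$alignments,
                          ort_c$subject_genome, p)
  })
  res <- conservation_tests(rep_calls, ctrl_calls)
  expect_equal(nrow(res), 5)
  expect_true(all(c("category", "repeat_value", "control_1", "control_5",
                    "t_stat", "df", "p_two_sided") %in% names(res)))
  expect_equal(res$repeat_value[res$category == "no_change"], 1)
  expect_equal(res$df, rep(4L, 5))
})
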