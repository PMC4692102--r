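p_xan <- builtin_presets()$xan

test_that("generators are pure functions of params and seed", {
  par <- survey_params(n_repeats = 15, genome_length = 60000, seed = 5)
  s1 <- simulate_survey(par, p_xan)
  s2 <- simulate_survey(par, p_xan)
  expect_identical(s1$genome$sequence, s2$genome$sequence)
  expect_identical(s1$orfs, s2$orfs)
  expect_identical(s1$truth$planted_repeats, s2$truth$planted_repeats)
  s3 <- simulate_survey(survey_params(n_repeats = 15, genome_length = 60000,
                                      seed = 6), p_xan)
  expect_false(identical(s1$genome$sequence, s3$genome$sequence))
})

test_that("zero-noise surveys are recovered exactly by the scanner", {
  for (seed in c(1, 2)) {
    sim <- simulate_survey(survey_params(n_repeats = 25,
                                         genome_length = 90000,
                                         degenerate_position_mut_rate = 0,
                                         seed = seed), p_xan)
    hits <- scan_repeats(sim$genome, p_xan)
    expect_equal(repeat_hit_key(hits),
                 repeat_hit_key(sim$truth$planted_repeats))
  }
  # ana preset too
  sim <- simulate_survey(survey_params(n_repeats = 20, genome_length = 90000,
                                       gc_content = 0.41,
                                       degenerate_position_mut_rate = 0,
                                       seed = 3), builtin_presets()$ana)
  hits <- scan_repeats(sim$genome, builtin_presets()$ana)
  expect_equal(repeat_hit_key(hits),
               repeat_hit_key(sim$truth$planted_repeats))
})

test_that("scrubbed background with nothing planted yields no hits", {
  sim <- simulate_survey(survey_params(n_repeats = 0, genome_length = 30000,
                                       seed = 4), p_xan)
  expect_equal(nrow(scan_repeats(sim$genome, p_xan)), 0)
})

test_that("G-tract mutations split arrays into truth segments", {
  sim <- simulate_survey(survey_params(n_repeats = 30, genome_length = 120000,
                                       g_tract_mut_rate = 0.3, seed = 8),
                         p_xan)
  hits <- scan_repeats(sim$genome, p_xan)
  expect_equal(repeat_hit_key(hits),
               repeat_hit_key(sim$truth$planted_repeats))
  # mutation pressure leaves some multi-segment or shortened arrays behind
  expect_true(nrow(sim$truth$planted_repeats) > 0)
})

test_that("planted inverted pairs are detected", {
  sim <- simulate_survey(survey_params(n_repeats = 30,
                                       inverted_pair_fraction = 0.3,
                                       genome_length = 120000, seed = 9),
                         p_xan)
  expect_gt(nrow(sim$truth$planted_pairs), 0)
  hits <- scan_repeats(sim$genome, p_xan)
  pairs <- detect_inverted_pairs(hits, max_gap = 100)
  truth_keys <- paste(sim$truth$planted_pairs$plus_repeat_id,
                      sim$truth$planted_pairs$minus_repeat_id)
  got_keys <- paste(pairs$plus_repeat_id, pairs$minus_repeat_id)
  expect_true(all(truth_keys %in% got_keys))
})

test_that("an over-full genome raises the placement contract error", {
  expect_error(
    simulate_survey(survey_params(n_repeats = 50, genome_length = 10000,
                                  seed = 1), p_xan),
    "increase genome_length")
})

test_that("transcript generator realizes each class mix exactly", {
  sim <- simulate_survey(survey_params(n_repeats = 24, genome_length = 90000,
                                       seed = 10), p_xan)
  hits <- scan_repeats(sim$genome, p_xan)
  ctx <- annotate_context(hits, sim$orfs)

  tx <- simulate_transcripts(sim$genome, sim$orfs, sim$truth,
                             class_mix = c(start = 1), seed = 2)
  calls <- classify_transcripts(hits, ctx, tx$transcripts)
  expect_true(all(calls$position_class == "start"))

  tx <- simulate_transcripts(sim$genome, sim$orfs, sim$truth,
                             class_mix = c(no_transcript = 1), seed = 2)
  expect_equal(nrow(tx$transcripts), 0)

  tx <- simulate_transcripts(sim$genome, sim$orfs, sim$truth,
                             class_mix = c(start = 0.3, stop = 0.3,
                                           middle = 0.2, no_transcript = 0.2),
                             seed = 3)
  calls <- classify_transcripts(hits, ctx, tx$transcripts)
  m <- dplyr::left_join(calls, tx$planted_classes, by = "repeat_id",
                        suffix = c("", "_truth"))
  expect_equal(m$position_class, m$position_class_truth)
  ok <- !is.na(m$strand_content_truth)
  expect_equal(m$strand_content[ok], m$strand_content_truth[ok])
})

test_that("survey reports aggregate the headline statistics", {
  sim <- simulate_survey(survey_params(n_repeats = 20, genome_length = 80000,
                                       seed = 12), p_xan)
  rep <- survey_report(sim$genome, sim$orfs)
  expect_equal(rep$repeat_count, nrow(sim$truth$planted_repeats))
  expect_equal(sum(rep$unit_histogram$n_repeats), rep$repeat_count)
  expect_s3_class(rep$pfm, "g4_pfm")
  f <- withr::local_tempfile(fileext = ".json")
  write_survey_report(rep, f)
  js <- jsonlite::fromJSON(f)
  expect_equal(js$repeat_count, rep$repeat_count)
  expect_match(js$coordinate_convention, "0-based")
})
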