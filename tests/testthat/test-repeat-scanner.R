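xan <- builtin_presets()$xan
ana <- builtin_presets()$ana

test_that("builtin presets encode the repeat family definitions", {
  expect_equal(xan$seed_units, "GGGAATC")
  expect_equal(xan$degenerate_unit, "GGGANTN")
  expect_equal(xan$min_units, 2L)
  expect_equal(xan$min_total_length, 14L)
  expect_equal(ana$seed_units, c("GGGGATT", "GGGGACT"))
  expect_equal(ana$min_seed_units, 2L)
  for (p in builtin_presets()) {
    sets <- g4repeats:::iupac_pattern_sets(p$degenerate_unit)
    for (s in p$seed_units) {
      expect_true(g4repeats:::matches_iupac(s, sets))
    }
  }
  expect_error(repeat_preset("bad", "GGGAATC", "GGGGANT"), "does not match")
  expect_error(repeat_preset("bad", "GGGAATC", "GGGANTN", min_units = 1),
               "min_units")
})

test_that("preset config files round trip", {
  f <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("name = ana2", "seed_units = GGGGATT, GGGGACT",
               "degenerate_unit = GGGGANT", "min_seed_units = 2",
               "# a comment", "min_total_length = 14"), f)
  p <- read_preset_config(f)
  expect_equal(p$seed_units, c("GGGGATT", "GGGGACT"))
  expect_equal(p$min_seed_units, 2L)
  writeLines("unknown_key = 1", f)
  expect_error(read_preset_config(f), "unknown preset key")
})

test_that("perfect, partial-tract and reverse-complement arrays are detected", {
  g <- genome_record("g1", paste0("TT", strrep("GGGAATC", 4), "TT"))
  h <- scan_repeats(g, xan)
  expect_equal(nrow(h), 1)
  expect_equal(h$start, 2L)
  expect_equal(h$end, 30L)
  expect_equal(h$strand, "+")
  expect_equal(h$n_units, 4L)
  expect_equal(h$n_seed_units, 4L)
  expect_true(h$g4_capable)

  # minimal G4-capable motif: three units plus a trailing G-tract
  g <- genome_record("g1", paste0("AA", strrep("GGGAATC", 3), "GGGTTCA"))
  h <- scan_repeats(g, xan)
  expect_equal(h$n_units, 3L)
  expect_equal(h$trailing_partial, "GGG")
  expect_equal(h$end - h$start, 24L)
  expect_true(h$g4_capable)

  # a lone seed fails min_units
  g <- genome_record("g1", "ACCTAGGGAATCAGTTACA")
  expect_equal(nrow(scan_repeats(g, xan)), 0)

  # reverse complement of two seeds is a minus-strand hit
  g <- genome_record("g1", "ACGTGATTCCCGATTCCCTTAA")
  h <- scan_repeats(g, xan)
  expect_equal(h$strand, "-")
  expect_equal(h$start, 4L)
  expect_equal(h$end, 18L)
  expect_equal(h$n_units, 2L)
  expect_equal(h$units[[1]], c("GGGAATC", "GGGAATC"))
})

test_that("windows containing N never match", {
  g <- genome_record("g1", paste0("TT", "GGGAATC", "GGGANTC", "GGGAATC", "TT"))
  h <- scan_repeats(g, xan)
  # the N window breaks the array into two, each a lone seed -> dropped
  expect_equal(nrow(h), 0)
})

test_that("G4 capability requires four consecutive intact tracts", {
  r <- call_g4_capability(rep("GGGAATC", 4))
  expect_equal(r$intact_tracts_max_run, 4L)
  expect_true(r$g4_capable)

  r <- call_g4_capability(c("GGGAATC", "GTGAATC", "GGGAATC", "GGGAATC"))
  expect_equal(r$intact_tracts_max_run, 2L)
  expect_false(r$g4_capable)

  r <- call_g4_capability(rep("GGGAATC", 3), "GGG")
  expect_equal(r$intact_tracts_max_run, 4L)
  expect_true(r$g4_capable)

  expect_error(call_g4_capability(character(0)), "non-empty")
})

test_that("ana preset needs two seed units and tolerates degenerate ones", {
  g <- genome_record("g1", paste0("AT", "GGGGATT", "GGGGACT", "GGGGAGT", "AT"))
  h <- scan_repeats(g, ana)
  expect_equal(h$n_units, 3L)
  expect_equal(h$n_seed_units, 2L)
  # only one seed unit: dropped
  g <- genome_record("g1", paste0("AT", "GGGGATT", "GGGGAGT", "AT"))
  expect_equal(nrow(scan_repeats(g, ana)), 0)
})

test_that("hit sequence reconstructs from units plus trailing partial", {
  for (seed in 1:5) {
    s <- random_motif_sequence(3000, seed, xan)
    g <- genome_record("g", s)
    h <- scan_repeats(g, xan)
    for (i in seq_len(nrow(h))) {
      slice <- substr(s, h$start[i] + 1, h$end[i])
      if (h$strand[i] == "-") slice <- revcomp(slice)
      expect_equal(slice, paste0(paste(h$units[[i]], collapse = ""),
                                 h$trailing_partial[i]))
    }
  }
})

test_that("scanning is strand symmetric", {
  for (seed in 1:5) {
    s <- random_motif_sequence(2500, seed, xan)
    g <- genome_record("g", s)
    grc <- genome_record("g", revcomp(s))
    h <- scan_repeats(g, xan)
    hrc <- scan_repeats(grc, xan)
    n <- nchar(s)
    mirrored <- tibble::tibble(
      start = n - h$end, end = n - h$start,
      strand = ifelse(h$strand == "+", "-", "+"),
      n_units = h$n_units, n_seed_units = h$n_seed_units)
    expect_setequal(
      paste(mirrored$start, mirrored$end, mirrored$strand, mirrored$n_units,
            mirrored$n_seed_units),
      paste(hrc$start, hrc$end, hrc$strand, hrc$n_units, hrc$n_seed_units))
  }
})

test_that("raising min_units only removes hits", {
  strict <- repeat_preset("xan3", "GGGAATC", "GGGANTN", min_units = 3L)
  for (seed in 1:5) {
    s <- random_motif_sequence(2500, seed, xan)
    g <- genome_record("g", s)
    h2 <- scan_repeats(g, xan)
    h3 <- scan_repeats(g, strict)
    expect_true(all(h3$repeat_id %in% h2$repeat_id))
    kept <- h2[h2$repeat_id %in% h3$repeat_id, ]
    expect_equal(repeat_hit_key(h3), repeat_hit_key(kept))
  }
})

test_that("scanner matches the brute-force oracle on random sequences", {
  for (seed in 1:10) {
    s <- random_motif_sequence(1500, seed, xan)
    h <- scan_repeats(genome_record("g", s), xan)
    o <- oracle_scan_repeats(s, xan)
    expect_equal(repeat_hit_key(h), repeat_hit_key(o), label = paste("seed", seed))
  }
  for (seed in 1:5) {
    s <- random_motif_sequence(1500, seed + 100, ana)
    h <- scan_repeats(genome_record("g", s), ana)
    o <- oracle_scan_repeats(s, ana)
    expect_equal(repeat_hit_key(h), repeat_hit_key(o), label = paste("ana seed", seed))
  }
})
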