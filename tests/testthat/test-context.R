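mk_orfs <- function(starts, ends, strands) {
  tibble::tibble(genome_id = "g", start = as.integer(starts),
                 end = as.integer(ends), strand = strands,
                 locus_tag = sprintf("orf%02d", seq_along(starts)),
                 product = "")
}

mk_hit <- function(start, end, strand) {
  tibble::tibble(genome_id = "g", start = as.integer(start),
                 end = as.integer(end), strand = strand,
                 repeat_id = sprintf("rep:g:%d-%d(%s)", start, end, strand))
}

test_that("distance bins have inclusive 50/100 edges", {
  expect_equal(distance_bin(0), "d0_50")
  expect_equal(distance_bin(50), "d0_50")
  expect_equal(distance_bin(51), "d50_100")
  expect_equal(distance_bin(100), "d50_100")
  expect_equal(distance_bin(101), "d_gt100")
  expect_error(distance_bin(-1), "non-negative")
})

test_that("location classification separates coding/noncoding/intergenic", {
  orfs <- mk_orfs(c(100, 600), c(400, 900), c("+", "+"))
  expect_equal(classify_location(mk_hit(150, 178, "+"), orfs)$location_class,
               "intragenic_coding")
  expect_equal(classify_location(mk_hit(150, 178, "-"), orfs)$location_class,
               "intragenic_noncoding")
  loc <- classify_location(mk_hit(450, 478, "+"), orfs)
  expect_equal(loc$location_class, "intergenic")
  expect_true(is.na(loc$overlapped_orf))
  # tie broken by larger overlap
  orfs2 <- mk_orfs(c(100, 160), c(400, 180), c("+", "-"))
  loc <- classify_location(mk_hit(150, 178, "+"), dplyr::arrange(orfs2, start))
  expect_equal(loc$overlapped_orf, "orf01")
})

test_that("orientation classes follow flanking ORF strands", {
  expect_equal(orientation_class("+", "+", "+"), "aligned_coding")
  expect_equal(orientation_class("+", "+", "-"), "aligned_noncoding")
  expect_equal(orientation_class("-", "-", "-"), "aligned_coding")
  expect_equal(orientation_class("+", "-", "+"), "convergent")
  expect_equal(orientation_class("+", "-", "-"), "convergent")
  expect_equal(orientation_class("-", "+", "+"), "divergent")
  expect_equal(orientation_class(NA_character_, "+", "+"), "undefined")
})

test_that("neighbor relations resolve all four ORF-strand x side cases", {
  # plus ORF downstream of the hit: repeat upstream, coding, distance 32
  orfs <- mk_orfs(c(0, 200), c(50, 500), c("+", "+"))
  rel <- neighbor_relations(mk_hit(140, 168, "+"), orfs)
  r <- rel[rel$side == "right", ]
  expect_equal(r$relation, "repeat_upstream_of_orf")
  expect_equal(r$strand_relation, "coding")
  expect_equal(r$distance, 32L)
  expect_equal(r$bin, "d0_50")

  # plus ORF upstream of the hit, hit on minus strand: downstream, noncoding
  orfs <- mk_orfs(c(100, 600), c(200, 700), c("+", "+"))
  rel <- neighbor_relations(mk_hit(205, 233, "-"), orfs)
  r <- rel[rel$side == "left", ]
  expect_equal(r$relation, "repeat_downstream_of_orf")
  expect_equal(r$strand_relation, "noncoding")
  expect_equal(r$distance, 5L)

  # minus ORF before the hit: its start codon is at its right edge, so the
  # repeat lies upstream of it
  orfs <- mk_orfs(c(600, 1200), c(900, 1400), c("-", "-"))
  rel <- neighbor_relations(mk_hit(930, 958, "+"), orfs)
  r <- rel[rel$side == "left", ]
  expect_equal(r$relation, "repeat_upstream_of_orf")
  expect_equal(r$strand_relation, "noncoding")
  expect_equal(r$distance, 30L)

  # minus ORF after the hit: stop codon at its left edge -> repeat downstream
  r <- neighbor_relations(mk_hit(930, 958, "+"), orfs)
  r <- r[r$side == "right", ]
  expect_equal(r$relation, "repeat_downstream_of_orf")
  expect_equal(r$distance, 242L)
  expect_equal(r$bin, "d_gt100")
})

test_that("annotation reports undefined orientation at genome ends", {
  orfs <- mk_orfs(700, 900, "+")
  hit <- mk_hit(500, 528, "+")
  ctx <- annotate_context(hit, orfs)
  expect_equal(ctx$location_class, "intergenic")
  expect_equal(ctx$orientation_class, "undefined")
  expect_true(is.na(ctx$left_locus_tag))
  expect_equal(ctx$right_locus_tag, "orf01")
})

test_that("inverted pair detection is orientation- and gap-aware", {
  hits <- dplyr::bind_rows(mk_hit(100, 128, "+"), mk_hit(160, 188, "-"))
  p <- detect_inverted_pairs(hits)
  expect_equal(nrow(p), 1)
  expect_equal(p$gap, 32L)

  # divergent layout (minus before plus) is not a pair
  hits <- dplyr::bind_rows(mk_hit(100, 128, "-"), mk_hit(160, 188, "+"))
  expect_equal(nrow(detect_inverted_pairs(hits)), 0)

  # gap above max_gap is not a pair
  hits <- dplyr::bind_rows(mk_hit(100, 128, "+"), mk_hit(278, 306, "-"))
  expect_equal(nrow(detect_inverted_pairs(hits, max_gap = 100)), 0)
  expect_equal(nrow(detect_inverted_pairs(hits, max_gap = 200)), 1)

  # each hit pairs at most once, nearest gap first
  hits <- dplyr::bind_rows(mk_hit(100, 128, "+"), mk_hit(140, 168, "+"),
                           mk_hit(200, 228, "-"))
  p <- detect_inverted_pairs(hits)
  expect_equal(nrow(p), 1)
  expect_equal(p$plus_repeat_id, "rep:g:140-168(+)")
})

test_that("classification is invariant under genome mirroring", {
  p <- builtin_presets()$xan
  sim <- simulate_survey(survey_params(n_repeats = 24, genome_length = 80000,
                                       seed = 42), p)
  g <- sim$genome
  hits <- scan_repeats(g, p)
  ctx <- annotate_context(hits, sim$orfs)

  L <- g$length
  g_m <- genome_record(g$id, revcomp(g$sequence))
  orfs_m <- sim$orfs
  tmp_start <- L - orfs_m$end
  orfs_m$end <- L - orfs_m$start
  orfs_m$start <- tmp_start
  orfs_m$strand <- ifelse(orfs_m$strand == "+", "-", "+")
  hits_m <- scan_repeats(g_m, p)
  ctx_m <- annotate_context(hits_m, orfs_m)

  expect_equal(sort(table(ctx$location_class)),
               sort(table(ctx_m$location_class)))
  expect_equal(sort(table(ctx$orientation_class)),
               sort(table(ctx_m$orientation_class)))
  # distances survive with left/right swapped
  d <- sort(c(ctx$left_distance, ctx$right_distance))
  d_m <- sort(c(ctx_m$left_distance, ctx_m$right_distance))
  expect_equal(d, d_m)
})
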