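#' Parameters for the synthetic repeat survey generator
#'
#' The generator emulates a bacterial genome carrying planted heptameric
#' G-rich tandem arrays: a unit-count distribution peaked at 4 units,
#' per-position unit degeneracy at the non-conserved positions, occasional
#' G-tract point mutations, arrays on both strands, convergent inverted
#' pairs, and ORF layouts realizing a stated mix of neighbor-orientation
#' categories.
#'
#' @param genome_length Genome length in bases.
#' @param gc_content Background GC fraction.
#' @param n_repeats Number of planted arrays.
#' @param unit_count_distribution Named numeric vector: probability per unit
#'   count; must sum to 1.
#' @param degenerate_position_mut_rate Per-position mutation probability at
#'   the degenerate (N) unit positions.
#' @param g_tract_mut_rate Per-unit probability of a point mutation inside
#'   the leading G-tract. Such a unit no longer matches the degenerate
#'   pattern, so it splits its array; truth records the surviving segments.
#' @param minus_strand_prob Probability that a (non-pair) array is planted on
#'   the minus strand.
#' @param inverted_pair_fraction Fraction of arrays arranged as convergent
#'   plus/minus pairs.
#' @param pair_gap_range Gap range (bases) between pair members; minimum 8.
#' @param orientation_mix Named fractions over
#'   intragenic_coding, intragenic_noncoding, aligned_coding,
#'   aligned_noncoding, convergent, divergent; must sum to 1. Category
#'   counts are assigned by largest-remainder rounding, so planted
#'   composition is exact.
#' @param orf_length_range ORF length range in bases.
#' @param gap_range Repeat-to-ORF gap range in bases (minimum 8).
#' @param min_spacer Minimum background spacer between cassettes.
#' @param seed Integer seed; the generator is a pure function of
#'   (params, preset).
#' @return List of class `survey_params`.
#' @export
survey_params <- function(genome_length = 150000L,
                          gc_content = 0.6,
                          n_repeats = 60L,
                          unit_count_distribution = c(
                            "2" = 0.2, "3" = 0.15, "4" = 0.4, "5" = 0.15,
                            "6" = 0.06, "7" = 0.04),
                          degenerate_position_mut_rate = 0.1,
                          g_tract_mut_rate = 0,
                          minus_strand_prob = 0.5,
                          inverted_pair_fraction = 0.1,
                          pair_gap_range = c(20L, 80L),
                          orientation_mix = c(
                            aligned_coding = 0.25, aligned_noncoding = 0.30,
                            convergent = 0.16, divergent = 0.09,
                            intragenic_coding = 0.10,
                            intragenic_noncoding = 0.10),
                          orf_length_range = c(300L, 900L),
                          gap_range = c(10L, 140L),
                          min_spacer = 200L,
                          seed = 1L) {
  probs <- c(unit_count_distribution, orientation_mix,
             degenerate_position_mut_rate, g_tract_mut_rate,
             minus_strand_prob, inverted_pair_fraction, gc_content)
  assert_that(all(probs >= 0 & probs <= 1), "probabilities must lie in [0,1]")
  assert_that(abs(sum(unit_count_distribution) - 1) < 1e-9,
              "unit_count_distribution must sum to 1")
  assert_that(abs(sum(orientation_mix) - 1) < 1e-9,
              "orientation_mix must sum to 1")
  known <- c("intragenic_coding", "intragenic_noncoding", "aligned_coding",
             "aligned_noncoding", "convergent", "divergent")
  assert_that(all(names(orientation_mix) %in% known),
              "unknown orientation category in orientation_mix")
  assert_that(pair_gap_range[1] >= 8, "pair_gap_range minimum is 8 bases")
  assert_that(gap_range[1] >= 8, "gap_range minimum is 8 bases")
  structure(as.list(environment())[c(
    "genome_length", "gc_content", "n_repeats", "unit_count_distribution",
    "degenerate_position_mut_rate", "g_tract_mut_rate", "minus_strand_prob",
    "inverted_pair_fraction", "pair_gap_range", "orientation_mix",
    "orf_length_range", "gap_range", "min_spacer", "seed")],
    class = "survey_params")
}

random_bases <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# Remove every occurrence of the given words (and nothing else) that touches
# at least one unprotected position, by resampling the unprotected bases of
# the occurrence. Occurrences fully inside protected spans are left alone.
scrub_words <- function(chars, words, protected, gc, max_iter = 100L) {
  for (iter in seq_len(max_iter)) {
    dirty <- FALSE
    for (w in words) {
      hits <- which(window_equals(chars, w))
      for (p in hits) {
        idx <- p:(p + nchar(w) - 1L)
        free <- idx[!protected[idx]]
        if (length(free) == 0) next
        chars[free] <- random_bases(length(free), gc)
        dirty <- TRUE
      }
    }
    if (!dirty) return(chars)
  }
  abort("failed to scrub seed occurrences from background")
}

# Draw one unit list for an array: per-unit seed choice, degenerate-position
# mutations (kept within the degenerate pattern), a floor of exact seed
# units, then optional G-tract mutations with a `mutated` flag per unit.
draw_units <- function(k, preset, deg_rate, gtract_rate) {
  seeds <- sample(preset$seed_units, k, replace = TRUE)
  units <- seeds
  pat <- strsplit(preset$degenerate_unit, "", fixed = TRUE)[[1]]
  deg_pos <- which(pat == "N")
  for (i in seq_len(k)) {
    for (j in deg_pos) {
      if (runif(1) < deg_rate) {
        cur <- substr(units[i], j, j)
        substr(units[i], j, j) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
      }
    }
  }
  n_seed <- sum(units %in% preset$seed_units)
  if (n_seed < preset$min_seed_units) {
    revert <- sample_vec(which(!units %in% preset$seed_units),
                         preset$min_seed_units - n_seed)
    units[revert] <- seeds[revert]
  }
  mutated <- rep(FALSE, k)
  if (gtract_rate > 0) {
    for (i in seq_len(k)) {
      if (runif(1) < gtract_rate) {
        j <- sample_vec(seq_len(preset$tract_prefix_length), 1)
        substr(units[i], j, j) <- sample(c("A", "C", "T"), 1)
        mutated[i] <- TRUE
      }
    }
  }
  # never mutate every seed away: keep at least min_seed_units intact seeds
  if (sum(units %in% preset$seed_units) < preset$min_seed_units) {
    fix <- sample_vec(which(mutated), min(sum(mutated),
                                          preset$min_seed_units))
    units[fix] <- seeds[fix]
    mutated[fix] <- FALSE
  }
  list(units = units, mutated = mutated)
}

# Truth hits for one planted array, honoring the scanner's semantics:
# G-tract-mutated units split the array; each surviving segment must meet
# the preset thresholds.
truth_hits_for_array <- function(units, mutated, strand, start0, preset,
                                 genome_id, category, pair_id) {
  k <- length(units)
  runs <- rle(!mutated)
  out <- list()
  pos <- 1L
  for (ri in seq_along(runs$lengths)) {
    len <- runs$lengths[ri]
    if (runs$values[ri]) {
      i <- pos; j <- pos + len - 1L
      seg <- units[i:j]
      n_seed <- sum(seg %in% preset$seed_units)
      if (len >= preset$min_units && n_seed >= preset$min_seed_units &&
          7L * len >= preset$min_total_length) {
        if (strand == "+") {
          s0 <- start0 + 7L * (i - 1L); e0 <- start0 + 7L * j
        } else {
          s0 <- start0 + 7L * (k - j); e0 <- start0 + 7L * (k - i + 1L)
        }
        g4 <- call_g4_capability(seg, "", preset$tract_prefix_length)
        out[[length(out) + 1L]] <- tibble(
          genome_id = genome_id, start = s0, end = e0, strand = strand,
          units = list(seg), n_units = len, n_seed_units = n_seed,
          trailing_partial = "",
          intact_tracts_max_run = g4$intact_tracts_max_run,
          g4_capable = g4$g4_capable,
          preset_name = preset$name,
          repeat_id = hit_id(genome_id, s0, e0, strand),
          orientation_category = category,
          pair_id = pair_id)
      }
    }
    pos <- pos + len
  }
  bind_rows(out)
}

#' Simulate a repeat survey genome with full ground truth
#'
#' Generates a background genome at the requested GC content, scrubbed so
#' that no seed heptamer (or its reverse complement) survives outside the
#' planted arrays, then plants repeat arrays and ORF annotations realizing
#' the orientation mix. Array flanks are additionally scrubbed so that no
#' array can be extended by an accidental degenerate unit or trailing
#' G-tract: with zero mutation rates, [scan_repeats()] recovers exactly the
#' planted set.
#'
#' @param params A [survey_params()].
#' @param preset A [repeat_preset()].
#' @return List: `genome` ([genome_record()]), `orfs` (annotation tibble),
#'   `truth` (list with `planted_repeats`, `planted_orfs`, `planted_pairs`,
#'   `categories`).
#' @export
simulate_survey <- function(params, preset = builtin_presets()$xan) {
  assert_that(inherits(params, "survey_params"), "params must be survey_params()")
  withr::with_seed(params$seed, simulate_survey_impl(params, preset))
}

simulate_survey_impl <- function(params, preset) {
  n_rep <- params$n_repeats
  cats <- names(params$orientation_mix)
  quota <- largest_remainder(as.numeric(params$orientation_mix), n_rep)
  cat_vec <- rep(cats, quota)

  # pairs live between convergent/divergent ORFs; both members share the
  # cassette and its category
  n_pairs <- floor(n_rep * params$inverted_pair_fraction / 2)
  pair_cats <- character(0)
  for (pc in c("convergent", "divergent")) {
    while (n_pairs > length(pair_cats) && sum(cat_vec == pc) >= 2) {
      pair_cats <- c(pair_cats, pc)
      cat_vec <- cat_vec[-which(cat_vec == pc)[1:2]]
    }
  }
  n_pairs <- length(pair_cats)

  sample_range <- function(rng) sample_vec(rng[1]:rng[2], 1)
  uc <- params$unit_count_distribution

  new_array <- function(strand) {
    k <- as.integer(sample(names(uc), 1, prob = uc))
    d <- draw_units(k, preset, params$degenerate_position_mut_rate,
                    params$g_tract_mut_rate)
    list(strand = strand, units = d$units, mutated = d$mutated,
         width = 7L * k)
  }

  cassettes <- list()
  for (pc in pair_cats) {
    cassettes[[length(cassettes) + 1L]] <- list(
      type = "pair", category = pc,
      arrays = list(new_array("+"), new_array("-")),
      pair_gap = sample_range(params$pair_gap_range))
  }
  for (cat in sample(cat_vec)) {
    strand <- if (runif(1) < params$minus_strand_prob) "-" else "+"
    cassettes[[length(cassettes) + 1L]] <- list(
      type = if (startsWith(cat, "intragenic")) "intragenic" else "single",
      category = cat, arrays = list(new_array(strand)))
  }
  cassettes <- cassettes[sample(length(cassettes))]

  # per-cassette layout: element offsets relative to cassette start
  for (i in seq_along(cassettes)) {
    cs <- cassettes[[i]]
    if (cs$type == "intragenic") {
      aw <- cs$arrays[[1]]$width
      margin <- 30L
      w <- max(sample_range(params$orf_length_range), aw + 2L * margin)
      off <- sample_vec(margin:(w - aw - margin), 1)
      rs <- cs$arrays[[1]]$strand
      orf_strand <- if (cs$category == "intragenic_coding") rs
                    else if (rs == "+") "-" else "+"
      cs$orfs <- tibble(off = 0L, len = w, strand = orf_strand)
      cs$array_offs <- off
      cs$width <- w
    } else {
      gapL <- sample_range(params$gap_range)
      gapR <- sample_range(params$gap_range)
      wL <- sample_range(params$orf_length_range)
      wR <- sample_range(params$orf_length_range)
      rs <- cs$arrays[[1]]$strand
      strands <- switch(cs$category,
        aligned_coding = c(rs, rs),
        aligned_noncoding = if (rs == "+") c("-", "-") else c("+", "+"),
        convergent = c("+", "-"),
        divergent = c("-", "+"))
      inner <- if (cs$type == "pair") {
        c(cs$arrays[[1]]$width, cs$pair_gap, cs$arrays[[2]]$width)
      } else {
        cs$arrays[[1]]$width
      }
      cs$array_offs <- if (cs$type == "pair") {
        c(wL + gapL, wL + gapL + inner[1] + inner[2])
      } else {
        wL + gapL
      }
      cs$width <- wL + gapL + sum(inner) + gapR + wR
      cs$orfs <- tibble(off = c(0L, cs$width - wR), len = c(wL, wR),
                        strand = strands)
    }
    cassettes[[i]] <- cs
  }

  nc <- length(cassettes)
  need <- sum(vapply(cassettes, `[[`, numeric(1), "width")) +
    (nc + 1L) * params$min_spacer
  if (need > params$genome_length) {
    abort(sprintf(
      "cannot place %d repeats in %d bases (need >= %d): increase genome_length",
      n_rep, params$genome_length, need))
  }
  extra <- params$genome_length - need
  extra_split <- as.vector(stats::rmultinom(1, extra, rep(1, nc + 1L)))
  spacers <- params$min_spacer + extra_split

  genome_id <- sprintf("synth_%s_%d", preset$name, params$seed)
  chars <- random_bases(params$genome_length, params$gc_content)
  words <- unique(c(preset$seed_units, revcomp(preset$seed_units)))
  protected <- rep(FALSE, params$genome_length)
  chars <- scrub_words(chars, words, protected, params$gc_content)

  # place cassettes, write array bases, collect annotations and truth
  orf_rows <- list()
  truth_rows <- list()
  pair_rows <- list()
  array_spans <- list()
  pos <- 0L
  pair_i <- 0L
  for (ci in seq_len(nc)) {
    pos <- pos + spacers[ci]
    cs <- cassettes[[ci]]
    for (oi in seq_len(nrow(cs$orfs))) {
      orf_rows[[length(orf_rows) + 1L]] <- tibble(
        genome_id = genome_id,
        start = pos + cs$orfs$off[oi],
        end = pos + cs$orfs$off[oi] + cs$orfs$len[oi],
        strand = cs$orfs$strand[oi],
        product = "hypothetical protein")
    }
    pid <- NA_character_
    if (cs$type == "pair") {
      pair_i <- pair_i + 1L
      pid <- sprintf("pair_%03d", pair_i)
    }
    member_hits <- list()
    for (ai in seq_along(cs$arrays)) {
      arr <- cs$arrays[[ai]]
      a0 <- pos + cs$array_offs[ai]
      txt <- paste(arr$units, collapse = "")
      if (arr$strand == "-") txt <- revcomp(txt)
      idx <- (a0 + 1L):(a0 + arr$width)
      chars[idx] <- strsplit(txt, "", fixed = TRUE)[[1]]
      protected[idx] <- TRUE
      array_spans[[length(array_spans) + 1L]] <-
        list(start = a0, width = arr$width, strand = arr$strand)
      th <- truth_hits_for_array(arr$units, arr$mutated, arr$strand, a0,
                                 preset, genome_id, cs$category, pid)
      member_hits[[ai]] <- th
      if (nrow(th) > 0) truth_rows[[length(truth_rows) + 1L]] <- th
    }
    if (cs$type == "pair" &&
        nrow(member_hits[[1]]) > 0 && nrow(member_hits[[2]]) > 0) {
      ph <- member_hits[[1]][which.max(member_hits[[1]]$end), ]
      mh <- member_hits[[2]][which.min(member_hits[[2]]$start), ]
      pair_rows[[length(pair_rows) + 1L]] <- tibble(
        pair_id = pid, plus_repeat_id = ph$repeat_id,
        minus_repeat_id = mh$repeat_id,
        gap = mh$start - ph$end)
    }
    pos <- pos + cs$width
  }

  chars <- fix_array_flanks(chars, array_spans, protected, preset,
                            params$gc_content, words)

  orfs <- if (length(orf_rows) > 0) {
    o <- bind_rows(orf_rows) |> arrange(.data$start)
    o$locus_tag <- sprintf("orf_%04d", seq_len(nrow(o)))
    select(o, "genome_id", "start", "end", "strand", "locus_tag", "product")
  } else {
    tibble(genome_id = character(), start = integer(), end = integer(),
           strand = character(), locus_tag = character(),
           product = character())
  }
  planted <- if (length(truth_rows) > 0) {
    bind_rows(truth_rows) |> arrange(.data$start)
  } else {
    dplyr::mutate(empty_repeat_hits(), orientation_category = character(0),
                  pair_id = character(0))
  }
  truth <- list(
    planted_repeats = planted,
    planted_orfs = orfs,
    planted_pairs = if (length(pair_rows) > 0) bind_rows(pair_rows) else
      tibble(pair_id = character(), plus_repeat_id = character(),
             minus_repeat_id = character(), gap = integer()),
    categories = cats)
  genome <- genome_record(genome_id, paste(chars, collapse = ""))
  list(genome = genome, orfs = orfs, truth = truth)
}

# Ensure no planted array can be extended: the in-frame windows flanking an
# array (read on its strand) must not match the degenerate unit, and the
# bases past its 3' (strand-wise) end must not form a trailing G-tract.
# Resampled bases are re-scrubbed for seed words.
fix_array_flanks <- function(chars, array_spans, protected, preset, gc,
                             words) {
  n <- length(chars)
  sets <- iupac_pattern_sets(preset$degenerate_unit)
  gpref <- strrep("G", preset$tract_prefix_length)
  get_win <- function(i1, i2) paste(chars[i1:i2], collapse = "")
  bad_window <- function(i1, i2, strand, check) {
    if (i1 < 1 || i2 > n) return(FALSE)
    w <- get_win(i1, i2)
    if (strand == "-") w <- revcomp(w)
    if (check == "deg") matches_iupac(w, sets) else w == gpref
  }
  for (iter in 1:100) {
    dirty <- FALSE
    for (sp in array_spans) {
      a1 <- sp$start + 1L; a2 <- sp$start + sp$width  # 1-based inclusive
      tp <- preset$tract_prefix_length
      wins <- if (sp$strand == "+") {
        list(c(a1 - 7L, a1 - 1L, "deg"), c(a2 + 1L, a2 + 7L, "deg"),
             c(a2 + 1L, a2 + tp, "gpref"))
      } else {
        list(c(a2 + 1L, a2 + 7L, "deg"), c(a1 - 7L, a1 - 1L, "deg"),
             c(a1 - tp, a1 - 1L, "gpref"))
      }
      for (w in wins) {
        i1 <- as.integer(w[1]); i2 <- as.integer(w[2])
        if (bad_window(i1, i2, sp$strand, w[3])) {
          idx <- i1:i2
          free <- idx[idx >= 1 & idx <= n]
          free <- free[!protected[free]]
          if (length(free) > 0) {
            chars[free] <- random_bases(length(free), gc)
            dirty <- TRUE
          }
        }
      }
    }
    chars2 <- scrub_words(chars, words, protected, gc)
    if (!identical(chars2, chars)) dirty <- TRUE
    chars <- chars2
    if (!dirty) return(chars)
  }
  abort("failed to stabilize array flanks")
}
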