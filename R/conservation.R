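#' Parse a 12-column tabular local-alignment file
#'
#' The standard tabular hit format: query id, subject id, percent identity,
#' alignment length, mismatches, gap opens, query start/end (1-based
#' inclusive), subject start/end (1-based inclusive; subject end < start
#' means a minus-strand alignment), e-value, bit score. Fields may be
#' separated by tabs or whitespace.
#'
#' @param path Path to the alignment table.
#' @return Tibble with typed columns plus `orientation` ("+"/"-").
#' @export
parse_alignment_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(empty_alignments())
  }
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  if (any(nf != 12)) {
    abort(sprintf("line %d has %d columns, expected 12",
                  which(nf != 12)[1], nf[nf != 12][1]))
  }
  m <- do.call(rbind, fields)
  out <- tibble(
    query_id = m[, 1], subject_id = m[, 2],
    percent_identity = as.numeric(m[, 3]),
    aln_length = as.integer(m[, 4]),
    mismatches = as.integer(m[, 5]), gap_opens = as.integer(m[, 6]),
    qstart = as.integer(m[, 7]), qend = as.integer(m[, 8]),
    sstart = as.integer(m[, 9]), send = as.integer(m[, 10]),
    evalue = as.numeric(m[, 11]), bitscore = as.numeric(m[, 12]))
  assert_that(all(out$qstart <= out$qend), "qstart must be <= qend")
  assert_that(all(out$aln_length >= 1), "alignment length must be >= 1")
  out$orientation <- ifelse(out$send < out$sstart, "-", "+")
  out
}

empty_alignments <- function() {
  tibble(query_id = character(), subject_id = character(),
         percent_identity = double(), aln_length = integer(),
         mismatches = integer(), gap_opens = integer(),
         qstart = integer(), qend = integer(),
         sstart = integer(), send = integer(),
         evalue = double(), bitscore = double(),
         orientation = character())
}

#' Write alignments in the 12-column tabular format
#'
#' Inverse of [parse_alignment_table()]; the derived `orientation` column is
#' not written.
#'
#' @param alignments Alignment tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment_table <- function(alignments, path) {
  cols <- c("query_id", "subject_id", "percent_identity", "aln_length",
            "mismatches", "gap_opens", "qstart", "qend", "sstart", "send",
            "evalue", "bitscore")
  missing_cols <- setdiff(cols, names(alignments))
  if (length(missing_cols) > 0) {
    abort(sprintf("alignments missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  utils::write.table(alignments[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Build intergenic query regions from ORFs and repeat hits
#'
#' One region per consecutive pair of non-overlapping ORFs (sorted by start):
#' the intergenic span plus both flanking ORFs, flagged with any repeat whose
#' array overlaps the intergenic span. Regions at genome ends (a single
#' flanking ORF) are not built.
#'
#' @param orfs ORF tibble.
#' @param hits Repeat hits (may be empty).
#' @return Tibble of query regions: `region_id`, `genome_id`, left/right ORF
#'   coordinates, strands and locus tags, `inter_start`, `inter_end`,
#'   `region_start`, `region_end`, `contains_repeat`, `repeat_id`.
#' @export
build_query_regions <- function(orfs, hits) {
  orfs <- arrange(orfs, .data$start, .data$end)
  if (nrow(orfs) < 2) {
    return(tibble(region_id = character(), genome_id = character()))
  }
  rows <- list()
  for (i in seq_len(nrow(orfs) - 1)) {
    l <- orfs[i, ]; r <- orfs[i + 1, ]
    if (r$start < l$end) next  # overlapping ORFs bound no intergenic region
    ov <- hits$start < r$start & hits$end > l$end
    rid <- hits$repeat_id[ov][1] %||% NA_character_
    rows[[length(rows) + 1L]] <- tibble(
      region_id = sprintf("region_%s_%06d", l$genome_id, l$end),
      genome_id = l$genome_id,
      left_locus_tag = l$locus_tag, left_start = l$start, left_end = l$end,
      left_strand = l$strand,
      right_locus_tag = r$locus_tag, right_start = r$start,
      right_end = r$end, right_strand = r$strand,
      inter_start = l$end, inter_end = r$start,
      region_start = l$start, region_end = r$end,
      contains_repeat = any(ov),
      repeat_id = if (any(ov)) rid else NA_character_)
  }
  bind_rows(rows)
}

# Map a query interval (1-based inclusive, region-local) through one
# alignment row to absolute subject coordinates (1-based inclusive,
# unordered). The interval is clipped to the aligned query span.
map_query_to_subject <- function(aln, q1, q2) {
  a <- max(q1, aln$qstart); b <- min(q2, aln$qend)
  if (a > b) return(NULL)
  if (aln$orientation == "+") {
    s1 <- aln$sstart + (a - aln$qstart)
    s2 <- aln$sstart + (b - aln$qstart)
  } else {
    s1 <- aln$sstart - (a - aln$qstart)
    s2 <- aln$sstart - (b - aln$qstart)
  }
  c(min(s1, s2), max(s1, s2))
}

#' Classify repeat presence at an orthologous locus
#'
#' If no alignment covers at least half of the repeat's span within the query
#' region the status is `no_alignment`. Otherwise the covered span is mapped
#' to the subject genome, padded by `flank` bases, and rescanned with the
#' repeat preset: a qualifying array means `conserved`, none means
#' `absent_or_mutated`.
#'
#' @param region One-row query-region tibble (see [build_query_regions()]).
#' @param repeat_hit One-row repeat-hit tibble for the region's repeat.
#' @param alignments Alignment tibble (all queries; filtered internally).
#' @param subject_genome [genome_record()] of the subject genome.
#' @param preset The [repeat_preset()] used for the original scan.
#' @param flank Padding in bases around the mapped subject interval.
#' @return One of "conserved", "absent_or_mutated", "no_alignment".
#' @export
classify_repeat_presence <- function(region, repeat_hit, alignments,
                                     subject_genome, preset, flank = 100L) {
  subject_genome <- as_genome_record(subject_genome)
  aln <- alignments[alignments$query_id == region$region_id, ]
  q1 <- repeat_hit$start - region$region_start + 1L
  q2 <- repeat_hit$end - region$region_start
  span <- q2 - q1 + 1L
  ov <- pmin(q2, aln$qend) - pmax(q1, aln$qstart) + 1L
  ok <- which(ov >= 0.5 * span)
  if (length(ok) == 0) return("no_alignment")
  best <- ok[which.max(ov[ok])]
  s <- map_query_to_subject(aln[best, ], q1, q2)
  s1 <- max(1L, s[1] - flank)
  s2 <- min(subject_genome$length, s[2] + flank)
  assert_that(s1 <= subject_genome$length && s2 >= 1,
              "mapped subject interval lies outside the subject genome")
  window <- genome_record(subject_genome$id,
                          substr(subject_genome$sequence, s1, s2))
  hits <- scan_repeats(window, preset)
  if (nrow(hits) > 0) "conserved" else "absent_or_mutated"
}

#' Classify region-level change at an orthologous locus
#'
#' A flanking ORF "qualifies" when some single alignment covers at least
#' `min_coverage` of it at `min_identity` percent identity or better.
#' Neither qualifying is `no_homology`; exactly one is `flanking_change`.
#' When both qualify, the change in inter-ORF distance (subject minus query)
#' decides: at least `indel_threshold` more bases is an `insertion`, at
#' least that many fewer a `deletion`, otherwise `no_change`. Two qualifying
#' ORFs mapping to different subject sequences are coerced to
#' `flanking_change` (with a message).
#'
#' @param region One-row query-region tibble.
#' @param alignments Alignment tibble.
#' @param min_identity Minimum percent identity (default 80).
#' @param min_coverage Minimum covered fraction of the ORF (default 0.8).
#' @param indel_threshold Bases of inter-ORF distance change that call an
#'   insertion/deletion (default 300).
#' @return One of "no_change", "insertion", "deletion", "flanking_change",
#'   "no_homology".
#' @export
classify_region <- function(region, alignments, min_identity = 80,
                            min_coverage = 0.8, indel_threshold = 300L) {
  aln <- alignments[alignments$query_id == region$region_id, ]
  orf_span <- function(orf_start, orf_end) {
    c(orf_start - region$region_start + 1L, orf_end - region$region_start)
  }
  best_qualifying <- function(span) {
    if (nrow(aln) == 0) return(NULL)
    len <- span[2] - span[1] + 1L
    ov <- pmin(span[2], aln$qend) - pmax(span[1], aln$qstart) + 1L
    ok <- which(ov >= min_coverage * len & aln$percent_identity >= min_identity)
    if (length(ok) == 0) return(NULL)
    aln[ok[which.max(ov[ok])], ]
  }
  lspan <- orf_span(region$left_start, region$left_end)
  rspan <- orf_span(region$right_start, region$right_end)
  laln <- best_qualifying(lspan)
  raln <- best_qualifying(rspan)
  if (is.null(laln) && is.null(raln)) return("no_homology")
  if (is.null(laln) || is.null(raln)) return("flanking_change")
  if (laln$subject_id != raln$subject_id) {
    message(sprintf(
      "region %s: flanking ORFs align to different subjects (%s, %s); classified flanking_change",
      region$region_id, laln$subject_id, raln$subject_id))
    return("flanking_change")
  }
  sl <- map_query_to_subject(laln, lspan[1], lspan[2])
  sr <- map_query_to_subject(raln, rspan[1], rspan[2])
  # gap between the two subject intervals (0 if they touch or overlap)
  subj_dist <- max(0L, max(min(sr) - max(sl), min(sl) - max(sr)) - 1L)
  query_dist <- region$inter_end - region$inter_start
  delta <- subj_dist - query_dist
  if (delta >= indel_threshold) "insertion"
  else if (delta <= -indel_threshold) "deletion"
  else "no_change"
}

#' Conservation calls for a set of query regions
#'
#' Runs [classify_region()] on every region and, where the region contains a
#' repeat, [classify_repeat_presence()]. `repeat_status` is `no_alignment`
#' whenever the region class is `no_homology`.
#'
#' @param regions Query regions from [build_query_regions()].
#' @param hits Repeat hits (for repeat-containing regions).
#' @param alignments Alignment tibble from [parse_alignment_table()].
#' @param subject_genome Subject [genome_record()].
#' @param preset [repeat_preset()] used for scanning.
#' @inheritParams classify_region
#' @inheritParams classify_repeat_presence
#' @return Tibble: `region_id`, `repeat_id`, `repeat_status`, `region_class`.
#' @export
classify_conservation <- function(regions, hits, alignments, subject_genome,
                                  preset, min_identity = 80,
                                  min_coverage = 0.8, indel_threshold = 300L,
                                  flank = 100L) {
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    region <- regions[i, ]
    rc <- classify_region(region, alignments, min_identity, min_coverage,
                          indel_threshold)
    rs <- NA_character_
    if (isTRUE(region$contains_repeat)) {
      hit <- hits[hits$repeat_id == region$repeat_id, ]
      rs <- classify_repeat_presence(region, hit, alignments, subject_genome,
                                     preset, flank)
    }
    tibble(region_id = region$region_id, repeat_id = region$repeat_id,
           repeat_status = rs, region_class = rc)
  })
  bind_rows(rows)
}

#' Assemble control sets of repeat-free intergenic regions
#'
#' From all intergenic regions with two flanking ORFs and no repeat, a pool
#' of `pool_size` regions is drawn (seeded). Three set designs are
#' supported: `random` samples `set_size` regions without replacement;
#' `position_matched` greedily pairs each repeat region with the unused pool
#' region of nearest midpoint; `orientation_matched` samples so the
#' aligned / convergent / divergent composition of the flanking ORFs equals
#' the repeat set's composition (largest-remainder rounding).
#'
#' @param orfs ORF tibble.
#' @param repeat_regions Query regions containing repeats (the set being
#'   controlled for).
#' @param hits Repeat hits (to exclude repeat-overlapping regions from the
#'   pool).
#' @param pool_size Size of the repeat-free pool (default 260).
#' @param set_size Regions per control set (default 117).
#' @param designs Character vector from
#'   `c("random", "position_matched", "orientation_matched")`, one entry per
#'   control set to build (repeats allowed).
#' @param seed Integer seed; same seed gives identical sets.
#' @return Named list of query-region tibbles, one per design entry (names
#'   `control_1`, `control_2`, ...).
#' @export
build_control_sets <- function(orfs, repeat_regions, hits,
                               pool_size = 260L, set_size = 117L,
                               designs = c("random", "random", "random",
                                           "position_matched",
                                           "orientation_matched"),
                               seed = 1L) {
  designs <- match.arg(designs, c("random", "position_matched",
                                  "orientation_matched"),
                       several.ok = TRUE)
  all_regions <- build_query_regions(orfs, hits)
  eligible <- all_regions[!all_regions$contains_repeat, ]
  if (nrow(eligible) < pool_size) {
    abort(sprintf("pool too small: %d repeat-free regions available, %d needed (deficit %d)",
                  nrow(eligible), pool_size, pool_size - nrow(eligible)))
  }
  assert_that(set_size <= pool_size, "set_size must be <= pool_size")
  region_orientation <- function(r) {
    ifelse(r$left_strand == r$right_strand, "aligned",
           ifelse(r$left_strand == "+", "convergent", "divergent"))
  }
  withr::with_seed(seed, {
    pool <- eligible[sample(nrow(eligible), pool_size), ]
    pool <- arrange(pool, .data$region_start)
    out <- list()
    for (k in seq_along(designs)) {
      d <- designs[k]
      if (d == "random") {
        set <- pool[sample(nrow(pool), set_size), ]
      } else if (d == "position_matched") {
        assert_that(nrow(repeat_regions) >= set_size,
                    "position_matched needs at least set_size repeat regions")
        mid_pool <- (pool$region_start + pool$region_end) / 2
        used <- logical(nrow(pool))
        sel <- integer(0)
        for (i in seq_len(set_size)) {
          mid_r <- (repeat_regions$region_start[i] +
                      repeat_regions$region_end[i]) / 2
          dists <- abs(mid_pool - mid_r)
          dists[used] <- Inf
          j <- which.min(dists)
          used[j] <- TRUE
          sel <- c(sel, j)
        }
        set <- pool[sel, ]
      } else {
        target <- region_orientation(repeat_regions)
        comp <- table(factor(target, levels = c("aligned", "convergent",
                                                "divergent")))
        quota <- largest_remainder(as.numeric(comp) / sum(comp), set_size)
        names(quota) <- names(comp)
        pool_or <- region_orientation(pool)
        sel <- integer(0)
        for (cat in names(quota)) {
          avail <- which(pool_or == cat)
          if (length(avail) < quota[[cat]]) {
            abort(sprintf("pool too small for orientation '%s': %d available, %d needed",
                          cat, length(avail), quota[[cat]]))
          }
          sel <- c(sel, sample_vec(avail, quota[[cat]]))
        }
        set <- pool[sel, ]
      }
      out[[sprintf("control_%d", k)]] <- arrange(set, .data$region_start)
    }
    out
  })
}

# Deterministic largest-remainder rounding of fractions to integer counts
# summing to total. Ties go to the earlier category.
largest_remainder <- function(fractions, total) {
  raw <- fractions * total
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    ord <- order(-(raw - base), seq_along(raw))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' One-sample t-test of control fractions against a reference value
#'
#' t = (mean(controls) - reference) / (sd(controls) / sqrt(n)), df = n - 1,
#' with the two-sided p-value from the t distribution. A zero-variance
#' sample is degenerate unless its mean equals the reference (then t = 0,
#' p = 1).
#'
#' @param control_values Numeric vector of control fractions (n >= 2).
#' @param reference_value The observed fraction in the repeat group.
#' @param category Optional category label carried into the result.
#' @return Object of class `g4_ttest` with fields `category`,
#'   `repeat_value`, `control_values`, `t_stat`, `df`, `p_two_sided`.
#'   [generics::tidy()] and [generics::glance()] return one-row tibbles.
#' @export
#' @examples
#' one_sample_t(c(0.1, 0.2, 0.3, 0.4, 0.5), 0)
one_sample_t <- function(control_values, reference_value, category = NA_character_) {
  n <- length(control_values)
  assert_that(n >= 2, "need at least two control values")
  m <- mean(control_values)
  s <- sd(control_values)
  if (s == 0) {
    if (m == reference_value) {
      t_stat <- 0; p <- 1
    } else {
      abort("degenerate sample: zero variance with mean != reference")
    }
  } else {
    t_stat <- (m - reference_value) / (s / sqrt(n))
    p <- 2 * pt(-abs(t_stat), df = n - 1)
  }
  structure(list(category = category, repeat_value = reference_value,
                 control_values = control_values, t_stat = t_stat,
                 df = n - 1L, p_two_sided = p),
            class = "g4_ttest")
}

#' @export
print.g4_ttest <- function(x, ...) {
  cat(sprintf("<one-sample t-test%s>\n",
              if (is.na(x$category)) "" else paste0(" [", x$category, "]")))
  cat(sprintf("  reference %.4g vs %d controls (mean %.4g)\n",
              x$repeat_value, length(x$control_values),
              mean(x$control_values)))
  cat(sprintf("  t = %.4f, df = %d, p = %.4g\n", x$t_stat, x$df, x$p_two_sided))
  invisible(x)
}

#' Tidy a one-sample t-test
#'
#' @param x A `g4_ttest`.
#' @param ... Unused.
#' @return One-row tibble with the category, reference value, control
#'   values (`control_1` ... `control_n`), `t_stat`, `df`, `p_two_sided`.
#' @export
tidy.g4_ttest <- function(x, ...) {
  ctrl <- as.list(setNames(x$control_values,
                           sprintf("control_%d", seq_along(x$control_values))))
  dplyr::bind_cols(
    tibble(category = x$category, repeat_value = x$repeat_value),
    as_tibble(ctrl),
    tibble(t_stat = x$t_stat, df = x$df, p_two_sided = x$p_two_sided))
}

#' @rdname tidy.g4_ttest
#' @export
glance.g4_ttest <- function(x, ...) {
  tibble(t_stat = x$t_stat, df = x$df, p_two_sided = x$p_two_sided)
}

#' Category-wise t-tests of repeat conservation against control sets
#'
#' For every region class, the fraction observed in the repeat set is
#' compared against the fractions in the control sets with a one-sample
#' t-test (the controls are the sample, the repeat fraction the reference).
#'
#' @param repeat_calls Conservation calls for the repeat regions.
#' @param control_calls Named list of conservation-call tibbles, one per
#'   control set.
#' @return Tibble, one row per category: `category`, `repeat_value`,
#'   `control_1` ... , `t_stat`, `df`, `p_two_sided`.
#' @export
conservation_tests <- function(repeat_calls, control_calls) {
  cats <- c("no_change", "insertion", "deletion", "flanking_change",
            "no_homology")
  frac <- function(calls) {
    tab <- table(factor(calls$region_class, levels = cats))
    as.numeric(tab) / max(1L, nrow(calls))
  }
  rf <- frac(repeat_calls)
  cf <- vapply(control_calls, frac, numeric(length(cats)))
  rows <- lapply(seq_along(cats), function(i)
    tidy(one_sample_t(cf[i, ], rf[i], category = cats[i])))
  bind_rows(rows)
}
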