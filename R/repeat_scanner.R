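#' Call G4 capability from an array's units
#'
#' A unit contributes an intact G-tract iff its first `tract_prefix_length`
#' characters are all G. A qualifying trailing partial unit (itself a G run)
#' contributes one additional tract at the end of the array. An array is
#' G4-capable iff the longest run of consecutive intact tracts is at least 4
#' (four stacked G-tracts being the minimal requirement for an intramolecular
#' quadruplex; the minimal capable array is three intact units plus a
#' trailing G-tract).
#'
#' @param units Character vector of 7-mer units as read 5'->3' on the repeat
#'   strand. Must be non-empty.
#' @param trailing_partial Terminal partial unit, `""` if none. Counts as an
#'   intact tract iff it equals the G run of length `tract_prefix_length`.
#' @param tract_prefix_length Length of the unit's leading G run.
#' @return List with `intact_tracts_max_run` and `g4_capable`.
#' @export
#' @examples
#' call_g4_capability(rep("GGGAATC", 3), "GGG")
call_g4_capability <- function(units, trailing_partial = "",
                               tract_prefix_length = 3L) {
  assert_that(length(units) > 0, "unit list must be non-empty")
  gpref <- strrep("G", tract_prefix_length)
  intact <- substr(units, 1L, tract_prefix_length) == gpref
  if (identical(trailing_partial, gpref)) intact <- c(intact, TRUE)
  runs <- rle(intact)
  max_run <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  list(intact_tracts_max_run = as.integer(max_run),
       g4_capable = max_run >= 4L)
}

# Scan one strand-oriented sequence string for maximal seed-anchored arrays.
# Returns candidates in strand-local 1-based coordinates:
#   a tibble of (pos1, n_units, trailing_partial, units list).
scan_strand_arrays <- function(s, preset) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n < 7L) {
    return(tibble(pos1 = integer(), n_units = integer(),
                  trailing_partial = character(), units = list()))
  }
  sets <- iupac_pattern_sets(preset$degenerate_unit)
  deg_ok <- window_matches(chars, sets)
  seed_ok <- rep(FALSE, n - 6L)
  for (seed in preset$seed_units) seed_ok <- seed_ok | window_equals(chars, seed)
  seed_pos <- which(seed_ok)
  if (length(seed_pos) == 0) {
    return(tibble(pos1 = integer(), n_units = integer(),
                  trailing_partial = character(), units = list()))
  }
  nwin <- n - 6L
  gpref <- strrep("G", preset$tract_prefix_length)

  seen <- character(0)
  out <- vector("list", length(seed_pos))
  k_out <- 0L
  for (p in seed_pos) {
    l <- p
    while (l - 7L >= 1L && deg_ok[l - 7L]) l <- l - 7L
    r <- p
    while (r + 7L <= nwin && deg_ok[r + 7L]) r <- r + 7L
    key <- paste0(l, ":", r)
    if (key %in% seen) next
    seen <- c(seen, key)
    k <- (r - l) %/% 7L + 1L
    end_units <- l + 7L * k - 1L  # 1-based inclusive end of the full units
    tp <- ""
    if (end_units + preset$tract_prefix_length <= n &&
        substr(s, end_units + 1L,
               end_units + preset$tract_prefix_length) == gpref) {
      tp <- gpref
    }
    units <- substring(s, seq(l, by = 7L, length.out = k),
                       seq(l + 6L, by = 7L, length.out = k))
    k_out <- k_out + 1L
    out[[k_out]] <- list(pos1 = l, n_units = k, trailing_partial = tp,
                         units = units)
  }
  out <- out[seq_len(k_out)]
  tibble(
    pos1 = vapply(out, `[[`, integer(1), "pos1"),
    n_units = vapply(out, `[[`, integer(1), "n_units"),
    trailing_partial = vapply(out, `[[`, character(1), "trailing_partial"),
    units = lapply(out, `[[`, "units"))
}

# Resolve overlapping candidates on one strand: keep, in order of
# (more seed units, more units, smaller forward start), dropping any
# candidate overlapping an already-kept one.
resolve_overlaps <- function(df) {
  if (nrow(df) <= 1) return(df)
  ord <- order(-df$n_seed_units, -df$n_units, df$start)
  df <- df[ord, ]
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    ok <- TRUE
    if (any(keep)) {
      kept <- df[keep, ]
      ok <- all(df$end[i] <= kept$start | df$start[i] >= kept$end)
    }
    keep[i] <- ok
  }
  df[keep, ]
}

#' Scan a genome for heptameric tandem repeat arrays
#'
#' Detects maximal tandem arrays of degenerate 7-mer units on both strands.
#' Every exact seed occurrence is extended left and right in 7-base steps
#' while each adjacent window matches the preset's degenerate unit; a
#' candidate array is maximal. A terminal partial unit is recorded when the
#' bases following the last full unit equal the unit's leading G run; it is
#' never counted in `n_units` but feeds G4 calling. Candidates failing
#' `min_units`, `min_seed_units` or `min_total_length` are dropped.
#' Overlapping candidates on the same strand are resolved by keeping the one
#' with more seed units, then more units, then the smaller start; hits on
#' opposite strands may overlap and are both kept.
#'
#' Windows containing N never match. Minus-strand hits are found on the
#' reverse complement and reported in forward 0-based half-open coordinates;
#' their `units` are read 5'->3' on the minus strand.
#'
#' @param genome A [genome_record()].
#' @param preset A [repeat_preset()]; see [builtin_presets()].
#' @return Tibble of repeat hits sorted by start: `genome_id`, `start`,
#'   `end`, `strand`, `units` (list column), `n_units`, `n_seed_units`,
#'   `trailing_partial`, `intact_tracts_max_run`, `g4_capable`,
#'   `preset_name`, `repeat_id`.
#' @export
#' @examples
#' g <- genome_record("g1", paste0("TT", strrep("GGGAATC", 4), "TT"))
#' scan_repeats(g, builtin_presets()$xan)
scan_repeats <- function(genome, preset) {
  genome <- as_genome_record(genome)
  assert_that(inherits(preset, "repeat_preset"), "preset must be a repeat_preset")
  seq_fwd <- genome$sequence
  n <- genome$length
  per_strand <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq_fwd else revcomp(seq_fwd)
    cand <- scan_strand_arrays(s, preset)
    if (nrow(cand) == 0) next
    cand$n_seed_units <- vapply(cand$units, function(u)
      sum(u %in% preset$seed_units), integer(1))
    len <- 7L * cand$n_units + nchar(cand$trailing_partial)
    if (strand == "+") {
      cand$start <- cand$pos1 - 1L
    } else {
      cand$start <- n - (cand$pos1 - 1L) - len
    }
    cand$end <- cand$start + len
    cand <- cand[cand$n_units >= preset$min_units &
                   cand$n_seed_units >= preset$min_seed_units &
                   (7L * cand$n_units + nchar(cand$trailing_partial)) >=
                     preset$min_total_length, ]
    if (nrow(cand) == 0) next
    cand <- resolve_overlaps(cand)
    cand$strand <- strand
    per_strand[[strand]] <- cand
  }
  if (length(per_strand) == 0) return(empty_repeat_hits())
  hits <- bind_rows(per_strand)
  g4 <- lapply(seq_len(nrow(hits)), function(i)
    call_g4_capability(hits$units[[i]], hits$trailing_partial[i],
                       preset$tract_prefix_length))
  tibble(
    genome_id = genome$id,
    start = as.integer(hits$start),
    end = as.integer(hits$end),
    strand = hits$strand,
    units = hits$units,
    n_units = as.integer(hits$n_units),
    n_seed_units = as.integer(hits$n_seed_units),
    trailing_partial = hits$trailing_partial,
    intact_tracts_max_run = vapply(g4, `[[`, integer(1), "intact_tracts_max_run"),
    g4_capable = vapply(g4, `[[`, logical(1), "g4_capable"),
    preset_name = preset$name,
    repeat_id = hit_id(genome$id, as.integer(hits$start),
                       as.integer(hits$end), hits$strand)
  ) |> arrange(.data$start, .data$end, .data$strand)
}
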