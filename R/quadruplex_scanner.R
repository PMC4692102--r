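#' Scan a genome for putative G-quadruplex motifs
#'
#' Generic regex-style PQS scan: on each strand, a G-tract is a maximal run
#' of at least `g_min` guanines; consecutive tracts chain when separated by a
#' loop of `loop_min` to `loop_max` bases; a hit is a maximal chain of at
#' least `min_tracts` tracts. Hits are greedy, maximal and non-overlapping
#' per strand (a chain of five tracts is one five-tract hit, not two
#' overlapping four-tract hits). Minus-strand hits (C-tract patterns on the
#' forward strand) are found by scanning the reverse complement and reported
#' in forward 0-based half-open coordinates.
#'
#' @param genome A [genome_record()].
#' @param g_min Minimum G-tract length (>= 2); default 3.
#' @param loop_min,loop_max Loop length bounds in bases; defaults 1 and 5.
#' @param min_tracts Minimum number of chained tracts (>= 4).
#' @param g_max Optional maximum tract length. A maximal G run longer than
#'   `g_max` is not a qualifying tract (runs are never split), so chains
#'   break across it.
#' @return Tibble of hits sorted by start: `genome_id`, `start`, `end`,
#'   `strand`, `n_tracts`, `tract_lengths` (list), `loop_lengths` (list),
#'   `sequence` (on the hit strand), `pqs_id`.
#' @export
#' @examples
#' scan_pqs(genome_record("g1", "GGGAGGGTGGGCGGG"))
scan_pqs <- function(genome, g_min = 3L, loop_min = 1L, loop_max = 5L,
                     min_tracts = 4L, g_max = NULL) {
  genome <- as_genome_record(genome)
  assert_that(g_min >= 2, "g_min must be >= 2")
  assert_that(loop_min >= 1, "loop_min must be >= 1")
  assert_that(loop_max >= loop_min, "loop_max must be >= loop_min")
  assert_that(min_tracts >= 4, "min_tracts must be >= 4")
  n <- genome$length
  res <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") genome$sequence else revcomp(genome$sequence)
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    r <- rle(chars == "G")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    is_tract <- r$values & r$lengths >= g_min
    if (!is.null(g_max)) is_tract <- is_tract & r$lengths <= g_max
    t_start <- starts[is_tract]
    t_end <- ends[is_tract]
    t_len <- r$lengths[is_tract]
    m <- length(t_start)
    if (m < min_tracts) next
    gaps <- t_start[-1] - t_end[-m] - 1L
    chain_break <- gaps < loop_min | gaps > loop_max
    grp <- cumsum(c(0L, as.integer(chain_break)))
    for (g in unique(grp)) {
      idx <- which(grp == g)
      if (length(idx) < min_tracts) next
      h_start1 <- t_start[idx[1]]
      h_end1 <- t_end[idx[length(idx)]]
      len <- h_end1 - h_start1 + 1L
      if (strand == "+") {
        start0 <- h_start1 - 1L
      } else {
        start0 <- n - h_end1
      }
      res[[length(res) + 1L]] <- tibble(
        genome_id = genome$id,
        start = start0, end = start0 + len, strand = strand,
        n_tracts = length(idx),
        tract_lengths = list(as.integer(t_len[idx])),
        loop_lengths = list(as.integer(
          if (length(idx) > 1) gaps[idx[-length(idx)]] else integer(0))),
        sequence = substr(s, h_start1, h_end1))
    }
  }
  if (length(res) == 0) {
    return(tibble(genome_id = character(), start = integer(), end = integer(),
                  strand = character(), n_tracts = integer(),
                  tract_lengths = list(), loop_lengths = list(),
                  sequence = character(), pqs_id = character()))
  }
  out <- bind_rows(res) |> arrange(.data$start, .data$end, .data$strand)
  out$pqs_id <- hit_id(out$genome_id, out$start, out$end, out$strand,
                       prefix = "pqs")
  out
}
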