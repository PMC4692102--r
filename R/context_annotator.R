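#' Distance bin for repeat-to-ORF distances
#'
#' Repeats overlapping an ORF boundary or within 50 bp are grouped together;
#' the bins are 0-50 bp (inclusive), 50-100 bp and > 100 bp.
#'
#' @param d Non-negative distance(s) in bases.
#' @return Character vector of bins: "d0_50", "d50_100", "d_gt100".
#' @export
#' @examples
#' distance_bin(c(0, 50, 51, 101))
distance_bin <- function(d) {
  assert_that(all(d >= 0), "distance must be non-negative")
  dplyr::case_when(d <= 50 ~ "d0_50", d <= 100 ~ "d50_100", TRUE ~ "d_gt100")
}

#' Orientation class of the ORFs flanking an intergenic repeat
#'
#' @param left_strand,right_strand Strands ("+"/"-") of the left and right
#'   flanking ORFs in genomic order, or `NA` when a neighbor is missing
#'   (genome end).
#' @param repeat_strand Strand carrying the repeat's G-rich reading.
#' @return One of "aligned_coding", "aligned_noncoding", "convergent",
#'   "divergent", "undefined".
#' @export
#' @examples
#' orientation_class("+", "+", "+")
#' orientation_class("+", "-", "+")
orientation_class <- function(left_strand, right_strand, repeat_strand) {
  if (is.na(left_strand) || is.na(right_strand)) return("undefined")
  if (left_strand == right_strand) {
    if (repeat_strand == left_strand) "aligned_coding" else "aligned_noncoding"
  } else if (left_strand == "+" && right_strand == "-") {
    "convergent"
  } else {
    "divergent"
  }
}

# Index of the left (largest end <= start) and right (smallest start >= end)
# flanking ORFs for an interval, among ORFs sorted by start. Nested or
# overlapping ORFs: nearest by boundary distance, ties to the smaller start.
flanking_orfs <- function(start, end, orfs) {
  left_ok <- which(orfs$end <= start)
  right_ok <- which(orfs$start >= end)
  left <- if (length(left_ok)) {
    d <- start - orfs$end[left_ok]
    cand <- left_ok[d == min(d)]
    cand[which.min(orfs$start[cand])]
  } else NA_integer_
  right <- if (length(right_ok)) {
    d <- orfs$start[right_ok] - end
    cand <- right_ok[d == min(d)]
    cand[which.min(orfs$start[cand])]
  } else NA_integer_
  list(left = left, right = right)
}

#' Classify a repeat as intragenic or intergenic
#'
#' Any base overlap with an ORF makes the repeat intragenic: coding if the
#' repeat strand equals the ORF strand, otherwise noncoding. Ties among
#' several overlapped ORFs go to the largest overlap, then the smallest ORF
#' start.
#'
#' @param hit One-row tibble with `start`, `end`, `strand`.
#' @param orfs ORF tibble sorted by start (see [read_orfs()]).
#' @return List with `location_class` ("intragenic_coding",
#'   "intragenic_noncoding" or "intergenic") and `overlapped_orf` (locus tag
#'   or `NA`).
#' @export
classify_location <- function(hit, orfs) {
  ov <- pmin(orfs$end, hit$end) - pmax(orfs$start, hit$start)
  idx <- which(ov > 0)
  if (length(idx) == 0) {
    return(list(location_class = "intergenic", overlapped_orf = NA_character_))
  }
  best <- idx[order(-ov[idx], orfs$start[idx])][1]
  cls <- if (orfs$strand[best] == hit$strand) "intragenic_coding"
         else "intragenic_noncoding"
  list(location_class = cls, overlapped_orf = orfs$locus_tag[best])
}

# Relation of an intergenic hit to one flanking ORF.
# side: "left" (ORF genomically before the hit) or "right" (after).
neighbor_relation_one <- function(hit, orf, side) {
  gap <- if (side == "left") hit$start - orf$end else orf$start - hit$end
  gap <- max(gap, 0L)
  # The ORF's start codon sits at its 5' edge in its own orientation:
  # right edge for "-" ORFs, left edge for "+" ORFs.
  relation <- if (side == "right") {
    if (orf$strand == "+") "repeat_upstream_of_orf" else "repeat_downstream_of_orf"
  } else {
    if (orf$strand == "+") "repeat_downstream_of_orf" else "repeat_upstream_of_orf"
  }
  tibble(
    orf_locus_tag = orf$locus_tag,
    side = side,
    relation = relation,
    strand_relation = if (hit$strand == orf$strand) "coding" else "noncoding",
    distance = as.integer(gap),
    bin = distance_bin(gap))
}

#' Neighbor relations of an intergenic repeat
#'
#' Emits one relation per flanking ORF (up to two): the repeat is upstream of
#' an ORF whose start codon lies ahead of it in the ORF's own orientation,
#' and downstream of an ORF whose stop codon precedes it. Distance counts
#' the bases strictly between the repeat boundary and the codon boundary
#' (0 when adjacent or overlapping). `strand_relation` is coding iff the
#' repeat strand equals the ORF strand.
#'
#' @param hit One-row tibble with `start`, `end`, `strand` (intergenic).
#' @param orfs ORF tibble sorted by start.
#' @return Tibble with 0-2 rows: `orf_locus_tag`, `side`, `relation`,
#'   `strand_relation`, `distance`, `bin`.
#' @export
neighbor_relations <- function(hit, orfs) {
  fl <- flanking_orfs(hit$start, hit$end, orfs)
  out <- list()
  if (!is.na(fl$left)) {
    out[[length(out) + 1L]] <- neighbor_relation_one(hit, orfs[fl$left, ], "left")
  }
  if (!is.na(fl$right)) {
    out[[length(out) + 1L]] <- neighbor_relation_one(hit, orfs[fl$right, ], "right")
  }
  if (length(out) == 0) {
    return(tibble(orf_locus_tag = character(), side = character(),
                  relation = character(), strand_relation = character(),
                  distance = integer(), bin = character()))
  }
  bind_rows(out)
}

#' Annotate repeats relative to ORF annotations
#'
#' For every repeat hit: intragenic/intergenic location, neighbor-orientation
#' class (intergenic only; intragenic repeats are "undefined"), and the
#' relation, distance and distance bin to each flanking ORF. A missing
#' neighbor at a genome end yields an "undefined" orientation class, which is
#' reported, never dropped.
#'
#' @param hits Repeat hits from [scan_repeats()].
#' @param orfs ORF tibble from [read_orfs()].
#' @return Tibble with one row per hit: `repeat_id`, `location_class`,
#'   `overlapped_orf`, `orientation_class`, and for each of the left/right
#'   neighbors the locus tag, relation, strand relation, distance and bin
#'   (`NA` where absent or intragenic).
#' @export
annotate_context <- function(hits, orfs) {
  orfs <- arrange(orfs, .data$start, .data$end)
  rows <- lapply(seq_len(nrow(hits)), function(i) {
    hit <- hits[i, ]
    loc <- classify_location(hit, orfs)
    row <- tibble(
      repeat_id = hit$repeat_id,
      location_class = if (loc$location_class == "intergenic") "intergenic"
                       else loc$location_class,
      overlapped_orf = loc$overlapped_orf,
      orientation_class = NA_character_,
      left_locus_tag = NA_character_, left_relation = NA_character_,
      left_strand_relation = NA_character_, left_distance = NA_integer_,
      left_bin = NA_character_,
      right_locus_tag = NA_character_, right_relation = NA_character_,
      right_strand_relation = NA_character_, right_distance = NA_integer_,
      right_bin = NA_character_)
    if (loc$location_class != "intergenic") {
      row$orientation_class <- "undefined"
      return(row)
    }
    fl <- flanking_orfs(hit$start, hit$end, orfs)
    row$orientation_class <- orientation_class(
      if (is.na(fl$left)) NA_character_ else orfs$strand[fl$left],
      if (is.na(fl$right)) NA_character_ else orfs$strand[fl$right],
      hit$strand)
    rel <- neighbor_relations(hit, orfs)
    for (s in c("left", "right")) {
      r <- rel[rel$side == s, ]
      if (nrow(r) == 1) {
        row[[paste0(s, "_locus_tag")]] <- r$orf_locus_tag
        row[[paste0(s, "_relation")]] <- r$relation
        row[[paste0(s, "_strand_relation")]] <- r$strand_relation
        row[[paste0(s, "_distance")]] <- r$distance
        row[[paste0(s, "_bin")]] <- r$bin
      }
    }
    row
  })
  if (length(rows) == 0) {
    return(tibble(repeat_id = character(), location_class = character(),
                  overlapped_orf = character(), orientation_class = character()))
  }
  bind_rows(rows)
}

#' Detect convergent inverted repeat pairs
#'
#' A pair is a plus-strand (G-rich) array followed by a minus-strand array
#' (G-rich then C-rich on the forward strand) with a gap of at most
#' `max_gap` bases. Each hit joins at most one pair; candidate pairs are
#' matched nearest-gap first, ties to the leftmost partner.
#'
#' @param hits Repeat hits from one genome.
#' @param max_gap Maximum gap in bases between the two arrays (default 100).
#' @return Tibble: `plus_repeat_id`, `minus_repeat_id`, `gap`.
#' @export
detect_inverted_pairs <- function(hits, max_gap = 100L) {
  plus <- hits[hits$strand == "+", ]
  minus <- hits[hits$strand == "-", ]
  if (nrow(plus) == 0 || nrow(minus) == 0) {
    return(tibble(plus_repeat_id = character(),
                  minus_repeat_id = character(), gap = integer()))
  }
  cand <- tidyr::expand_grid(p = seq_len(nrow(plus)), m = seq_len(nrow(minus)))
  cand$gap <- minus$start[cand$m] - plus$end[cand$p]
  cand <- cand[cand$gap >= 0 & cand$gap <= max_gap, ]
  cand <- cand[order(cand$gap, plus$start[cand$p], minus$start[cand$m]), ]
  used_p <- logical(nrow(plus)); used_m <- logical(nrow(minus))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!used_p[cand$p[i]] && !used_m[cand$m[i]]) {
      keep[i] <- TRUE
      used_p[cand$p[i]] <- TRUE
      used_m[cand$m[i]] <- TRUE
    }
  }
  cand <- cand[keep, ]
  out <- tibble(plus_repeat_id = plus$repeat_id[cand$p],
                minus_repeat_id = minus$repeat_id[cand$m],
                gap = as.integer(cand$gap))
  arrange(out, .data$plus_repeat_id)
}
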