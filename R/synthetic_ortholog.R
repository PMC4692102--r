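#' Simulate an ortholog genome with truth alignments
#'
#' Derives a subject genome from a query genome by applying at most one edit
#' per query region: an `insertion` of foreign sequence into the intergenic
#' span, a `deletion` from it, `flanking_loss` (one flanking ORF replaced by
#' unrelated sequence), `locus_loss` (the whole region replaced), or `none`.
#' Edits never touch a planted repeat. Exact truth alignments (12-column
#' tabular format, 100% identity) are emitted for every unedited homologous
#' block, with query coordinates local to each region and subject
#' coordinates absolute on the subject genome.
#'
#' @param genome Query [genome_record()].
#' @param orfs Query ORF tibble.
#' @param truth Truth list from [simulate_survey()] (for repeat locations).
#' @param regions Query regions to edit; default: the repeat-containing
#'   regions of the survey.
#' @param edit_rates Named probabilities for `insertion`, `deletion`,
#'   `flanking_loss`, `locus_loss` (rest is `none`); must sum to <= 1.
#' @param sizes Named list of base ranges for `insertion` and `deletion`.
#' @param seed Integer seed; same seed gives an identical subject genome and
#'   alignment table.
#' @return List: `subject_genome`, `edits` (tibble: `region_id`,
#'   `edit_kind`, `size`), `alignments` (tibble as from
#'   [parse_alignment_table()]).
#' @export
simulate_ortholog <- function(genome, orfs, truth, regions = NULL,
                              edit_rates = c(insertion = 0, deletion = 0,
                                             flanking_loss = 0,
                                             locus_loss = 0),
                              sizes = list(insertion = c(400L, 800L),
                                           deletion = c(50L, 200L)),
                              seed = 1L) {
  assert_that(sum(edit_rates) <= 1 + 1e-9, "edit rates must sum to <= 1")
  genome <- as_genome_record(genome)
  hits <- truth$planted_repeats
  if (is.null(regions)) {
    regions <- build_query_regions(orfs, hits)
    regions <- regions[regions$contains_repeat, ]
  }
  regions <- arrange(regions, .data$region_start)
  withr::with_seed(seed, {
    kinds <- c("insertion", "deletion", "flanking_loss", "locus_loss")
    probs <- c(edit_rates[kinds], none = 1 - sum(edit_rates))
    probs[is.na(probs)] <- 0
    gc <- mean(strsplit(genome$sequence, "", fixed = TRUE)[[1]] %in% c("G", "C"))
    # keep foreign sequence free of any builtin seed so inserted material
    # never fakes a repeat locus
    seeds_words <- c("GGGAATC", "GGGGATT", "GGGGACT")
    seeds_words <- unique(c(seeds_words, revcomp(seeds_words)))
    foreign <- function(n) {
      ch <- random_bases(n, gc)
      paste(scrub_words(ch, seeds_words, rep(FALSE, n), gc), collapse = "")
    }
    subject_id <- paste0(genome$id, "_ortholog")
    parts <- character(0)
    last_cut <- 0L  # 0-based query position already emitted
    offset <- 0L    # subject - query coordinate shift
    aln_rows <- list()
    edit_rows <- list()
    emit_block <- function(region, q1_abs, q2_abs, offset) {
      # absolute 1-based query coords -> one alignment row
      if (q2_abs < q1_abs) return(NULL)
      tibble(query_id = region$region_id, subject_id = subject_id,
             percent_identity = 100, aln_length = q2_abs - q1_abs + 1L,
             mismatches = 0L, gap_opens = 0L,
             qstart = q1_abs - region$region_start,
             qend = q2_abs - region$region_start,
             sstart = q1_abs + offset, send = q2_abs + offset,
             evalue = 0, bitscore = 2 * (q2_abs - q1_abs + 1L),
             orientation = "+")
    }
    for (i in seq_len(nrow(regions))) {
      region <- regions[i, ]
      kind <- sample(names(probs), 1, prob = probs)
      r1 <- region$region_start + 1L  # 1-based absolute region span
      r2 <- region$region_end
      i1 <- region$inter_start + 1L   # 1-based intergenic span
      i2 <- region$inter_end
      rep_hit <- if (isTRUE(region$contains_repeat))
        hits[hits$repeat_id == region$repeat_id, ] else NULL
      size <- 0L
      if (kind == "insertion") {
        size <- sample_vec(sizes$insertion[1]:sizes$insertion[2], 1)
        # insertion point inside the intergenic span, clear of the repeat
        gaps <- free_intergenic_gaps(i1, i2, rep_hit)
        g <- gaps[[which.max(vapply(gaps, function(x) x[2] - x[1], numeric(1)))]]
        p <- as.integer(floor((g[1] + g[2]) / 2))
        aln_rows[[length(aln_rows) + 1L]] <- emit_block(region, r1, p, offset)
        parts <- c(parts, substr(genome$sequence, last_cut + 1L, p),
                   foreign(size))
        last_cut <- p
        aln_rows[[length(aln_rows) + 1L]] <-
          emit_block(region, p + 1L, r2, offset + size)
        offset <- offset + size
      } else if (kind == "deletion") {
        want <- sample_vec(sizes$deletion[1]:sizes$deletion[2], 1)
        gaps <- free_intergenic_gaps(i1, i2, rep_hit)
        g <- gaps[[which.max(vapply(gaps, function(x) x[2] - x[1], numeric(1)))]]
        room <- max(0L, g[2] - g[1] - 1L)
        size <- min(want, room)
        if (size > 0) {
          d1 <- as.integer(floor((g[1] + g[2]) / 2) - floor(size / 2))
          d2 <- d1 + size - 1L
          aln_rows[[length(aln_rows) + 1L]] <-
            emit_block(region, r1, d1 - 1L, offset)
          parts <- c(parts, substr(genome$sequence, last_cut + 1L, d1 - 1L))
          last_cut <- d2
          aln_rows[[length(aln_rows) + 1L]] <-
            emit_block(region, d2 + 1L, r2, offset - size)
          offset <- offset - size
        } else {
          kind <- "none"
          aln_rows[[length(aln_rows) + 1L]] <- emit_block(region, r1, r2, offset)
        }
      } else if (kind == "flanking_loss") {
        side <- sample(c("left", "right"), 1)
        if (side == "left") {
          lose1 <- r1; lose2 <- region$left_end
          keep1 <- i1; keep2 <- r2
        } else {
          lose1 <- region$right_start + 1L; lose2 <- r2
          keep1 <- r1; keep2 <- i2
        }
        size <- lose2 - lose1 + 1L
        aln_rows[[length(aln_rows) + 1L]] <- emit_block(region, keep1, keep2, offset)
        parts <- c(parts, substr(genome$sequence, last_cut + 1L, lose1 - 1L),
                   foreign(size))
        last_cut <- lose2
      } else if (kind == "locus_loss") {
        size <- r2 - r1 + 1L
        parts <- c(parts, substr(genome$sequence, last_cut + 1L, r1 - 1L),
                   foreign(size))
        last_cut <- r2
      } else {
        aln_rows[[length(aln_rows) + 1L]] <- emit_block(region, r1, r2, offset)
      }
      edit_rows[[length(edit_rows) + 1L]] <- tibble(
        region_id = region$region_id, edit_kind = kind, size = as.integer(size))
    }
    parts <- c(parts, substr(genome$sequence, last_cut + 1L, genome$length))
    subject <- genome_record(subject_id, paste(parts, collapse = ""))
    aln <- if (length(aln_rows) > 0) bind_rows(aln_rows) else
      empty_alignments()
    list(subject_genome = subject,
         edits = bind_rows(edit_rows),
         alignments = aln)
  })
}

# Sub-intervals (1-based inclusive) of the intergenic span [i1, i2] clear of
# the repeat array, with a 5-base safety margin.
free_intergenic_gaps <- function(i1, i2, rep_hit) {
  if (is.null(rep_hit) || nrow(rep_hit) == 0) return(list(c(i1, i2)))
  h1 <- min(rep_hit$start) + 1L - 5L
  h2 <- max(rep_hit$end) + 5L
  gaps <- list()
  if (h1 - 1L >= i1) gaps[[length(gaps) + 1L]] <- c(i1, h1 - 1L)
  if (i2 >= h2 + 1L) gaps[[length(gaps) + 1L]] <- c(h2 + 1L, i2)
  if (length(gaps) == 0) gaps <- list(c(i1, i1))
  gaps
}

#' Simulate transcripts realizing planted position classes
#'
#' For every intergenic planted repeat, assigns a transcript position class
#' (largest-remainder rounding of `class_mix`, shuffled deterministically
#' under the seed) and a strand content (g_rich fraction likewise), then
#' emits a transcript interval realizing exactly that class under the rules
#' of [classify_transcript_position()] — or withholds one for
#' `no_transcript`. Transcripts never touch any other planted repeat.
#'
#' @param genome [genome_record()] from [simulate_survey()].
#' @param orfs ORF tibble from the survey.
#' @param truth Truth list from [simulate_survey()].
#' @param class_mix Named fractions over `start`, `stop`, `middle`,
#'   `no_transcript`; must sum to 1.
#' @param g_rich_fraction Fraction of transcribed repeats whose transcript
#'   reads the G-rich strand.
#' @param max_after Stop window in bases (default 30).
#' @param seed Integer seed.
#' @return List: `transcripts` (tibble as from [read_transcripts()]),
#'   `planted_classes` (tibble: `repeat_id`, `position_class`,
#'   `strand_content`).
#' @export
simulate_transcripts <- function(genome, orfs, truth,
                                 class_mix = c(start = 0.25, stop = 0.25,
                                               middle = 0.25,
                                               no_transcript = 0.25),
                                 g_rich_fraction = 0.5, max_after = 30L,
                                 seed = 1L) {
  assert_that(abs(sum(class_mix) - 1) < 1e-9, "class_mix must sum to 1")
  genome <- as_genome_record(genome)
  all_hits <- arrange(truth$planted_repeats, .data$start)
  keep <- !startsWith(all_hits$orientation_category, "intragenic")
  n_all <- nrow(all_hits)
  # windows clear of *every* planted repeat (including intragenic ones)
  lo_all <- c(0L, all_hits$end[-n_all] + 1L)
  hi_all <- c(all_hits$start[-1] - 1L, genome$length)
  hits <- all_hits[keep, ]
  lo <- lo_all[keep]
  hi <- hi_all[keep]
  n <- nrow(hits)
  if (n == 0) {
    return(list(transcripts = tibble(), planted_classes = tibble()))
  }
  withr::with_seed(seed, {
    classes <- c("start", "stop", "middle", "no_transcript")
    cm <- class_mix[classes]
    cm[is.na(cm)] <- 0
    quota <- largest_remainder(as.numeric(cm), n)
    names(quota) <- classes
    n_tx <- n - quota[["no_transcript"]]
    n_grich <- largest_remainder(c(g_rich_fraction, 1 - g_rich_fraction),
                                 n_tx)[1]
    ord <- sample_vec(seq_len(n))
    assign <- rep(NA_character_, n)
    # a middle-class transcript needs max_after + 2 bases past the repeat on
    # its 3' side; assign middle first to repeats with room on some side
    room_right <- hi - hits$end
    room_left <- hits$start - lo
    need <- max_after + 2L
    feasible_mid <- room_right >= need | room_left >= need
    take <- ord[feasible_mid[ord]]
    assert_that(length(take) >= quota[["middle"]],
                "not enough room between repeats to realize 'middle' transcripts")
    take <- take[seq_len(quota[["middle"]])]
    assign[take] <- "middle"
    rest <- setdiff(ord, take)
    assign[rest] <- rep(c("start", "stop", "no_transcript"),
                        c(quota[["start"]], quota[["stop"]],
                          quota[["no_transcript"]]))
    tx_idx <- which(assign != "no_transcript")
    grich <- rep(NA, n)
    grich[sample_vec(tx_idx)] <- rep(c(TRUE, FALSE),
                                     c(n_grich, n_tx - n_grich))
    # middle transcripts are direction-constrained: the 3' side must have
    # room. Repair by swapping g-rich labels (counts preserved) with a
    # repeat whose class is direction-agnostic.
    for (i in which(assign == "middle")) {
      dir_ok <- c("+" = room_right[i] >= need, "-" = room_left[i] >= need)
      tx_strand <- if (grich[i]) hits$strand[i] else
        if (hits$strand[i] == "+") "-" else "+"
      if (dir_ok[[tx_strand]]) next
      needed_dir <- names(dir_ok)[dir_ok][1]
      needed_grich <- needed_dir == hits$strand[i]
      cand <- which(assign %in% c("start", "stop") & grich == needed_grich)
      assert_that(length(cand) > 0,
                  "cannot realize 'middle' transcript directions with this g_rich split")
      j <- cand[1]
      grich[j] <- grich[i]
      grich[i] <- needed_grich
    }
    tx_rows <- list()
    truth_rows <- list()
    for (i in seq_len(n)) {
      h <- hits[i, ]
      cls <- assign[i]
      if (cls == "no_transcript") {
        truth_rows[[length(truth_rows) + 1L]] <- tibble(
          repeat_id = h$repeat_id, position_class = cls,
          strand_content = NA_character_)
        next
      }
      tx_strand <- if (grich[i]) h$strand else if (h$strand == "+") "-" else "+"
      # choose the transcript's 3' side so the class is realizable
      span <- make_transcript_span(cls, tx_strand, h$start, h$end,
                                   lo[i], hi[i], max_after)
      tx_rows[[length(tx_rows) + 1L]] <- tibble(
        transcript_id = sprintf("tx_%04d", i),
        genome_id = genome$id,
        start = span[1], end = span[2], strand = tx_strand,
        expression = round(runif(1, 1, 500), 1))
      truth_rows[[length(truth_rows) + 1L]] <- tibble(
        repeat_id = h$repeat_id, position_class = cls,
        strand_content = if (grich[i]) "g_rich" else "c_rich")
    }
    list(transcripts = bind_rows(tx_rows),
         planted_classes = bind_rows(truth_rows))
  })
}

# 0-based half-open transcript span realizing a position class for a repeat
# [r1, r2) with transcript strand tx_strand, confined to [lo, hi].
make_transcript_span <- function(cls, tx_strand, r1, r2, lo, hi, max_after) {
  ext5 <- sample_vec(10:60, 1)  # extension on the 5' side when outside
  if (tx_strand == "+") {
    if (cls == "start") {
      s <- sample_vec(r1:(r2 - 1L), 1)
      e <- min(hi, r2 + sample_vec(0:40, 1))
      e <- max(e, s + 1L)
    } else if (cls == "stop") {
      s <- max(lo, r1 - ext5)
      off <- sample_vec(0:min(max_after, hi - r2), 1)
      e <- r2 + off
    } else {
      if (hi - r2 >= max_after + 2L) {
        s <- max(lo, r1 - ext5)
        e <- r2 + max_after + 1L +
          sample_vec(0:max(0L, hi - r2 - max_after - 1L), 1)
        e <- min(e, hi)
      } else {
        # not enough room on the right: flip to the minus strand would change
        # content; instead start inside is forbidden, so extend left and end
        # inside the repeat is also forbidden -> must have been guarded
        abort("internal: no room for a middle-class plus transcript")
      }
    }
  } else {
    if (cls == "start") {
      e <- sample_vec((r1 + 1L):r2, 1)
      s <- max(lo, r1 - sample_vec(0:40, 1))
      s <- min(s, e - 1L)
    } else if (cls == "stop") {
      e <- min(hi, r2 + ext5)
      off <- sample_vec(0:min(max_after, r1 - lo), 1)
      s <- r1 - off
    } else {
      if (r1 - lo >= max_after + 2L) {
        e <- min(hi, r2 + ext5)
        s <- r1 - max_after - 1L -
          sample_vec(0:max(0L, r1 - lo - max_after - 1L), 1)
        s <- max(s, lo)
      } else {
        abort("internal: no room for a middle-class minus transcript")
      }
    }
  }
  c(as.integer(s), as.integer(e))
}
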