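#' Split repeats into G4-capable and control sets
#'
#' Repeats located in coding regions (intragenic) are excluded; the rest are
#' labelled `g4` when G4-capable (at least four consecutive intact G-tracts)
#' and `control` otherwise. Both members of an inverted pair are retained
#' individually.
#'
#' @param hits Repeat hits.
#' @param contexts Context annotations covering all hits.
#' @return Tibble: `repeat_id`, `set_label`.
#' @export
assign_sets <- function(hits, contexts) {
  missing_ctx <- setdiff(hits$repeat_id, contexts$repeat_id)
  if (length(missing_ctx) > 0) {
    abort(sprintf("context missing for %d hit(s)", length(missing_ctx)))
  }
  ctx <- contexts[match(hits$repeat_id, contexts$repeat_id), ]
  keep <- ctx$location_class == "intergenic"
  tibble(repeat_id = hits$repeat_id[keep],
         set_label = ifelse(hits$g4_capable[keep], "g4", "control"))
}

#' Read transcript intervals from BED6 or GFF3
#'
#' @param path File path.
#' @param format "bed" or "gff3".
#' @return Tibble: `transcript_id`, `genome_id`, `start`, `end` (0-based
#'   half-open), `strand`, `expression` (BED score column or GFF3 score,
#'   NA when absent).
#' @export
read_transcripts <- function(path, format = c("bed", "gff3")) {
  format <- match.arg(format)
  if (format == "bed") {
    df <- read_intervals(path, "bed")
    tibble(transcript_id = df$name, genome_id = df$genome_id,
           start = df$start, end = df$end, strand = df$strand,
           expression = as.numeric(df$score))
  } else {
    gr <- rtracklayer::import(path)
    df <- as.data.frame(gr)
    id <- if ("ID" %in% names(df)) as.character(df$ID)
          else sprintf("tx_%d", seq_len(nrow(df)))
    tibble(transcript_id = id,
           genome_id = as.character(df$seqnames),
           start = as.integer(df$start) - 1L,
           end = as.integer(df$end),
           strand = ifelse(as.character(df$strand) == "-", "-", "+"),
           expression = if ("score" %in% names(df)) as.numeric(df$score)
                        else NA_real_)
  }
}

# Position class of one repeat against one chosen transcript.
transcript_position_class <- function(hit, tx, max_after) {
  if (tx$strand == "+") {
    five_inside <- tx$start >= hit$start && tx$start < hit$end
    stop_cond <- tx$end <= hit$end + max_after && tx$end > hit$start
  } else {
    five_inside <- tx$end <= hit$end && tx$end > hit$start
    stop_cond <- tx$start >= hit$start - max_after && tx$start < hit$end
  }
  if (five_inside) "start" else if (stop_cond) "stop" else "middle"
}

#' Classify repeat positions on assembled transcripts
#'
#' For every repeat, candidate transcripts are those overlapping it by at
#' least one base, plus transcripts abutting the repeat whose 3' end lies
#' within `max_after` bases downstream of it (in the transcript's reading
#' direction). With no candidate the class is `no_transcript`. Otherwise the
#' transcript with the greatest overlap wins (ties: higher expression, then
#' longer, then smaller start) and the repeat is classified: transcript
#' 5' end inside the repeat span is `start`; 3' end inside the span or at
#' most `max_after` bases past the repeat's boundary in transcript direction
#' is `stop`; anything else is `middle`. `strand_content` is `g_rich` when
#' the transcript strand equals the repeat's G-rich strand, else `c_rich`.
#'
#' @param hits Repeat hits.
#' @param transcripts Transcript tibble (see [read_transcripts()]); an
#'   `expression` column is optional.
#' @param max_after Stop window in bases past the repeat (default 30).
#' @return Tibble, one row per hit: `repeat_id`, `position_class`,
#'   `transcript_id`, `strand_content`.
#' @export
classify_transcript_position <- function(hits, transcripts, max_after = 30L) {
  if (!"expression" %in% names(transcripts)) transcripts$expression <- NA_real_
  rows <- lapply(seq_len(nrow(hits)), function(i) {
    hit <- hits[i, ]
    ov <- pmin(transcripts$end, hit$end) - pmax(transcripts$start, hit$start)
    # transcripts running past the repeat's 3' side within the stop window,
    # touching the repeat locus
    abut_stop <- ifelse(
      transcripts$strand == "+",
      transcripts$start == hit$end &
        transcripts$end <= hit$end + max_after,
      transcripts$end == hit$start &
        transcripts$start >= hit$start - max_after)
    cand <- which(ov >= 1 | (ov == 0 & abut_stop))
    if (length(cand) == 0) {
      return(tibble(repeat_id = hit$repeat_id,
                    position_class = "no_transcript",
                    transcript_id = NA_character_,
                    strand_content = NA_character_))
    }
    expr <- transcripts$expression[cand]
    expr[is.na(expr)] <- -Inf
    len <- transcripts$end[cand] - transcripts$start[cand]
    best <- cand[order(-ov[cand], -expr, -len, transcripts$start[cand])][1]
    tx <- transcripts[best, ]
    tibble(repeat_id = hit$repeat_id,
           position_class = transcript_position_class(hit, tx, max_after),
           transcript_id = tx$transcript_id,
           strand_content = if (tx$strand == hit$strand) "g_rich" else "c_rich")
  })
  if (length(rows) == 0) {
    return(tibble(repeat_id = character(), position_class = character(),
                  transcript_id = character(), strand_content = character()))
  }
  bind_rows(rows)
}

#' Transcript position calls for G4 and control repeat sets
#'
#' Convenience wrapper: excludes intragenic repeats, labels the rest g4 /
#' control ([assign_sets()]) and classifies each against the transcripts.
#'
#' @inheritParams classify_transcript_position
#' @param contexts Context annotations.
#' @return Calls tibble with `set_label` added.
#' @export
classify_transcripts <- function(hits, contexts, transcripts, max_after = 30L) {
  sets <- assign_sets(hits, contexts)
  kept <- hits[hits$repeat_id %in% sets$repeat_id, ]
  calls <- classify_transcript_position(kept, transcripts, max_after)
  left_join(calls, sets, by = "repeat_id")
}

#' Summarise transcript position calls
#'
#' Fractions per set label and position class; optionally split further by
#' strand content. Fractions sum to 1 within each set label.
#'
#' @param calls Calls from [classify_transcripts()] (must carry `set_label`).
#' @param by_strand Also split by `strand_content`?
#' @return Tibble: `set_label`, `position_class`, (`strand_content`,) `n`,
#'   `fraction` (within the set label).
#' @export
position_summary <- function(calls, by_strand = FALSE) {
  if (nrow(calls) == 0) {
    return(tibble(set_label = character(), position_class = character(),
                  n = integer(), fraction = double()))
  }
  keys <- c("set_label", "position_class",
            if (by_strand) "strand_content")
  calls |>
    dplyr::count(dplyr::across(dplyr::all_of(keys)), name = "n") |>
    group_by(.data$set_label) |>
    mutate(fraction = .data$n / sum(.data$n)) |>
    ungroup()
}
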