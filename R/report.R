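#' Aggregate survey report for one genome
#'
#' Runs the full survey on one genome — repeat scan, context annotation,
#' inverted pairs, unit histogram, composition, distance-bin table, PFM —
#' and collects the headline statistics in one list, writable as JSON.
#'
#' @param genome A [genome_record()].
#' @param orfs ORF annotation tibble.
#' @param preset A [repeat_preset()] (default: the xan preset).
#' @param max_gap Maximum gap for inverted-pair detection.
#' @return List of class `g4_survey`: `genome_id`, `genome_length`,
#'   `preset`, `repeat_count`, `g4_capable_count`, `pair_count`,
#'   `unit_histogram`, `composition`, `distance_bins`, `pfm`, plus the
#'   underlying `hits`, `contexts` and `pairs` tibbles.
#' @export
survey_report <- function(genome, orfs, preset = builtin_presets()$xan,
                          max_gap = 100L) {
  genome <- as_genome_record(genome)
  hits <- scan_repeats(genome, preset)
  contexts <- annotate_context(hits, orfs)
  pairs <- detect_inverted_pairs(hits, max_gap)
  structure(list(
    genome_id = genome$id,
    genome_length = genome$length,
    preset = preset$name,
    repeat_count = nrow(hits),
    g4_capable_count = sum(hits$g4_capable),
    pair_count = nrow(pairs),
    unit_histogram = unit_histogram(hits),
    composition = if (nrow(hits) > 0) composition_summary(hits, contexts)
                  else tibble(),
    distance_bins = distance_bin_table(contexts),
    pfm = if (nrow(hits) > 0) build_pfm(hits) else NULL,
    hits = hits, contexts = contexts, pairs = pairs
  ), class = "g4_survey")
}

#' @export
print.g4_survey <- function(x, ...) {
  cat(sprintf("<g4_survey of %s (%d bp), preset '%s'>\n",
              x$genome_id, x$genome_length, x$preset))
  cat(sprintf("  %d repeats (%d G4-capable), %d inverted pairs\n",
              x$repeat_count, x$g4_capable_count, x$pair_count))
  if (x$repeat_count > 0) {
    ig <- x$composition[x$composition$partition == "location" &
                          x$composition$category == "intergenic", ]
    if (nrow(ig) == 1) {
      cat(sprintf("  intergenic fraction: %.2f\n", ig$fraction))
    }
  }
  invisible(x)
}

#' Write a survey report as JSON
#'
#' Coordinates use the 0-based half-open convention; the report records it.
#'
#' @param report A `g4_survey` from [survey_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_survey_report <- function(report, path) {
  out <- list(
    schema = "g4repeats/survey-report/1",
    coordinate_convention = "0-based half-open, forward strand",
    genome_id = report$genome_id,
    genome_length = report$genome_length,
    preset = report$preset,
    repeat_count = report$repeat_count,
    g4_capable_count = report$g4_capable_count,
    pair_count = report$pair_count,
    unit_histogram = report$unit_histogram,
    composition = report$composition,
    distance_bins = report$distance_bins,
    pfm_frequencies = if (!is.null(report$pfm)) report$pfm$frequencies,
    pfm_info_bits = if (!is.null(report$pfm)) report$pfm$info_bits)
  writeLines(jsonlite::toJSON(out, dataframe = "rows", auto_unbox = TRUE,
                              digits = NA, pretty = TRUE), path)
  invisible(path)
}
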