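#' Define a heptamer repeat preset
#'
#' A preset bundles the definition of a G-rich heptameric tandem repeat
#' family: the exact seed heptamer(s) an array must contain, the degenerate
#' IUPAC unit that extension must match, and the thresholds that a candidate
#' array must meet. Unit length is fixed at 7.
#'
#' @param name Preset name ("xan", "ana", or anything for custom presets).
#' @param seed_units Character vector of exact 7-mers; every seed must match
#'   `degenerate_unit`.
#' @param degenerate_unit 7-character IUPAC pattern that every unit of an
#'   array must match.
#' @param min_units Minimum number of full units per array (>= 2).
#' @param min_seed_units Minimum number of units exactly equal to a seed.
#' @param min_total_length Minimum array length in bases (including any
#'   trailing partial unit).
#' @param tract_prefix_length Length of the unit's leading G run used for
#'   G4-capability calls (a unit's tract is intact iff its first
#'   `tract_prefix_length` bases are all G).
#' @return A list of class `repeat_preset`.
#' @export
#' @examples
#' repeat_preset("xan", "GGGAATC", "GGGANTN")
repeat_preset <- function(name, seed_units, degenerate_unit,
                          min_units = 2L, min_seed_units = 1L,
                          min_total_length = 14L, tract_prefix_length = 3L) {
  seed_units <- toupper(seed_units)
  degenerate_unit <- toupper(degenerate_unit)
  assert_that(nchar(degenerate_unit) == 7, "degenerate_unit must be 7 characters")
  assert_that(all(nchar(seed_units) == 7), "every seed unit must be 7 characters")
  assert_that(min_units >= 2, "min_units must be >= 2")
  assert_that(min_seed_units >= 1, "min_seed_units must be >= 1")
  assert_that(min_total_length <= 7 * min_units + 7,
              "min_total_length must be <= 7 * min_units + 7")
  sets <- iupac_pattern_sets(degenerate_unit)
  for (s in seed_units) {
    assert_that(matches_iupac(s, sets),
                sprintf("seed '%s' does not match degenerate unit '%s'",
                        s, degenerate_unit))
  }
  structure(
    list(name = name, seed_units = seed_units,
         degenerate_unit = degenerate_unit,
         min_units = as.integer(min_units),
         min_seed_units = as.integer(min_seed_units),
         min_total_length = as.integer(min_total_length),
         tract_prefix_length = as.integer(tract_prefix_length)),
    class = "repeat_preset")
}

#' Built-in repeat presets
#'
#' Two presets are shipped:
#' \describe{
#'   \item{xan}{The xanthomonad GGGAATC family: arrays of the degenerate unit
#'     GGGANTN containing at least one exact GGGAATC seed, at least 2 units
#'     and a total length of at least 14 bp.}
#'   \item{ana}{The cyanobacterial GGGGA(C/T)T family: arrays of the
#'     degenerate unit GGGGANT containing at least two exact seeds
#'     (GGGGATT or GGGGACT).}
#' }
#' Both presets call G4 capability from the leading 3-base G run of each unit.
#'
#' @return Named list of [repeat_preset()] objects.
#' @export
#' @examples
#' builtin_presets()$xan
builtin_presets <- function() {
  list(
    xan = repeat_preset(
      name = "xan", seed_units = "GGGAATC", degenerate_unit = "GGGANTN",
      min_units = 2L, min_seed_units = 1L, min_total_length = 14L,
      tract_prefix_length = 3L),
    ana = repeat_preset(
      name = "ana", seed_units = c("GGGGATT", "GGGGACT"),
      degenerate_unit = "GGGGANT",
      min_units = 2L, min_seed_units = 2L, min_total_length = 14L,
      tract_prefix_length = 3L)
  )
}

#' @export
print.repeat_preset <- function(x, ...) {
  cat(sprintf("<repeat_preset '%s'>\n", x$name))
  cat(sprintf("  seeds: %s\n", paste(x$seed_units, collapse = ", ")))
  cat(sprintf("  degenerate unit: %s\n", x$degenerate_unit))
  cat(sprintf("  min units: %d (>= %d seed), min total length: %d bp\n",
              x$min_units, x$min_seed_units, x$min_total_length))
  cat(sprintf("  G-tract prefix: %d\n", x$tract_prefix_length))
  invisible(x)
}

#' Read a repeat preset from a key=value config file
#'
#' Plain-text config with one `key = value` pair per line; `#` starts a
#' comment. Recognised keys mirror the [repeat_preset()] arguments;
#' `seed_units` takes a comma-separated list.
#'
#' @param path Path to the config file.
#' @return A [repeat_preset()].
#' @export
read_preset_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, function(x) length(x) != 2, logical(1))
  if (any(bad)) abort(sprintf("malformed config line: '%s'", lines[bad][1]))
  keys <- trimws(vapply(kv, `[`, character(1), 1))
  vals <- trimws(vapply(kv, `[`, character(1), 2))
  conf <- setNames(as.list(vals), keys)
  known <- c("name", "seed_units", "degenerate_unit", "min_units",
             "min_seed_units", "min_total_length", "tract_prefix_length")
  unknown <- setdiff(keys, known)
  if (length(unknown) > 0) {
    abort(sprintf("unknown preset key(s): %s", paste(unknown, collapse = ", ")))
  }
  repeat_preset(
    name = conf$name %||% "custom",
    seed_units = trimws(strsplit(conf$seed_units, ",", fixed = TRUE)[[1]]),
    degenerate_unit = conf$degenerate_unit,
    min_units = as.integer(conf$min_units %||% 2L),
    min_seed_units = as.integer(conf$min_seed_units %||% 1L),
    min_total_length = as.integer(conf$min_total_length %||% 14L),
    tract_prefix_length = as.integer(conf$tract_prefix_length %||% 3L))
}
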