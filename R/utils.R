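#' @importFrom rlang abort %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr arrange mutate filter select bind_rows group_by summarise ungroup desc n left_join
#' @importFrom stats pt sd setNames runif rbinom
NULL

# IUPAC nucleotide codes -> the set of concrete bases each matches.
# N deliberately matches only {A,C,G,T}: an ambiguous base in the *genome*
# never satisfies a pattern position.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Reverse complement of a DNA string
#'
#' Plain-character-string reverse complement over the alphabet {A,C,G,T,N}.
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("GGGAATC")
revcomp <- function(x) {
  vapply(x, function(s) {
    comp <- chartr("ACGTN", "TGCAN", s)
    paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Translate an IUPAC pattern into a per-position list of allowed base sets.
iupac_pattern_sets <- function(pattern) {
  chars <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  bad <- setdiff(chars, names(IUPAC_SETS))
  if (length(bad) > 0) {
    abort(sprintf("pattern contains non-IUPAC character(s): %s",
                  paste(unique(bad), collapse = ", ")))
  }
  lapply(chars, function(ch) IUPAC_SETS[[ch]])
}

# Does `unit` (exact string, length == pattern length) match the IUPAC pattern?
matches_iupac <- function(unit, pattern_sets) {
  chars <- strsplit(unit, "", fixed = TRUE)[[1]]
  if (length(chars) != length(pattern_sets)) return(FALSE)
  all(mapply(function(ch, set) ch %in% set, chars, pattern_sets))
}

# Logical vector over window start positions (1-based): does the k-window at i
# match the pattern? chars is the character vector of the sequence.
window_matches <- function(chars, pattern_sets) {
  k <- length(pattern_sets)
  n <- length(chars)
  if (n < k) return(logical(0))
  ok <- rep(TRUE, n - k + 1L)
  for (j in seq_len(k)) {
    ok <- ok & chars[j:(n - k + j)] %in% pattern_sets[[j]]
  }
  ok
}

# Exact-match window positions for a fixed word.
window_equals <- function(chars, word) {
  w <- strsplit(word, "", fixed = TRUE)[[1]]
  k <- length(w)
  n <- length(chars)
  if (n < k) return(logical(0))
  ok <- rep(TRUE, n - k + 1L)
  for (j in seq_len(k)) {
    ok <- ok & chars[j:(n - k + j)] == w[j]
  }
  ok
}

# sample from the elements of x (robust to length-1 x)
sample_vec <- function(x, size = length(x)) {
  x[sample.int(length(x), size)]
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg)
  invisible(TRUE)
}

#' Construct a genome record
#'
#' A genome record is a one-row tibble holding a single sequence with its id,
#' length and topology. All scanners and annotators take genome records;
#' coordinates are 0-based half-open on the forward strand throughout.
#'
#' @param id Non-empty sequence identifier.
#' @param sequence Nucleotide string; lowercase is upcased and U mapped to T.
#'   Characters outside {A,C,G,T,N} are rejected.
#' @param topology "linear" or "circular". The flag is stored; scanners do not
#'   wrap around the origin.
#' @return One-row tibble with columns `id`, `sequence`, `length`, `topology`.
#' @export
#' @examples
#' genome_record("g1", "acgtACGT")
genome_record <- function(id, sequence, topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  assert_that(is.character(id) && length(id) == 1 && nzchar(id),
              "genome id must be a non-empty string")
  sequence <- chartr("u", "t", sequence)
  sequence <- toupper(sequence)
  sequence <- chartr("U", "T", sequence)
  bad <- regexpr("[^ACGTN]", sequence)
  if (bad > 0) {
    abort(sprintf(
      "illegal character '%s' at position %d of sequence '%s'",
      substr(sequence, bad, bad), as.integer(bad), id))
  }
  tibble(id = id, sequence = sequence, length = nchar(sequence),
         topology = topology)
}

# Accept either a one-row genome tibble or a raw (id, sequence) pair.
as_genome_record <- function(genome) {
  assert_that(is.data.frame(genome) && nrow(genome) == 1 &&
                all(c("id", "sequence") %in% names(genome)),
              "genome must be a one-row tibble with columns id and sequence")
  if (!"length" %in% names(genome)) genome$length <- nchar(genome$sequence)
  if (!"topology" %in% names(genome)) genome$topology <- "linear"
  genome
}

# Stable identifier for a located hit.
hit_id <- function(genome_id, start, end, strand, prefix = "rep") {
  sprintf("%s:%s:%d-%d(%s)", prefix, genome_id, start, end, strand)
}

empty_repeat_hits <- function() {
  tibble(
    genome_id = character(), start = integer(), end = integer(),
    strand = character(), units = list(), n_units = integer(),
    n_seed_units = integer(), trailing_partial = character(),
    intact_tracts_max_run = integer(), g4_capable = logical(),
    preset_name = character(), repeat_id = character()
  )
}
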