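#' Build the consensus position frequency matrix of repeat units
#'
#' Every full 7-mer unit of every hit, read on the repeat strand, contributes
#' one count per position; trailing partial units are excluded. Per-position
#' information content is computed against the uniform background:
#' 2 + sum(f * log2 f) bits, with 0 * log 0 = 0 and no small-sample
#' correction.
#'
#' @param hits Repeat hits from [scan_repeats()] with at least one full unit.
#' @return Object of class `g4_pfm`: list with `counts` (4x7 matrix, rows
#'   A,C,G,T), `frequencies`, `info_bits` (length 7) and `n_units_total`.
#'   Use [generics::tidy()] for a long tibble.
#' @export
build_pfm <- function(hits) {
  units <- unlist(hits$units)
  assert_that(length(units) > 0, "no units: need at least one hit with a full unit")
  mat <- do.call(rbind, strsplit(units, "", fixed = TRUE))
  bases <- c("A", "C", "G", "T")
  counts <- vapply(seq_len(7), function(j)
    vapply(bases, function(b) sum(mat[, j] == b), numeric(1)),
    numeric(4))
  dimnames(counts) <- list(bases, paste0("p", 1:7))
  n_total <- length(units)
  freq <- counts / n_total
  info <- apply(freq, 2, function(f) {
    f <- f[f > 0]
    2 + sum(f * log2(f))
  })
  structure(list(counts = counts, frequencies = freq,
                 info_bits = unname(info), n_units_total = n_total),
            class = "g4_pfm")
}

#' @export
print.g4_pfm <- function(x, ...) {
  cat(sprintf("<g4_pfm: %d units>\n", x$n_units_total))
  print(round(x$frequencies, 3))
  cat("info (bits):", paste(sprintf("%.2f", x$info_bits), collapse = " "), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a position frequency matrix
#'
#' @param x A `g4_pfm` from [build_pfm()].
#' @param ... Unused.
#' @return Long tibble: `position`, `base`, `count`, `frequency`,
#'   `info_bits` (per position).
#' @export
tidy.g4_pfm <- function(x, ...) {
  tibble(
    position = rep(1:7, each = 4),
    base = rep(rownames(x$counts), 7),
    count = as.vector(x$counts),
    frequency = as.vector(x$frequencies),
    info_bits = rep(x$info_bits, each = 4))
}

#' @rdname tidy.g4_pfm
#' @export
glance.g4_pfm <- function(x, ...) {
  tibble(n_units_total = x$n_units_total,
         total_info_bits = sum(x$info_bits))
}

#' Write a PFM as TSV (4 base rows x 7 position columns)
#'
#' @param pfm A `g4_pfm`.
#' @param path Output path.
#' @param what "counts" or "frequencies".
#' @return `path`, invisibly.
#' @export
write_pfm <- function(pfm, path, what = c("counts", "frequencies")) {
  what <- match.arg(what)
  m <- pfm[[what]]
  df <- data.frame(base = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Unit-count histogram
#'
#' Exact multiset count of repeats per unit count; unit counts with zero
#' repeats are absent.
#'
#' @param hits Repeat hits.
#' @return Tibble: `n_units`, `n_repeats`, sorted by `n_units`.
#' @export
unit_histogram <- function(hits) {
  if (nrow(hits) == 0) return(tibble(n_units = integer(), n_repeats = integer()))
  hits |>
    dplyr::count(.data$n_units, name = "n_repeats") |>
    arrange(.data$n_units)
}

#' Strand, location and orientation composition of a repeat set
#'
#' Fractions over all hits in three partitions: strand (+/-), location
#' (intergenic vs intragenic) and the six orientation categories (intragenic
#' coding/noncoding strand; intergenic between aligned ORFs on the
#' coding/noncoding strand, convergent or divergent ORFs), plus "undefined"
#' for intergenic repeats missing a neighbor. Fractions sum to 1 within each
#' partition.
#'
#' @param hits Repeat hits.
#' @param contexts Context annotations from [annotate_context()] covering all
#'   hits.
#' @return Tibble: `partition`, `category`, `n`, `fraction`.
#' @export
composition_summary <- function(hits, contexts) {
  missing_ctx <- setdiff(hits$repeat_id, contexts$repeat_id)
  if (length(missing_ctx) > 0) {
    abort(sprintf("context missing for %d hit(s), e.g. %s",
                  length(missing_ctx), missing_ctx[1]))
  }
  ctx <- contexts[match(hits$repeat_id, contexts$repeat_id), ]
  n_all <- nrow(hits)
  count_part <- function(values, partition) {
    tibble(category = values) |>
      dplyr::count(.data$category, name = "n") |>
      mutate(partition = partition, fraction = .data$n / n_all) |>
      select("partition", "category", "n", "fraction")
  }
  strand_part <- count_part(hits$strand, "strand")
  loc <- ifelse(ctx$location_class == "intergenic", "intergenic", "intragenic")
  loc_part <- count_part(loc, "location")
  orient <- ifelse(ctx$location_class == "intergenic",
                   ctx$orientation_class, ctx$location_class)
  orient_part <- count_part(orient, "orientation")
  bind_rows(strand_part, loc_part, orient_part)
}

#' Distance-bin table of neighbor relations
#'
#' Counts neighbor relations (from [annotate_context()]) per relation,
#' strand relation and distance bin, pooling the left and right neighbors of
#' every intergenic repeat.
#'
#' @param contexts Context annotations.
#' @return Tibble: `relation`, `strand_relation`, `bin`, `n`, `fraction`
#'   (of all emitted relations).
#' @export
distance_bin_table <- function(contexts) {
  long <- bind_rows(
    tibble(relation = contexts$left_relation,
           strand_relation = contexts$left_strand_relation,
           bin = contexts$left_bin),
    tibble(relation = contexts$right_relation,
           strand_relation = contexts$right_strand_relation,
           bin = contexts$right_bin))
  long <- long[!is.na(long$relation), ]
  if (nrow(long) == 0) {
    return(tibble(relation = character(), strand_relation = character(),
                  bin = character(), n = integer(), fraction = double()))
  }
  long |>
    dplyr::count(.data$relation, .data$strand_relation, .data$bin, name = "n") |>
    mutate(fraction = .data$n / sum(.data$n))
}
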