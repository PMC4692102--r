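#' Read genome sequences from FASTA or GenBank
#'
#' Sequences are upcased, U is mapped to T, and any character outside
#' {A,C,G,T,N} raises a format error naming the offending position. GenBank
#' topology (linear/circular) is taken from the LOCUS line; FASTA records are
#' linear.
#'
#' @param path Path to the sequence file.
#' @param format "fasta" or "genbank".
#' @return Tibble with one row per sequence entry: `id`, `sequence`,
#'   `length`, `topology`.
#' @export
read_genome <- function(path, format = c("fasta", "genbank")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("cannot read file '%s'", path))
  if (format == "fasta") {
    seqs <- Biostrings::readBStringSet(path)
    if (length(seqs) == 0) abort(sprintf("no sequences in '%s'", path))
    ids <- sub("\\s.*$", "", names(seqs))
    recs <- lapply(seq_along(seqs), function(i)
      genome_record(ids[i], as.character(seqs[[i]])))
    bind_rows(recs)
  } else {
    recs <- parse_genbank(path)
    if (length(recs) == 0) abort(sprintf("no GenBank records in '%s'", path))
    bind_rows(lapply(recs, function(r)
      genome_record(r$id, r$sequence, r$topology)))
  }
}

# Minimal GenBank flat-file parser: LOCUS id/topology, FEATURES CDS
# locations (a..b, complement(a..b), join(...) collapsed to its span, < and >
# partial markers stripped), /locus_tag and /product qualifiers, ORIGIN
# sequence. Returns a list of records, each with id, topology, sequence and
# a features data frame.
parse_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec_starts <- grep("^LOCUS", lines)
  if (length(rec_starts) == 0) return(list())
  rec_ends <- c(rec_starts[-1] - 1L, length(lines))
  lapply(seq_along(rec_starts), function(k) {
    block <- lines[rec_starts[k]:rec_ends[k]]
    locus <- strsplit(trimws(block[1]), "\\s+")[[1]]
    id <- locus[2]
    topology <- if (any(tolower(locus) == "circular")) "circular" else "linear"
    origin_i <- grep("^ORIGIN", block)
    seq_txt <- ""
    if (length(origin_i) == 1) {
      end_i <- grep("^//", block)
      end_i <- if (length(end_i)) end_i[1] - 1L else length(block)
      seq_lines <- block[(origin_i + 1L):end_i]
      seq_txt <- toupper(gsub("[0-9 /]", "", paste(seq_lines, collapse = "")))
    }
    feat_i <- grep("^FEATURES", block)
    feats <- list()
    if (length(feat_i) == 1) {
      stop_i <- if (length(origin_i)) origin_i - 1L else length(block)
      fl <- block[(feat_i + 1L):stop_i]
      # feature headers sit at column 6; qualifiers at column 22
      hdr <- grepl("^ {5}\\S", fl)
      idx <- which(hdr)
      for (j in seq_along(idx)) {
        from <- idx[j]
        to <- if (j < length(idx)) idx[j + 1L] - 1L else length(fl)
        parts <- strsplit(trimws(fl[from]), "\\s+")[[1]]
        type <- parts[1]
        if (type != "CDS") next
        # location may continue over lines until the first qualifier
        body <- fl[from:to]
        qual_start <- grep("^\\s+/", body)
        loc_end <- if (length(qual_start)) qual_start[1] - 1L else length(body)
        loc <- paste0(parts[-1], collapse = "")
        if (loc_end > 1) {
          loc <- paste0(loc, paste(trimws(body[2:loc_end]), collapse = ""))
        }
        parsed <- parse_genbank_location(loc)
        qual <- paste(trimws(body), collapse = " ")
        locus_tag <- stringr::str_match(qual, '/locus_tag="([^"]*)"')[, 2]
        product <- stringr::str_match(qual, '/product="([^"]*)"')[, 2]
        feats[[length(feats) + 1L]] <- tibble(
          start1 = parsed$start1, end1 = parsed$end1, strand = parsed$strand,
          locus_tag = locus_tag %||% NA_character_,
          product = product %||% NA_character_)
      }
    }
    features <- if (length(feats)) bind_rows(feats) else
      tibble(start1 = integer(), end1 = integer(), strand = character(),
             locus_tag = character(), product = character())
    list(id = id, topology = topology, sequence = seq_txt, features = features)
  })
}

parse_genbank_location <- function(loc) {
  strand <- "+"
  loc <- gsub("[<>]", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  }
  nums <- as.integer(unlist(regmatches(loc, gregexpr("[0-9]+", loc))))
  if (length(nums) < 2) abort(sprintf("cannot parse GenBank location '%s'", loc))
  list(start1 = min(nums), end1 = max(nums), strand = strand)
}

#' Read ORF annotations from GenBank or GFF3
#'
#' External 1-based inclusive coordinates are converted to the internal
#' 0-based half-open convention; complement / negative-strand features get
#' strand "-". Output is sorted by start then end. Overlapping features are
#' kept as-is, never merged.
#'
#' @param path Path to the annotation file.
#' @param format "genbank" or "gff3".
#' @param feature_type GFF3 feature type to keep (default "CDS").
#' @param genome_length Optional genome length; features extending beyond it
#'   raise a format error.
#' @return Tibble of ORF annotations sorted by start: `genome_id`, `start`,
#'   `end`, `strand`, `locus_tag`, `product`.
#' @export
read_orfs <- function(path, format = c("genbank", "gff3"),
                      feature_type = "CDS", genome_length = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("cannot read file '%s'", path))
  if (format == "genbank") {
    recs <- parse_genbank(path)
    if (length(recs) == 0) abort(sprintf("no GenBank records in '%s'", path))
    orfs <- bind_rows(lapply(recs, function(r) {
      f <- r$features
      tibble(genome_id = r$id,
             start = f$start1 - 1L, end = f$end1,
             strand = f$strand,
             locus_tag = ifelse(is.na(f$locus_tag),
                                sprintf("%s_cds_%d", r$id, seq_len(nrow(f))),
                                f$locus_tag),
             product = ifelse(is.na(f$product), "", f$product))
    }))
  } else {
    gr <- rtracklayer::import(path)
    df <- as.data.frame(gr)
    if ("type" %in% names(df)) {
      df <- df[as.character(df$type) == feature_type, , drop = FALSE]
    }
    if (nrow(df) == 0) {
      return(tibble(genome_id = character(), start = integer(),
                    end = integer(), strand = character(),
                    locus_tag = character(), product = character()))
    }
    tag <- if ("locus_tag" %in% names(df)) as.character(df$locus_tag)
           else if ("ID" %in% names(df)) as.character(df$ID)
           else sprintf("cds_%d", seq_len(nrow(df)))
    prod <- if ("product" %in% names(df)) as.character(df$product)
            else rep("", nrow(df))
    orfs <- tibble(
      genome_id = as.character(df$seqnames),
      start = as.integer(df$start) - 1L,
      end = as.integer(df$end),
      strand = ifelse(as.character(df$strand) == "-", "-", "+"),
      locus_tag = ifelse(is.na(tag), sprintf("cds_%d", seq_len(nrow(df))), tag),
      product = ifelse(is.na(prod), "", prod))
  }
  if (any(orfs$start >= orfs$end)) {
    abort("annotation with start > end is not a valid feature")
  }
  if (!is.null(genome_length) && any(orfs$end > genome_length)) {
    bad <- orfs$locus_tag[orfs$end > genome_length][1]
    abort(sprintf("feature '%s' extends beyond genome length %d",
                  bad, genome_length))
  }
  arrange(orfs, .data$start, .data$end)
}

#' Write located hits to BED6, TSV or JSON
#'
#' BED uses 0-based half-open coordinates with strand in column 6; TSV and
#' JSON carry all (non-list) fields. Output is byte-identical across runs for
#' identical input: field order is stable and floats are written with
#' fixed formatting.
#'
#' @param records Tibble of located hits; must carry `genome_id`, `start`,
#'   `end`, `strand`.
#' @param path Output file path.
#' @param format "bed", "tsv" or "json".
#' @param name_col Column used for the BED name field (default: first of
#'   `repeat_id`/`pqs_id`, else "region").
#' @return `path`, invisibly.
#' @export
write_intervals <- function(records, path, format = c("bed", "tsv", "json"),
                            name_col = NULL) {
  format <- match.arg(format)
  required <- c("genome_id", "start", "end", "strand")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    abort(sprintf("records missing required field(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  flat <- records[, !vapply(records, is.list, logical(1)), drop = FALSE]
  if (format == "bed") {
    name_col <- name_col %||%
      intersect(c("repeat_id", "pqs_id", "region_id"), names(records))[1]
    nm <- if (!is.null(name_col) && !is.na(name_col)) records[[name_col]]
          else rep("region", nrow(records))
    lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                     records$genome_id, records$start, records$end,
                     nm, records$strand)
    writeLines(lines, path)
  } else if (format == "tsv") {
    num <- vapply(flat, is.double, logical(1))
    flat[num] <- lapply(flat[num], function(x) sprintf("%.6g", x))
    utils::write.table(flat, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  } else {
    json <- jsonlite::toJSON(flat, dataframe = "rows", auto_unbox = FALSE,
                             digits = NA, pretty = TRUE)
    writeLines(json, path)
  }
  invisible(path)
}

#' Read intervals written by [write_intervals()]
#'
#' @param path File path.
#' @param format "bed", "tsv" or "json".
#' @return Tibble with at least `genome_id`, `start`, `end`, `strand`.
#' @export
read_intervals <- function(path, format = c("bed", "tsv", "json")) {
  format <- match.arg(format)
  if (format == "bed") {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            col.names = c("genome_id", "start", "end",
                                          "name", "score", "strand"),
                            colClasses = c("character", "integer", "integer",
                                           "character", "integer", "character"))
    as_tibble(df)
  } else if (format == "tsv") {
    as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE))
  } else {
    as_tibble(jsonlite::fromJSON(path))
  }
}
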