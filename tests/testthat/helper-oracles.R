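# Independent brute-force oracles. These deliberately share no code with the
# package scanners: degenerate matching goes through regexes, extension is
# checked by enumerating every (strand, start, unit-count) combination, and
# G-tract runs are recomputed from scratch.

oracle_iupac_regex <- function(pattern) {
  map <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT", S = "CG",
           W = "AT", K = "GT", M = "AC", B = "CGT", D = "AGT", H = "ACT",
           V = "ACG", N = "ACGT")
  paste0("^", paste0("[", map[strsplit(pattern, "")[[1]]], "]",
                     collapse = ""), "$")
}

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

# Enumerates all maximal seed-containing arrays and applies the same
# (seed count, unit count, leftmost) overlap resolution, per strand.
oracle_scan_repeats <- function(sequence, preset) {
  n <- nchar(sequence)
  rx <- oracle_iupac_regex(preset$degenerate_unit)
  gpref <- strrep("G", preset$tract_prefix_length)
  cands <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") sequence else oracle_revcomp(sequence)
    if (n < 7) next
    deg <- vapply(1:(n - 6), function(i) grepl(rx, substr(s, i, i + 6)),
                  logical(1))
    degf <- function(i) i >= 1 && i <= n - 6 && deg[i]
    for (i in 1:(n - 6)) {
      kmax <- (n - i + 1) %/% 7
      for (k in seq_len(kmax)) {
        ws <- i + 7 * (0:(k - 1))
        if (!all(deg[ws])) break
        if (k < preset$min_units) next
        if (degf(i - 7) || degf(i + 7 * k)) next  # extendable: not maximal
        units <- substring(s, ws, ws + 6)
        nseed <- sum(units %in% preset$seed_units)
        if (nseed < preset$min_seed_units) next
        after <- i + 7 * k
        tp <- if (after + nchar(gpref) - 1 <= n &&
                  substr(s, after, after + nchar(gpref) - 1) == gpref) gpref
              else ""
        len <- 7 * k + nchar(tp)
        if (len < preset$min_total_length) next
        start <- if (strand == "+") i - 1 else n - (i - 1) - len
        intact <- substr(units, 1, preset$tract_prefix_length) == gpref
        if (tp == gpref) intact <- c(intact, TRUE)
        run <- 0; best <- 0
        for (b in intact) { run <- if (b) run + 1 else 0; best <- max(best, run) }
        cands[[length(cands) + 1]] <- data.frame(
          start = start, end = start + len, strand = strand, n_units = k,
          n_seed_units = nseed, trailing_partial = tp,
          units_cat = paste(units, collapse = ","),
          intact_tracts_max_run = best, g4_capable = best >= 4)
      }
    }
  }
  if (length(cands) == 0) {
    return(data.frame(start = integer(), end = integer(), strand = character(),
                      n_units = integer(), n_seed_units = integer(),
                      trailing_partial = character(), units_cat = character(),
                      intact_tracts_max_run = integer(),
                      g4_capable = logical()))
  }
  df <- unique(do.call(rbind, cands))
  out <- NULL
  for (strand in c("+", "-")) {
    d <- df[df$strand == strand, ]
    d <- d[order(-d$n_seed_units, -d$n_units, d$start), ]
    kept <- d[0, ]
    for (r in seq_len(nrow(d))) {
      if (nrow(kept) == 0 ||
          all(d$end[r] <= kept$start | d$start[r] >= kept$end)) {
        kept <- rbind(kept, d[r, ])
      }
    }
    out <- rbind(out, kept)
  }
  out[order(out$start, out$end, out$strand), ]
}

# Enumerates all maximal chains of G-tracts per strand.
oracle_scan_pqs <- function(sequence, g_min = 3, loop_min = 1, loop_max = 5,
                            min_tracts = 4) {
  n <- nchar(sequence)
  out <- NULL
  for (strand in c("+", "-")) {
    s <- if (strand == "+") sequence else oracle_revcomp(sequence)
    ch <- strsplit(s, "")[[1]]
    # maximal G runs by explicit scan
    runs <- list(); i <- 1
    while (i <= n) {
      if (ch[i] == "G") {
        j <- i
        while (j < n && ch[j + 1] == "G") j <- j + 1
        if (j - i + 1 >= g_min) runs[[length(runs) + 1]] <- c(i, j)
        i <- j + 1
      } else i <- i + 1
    }
    m <- length(runs)
    if (m < min_tracts) next
    rs <- vapply(runs, `[`, numeric(1), 1)
    re <- vapply(runs, `[`, numeric(1), 2)
    chainable <- function(a) {
      g <- rs[a + 1] - re[a] - 1
      g >= loop_min && g <= loop_max
    }
    for (i1 in 1:m) {
      for (j1 in i1:m) {
        if (j1 - i1 + 1 < min_tracts) next
        if (j1 > i1 && !all(vapply(i1:(j1 - 1), chainable, logical(1)))) next
        if (i1 > 1 && chainable(i1 - 1)) next      # extendable left
        if (j1 < m && chainable(j1)) next          # extendable right
        h1 <- rs[i1]; h2 <- re[j1]
        start <- if (strand == "+") h1 - 1 else n - h2
        out <- rbind(out, data.frame(
          start = start, end = start + (h2 - h1 + 1), strand = strand,
          n_tracts = j1 - i1 + 1))
      }
    }
  }
  if (is.null(out)) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), n_tracts = integer()))
  }
  out[order(out$start, out$end, out$strand), ]
}

# Random test sequences enriched with motif-like fragments so scanner/oracle
# comparisons exercise real hits, mutated units, partial tracts and both
# strands.
random_motif_sequence <- function(n, seed, preset = NULL) {
  withr::with_seed(seed, {
    base <- sample(c("A", "C", "G", "T"), n, replace = TRUE,
                   prob = c(0.2, 0.3, 0.3, 0.2))
    frags <- c("GGGAATC", "GGGACTC", "GGGAGTA", "GATTCCC", "GGG", "GGGG",
               "CCC", "GGGGATT", "GGGGACT", "AGTCCCC", "AATCCCC")
    if (!is.null(preset)) frags <- c(frags, preset$seed_units,
                                     oracle_revcomp(preset$seed_units[1]))
    for (k in seq_len(max(3, n %/% 40))) {
      f <- strsplit(sample(frags, 1), "")[[1]]
      p <- sample(n - length(f), 1)
      base[p:(p + length(f) - 1)] <- f
    }
    paste(base, collapse = "")
  })
}

repeat_hit_key <- function(hits) {
  units_cat <- if ("units" %in% names(hits) && is.list(hits$units)) {
    vapply(hits$units, paste, character(1), collapse = ",")
  } else hits$units_cat
  sort(paste(hits$start, hits$end, hits$strand, hits$n_units,
             hits$n_seed_units, hits$trailing_partial, units_cat,
             hits$intact_tracts_max_run, hits$g4_capable, sep = "|"))
}

pqs_hit_key <- function(hits) {
  sort(paste(hits$start, hits$end, hits$strand, hits$n_tracts, sep = "|"))
}
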