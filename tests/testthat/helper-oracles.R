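# Brute-force digestion oracle, independent of digest(): enumerates every
# substring of the sequence and keeps those satisfying the cleavage rules
# literally.
oracle_boundaries <- function(res, protease, no_cleave_before_proline = TRUE) {
  n <- length(res)
  b <- integer(0)
  for (i in seq_len(max(0L, n - 1L))) {
    cut <- if (protease == "trypsin") {
      res[i] %in% c("K", "R") &&
        (!no_cleave_before_proline || res[i + 1L] != "P")
    } else {
      res[i + 1L] == "K"
    }
    if (cut) b <- c(b, i)
  }
  sort(unique(c(0L, b, n)))
}

oracle_digest <- function(sequence, protease, specificity,
                          missed_cleavages = 1L) {
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  B <- oracle_boundaries(res, protease)
  full <- list()
  for (a in B) for (b in B) {
    if (b <= a) next
    if (sum(B > a & B < b) <= missed_cleavages) {
      full[[length(full) + 1L]] <- c(a, b)
    }
  }
  if (specificity == "full") {
    windows <- full
  } else {
    windows <- list()
    for (i in 1:n) for (j in i:n) {
      ok <- any(vapply(full, function(w) {
        (w[1] + 1L == i && j <= w[2]) || (w[2] == j && i >= w[1] + 1L)
      }, logical(1)))
      if (ok) windows[[length(windows) + 1L]] <- c(i - 1L, j)
    }
  }
  keys <- unique(vapply(windows, function(w) {
    paste0(w[1] + 1L, ":", substr(sequence, w[1] + 1L, w[2]))
  }, character(1)))
  sort(keys)
}

digest_keys <- function(...) {
  d <- digest(...)
  sort(unique(paste0(d$start, ":", d$peptide)))
}

random_protein <- function(min_len = 5L, max_len = 60L) {
  l <- sample(min_len:max_len, 1L)
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], l, replace = TRUE),
        collapse = "")
}

# Minimal ratio-pair table, as produced by pair_replicates()
make_pairs <- function(r1, r2, accession = NULL, peptide = NULL, mod = "|") {
  n <- max(length(r1), length(r2))
  if (is.null(accession)) accession <- sprintf("P%05d", seq_len(n))
  if (is.null(peptide)) peptide <- sprintf("PEPTIDEK%05d", seq_len(n))
  both <- !is.na(r1) & !is.na(r2)
  data.frame(accession = accession, peptide = peptide, mod = mod,
             r1 = r1, r2 = r2,
             mean_ratio = ifelse(both, (r1 + r2) / 2,
                                 ifelse(is.na(r1), r2, r1)),
             n_replicates = ifelse(both, 2L, 1L), consistent = NA,
             stringsAsFactors = FALSE)
}

# Minimal quant-table rows
quant_row <- function(peptide = "MDSQPVDVDNK", accession = "YER133W",
                      start = 1L, acetyl = FALSE, phospho = "",
                      score = 50, i14 = 1000, i15 = 1000, rep = 1L) {
  data.frame(peptide = peptide, accession = accession, start = start,
             nterm_acetyl = acetyl, phospho_positions = phospho,
             score = score, intensity_14N = i14, intensity_15N = i15,
             replicate_id = rep, stringsAsFactors = FALSE)
}
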