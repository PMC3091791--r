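#' Positional amino-acid frequency matrix for N-terminal sequences
#'
#' The numeric backbone of a sequence logo: relative residue frequencies at
#' each of the first `k` N-terminal positions across a set of sequences.
#'
#' @param sequences Character vector of sequences, each at least `k` long.
#' @param k Number of N-terminal positions (default 5).
#' @return A `k` x 20 matrix (rows `pos1..posk`, columns the standard
#'   residues); each row sums to 1.
#' @export
frequency_matrix <- function(sequences, k = 5L) {
  if (length(sequences) == 0L) stop("no sequences supplied")
  short <- sequences[nchar(sequences) < k]
  if (length(short) > 0L) {
    stop("sequence(s) shorter than k = ", k, ": ",
         paste(utils::head(short, 3), collapse = ", "))
  }
  mat <- matrix(0, nrow = k, ncol = length(AA_ALPHABET),
                dimnames = list(paste0("pos", seq_len(k)), AA_ALPHABET))
  for (p in seq_len(k)) {
    res <- toupper(substr(sequences, p, p))
    tab <- table(factor(res, levels = AA_ALPHABET))
    mat[p, ] <- as.numeric(tab) / length(sequences)
  }
  mat
}

#' Percent contribution of each category to an item set
#'
#' Items may belong to several categories (e.g. multi-localized proteins);
#' an item counts once per category it belongs to, so percentages need not
#' sum to 100.
#'
#' @param annotations Data frame with columns `item` and `category`.
#' @param items Character vector of items in the set.
#' @return Named numeric vector: percent of `items` in each category.
#' @export
category_contributions <- function(annotations, items) {
  if (length(items) == 0L) stop("empty item set")
  items <- unique(items)
  ann <- unique(annotations[annotations$item %in% items,
                            c("item", "category")])
  cats <- sort(unique(annotations$category))
  counts <- vapply(cats, function(cc) {
    length(unique(ann$item[ann$category == cc]))
  }, numeric(1))
  100 * counts / length(items)
}

#' Normalized category over-representation with chi-square testing
#'
#' For each category, the foreground percentage (share of foreground items
#' annotated to the category) is divided by the background percentage to
#' give the normalized contribution, and a Pearson chi-square test with one
#' degree of freedom is run on the 2x2 table of in/out counts. P-values are
#' corrected over the tested categories (Bonferroni by default). Categories
#' with no background members are omitted with a warning (their ratio is
#' undefined); categories where any expected cell is below 5 are flagged
#' `low_count`.
#'
#' @param foreground,background Character vectors of items (for the
#'   elevated-versus-unchanged design these must be disjoint; see
#'   [localization_profile()] for the nested design).
#' @param annotations Data frame with columns `item`, `category`.
#' @param correction `"bonferroni"` (default) or `"BH"`.
#' @param continuity Apply the Yates continuity correction
#'   (default `FALSE`: plain Pearson chi-square).
#' @param check_disjoint Enforce disjoint foreground/background.
#' @return Data frame of class `enrichment_result`: `category`,
#'   `fg_percent`, `bg_percent`, `normalized_contribution`, `chi2`, `p`,
#'   `p_corrected`, `low_count`, sorted by normalized contribution
#'   descending.
#' @export
normalized_enrichment <- function(foreground, background, annotations,
                                  correction = c("bonferroni", "BH"),
                                  continuity = FALSE,
                                  check_disjoint = TRUE) {
  correction <- match.arg(correction)
  foreground <- unique(foreground)
  background <- unique(background)
  if (check_disjoint && length(intersect(foreground, background)) > 0L) {
    stop("foreground and background must be disjoint item sets")
  }
  if (length(foreground) == 0L || length(background) == 0L) {
    stop("foreground and background must be non-empty")
  }
  cats <- sort(unique(annotations$category))
  in_cat <- function(items, cc) {
    sum(items %in% annotations$item[annotations$category == cc])
  }
  rows <- lapply(cats, function(cc) {
    fg_in <- in_cat(foreground, cc)
    bg_in <- in_cat(background, cc)
    if (bg_in == 0L) return(NULL)
    fg_pct <- 100 * fg_in / length(foreground)
    bg_pct <- 100 * bg_in / length(background)
    tab <- matrix(c(fg_in, length(foreground) - fg_in,
                    bg_in, length(background) - bg_in),
                  nrow = 2, byrow = TRUE)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    ht <- suppressWarnings(stats::chisq.test(tab, correct = continuity))
    data.frame(category = cc, fg_percent = fg_pct, bg_percent = bg_pct,
               normalized_contribution = fg_pct / bg_pct,
               chi2 = unname(ht$statistic), p = ht$p.value,
               low_count = any(expected < 5), stringsAsFactors = FALSE)
  })
  dropped <- cats[vapply(rows, is.null, logical(1))]
  if (length(dropped) > 0L) {
    warning("categor(ies) absent from background omitted: ",
            paste(dropped, collapse = ", "))
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no category has background members")
  out$p_corrected <- stats::p.adjust(
    out$p, method = if (correction == "bonferroni") "bonferroni" else "BH")
  out <- out[, c("category", "fg_percent", "bg_percent",
                 "normalized_contribution", "chi2", "p", "p_corrected",
                 "low_count")]
  out <- out[order(-out$normalized_contribution, out$category), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Localization profile of elevated proteins against all detected proteins
#'
#' Same machinery as [normalized_enrichment()] but with the nested design
#' used for subcellular localization: the background is the full set of
#' detected proteins (the elevated set is a subset of it), so the
#' normalized contribution reads as enrichment relative to the overall
#' localization distribution, and the two-sided chi-square reports both
#' over- and under-representation. Proteins without any localization
#' annotation are excluded from both sets.
#'
#' @param elevated Character vector of up-regulated protein accessions
#'   (must all be among `detected`).
#' @param detected Character vector of all detected protein accessions.
#' @param annotations Data frame with columns `item` (accession) and
#'   `category` (localization term).
#' @inheritParams normalized_enrichment
#' @return An `enrichment_result` data frame (see
#'   [normalized_enrichment()]).
#' @export
localization_profile <- function(elevated, detected, annotations,
                                 correction = c("bonferroni", "BH"),
                                 continuity = FALSE) {
  if (!all(elevated %in% detected)) {
    stop("all elevated proteins must be in the detected set")
  }
  annotated <- unique(annotations$item)
  elevated <- intersect(unique(elevated), annotated)
  detected <- intersect(unique(detected), annotated)
  normalized_enrichment(elevated, detected, annotations,
                        correction = match.arg(correction),
                        continuity = continuity, check_disjoint = FALSE)
}
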