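#' Label orientation of a label-swap replicate pair
#'
#' In a metabolic 15N label-swap design the two biological replicates carry
#' opposite isotope assignments: in the default orientation replicate 1 grew
#' the knockout strain on light (14N) medium and the wild type on heavy
#' (15N), and replicate 2 reversed the labels. The orientation decides which
#' intensity channel is the knockout when forming log2(KO/WT) ratios.
#'
#' @param ko_channel_rep1,ko_channel_rep2 Which isotope channel ("14N" or
#'   "15N") holds the knockout strain in each replicate. The two replicates
#'   must have opposite orientations.
#' @return An object of class `label_orientation`: a named character vector
#'   mapping replicate id to the knockout channel.
#' @export
label_orientation <- function(ko_channel_rep1 = "14N", ko_channel_rep2 = "15N") {
  ch <- c("14N", "15N")
  stopifnot(ko_channel_rep1 %in% ch, ko_channel_rep2 %in% ch)
  if (ko_channel_rep1 == ko_channel_rep2) {
    stop("label-swap design requires opposite orientations in the two replicates")
  }
  structure(c(`1` = ko_channel_rep1, `2` = ko_channel_rep2),
            class = "label_orientation")
}

#' Filter identified peptides by identification score
#'
#' Unmodified and N-terminally acetylated peptides are kept when their ion
#' score is at least `regular_min` (default 30); phosphopeptides, which
#' fragment less informatively, use the lower threshold `phospho_min`
#' (default 25). Both cutoffs are applied as `>=`.
#'
#' @param peptides Quant-table data frame (see [read_quant_table()]).
#' @param regular_min Minimum score for unmodified/acetylated peptides.
#' @param phospho_min Minimum score for phosphopeptides.
#' @return The filtered data frame.
#' @export
filter_by_score <- function(peptides, regular_min = 30, phospho_min = 25) {
  if (nrow(peptides) == 0L) return(peptides)
  is_phospho <- nzchar(peptides$phospho_positions)
  keep <- ifelse(is_phospho,
                 peptides$score >= phospho_min,
                 peptides$score >= regular_min)
  peptides[keep, , drop = FALSE]
}

# Modification signature used to key peptides across replicates: acetylation
# flag plus the phospho-position list, so the same peptide in different
# modification states is never averaged together.
mod_signature <- function(peptides) {
  ac <- ifelse(peptides$nterm_acetyl, "ac", "")
  ph <- ifelse(nzchar(peptides$phospho_positions),
               paste0("p", peptides$phospho_positions), "")
  paste(ac, ph, sep = "|")
}

#' Compute log2 knockout/wild-type ratios for one replicate
#'
#' Forms log2(KO channel / WT channel) per peptide row, with the channel
#' assignment taken from the label orientation so that ratios from both
#' label-swapped replicates are harmonized to the same KO/WT scale
#' (negative = lower in the knockout). Rows with a missing or zero channel
#' are unquantifiable and are excluded.
#'
#' @param peptides Quant-table data frame for a single replicate.
#' @param orientation A [label_orientation()].
#' @return Data frame with `accession`, `peptide`, `mod`, `replicate_id`,
#'   `ratio` (log2 KO/WT).
#' @export
log2_ko_wt_ratio <- function(peptides, orientation = label_orientation()) {
  stopifnot(inherits(orientation, "label_orientation"))
  rid <- unique(peptides$replicate_id)
  if (nrow(peptides) > 0L && length(rid) != 1L) {
    stop("peptides must come from a single replicate")
  }
  quantifiable <- !is.na(peptides$intensity_14N) & peptides$intensity_14N > 0 &
    !is.na(peptides$intensity_15N) & peptides$intensity_15N > 0
  p <- peptides[quantifiable, , drop = FALSE]
  if (nrow(p) == 0L) {
    return(data.frame(accession = character(), peptide = character(),
                      mod = character(), replicate_id = integer(),
                      ratio = numeric(), stringsAsFactors = FALSE))
  }
  ko_channel <- orientation[[as.character(p$replicate_id[1])]]
  ratio <- if (ko_channel == "14N") {
    log2(p$intensity_14N / p$intensity_15N)
  } else {
    log2(p$intensity_15N / p$intensity_14N)
  }
  data.frame(accession = p$accession, peptide = p$peptide,
             mod = mod_signature(p), replicate_id = p$replicate_id,
             ratio = ratio, stringsAsFactors = FALSE)
}

#' Pair harmonized ratios from the two label-swapped replicates
#'
#' Joins the two replicates' ratio tables on (accession, peptide,
#' modification signature). Peptides quantified in a single replicate are
#' retained with `n_replicates = 1`; duplicate measurements of the same key
#' within a replicate are averaged first.
#'
#' @param ratios_rep1,ratios_rep2 Outputs of [log2_ko_wt_ratio()].
#' @return Data frame of ratio pairs: `accession`, `peptide`, `mod`, `r1`,
#'   `r2`, `mean_ratio`, `n_replicates`, `consistent` (`NA` until a
#'   confidence band is applied; defined only for complete pairs).
#' @export
pair_replicates <- function(ratios_rep1, ratios_rep2) {
  collapse <- function(r, col) {
    if (nrow(r) == 0L) {
      return(data.frame(accession = character(), peptide = character(),
                        mod = character(), ratio = numeric(),
                        stringsAsFactors = FALSE))
    }
    agg <- stats::aggregate(ratio ~ accession + peptide + mod, data = r,
                            FUN = mean)
    agg
  }
  a <- collapse(ratios_rep1)
  b <- collapse(ratios_rep2)
  names(a)[names(a) == "ratio"] <- "r1"
  names(b)[names(b) == "ratio"] <- "r2"
  m <- merge(a, b, by = c("accession", "peptide", "mod"), all = TRUE)
  both <- !is.na(m$r1) & !is.na(m$r2)
  m$mean_ratio <- ifelse(both, (m$r1 + m$r2) / 2,
                         ifelse(is.na(m$r1), m$r2, m$r1))
  m$n_replicates <- ifelse(both, 2L, 1L)
  m$consistent <- rep(NA, nrow(m))
  m <- m[order(m$accession, m$peptide, m$mod), , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Fit the 95% replicate-consistency band
#'
#' Reproducibility between the two biological replicates is summarised by
#' the inter-replicate difference d = r1 - r2 of each complete ratio pair.
#' The band is +/- 1.96 x SD(d) around the identity line; a pair is
#' consistent when |d| is at most the halfwidth. The default SD estimate is
#' robust (median absolute deviation scaled by 1.4826), which resists the
#' heavy tails produced by genuinely regulated peptides; `method = "sd"`
#' uses the plain sample SD.
#'
#' @param pairs Output of [pair_replicates()].
#' @param method `"mad"` (robust, default) or `"sd"`.
#' @param min_pairs Minimum number of complete pairs required for a reliable
#'   fit.
#' @return An object of class `confidence_band`: list with `halfwidth`,
#'   `sd_estimate`, `n_pairs`, `method`.
#' @export
fit_confidence_band <- function(pairs, method = c("mad", "sd"),
                                min_pairs = 20L) {
  method <- match.arg(method)
  d <- pairs$r1[pairs$n_replicates == 2L] - pairs$r2[pairs$n_replicates == 2L]
  if (length(d) < min_pairs) {
    stop("need at least ", min_pairs,
         " complete pairs to fit the confidence band (got ", length(d), ")")
  }
  s <- if (method == "mad") stats::mad(d) else stats::sd(d)
  structure(list(halfwidth = 1.96 * s, sd_estimate = s,
                 n_pairs = length(d), method = method),
            class = "confidence_band")
}

#' @export
print.confidence_band <- function(x, ...) {
  cat(sprintf(
    "95%% replicate-consistency band: +/- %.3f log2 units (%s SD %.3f, n = %d)\n",
    x$halfwidth, x$method, x$sd_estimate, x$n_pairs))
  invisible(x)
}

#' Flag ratio pairs against a fitted consistency band
#'
#' @param pairs Output of [pair_replicates()].
#' @param band A [fit_confidence_band()] result; fitted from `pairs` when
#'   `NULL`.
#' @param ... Passed to [fit_confidence_band()] when `band` is `NULL`.
#' @return `pairs` with the `consistent` column filled for complete pairs
#'   (`NA` for singletons).
#' @export
flag_consistent <- function(pairs, band = NULL, ...) {
  if (is.null(band)) band <- fit_confidence_band(pairs, ...)
  stopifnot(inherits(band, "confidence_band"))
  d <- pairs$r1 - pairs$r2
  pairs$consistent <- ifelse(pairs$n_replicates == 2L,
                             abs(d) <= band$halfwidth, NA)
  pairs
}

#' Classify ratio pairs by fold change
#'
#' A pair is `up` when its mean log2 KO/WT ratio is at least `log2(fold)`,
#' `down` when at most `-log2(fold)`, else `unchanged`. The default
#' three-fold threshold matches the study design's arbitrary cutoff for
#' diminished or elevated levels.
#'
#' @param pairs Data frame with a `mean_ratio` column, or a numeric vector
#'   of mean log2 ratios.
#' @param fold Fold-change threshold (> 1).
#' @return Factor with levels `down`, `unchanged`, `up`.
#' @export
classify_fold_change <- function(pairs, fold = 3) {
  if (fold <= 1) stop("fold-change threshold must be > 1")
  x <- if (is.data.frame(pairs)) pairs$mean_ratio else pairs
  cut_ <- log2(fold)
  factor(ifelse(x >= cut_, "up", ifelse(x <= -cut_, "down", "unchanged")),
         levels = c("down", "unchanged", "up"))
}

#' Aggregate consistent peptide ratios to protein-level ratios
#'
#' Per accession, the mean of the mean ratios of its consistent, unmodified
#' peptide pairs. Proteins whose only pairs are flagged inconsistent (or
#' that have no unmodified pairs) are excluded.
#'
#' @param pairs Output of [flag_consistent()].
#' @param require_consistent Drop pairs flagged outside the band
#'   (default `TRUE`; singleton pairs with `consistent = NA` are kept).
#' @return Data frame with `accession`, `protein_ratio`, `n_peptides`.
#' @export
aggregate_protein_ratios <- function(pairs, require_consistent = TRUE) {
  unmod <- pairs[pairs$mod == "|", , drop = FALSE]
  if (require_consistent) {
    unmod <- unmod[is.na(unmod$consistent) | unmod$consistent, , drop = FALSE]
  }
  if (nrow(unmod) == 0L) {
    return(data.frame(accession = character(), protein_ratio = numeric(),
                      n_peptides = integer(), stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(mean_ratio ~ accession, data = unmod, FUN = mean)
  cnt <- stats::aggregate(mean_ratio ~ accession, data = unmod, FUN = length)
  out <- data.frame(accession = agg$accession,
                    protein_ratio = agg$mean_ratio,
                    n_peptides = as.integer(cnt$mean_ratio),
                    stringsAsFactors = FALSE)
  out[order(out$accession), , drop = FALSE]
}

#' Run the ratio-quantification stage on both replicates
#'
#' Convenience wrapper: score filtering, per-replicate log2 KO/WT ratios,
#' replicate pairing, confidence-band fitting and consistency flagging.
#'
#' @param peptides_rep1,peptides_rep2 Quant tables of the two replicates.
#' @param orientation [label_orientation()] of the label swap.
#' @param score_min_regular,score_min_phospho Identification-score cutoffs.
#' @param ci_method Confidence-band SD estimator, `"mad"` or `"sd"`.
#' @return List with `pairs` (flagged ratio pairs) and `band`.
#' @export
quantify_ratios <- function(peptides_rep1, peptides_rep2,
                            orientation = label_orientation(),
                            score_min_regular = 30, score_min_phospho = 25,
                            ci_method = c("mad", "sd")) {
  ci_method <- match.arg(ci_method)
  p1 <- filter_by_score(peptides_rep1, score_min_regular, score_min_phospho)
  p2 <- filter_by_score(peptides_rep2, score_min_regular, score_min_phospho)
  r1 <- log2_ko_wt_ratio(p1, orientation)
  r2 <- log2_ko_wt_ratio(p2, orientation)
  pairs <- pair_replicates(r1, r2)
  band <- fit_confidence_band(pairs, method = ci_method)
  list(pairs = flag_consistent(pairs, band), band = band)
}
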