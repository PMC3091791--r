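#' Call NatB substrates from N-terminal events and harmonized ratios
#'
#' A substrate call requires (a) an acetylated terminus whose first two
#' residues at the event position match the NatB consensus (MD/ME/MN) —
#' internal consensus termini, i.e. alternative translation starts, are
#' eligible and carried with their `position_class` — and (b) drastic
#' down-regulation in the knockout: mean log2 KO/WT ratio at or below
#' `-log2(fold)`, quantified in both label-swapped replicates unless
#' `require_both_replicates = FALSE`. Events that meet the consensus but
#' not the ratio criterion are reported in the `consensus-only` tier so a
#' full substrate-table-style report can be produced; the headline
#' substrate count uses only the threshold tier.
#'
#' @param events Classified N-terminal events from [nterm_events()].
#' @param pairs Flagged ratio pairs from [quantify_ratios()] /
#'   [flag_consistent()].
#' @param fold Fold-change threshold for "drastic down-regulation".
#' @param require_both_replicates Require quantification in both
#'   replicates (default `TRUE`).
#' @param require_consistent Additionally require complete pairs to lie
#'   inside the replicate 95% band (default `FALSE`: a genuinely regulated
#'   peptide can fall outside a band fitted to the mostly-null bulk, so the
#'   band is not used to veto substrate calls).
#' @return Data frame of calls sorted by mean ratio ascending then
#'   accession: `accession`, `peptide`, `first_five`, `start`,
#'   `position_class`, `alt_start_candidate`, `mean_ratio`,
#'   `n_replicates`, `call`, `reason`.
#' @export
call_natb_substrates <- function(events, pairs, fold = 3,
                                 require_both_replicates = TRUE,
                                 require_consistent = FALSE) {
  if (fold <= 1) stop("fold-change threshold must be > 1")
  ev <- events[events$acetylated, , drop = FALSE]
  acetyl_pairs <- pairs[grepl("^ac", pairs$mod), , drop = FALSE]
  m <- merge(ev, acetyl_pairs[, c("accession", "peptide", "mean_ratio",
                                  "n_replicates", "consistent")],
             by = c("accession", "peptide"))
  if (nrow(m) == 0L) {
    return(data.frame(accession = character(), peptide = character(),
                      first_five = character(), start = integer(),
                      position_class = character(),
                      alt_start_candidate = logical(),
                      mean_ratio = numeric(), n_replicates = integer(),
                      call = logical(), reason = character(),
                      stringsAsFactors = FALSE))
  }
  consensus <- natb_consensus(substr(m$first_five, 1L, 2L))
  replicate_ok <- if (require_both_replicates) m$n_replicates == 2L else TRUE
  consistent_ok <- if (require_consistent) {
    is.na(m$consistent) | m$consistent
  } else TRUE
  down <- m$mean_ratio <= -log2(fold)
  m$call <- consensus & down & replicate_ok & consistent_ok
  m$reason <- ifelse(!consensus, "no-consensus",
                     ifelse(m$call, "consensus+down", "consensus-only"))
  m <- m[, c("accession", "peptide", "first_five", "start", "position_class",
             "alt_start_candidate", "mean_ratio", "n_replicates", "call",
             "reason")]
  m <- m[order(m$mean_ratio, m$accession, m$peptide), , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Unique substrate proteins among calls
#'
#' Deduplicates positive calls by accession (several acetylated N-terminal
#' peptide forms can report the same protein) and returns a
#' deterministically ordered list: mean ratio ascending, then accession.
#'
#' @param calls Output of [call_natb_substrates()], or any data frame with
#'   `accession` (+ optional `call`, `mean_ratio`) columns.
#' @return List with `n` (unique protein count) and `accessions`.
#' @export
unique_substrate_proteins <- function(calls) {
  x <- calls
  if ("call" %in% names(x)) x <- x[x$call, , drop = FALSE]
  if (nrow(x) == 0L) return(list(n = 0L, accessions = character(0)))
  if ("mean_ratio" %in% names(x)) {
    x <- x[order(x$mean_ratio, x$accession), , drop = FALSE]
  } else {
    x <- x[order(x$accession), , drop = FALSE]
  }
  acc <- x$accession[!duplicated(x$accession)]
  list(n = length(acc), accessions = acc)
}

#' Overlap of called substrates with a user-supplied known list
#'
#' @param calls Output of [call_natb_substrates()] (positive calls are
#'   used), or a character vector of accessions.
#' @param known Character vector of previously known substrate accessions.
#' @return List with `n_known`, `n_recovered`, `recovered`.
#' @export
overlap_with_known <- function(calls, known) {
  called <- if (is.character(calls)) unique(calls)
  else unique_substrate_proteins(calls)$accessions
  known <- unique(known)
  recovered <- sort(intersect(known, called))
  list(n_known = length(known), n_recovered = length(recovered),
       recovered = recovered)
}
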