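NATB_CONSENSUS <- c("MD", "ME", "MN")
NATA_RESIDUES <- c("S", "A", "T", "V", "G")
NATC_SECOND <- c("I", "L", "W", "F")
# Penultimate residues permitting initiator-Met removal by Met aminopeptidase
# (the "small residue" rule).
MAP_SMALL_RESIDUES <- c("A", "C", "G", "P", "S", "T", "V")

#' In-silico proteolytic digestion
#'
#' Digests a protein sequence with trypsin (cleaving C-terminal to K or R,
#' by default not before proline) or Lys-N (cleaving N-terminal to K).
#' Fully-specific digestion returns every fragment between cleavage
#' boundaries containing at most `missed_cleavages` internal cleavage
#' sites. Semi-specific digestion additionally returns every prefix and
#' suffix of each fully-specific peptide, i.e. peptides with one
#' non-canonical terminus, which is how non-annotated internal protein
#' N-termini become identifiable.
#'
#' @param sequence Protein sequence (single string).
#' @param protease `"trypsin"` or `"lysn"`.
#' @param specificity `"full"` or `"semi"`.
#' @param missed_cleavages Maximum internal missed cleavage sites
#'   (default 1).
#' @param no_cleave_before_proline Suppress tryptic cleavage when the
#'   following residue is P (default `TRUE`).
#' @return Data frame with columns `peptide` and `start` (1-based position
#'   of the peptide's first residue), unique rows, ordered by start then
#'   length.
#' @export
digest <- function(sequence, protease = c("trypsin", "lysn"),
                   specificity = c("full", "semi"), missed_cleavages = 1L,
                   no_cleave_before_proline = TRUE) {
  protease <- match.arg(protease)
  specificity <- match.arg(specificity)
  stopifnot(length(sequence) == 1L, missed_cleavages >= 0L)
  if (is.na(sequence) || !nzchar(sequence)) {
    stop("cannot digest an empty sequence")
  }
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  # Boundary i sits between residues i and i+1 (0 = N-terminus, n = C-terminus).
  internal <- if (protease == "trypsin") {
    i <- which(res %in% c("K", "R"))
    i <- i[i < n]
    if (no_cleave_before_proline) i <- i[res[i + 1L] != "P"]
    i
  } else {
    which(res == "K") - 1L
  }
  internal <- sort(unique(internal[internal > 0L & internal < n]))
  bounds <- c(0L, internal, n)
  nb <- length(bounds)
  starts <- integer(0)
  ends <- integer(0)
  for (i in seq_len(nb - 1L)) {
    jmax <- min(nb, i + 1L + missed_cleavages)
    for (j in (i + 1L):jmax) {
      starts <- c(starts, bounds[i] + 1L)
      ends <- c(ends, bounds[j])
    }
  }
  if (specificity == "semi") {
    semi_s <- integer(0)
    semi_e <- integer(0)
    for (k in seq_along(starts)) {
      a <- starts[k]; b <- ends[k]
      # prefixes keep the canonical N-side boundary, suffixes the C-side
      semi_s <- c(semi_s, rep(a, b - a + 1L), a:b)
      semi_e <- c(semi_e, a:b, rep(b, b - a + 1L))
    }
    starts <- semi_s
    ends <- semi_e
  }
  keep <- !duplicated(paste(starts, ends))
  starts <- starts[keep]; ends <- ends[keep]
  ord <- order(starts, ends)
  data.frame(peptide = substring(sequence, starts[ord], ends[ord]),
             start = starts[ord], stringsAsFactors = FALSE)
}

#' Map a peptide onto a protein sequence
#'
#' Returns every 1-based exact-substring match position, including
#' overlapping ones, in ascending order. An empty result means the peptide
#' does not occur; the caller decides how severe that is.
#'
#' @param peptide Peptide sequence.
#' @param sequence Protein sequence.
#' @return Integer vector of 1-based start positions.
#' @export
map_peptide <- function(peptide, sequence) {
  stopifnot(nzchar(peptide), nzchar(sequence))
  if (nchar(peptide) > nchar(sequence)) return(integer(0))
  m <- Biostrings::matchPattern(peptide, Biostrings::BString(sequence))
  as.integer(Biostrings::start(m))
}

#' Test the NatB recognition consensus
#'
#' The NatB complex acetylates initiator methionines whose penultimate
#' residue is aspartate, glutamate or asparagine: the consensus is MD, ME
#' or MN at the first two positions.
#'
#' @param two_residues Character vector of length-2 residue strings.
#' @return Logical vector.
#' @export
natb_consensus <- function(two_residues) {
  if (any(nchar(two_residues) != 2L)) {
    stop("natb_consensus expects length-2 residue strings")
  }
  toupper(two_residues) %in% NATB_CONSENSUS
}

#' Classify an N-terminal event by position and Nat-complex consensus
#'
#' Position classes: `position1` (annotated initiator Met retained),
#' `position2` (initiator Met removed), `internal` (position 3 or higher —
#' a non-annotated terminus). Nat classes follow the canonical recognition
#' motifs: NatB for M followed by D/E/N at position 1, NatA-type for
#' S/A/T/V/G exposed at position 2, NatC-type for M followed by I/L/W/F at
#' position 1; everything else is `other`. An event is an
#' alternative-translation-start candidate when the residue at the event
#' position is Met or is preceded by a Met.
#'
#' @param sequence Protein sequence (annotated, position 1 = initiator Met).
#' @param start 1-based event position.
#' @param acetylated Whether the terminus carries an N-terminal acetyl
#'   group.
#' @param accession Optional accession carried through to the output.
#' @return One-row data frame: `accession`, `start`, `acetylated`,
#'   `position_class`, `nat_class`, `alt_start_candidate`.
#' @export
classify_event <- function(sequence, start, acetylated = TRUE,
                           accession = NA_character_) {
  n <- nchar(sequence)
  if (is.na(start) || start < 1L || start > n) {
    stop("start position ", start, " outside protein of length ", n)
  }
  first <- substr(sequence, start, start)
  second <- if (start < n) substr(sequence, start + 1L, start + 1L) else ""
  position_class <- if (start == 1L) "position1"
  else if (start == 2L) "position2" else "internal"
  nat_class <- "other"
  if (start == 1L && nchar(second) == 1L &&
      natb_consensus(paste0(first, second))) {
    nat_class <- "NatB"
  } else if (start == 2L && first %in% NATA_RESIDUES) {
    nat_class <- "NatA-type"
  } else if (start == 1L && first == "M" && second %in% NATC_SECOND) {
    nat_class <- "NatC-type"
  }
  preceded_by_met <- start > 1L && substr(sequence, start - 1L, start - 1L) == "M"
  data.frame(accession = accession, start = as.integer(start),
             acetylated = acetylated, position_class = position_class,
             nat_class = nat_class,
             alt_start_candidate = first == "M" || preceded_by_met,
             stringsAsFactors = FALSE)
}

#' Build N-terminal events from identified acetylated peptides
#'
#' Maps each N-terminally acetylated peptide onto its protein (using the
#' reported `start` when present, otherwise exact-substring mapping) and
#' classifies the resulting terminus. Peptides whose sequence cannot be
#' placed, or that place ambiguously at several positions, are skipped with
#' a warning: downstream substrate calling uses only unambiguous
#' single-placement events.
#'
#' @param peptides Quant-table data frame; only rows with
#'   `nterm_acetyl = TRUE` are used.
#' @param proteins Protein database data frame from [read_fasta()].
#' @return Data frame of classified events, one per distinct
#'   (accession, start), with the peptide and its first five residues.
#' @export
nterm_events <- function(peptides, proteins) {
  ac <- peptides[peptides$nterm_acetyl, , drop = FALSE]
  ac <- ac[!duplicated(paste(ac$accession, ac$peptide)), , drop = FALSE]
  seqs <- stats::setNames(proteins$sequence, proteins$accession)
  out <- vector("list", nrow(ac))
  skipped <- character(0)
  for (i in seq_len(nrow(ac))) {
    acc <- ac$accession[i]
    seqi <- seqs[[acc]]
    if (is.null(seqi)) { skipped <- c(skipped, acc); next }
    start <- ac$start[i]
    if (is.na(start)) {
      hits <- map_peptide(ac$peptide[i], seqi)
      if (length(hits) != 1L) {
        skipped <- c(skipped, paste0(acc, ":", ac$peptide[i]))
        next
      }
      start <- hits
    }
    ev <- classify_event(seqi, start, acetylated = TRUE, accession = acc)
    ev$peptide <- ac$peptide[i]
    ev$first_five <- substr(seqi, start, start + 4L)
    out[[i]] <- ev
  }
  if (length(skipped) > 0L) {
    warning("skipped ", length(skipped),
            " unmapped or ambiguous acetylated peptide(s): ",
            paste(utils::head(skipped, 5), collapse = ", "))
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) {
    res <- data.frame(accession = character(), start = integer(),
                      acetylated = logical(), position_class = character(),
                      nat_class = character(), alt_start_candidate = logical(),
                      peptide = character(), first_five = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Plausible mature N-termini after initiator-Met processing
#'
#' Methionine aminopeptidases remove the initiator Met when the penultimate
#' residue is small (A, C, G, P, S, T or V). Returns the set of plausible
#' mature N-terminal positions: always 1, plus 2 when the Met can be
#' cleaved. Sequences not starting with Met return only position 1.
#'
#' @param sequence Protein sequence.
#' @return Integer vector of candidate mature start positions.
#' @export
met_cleavage_variants <- function(sequence) {
  stopifnot(nzchar(sequence))
  if (substr(sequence, 1L, 1L) != "M" || nchar(sequence) < 2L) {
    return(1L)
  }
  if (substr(sequence, 2L, 2L) %in% MAP_SMALL_RESIDUES) c(1L, 2L) else 1L
}

#' Theoretical observability of protein N-termini
#'
#' A protein's N-terminus counts as theoretically observable when at least
#' one fully-specific N-terminal peptide — trypsin or Lys-N, up to one
#' missed cleavage, from the annotated start or from the Met-cleaved mature
#' start where applicable — has a length within the instrument-accessible
#' window (default 5 to 45 residues). The summary also reports how many
#' observable proteins carry the NatB recognition sequence at their
#' annotated N-terminus.
#'
#' @param proteins Protein database data frame from [read_fasta()].
#' @param min_len,max_len Observable peptide-length window, residues.
#' @param missed_cleavages Missed cleavages allowed in the N-terminal
#'   peptide.
#' @return List with `per_protein` (accession, observable, natb_consensus)
#'   and `summary` (`n_observable`, `n_observable_natb`,
#'   `fraction_natb`).
#' @export
theoretical_observability <- function(proteins, min_len = 5L, max_len = 45L,
                                      missed_cleavages = 1L) {
  if (nrow(proteins) == 0L) stop("proteome is empty")
  if (min_len > max_len) stop("min_len must not exceed max_len")
  obs <- logical(nrow(proteins))
  for (i in seq_len(nrow(proteins))) {
    seqi <- proteins$sequence[i]
    for (s in met_cleavage_variants(seqi)) {
      mature <- substring(seqi, s)
      for (enz in c("trypsin", "lysn")) {
        d <- digest(mature, enz, "full", missed_cleavages)
        lens <- nchar(d$peptide[d$start == 1L])
        if (any(lens >= min_len & lens <= max_len)) obs[i] <- TRUE
      }
      if (obs[i]) break
    }
  }
  two <- substr(proteins$sequence, 1L, 2L)
  consensus <- nchar(two) == 2L & toupper(two) %in% NATB_CONSENSUS
  per_protein <- data.frame(accession = proteins$accession,
                            observable = obs, natb_consensus = consensus,
                            stringsAsFactors = FALSE)
  n_obs <- sum(obs)
  n_natb <- sum(obs & consensus)
  list(per_protein = per_protein,
       summary = list(n_observable = n_obs, n_observable_natb = n_natb,
                      fraction_natb = if (n_obs > 0) n_natb / n_obs else NaN))
}
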