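#' Read ortholog groups from a manifest of per-group FASTA files
#'
#' Each ortholog group is one FASTA file whose headers are
#' `species|sequence_id`; the manifest is a TSV with columns `accession`
#' (the yeast anchor protein) and `fasta_path` (absolute, or relative to
#' the manifest's directory).
#'
#' @param manifest_path Path to the manifest TSV.
#' @return Named list (by anchor accession) of data frames with columns
#'   `species`, `id`, `sequence`.
#' @export
read_ortholog_groups <- function(manifest_path) {
  man <- utils::read.delim(manifest_path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  stopifnot(all(c("accession", "fasta_path") %in% names(man)))
  base <- dirname(manifest_path)
  groups <- lapply(seq_len(nrow(man)), function(i) {
    p <- man$fasta_path[i]
    if (!file.exists(p)) p <- file.path(base, man$fasta_path[i])
    aa <- Biostrings::readBStringSet(p)
    parts <- strsplit(names(aa), "|", fixed = TRUE)
    bad <- lengths(parts) < 2L
    if (any(bad)) {
      stop("ortholog FASTA header not 'species|id' in ", p, ": ",
           names(aa)[bad][1])
    }
    data.frame(species = vapply(parts, `[`, "", 1L),
               id = vapply(parts, function(x) paste(x[-1], collapse = "|"), ""),
               sequence = toupper(as.character(aa)),
               stringsAsFactors = FALSE)
  })
  names(groups) <- man$accession
  groups
}

starts_with_consensus <- function(sequences) {
  nchar(sequences) >= 2L & toupper(substr(sequences, 1L, 2L)) %in% NATB_CONSENSUS
}

#' Per-species conservation of the NatB recognition motif
#'
#' For each species, the percentage of its ortholog sequences whose first
#' two residues are MD, ME or MN. With the default `"pooled"` method every
#' member sequence of every group is counted individually (in-paralogs
#' count separately); `"group_mean"` first scores each group per species
#' and then averages over the groups in which the species occurs.
#'
#' @param groups List of ortholog-group data frames
#'   (see [read_ortholog_groups()]).
#' @param method `"pooled"` (default) or `"group_mean"`.
#' @return Named numeric vector: percent conserved per species, sorted by
#'   species name.
#' @export
species_conservation <- function(groups, method = c("pooled", "group_mean")) {
  method <- match.arg(method)
  if (length(groups) == 0L) stop("no ortholog groups supplied")
  all_members <- do.call(rbind, lapply(seq_along(groups), function(i) {
    g <- groups[[i]]
    g$group <- i
    g
  }))
  all_members$conserved <- starts_with_consensus(all_members$sequence)
  if (method == "pooled") {
    agg <- stats::aggregate(conserved ~ species, data = all_members,
                            FUN = function(x) 100 * mean(x))
  } else {
    per_group <- stats::aggregate(conserved ~ species + group,
                                  data = all_members,
                                  FUN = function(x) 100 * mean(x))
    agg <- stats::aggregate(conserved ~ species, data = per_group, FUN = mean)
  }
  out <- stats::setNames(agg$conserved, agg$species)
  out[order(names(out))]
}

#' Per-protein conservation of the NatB recognition motif
#'
#' The percentage of species represented in one ortholog group that
#' conserve the motif, where a species conserves when at least one of its
#' member sequences (collapsing in-paralogs) starts with MD, ME or MN.
#'
#' @param group One ortholog-group data frame.
#' @return Percent of represented species conserving the motif.
#' @export
protein_conservation <- function(group) {
  if (nrow(group) == 0L) stop("empty ortholog group")
  conserved <- starts_with_consensus(group$sequence)
  per_species <- tapply(conserved, group$species, any)
  100 * mean(per_species)
}

#' Rank ortholog groups by motif conservation and re-score the top k
#'
#' Groups are ranked by [protein_conservation()] descending (ties broken
#' by accession, lexicographically) and the per-species conservation is
#' re-computed on the `k` most conserved proteins only.
#'
#' @param groups Named list of ortholog-group data frames.
#' @param k Number of top proteins (default 5).
#' @param method Passed to [species_conservation()] for the re-analysis.
#' @return List with `ranking` (data frame `accession`,
#'   `protein_conservation`), `top` (the selected accessions) and
#'   `species_subset` (per-species conservation over the top groups).
#' @export
top_conserved <- function(groups, k = 5L, method = c("pooled", "group_mean")) {
  if (k <= 0L) stop("k must be positive")
  if (k > length(groups)) stop("k exceeds the number of groups")
  pc <- vapply(groups, protein_conservation, numeric(1))
  ranking <- data.frame(accession = names(groups),
                        protein_conservation = unname(pc),
                        stringsAsFactors = FALSE)
  ranking <- ranking[order(-ranking$protein_conservation, ranking$accession), ,
                     drop = FALSE]
  rownames(ranking) <- NULL
  top <- ranking$accession[seq_len(k)]
  list(ranking = ranking, top = top,
       species_subset = species_conservation(groups[top],
                                             method = match.arg(method)))
}
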