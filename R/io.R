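# Residues allowed in protein records: the 20 standard amino acids plus X.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

QUANT_COLUMNS <- c("peptide", "accession", "start", "nterm_acetyl",
                   "phospho_positions", "score", "intensity_14N",
                   "intensity_15N")

#' Read a protein sequence database from FASTA
#'
#' Headers are parsed as `>accession [gene_name]`; everything after the first
#' whitespace-separated token is taken as an optional gene name. Sequences are
#' uppercased and trailing `*` stop characters stripped. Position 1 of every
#' sequence is the initiator Met as annotated in the database; all terminus
#' coordinates in the package are 1-based in this frame.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped).
#' @return A data frame with columns `accession`, `gene_name` (`NA` when the
#'   header has no second token) and `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  aa <- Biostrings::readBStringSet(path)
  if (length(aa) == 0L) {
    stop("FASTA file is empty: ", path)
  }
  headers <- names(aa)
  accession <- sub("\\s.*$", "", headers)
  gene_name <- ifelse(grepl("\\s", headers),
                      sub("^\\S+\\s+", "", headers), NA_character_)
  dup <- accession[duplicated(accession)]
  if (length(dup) > 0L) {
    stop("duplicate accession(s) in FASTA: ", paste(unique(dup), collapse = ", "))
  }
  sequence <- toupper(gsub("\\*+$", "", as.character(aa)))
  if (any(!nzchar(sequence))) {
    stop("empty sequence for accession(s): ",
         paste(accession[!nzchar(sequence)], collapse = ", "))
  }
  bad <- vapply(strsplit(sequence, ""), function(s) {
    any(!s %in% c(AA_ALPHABET, "X"))
  }, logical(1))
  if (any(bad)) {
    stop("non-standard residues in sequence(s): ",
         paste(accession[bad], collapse = ", "))
  }
  data.frame(accession = accession, gene_name = gene_name,
             sequence = sequence, stringsAsFactors = FALSE)
}

#' Write protein records to FASTA
#'
#' @param proteins Data frame with `accession`, optional `gene_name`, and
#'   `sequence` columns, as returned by [read_fasta()].
#' @param path Output path.
#' @param width Line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 60L) {
  stopifnot(all(c("accession", "sequence") %in% names(proteins)))
  set <- Biostrings::BStringSet(proteins$sequence)
  gene <- if ("gene_name" %in% names(proteins)) proteins$gene_name else NA
  names(set) <- ifelse(is.na(gene) | !nzchar(gene),
                       proteins$accession,
                       paste(proteins$accession, gene))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a peptide identification/quantification table
#'
#' The table is the package's surrogate for a search-engine export: one row
#' per identified peptide in one biological replicate, tab-separated with the
#' header `peptide, accession, start, nterm_acetyl, phospho_positions, score,
#' intensity_14N, intensity_15N`. `phospho_positions` holds comma-separated
#' 1-based positions within the peptide (empty for none); `start` may be
#' empty and is then filled later by mapping the peptide onto its protein.
#' A missing intensity is encoded as an empty field (or `NA`) and kept as
#' `NA`, which is distinct from zero: such rows are excluded from ratio
#' computation but retained for identification-level outputs.
#'
#' @param path Path to a TSV file with the documented header.
#' @param replicate_id Biological replicate (1 or 2), stamped on every row.
#' @return A data frame with the schema columns plus `replicate_id`.
#' @export
read_quant_table <- function(path, replicate_id) {
  stopifnot(replicate_id %in% c(1L, 2L))
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", na.strings = c("NA", ""),
                           check.names = FALSE)
  unknown <- setdiff(names(tab), QUANT_COLUMNS)
  if (length(unknown) > 0L || !all(QUANT_COLUMNS %in% names(tab))) {
    stop("quant table columns must be exactly {",
         paste(QUANT_COLUMNS, collapse = ", "), "}; got {",
         paste(names(tab), collapse = ", "), "}")
  }
  out <- data.frame(
    peptide = as.character(tab$peptide),
    accession = as.character(tab$accession),
    start = suppressWarnings(as.integer(tab$start)),
    nterm_acetyl = parse_flag(tab$nterm_acetyl),
    phospho_positions = ifelse(is.na(tab$phospho_positions), "",
                               tab$phospho_positions),
    score = as.numeric(tab$score),
    intensity_14N = as.numeric(tab$intensity_14N),
    intensity_15N = as.numeric(tab$intensity_15N),
    replicate_id = rep(as.integer(replicate_id), nrow(tab)),
    stringsAsFactors = FALSE
  )
  validate_quant_table(out)
  out
}

#' Write a peptide quantification table
#'
#' Inverse of [read_quant_table()]; the `replicate_id` column is dropped on
#' output so that written tables round-trip through the reader.
#'
#' @param peptides Quant-table data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(peptides, path) {
  out <- peptides[, QUANT_COLUMNS]
  out$nterm_acetyl <- ifelse(out$nterm_acetyl, "yes", "no")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

parse_flag <- function(x) {
  x <- tolower(as.character(x))
  ok <- x %in% c("yes", "no", "true", "false", "1", "0")
  if (any(!ok)) {
    stop("nterm_acetyl must be yes/no (row ", which(!ok)[1], ")")
  }
  x %in% c("yes", "true", "1")
}

validate_quant_table <- function(tab) {
  if (nrow(tab) == 0L) return(invisible(tab))
  neg <- which(!is.na(tab$intensity_14N) & tab$intensity_14N < 0 |
                 !is.na(tab$intensity_15N) & tab$intensity_15N < 0)
  if (length(neg) > 0L) {
    stop("negative intensity at row ", neg[1])
  }
  if (any(is.na(tab$score) | tab$score < 0)) {
    stop("score must be present and >= 0")
  }
  both_missing <- is.na(tab$intensity_14N) & is.na(tab$intensity_15N)
  if (any(both_missing)) {
    stop("both intensities missing at row ", which(both_missing)[1])
  }
  plist <- parse_phospho(tab$phospho_positions)
  bad <- mapply(function(p, pep) length(p) > 0 && any(p < 1 | p > nchar(pep)),
                plist, tab$peptide)
  if (any(bad)) {
    stop("phospho position outside peptide at row ", which(bad)[1])
  }
  invisible(tab)
}

parse_phospho <- function(x) {
  lapply(strsplit(ifelse(is.na(x), "", x), ","), function(p) {
    p <- p[nzchar(p)]
    as.integer(p)
  })
}

#' Load the packaged table of detected NatB substrates
#'
#' A small packaged fixture listing the 59 NatB substrate proteins detected
#' in the reference wild-type versus *nat3* deletion experiment: accession,
#' gene name, identification score, the first five residues of the acetylated
#' N-terminal peptide, its 1-based start position in the protein, and the
#' average log2 knockout/wild-type ratio over the two label-swapped
#' replicates. Four rows are internal (alternative-start) termini with
#' `start > 1`.
#'
#' @return A data frame with columns `accession`, `name`, `score`,
#'   `sequence`, `start`, `average_ratio`.
#' @export
load_natb_substrate_table <- function() {
  path <- system.file("extdata", "table1_natb_substrates.tsv",
                      package = "ntaq", mustWork = TRUE)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           na.strings = c("NA"), stringsAsFactors = FALSE)
  tab$name <- ifelse(is.na(tab$name), "", tab$name)
  tab
}
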