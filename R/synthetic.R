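# Approximate amino-acid background frequencies of the yeast proteome,
# used for random sequence generation.
AA_FREQS <- c(A = 0.055, C = 0.013, D = 0.058, E = 0.065, F = 0.045,
              G = 0.050, H = 0.022, I = 0.066, K = 0.073, L = 0.096,
              M = 0.021, N = 0.061, P = 0.044, Q = 0.039, R = 0.044,
              S = 0.090, T = 0.059, V = 0.056, W = 0.010, Y = 0.034)

#' Configuration for the synthetic-data generator
#'
#' Defines the study conditions the generator emulates: a proteome in which
#' 16% of proteins carry the NatB consensus at their N-terminus, two
#' label-swapped replicates with log-normal intensity noise, a planted set
#' of NatB substrates whose acetylated N-terminal peptides drop strongly in
#' the knockout while their protein levels barely move, and a
#' phosphoproteome in which 23% of sites are more than three-fold
#' up-regulated with the planted kinase's sites over-represented among
#' them. All randomness is governed by `seed`: identical configurations
#' produce identical outputs.
#'
#' @param seed Integer seed for all generators.
#' @param n_proteins Number of proteins in the synthetic proteome.
#' @param fraction_natb_consensus Fraction of proteins with an MD/ME/MN
#'   N-terminus.
#' @param n_natb_substrates Number of planted NatB substrates (drawn from
#'   the consensus proteins).
#' @param natb_effect_log2 True log2 KO/WT effect on substrates' acetylated
#'   N-terminal peptides.
#' @param protein_effect_sd SD of true protein-level log2 effects (protein
#'   abundance is largely unperturbed).
#' @param noise_sd SD of the per-replicate measurement noise on the log2
#'   ratio scale.
#' @param fraction_acetylated Fraction of non-substrate proteins whose
#'   acetylated N-terminal peptide is also detected.
#' @param abundance_meanlog,abundance_sdlog Log-normal parameters of the
#'   per-protein base intensity (arbitrary units); the wide sdlog gives the
#'   heavy-tailed dynamic range typical of shotgun proteomics.
#' @param detection_floor Intensity below which a channel drops out
#'   (recorded as missing, producing singleton-replicate peptides).
#' @param n_phospho_sites Number of phosphorylation sites.
#' @param fraction_phospho_up,fraction_phospho_down Fractions of sites with
#'   planted up/down effects.
#' @param phospho_up_log2,phospho_down_log2 True log2 effects of regulated
#'   sites.
#' @param kinases Named numeric vector of kinase base probabilities
#'   (normalised internally).
#' @param kinase_multipliers Named numeric vector of enrichment multipliers
#'   applied to kinase probabilities among up-regulated sites (default: the
#'   planted kinase SNF1 at 5, all others 1).
#' @param localizations Named numeric vector of localization base
#'   probabilities.
#' @param localization_multipliers Multipliers applied among up-regulated
#'   sites (default: bud enriched, cytoplasm depleted).
#' @param n_ortholog_groups,n_species Ortholog-survey dimensions.
#' @param n_top_conserved Number of groups planted at full motif
#'   conservation.
#' @param background_conservation_max Non-planted groups draw their
#'   per-sequence conservation probability uniformly from
#'   `[0, background_conservation_max]`.
#' @param species_presence_prob Probability that a species is represented
#'   in a group.
#' @param inparalog_prob Probability that a represented species contributes
#'   a second (in-paralog) sequence.
#' @return Object of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_proteins = 4000L,
                              fraction_natb_consensus = 0.16,
                              n_natb_substrates = 60L,
                              natb_effect_log2 = -5,
                              protein_effect_sd = 0.3,
                              noise_sd = 0.5,
                              fraction_acetylated = 0.19,
                              abundance_meanlog = log(1e6),
                              abundance_sdlog = 1.5,
                              detection_floor = 300,
                              n_phospho_sites = 2300L,
                              fraction_phospho_up = 0.23,
                              fraction_phospho_down = 0.035,
                              phospho_up_log2 = 2.5,
                              phospho_down_log2 = -2.5,
                              kinases = c(SNF1 = 0.14, CDC28 = 0.14,
                                          PKA1 = 0.12, HOG1 = 0.10,
                                          CKA1 = 0.10, PKC1 = 0.10,
                                          KIN28 = 0.08, STE20 = 0.08,
                                          RIM11 = 0.07, YAK1 = 0.07),
                              kinase_multipliers = c(SNF1 = 5),
                              localizations = c(cytoplasm = 0.35,
                                                nucleus = 0.25,
                                                mitochondrion = 0.12,
                                                ER = 0.10, membrane = 0.08,
                                                bud = 0.05, vacuole = 0.05),
                              localization_multipliers = c(bud = 3,
                                                           cytoplasm = 0.5),
                              n_ortholog_groups = 59L,
                              n_species = 52L,
                              n_top_conserved = 5L,
                              background_conservation_max = 0.5,
                              species_presence_prob = 0.8,
                              inparalog_prob = 0.1) {
  cfg <- list(seed = as.integer(seed), n_proteins = as.integer(n_proteins),
              fraction_natb_consensus = fraction_natb_consensus,
              n_natb_substrates = as.integer(n_natb_substrates),
              natb_effect_log2 = natb_effect_log2,
              protein_effect_sd = protein_effect_sd, noise_sd = noise_sd,
              fraction_acetylated = fraction_acetylated,
              abundance_meanlog = abundance_meanlog,
              abundance_sdlog = abundance_sdlog,
              detection_floor = detection_floor,
              n_phospho_sites = as.integer(n_phospho_sites),
              fraction_phospho_up = fraction_phospho_up,
              fraction_phospho_down = fraction_phospho_down,
              phospho_up_log2 = phospho_up_log2,
              phospho_down_log2 = phospho_down_log2,
              kinases = kinases / sum(kinases),
              kinase_multipliers = kinase_multipliers,
              localizations = localizations / sum(localizations),
              localization_multipliers = localization_multipliers,
              n_ortholog_groups = as.integer(n_ortholog_groups),
              n_species = as.integer(n_species),
              n_top_conserved = as.integer(n_top_conserved),
              background_conservation_max = background_conservation_max,
              species_presence_prob = species_presence_prob,
              inparalog_prob = inparalog_prob)
  fr <- c(cfg$fraction_natb_consensus, cfg$fraction_acetylated,
          cfg$fraction_phospho_up, cfg$fraction_phospho_down,
          cfg$species_presence_prob, cfg$inparalog_prob)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (cfg$noise_sd <= 0) stop("noise_sd must be positive")
  if (cfg$n_proteins <= 0L) stop("n_proteins must be positive")
  if (cfg$fraction_phospho_up + cfg$fraction_phospho_down > 1) {
    stop("phospho up + down fractions exceed 1")
  }
  class(cfg) <- "sim_config"
  cfg
}

random_tail <- function(n, len) {
  vapply(len, function(l) {
    paste(sample(names(AA_FREQS), l, replace = TRUE, prob = AA_FREQS),
          collapse = "")
  }, character(1))
}

#' Generate a synthetic proteome with ground truth
#'
#' Random protein sequences (length 50-600, yeast-like residue
#' composition) starting with Met; a configured fraction receives a NatB
#' consensus second residue (D/E/N), the rest draw their second residue
#' from the remaining alphabet. NatB substrates are drawn from the
#' consensus proteins; every protein gets a true protein-level log2 effect
#' (centred on zero) and substrates additionally a strong negative effect
#' on their acetylated N-terminus.
#'
#' @param config A [simulation_config()].
#' @param dir Optional directory: writes `proteome.fasta` and
#'   `ground_truth.tsv` there.
#' @return List with `proteins` (accession, gene_name, sequence) and
#'   `truth` (accession, consensus, natb_substrate, acetyl_detected,
#'   protein_effect, acetyl_effect).
#' @export
generate_proteome <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_proteins
  accession <- sprintf("YSY%04dW", seq_len(n))
  lens <- sample(50:600, n, replace = TRUE)
  n_cons <- round(config$fraction_natb_consensus * n)
  consensus <- rep(FALSE, n)
  consensus[sample.int(n, n_cons)] <- TRUE
  den <- c("D", "E", "N")
  other_second <- setdiff(names(AA_FREQS), den)
  second <- ifelse(consensus,
                   sample(den, n, replace = TRUE),
                   sample(other_second, n, replace = TRUE,
                          prob = AA_FREQS[other_second]))
  tails <- random_tail(n, lens - 2L)
  sequence <- paste0("M", second, tails)
  if (config$n_natb_substrates > n_cons) {
    stop("fewer consensus proteins than requested substrates")
  }
  substrate <- rep(FALSE, n)
  substrate[sample(which(consensus), config$n_natb_substrates)] <- TRUE
  protein_effect <- stats::rnorm(n, 0, config$protein_effect_sd)
  acetyl_effect <- ifelse(substrate, config$natb_effect_log2, protein_effect)
  acetyl_detected <- substrate |
    stats::runif(n) < config$fraction_acetylated
  proteins <- data.frame(accession = accession, gene_name = NA_character_,
                         sequence = sequence, stringsAsFactors = FALSE)
  truth <- data.frame(accession = accession, consensus = consensus,
                      natb_substrate = substrate,
                      acetyl_detected = acetyl_detected,
                      protein_effect = protein_effect,
                      acetyl_effect = acetyl_effect,
                      stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(proteins, file.path(dir, "proteome.fasta"))
    utils::write.table(truth, file.path(dir, "ground_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(proteins = proteins, truth = truth)
}

# N-terminal fully-specific tryptic peptide used as the acetylated
# N-terminal peptide of a protein: the shortest one of length >= 5
# (allowing one missed cleavage), else the 0-missed fragment.
nterm_acetyl_peptide <- function(sequence) {
  d <- digest(sequence, "trypsin", "full", missed_cleavages = 1L)
  nterm <- d[d$start == 1L, , drop = FALSE]
  ok <- nterm$peptide[nchar(nterm$peptide) >= 5L]
  if (length(ok) > 0L) ok[which.min(nchar(ok))] else nterm$peptide[1L]
}

simulate_channels <- function(base, effect, noise_sd) {
  half <- noise_sd / sqrt(2)
  wt <- base * 2^stats::rnorm(length(base), 0, half)
  ko <- base * 2^(effect + stats::rnorm(length(base), 0, half))
  list(wt = wt, ko = ko)
}

apply_floor <- function(x, floor) ifelse(x < floor, NA_real_, x)

#' Generate the two label-swapped replicate quantification tables
#'
#' For every protein, 1-10 unmodified fully-tryptic peptides plus (for the
#' acetyl-detected subset) its acetylated N-terminal peptide. Channel
#' intensities are log-normal around a heavy-tailed per-protein base
#' abundance, with the knockout channel scaled by two to the true log2
#' effect; measurement noise is drawn independently per replicate and
#' channel, and replicate 2 swaps the isotope-channel assignment.
#' Intensities below the detection floor drop out (missing, not zero), so
#' singleton-replicate peptides occur.
#'
#' @param proteome Output of [generate_proteome()].
#' @param config The same [simulation_config()].
#' @param dir Optional directory: writes `quant_rep1.tsv` and
#'   `quant_rep2.tsv`.
#' @return List with quant-table data frames `rep1`, `rep2` and the
#'   `orientation` used (replicate 1: knockout on the 14N channel).
#' @export
generate_quant_tables <- function(proteome, config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  proteins <- proteome$proteins
  truth <- proteome$truth
  rows <- vector("list", nrow(proteins))
  for (i in seq_len(nrow(proteins))) {
    seqi <- proteins$sequence[i]
    d <- digest(seqi, "trypsin", "full", missed_cleavages = 0L)
    cand <- d[nchar(d$peptide) >= 6L & nchar(d$peptide) <= 45L, , drop = FALSE]
    npep <- min(sample.int(10L, 1L), nrow(cand))
    pick <- if (npep > 0L) cand[sample.int(nrow(cand), npep), , drop = FALSE]
    else cand
    pep <- pick$peptide
    start <- pick$start
    acetyl <- rep(FALSE, length(pep))
    effect <- rep(truth$protein_effect[i], length(pep))
    if (truth$acetyl_detected[i]) {
      ac_pep <- nterm_acetyl_peptide(seqi)
      pep <- c(pep, ac_pep)
      start <- c(start, 1L)
      acetyl <- c(acetyl, TRUE)
      effect <- c(effect, truth$acetyl_effect[i])
    }
    if (length(pep) == 0L) next
    rows[[i]] <- data.frame(accession = proteins$accession[i], peptide = pep,
                            start = start, acetyl = acetyl, effect = effect,
                            stringsAsFactors = FALSE)
  }
  all_pep <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  n <- nrow(all_pep)
  abundance <- stats::rlnorm(length(unique(all_pep$accession)),
                             config$abundance_meanlog, config$abundance_sdlog)
  names(abundance) <- unique(all_pep$accession)
  ionization <- stats::rlnorm(n, 0, 0.5)
  base <- abundance[all_pep$accession] * ionization
  score <- ifelse(all_pep$acetyl, round(stats::runif(n, 31, 120)),
                  round(stats::runif(n, 20, 120)))
  make_rep <- function(replicate_id) {
    ch <- simulate_channels(base, all_pep$effect, config$noise_sd)
    if (replicate_id == 1L) {
      i14 <- ch$ko; i15 <- ch$wt
    } else {
      i14 <- ch$wt; i15 <- ch$ko
    }
    tab <- data.frame(
      peptide = all_pep$peptide, accession = all_pep$accession,
      start = all_pep$start, nterm_acetyl = all_pep$acetyl,
      phospho_positions = "", score = score,
      intensity_14N = apply_floor(round(i14, 2), config$detection_floor),
      intensity_15N = apply_floor(round(i15, 2), config$detection_floor),
      replicate_id = replicate_id, stringsAsFactors = FALSE)
    tab <- tab[!(is.na(tab$intensity_14N) & is.na(tab$intensity_15N)), ,
               drop = FALSE]
    rownames(tab) <- NULL
    tab
  }
  rep1 <- make_rep(1L)
  rep2 <- make_rep(2L)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_quant_table(rep1, file.path(dir, "quant_rep1.tsv"))
    write_quant_table(rep2, file.path(dir, "quant_rep2.tsv"))
  }
  list(rep1 = rep1, rep2 = rep2, orientation = label_orientation())
}

sample_categories <- function(n, probs, multipliers = NULL) {
  p <- probs
  if (!is.null(multipliers) && length(multipliers) > 0L) {
    m <- multipliers[names(p)]
    m[is.na(m)] <- 1
    p <- p * m
  }
  sample(names(p), n, replace = TRUE, prob = p / sum(p))
}

#' Generate a synthetic phosphoproteome with site annotations
#'
#' Phosphorylation sites are placed on distinct proteins; a configured
#' fraction receives a planted up-regulation effect (and a smaller fraction
#' a down effect). Each site is annotated with a predicted kinase and its
#' host protein's localization; among up-regulated sites the kinase and
#' localization draws are re-weighted by the configured enrichment
#' multipliers, planting the over-representation signal the enrichment
#' module is meant to recover.
#'
#' @param proteome Output of [generate_proteome()].
#' @param config The same [simulation_config()].
#' @param dir Optional directory: writes `phospho_rep1.tsv`,
#'   `phospho_rep2.tsv`, `site_kinase.tsv` and `protein_localization.tsv`.
#' @return List with quant tables `rep1`, `rep2`, and `sites` (site_id,
#'   accession, peptide, kinase, localization, class, true_effect).
#' @export
generate_phospho_table <- function(proteome, config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  n <- config$n_phospho_sites
  if (n == 0L) {
    empty <- data.frame(peptide = character(), accession = character(),
                        start = integer(), nterm_acetyl = logical(),
                        phospho_positions = character(), score = numeric(),
                        intensity_14N = numeric(), intensity_15N = numeric(),
                        replicate_id = integer(), stringsAsFactors = FALSE)
    return(list(rep1 = empty, rep2 = empty,
                sites = data.frame(site_id = character(),
                                   accession = character(),
                                   kinase = character(),
                                   localization = character(),
                                   stringsAsFactors = FALSE)))
  }
  proteins <- proteome$proteins
  if (n > nrow(proteins)) {
    stop("n_phospho_sites exceeds the number of proteins (one site per ",
         "protein)")
  }
  host <- proteins[sample.int(nrow(proteins), n), , drop = FALSE]
  len <- nchar(host$sequence)
  pos <- pmin(pmax(2L, floor(stats::runif(n) * (len - 2L)) + 2L), len - 1L)
  pstart <- pmax(1L, pos - 5L)
  pend <- pmin(len, pos + 6L)
  peptide <- substr(host$sequence, pstart, pend)
  within <- pos - pstart + 1L
  u <- stats::runif(n)
  class_ <- ifelse(u < config$fraction_phospho_up, "up",
                   ifelse(u < config$fraction_phospho_up +
                            config$fraction_phospho_down, "down",
                          "unchanged"))
  effect <- ifelse(class_ == "up", config$phospho_up_log2,
                   ifelse(class_ == "down", config$phospho_down_log2, 0))
  kinase <- character(n)
  localization <- character(n)
  is_up <- class_ == "up"
  kinase[is_up] <- sample_categories(sum(is_up), config$kinases,
                                     config$kinase_multipliers)
  kinase[!is_up] <- sample_categories(sum(!is_up), config$kinases)
  localization[is_up] <- sample_categories(sum(is_up), config$localizations,
                                           config$localization_multipliers)
  localization[!is_up] <- sample_categories(sum(!is_up), config$localizations)
  site_id <- paste0(host$accession, "_", pos)
  abundance <- stats::rlnorm(n, config$abundance_meanlog,
                             config$abundance_sdlog)
  score <- round(stats::runif(n, 26, 110))
  make_rep <- function(replicate_id) {
    ch <- simulate_channels(abundance, effect, config$noise_sd)
    if (replicate_id == 1L) {
      i14 <- ch$ko; i15 <- ch$wt
    } else {
      i14 <- ch$wt; i15 <- ch$ko
    }
    tab <- data.frame(
      peptide = peptide, accession = host$accession, start = pstart,
      nterm_acetyl = FALSE, phospho_positions = as.character(within),
      score = score,
      intensity_14N = apply_floor(round(i14, 2), config$detection_floor),
      intensity_15N = apply_floor(round(i15, 2), config$detection_floor),
      replicate_id = replicate_id, stringsAsFactors = FALSE)
    tab <- tab[!(is.na(tab$intensity_14N) & is.na(tab$intensity_15N)), ,
               drop = FALSE]
    rownames(tab) <- NULL
    tab
  }
  sites <- data.frame(site_id = site_id, accession = host$accession,
                      peptide = peptide, kinase = kinase,
                      localization = localization, class = class_,
                      true_effect = effect, stringsAsFactors = FALSE)
  out <- list(rep1 = make_rep(1L), rep2 = make_rep(2L), sites = sites)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_quant_table(out$rep1, file.path(dir, "phospho_rep1.tsv"))
    write_quant_table(out$rep2, file.path(dir, "phospho_rep2.tsv"))
    utils::write.table(sites[, c("site_id", "kinase")],
                       file.path(dir, "site_kinase.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(unique(sites[, c("accession", "localization")]),
                       file.path(dir, "protein_localization.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' Generate synthetic ortholog groups with planted conserved proteins
#'
#' One group per anchor protein; each of the configured species is present
#' with the configured probability and contributes one (occasionally two,
#' in-paralog) sequences. A planted subset of groups conserves the NatB
#' recognition motif in every member sequence; the remaining groups draw a
#' per-sequence conservation probability uniformly below
#' `background_conservation_max`, mirroring the sporadic conservation seen
#' across the phylogenetic tree.
#'
#' @param config A [simulation_config()].
#' @param dir Optional directory: writes one FASTA per group plus
#'   `manifest.tsv`.
#' @return List with `groups` (named list of group data frames), and
#'   `truth` (accession, conservation_prob, planted).
#' @export
generate_ortholog_groups <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  ng <- config$n_ortholog_groups
  if (config$n_top_conserved > ng) {
    stop("n_top_conserved exceeds the number of groups")
  }
  accession <- sprintf("YSY%04dC", seq_len(ng))
  species <- sprintf("species_%02d", seq_len(config$n_species))
  planted <- rep(FALSE, ng)
  planted[sample.int(ng, config$n_top_conserved)] <- TRUE
  prob <- ifelse(planted, 1,
                 stats::runif(ng, 0, config$background_conservation_max))
  den <- c("D", "E", "N")
  groups <- vector("list", ng)
  for (g in seq_len(ng)) {
    present <- stats::runif(config$n_species) < config$species_presence_prob
    if (!any(present)) present[1] <- TRUE
    sp <- species[present]
    nseq <- 1L + stats::rbinom(length(sp), 1L, config$inparalog_prob)
    sp_all <- rep(sp, nseq)
    m <- length(sp_all)
    conserving <- stats::runif(m) < prob[g]
    head2 <- ifelse(conserving,
                    paste0("M", sample(den, m, replace = TRUE)),
                    ifelse(stats::runif(m) < 0.7,
                           paste0("M", sample(setdiff(names(AA_FREQS), den),
                                              m, replace = TRUE)),
                           random_tail(m, rep(2L, m))))
    groups[[g]] <- data.frame(
      species = sp_all,
      id = paste0(accession[g], "_", sp_all, "_",
                  stats::ave(seq_len(m), sp_all, FUN = seq_along)),
      sequence = paste0(head2, random_tail(m, rep(8L, m))),
      stringsAsFactors = FALSE)
  }
  names(groups) <- accession
  truth <- data.frame(accession = accession, conservation_prob = prob,
                      planted = planted, stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- character(ng)
    for (g in seq_len(ng)) {
      paths[g] <- paste0(accession[g], ".fasta")
      set <- Biostrings::BStringSet(groups[[g]]$sequence)
      names(set) <- paste0(groups[[g]]$species, "|", groups[[g]]$id)
      Biostrings::writeXStringSet(set, file.path(dir, paths[g]))
    }
    utils::write.table(data.frame(accession = accession, fasta_path = paths),
                       file.path(dir, "manifest.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(groups = groups, truth = truth)
}
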