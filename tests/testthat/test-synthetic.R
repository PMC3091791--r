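test_that("configuration validates fractions and sizes", {
  expect_s3_class(simulation_config(), "sim_config")
  expect_error(simulation_config(fraction_natb_consensus = 1.2), "fractions")
  expect_error(simulation_config(noise_sd = 0), "noise_sd")
  expect_error(simulation_config(n_proteins = 0), "n_proteins")
  expect_error(simulation_config(fraction_phospho_up = 0.9,
                                 fraction_phospho_down = 0.2), "exceed")
})

test_that("generation is fully deterministic under a fixed seed", {
  cfg <- simulation_config(seed = 314, n_proteins = 60,
                           n_natb_substrates = 5, n_phospho_sites = 40,
                           n_ortholog_groups = 6, n_species = 4,
                           n_top_conserved = 2)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- generate_proteome(cfg, dir = d1)
  p2 <- generate_proteome(cfg, dir = d2)
  expect_identical(p1, p2)
  expect_identical(readLines(file.path(d1, "proteome.fasta")),
                   readLines(file.path(d2, "proteome.fasta")))
  q1 <- generate_quant_tables(p1, cfg)
  q2 <- generate_quant_tables(p2, cfg)
  expect_identical(q1$rep1, q2$rep1)
  expect_identical(q1$rep2, q2$rep2)
  o1 <- generate_ortholog_groups(cfg, dir = d1)
  o2 <- generate_ortholog_groups(cfg, dir = d2)
  expect_identical(o1, o2)
  f1 <- file.path(d1, paste0(names(o1$groups)[1], ".fasta"))
  f2 <- file.path(d2, paste0(names(o2$groups)[1], ".fasta"))
  expect_identical(readLines(f1), readLines(f2))
})

test_that("the proteome honours the consensus fraction and sequence rules", {
  cfg <- simulation_config(seed = 2, n_proteins = 500, n_natb_substrates = 10)
  pt <- generate_proteome(cfg)
  expect_true(all(grepl("^M", pt$proteins$sequence)))
  expect_equal(mean(pt$truth$consensus), 0.16, tolerance = 0.01)
  two <- substr(pt$proteins$sequence, 2, 2)
  expect_true(all(two[pt$truth$consensus] %in% c("D", "E", "N")))
  expect_false(any(two[!pt$truth$consensus] %in% c("D", "E", "N")))
  expect_true(all(pt$truth$natb_substrate <= pt$truth$consensus))

  none <- generate_proteome(simulation_config(seed = 2, n_proteins = 50,
                                              fraction_natb_consensus = 0,
                                              n_natb_substrates = 0))
  expect_false(any(none$truth$consensus))
})

test_that("generated quant tables pass the io schema validation", {
  cfg <- simulation_config(seed = 6, n_proteins = 40, n_natb_substrates = 3,
                           n_phospho_sites = 30)
  pt <- generate_proteome(cfg)
  d <- withr::local_tempdir()
  qt <- generate_quant_tables(pt, cfg, dir = d)
  back <- read_quant_table(file.path(d, "quant_rep1.tsv"), 1L)
  expect_equal(back, qt$rep1, ignore_attr = TRUE)
  ph <- generate_phospho_table(pt, cfg, dir = d)
  back <- read_quant_table(file.path(d, "phospho_rep2.tsv"), 2L)
  expect_equal(back, ph$rep2, ignore_attr = TRUE)
})

test_that("null proteins have near-zero harmonized ratios, planted strong", {
  cfg <- simulation_config(seed = 9, n_proteins = 300, n_natb_substrates = 20)
  pt <- generate_proteome(cfg)
  qt <- generate_quant_tables(pt, cfg)
  q <- quantify_ratios(qt$rep1, qt$rep2)
  ac <- q$pairs[grepl("^ac", q$pairs$mod) & q$pairs$n_replicates == 2L, ]
  m <- merge(ac, pt$truth, by = "accession")
  sub <- m[m$natb_substrate, ]
  expect_true(all(abs(sub$mean_ratio - cfg$natb_effect_log2) < 2))
  expect_lt(abs(mean(sub$mean_ratio) - cfg$natb_effect_log2), 0.5)
  null_prot <- m[!m$natb_substrate & abs(m$protein_effect) < 0.1, ]
  bound <- 3 * cfg$noise_sd / sqrt(2) + 0.1
  expect_gt(mean(abs(null_prot$mean_ratio) <= bound), 0.95)
})

test_that("running a replicate with the wrong orientation negates its ratios", {
  cfg <- simulation_config(seed = 13, n_proteins = 30, n_natb_substrates = 2)
  pt <- generate_proteome(cfg)
  qt <- generate_quant_tables(pt, cfg)
  good <- log2_ko_wt_ratio(qt$rep2, label_orientation())
  flipped <- log2_ko_wt_ratio(qt$rep2, label_orientation("15N", "14N"))
  expect_equal(flipped$ratio, -good$ratio)
})

test_that("the phospho generator plants the configured up-fraction", {
  cfg <- simulation_config(seed = 21)
  pt <- generate_proteome(cfg)
  ph <- generate_phospho_table(pt, cfg)
  q <- quantify_ratios(ph$rep1, ph$rep2)
  frac_up <- mean(classify_fold_change(q$pairs) == "up")
  expect_gte(frac_up, 0.18)
  expect_lte(frac_up, 0.28)
  expect_true(all(ph$sites$kinase %in% names(cfg$kinases)))

  none <- generate_phospho_table(pt, simulation_config(seed = 21,
                                                       n_phospho_sites = 0))
  expect_equal(nrow(none$rep1), 0L)
  expect_equal(nrow(none$sites), 0L)
})
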