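test_that("frequency matrices hold per-position relative frequencies", {
  m <- frequency_matrix("MDSQP")
  expect_equal(m["pos1", "M"], 1.0)
  expect_equal(m["pos2", "D"], 1.0)

  m <- frequency_matrix(c("MDAAA", "MNAAA"))
  expect_equal(m["pos2", "D"], 0.5)
  expect_equal(m["pos2", "N"], 0.5)
  expect_equal(unname(rowSums(m)), rep(1, 5))

  # invariant under duplicating the whole sequence set
  expect_equal(frequency_matrix(rep(c("MDAAA", "MNAAA"), 3)), m)

  expect_error(frequency_matrix(character(0)), "no sequences")
  expect_error(frequency_matrix(c("MDSQP", "MDS")), "MDS")
})

test_that("the substrate-table 5-mers give the NatB logo structure", {
  t1 <- load_natb_substrate_table()
  m <- frequency_matrix(t1$sequence, k = 5)
  expect_equal(m["pos1", "M"], 1.0)
  support <- colnames(m)[m["pos2", ] > 0]
  expect_setequal(support, c("D", "E", "N"))
})

test_that("category contributions count multi-membership once per category", {
  ann <- data.frame(item = c(paste0("i", 1:3), "i1", "i4"),
                    category = c(rep("nucleus", 3), "cytoplasm", "cytoplasm"),
                    stringsAsFactors = FALSE)
  pct <- category_contributions(ann, paste0("i", 1:10))
  expect_equal(pct[["nucleus"]], 30)
  expect_equal(pct[["cytoplasm"]], 20)  # i1 counts in both categories

  pct <- category_contributions(ann, c("x1", "x2"))
  expect_true(all(pct == 0))
  expect_error(category_contributions(ann, character(0)), "empty")
})

test_that("chi-square matches the hand-computed Pearson oracle", {
  # fg: 30 of 100 in the category; bg: 10 of 100
  ann <- data.frame(
    item = c(paste0("f", 1:30), paste0("b", 1:10)),
    category = "kin", stringsAsFactors = FALSE)
  res <- normalized_enrichment(paste0("f", 1:100), paste0("b", 1:100), ann)
  expect_equal(res$normalized_contribution, 3.0)
  # oracle: sum((O - E)^2 / E) over the 2x2 table [[30,70],[10,90]]
  O <- c(30, 70, 10, 90)
  E <- c(40, 160, 40, 160) * 100 / 200
  chi2_oracle <- sum((O - E)^2 / E)
  expect_equal(res$chi2, chi2_oracle)
  expect_equal(chi2_oracle, 12.5)
  expect_equal(res$p, pchisq(12.5, df = 1, lower.tail = FALSE))
  expect_gte(res$p_corrected, res$p)
})

test_that("identical foreground and background composition is null", {
  ann <- data.frame(item = c(paste0("f", 1:5), paste0("b", 1:5)),
                    category = rep(c("k1", "k1", "k1", "k2", "k2"), 2),
                    stringsAsFactors = FALSE)
  res <- normalized_enrichment(paste0("f", 1:10), paste0("b", 1:10), ann)
  expect_equal(res$normalized_contribution, c(1, 1))
  expect_equal(res$chi2, c(0, 0))
  expect_equal(res$p, c(1, 1))
})

test_that("swapping foreground and background keeps the statistic", {
  ann <- data.frame(item = c(paste0("f", 1:30), paste0("b", 1:10)),
                    category = "kin", stringsAsFactors = FALSE)
  fwd <- normalized_enrichment(paste0("f", 1:100), paste0("b", 1:100), ann)
  swp <- normalized_enrichment(paste0("b", 1:100), paste0("f", 1:100), ann)
  expect_equal(swp$chi2, fwd$chi2)
  expect_equal(swp$normalized_contribution, 1 / fwd$normalized_contribution)
})

test_that("categories without background members are omitted with a warning", {
  ann <- data.frame(item = c("f1", "f2", "b1"),
                    category = c("only_fg", "shared", "shared"),
                    stringsAsFactors = FALSE)
  expect_warning(res <- normalized_enrichment(c("f1", "f2"), c("b1", "b2"),
                                              ann),
                 "only_fg")
  expect_equal(res$category, "shared")
  expect_error(normalized_enrichment(c("a"), c("a", "b"), ann), "disjoint")
})

test_that("a planted 5x-enriched kinase is recovered top-ranked", {
  cfg <- simulation_config(seed = 23)
  pt <- generate_proteome(cfg)
  ph <- generate_phospho_table(pt, cfg)
  q <- quantify_ratios(ph$rep1, ph$rep2)
  m <- merge(q$pairs, ph$sites, by = "accession")
  cls <- classify_fold_change(m$mean_ratio)
  ann <- data.frame(item = ph$sites$site_id, category = ph$sites$kinase,
                    stringsAsFactors = FALSE)
  res <- normalized_enrichment(m$site_id[cls == "up"],
                               m$site_id[cls == "unchanged"], ann)
  expect_equal(res$category[1], "SNF1")
  expect_lt(res$p_corrected[1], 0.05)
})

test_that("localization profiling treats detected proteins as background", {
  ann <- data.frame(item = paste0("p", 1:10),
                    category = rep(c("bud", "cytoplasm"), 5),
                    stringsAsFactors = FALSE)
  # elevated set == detected set: all ratios 1, nothing significant
  res <- localization_profile(paste0("p", 1:10), paste0("p", 1:10), ann)
  expect_equal(res$normalized_contribution, c(1, 1))
  expect_equal(res$chi2, c(0, 0))

  # unannotated proteins are excluded from numerator and denominator
  res2 <- localization_profile(c(paste0("p", 1:10), "noann"),
                               c(paste0("p", 1:10), "noann"), ann)
  expect_equal(res2$fg_percent, res$fg_percent)
  expect_error(localization_profile("zz", paste0("p", 1:10), ann),
               "detected")
})

test_that("a planted bud-enriched phospho set ranks bud on top", {
  cfg <- simulation_config(seed = 31)
  pt <- generate_proteome(cfg)
  ph <- generate_phospho_table(pt, cfg)
  ann <- data.frame(item = ph$sites$accession,
                    category = ph$sites$localization,
                    stringsAsFactors = FALSE)
  elevated <- ph$sites$accession[ph$sites$class == "up"]
  res <- localization_profile(elevated, ph$sites$accession, ann)
  expect_equal(res$category[1], "bud")
  expect_lt(res$normalized_contribution[nrow(res)], 1)  # cytoplasm depleted
})

test_that("null category assignment yields ~5% raw-p false positives", {
  set.seed(88)
  hits <- 0L
  total <- 0L
  for (i in 1:25) {
    n_fg <- 200; n_bg <- 800
    items <- paste0("s", 1:(n_fg + n_bg))
    ann <- data.frame(item = items,
                      category = sample(paste0("k", 1:8), n_fg + n_bg,
                                        replace = TRUE),
                      stringsAsFactors = FALSE)
    res <- normalized_enrichment(items[1:n_fg], items[-(1:n_fg)], ann)
    hits <- hits + sum(res$p < 0.05)
    total <- total + nrow(res)
  }
  expect_gte(hits / total, 0.01)
  expect_lte(hits / total, 0.10)
})
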