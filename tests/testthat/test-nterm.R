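test_that("fully-specific digestion follows the protease rules", {
  d <- digest("MDKRAAK", "trypsin", "full", missed_cleavages = 0L)
  expect_equal(d$peptide, c("MDK", "R", "AAK"))
  expect_equal(d$start, c(1L, 4L, 5L))

  d <- digest("MKAK", "lysn", "full", missed_cleavages = 0L)
  expect_equal(d$peptide, c("M", "KA", "K"))
  expect_equal(d$start, c(1L, 2L, 4L))

  # trypsin does not cleave K|P by default, but can be told to
  expect_equal(digest("AKPR", "trypsin", "full", 0L)$peptide, c("AKPR"))
  expect_equal(digest("AKPR", "trypsin", "full", 0L,
                      no_cleave_before_proline = FALSE)$peptide,
               c("AK", "PR"))
  expect_error(digest("", "trypsin"), "empty")
})

test_that("semi-specific output contains the fully-specific output", {
  for (seq in c("MDKRAAK", "MKAK", "MDSQPVDVDNIIDRLLEVR")) {
    for (enz in c("trypsin", "lysn")) {
      full <- digest_keys(seq, enz, "full", 1L)
      semi <- digest_keys(seq, enz, "semi", 1L)
      expect_true(all(full %in% semi))
    }
  }
})

test_that("digestion equals the brute-force enumeration oracle", {
  set.seed(1913)
  for (i in 1:40) {
    seq <- random_protein()
    enz <- sample(c("trypsin", "lysn"), 1)
    spec <- sample(c("full", "semi"), 1)
    mc <- sample(0:1, 1)
    expect_equal(digest_keys(seq, enz, spec, mc),
                 oracle_digest(seq, enz, spec, mc),
                 info = paste(seq, enz, spec, mc))
  }
})

test_that("every digestion product maps back to its reported start", {
  set.seed(7)
  for (i in 1:10) {
    seq <- random_protein()
    d <- digest(seq, "trypsin", "semi", 1L)
    ok <- mapply(function(p, s) s %in% map_peptide(p, seq), d$peptide, d$start)
    expect_true(all(ok))
  }
})

test_that("peptide mapping reports all overlapping match positions", {
  glc7 <- "MDSQPVDVDNIIDRLLEVR"
  expect_equal(map_peptide("MDSQP", glc7), 1L)
  expect_equal(map_peptide("AA", "AAAA"), c(1L, 2L, 3L))
  expect_equal(map_peptide("WWW", glc7), integer(0))
})

test_that("NatB consensus is exactly MD, ME, MN", {
  expect_true(all(natb_consensus(c("MD", "ME", "MN"))))
  expect_false(any(natb_consensus(c("MA", "MQ", "DM", "AD"))))
  expect_error(natb_consensus("MDS"), "length-2")
})

test_that("N-terminal events classify by position and Nat consensus", {
  glc7 <- "MDSQPVDVDNIIDRLLEVR"
  ev <- classify_event(glc7, 1L, accession = "YER133W")
  expect_equal(ev$position_class, "position1")
  expect_equal(ev$nat_class, "NatB")
  expect_true(ev$alt_start_candidate)

  # internal terminus whose local sequence is a NatB-style alternative start
  sti1 <- paste0(strrep("A", 197), "MDDINAAK")
  ev <- classify_event(sti1, 198L)
  expect_equal(ev$position_class, "internal")
  expect_true(ev$alt_start_candidate)
  expect_equal(ev$nat_class, "other")

  ev <- classify_event("MSATVLLK", 2L)
  expect_equal(ev$position_class, "position2")
  expect_equal(ev$nat_class, "NatA-type")

  expect_equal(classify_event("MILVK", 1L)$nat_class, "NatC-type")
  expect_error(classify_event("MDSQP", 9L), "outside")
})

test_that("position classes partition all starts and NatB implies position 1", {
  seq <- "MDAMSATVKLLDK"
  for (s in seq_len(nchar(seq))) {
    ev <- classify_event(seq, s)
    expected <- if (s == 1L) "position1" else if (s == 2L) "position2"
    else "internal"
    expect_equal(ev$position_class, expected)
    if (ev$nat_class == "NatB") expect_equal(s, 1L)
  }
})

test_that("initiator Met cleavage follows the small-residue rule", {
  expect_equal(met_cleavage_variants("MSATVK"), c(1L, 2L))
  expect_equal(met_cleavage_variants("MDSQPK"), 1L)  # NatB substrates keep Met
  expect_equal(met_cleavage_variants("M"), 1L)
  expect_equal(met_cleavage_variants("DSATVK"), 1L)
})

test_that("theoretical observability uses the peptide-length window", {
  one <- data.frame(accession = "P1", sequence = "MDAAAAAAK",
                    stringsAsFactors = FALSE)
  obs <- theoretical_observability(one)
  expect_true(obs$per_protein$observable)
  expect_true(obs$per_protein$natb_consensus)
  expect_equal(obs$summary$fraction_natb, 1.0)

  # trypsin N-terminal peptides MDK/MDKR are both too short, but Lys-N with
  # one missed cleavage yields MDKRAAAA (length 8): observable by hand
  hard <- data.frame(accession = "P2", sequence = "MDKRAAAAK",
                     stringsAsFactors = FALSE)
  expect_true(theoretical_observability(hard)$per_protein$observable)

  # all N-terminal peptides below the window
  tiny <- data.frame(accession = "P3", sequence = "MKRK",
                     stringsAsFactors = FALSE)
  expect_false(theoretical_observability(tiny)$per_protein$observable)

  expect_error(theoretical_observability(one, min_len = 10, max_len = 5),
               "min_len")
})

test_that("the NatB-consensus fraction is invariant under duplication", {
  prot <- data.frame(accession = c("A", "B", "C"),
                     sequence = c("MDAAAAAAK", "MSAAAAAAK", "MNLLLLLLK"),
                     stringsAsFactors = FALSE)
  dup <- prot
  dup$accession <- paste0(dup$accession, "dup")
  f1 <- theoretical_observability(prot)$summary$fraction_natb
  f2 <- theoretical_observability(rbind(prot, dup))$summary$fraction_natb
  expect_equal(f1, f2)
})

test_that("acetylated peptides become classified events via mapping", {
  prot <- data.frame(
    accession = c("YER133W", "REP"),
    sequence = c("MDSQPVDVDNIIDRLLEVR", "AAAAAAAA"),
    stringsAsFactors = FALSE)
  peps <- rbind(
    quant_row("MDSQPVDVDNIIDR", "YER133W", start = NA, acetyl = TRUE),
    quant_row("AAA", "REP", start = NA, acetyl = TRUE),   # ambiguous
    quant_row("LLDVK", "YER133W", start = NA, acetyl = FALSE))
  expect_warning(ev <- nterm_events(peps, prot), "ambiguous")
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$accession, "YER133W")
  expect_equal(ev$start, 1L)
  expect_equal(ev$first_five, "MDSQP")
  expect_equal(ev$nat_class, "NatB")
})
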