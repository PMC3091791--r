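---
title: "Identifying NatB substrates from label-swap 15N proteomics: methods and design"
author: "ntaq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying NatB substrates from label-swap 15N proteomics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The experimental design being analysed

A wild-type yeast strain and a strain deleted for the catalytic subunit of
the NatB N-acetyltransferase complex are grown on light (¹⁴N) and heavy
(¹⁵N) nitrogen, mixed 1:1, digested with trypsin or Lys-N, and analysed by
LC-MS/MS. Because metabolic labeling makes every peptide of one strain
uniformly heavy, the MS¹ intensity ratio of the ¹⁴N and ¹⁵N isotope
envelopes of a peptide measures its relative abundance in the two strains.
Two biological replicates are run with *reversed* label assignment (the
label swap), so any label-specific bias flips sign between replicates
while true biology does not.

NatB acetylates the initiator methionine when the penultimate residue is
D, E or N. In the deletion strain the acetylated form of a true substrate's
N-terminal peptide essentially vanishes, so its log₂(KO/WT) ratio is
strongly negative in both replicates, while the protein's unmodified
peptides stay near zero. That double signature — consensus sequence plus
replicated drastic down-regulation of the *acetylated* N-terminal peptide —
is what the substrate caller tests.

## Ratio quantification and the replicate band

Per replicate, `log2_ko_wt_ratio()` computes `log2(I_KO / I_WT)` with the
channel assignment taken from a `label_orientation()` object; both
replicates are thereby harmonized to the same KO/WT scale (negative =
lower in the knockout), which also reproduces the sign convention of the
packaged substrate table. A missing or zero channel makes a row
unquantifiable: it is excluded from ratio work but kept for
identification-level outputs, and missingness is kept distinct from an
actual zero intensity throughout the I/O layer.

Identification-score filtering keeps unmodified and acetylated peptides at
score ≥ 30 and phosphopeptides at score ≥ 25. The sources describing the
design use "above 30" for one filter and "a minimum score of 25" for the
other; we apply `>=` uniformly — at integer-valued scores the difference
is a single boundary value, and a uniform convention is easier to reason
about and to configure.

Replicate agreement is summarised on the inter-replicate difference
`d = r1 − r2` of peptides quantified in both replicates. The 95% band is
`±1.96·SD(d)`. Two estimators are offered:

* `method = "mad"` (default): `1.4826 × MAD(d)`. The population of pairs
  mixes a large null bulk with genuinely regulated peptides whose `d` has
  the same spread but whose presence fattens the tails; the MAD ignores
  them.
* `method = "sd"`: the plain sample SD, for comparability with the
  textbook calculation.

A pair is *consistent* when `|d| ≤ 1.96·SD`. On a pure-noise simulation
the flagged fraction sits at the nominal ~5%, which is exactly what the
test suite and acceptance script verify. At least 20 complete pairs are
required before a band is fitted; fewer is an error rather than a silent,
unstable estimate.

Two averaging decisions are deliberately simple. Replicate ratios are
averaged unweighted (whether the original analysis weighted by intensity
is unstated; an unweighted mean is unbiased under the generator's noise
model and keeps the estimator transparent). Protein-level ratios are the
unweighted mean of the protein's consistent unmodified peptide pairs, and
a protein whose only pairs are inconsistent is dropped rather than
reported from outlier data.

Peptides quantified in a single replicate are retained with
`n_replicates = 1`: they are excluded from band fitting and, by default,
from substrate calling, but remain available for descriptive outputs.

## Digestion, terminus mapping and classification

`digest()` implements trypsin (cleaves C-terminal to K/R) and Lys-N
(cleaves N-terminal to K). The common "no cleavage before proline" rule
for trypsin is applied by default but can be switched off — it is a
property of the enzyme widely used by search engines, not something the
analysis depends on. Fully-specific digestion enumerates fragments between
cleavage boundaries with at most the configured number of internal missed
sites (default 1); semi-specific digestion adds every prefix and suffix of
each fully-specific peptide, which is how acetylated termini at
non-annotated positions become identifiable. The engine is verified
against a brute-force enumeration oracle that classifies every substring
of random sequences directly from the cleavage rules.

Classification of an acetylated terminus at protein position `s`:

* `position1` (`s = 1`), `position2` (`s = 2`), `internal` (`s ≥ 3`). The
  internal boundary at 3 follows the convention that positions 1 and 2 are
  the two co-translational possibilities (Met retained or Met removed);
  position 2 remains "NatA territory" even when its residue is not a
  canonical NatA residue (such events classify as `other`).
* Nat classes from the canonical motifs: NatB = M followed by D/E/N at
  position 1; NatA-type = S/A/T/V/G exposed at position 2; NatC-type = M
  followed by I/L/W/F at position 1. One source sentence describes NatB
  specificity as D/E/Q at the penultimate position; the observed consensus
  in the data this package models is unambiguously MD/ME/MN, and that is
  what `natb_consensus()` implements.
* An event is an alternative-start candidate when its residue is Met or is
  preceded by Met — the situation in which an internal acetylated terminus
  plausibly marks an alternative translation start.

Peptides are placed on proteins by exact substring match
(`map_peptide()`, overlapping matches included). A peptide that places
ambiguously is skipped for event building with a warning: substrate calls
should rest on unambiguous coordinates, mirroring the one-start-per-row
structure of the packaged substrate table.

`met_cleavage_variants()` uses the standard Met-aminopeptidase rule: the
initiator Met can be removed when the penultimate residue is one of the
seven small residues A/C/G/P/S/T/V. The sources state the dependence but
not the set; the MAP rule is the field's default.

`theoretical_observability()` asks, per protein, whether any
fully-specific N-terminal peptide (either protease, ≤ 1 missed cleavage,
from the annotated start or the Met-cleaved start where allowed) falls in
the 5–45-residue window that the instrumentation can measure. On
yeast-like synthetic proteomes ~16% of observable N-termini carry the NatB
consensus, the fraction the generator is parameterised to.

## Substrate calling

`call_natb_substrates()` joins acetylated events to their ratio pairs and
calls a substrate when the first two residues at the event position
satisfy the consensus *and* the mean ratio is ≤ −log₂(fold) (default
fold = 3) with both replicates quantified. Internal consensus events are
eligible and flagged via `position_class`/`alt_start_candidate`.

Two deliberate choices:

* The 95% consistency band is **not** used to veto calls by default. The
  band is fitted to the mostly-null bulk, so a genuinely regulated peptide
  has the same ~5% chance of falling outside it as any other pair;
  vetoing on it would systematically discard true substrates while adding
  little specificity (the fold threshold and replicate requirement already
  do that work). `require_consistent = TRUE` restores the stricter
  behaviour.
* Consensus events above the fold cut are reported in a `consensus-only`
  tier rather than dropped, so a full report resembling the packaged
  substrate table (which contains rows above the three-fold cut) can be
  produced while the headline count uses the threshold tier only. Reports
  are ordered by mean ratio ascending, ties by accession.

## Enrichment statistics

`frequency_matrix()` computes per-position residue frequencies over the
first *k* residues (default 5), the numeric content of a sequence logo.

`normalized_enrichment()` implements the study's effect size — the
*normalized contribution* `fg% / bg%` of a category — plus a Pearson
chi-square test (1 df) on the 2×2 table `[[fg_in, fg_out], [bg_in,
bg_out]]`. Numerical/statistical choices:

* No Yates continuity correction by default: the statistic is named and
  computed as Pearson's; the correction is available via `continuity`.
* Multiple-testing correction is Bonferroni over the tested categories —
  conservative and appropriate when the emphasis lands on a single
  top-ranked hypothesis; Benjamini–Hochberg is available via `correction`.
* A category with no background members has an undefined ratio and is
  omitted with a warning, never reported as infinite. Categories with any
  expected cell below 5 are flagged `low_count` rather than suppressed.
* Items annotated to several categories (multi-localized proteins,
  phospho-sites with several predicted kinases) count once per category.

`localization_profile()` runs the same machinery in the nested design used
for localization: background = all detected proteins, foreground a subset
of it, unannotated proteins excluded from both sides.

## Conservation scoring

Two units of counting, matching the two questions asked of ortholog
groups:

* `species_conservation()` (per species): percentage of *sequences* whose
  first two residues are MD/ME/MN, pooled across all groups by default.
  In-paralogs count individually — each sequence is an independent
  observation of that species' N-terminal usage. A per-group-then-average
  alternative (`method = "group_mean"`) is available.
* `protein_conservation()` (per group): percentage of *species* with at
  least one motif-bearing member — a species either conserves the motif
  for that protein or it does not, so in-paralogs collapse to any-member.

`top_conserved()` ranks groups by the latter (ties broken
lexicographically by accession — deterministic and convention-free) and
re-scores the top *k* per species. Ortholog sequences are used exactly as
given; no Met-cleavage preprocessing is applied to them, since the
annotation state of downloaded ortholog sequences is heterogeneous and
second-guessing it would be invisible to the user.

## What the synthetic generator emulates — and what it does not

`simulation_config()` pins the study conditions; the generators are
deterministic given `seed`. Key defaults, with the reasoning:

| parameter | default | why |
|---|---|---|
| `n_proteins` | 4000 | the scale of theoretically observable yeast N-termini |
| `fraction_natb_consensus` | 0.16 | share of observable termini with MD/ME/MN |
| `n_natb_substrates` | 60 | detected-substrate scale of the modelled study |
| `natb_effect_log2` | −5 | drastic loss of the acetylated form in the knockout |
| `protein_effect_sd` | 0.3 (log₂) | protein levels barely move |
| `noise_sd` | 0.5 (log₂, per replicate ratio) | reproduces a ±1.4 log₂ replicate band |
| `fraction_acetylated` | 0.19 | detected acetylated termini per observable terminus |
| `abundance_meanlog/sdlog` | log(10⁶)/1.5 | heavy-tailed dynamic range of shotgun data |
| `detection_floor` | 300 (intensity units) | dropout produces singleton-replicate peptides |
| `n_phospho_sites` | 2300 | quantified phospho-site scale |
| `fraction_phospho_up` | 0.23, effect +2.5 | elevated-phosphorylation phenotype |
| `kinase_multipliers` | SNF1 × 5 | one kinase drives the elevated sites |
| `localization_multipliers` | bud × 3, cytoplasm × 0.5 | bud-enriched, cytoplasm-depleted up-set |
| ortholog survey | 59 groups × 52 species, 5 planted | conservation-analysis dimensions |

Mechanics: per-protein base abundance is log-normal with a wide sdlog
(heavy tail); each channel observation multiplies in log-normal noise of
log₂-SD `noise_sd/√2`, so a single-replicate ratio has SD `noise_sd` and
the two-replicate mean SD `noise_sd/√2`; replicate 2 swaps the channel
assignment; intensities below the detection floor become missing. Planted
effects act on the log₂ scale directly, on the acetylated N-terminal
peptide for substrates and on all peptides for protein-level effects.

The generator intentionally does **not** emulate: chromatographic
separation and co-elution, isotope-envelope overlap or ¹⁵N incorporation
efficiency, peptide-level identification error (scores are drawn
independently of intensity), shared peptides between homologous proteins,
partial acetylation stoichiometry, or multiple phospho-sites per protein
(each synthetic site lives on its own protein, which keeps site- and
protein-level annotations trivially consistent). Passing recovery tests on
this generator therefore demonstrates that the *statistical pipeline* is
correct and calibrated under the stated noise model — not that it is
robust to every artefact of real spectra; those upstream artefacts are the
responsibility of the search engine and quantification software whose
exports this package consumes.

Problem sizes used by the test suite and acceptance script — the full
4,000-protein study for recovery, 5,000 pairs for band calibration, 200
random proteins for the digestion oracle, ten simulated studies for the
null enrichment calibration — were chosen as the smallest sizes at which
the binomial/selection noise of each check is comfortably below the
thresholds being asserted.

## Degenerate inputs and numerical conventions

* Coordinates are 1-based inclusive everywhere; position 1 is the
  annotated initiator Met.
* `fit_confidence_band()` on identical replicates returns halfwidth 0 and
  flags everything consistent (a valid degenerate band).
* `classify_fold_change()` uses closed boundaries (`≥ log2(fold)` /
  `≤ −log2(fold)`), so a ratio exactly at the threshold is called
  regulated, symmetrically on both sides.
* Frequency matrices error on empty input and on sequences shorter than
  `k`, naming the offending sequence.
* Duplicate FASTA accessions, negative intensities (with row number),
  unknown quant-table columns (with the accepted schema) and phospho
  positions outside their peptide are all hard errors at read time:
  malformed input should fail loudly before statistics are computed.

## Known limitations

* Substrate calling keys on exact peptide placement; proteins whose
  N-terminal peptide is shared verbatim with another database entry
  (recent paralogs) are skipped as ambiguous rather than resolved by
  protein-inference heuristics.
* The chi-square machinery is applied uniformly to kinase and
  localization enrichment; small categories are flagged, not switched to
  an exact test.
* The packaged substrate table records one peptide form per protein row;
  peptide-form multiplicity (e.g. missed-cleavage variants of the same
  terminus) is not recoverable from it.
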