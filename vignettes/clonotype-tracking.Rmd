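---
title: "Tracking vaccine-enriched TCR clonotypes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking vaccine-enriched TCR clonotypes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonotrace)
```

## The problem

Therapeutic cancer vaccines aim to raise T cell clones against tumor
antigens, but the clones they induce are rare in blood and hard to tell
apart from the bystander repertoire. A practical detection strategy is to
sequence the TRB repertoire of a patient's PBMCs before and after a 10-day
in vitro expansion with the vaccine peptides: clones that respond to the
peptides proliferate and become dramatically over-represented in the
stimulated aliquot. Clonotypes significantly enriched by stimulation — and
absent from the pre-treatment baseline — are candidate vaccine-induced
clones, which can then be looked up in later unstimulated blood samples and
in tumor biopsies to ask whether the vaccine response persists and traffics
to the tumor. In parallel, a classical lymphocyte proliferation assay
(3H-thymidine incorporation) provides a per-patient functional readout, the
stimulation index, from which cohort-level immune-response rates are
called.

`clonotrace` implements this pipeline end to end on clone-level repertoire
tables, together with a synthetic-data generator that provides ground truth
for every stage.

## Clone identity and input handling

A clone (clonotype) is the set of receptor reads sharing one CDR3
amino-acid sequence. V/J gene calls are carried as annotation only and are
blanked when merged rows disagree; they never enter clone identity. This
is deliberately permissive — two rearrangements with different V genes but
the same CDR3 amino-acid sequence are counted as one clone — because it
makes clone keys directly comparable across samples and platforms.

Input is AIRR-style rearrangement TSV (default columns `junction_aa`,
`v_call`, `j_call`, `duplicate_count`, remappable via `airr_columns()`).
Rows with an empty CDR3 or non-positive count are skipped and tallied; rows
whose CDR3 contains ambiguity letters (B, J, O, U, X, Z) are skipped with a
warning, since an ambiguous clone cannot be matched across samples.
Stop-codon-containing (non-productive) CDR3s are retained by default — they
still mark a clone lineage — and `read_repertoire(productive_only = TRUE)`
drops them. Read-extraction QC (`qc_extraction()`) flags samples at or
below 95% extraction but never excludes them; low-extraction samples stay
in the analysis.

## Depth normalization by downsampling

Sequencing depth differs across samples, and every count-based statistic
downstream is depth-sensitive. All cross-sample comparisons therefore
first downsample every repertoire in the compared set to the set's minimum
depth (`common_depth()`), drawing reads without replacement from the
sample's read multiset — a multivariate hypergeometric draw, realized by
sequential conditional `rhyper()` draws. Sampling without replacement
preserves count integerness, can never inflate a clone, and reproduces the
hypergeometric expectation for every clone (verified against the
closed-form mean in the test suite). Every draw is seeded and reproducible.

## Diversity and clonality

On depth-matched repertoires the package reports:

* **richness** — number of unique clonotypes, the primary diversity
  readout (least-assumption choice once depths are matched);
* **Shannon entropy** `H = -Σ p_i ln p_i` in nats;
* **clonality** `1 - H / ln R`, the standard immunosequencing
  normalization: 0 for a perfectly even repertoire, 1 for a monoclonal one
  (the single-clone repertoire is defined as clonality 1).

Because "diversity" is an overloaded term, both richness and entropy are
always emitted so either comparison can be reproduced. Overlap analysis
(`overlap()`) partitions clone keys into shared and compartment-unique
sets, and `repertoire_fraction()` implements the summed-normalized-count
fraction: the summed read count of a clone set divided by the sample's
total, so fractions over a partition of all keys sum to exactly 1.

## The enrichment test

After depth matching, each clone present in either member of a sample pair
is tested with a two-sided Fisher exact test on its 2×2 clone-vs-rest
table (clone reads vs all other reads, reference vs comparison sample).
Conditional on the clone's total read count the alt-sample count is
hypergeometric, and the two-sided p-value follows the minimum-likelihood
convention — the sum of probabilities of all tables no more probable than
the observed one, with the customary 1e-7 relative guard on the equality
comparison. The implementation enumerates the hypergeometric support once
per distinct clone total, so a full repertoire pair (thousands of clones)
tests in well under a second.

This exact conditional test was chosen as the in-repo statistic because
depth-matched integer counts make it the assumption-free option: there is
no dispersion to estimate across a single pair of samples, and a
negative-binomial exact test reduces toward this conditional test as
dispersion vanishes. Empirically the test is conservative on discrete
counts: under the null (two seeded draws from one clone distribution) the
fraction of clones with p < 0.05 is about 0.01, versus the nominal 0.05.

Fold changes are `log2((count_alt + 0.5) / (count_ref + 0.5))`; the 0.5
pseudocount defines the statistic for clones absent from one sample, and
log base 2 is the differential-abundance convention. Multiple testing is
Benjamini–Hochberg over all clones tested in the pair, with no independent
filtering. Clones are tiered per the volcano-plot convention: *nominal*
for log2 fold change above 5 with unadjusted p < 0.05, *significant* when
additionally the BH-adjusted p < 0.05; the significant set is by
construction nested in the nominal set.

Finally, `filter_baseline()` removes every enriched clone already present
(any count ≥ 1) in the patient's pre-treatment unstimulated sample: such a
clone existed before vaccination and cannot be attributed to it.

## Tracking and intratumoral dynamics

`track_clones()` follows the vaccine-enriched keys across a patient's
samples, depth-matching within each compartment, and reports per-sample
counts and repertoire fractions plus a per-clone tumor-detection flag.
"Detected" means count ≥ 1 after depth matching — the most permissive
reading, adopted because no detection threshold beyond presence is
defensible at these depths. Output ordering is canonical (rank, then
compartment, then timepoint), so results do not depend on the order
samples are supplied.

`persisting_abundance()` compares normalized counts of clones shared
between baseline and post-treatment tumor biopsies with a paired two-sided
Wilcoxon signed-rank test (exact null up to 25 shared clones; fewer than 2
shared clones skips the test with a flag; an all-zero difference vector is
flagged degenerate with p = 1). The signed-rank test was chosen because
the paired clone counts are heavily non-normal and the question is a shift
in matched pairs. `post_unique_in_blood()` takes the clones unique to the
post-treatment biopsy and reports, per PBMC timepoint, how many are
detected in blood and their summed repertoire fraction; PBMC samples are
depth-matched across timepoints first, and the depth used is recorded in
the output.

## The stimulation-index caller

The stimulation index of a triplicate proliferation assay is the mean
count in peptide-stimulated wells divided by the mean count in
unstimulated wells; it is dimensionless and scale-invariant. A zero
unstimulated mean flags the assay invalid rather than producing an
infinite SI. A patient is immune-response positive when any peptide (or
the mix) reaches **SI ≥ 3** — the threshold is inclusive — in any
post-baseline assay within the evaluation window; a patient with no
evaluable post-baseline assay is non-evaluable, which is distinct from a
non-responder and excluded from the cohort denominator. The alternative
reading, a three-fold rise over the patient's own baseline SI, is exposed
as `call_response(relative_to_baseline = TRUE)` but is not the default.

## The synthetic-data generator

`simulate_patient()` generates, from one master seed, the full sample set
the pipeline expects: baseline PBMC, week-7 PBMC before and after in vitro
stimulation, a later PBMC sample, and baseline/post-treatment tumor
biopsies, with a ground-truth table of the planted vaccine clones. Its
defaults are the conditions under which the package's claims are tested:

| parameter | default | rationale |
|---|---|---|
| `n_clones` | 5000 | clones per blood sample |
| `depth` | 50000 | reads per sample |
| `zipf_exponent` | 1 | clone frequencies ∝ rank^-1, the standard null for clone-size distributions |
| `persistence` | 0.3 | most clonotypes turn over between serial samples |
| `tumor_share` | 0.1 | modest blood–tumor clonotype sharing |
| `n_spike` | 10 | vaccine-reactive clones per patient |
| `spike_fold` | 64 | stimulation expansion (log2 fold 6, above the tier threshold of 5) |
| `spike_freq_range` | 1e-3 … 5e-5 | spikes span well-detected to near the detection limit at the default depth |
| `si_true` | 11.5 | cohort-median stimulation index |
| `noise_cv` | 0.1 | replicate count coefficient of variation |

Spiked clones are absent from baseline by construction, so the
enrichment-then-baseline-filter path has known positives;
`leak_to_baseline = TRUE` deliberately plants them at baseline to verify
the filter removes 100% of them. Stimulated frequencies are the spiked
frequencies times `spike_fold`, renormalized — so the realized fold is
slightly below the nominal fold (recorded per clone in the ground-truth
table), exactly as real stimulation compresses the rest of the repertoire.
Counts are multinomial at the configured depth; proliferation replicates
are log-normal with the configured CV, so `noise_cv = 0` recovers the true
SI exactly.

What the generator does **not** emulate: sequence-level reads and PCR or
sequencing error (clone tables are taken as given, as from an upstream
extraction platform), V(D)J recombination statistics, cross-patient clone
sharing, and clock-time expansion kinetics between timepoints. Passing
tests on synthetic data therefore demonstrate the statistical machinery —
normalization, testing, filtering, tracking, calling — under a realistic
clone-size law, not robustness to upstream extraction artifacts.

## Numerical choices and degenerate inputs

* Ties in output ordering break lexicographically by CDR3 (file rows,
  enrichment ranks), making every artifact byte-deterministic for a seed.
* All randomness (downsampling, simulation) flows through per-call integer
  seeds; the caller's RNG state is saved and restored.
* Clonality of a single-clone repertoire is 1 by convention; entropy of a
  single-clone repertoire is 0; empty repertoires are domain errors for
  all metrics.
* The Fisher p-value is clamped to at most 1; a clone total of 0 gives
  p = 1.
* Problem sizes in the test suite: the exhaustive Fisher-vs-enumeration
  sweep covers all equal-depth tables up to 25 reads per arm plus 4000
  random tables with margins up to 200; null and spike-in simulations use
  20 seeded replicates at depth 50000 with 5000 clones; assay recovery
  uses 100 seeded replicates.

## Known limitations

* Clone identity by CDR3 amino-acid sequence alone can merge distinct
  rearrangements (convergent recombination); this is intrinsic to the
  chosen identity rule.
* The exact test treats reads as independent draws; PCR duplication
  violates this upstream of the clone table and would make p-values
  anti-conservative on poorly deduplicated data.
* Single-pair testing has no dispersion estimate; biological replicate
  variability beyond counting noise is not modeled.
* Depth matching discards reads; with very unequal depths the shallower
  sample dictates sensitivity, and detection ("count ≥ 1") probabilities
  change accordingly.
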