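---
title: "Presence calling and differential secretion signatures for neuropeptidomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Presence calling and differential secretion signatures for neuropeptidomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuropepsig)
```

## The analysis model

Secreted neuropeptidomics asks a presence question before a quantity
question. An identification engine (PEAKS-style) reports, per technical
injection, which peptide features it identified and with what XIC
area, feature quality, retention time and precursor m/z. Individual
injections are noisy: features drop out, spurious identifications
occur, and abundances vary log-normally. The analysis therefore
declares a peptide *present* only when detections are consistent across
the nested experimental design:

* **culture level** — detected in at least 1 of 2 technical
  injections (distinct injections, not spectral counts);
* **subject level** — present in at least 2 of 3 culture replicates;
* **group level** — present in at least 5 of 7 SZ subjects, or 4 of 6
  healthy-control subjects.

All thresholds live in `study_design()` and are configurable; the
defaults are the study's. Everything downstream — Venn partitions of
group-unique versus shared peptides per condition, KCl-versus-basal
partitions per group, per-precursor tallies, coverage maps — is exact
set algebra over these boolean calls (`signature_report()`), so the
statistical subtlety is concentrated in the calling rule, not in the
summaries.

## Filters and their boundaries

`filter_config()` holds the observation-level gates:

| parameter | default | unit | behaviour |
|---|---|---|---|
| `min_abundance` | 1e4 | XIC area (arbitrary) | strict `>` |
| `min_quality` | 0.3 | unitless | strict `>` |
| `rt_tolerance_min` | 3.0 | minutes | span `<=` within feature group |
| `ms1_ppm_tol` | 20 | ppm | deviation from group median m/z |
| `fdr_max` | 0.003 | proportion | target-decoy bound |

Abundance and quality cuts are strict inequalities: a feature at
exactly 1×10⁴ or 0.30 is rejected. The reliability gate groups
observations by peptide identity within subject × condition × culture
and keeps the largest subset whose retention times span at most 3 min
and whose m/z values sit within 20 ppm of the subset median; ties are
broken by total abundance, then earliest RT (the tolerance is given by
the method; the subset-selection rule is this package's choice and is
deliberately deterministic). Peak-height and isotope-pattern
consistency, which engines use internally, have no published numeric
thresholds and are represented only by the ppm gate.

The target-decoy FDR filter is a standard score-cutoff scan (retain
targets at the smallest cutoff with #decoys/#targets ≤ `fdr_max`,
decoys always removed). Real engine exports arrive already
FDR-filtered, so the gate defaults to off in `run_pipeline()`; the
synthetic generator labels decoys so the gate can be exercised
end-to-end.

## Precursor mapping conventions

Peptides are anchored by exhaustive substring search over all
precursors (`map_peptide()`), coordinates 1-based inclusive over the
*full* precursor sequence, signal peptide included — the convention
that reproduces printed spans such as CHGB 588–596. Users supplying
mature-chain FASTA should expect shifted offsets. Isoleucine and
leucine are kept distinct (engines report sequences; collapsing them
would manufacture ambiguity). The supported PTMs are all mass-only
with respect to residue letters — oxidation, N-terminal acetylation,
amidation, and pyro-glutamate (which forms from the encoded Q/E) — so
`normalize_for_matching()` validates them but never rewrites the
backbone, and mapping is invariant under them (property-tested).
Peptides matching more than one site are flagged `ambiguous`, called at
their lexicographically smallest site, counted in whole-condition
totals, but excluded from per-precursor tallies, which assume unique
assignment.

## Quantitation

Subject-level abundance is the mean of culture means, each culture
being the mean of its technical injections (`subject_abundance()`) —
respecting the nesting rather than pooling injections, a choice this
package makes explicit since aggregation order is rarely stated.
Missing values stay missing; zeros are never imputed. Group summaries
are mean ± s.e.m. (sample sd/√n). Between-group tests are
pooled-variance two-tailed Student's t (df = n₁+n₂−2), chosen over
Welch because the method's premise is similar group variances; the
implementation is cross-checked in the test suite against an
independent reference (`stats::t.test(var.equal = TRUE)`) to 1×10⁻⁸ on
random instances, and is scale-invariant by construction. Tests are
computed only for peptides the presence matrix calls present in both
arms of a contrast. P-values are raw by default (that is how the
companion significance rule, p < 0.05, was defined); Benjamini–Hochberg
is available via `p_adjust = "BH"`. Condition contrasts are unpaired by
default with a paired option (subjects are matched across conditions,
but the published analysis does not state pairing).

No cross-run intensity normalisation is applied anywhere: none is
described for the source data, and silently normalising would change
means and t-statistics. This is a documented behaviour, not an
oversight; users with drifting runs should normalise upstream.

Degenerate t inputs are handled by convention: both variances zero with
equal means gives t = 0, p = 1; with unequal means, p = 0 plus a
warning (the statistic is unbounded and the result should be treated as
qualitative).

## The synthetic generator and what it does (not) show

`ground_truth()` + `generate_observations()` emulate an engine's
peptide export for the full design: 7 + 6 subjects, 2 conditions, 3
cultures, 2 injections. Defaults: per-injection detection probability
0.9 for truly present peptides, 1% spurious detection, log-normal
intensities (per-peptide log-mean ~ N(log 10⁶, 0.7), injection log-sd
0.5 — typical LFQ dispersion; no distribution is published), RT jitter
sd 0.5 min, quality ~ Beta(4.5, 3) (≈95% of target draws above the 0.3
gate), 5% shuffled-sequence decoys (rejection-sampled to match no
precursor, so they are guaranteed to fail mapping), and m/z at the
theoretical monoisotopic value with 2 ppm error. True presence states
default to independent coin flips per peptide × group × condition
(probability 0.5) — a neutral choice; real signatures are structured
(nested ladders, group asymmetries), which is exactly why the printed
29-peptide matrix, not the generator, is the reference fixture.
Per-subject heterogeneity beyond detection dropout (subject-specific
dropout rates, batch effects, shared-media correlations) is not
modelled, so passing recovery tests demonstrate correctness of the
calling rule under independent noise, not robustness to structured
artefacts in real data.

`observations_from_fixture()` realises any presence matrix as a
*minimal* noiseless table — threshold-many subjects for `+` cells,
threshold-minus-one for `-` cells, 2 of 3 cultures, 1 injection — so
the end-to-end reconstruction test is human-auditable and sensitive to
off-by-one errors in every threshold simultaneously.

`recovery_experiment()` estimates sensitivity/specificity of the calls
against truth by simulation. By default it skips the quality/RT
filters: then the only stochastic gate is detection, and sensitivity
has the exact form

p_culture = P(Bin(2, p) ≥ 1), p_subject = P(Bin(3, p_culture) ≥ 2),
p_group = P(Bin(n_g, p_subject) ≥ t_g),

implemented in `recovery_sensitivity_exact()` and verified in the tests
within 3 Monte-Carlo standard errors at 1,000 simulated experiments.
With filters on, the effective per-injection probability shrinks by the
quality-gate pass rate and the closed form is an upper bound.

The synthetic precursors (`synthetic_precursors()`) are random
sequences at the real proteins' lengths (CHGB 677 aa, etc.),
deterministic and verified so that every fixture peptide occurs exactly
once across the set. They are stand-ins, clearly labelled synthetic:
coordinates and counts are faithful, biological sequence content is
not.

## Problem sizes and numerical choices

The shipped analyses and tests run at desk scale: the 29-peptide
fixture (936 observation rows) for all count reproductions; exhaustive
enumeration of all 2²/2³/2⁷/2⁶ detection patterns for the threshold
verifications; 1,000 simulated experiments with a 6-peptide panel for
the recovery check (about a minute on one core); 25 null runs with
12-peptide panels for the type-I calibration in
`analysis/03_quantitation_null.R`, which lands near the nominal 5%
(4.5% in the shipped run). RT subset selection enumerates subsets
exactly up to 12 members (groups are technical injections, so 2 in
practice) and falls back to a greedy RT-window scan above that.
Ties in the FDR scan resolve to the most permissive passing cutoff.

## Known limitations

* Presence calling is deterministic counting, as defined; no
  probabilistic model of detection is fitted.
* Per-precursor tallies assume unambiguous mapping; heavily repetitive
  precursor sets will push peptides into the flagged-ambiguous pool.
* The quantitative stage reports relative XIC areas; absolute
  comparisons across instruments/runs require upstream normalisation.
* Incomplete designs (subjects with <3 cultures) are called against
  the same absolute thresholds, which is conservative.
* Printed per-precursor count tables can disagree with the presence
  matrix they accompany (the reference fixture's published companion
  table carries one such row: an SZ count of 2 where the matrix implies
  1). The set-algebra identities here are enforced, so the package
  always reports the matrix-consistent value and does not special-case
  such discrepancies.
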