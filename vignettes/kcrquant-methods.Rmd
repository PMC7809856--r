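---
title: "Quantifying lysine crotonylation: models and methods in kcrquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying lysine crotonylation: models and methods in kcrquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kcrquant)
```

kcrquant implements the downstream analysis of a TMT-labelled lysine
crotonylation (Kcr) experiment with three control (CK) and three treatment
(T) channels: protein and modification-site differential quantification,
protein/PTM crosstalk, sequence-motif discovery around modified lysines,
cross-species conservation of modified lysines, and Fisher-exact term
enrichment. Because real reporter-ion data require a search engine upstream,
every stage is validated on synthetic data whose ground truth is known
exactly; the generator is a first-class, tested part of the package.

## The quantification model

Reporter intensities are modelled as log-normal. For a peptide of protein
$p$, the log2 intensity in channel $c$ is

$$
y = \mu + b_p + o + \delta_p \cdot \mathbf{1}[c \in T] + \varepsilon,
\qquad \varepsilon \sim N(0, \sigma^2),
$$

with grand location $\mu$ (`base_log2_mean`, default 20 — the scale of
reporter ions), protein baseline $b_p \sim N(0, 2^2)$, a per-peptide offset
$o \sim N(0, 1)$ standing in for ionization-efficiency differences (it
cancels in every ratio), a protein-level treatment effect $\delta_p$, and
measurement noise $\sigma$ (default 0.3; the calibration analyses use 0.25).
Site rows add a site-level effect $\gamma_s$ on top of $\delta_p$, which is
exactly the separation the protein normalization below is designed to
recover. Cells are deleted completely at random at `missing_rate`.

The analysis chain mirrors standard TMT practice:

1. **Mean normalization.** Each channel is rescaled multiplicatively so its
   mean over non-missing rows equals the grand mean of the per-channel
   means. We read "mean-normalized at peptide level to center the
   distribution of quantitative values" as per-channel scaling of raw
   intensities; a per-row centering reading exists but would erase all
   protein-level fold changes, so it was rejected. A corollary worth
   knowing: any treatment effect common to most rows is absorbed into the
   channel means and is unidentifiable; simulations validating the pipeline
   therefore plant sign-balanced or sparse effects.
2. **Peptide ratios.** Per unique peptide, ratio = mean(T)/mean(CK) over
   non-missing values, each group needing at least `min_values_per_group`
   (default 2 of 3) values; there is no imputation.
3. **Protein ratio** = median of its unique-peptide ratios. Shared peptides
   are excluded entirely (no razor-peptide logic).
4. **Protein p-value**: two-sample two-tailed t-test on per-channel log2
   protein intensities, the channel intensity being the sum of
   unique-peptide intensities. Welch's unequal-variance form is the default
   (`var_equal = FALSE`); the pooled form is a switch. Under the log-normal
   model the test is correctly specified, and on 1000 null proteins its
   empirical type-I error at $\alpha = 0.05$ sits inside [0.03, 0.07]
   (checked by the test suite).
5. **Regulation calls**: up if ratio > 1.2 and p < 0.05, down if
   ratio < 1/1.2 and p < 0.05. The fold cutoff of 1.2 is the field's
   convention for TMT, where ratio compression dampens fold changes.
   `use_pvalue = FALSE` switches to the ratio-only rule, a reading some
   site-level reports use; the default applies both conditions at both
   levels, since a ratio rule alone lets ~10% of null sites through at
   realistic noise, while the joint rule keeps false calls under 5%.
6. **Site quantification**: sites with localization probability not above
   0.75 are removed first. The raw site ratio and p-value are computed as
   for a single peptide; the normalized ratio divides by the parent
   protein's ratio, so `norm_ratio * protein_ratio = raw_ratio` holds to
   1e-9 relative error by construction, and a site that merely tracks its
   protein's abundance is classified unchanged. Sites on unquantified
   proteins fall back to the raw ratio and carry `norm_basis = "raw"`.

**Crosstalk.** Proteins present in both datasets are labelled by the joint
direction of protein and site regulation: `consistent` (same direction,
no contradicting site), `opposite` (all regulated sites against the
protein), `mixed` (sites both ways), or `none` when either layer is
unregulated — the last level is ours: most overlapping proteins fall there,
and the published classification schemes leave them unnamed. The quadrant
uses the representative site (smallest p-value) in the (protein log2,
site normalized log2) plane, with quadrants 2 and 4 holding the
anticorrelated proteins.

## Motif discovery

Windows are 21-mers (±10 residues) around each modified K, padded with `_`
at protein termini; the background is the window set of *every* lysine in
the database. Discovery is the classic iterative residue/position strategy:
at each step, each unfixed (offset, residue) pair is scored by the binomial
upper-tail probability of its foreground count at the background's
positional frequency; the best candidate with $p \le 10^{-6}$ and at least
20 foreground occurrences is fixed, and both sets are reduced to matching
windows. When nothing passes, the motif is emitted, its matching foreground
windows are consumed, and the background is restored for the next motif.
The two thresholds follow the original convention of the method, since
published applications rarely state them; both are arguments. Pad
characters count in neither numerator nor denominator. Ties on the p-value
break deterministically (smaller |offset|, then upstream before downstream,
then alphabetical residue), so window order never matters. Reported counts
and fold increase are always computed against the original input sets.
On foreground/background sets of a few hundred windows, the first accepted
constraint provably equals the argmin of the brute-force 20×20 p-value
table (the suite carries that scan as an oracle), and a planted
two-constraint motif such as F at −1 with E at +1 at 30% prevalence over
500+ sites is recovered exactly.

The companion position-by-residue matrix reports log2 odds of foreground
versus background frequency with a symmetric pseudocount of 0.5; cells for
residues absent from both sets (and the center column) stay `NA` rather
than inheriting a pseudocount artifact.

## Orthology and conservation

BLASTP-style hit ranking is replaced by exact Smith–Waterman local
alignment with BLOSUM62 and affine gaps (open 11, extend 1 — the BLAST
defaults); at desk scale the exact algorithm is affordable and
deterministic, and hits are ranked by raw score with a floor of 50 to
suppress spurious pairs between short unrelated proteins (no E-value
model). Orthologs are reciprocal best hits, with lexicographic
tie-breaking. Conservation is then counted per ortholog pair on the global
(Needleman–Wunsch) alignment: a query lysine is conserved if its aligned
column in the subject is lysine; a gap is not conserved. Lysines split into
crotonylated and control (every other lysine of the query), counts
accumulate per species, and the class difference is tested with a
two-tailed Fisher exact test. We count conservation pairwise per species
rather than within one joint multiple alignment: the per-species counts
this produces are what conservation tables report, and pairwise global
alignment is exact where a joint MSA is heuristic.

The simulated orthologs substitute residues independently (no indels) and
never substitute *into* lysine at a former-lysine column, so the recorded
retention draws are, provably, the conservation counts the aligner must
report — the suite checks exact equality, not approximation. Retention
defaults (`kcr_keep` 0.8, `control_keep` 0.5) put crotonylated lysines
clearly above background, the regime the conservation test is meant to
detect.

## Fisher exact test and enrichment

`fisher_two_tailed()` computes the exact two-sided p-value by summing, over
the hypergeometric support at fixed margins, every table probability not
exceeding the observed one — with a relative tolerance of 1e-7 so that
equiprobable far-tail tables are not lost to floating-point rounding. It is
cross-checked against an explicit enumeration oracle and against an
independent implementation to 1e-10 on a thousand random tables. Term
enrichment builds the standard 2×2 per term (differential/background ×
with/without term), applies the same kernel, and corrects across terms with
Benjamini–Hochberg (Bonferroni as a switch); both raw and corrected
p-values are reported because published cutoffs are often ambiguous about
which was thresholded.

## The synthetic-data generator, and what passing tests mean

The generator emulates: a protein database with realistic average residue
composition; tryptic peptides (cleavage after K/R except before P, 7–45
residues kept); Kcr sites planted on lysines at a set fraction; sequence
motifs written into flanks at controlled prevalence (sites are kept ≥11
residues apart within a protein when motifs are planted, so edits can
never destroy another site's lysine and the truth stays exact);
localization probabilities from a Beta mixture (85% near 0.95, the rest
near 0.5) so the 0.75 filter removes a controllable slice; and ortholog
proteomes with controlled lysine retention. All randomness flows through
explicit seeds; identical seeds give byte-identical outputs.

What it does *not* emulate: spectra and peptide-spectrum matching,
search-engine FDR, isobaric reporter interference (ratio compression),
co-eluting peptide contamination, intensity-dependent missingness, batch
effects, or indels in ortholog evolution. Passing tests therefore
demonstrate that the implementation is correct under its stated model, not
that the model captures every pathology of real reporter data. The
distributional choice itself (log-normal) is a modelling decision, not an
inference from any particular dataset.

Problem sizes used by the validation analyses were chosen to make the
statistical checks sharp at interactive cost: 1000 proteins for null
calibration of the t-test; ~2000 sites with 40 planted +1.5 log2 effects
for site-effect recovery (sparse enough that one-sided planting does not
bias the normalization, see above); ~550 sites at 30% prevalence for motif
recovery; 30-protein proteomes for orthology, where exact all-vs-all
alignment is instant.

## Numerical and degenerate-input policy

* Ratios require ≥2 non-missing values per group; otherwise the protein or
  site is `unquantified` (a class, not an error).
* An all-missing channel is an error naming the channel; a missing cell is
  data.
* t-tests on constant log2 values return p = 1 when means agree, `NA`
  otherwise; `NA` p-values never produce regulation calls.
* The binomial tail uses the regularized incomplete-beta form, stable for
  tiny tails; `P(X ≥ 0) = 1` exactly.
* Site positions are 1-based residue indices; motif offsets are signed
  with 0 at the modified K. Output TSVs are tab-separated, `.`-decimal,
  unquoted, with a provenance header (package version + config hash).

## A short tour

```{r, eval = FALSE}
run <- pipeline_run(run_config(seed = 1, n_proteins = 150,
                               site_fraction = 0.12,
                               species = c("tea", "rice")))
run                       # report-style summary
glance(run$protein_results)
tidy(run$site_results)
glance(crosstalk(run$protein_results, run$site_results))
autoplot(run$site_results)            # volcano
autoplot(run$crosstalk)               # quadrant plot
fg <- extract_windows(run$proteins, run$sites)$window
bg <- background_windows(run$proteins)$window
autoplot(enrichment_matrix(fg, bg))   # residue heatmap
tidy(run$conservation)
```

## Known limitations

Shared-peptide (razor) protein inference, isobaric interference
correction, multi-batch bridging, imputation, GO graph propagation, and
heuristic seeded search for large proteomes are out of scope. The exact
all-vs-all aligner is quadratic in database size and intended for desk-
scale conservation analyses (hundreds, not tens of thousands, of
proteins); an external MSA or BLAST can be substituted upstream by feeding
`count_conservation()` pre-computed alignments.
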