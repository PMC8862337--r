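---
title: "Glucosinolate profiling and metabolic-gene evolution: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Glucosinolate profiling and metabolic-gene evolution: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gslprofiler)
```

## Overview

`gslprofiler` implements the computational chain behind a glucosinolate
(GSL) profiling and gene-evolution study in *Isatis indigotica*: rule-based
LC-MS/MS screening of desulfo-GSLs, internal-standard HPLC quantification,
accumulation statistics with compact letter displays, qRT-PCR relative
expression, reciprocal-best-hit homolog pairing, NG86 Ka/Ks estimation with
divergence dating, and duplicate-gene classification. Because raw instrument
files and the genome assembly are not redistributable, a first-class
synthetic-data module generates inputs with the statistical structure each
stage assumes, together with machine-readable ground truth, so every stage is
validated end to end.

## The compound registry and mass arithmetic

The registry (`load_registry()`) carries the ten GSLs detected in
*I. indigotica* plus the sinigrin internal standard: nominal molecular
weight, desulfo m/z, retention time, UV correction coefficient and chemical
class (aliphatic/aromatic/indole). Masses are nominal integers throughout —
the analyses were run on a unit-resolution triple quadrupole, and
accurate-mass arithmetic is deliberately out of scope. Sulfatase desulfation
removes SO3, so `desulfo_mass(mw) = mw - 80`; this identity holds for every
registry row and is the first sanity check on any edited registry file.
(R,S)-glucoisatisin elutes as two epimers and is stored as one record with
both retention times; matching accepts either. The registry copies the
published catalogue verbatim, including its correction coefficient of 1 for
(R,S)-glucoisatisin — atypical for a non-reference aliphatic GSL, but we do
not second-guess the published calibration.

Instrument heuristics: fragmentor voltage about one third of the molecular
weight and collision energy about one fifteenth, rounded half away from zero
(`suggest_ms_params()`). "About" in the source protocol is operationalised as
nearest-integer rounding; this is a presentation choice with no downstream
effect.

## MS/MS screening rules

A desulfo-GSL spectrum shows four diagnostics: the sulfide-oxime fragment at
m/z 75 (negative mode), a neutral loss of 162 Da (thioglucose) or 198 Da (the
chloride-contaminated variant — both are accepted as equivalent evidence),
the aglycone fragments m/z 144/146/160 in positive mode, and an even nominal
molecular mass (nitrogen rule). Candidacy requires the m/z 75 fragment plus
molecular-ion evidence: either the neutral loss or an explicit precursor
annotation from the acquisition software, because raw molecular-ion labels
are instrument specific. The aglycone rule requires two of the three
fragments rather than any one, trading a little sensitivity for fewer false
positives; the source protocol lists all three without a threshold.
Candidacy is decided from negative-mode evidence; positive-mode spectra
corroborate but do not veto (the study protocol does not state whether both
modes were mandatory, so we chose the laxer reading and expose the flags so
users can filter harder).

Library assignment matches a candidate's precursor to a registry desulfo m/z
within 0.5 Da and its retention time within 0.5 min (both configurable; the
defaults reflect unit resolution and the sharpness of the published
chromatograms). Compounds sharing a desulfo mass — progoitrin and
epiprogoitrin at m/z 309, and the two methoxy-indolyl GSLs at 398 — are
disambiguated by retention time, with the nearest time winning ties.
Candidates outside every window stay unassigned: that is exactly the state
of the six putative indole GSLs, whose structure elucidation is a non-goal.

## Quantification

Contents are computed by the internal-standard method:

$$ w = \frac{k}{m_{sample}} \cdot \frac{A}{A_{IS}} \cdot
       \frac{c_{IS} V_{IS}}{M_{IS}} \cdot 10^3 \quad
       [\mu mol\, g^{-1}\, FW] $$

with defaults `c_IS = 1.0` mg/mL, `V_IS = 0.040` mL and `M_IS = 397.5` g/mol
(the sinigrin spike). All internal arithmetic is full precision; rounding to
published precision (contents to 3 decimals, percentages to 1) happens only
in `format_class_table()`, using half-away-from-zero rounding so printed
halves agree with the published tables. Class totals are sums of
full-precision member contents — never of rounded values — which is what
makes the published composition table internally consistent. Classes with no
detected compound are reported "N.D." rather than 0.0. Replicates are
quantified individually and summarised downstream as mean and SD (n = 3 in
the study design); sample masses are taken per record.

The synthetic peak generator inverts the formula algebraically with the
internal-standard area fixed at 10^6 AU, so a noiseless round trip recovers
planted contents to floating-point accuracy (the acceptance suite requires
1e-9 relative error). Area noise, when requested, is multiplicative
lognormal with mean 1 — the simplest model matching a detector's
scale-proportional error.

## Group statistics and letters

`one_way_anova()` is the classical fixed-effects F test with pairwise
two-sample t tests pooled on the ANOVA error variance and Bonferroni
multiplication by the number of pairs (capped at 1). `kruskal_wallis()` is
the tie-corrected H test (delegated to `stats::kruskal.test`) with Dunn-type
z comparisons on mean ranks, Bonferroni adjusted; Dunn's test is our
interpretation of "Kruskal–Wallis followed by Bonferroni", which the study
protocol names without detail. Both are exposed uniformly so content data
and Ka/Ks distributions can use either. The significance level defaults to
0.05.

Letters come from the insert-and-absorb compact-letter-display algorithm:
start with one column holding all groups; for each significant pair split
every column containing both; absorb subset columns. The defining property —
two groups share a letter iff they are not significantly different — is
property-tested on random five-group significance patterns. Letters are
assigned in descending group-mean order (ties by label), so output is
deterministic. Because the published organ table's post-hoc machinery is not
fully specified, its letter annotations are not used as numeric checks; only
its contents and percentages are.

With all observations identical, F is defined as 0 with p = 1 (the
degenerate no-variance path), and H is 0 with p = 1, guarding the
tie-correction denominator.

## Relative expression

`delta_delta_ct()` implements mean-Ct-first 2^-ddCt: replicate Cts are
averaged before dCt, matching the standard formulation (the alternative —
averaging per-replicate fold values — is exposed only through the reported
SD, which is computed on per-replicate fold values). The reference value is
the mean Ct of the single reference gene; when several reference genes are
given the arithmetic mean of per-gene means is used — a documented extension
beyond the study design, which used one reference gene per experiment. The
calibrator sample is exactly 1 by construction, and adding a constant to all
of a sample's Cts (a plate-wide shift) cancels. Amplification-efficiency
correction is out of scope. Missing reference wells raise an error: silent
sample drops are how qPCR tables go wrong.

## Orthology

`parse_blast_tab()` reads 12-column tabular BLAST output, removes self hits
and keeps the best HSP per query-subject pair. `best_hits()` ranks by bit
score (descending), breaking ties by e-value then subject id; bit score is
preferred as the primary key because e-values saturate at zero and rank
unstably across database sizes — the study protocol does not state its key,
so this is a documented package choice. `reciprocal_best_pairs()` generalises
reciprocal-best-hit pairing to top-k candidate sets (k = 2 reproduces the
"best two hits" screen; k applies to both directions since the protocol does
not distinguish them). The default e-value cutoff 1e-20 is the stated
protein-search threshold; 1e-5 suits nucleotide-library screens. Pairing is
verified against exhaustive enumeration on random instances.

## Ka/Ks and divergence time

The estimator is Nei–Gojobori (1986) with Jukes–Cantor correction,
implemented from first principles: per-codon synonymous site fractions
(mutations to stops count as nonsynonymous), pathway-averaged difference
counts for multi-hit codons (pathways through stops are skipped; if all are
blocked the average is over all), site totals averaged over the two
sequences, and d = -(3/4) log(1 - 4p/3). Saturation (p >= 3/4) is flagged,
and Ka/Ks is NA when Ks = 0 — never infinity. Significance is Fisher's exact
test on the 2x2 table of rounded substitution counts versus remaining sites,
the convention of the common Ka/Ks calculators; pairs with p > 0.05 are
removed by `filter_pairs()`. The study itself ran a Ka/Ks calculator whose
method is unstated, so reproduction of its rates from raw sequence is not a
numeric target; the published ratios and divergence times are instead
reproduced from the printed (Ka, Ks) pairs via `kaks_derive()`, which is
estimator independent. Divergence time is T = Ks / 2λ with the Brassicaceae
clock λ = 1.5e-8 substitutions/site/year, reported in Myr to 2 decimals.

Codon alignment is protein guided (`backtranslate_align()`): global BLOSUM62
alignment with affine gaps (opening 10, extension 0.5 — Biostrings
conventions), mapped back onto codons; columns opposite gaps are dropped and
terminal stops stripped. Internal stops and out-of-frame CDSs are errors.

Both counters are checked exhaustively: site fractions over all 61 sense
codons and pathway averages over all 61 x 61 codon pairs against an
independent enumeration oracle. The synthetic generator plants at most one
nucleotide change per codon, which makes the realized pN and pS exact by
construction; recovery of the planted Ka/Ks at 1,000 codons over 20 seeded
pairs is required to be within 10%.

## Duplicate-gene classification

Genes are ranked along chromosomes by start position (ties by end then id).
Collinear blocks are found by dynamic-programming chaining over anchors (a
homolog pair plotted at its two ranks): a chain extends when both rank
increments are in (0, 25], forward or inverted, and chains with at least 5
anchors become blocks, extracted greedily by size with each anchor used
once. This is a simplified unit-score version of the MCScanX chaining —
classification needs block membership, not block scores — and it is verified
against an exhaustive subset oracle on instances of up to 12 anchors.
Same-chromosome anchors closer than the proximal window are excluded from
chaining: those near-diagonal pairs are tandem/proximal candidates, and
letting them chain would misread a run of tandem arrays as a segmental
block in self-genome mode (anchors are deduplicated as unordered pairs and
the self-diagonal removed).

Categories follow the MCScanX notion with priority wgd_segmental > tandem >
proximal > dispersed > singleton: block anchors are WGD/segmental; otherwise
a same-chromosome homolog at rank distance <= 1 makes both genes tandem, <=
10 proximal; any other homolog means dispersed; no homolog, singleton. The
tandem window of 1 (strictly consecutive) matches the usual definition but
is configurable, because pseudogene fragments can interleave functional
copies. The proximal window of 10 genes is our default — the constant used
by the study's classifier run is not stated — and is exposed as a parameter.
For that reason the study's published per-category counts are not numeric
targets; instead the classifier must recover 100% of planted categories on
noiseless synthetic genomes and match the chaining oracle.

The genome generator plants tandem pairs at adjacent ranks, proximal pairs
two ranks apart with a singleton filler between, segmental blocks of five
anchors across distinct chromosome pairs, dispersed pairs on different
chromosomes capped at four per chromosome pair (one below the block
threshold, so they can never chain into a spurious block), and pair-free
singletons. Coordinates are non-overlapping 1 kb genes spaced 1 kb apart.

## Pipeline, configuration and sizes

`run_pipeline()` wires the stages into reproducible runs with subcommands
`simulate`, `screen`, `quantify`, `stats`, `expr`, `orthologs`, `kaks`
(including a `derive` mode that recomputes ratio and dating columns from
printed rates), `dupclass`, and `all` (simulate, then every stage on the
simulated outputs). All thresholds surface in one nested configuration with
the study defaults (alpha 0.05, e-value 1e-20/1e-5, lambda 1.5e-8, 0.5
Da/min tolerances); unknown keys are rejected, and a resolved copy of the
full configuration is written into every output directory. Deterministic
stages are idempotent: identical seeds give byte-identical trees. The
package's functions are the interface; the pipeline driver is an R function
rather than a shell executable, and a one-line Rscript wrapper around it is
all a shell deployment needs.

Validation problem sizes were chosen to exercise each stage well past its
structural edge cases while staying quick on a laptop: 500-gene planted
genomes, 1,000-codon pairs over 20 seeds, 10,000 null simulations for the
ANOVA type-I calibration (expected 5% +- 1%), and 20-gene orthology
instances for the exhaustive pairing oracle.

## What the synthetic data does and does not show

The generators reproduce the *structure* each stage assumes: formula-exact
peak tables, spectra that satisfy or violate one named rule each, codon
pairs with exactly known substitution counts, genomes with planted
duplication categories, and Ct tables with planted folds. Passing those
tests demonstrates the algorithms are correct on inputs matching their
models. It does not demonstrate robustness to what real instruments add —
retention-time drift, co-elution, saturated detectors, heteroscedastic Ct
noise, fragmented gene models, or paralog-rich BLAST tables with domain-only
hits. Tolerances and thresholds are exposed precisely so users can tighten
or relax them against their own instrument behaviour.

## Known limitations

- Nominal-mass arithmetic only; no adduct enumeration beyond the chloride
  neutral-loss variant, no isotope patterns.
- NG86 is the only Ka/Ks estimator; no maximum-likelihood codon models or
  rate variation.
- The duplicate classifier's proximal window and chaining parameters are
  package defaults, not study-calibrated constants.
- qPCR assumes 100% amplification efficiency (no Pfaffl correction).
- Peak areas are inputs; chromatogram integration and calibration curves are
  out of scope.
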