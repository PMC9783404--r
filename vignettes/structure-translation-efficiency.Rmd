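---
title: "Linking mRNA secondary structure to translation efficiency with teshape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking mRNA secondary structure to translation efficiency with teshape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teshape)
library(dplyr)
```

## The question and the model

Ribosome profiling (Ribo-seq) together with RNA-seq measures how efficiently
each mRNA is translated: the translation efficiency of a transcript is

$$\mathrm{TE} = \log_2 \frac{\mathrm{RPKM}_{\mathrm{Ribo}}}{\mathrm{RPKM}_{\mathrm{RNA}}},
\qquad \mathrm{RPKM} = \frac{\text{count} \times 10^9}{\text{length} \times \text{library total}}.$$

Chemical probing of RNA structure (icSHAPE, DMS-seq) measures, per
nucleotide, how accessible — how single-stranded — the molecule is, both
inside living cells (in vivo) and on refolded RNA (in vitro). `teshape`
connects the two measurements: it asks where along an mRNA secondary
structure matters for translation, and whether the in-cell conformation
carries information the refolded one does not.

The analysis has four stages, each a small set of pipeable functions:

1. **TE quantification** (`quantify_te()`): RPKM for both libraries, the
   log2 ratio, an expression filter (RNA-seq RPKM strictly above 1, so
   lowly expressed transcripts cannot contribute extreme ratios), and class
   labels — the top 25% of transcripts by TE are the *high* class, the
   bottom 25% the *low* class, the middle half is set aside.
2. **Feature extraction**: sequence features (nucleotide/codon/amino-acid
   frequencies, GC content, repetitive rates, region lengths; 111 features
   under the default registry) and structural features (60-bin metagene
   reactivity profiles per probing condition, CDS-head reactivity,
   in-silico folding energies; 132 features).
3. **Classification** (`train_te_classifiers()`): a probability random
   forest and an elastic-net logistic regression, evaluated over repeated
   stratified 70/30 splits (100 by default) with 10-fold cross-validated
   grid tuning inside every training partition, scored by rank AUC on the
   held-out 30%, and compared by a paired t-test. The forest's normalised
   impurity importances, summed within feature groups (sequence / vivo /
   vitro / insilico) and averaged per metagene bin, localise the signal.
4. **Per-bin differential statistics** (`summarize_bins()`): for each of
   the 60 bins and each condition, a two-sample Kolmogorov–Smirnov test
   between the high- and low-TE transcripts' bin reactivities, adjusted by
   Benjamini–Hochberg within condition, alongside the *delta reactivity*
   (in vivo minus in vitro bin mean) per class.

## The metagene coordinate system

Transcripts differ in length, so per-nucleotide tracks are compressed to a
fixed grid: 20 bins for each of the 5'UTR, CDS and 3'UTR, 60 bins in total
(bins 1–20, 21–40, 41–60). Within a region of length $L$, bin $k$
(0-based) covers nucleotides $[\lfloor kL/B \rfloor, \lfloor (k+1)L/B
\rfloor)$ — a rule chosen because it is deterministic and partitions the
region exactly: every nucleotide belongs to one bin, so the
length-weighted mean of bin values always reproduces the region mean on a
gap-free track (this conservation is enforced by a property test). A bin
value is the mean of the non-missing reactivities it contains; a bin with
no nucleotides (region shorter than 20 nt) or only missing values is `NA`
and is median-imputed inside each training partition, never across the
train/test boundary.

The *CDS head* — the first six codons (18 nt) of the coding region — gets
its own feature per condition, since structure around the initiation site
is the classical determinant of translation efficiency.

## Numerical choices worth knowing

* **KS p-values** are exact whenever $|x| \cdot |y| \le 10{,}000$: the
  permutation tail probability computed by lattice-path counting, which
  for tie-free data equals full enumeration over all
  $\binom{n+m}{n}$ assignments (the test suite checks this equivalence
  directly, and cross-checks `stats::ks.test`). Above the limit the
  asymptotic Kolmogorov distribution is used. Exact p-values are floored
  at $1/\binom{n+m}{n}$, their smallest attainable value, so downstream
  `-log10` transforms stay finite. Each observation entering a test is
  one transcript's bin mean, not a nucleotide: the per-bin sample size is
  the number of transcripts.
* **Multiple testing** uses Benjamini–Hochberg within each condition
  across its 60 bins; the familywise unit is the metagene curve a reader
  inspects as a whole.
* **AUC** is the rank-based (Mann–Whitney) formulation with ties counting
  one half; it equals pairwise concordance counting, which the tests use
  as the independent oracle.
* **Tuning** is an exhaustive grid search maximising mean cross-validated
  AUC, ties broken by grid order; a single-point grid skips the search. The
  default grids (forest: trees {100, 500} × mtry {√p, p/3} × min leaf
  {1, 5}; elastic net: mixing {0.1, 0.5, 0.9} × 10 log-spaced penalties)
  are deliberately small and fully configurable — there is no published
  grid to reproduce.
* **Splits and folds are stratified** by class. The protocol does not
  require stratification, but with 50-transcript classes an unstratified
  split can starve one side of a class; stratification removes that
  failure mode without changing the expected behaviour.
* **Ties in the TE ranking** at a quantile boundary are broken by
  transcript id through a single ascending ordering, which keeps the two
  tails disjoint even in degenerate all-tied inputs and makes runs
  reproducible.
* **Transcripts with zero ribosome-footprint counts** are excluded rather
  than assigned $-\infty$ TE.
* **Coordinates** are 0-based half-open in the region table (5'UTR =
  `[0, len_utr5)`); bin indices in R outputs are 1-based.

## The built-in folding model

In-silico structural features are folding energies for five scopes (whole
transcript, the three regions, the CDS head), raw and per-nucleotide. The
built-in folder is deliberately minimal: Nussinov base-pair maximisation —
energy −1 per Watson–Crick or G·U pair, hairpin loops of at least 3 nt —
implemented in C++ and verified against exhaustive structure enumeration
for short sequences. It is not a thermodynamic model; its role is to
provide a deterministic, dependency-free, testable stand-in with the same
qualitative behaviour (more pairable sequence → lower energy). When
energies from a nearest-neighbour folding tool are available,
`import_external_mfe()` swaps them in behind the same feature names.

## What the synthetic generator emulates

Real probing studies cannot be re-derived at desk scale, so every stage is
exercised on synthetic data whose ground truth is known by construction
(`synthetic_config()`, `simulate_te_dataset()`):

* **Transcripts**: three contiguous regions with uniform lengths — 5'UTR
  60–120 nt, CDS 150–300 nt (multiple of 3, `ATG`...stop), 3'UTR 90–180
  nt, i.i.d. nucleotides. These are several-fold shorter than typical
  mammalian mRNAs; they keep whole-transcript folding of 400 transcripts
  cheap while leaving every region long enough for the 20-bin grid.
* **Counts**: negative binomial (dispersion 0.1) with log-normal
  per-transcript means (log-mean log 200, log-sd 1); ribosome loading is
  the RNA mean scaled by $2^{\pm 2}$ for the high-/low-tendency halves, so
  the TE quantile stage recovers the planted classes almost perfectly.
* **Reactivities**: i.i.d. Beta(2, 5) baseline per nucleotide (right-
  skewed, bounded, like normalised probing signals), 10% missing at
  random, with scenario-specific additive effects on high-TE transcripts:
  * `mesc_like` — +0.15 on the in vivo 3'UTR with a front-loaded profile
    (flat peak over the first 30% of the 3'UTR, decaying to zero at the 3'
    end, mirroring a signal that is strongest just after the stop codon
    and absent at the very 3' end) and −0.05 uniformly on the in vitro
    3'UTR.
  * `zebrafish_like` — +0.12 on the 3'UTR in *both* conditions (so the
    vivo−vitro delta cancels) plus +0.05 on the in vivo 5'UTR and
    proximal CDS.
  * `null` — nothing planted; the negative control.

The generator is deliberately simple: effects are additive with a known
position profile, reactivity is independent of the actual sequence, and
there is no ribosome periodicity, RBP footprint or sequence-dependent
folding. Passing the recovery tests therefore shows that the pipeline
detects and localises a planted structure–TE coupling of realistic
magnitude under realistic noise — not that real mESC or zebrafish data
would yield a particular AUC.

## A worked run

```{r pipeline, eval = FALSE}
sim <- simulate_te_dataset(synthetic_config("mesc_like", n_transcripts = 400,
                                            seed = 7))
te <- quantify_te(sim$counts, sim$transcripts)
features <- combine_features(
  assemble_sequence_features(sim$transcripts),
  assemble_structural_features(
    bin_profile(sim$tracks, sim$transcripts),
    cds_head_reactivity(sim$tracks, sim$transcripts),
    mfe_features(sim$transcripts)
  )
)
fit <- train_te_classifiers(features, te_labels(te), n_splits = 20,
                            base_seed = 7)
glance(fit)
plot_importance_bins(grouped_importance(fit))

bins <- summarize_bins(bin_profile(sim$tracks, sim$transcripts), te)
plot_bin_significance(bins)
plot_delta_profile(delta_profile(bin_profile(sim$tracks, sim$transcripts), te))
```

The problem sizes used throughout the tests and the acceptance script —
400 transcripts for the planted scenarios, 200 for the null controls, 20
random splits with a single-point tuning grid — were chosen as the
smallest sizes at which the planted effects are comfortably detectable
and the null is stable; the full protocol (100 splits, complete grids) is
the package default and runs unchanged, just longer.

## Known limitations

* The feature registries are a documented default census (111 sequence +
  132 structural features), not a canonical list: richer sets used in
  icSHAPE/DMS-seq studies of translation exist, and the registry mechanism
  is there so additional families can be added without touching the
  modelling code.
* The repetitive-rate definition (fraction of adjacent identical symbols)
  is the simplest reading of the name; it is isolated behind one function
  so an alternative can be swapped in.
* Whether RPKM should use full transcript length or CDS length is not
  fixed by the protocol; full transcript length is the default, with
  `length_mode = "cds"` available.
* The built-in folder ignores stacking energies, loop penalties and
  pseudoknots; treat its energies as comparative, not thermodynamic.
* Transcripts missing a probing condition entirely are retained with `NA`
  structural features (imputed at training time) rather than dropped.
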