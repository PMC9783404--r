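# teshape

Where along an mRNA does secondary structure matter for translation?
`teshape` is an R pipeline that relates transcriptome-wide RNA structure
probing data (icSHAPE, DMS-seq — in vivo and in vitro) to translation
efficiency measured by Ribo-seq/RNA-seq, and localises the association
along the transcript.

The core quantities:

- **Translation efficiency** per transcript:
  `TE = log2(RPKM_ribo / RPKM_rna)` with `RPKM = count * 1e9 / (length *
  library_total)`; transcripts with RNA-seq RPKM ≤ 1 are excluded, the top
  and bottom TE quartiles form the *high* and *low* classes.
- **Metagene reactivity profiles**: each transcript's per-nucleotide
  reactivity track is compressed to 60 bins — 20 per region (5'UTR, CDS,
  3'UTR) — plus the mean reactivity of the CDS head (first 6 codons).
- **Classification**: a random forest and an elastic-net logistic
  regression trained over repeated stratified 70/30 splits (10-fold
  cross-validated tuning inside each training partition), scored by rank
  AUC; grouped and per-bin impurity importances show *which* features and
  *where* along the transcript the signal lives.
- **Per-bin differential statistics**: two-sample Kolmogorov–Smirnov tests
  between high- and low-TE transcripts per bin and condition
  (Benjamini–Hochberg adjusted within condition), and the *delta
  reactivity* (in vivo − in vitro) profile per class — a readout of
  structural rearrangement inside cells.

A fully specified synthetic generator (`simulate_te_dataset()`) produces
transcripts, negative-binomial count tables and reactivity tracks with
plantable TE–structure coupling (mESC-like, zebrafish-like, or null), so
the whole pipeline is testable end to end without any downloads.

## Worked example

```r
library(teshape)

sim <- simulate_te_dataset(synthetic_config("mesc_like", n_transcripts = 400,
                                            seed = 7))
te <- quantify_te(sim$counts, sim$transcripts)
table(te$te_class)
#>         high intermediate          low
#>          100          200          100

features <- combine_features(
  assemble_sequence_features(sim$transcripts),          # 111 sequence features
  assemble_structural_features(                         # 132 structural features
    bin_profile(sim$tracks, sim$transcripts),
    cds_head_reactivity(sim$tracks, sim$transcripts),
    mfe_features(sim$transcripts)
  )
)

fit <- train_te_classifiers(features, te_labels(te), n_splits = 20,
                            rf_grid = tibble::tibble(num_trees = 200L,
                                                     mtry_rule = "sqrt",
                                                     min_node = 1L),
                            en_grid = tibble::tibble(alpha = 0.5, lambda = 0.01),
                            base_seed = 7)
fit
#> <te_split_results> 20 splits, 200 samples, 243 features
#>   mean test AUC (random forest): 1.000
#>   mean test AUC (elastic net):   1.000
```

Both models separate the classes perfectly here because the simulation
plants a strong in vivo 3'UTR reactivity difference between high- and
low-TE transcripts. The importance analysis localises it:

```r
gi <- grouped_importance(fit)
dplyr::summarise(dplyr::group_by(gi$groups, group), mean = mean(importance))
#>   group       mean
#> 1 insilico 0.00680
#> 2 sequence 0.0863
#> 3 vitro    0.163
#> 4 vivo     0.743
plot_importance_bins(gi)   # per-bin curves peak in the vivo 3'UTR bins
```

The in vivo feature group carries ~74% of the forest's importance — the
planted coupling — while sequence and in silico (folding-energy) features
contribute little, as nothing was planted there. Per-bin statistics tell
the same story positionally:

```r
bins <- summarize_bins(bin_profile(sim$tracks, sim$transcripts), te)
sig <- bins[bins$significant, ]
table(sig$region)
#>  cds utr3 utr5
#>    3   38    1
plot_bin_significance(bins)
plot_delta_profile(delta_profile(bin_profile(sim$tracks, sim$transcripts), te))
```

Significant bins concentrate in the 3'UTR, and the delta-reactivity
profile shows the high-TE class unfolding its 3'UTR in vivo — maximal just
after the stop codon, exactly as planted.

File-based inputs use plain text formats throughout: FASTA plus a
4-column region table (`read_transcripts()`), tab-delimited reactivity
tracks with `NA` for missing values (`read_reactivity()`), and count
tables with library sizes (`read_counts()`); `write_te_dataset()` emits a
complete simulated study in these formats.

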