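# synthetic transcripts, counts and reactivity tracks with plantable
# TE-structure coupling; the ground truth travels with every dataset

#' Configuration for the synthetic dataset generator
#'
#' Fixes every parameter of the generator. Three scenarios plant different
#' couplings between TE class and reactivity:
#'
#' * `mesc_like` — high-TE transcripts gain in vivo 3'UTR reactivity with a
#'   front-loaded profile (strongest in the first 30% of the 3'UTR, fading
#'   to nothing at the 3' end) and lose in vitro 3'UTR reactivity uniformly;
#'   the pattern of strong in-cell unfolding of the 3'UTR seen in mouse
#'   embryonic stem cells.
#' * `zebrafish_like` — high-TE transcripts gain the same reactivity in both
#'   conditions across the 3'UTR (so the vivo - vitro delta stays near
#'   zero) plus a small in vivo gain over the 5'UTR and proximal CDS; the
#'   pattern seen in zebrafish embryos.
#' * `null` — nothing planted: counts and reactivities are independent of
#'   class, for negative controls.
#'
#' @param scenario One of `"mesc_like"`, `"zebrafish_like"`, `"null"`.
#' @param n_transcripts Number of transcripts, default 400.
#' @param seed Seed; everything downstream is deterministic in it.
#' @param utr5_range,cds_range,utr3_range Region-length ranges in
#'   nucleotides (CDS lengths are rounded to multiples of 3, minimum 18).
#' @param rna_log_mean,rna_log_sd Log-normal distribution of per-transcript
#'   RNA-seq mean counts.
#' @param dispersion Negative-binomial dispersion (`1/size`), default 0.1.
#' @param te_effect Log2 ribosome-loading multiplier separating the
#'   high-tendency and low-tendency halves (`+te_effect` vs `-te_effect`);
#'   0 under the null scenario.
#' @param beta_shape1,beta_shape2 Beta baseline of per-nucleotide
#'   reactivities, default Beta(2, 5) (right-skewed, bounded like
#'   normalised probing reactivities).
#' @param delta_vivo mesc_like: peak in vivo 3'UTR gain for high-TE
#'   transcripts, default 0.15.
#' @param delta_vitro mesc_like: uniform in vitro 3'UTR loss for high-TE
#'   transcripts, default 0.05.
#' @param delta_shared zebrafish_like: shared 3'UTR gain in both conditions,
#'   default 0.12.
#' @param delta_head zebrafish_like: in vivo 5'UTR/proximal-CDS gain,
#'   default 0.05.
#' @param missing_rate Fraction of nucleotides with missing reactivity,
#'   default 0.1.
#' @param gc_shift Optional GC-composition shift (fraction) coupling
#'   sequence to class; 0 (off) by default.
#' @param count_inflation Library totals are the column sums times this
#'   factor (a transcriptome-wide library is larger than any subset),
#'   default 10.
#' @return A validated list of class `te_synthetic_config`.
#' @export
synthetic_config <- function(scenario = c("mesc_like", "zebrafish_like", "null"),
                             n_transcripts = 400L, seed = 1L,
                             utr5_range = c(60L, 120L),
                             cds_range = c(150L, 300L),
                             utr3_range = c(90L, 180L),
                             rna_log_mean = log(200), rna_log_sd = 1,
                             dispersion = 0.1, te_effect = 2,
                             beta_shape1 = 2, beta_shape2 = 5,
                             delta_vivo = 0.15, delta_vitro = 0.05,
                             delta_shared = 0.12, delta_head = 0.05,
                             missing_rate = 0.1, gc_shift = 0,
                             count_inflation = 10) {
  scenario <- match.arg(scenario)
  if (scenario == "null") te_effect <- 0
  assert_scalar_number(n_transcripts, "n_transcripts", min = 4)
  for (r in list(utr5_range = utr5_range, cds_range = cds_range, utr3_range = utr3_range)) {
    if (length(r) != 2L || any(r <= 0) || r[1] > r[2]) {
      abort("Region ranges must be positive length-2 vectors with min <= max.")
    }
  }
  if (cds_range[2] < 18L) abort("CDS range must allow lengths >= 18.")
  assert_scalar_number(dispersion, "dispersion", min = 0, strict_min = TRUE)
  assert_scalar_number(missing_rate, "missing_rate", min = 0)
  if (missing_rate >= 1) abort("`missing_rate` must be < 1.")
  for (nm in c("delta_vivo", "delta_vitro", "delta_shared", "delta_head")) {
    assert_scalar_number(get(nm), nm, min = 0)
  }
  baseline_mean <- beta_shape1 / (beta_shape1 + beta_shape2)
  if (delta_vitro >= baseline_mean) {
    abort("`delta_vitro` would push reactivities systematically below zero.")
  }
  structure(
    list(scenario = scenario, n_transcripts = as.integer(n_transcripts),
         seed = as.integer(seed), utr5_range = as.integer(utr5_range),
         cds_range = as.integer(cds_range), utr3_range = as.integer(utr3_range),
         rna_log_mean = rna_log_mean, rna_log_sd = rna_log_sd,
         dispersion = dispersion, te_effect = te_effect,
         beta_shape1 = beta_shape1, beta_shape2 = beta_shape2,
         delta_vivo = delta_vivo, delta_vitro = delta_vitro,
         delta_shared = delta_shared, delta_head = delta_head,
         missing_rate = missing_rate, gc_shift = gc_shift,
         count_inflation = count_inflation),
    class = "te_synthetic_config"
  )
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Generate synthetic transcript models
#'
#' Region lengths are uniform in their configured ranges (CDS rounded down
#' to a multiple of 3, floored at 18); nucleotides are i.i.d.; every CDS
#' starts with `ATG` and ends with a stop codon. All outputs satisfy the
#' transcript invariants and the run is deterministic in `cfg$seed`.
#'
#' @param cfg A [synthetic_config()].
#' @param truth Optional truth table (for the GC-composition coupling when
#'   `gc_shift > 0`).
#' @return Transcript tibble as from [read_transcripts()].
#' @export
generate_transcripts <- function(cfg, truth = NULL) {
  stopifnot(inherits(cfg, "te_synthetic_config"))
  n <- cfg$n_transcripts
  with_seed(derive_seed(cfg$seed, 11L), {
    ids <- sprintf("tx%04d", seq_len(n))
    sample_range <- function(r) r[1] + sample.int(r[2] - r[1] + 1L, n, replace = TRUE) - 1L
    len5 <- sample_range(cfg$utr5_range)
    lenc <- pmax(18L, (sample_range(cfg$cds_range) %/% 3L) * 3L)
    len3 <- sample_range(cfg$utr3_range)
    gc <- rep(0.5, n)
    if (cfg$gc_shift > 0 && !is.null(truth)) {
      gc <- ifelse(truth$true_class[match(ids, truth$transcript_id)] == "high",
                   0.5 + cfg$gc_shift, 0.5 - cfg$gc_shift)
    }
    seqs <- vapply(seq_len(n), function(i) {
      p <- c((1 - gc[i]) / 2, gc[i] / 2, gc[i] / 2, (1 - gc[i]) / 2)
      total <- len5[i] + lenc[i] + len3[i]
      s <- sample(c("A", "C", "G", "T"), total, replace = TRUE, prob = p)
      s[(len5[i] + 1):(len5[i] + 3)] <- c("A", "T", "G")
      s[(len5[i] + lenc[i] - 2):(len5[i] + lenc[i])] <-
        strsplit(sample(STOP_CODONS, 1L), "")[[1]]
      paste(s, collapse = "")
    }, character(1))
    tibble(transcript_id = ids, sequence = seqs, len_utr5 = len5,
           len_cds = lenc, len_utr3 = len3, length = len5 + lenc + len3)
  })
}

#' Assign ground-truth TE tendencies
#'
#' Half the transcripts are high-tendency (`+te_effect` log2 ribosome
#' loading), half low-tendency (`-te_effect`); under the null scenario the
#' multiplier is 0 for everyone and the class labels are exchangeable.
#'
#' @param cfg A [synthetic_config()].
#' @return Truth tibble: `transcript_id`, `true_class`, `te_multiplier`
#'   (log2).
#' @export
assign_truth <- function(cfg) {
  stopifnot(inherits(cfg, "te_synthetic_config"))
  n <- cfg$n_transcripts
  with_seed(derive_seed(cfg$seed, 12L), {
    cls <- sample(rep(c("high", "low"), length.out = n))
    tibble(
      transcript_id = sprintf("tx%04d", seq_len(n)),
      true_class = cls,
      te_multiplier = ifelse(cls == "high", cfg$te_effect, -cfg$te_effect)
    )
  })
}

#' Generate negative-binomial count tables
#'
#' RNA-seq counts are NB with a log-normal per-transcript mean and the
#' configured dispersion; Ribo-seq counts are NB with the same mean scaled
#' by `2^te_multiplier`, so the planted class tendency is recoverable as a
#' log2 count ratio. Library totals are the column sums inflated by
#' `count_inflation`.
#'
#' @param cfg A [synthetic_config()].
#' @param truth Truth tibble from [assign_truth()].
#' @return Count tibble with `ribo_total` / `rna_total` attributes, as from
#'   [read_counts()].
#' @export
generate_counts <- function(cfg, truth) {
  stopifnot(inherits(cfg, "te_synthetic_config"))
  n <- cfg$n_transcripts
  size <- 1 / cfg$dispersion
  with_seed(derive_seed(cfg$seed, 13L), {
    mu <- exp(rnorm(n, cfg$rna_log_mean, cfg$rna_log_sd))
    rna <- rnbinom(n, size = size, mu = mu)
    ribo <- rnbinom(n, size = size, mu = mu * 2^truth$te_multiplier)
    out <- tibble(transcript_id = truth$transcript_id,
                  ribo_count = as.integer(ribo), rna_count = as.integer(rna))
    attr(out, "ribo_total") <- max(1, round(sum(ribo) * cfg$count_inflation))
    attr(out, "rna_total") <- max(1, round(sum(rna) * cfg$count_inflation))
    out
  })
}

# planted additive shift for one nucleotide set; u = relative position in
# region [0, 1); the mesc-like vivo profile is front-loaded: flat at the
# peak over the first 30% of the 3'UTR, then decaying linearly to 0
front_loaded_weight <- function(u) {
  ifelse(u < 0.3, 1, pmax(0, (1 - u) / 0.7))
}

#' Generate reactivity tracks for both probing conditions
#'
#' Per-nucleotide baseline reactivities are i.i.d. Beta draws; the
#' scenario's additive effects are planted on top for high-TE-tendency
#' transcripts (see [synthetic_config()]), values are clipped at zero, and
#' a missing mask is applied i.i.d. at `missing_rate`.
#'
#' @param cfg A [synthetic_config()].
#' @param truth Truth tibble.
#' @param transcripts Transcript tibble from [generate_transcripts()].
#' @return Long reactivity tibble covering both conditions.
#' @export
generate_reactivity <- function(cfg, truth, transcripts) {
  stopifnot(inherits(cfg, "te_synthetic_config"))
  with_seed(derive_seed(cfg$seed, 14L), {
    per_tx <- lapply(seq_len(nrow(transcripts)), function(i) {
      tx <- transcripts[i, ]
      total <- tx$length
      is_high <- truth$true_class[truth$transcript_id == tx$transcript_id] == "high"
      pos0 <- seq_len(total) - 1L
      in_utr3 <- pos0 >= tx$len_utr5 + tx$len_cds
      u3 <- ifelse(in_utr3, (pos0 - tx$len_utr5 - tx$len_cds) / tx$len_utr3, NA_real_)
      in_head_zone <- pos0 < tx$len_utr5 + ceiling(0.3 * tx$len_cds)

      vivo <- rbeta(total, cfg$beta_shape1, cfg$beta_shape2)
      vitro <- rbeta(total, cfg$beta_shape1, cfg$beta_shape2)
      if (is_high && cfg$scenario == "mesc_like") {
        vivo[in_utr3] <- vivo[in_utr3] + cfg$delta_vivo * front_loaded_weight(u3[in_utr3])
        vitro[in_utr3] <- vitro[in_utr3] - cfg$delta_vitro
      } else if (is_high && cfg$scenario == "zebrafish_like") {
        vivo[in_utr3] <- vivo[in_utr3] + cfg$delta_shared
        vitro[in_utr3] <- vitro[in_utr3] + cfg$delta_shared
        vivo[in_head_zone] <- vivo[in_head_zone] + cfg$delta_head
      }
      vivo <- pmax(vivo, 0)
      vitro <- pmax(vitro, 0)
      if (cfg$missing_rate > 0) {
        vivo[runif(total) < cfg$missing_rate] <- NA_real_
        vitro[runif(total) < cfg$missing_rate] <- NA_real_
      }
      tibble(transcript_id = tx$transcript_id,
             condition = rep(c("vivo", "vitro"), each = total),
             position = rep(seq_len(total), 2L),
             reactivity = c(vivo, vitro))
    })
    bind_rows(per_tx)
  })
}

#' Generate a complete synthetic study dataset
#'
#' One call produces everything the pipeline consumes — transcripts, count
#' tables, reactivity tracks for both conditions — together with the ground
#' truth that generated them.
#'
#' @param cfg A [synthetic_config()].
#' @return A list of class `te_simulation`: `transcripts`, `counts`,
#'   `tracks`, `truth`, `config`.
#' @examples
#' sim <- simulate_te_dataset(synthetic_config("null", n_transcripts = 30, seed = 3))
#' names(sim)
#' @export
simulate_te_dataset <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "te_synthetic_config"))
  truth <- assign_truth(cfg)
  transcripts <- generate_transcripts(cfg, truth)
  counts <- generate_counts(cfg, truth)
  tracks <- generate_reactivity(cfg, truth, transcripts)
  structure(list(transcripts = transcripts, counts = counts, tracks = tracks,
                 truth = truth, config = cfg),
            class = "te_simulation")
}

#' @exportS3Method base::print
print.te_simulation <- function(x, ...) {
  cat(sprintf("<te_simulation> scenario '%s': %d transcripts, seed %d\n",
              x$config$scenario, x$config$n_transcripts, x$config$seed))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Writes `tx.fa`, `regions.tsv`, `counts.tsv`, `vivo.tsv`, `vitro.tsv` and
#' `truth.tsv` in the package's text formats; reading them back with the
#' `read_*` functions reproduces the in-memory objects.
#'
#' @param sim A `te_simulation`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_te_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "te_simulation"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_transcripts(sim$transcripts, file.path(dir, "tx.fa"), file.path(dir, "regions.tsv"))
  write_counts(sim$counts, file.path(dir, "counts.tsv"))
  write_reactivity(filter(sim$tracks, .data$condition == "vivo"), file.path(dir, "vivo.tsv"))
  write_reactivity(filter(sim$tracks, .data$condition == "vitro"), file.path(dir, "vitro.tsv"))
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"), progress = FALSE)
  invisible(dir)
}
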