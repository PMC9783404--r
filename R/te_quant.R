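#' Reads per kilobase per million (RPKM)
#'
#' `count * 1e9 / (length * library_total)`, vectorised over counts and
#' lengths.
#'
#' @param count Non-negative read count(s).
#' @param transcript_length Transcript length(s) in nucleotides, > 0.
#' @param library_total Total mapped reads in the library, > 0.
#' @return Numeric RPKM value(s).
#' @export
compute_rpkm <- function(count, transcript_length, library_total) {
  if (any(transcript_length <= 0)) abort("`transcript_length` must be > 0.")
  if (any(library_total <= 0)) abort("`library_total` must be > 0.")
  if (any(count < 0)) abort("`count` must be >= 0.")
  as.numeric(count) * 1e9 / (as.numeric(transcript_length) * as.numeric(library_total))
}

#' Translation efficiency
#'
#' TE of a transcript is the log2 ratio of ribosome-footprint abundance over
#' mRNA abundance: `log2(rpkm_ribo / rpkm_rna)`. Returns `NA` where either
#' RPKM is zero (such transcripts are excluded rather than assigned an
#' infinite TE).
#'
#' @param rpkm_ribo,rpkm_rna Non-negative RPKM values (vectorised).
#' @return Numeric TE value(s); `NA` where undefined.
#' @export
compute_te <- function(rpkm_ribo, rpkm_rna) {
  if (any(rpkm_ribo < 0) || any(rpkm_rna < 0)) abort("RPKM values must be >= 0.")
  ifelse(rpkm_ribo > 0 & rpkm_rna > 0, log2(rpkm_ribo / rpkm_rna), NA_real_)
}

#' Mark transcripts passing the expression filter
#'
#' Retains transcripts with RNA-seq RPKM strictly greater than the threshold
#' (default 1); the rest are marked `excluded`, which protects TE from the
#' extreme values produced by lowly expressed transcripts. Transcripts with
#' zero ribosome-footprint signal are excluded too (their TE is undefined).
#'
#' @param records Tibble with at least `rpkm_rna`, `rpkm_ribo` and `te`.
#' @param threshold RPKM cutoff, > 0; strict inequality.
#' @return `records` with a `te_class` column: `excluded` below threshold,
#'   `intermediate` otherwise (class labels are assigned later by
#'   [select_te_groups()]).
#' @export
filter_expressed <- function(records, threshold = 1.0) {
  assert_scalar_number(threshold, "threshold", min = 0, strict_min = TRUE)
  assert_columns(records, c("rpkm_rna", "rpkm_ribo", "te"), "Expression table")
  mutate(records, te_class = ifelse(
    .data$rpkm_rna > .env$threshold & !is.na(.data$te), "intermediate", "excluded"
  ))
}

#' Label high- and low-TE classes by TE quantile
#'
#' Ranks transcripts with a defined TE and labels the `floor(q * N)` highest
#' as `high` (positive class) and the `floor(q * N)` lowest as `low`
#' (negative class); everything in between stays `intermediate` and is
#' dropped from downstream modelling. Ties at a quantile boundary are broken
#' by transcript id so runs are deterministic.
#'
#' @param records Expression tibble with `transcript_id`, `te` and `te_class`
#'   (as produced by [filter_expressed()]); rows marked `excluded` are
#'   ignored.
#' @param q Fraction per class, in (0, 0.5); default 0.25 labels the top and
#'   bottom quartiles.
#' @return `records` with `te_class` in `{high, low, intermediate, excluded}`.
#' @export
select_te_groups <- function(records, q = 0.25) {
  assert_scalar_number(q, "q", min = 0, strict_min = TRUE)
  if (q >= 0.5) abort("`q` must be < 0.5 so both classes fit.")
  assert_columns(records, c("transcript_id", "te", "te_class"), "Expression table")
  eligible <- records$te_class != "excluded" & !is.na(records$te)
  n <- sum(eligible)
  if (n < 4L) abort("Need at least 4 transcripts with defined TE to form both classes.")
  k <- floor(q * n)
  if (k < 1L) abort("`q` too small: floor(q * N) is zero.")
  elig <- records[eligible, c("transcript_id", "te")]
  # one ascending ordering keeps the tails disjoint even under heavy ties
  ord <- order(elig$te, elig$transcript_id)
  low_ids <- elig$transcript_id[ord][seq_len(k)]
  high_ids <- elig$transcript_id[ord][seq.int(n - k + 1L, n)]
  mutate(records, te_class = dplyr::case_when(
    .data$transcript_id %in% high_ids ~ "high",
    .data$transcript_id %in% low_ids ~ "low",
    TRUE ~ .data$te_class
  ))
}

#' Quantify translation efficiency and define TE classes
#'
#' End-to-end TE stage: RPKM for both libraries, `TE = log2(RPKM_ribo /
#' RPKM_rna)`, the RNA-seq expression filter, and the top/bottom quantile
#' class labels.
#'
#' @param counts Count tibble from [read_counts()] (or with `ribo_total` /
#'   `rna_total` passed explicitly).
#' @param transcripts Transcript tibble from [read_transcripts()].
#' @param rpkm_threshold RNA-seq RPKM cutoff (strict), default 1.
#' @param q Class fraction per tail, default 0.25.
#' @param length_mode RPKM length denominator: full `"transcript"` length
#'   (default) or `"cds"` length.
#' @param ribo_total,rna_total Library sizes; default to `counts` attributes.
#' @return A tibble with `transcript_id`, `rpkm_ribo`, `rpkm_rna`, `te`,
#'   `te_class`.
#' @examples
#' sim <- simulate_te_dataset(synthetic_config(n_transcripts = 40, seed = 1))
#' quantify_te(sim$counts, sim$transcripts)
#' @export
quantify_te <- function(counts, transcripts, rpkm_threshold = 1.0, q = 0.25,
                        length_mode = c("transcript", "cds"),
                        ribo_total = NULL, rna_total = NULL) {
  length_mode <- match.arg(length_mode)
  ribo_total <- ribo_total %||% attr(counts, "ribo_total")
  rna_total <- rna_total %||% attr(counts, "rna_total")
  if (is.null(ribo_total) || is.null(rna_total)) abort("Library sizes missing.")
  assert_columns(counts, c("transcript_id", "ribo_count", "rna_count"), "Count table")
  assert_columns(transcripts, c("transcript_id", "length", "len_cds"), "Transcript table")

  rec <- inner_join(counts, transcripts[, c("transcript_id", "length", "len_cds")],
                    by = "transcript_id")
  if (nrow(rec) == 0L) abort("No transcript ids shared between counts and transcripts.")
  len <- if (length_mode == "transcript") rec$length else rec$len_cds
  rec <- mutate(rec,
    rpkm_ribo = compute_rpkm(.data$ribo_count, .env$len, .env$ribo_total),
    rpkm_rna = compute_rpkm(.data$rna_count, .env$len, .env$rna_total),
    te = compute_te(.data$rpkm_ribo, .data$rpkm_rna)
  )
  rec <- filter_expressed(rec, threshold = rpkm_threshold)
  rec <- select_te_groups(rec, q = q)
  rec[, c("transcript_id", "rpkm_ribo", "rpkm_rna", "te", "te_class")]
}

#' Labelled high/low subset of a TE table
#'
#' Convenience accessor for the modelling stages: drops `intermediate` and
#' `excluded` transcripts.
#'
#' @param te_table Output of [quantify_te()].
#' @return Tibble with `transcript_id` and `te_class` restricted to
#'   `high`/`low`.
#' @export
te_labels <- function(te_table) {
  assert_columns(te_table, c("transcript_id", "te_class"), "TE table")
  out <- filter(te_table, .data$te_class %in% c("high", "low"))
  out[, c("transcript_id", "te_class")]
}
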