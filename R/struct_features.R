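#' Length-normalised 60-bin metagene reactivity profiles
#'
#' Compresses each transcript's per-nucleotide reactivity track into a fixed
#' number of bins per region (default 20 per region, 60 in total: bins 1-20
#' cover the 5'UTR, 21-40 the CDS, 41-60 the 3'UTR) so transcripts of
#' different lengths share one coordinate system. Within a region of length
#' `L`, bin `k` (0-based within the region) covers nucleotide indices
#' `[floor(k*L/B), floor((k+1)*L/B))` — a deterministic rule that partitions
#' the region exactly — and its value is the mean of the non-missing
#' reactivities it contains. A bin with no nucleotides (region shorter than
#' `B`) or no non-missing values is `NA`.
#'
#' @param tracks Long reactivity tibble ([read_reactivity()] /
#'   [generate_reactivity()]).
#' @param transcripts Transcript tibble; track lengths are validated against
#'   it.
#' @param bins_per_region Bins per region, default 20.
#' @return A long tibble: `transcript_id`, `condition`, `bin` (1-based,
#'   1..3*B), `region` (`utr5`/`cds`/`utr3`), `reactivity`.
#' @export
bin_profile <- function(tracks, transcripts, bins_per_region = 20L) {
  assert_scalar_number(bins_per_region, "bins_per_region", min = 1)
  B <- as.integer(bins_per_region)
  assert_columns(tracks, c("transcript_id", "condition", "position", "reactivity"),
                 "Reactivity table")
  validate_tracks(tracks, transcripts)

  tx <- transcripts[, c("transcript_id", "len_utr5", "len_cds", "len_utr3")]
  dat <- inner_join(tracks, tx, by = "transcript_id")
  # region and 0-based offset within region for every nucleotide
  pos0 <- dat$position - 1L
  in_utr5 <- pos0 < dat$len_utr5
  in_cds <- !in_utr5 & pos0 < dat$len_utr5 + dat$len_cds
  region <- ifelse(in_utr5, "utr5", ifelse(in_cds, "cds", "utr3"))
  offset <- ifelse(in_utr5, pos0,
                   ifelse(in_cds, pos0 - dat$len_utr5, pos0 - dat$len_utr5 - dat$len_cds))
  L <- ifelse(in_utr5, dat$len_utr5, ifelse(in_cds, dat$len_cds, dat$len_utr3))
  # nucleotide at offset o falls in bin k iff floor(kL/B) <= o < floor((k+1)L/B)
  k <- floor(((offset + 1) * B - 1) / L) # inverse of the floor boundary rule
  region_base <- ifelse(in_utr5, 0L, ifelse(in_cds, B, 2L * B))
  dat$bin <- as.integer(region_base + k + 1L)
  dat$region <- region

  binned <- summarise(
    group_by(dat, .data$transcript_id, .data$condition, .data$bin, .data$region),
    reactivity = if (all(is.na(.data$reactivity))) NA_real_ else
      mean(.data$reactivity, na.rm = TRUE),
    .groups = "drop"
  )
  # complete to the full 3B-bin grid so empty bins appear as NA
  grid <- tidyr::expand_grid(
    distinct(tracks[, c("transcript_id", "condition")]),
    bin = seq_len(3L * B)
  )
  grid$region <- rep(region_levels, each = B)[grid$bin]
  out <- left_join(grid, binned, by = c("transcript_id", "condition", "bin", "region"))
  arrange(out, .data$transcript_id, .data$condition, .data$bin)
}

#' Mean reactivity over the CDS head
#'
#' The CDS head is the first `n_codons` codons (default 6, i.e. 18 nt) of the
#' coding region — the window classically tied to initiation-limited
#' translation. Returns the mean of the non-missing reactivities over those
#' nucleotides; `NA` when the CDS is shorter than the head or the head is
#' entirely missing.
#'
#' @inheritParams bin_profile
#' @param n_codons Number of codons in the head, default 6.
#' @return Tibble `transcript_id`, `condition`, `cds_head_reactivity`.
#' @export
cds_head_reactivity <- function(tracks, transcripts, n_codons = 6L) {
  assert_scalar_number(n_codons, "n_codons", min = 1)
  head_nt <- 3L * as.integer(n_codons)
  validate_tracks(tracks, transcripts)
  dat <- inner_join(tracks, transcripts[, c("transcript_id", "len_utr5", "len_cds")],
                    by = "transcript_id")
  dat <- filter(dat,
                .data$len_cds >= .env$head_nt,
                .data$position > .data$len_utr5,
                .data$position <= .data$len_utr5 + .env$head_nt)
  out <- summarise(group_by(dat, .data$transcript_id, .data$condition),
                   cds_head_reactivity = if (all(is.na(.data$reactivity))) NA_real_ else
                     mean(.data$reactivity, na.rm = TRUE),
                   .groups = "drop")
  # transcripts with too short a CDS drop out of `dat`; reinstate as NA
  grid <- distinct(tracks[, c("transcript_id", "condition")])
  left_join(grid, out, by = c("transcript_id", "condition"))
}

#' Minimum free energy by base-pair maximisation
#'
#' Built-in folding model: Nussinov dynamic programming that maximises the
#' number of nested Watson-Crick or G-U wobble pairs subject to a minimum
#' hairpin loop of `min_loop` unpaired nucleotides, with an energy of -1 per
#' pair. It is a deliberately simple, exhaustively testable model; outputs
#' from a thermodynamic folding tool can replace it via
#' [import_external_mfe()].
#'
#' @param seq Character vector of sequences (DNA or RNA alphabet).
#' @param min_loop Minimum number of unpaired nucleotides in a hairpin loop,
#'   default 3.
#' @return Numeric vector of energies, `-(maximum number of pairs)`, each
#'   <= 0. Sequences too short to pair fold to 0.
#' @examples
#' fold_mfe(c("AAAAA", "GGGAAACCC"))
#' @export
fold_mfe <- function(seq, min_loop = 3L) {
  assert_scalar_number(min_loop, "min_loop", min = 0)
  seq <- gsub("U", "T", toupper(as.character(seq)), fixed = TRUE)
  nussinov_energy_cpp(seq, as.integer(min_loop))
}

mfe_scopes <- c("whole", "utr5", "cds", "utr3", "cds_head")

#' In-silico folding-energy features per transcript
#'
#' Folds five scopes of each transcript — the whole transcript, the three
#' regions, and the CDS head (first `n_codons` codons) — and reports the raw
#' energy plus the per-nucleotide (length-normalised) energy for each, ten
#' features in total. Empty scopes yield `NA`.
#'
#' @param transcripts Transcript tibble.
#' @param min_loop Passed to [fold_mfe()].
#' @param n_codons CDS-head size in codons, default 6.
#' @return Tibble `transcript_id` plus `mfe_<scope>` and
#'   `mfe_<scope>_per_nt` columns.
#' @export
mfe_features <- function(transcripts, min_loop = 3L, n_codons = 6L) {
  assert_columns(transcripts, c("transcript_id", "sequence", "len_utr5", "len_cds", "len_utr3"),
                 "Transcript table")
  head_nt <- 3L * as.integer(n_codons)
  out <- tibble(transcript_id = transcripts$transcript_id)
  for (s in mfe_scopes) {
    subseqs <- mapply(scope_sequence, transcripts$sequence, transcripts$len_utr5,
                      transcripts$len_cds, transcripts$len_utr3,
                      MoreArgs = list(scope = s, head_nt = head_nt), USE.NAMES = FALSE)
    lens <- nchar(subseqs)
    e <- ifelse(lens == 0L, NA_real_, fold_mfe(subseqs, min_loop = min_loop))
    out[[paste0("mfe_", s)]] <- e
    out[[paste0("mfe_", s, "_per_nt")]] <- ifelse(lens == 0L, NA_real_, e / lens)
  }
  out
}

#' Import folding energies from an external folding tool
#'
#' Replaces the built-in base-pair-maximisation energies with
#' thermodynamic-model energies (kcal/mol) computed outside the package,
#' e.g. by RNAfold. The table must be tab-delimited with a `transcript_id`
#' column plus one column per scope named `mfe_<scope>` for scopes `whole`,
#' `utr5`, `cds`, `utr3`, `cds_head`; per-nucleotide variants are derived
#' from the supplied `len_*` columns of `transcripts`.
#'
#' @param table_path Path to the energy table.
#' @param transcripts Transcript tibble (for scope lengths).
#' @param n_codons CDS-head size in codons, default 6.
#' @return Tibble in the same shape as [mfe_features()].
#' @export
import_external_mfe <- function(table_path, transcripts, n_codons = 6L) {
  if (!file.exists(table_path)) abort(sprintf("MFE table not found: %s", table_path))
  tab <- readr::read_tsv(table_path, show_col_types = FALSE, progress = FALSE)
  cols <- paste0("mfe_", mfe_scopes)
  assert_columns(tab, c("transcript_id", cols), "External MFE table")
  for (col in cols) {
    if (any(tab[[col]] > 0, na.rm = TRUE)) {
      abort(sprintf("Positive energies in column `%s`: MFE must be <= 0.", col))
    }
  }
  head_nt <- 3L * as.integer(n_codons)
  tab <- inner_join(tab[, c("transcript_id", cols)],
                    transcripts[, c("transcript_id", "len_utr5", "len_cds", "len_utr3")],
                    by = "transcript_id")
  lens <- list(whole = tab$len_utr5 + tab$len_cds + tab$len_utr3,
               utr5 = tab$len_utr5, cds = tab$len_cds, utr3 = tab$len_utr3,
               cds_head = ifelse(tab$len_cds >= head_nt, head_nt, 0L))
  out <- tibble(transcript_id = tab$transcript_id)
  for (s in mfe_scopes) {
    e <- tab[[paste0("mfe_", s)]]
    out[[paste0("mfe_", s)]] <- ifelse(lens[[s]] == 0L, NA_real_, e)
    out[[paste0("mfe_", s, "_per_nt")]] <- ifelse(lens[[s]] == 0L, NA_real_, e / lens[[s]])
  }
  out
}

#' Assemble the structural feature table
#'
#' Combines the 60-bin metagene profiles of both probing conditions, the
#' CDS-head reactivities, and the in-silico folding energies into one wide
#' feature table. The default census is 132 structural features: 60 in vivo
#' bins + 60 in vitro bins + 2 CDS-head reactivities + 10 folding-energy
#' features. A transcript missing a condition's track simply carries `NA`s
#' in that condition's columns (flagged for training-time imputation).
#'
#' @param profiles Long bin-profile tibble from [bin_profile()] (both
#'   conditions stacked).
#' @param heads CDS-head tibble from [cds_head_reactivity()].
#' @param mfe MFE tibble from [mfe_features()] or [import_external_mfe()].
#' @return Wide tibble, `transcript_id` plus named feature columns, with a
#'   `feature_groups` attribute mapping each feature to `vivo`, `vitro` or
#'   `insilico`.
#' @export
assemble_structural_features <- function(profiles, heads, mfe) {
  assert_columns(profiles, c("transcript_id", "condition", "bin", "reactivity"),
                 "Bin profiles")
  n_bins <- max(profiles$bin)
  wide <- tidyr::pivot_wider(
    mutate(profiles, name = sprintf("%s_bin_%02d", .data$condition, .data$bin)),
    id_cols = "transcript_id", names_from = "name", values_from = "reactivity"
  )
  head_wide <- tidyr::pivot_wider(
    mutate(heads, name = paste0(.data$condition, "_cds_head")),
    id_cols = "transcript_id", names_from = "name", values_from = "cds_head_reactivity"
  )
  bin_names <- as.vector(outer(sprintf("_bin_%02d", seq_len(n_bins)),
                               c("vivo", "vitro"),
                               function(b, cond) paste0(cond, b)))
  want <- c(bin_names, "vivo_cds_head", "vitro_cds_head")
  out <- left_join(wide, head_wide, by = "transcript_id")
  for (nm in setdiff(want, names(out))) out[[nm]] <- NA_real_
  out <- left_join(out[, c("transcript_id", want)], mfe, by = "transcript_id")
  mfe_names <- setdiff(names(mfe), "transcript_id")
  groups <- tibble(
    feature = c(want, mfe_names),
    group = c(ifelse(startsWith(want, "vivo"), "vivo", "vitro"),
              rep("insilico", length(mfe_names)))
  )
  attr(out, "feature_groups") <- groups
  out
}

#' Join feature tables into one modelling matrix
#'
#' Joins wide feature tables by `transcript_id` and concatenates their
#' `feature_groups` attributes, preserving the group registry the importance
#' analysis needs.
#'
#' @param ... Two or more wide feature tibbles carrying a `feature_groups`
#'   attribute.
#' @return A single wide tibble with the merged `feature_groups` attribute.
#' @export
combine_features <- function(...) {
  tabs <- list(...)
  if (length(tabs) < 1L) abort("Nothing to combine.")
  out <- tabs[[1L]]
  groups <- attr(out, "feature_groups")
  if (is.null(groups)) abort("Inputs must carry a `feature_groups` attribute.")
  for (tab in tabs[-1L]) {
    g <- attr(tab, "feature_groups")
    if (is.null(g)) abort("Inputs must carry a `feature_groups` attribute.")
    out <- inner_join(out, tab, by = "transcript_id")
    groups <- bind_rows(groups, g)
  }
  if (anyDuplicated(groups$feature)) abort("Duplicate feature names across tables.")
  attr(out, "feature_groups") <- groups
  out
}
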