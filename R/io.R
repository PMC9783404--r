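#' Read transcript models from FASTA plus a region table
#'
#' Builds the transcript coordinate frame used by every downstream feature:
#' each transcript is a contiguous 5'UTR -> CDS -> 3'UTR arrangement in
#' transcript coordinates. Sequences are canonicalised to the DNA alphabet
#' (`U` becomes `T`, case-folded to upper case); the only letters accepted are
#' `A`, `C`, `G`, `T`/`U`, `N`.
#'
#' Records violating the transcript invariants (region lengths must sum to the
#' sequence length; a non-empty CDS must be a multiple of 3) are rejected
#' individually with a logged reason. Ids present in only one of the two
#' inputs are a hard error.
#'
#' @param fasta_path Path to a FASTA file of transcript sequences.
#' @param regions_path Path to a tab-delimited region table with header
#'   `transcript_id`, `len_utr5`, `len_cds`, `len_utr3` (lengths in
#'   nucleotides; 0-based half-open region coordinates are implied:
#'   5'UTR = `[0, len_utr5)`, CDS = `[len_utr5, len_utr5+len_cds)`).
#' @param verbose Emit per-record rejection messages.
#' @return A tibble with columns `transcript_id`, `sequence`, `len_utr5`,
#'   `len_cds`, `len_utr3`, `length`, one row per validated transcript.
#' @export
read_transcripts <- function(fasta_path, regions_path, verbose = TRUE) {
  if (!file.exists(fasta_path)) abort(sprintf("FASTA file not found: %s", fasta_path))
  if (!file.exists(regions_path)) abort(sprintf("Region table not found: %s", regions_path))

  seqs <- Biostrings::readBStringSet(fasta_path)
  seq_tbl <- tibble(
    transcript_id = sub("\\s.*$", "", names(seqs)),
    sequence = unname(toupper(as.character(seqs)))
  )
  seq_tbl$sequence <- gsub("U", "T", seq_tbl$sequence, fixed = TRUE)
  bad_alpha <- grepl("[^ACGTN]", seq_tbl$sequence)
  if (any(bad_alpha)) {
    abort(sprintf(
      "Sequences with letters outside {A,C,G,T,U,N}: %s",
      paste(seq_tbl$transcript_id[bad_alpha], collapse = ", ")
    ))
  }

  regions <- readr::read_tsv(regions_path, show_col_types = FALSE, progress = FALSE)
  assert_columns(regions, c("transcript_id", "len_utr5", "len_cds", "len_utr3"), "Region table")

  only_fasta <- setdiff(seq_tbl$transcript_id, regions$transcript_id)
  only_regions <- setdiff(regions$transcript_id, seq_tbl$transcript_id)
  if (length(only_fasta) > 0 || length(only_regions) > 0) {
    abort(sprintf(
      "Transcript ids present in only one input. FASTA-only: %s; region-table-only: %s",
      paste(only_fasta, collapse = ", "), paste(only_regions, collapse = ", ")
    ))
  }

  tx <- inner_join(seq_tbl, regions, by = "transcript_id")
  tx <- mutate(tx,
    across(all_of(c("len_utr5", "len_cds", "len_utr3")), as.integer),
    length = nchar(.data$sequence)
  )
  validate_transcripts(tx, verbose = verbose)
}

# applies the TranscriptModel invariants row-wise; drops offenders with a reason
validate_transcripts <- function(tx, verbose = TRUE) {
  bad_len <- with(tx, len_utr5 + len_cds + len_utr3 != length)
  bad_neg <- with(tx, len_utr5 < 0 | len_cds < 0 | len_utr3 < 0)
  bad_cds <- with(tx, len_cds > 0 & len_cds %% 3L != 0L)
  reject <- bad_len | bad_neg | bad_cds
  if (any(reject)) {
    reason <- dplyr::case_when(
      bad_neg ~ "negative region length",
      bad_len ~ "region lengths do not sum to sequence length",
      bad_cds ~ "CDS length not a multiple of 3"
    )[reject]
    for (i in seq_along(reason)) {
      log_msg(verbose, "rejected transcript %s: %s", tx$transcript_id[reject][i], reason[i])
    }
    log_msg(verbose, "rejected %d of %d transcripts", sum(reject), nrow(tx))
  }
  out <- tx[!reject, , drop = FALSE]
  attr(out, "n_rejected") <- sum(reject)
  out
}

#' Write transcript models to FASTA plus a region table
#'
#' Inverse of [read_transcripts()]; a write followed by a read reproduces the
#' input field for field.
#'
#' @param transcripts Transcript tibble as returned by [read_transcripts()].
#' @param fasta_path,regions_path Output paths.
#' @export
write_transcripts <- function(transcripts, fasta_path, regions_path) {
  assert_columns(transcripts, c("transcript_id", "sequence", "len_utr5", "len_cds", "len_utr3"),
                 "Transcript table")
  seqs <- Biostrings::DNAStringSet(transcripts$sequence)
  names(seqs) <- transcripts$transcript_id
  Biostrings::writeXStringSet(seqs, fasta_path, width = 70L)
  readr::write_tsv(
    transcripts[, c("transcript_id", "len_utr5", "len_cds", "len_utr3")],
    regions_path, progress = FALSE
  )
  invisible(transcripts)
}

#' Read a per-nucleotide reactivity track file
#'
#' The track format is tab-delimited: `transcript_id` TAB comma-separated
#' per-nucleotide reactivities ordered 5' to 3', with the (case-insensitive)
#' token `NA` marking missing values. Reactivities are chemical-probing
#' accessibilities and must be non-negative.
#'
#' @param track_path Path to the track file (no header).
#' @param condition `"vivo"` (probing in living cells) or `"vitro"`
#'   (refolded RNA probed outside cells).
#' @return A long tibble with columns `transcript_id`, `condition`,
#'   `position` (1-based), `reactivity` (`NA` where missing).
#' @export
read_reactivity <- function(track_path, condition = c("vivo", "vitro")) {
  condition <- match.arg(condition)
  if (!file.exists(track_path)) abort(sprintf("Track file not found: %s", track_path))
  lines <- readr::read_lines(track_path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) abort(sprintf("Track file is empty: %s", track_path))
  parts <- stringr::str_split_fixed(lines, "\t", 2L)
  if (any(!nzchar(parts[, 2L]))) {
    abort(sprintf(
      "Empty reactivity track for transcript(s): %s",
      paste(parts[!nzchar(parts[, 2L]), 1L], collapse = ", ")
    ))
  }
  values <- stringr::str_split(parts[, 2L], ",")
  out <- tibble(
    transcript_id = rep(parts[, 1L], lengths(values)),
    condition = condition,
    reactivity = suppressWarnings(as.numeric(ifelse(
      toupper(trimws(unlist(values))) == "NA", NA_character_, trimws(unlist(values))
    )))
  )
  bad_token <- is.na(out$reactivity) & toupper(trimws(unlist(values))) != "NA"
  if (any(bad_token)) {
    abort(sprintf(
      "Unparseable reactivity values for transcript(s): %s",
      paste(unique(out$transcript_id[bad_token]), collapse = ", ")
    ))
  }
  if (any(out$reactivity < 0, na.rm = TRUE)) {
    abort(sprintf(
      "Negative reactivity values for transcript(s): %s",
      paste(unique(out$transcript_id[!is.na(out$reactivity) & out$reactivity < 0]), collapse = ", ")
    ))
  }
  out <- group_by(out, .data$transcript_id)
  out <- mutate(out, position = row_number())
  ungroup(out)[, c("transcript_id", "condition", "position", "reactivity")]
}

#' Write a reactivity track file
#'
#' @param tracks Long reactivity tibble as returned by [read_reactivity()];
#'   must hold a single condition.
#' @param track_path Output path.
#' @export
write_reactivity <- function(tracks, track_path) {
  assert_columns(tracks, c("transcript_id", "position", "reactivity"), "Reactivity table")
  if ("condition" %in% names(tracks) && length(unique(tracks$condition)) > 1L) {
    abort("write_reactivity() writes one condition per file; filter first.")
  }
  tracks <- arrange(tracks, .data$transcript_id, .data$position)
  by_tx <- split(tracks$reactivity, tracks$transcript_id)
  lines <- vapply(names(by_tx), function(id) {
    vals <- by_tx[[id]]
    paste0(id, "\t", paste(ifelse(is.na(vals), "NA", format(vals, trim = TRUE, digits = 15)),
                           collapse = ","))
  }, character(1))
  readr::write_lines(lines, track_path)
  invisible(tracks)
}

#' Check reactivity tracks against transcript lengths
#'
#' Every track must have exactly one value per nucleotide of its transcript.
#' Tracks for unknown transcripts, and transcripts whose track length
#' mismatches, are a hard error.
#'
#' @param tracks Long reactivity tibble.
#' @param transcripts Transcript tibble.
#' @return `tracks`, invisibly, on success.
#' @export
validate_tracks <- function(tracks, transcripts) {
  lens <- summarise(group_by(tracks, .data$transcript_id, .data$condition),
                    track_len = n(), .groups = "drop")
  lens <- left_join(lens, transcripts[, c("transcript_id", "length")], by = "transcript_id")
  if (any(is.na(lens$length))) {
    abort(sprintf(
      "Reactivity tracks for unknown transcript(s): %s",
      paste(unique(lens$transcript_id[is.na(lens$length)]), collapse = ", ")
    ))
  }
  bad <- lens$track_len != lens$length
  if (any(bad)) {
    abort(sprintf(
      "Track length does not match transcript length for: %s",
      paste(sprintf("%s/%s (%d vs %d)", lens$transcript_id[bad], lens$condition[bad],
                    lens$track_len[bad], lens$length[bad]), collapse = ", ")
    ))
  }
  invisible(tracks)
}

#' Read a per-transcript read-count table
#'
#' Expects a tab-delimited file with header `transcript_id`, `ribo_count`,
#' `rna_count` and library sizes either in a leading comment line
#' `#ribo_total=<int> rna_total=<int>` or supplied as arguments (arguments
#' win). Counts must be non-negative integers; totals must be positive.
#'
#' @param counts_path Path to the count table.
#' @param ribo_total,rna_total Optional library sizes overriding the header
#'   comment.
#' @return A tibble with columns `transcript_id`, `ribo_count`, `rna_count`
#'   and attributes `ribo_total`, `rna_total`.
#' @export
read_counts <- function(counts_path, ribo_total = NULL, rna_total = NULL) {
  if (!file.exists(counts_path)) abort(sprintf("Count table not found: %s", counts_path))
  first <- readr::read_lines(counts_path, n_max = 1L, progress = FALSE)
  if (startsWith(first, "#")) {
    m_ribo <- stringr::str_match(first, "ribo_total=([0-9]+)")[, 2L]
    m_rna <- stringr::str_match(first, "rna_total=([0-9]+)")[, 2L]
    if (is.null(ribo_total) && !is.na(m_ribo)) ribo_total <- as.numeric(m_ribo)
    if (is.null(rna_total) && !is.na(m_rna)) rna_total <- as.numeric(m_rna)
  }
  if (is.null(ribo_total) || is.null(rna_total)) {
    abort("Library sizes missing: supply ribo_total/rna_total or a '#ribo_total=... rna_total=...' header line.")
  }
  assert_scalar_number(ribo_total, "ribo_total", min = 0, strict_min = TRUE)
  assert_scalar_number(rna_total, "rna_total", min = 0, strict_min = TRUE)

  counts <- readr::read_tsv(counts_path, comment = "#", show_col_types = FALSE, progress = FALSE)
  assert_columns(counts, c("transcript_id", "ribo_count", "rna_count"), "Count table")
  for (col in c("ribo_count", "rna_count")) {
    v <- counts[[col]]
    if (!is.numeric(v) || any(is.na(v)) || any(v < 0) || any(v != floor(v))) {
      abort(sprintf("Column `%s` must contain non-negative integers.", col))
    }
    counts[[col]] <- as.integer(v)
  }
  out <- as_tibble(counts[, c("transcript_id", "ribo_count", "rna_count")])
  attr(out, "ribo_total") <- ribo_total
  attr(out, "rna_total") <- rna_total
  out
}

#' Write a per-transcript read-count table
#'
#' @param counts Count tibble with `ribo_total`/`rna_total` attributes (or
#'   supplied explicitly).
#' @param counts_path Output path.
#' @param ribo_total,rna_total Library sizes; default to the tibble's
#'   attributes.
#' @export
write_counts <- function(counts, counts_path, ribo_total = NULL, rna_total = NULL) {
  ribo_total <- ribo_total %||% attr(counts, "ribo_total")
  rna_total <- rna_total %||% attr(counts, "rna_total")
  if (is.null(ribo_total) || is.null(rna_total)) abort("Library sizes missing on write.")
  header <- sprintf("#ribo_total=%d rna_total=%d", as.integer(ribo_total), as.integer(rna_total))
  readr::write_lines(header, counts_path)
  readr::write_tsv(counts[, c("transcript_id", "ribo_count", "rna_count")],
                   counts_path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(counts)
}
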