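# sequence feature families: frequencies, GC, repetitive rates, lengths

CODONS <- as.vector(outer(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                paste0), c("A", "C", "G", "T"), paste0))
AA_SYMBOLS <- c(sort(setdiff(unique(Biostrings::GENETIC_CODE), "*")), "*")

#' Nucleotide frequencies of a sequence
#'
#' Fraction of each of A, C, G, T; `N` bases are dropped from both numerator
#' and denominator.
#'
#' @param seq A single DNA-alphabet sequence string.
#' @return Named numeric of length 4 (A, C, G, T); all `NA` for an empty (or
#'   all-`N`) sequence.
#' @export
nucleotide_frequency <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  chars <- chars[chars != "N"]
  if (length(chars) == 0L) {
    return(setNames(rep(NA_real_, 4L), c("A", "C", "G", "T")))
  }
  counts <- table(factor(chars, levels = c("A", "C", "G", "T")))
  as.vector(counts) / length(chars) -> freq
  setNames(freq, c("A", "C", "G", "T"))
}

#' GC content of a sequence
#'
#' `(G + C) / (A + C + G + T)`; `N` bases are excluded.
#'
#' @inheritParams nucleotide_frequency
#' @return A single fraction in `[0, 1]`, or `NA` for an empty sequence.
#' @export
gc_content <- function(seq) {
  f <- nucleotide_frequency(seq)
  if (anyNA(f)) NA_real_ else unname(f["G"] + f["C"])
}

# in-frame codon list of a CDS
split_codons <- function(cds) {
  n <- nchar(cds)
  if (n == 0L || n %% 3L != 0L) abort("CDS must be a non-empty multiple of 3.")
  substring(cds, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

#' In-frame codon frequencies of a CDS
#'
#' Each of the 64 codons as a fraction of the `len/3` in-frame codons; codons
#' containing `N` are dropped from both numerator and denominator.
#'
#' @param cds A CDS sequence (length a positive multiple of 3).
#' @return Named numeric of length 64 summing to 1.
#' @export
codon_frequency <- function(cds) {
  codons <- split_codons(toupper(cds))
  codons <- codons[!grepl("N", codons)]
  if (length(codons) == 0L) return(setNames(rep(NA_real_, 64L), CODONS))
  counts <- table(factor(codons, levels = CODONS))
  setNames(as.vector(counts) / length(codons), CODONS)
}

#' Amino-acid frequencies of a CDS
#'
#' Translation by the standard genetic code; the stop signal `*` is counted
#' as a 21st symbol.
#'
#' @inheritParams codon_frequency
#' @return Named numeric of length 21 summing to 1.
#' @export
amino_acid_frequency <- function(cds) {
  codons <- split_codons(toupper(cds))
  codons <- codons[!grepl("N", codons)]
  if (length(codons) == 0L) return(setNames(rep(NA_real_, 21L), AA_SYMBOLS))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  counts <- table(factor(aa, levels = AA_SYMBOLS))
  setNames(as.vector(counts) / length(aa), AA_SYMBOLS)
}

#' Repetitive rate of a symbol list
#'
#' Fraction of adjacent identical pairs: `(# positions i with s[i] ==
#' s[i+1]) / (length - 1)`. Applied to the in-frame codon list for the codon
#' repetitive rate and to the translated amino-acid list for the amino-acid
#' repetitive rate. Equals 1 iff all symbols are identical and 0 iff no two
#' neighbours repeat.
#'
#' @param symbols Character vector of symbols, length >= 2 for a defined
#'   value.
#' @return A fraction in `[0, 1]`, or `NA` when fewer than 2 symbols.
#' @export
repetitive_rate <- function(symbols) {
  n <- length(symbols)
  if (n < 2L) return(NA_real_)
  sum(symbols[-n] == symbols[-1L]) / (n - 1L)
}

#' Region length features of a transcript
#'
#' @param len_utr5,len_cds,len_utr3 Region lengths in nucleotides.
#' @return Named numeric: `len_utr5`, `len_cds`, `len_utr3`, `len_total`.
#' @export
length_features <- function(len_utr5, len_cds, len_utr3) {
  c(len_utr5 = as.numeric(len_utr5), len_cds = as.numeric(len_cds),
    len_utr3 = as.numeric(len_utr3), len_total = as.numeric(len_utr5 + len_cds + len_utr3))
}

#' Default sequence-feature registry
#'
#' The registry fixes which feature families are computed and how features
#' map to importance groups. The default census is 111 sequence features:
#' nucleotide frequency over 4 scopes (16), GC content over 4 scopes (4),
#' codon frequency (64), amino-acid frequency (21), codon and amino-acid
#' repetitive rates (2), and region lengths (4).
#'
#' @param families Character vector of enabled families, any of
#'   `"nucleotide_frequency"`, `"gc_content"`, `"codon_frequency"`,
#'   `"amino_acid_frequency"`, `"codon_repeat_rate"`, `"aa_repeat_rate"`,
#'   `"lengths"`.
#' @param scopes Scopes for the nucleotide-frequency and GC families.
#' @return An object of class `te_feature_registry`.
#' @export
sequence_registry <- function(families = c("nucleotide_frequency", "gc_content",
                                           "codon_frequency", "amino_acid_frequency",
                                           "codon_repeat_rate", "aa_repeat_rate",
                                           "lengths"),
                              scopes = c("whole", "utr5", "cds", "utr3")) {
  known <- c("nucleotide_frequency", "gc_content", "codon_frequency",
             "amino_acid_frequency", "codon_repeat_rate", "aa_repeat_rate", "lengths")
  unknown <- setdiff(families, known)
  if (length(unknown) > 0) {
    abort(sprintf("Unknown feature family: %s", paste(unknown, collapse = ", ")))
  }
  scopes <- match.arg(scopes, several.ok = TRUE)
  structure(list(families = families, scopes = scopes), class = "te_feature_registry")
}

# feature-name census for a registry, in deterministic order
sequence_feature_names <- function(registry) {
  out <- character(0)
  fam <- registry$families
  if ("nucleotide_frequency" %in% fam) {
    out <- c(out, as.vector(t(outer(registry$scopes, c("A", "C", "G", "T"),
                                    function(s, b) paste0("nt_freq_", s, "_", b)))))
  }
  if ("gc_content" %in% fam) out <- c(out, paste0("gc_", registry$scopes))
  if ("codon_frequency" %in% fam) out <- c(out, paste0("codon_freq_", CODONS))
  if ("amino_acid_frequency" %in% fam) {
    out <- c(out, paste0("aa_freq_", sub("\\*", "stop", AA_SYMBOLS)))
  }
  if ("codon_repeat_rate" %in% fam) out <- c(out, "codon_repeat_rate")
  if ("aa_repeat_rate" %in% fam) out <- c(out, "aa_repeat_rate")
  if ("lengths" %in% fam) out <- c(out, c("len_utr5", "len_cds", "len_utr3", "len_total"))
  out
}

# one transcript -> named numeric vector of sequence features
sequence_features_one <- function(sequence, len_utr5, len_cds, len_utr3, registry) {
  fam <- registry$families
  vals <- numeric(0)
  if (any(c("nucleotide_frequency", "gc_content") %in% fam)) {
    for (s in registry$scopes) {
      sub_seq <- scope_sequence(sequence, len_utr5, len_cds, len_utr3, s)
      if ("nucleotide_frequency" %in% fam) {
        f <- nucleotide_frequency(sub_seq)
        vals <- c(vals, setNames(unname(f), paste0("nt_freq_", s, "_", names(f))))
      }
      if ("gc_content" %in% fam) {
        vals <- c(vals, setNames(gc_content(sub_seq), paste0("gc_", s)))
      }
    }
  }
  cds <- scope_sequence(sequence, len_utr5, len_cds, len_utr3, "cds")
  has_cds <- nchar(cds) > 0L && nchar(cds) %% 3L == 0L
  codons <- if (has_cds) split_codons(cds) else character(0)
  if ("codon_frequency" %in% fam) {
    f <- if (has_cds) codon_frequency(cds) else setNames(rep(NA_real_, 64L), CODONS)
    vals <- c(vals, setNames(unname(f), paste0("codon_freq_", names(f))))
  }
  if ("amino_acid_frequency" %in% fam) {
    f <- if (has_cds) amino_acid_frequency(cds) else setNames(rep(NA_real_, 21L), AA_SYMBOLS)
    vals <- c(vals, setNames(unname(f), paste0("aa_freq_", sub("\\*", "stop", names(f)))))
  }
  if ("codon_repeat_rate" %in% fam) {
    vals <- c(vals, codon_repeat_rate = repetitive_rate(codons))
  }
  if ("aa_repeat_rate" %in% fam) {
    aa <- if (has_cds) unname(Biostrings::GENETIC_CODE[codons[!grepl("N", codons)]]) else character(0)
    vals <- c(vals, aa_repeat_rate = repetitive_rate(aa))
  }
  if ("lengths" %in% fam) {
    vals <- c(vals, length_features(len_utr5, len_cds, len_utr3))
  }
  vals[sequence_feature_names(registry)]
}

#' Assemble the sequence feature table
#'
#' Pure function of the transcript table and the registry: the same inputs
#' always produce the same feature matrix, column for column. Features whose
#' scope is empty (e.g. a transcript without a 5'UTR) are `NA` and left for
#' training-time median imputation.
#'
#' @param transcripts Transcript tibble from [read_transcripts()] or
#'   [generate_transcripts()].
#' @param registry Registry from [sequence_registry()].
#' @return A wide tibble, `transcript_id` plus one column per feature, with a
#'   `feature_groups` attribute (tibble `feature`, `group`; all `"sequence"`
#'   here) consumed by the importance analysis.
#' @export
assemble_sequence_features <- function(transcripts, registry = sequence_registry()) {
  assert_columns(transcripts, c("transcript_id", "sequence", "len_utr5", "len_cds", "len_utr3"),
                 "Transcript table")
  if (!inherits(registry, "te_feature_registry")) abort("`registry` must come from sequence_registry().")
  feat_names <- sequence_feature_names(registry)
  mat <- t(mapply(sequence_features_one,
                  transcripts$sequence, transcripts$len_utr5,
                  transcripts$len_cds, transcripts$len_utr3,
                  MoreArgs = list(registry = registry), USE.NAMES = FALSE))
  colnames(mat) <- feat_names
  out <- bind_cols(tibble(transcript_id = transcripts$transcript_id), as_tibble(mat))
  attr(out, "feature_groups") <- tibble(feature = feat_names, group = "sequence")
  out
}
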