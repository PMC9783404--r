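# fixtures are built in code at test time

# a hand-sized transcript table with known region arithmetic
make_toy_transcripts <- function() {
  tibble::tibble(
    transcript_id = c("t1", "t2"),
    sequence = c(
      paste0(strrep("A", 20), "ATG", strrep("GAC", 6), "TAA", strrep("T", 22)),
      paste0(strrep("C", 10), "ATG", strrep("TTT", 8), "TGA", strrep("G", 14))
    ),
    len_utr5 = c(20L, 10L),
    len_cds = c(24L, 30L),
    len_utr3 = c(22L, 14L)
  ) |>
    dplyr::mutate(length = len_utr5 + len_cds + len_utr3)
}

# constant-valued reactivity tracks for a transcript table
make_constant_tracks <- function(transcripts, value = 0.5,
                                 conditions = c("vivo", "vitro")) {
  purrr::map_dfr(conditions, function(cond) {
    purrr::map_dfr(seq_len(nrow(transcripts)), function(i) {
      tibble::tibble(
        transcript_id = transcripts$transcript_id[i],
        condition = cond,
        position = seq_len(transcripts$length[i]),
        reactivity = value
      )
    })
  })
}

# brute-force two-sample KS oracle: statistic from pooled ECDFs, exact p by
# enumerating every assignment of pooled values to the two samples
ks_oracle <- function(x, y) {
  D_of <- function(xx, yy) {
    grid <- sort(unique(c(xx, yy)))
    Fx <- vapply(grid, function(g) mean(xx <= g), numeric(1))
    Fy <- vapply(grid, function(g) mean(yy <= g), numeric(1))
    max(abs(Fx - Fy))
  }
  n <- length(x)
  pooled <- c(x, y)
  D_obs <- D_of(x, y)
  combos <- utils::combn(length(pooled), n)
  d_all <- apply(combos, 2L, function(idx) D_of(pooled[idx], pooled[-idx]))
  list(D = D_obs, p = mean(d_all >= D_obs - 1e-12))
}

# brute-force folding oracle: recursively enumerate every nested structure
# with hairpin loops >= min_loop and report the maximum pair count
fold_oracle_pairs <- function(seq, min_loop = 3L) {
  s <- strsplit(gsub("U", "T", toupper(seq), fixed = TRUE), "")[[1]]
  pairable <- function(a, b) {
    paste0(a, b) %in% c("AT", "TA", "GC", "CG", "GT", "TG")
  }
  rec <- function(i, j) {
    if (j - i < min_loop + 1L) return(0L)
    best <- rec(i + 1L, j) # i unpaired
    for (k in (i + min_loop + 1L):j) {
      if (pairable(s[i], s[k])) {
        left <- if (k - 1L >= i + 1L) rec(i + 1L, k - 1L) else 0L
        right <- if (j >= k + 1L) rec(k + 1L, j) else 0L
        best <- max(best, 1L + left + right)
      }
    }
    best
  }
  if (length(s) < 2L) return(0L)
  rec(1L, length(s))
}

# random sequence helper
random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")
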