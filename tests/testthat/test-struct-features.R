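test_that("binning a constant track gives 60 constant bins", {
  tx <- tibble::tibble(transcript_id = "t1",
                       sequence = strrep("A", 61),
                       len_utr5 = 20L, len_cds = 21L, len_utr3 = 20L, length = 61L)
  tracks <- make_constant_tracks(tx, 0.5, conditions = "vivo")
  prof <- bin_profile(tracks, tx)
  expect_equal(nrow(prof), 60L)
  expect_equal(prof$reactivity, rep(0.5, 60))
  expect_equal(prof$region, rep(c("utr5", "cds", "utr3"), each = 20))
  expect_equal(prof$bin, 1:60)
})

test_that("bin boundaries follow the floor rule and partition each region", {
  # region of length 40, values 0..39: bin k mean is 2k + 0.5
  tx <- tibble::tibble(transcript_id = "t1", sequence = strrep("A", 120),
                       len_utr5 = 40L, len_cds = 39L, len_utr3 = 41L, length = 120L)
  tracks <- tibble::tibble(transcript_id = "t1", condition = "vivo",
                           position = 1:120,
                           reactivity = c(0:39, rep(1, 80)))
  prof <- bin_profile(tracks, tx)
  utr5_bins <- prof$reactivity[prof$region == "utr5"]
  expect_equal(utr5_bins, 2 * (0:19) + 0.5)

  # partition property: every nucleotide lands in exactly one bin,
  # so the length-weighted mean of bin means equals the region mean
  set.seed(9)
  for (L in c(20, 23, 40, 60, 157)) {
    txr <- tibble::tibble(transcript_id = "r", sequence = strrep("A", L + 39),
                          len_utr5 = as.integer(L), len_cds = 21L,
                          len_utr3 = 18L, length = as.integer(L) + 39L)
    vals <- runif(L + 39)
    tr <- tibble::tibble(transcript_id = "r", condition = "vivo",
                         position = seq_len(L + 39), reactivity = vals)
    prof <- bin_profile(tr, txr)
    counts <- integer(20)
    for (o in 0:(L - 1)) {
      k <- floor(((o + 1) * 20 - 1) / L)
      counts[k + 1] <- counts[k + 1] + 1L
    }
    expect_equal(sum(counts), L)
    bins <- prof$reactivity[prof$region == "utr5"]
    w <- counts[!is.na(bins)]
    expect_equal(sum(bins[!is.na(bins)] * w) / sum(w), mean(vals[1:L]),
                 tolerance = 1e-9)
  }
})

test_that("regions shorter than the bin count yield NA bins, never errors", {
  tx <- tibble::tibble(transcript_id = "t1", sequence = strrep("A", 47),
                       len_utr5 = 5L, len_cds = 24L, len_utr3 = 18L, length = 47L)
  tracks <- make_constant_tracks(tx, 0.3, conditions = "vivo")
  prof <- bin_profile(tracks, tx)
  utr5 <- prof$reactivity[prof$region == "utr5"]
  expect_equal(sum(!is.na(utr5)), 5L) # 5 nucleotides fill exactly 5 bins
  expect_equal(unique(utr5[!is.na(utr5)]), 0.3)
})

test_that("a monotone track produces monotone bin means within a region", {
  tx <- tibble::tibble(transcript_id = "t1", sequence = strrep("A", 150),
                       len_utr5 = 50L, len_cds = 60L, len_utr3 = 40L, length = 150L)
  tracks <- tibble::tibble(transcript_id = "t1", condition = "vivo",
                           position = 1:150, reactivity = sort(runif(150)))
  prof <- bin_profile(tracks, tx)
  for (reg in c("utr5", "cds", "utr3")) {
    b <- prof$reactivity[prof$region == reg]
    expect_true(all(diff(b[!is.na(b)]) >= 0))
  }
})

test_that("CDS-head reactivity averages exactly the first 18 nucleotides", {
  tx <- make_toy_transcripts()
  tracks <- make_constant_tracks(tx, 0.7)
  heads <- cds_head_reactivity(tracks, tx)
  expect_equal(unique(heads$cds_head_reactivity), 0.7)

  # distinct values: only CDS positions 1..18 contribute
  tr <- dplyr::filter(tracks, transcript_id == "t1", condition == "vivo")
  tr$reactivity <- seq_len(nrow(tr))
  h <- cds_head_reactivity(tr, tx[1, ])
  expect_equal(h$cds_head_reactivity, mean(21:38))

  # all-missing head is NA
  tr$reactivity[21:38] <- NA
  h2 <- cds_head_reactivity(tr, tx[1, ])
  expect_true(is.na(h2$cds_head_reactivity))

  # too-short CDS is NA
  tx_short <- tibble::tibble(transcript_id = "s", sequence = strrep("A", 20),
                             len_utr5 = 2L, len_cds = 15L, len_utr3 = 3L, length = 20L)
  h3 <- cds_head_reactivity(make_constant_tracks(tx_short, 1, "vivo"), tx_short)
  expect_true(is.na(h3$cds_head_reactivity))
})

test_that("built-in folder matches hand-checked cases", {
  expect_equal(fold_mfe("AAAAA"), 0)
  expect_equal(fold_mfe("GC"), 0) # loop constraint forbids pairing
  expect_equal(fold_mfe("GGGAAACCC"), -3)
  expect_equal(fold_mfe("GGGAAACCC", min_loop = 3), -3)
  # RNA alphabet accepted
  expect_equal(fold_mfe("GGGAAACCC"), fold_mfe("GGGAAACCC" |> chartr(old = "T", new = "U")))
})

test_that("built-in folder equals exhaustive structure enumeration (n <= 14)", {
  set.seed(17)
  for (i in 1:40) {
    s <- random_seq(sample(2:14, 1))
    expect_equal(fold_mfe(s), -fold_oracle_pairs(s), info = s)
  }
})

test_that("MFE features cover ten scopes and respect empty scopes", {
  tx <- make_toy_transcripts()
  mfe <- mfe_features(tx)
  expect_equal(ncol(mfe) - 1L, 10L)
  expect_true(all(as.matrix(mfe[, -1]) <= 0, na.rm = TRUE))
  expect_equal(mfe$mfe_whole_per_nt, mfe$mfe_whole / tx$length)

  tx0 <- dplyr::mutate(tx[1, ],
                       sequence = substr(sequence, len_utr5 + 1, length),
                       length = length - len_utr5, len_utr5 = 0L)
  mfe0 <- mfe_features(tx0)
  expect_true(is.na(mfe0$mfe_utr5))
  expect_true(is.na(mfe0$mfe_utr5_per_nt))
})

test_that("external MFE import replaces the built-in energies and validates sign", {
  tx <- make_toy_transcripts()
  dir <- withr::local_tempdir()
  path <- file.path(dir, "mfe.tsv")
  tab <- tibble::tibble(transcript_id = tx$transcript_id,
                        mfe_whole = c(-12.3, -10), mfe_utr5 = c(-2.1, -1),
                        mfe_cds = c(-8.0, -7), mfe_utr3 = c(-1.9, -2),
                        mfe_cds_head = c(-0.4, -0.2))
  readr::write_tsv(tab, path)
  ext <- import_external_mfe(path, tx)
  expect_equal(ext$mfe_whole, c(-12.3, -10))
  expect_equal(ext$mfe_whole_per_nt, c(-12.3, -10) / tx$length)

  tab$mfe_cds[1] <- 3
  readr::write_tsv(tab, path)
  expect_error(import_external_mfe(path, tx), "<= 0")

  readr::write_tsv(tab[, 1:3], path)
  expect_error(import_external_mfe(path, tx), "missing")
})

test_that("structural assembly yields 132 grouped features, NA for absent condition", {
  tx <- make_toy_transcripts()
  tracks <- make_constant_tracks(tx, 0.4)
  prof <- bin_profile(tracks, tx)
  heads <- cds_head_reactivity(tracks, tx)
  mfe <- mfe_features(tx)
  feats <- assemble_structural_features(prof, heads, mfe)
  expect_equal(ncol(feats) - 1L, 132L)
  groups <- attr(feats, "feature_groups")
  expect_equal(unname(table(groups$group)[c("vivo", "vitro", "insilico")]),
               c(61L, 61L, 10L), ignore_attr = TRUE)

  vivo_only <- dplyr::filter(tracks, condition == "vivo")
  feats2 <- assemble_structural_features(bin_profile(vivo_only, tx),
                                         cds_head_reactivity(vivo_only, tx), mfe)
  expect_equal(ncol(feats2) - 1L, 132L)
  expect_true(all(is.na(feats2$vitro_bin_21)))
  expect_false(anyNA(feats2$vivo_bin_21))
  expect_identical(names(feats), names(feats2))
})

test_that("combine_features merges tables and group registries", {
  tx <- make_toy_transcripts()
  seqf <- assemble_sequence_features(tx)
  tracks <- make_constant_tracks(tx, 0.4)
  stf <- assemble_structural_features(bin_profile(tracks, tx),
                                      cds_head_reactivity(tracks, tx),
                                      mfe_features(tx))
  both <- combine_features(seqf, stf)
  expect_equal(ncol(both) - 1L, 111L + 132L)
  expect_equal(nrow(attr(both, "feature_groups")), 243L)
  expect_error(combine_features(seqf, seqf), "Duplicate")
})
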