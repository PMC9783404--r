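test_that("KS statistic and exact p match hand-checked cases", {
  r <- ks_two_sample(c(1, 2), c(3, 4))
  expect_equal(r$statistic, 1)
  expect_equal(r$p.value, 1 / 3)
  expect_equal(r$method, "exact")

  same <- ks_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)

  sep <- ks_two_sample(c(0, 0, 0), c(1, 1, 1))
  expect_equal(sep$statistic, 1)

  expect_error(ks_two_sample(1, c(1, 2)), "at least 2")
})

test_that("KS equals the enumeration oracle on random small samples", {
  set.seed(41)
  for (i in 1:200) {
    n <- sample(2:8, 1)
    m <- sample(2:8, 1)
    x <- rnorm(n)
    y <- rnorm(m, mean = sample(c(0, 1), 1))
    got <- ks_two_sample(x, y)
    want <- ks_oracle(x, y)
    expect_equal(got$statistic, want$D, info = sprintf("case %d D", i))
    expect_equal(got$p.value, want$p, tolerance = 1e-9,
                 info = sprintf("case %d p", i))
  }
})

test_that("KS agrees with the reference implementation on continuous data", {
  set.seed(42)
  for (i in 1:20) {
    x <- rnorm(sample(5:40, 1))
    y <- rnorm(sample(5:40, 1), mean = runif(1, -1, 1))
    got <- ks_two_sample(x, y)
    ref <- suppressWarnings(stats::ks.test(x, y))
    expect_equal(got$statistic, unname(ref$statistic))
    if (got$method == "exact" && length(x) * length(y) < 10000) {
      expect_equal(got$p.value, ref$p.value, tolerance = 1e-8)
    }
  }
  # asymptotic branch engages above the exact limit
  big <- ks_two_sample(rnorm(150), rnorm(150, 0.3))
  expect_equal(big$method, "asymptotic")
  ref <- suppressWarnings(stats::ks.test(rnorm(150), rnorm(150)))
  expect_true(big$p.value >= 0 && big$p.value <= 1)
})

test_that("BH adjustment matches the hand-computed step-up and is monotone", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_pvalues(0.03), 0.03)
  expect_equal(adjust_pvalues(rep(0.2, 5)), rep(0.2, 5))
  expect_error(adjust_pvalues(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\(0, 1\\]")
  set.seed(43)
  for (i in 1:20) {
    p <- runif(sample(3:60, 1))
    q <- adjust_pvalues(p)
    expect_true(all(q >= p - 1e-12))
    expect_true(all(q <= 1))
    expect_equal(order(q[order(p)]), seq_along(p)) # order-preserving
    expect_equal(q, p.adjust(p, "BH"))
  }
})

test_that("group bin means average per-transcript bin values, skipping NAs", {
  tx <- tibble::tibble(transcript_id = c("a", "b"),
                       sequence = c(strrep("A", 61), strrep("A", 61)),
                       len_utr5 = 20L, len_cds = 21L, len_utr3 = 20L, length = 61L)
  tr <- dplyr::bind_rows(
    make_constant_tracks(tx[1, ], 0.2, "vivo"),
    make_constant_tracks(tx[2, ], 0.4, "vivo")
  )
  labs <- tibble::tibble(transcript_id = c("a", "b"), te_class = c("high", "high"))
  prof <- bin_profile(tr, tx)
  gm <- group_bin_means(prof, labs)
  expect_equal(unique(gm$mean_reactivity), 0.3)

  tr2 <- dplyr::mutate(tr, reactivity = ifelse(transcript_id == "a", NA, reactivity))
  gm2 <- group_bin_means(bin_profile(tr2, tx), labs)
  expect_equal(unique(gm2$mean_reactivity), 0.4)
  expect_equal(unique(gm2$n), 1L)
})

test_that("identical group profiles give equal means, zero delta everywhere", {
  sim <- simulate_te_dataset(synthetic_config("null", n_transcripts = 30,
                                              seed = 19, missing_rate = 0))
  # both groups see the same tracks: delta vivo - vitro has no class effect
  prof <- bin_profile(sim$tracks, sim$transcripts)
  labs <- tibble::tibble(transcript_id = sim$truth$transcript_id,
                         te_class = sim$truth$true_class)
  dp <- delta_profile(prof, labs)
  expect_equal(nrow(dp), 120L) # 60 bins x 2 classes
  expect_lt(max(abs(dp$delta), na.rm = TRUE), 0.15)

  # constant equal tracks in both conditions: delta exactly zero
  tx <- make_toy_transcripts()
  tr <- make_constant_tracks(tx, 0.5)
  labs2 <- tibble::tibble(transcript_id = tx$transcript_id,
                          te_class = c("high", "low"))
  dp2 <- delta_profile(bin_profile(tr, tx), labs2)
  expect_equal(unique(dp2$delta[!is.na(dp2$delta)]), 0)
})

test_that("summarize_bins assembles the full per-bin table", {
  sim <- simulate_te_dataset(synthetic_config("mesc_like", n_transcripts = 60,
                                              seed = 23, missing_rate = 0))
  prof <- bin_profile(sim$tracks, sim$transcripts)
  labs <- tibble::tibble(transcript_id = sim$truth$transcript_id,
                         te_class = sim$truth$true_class)
  bs <- summarize_bins(prof, labs)
  expect_s3_class(bs, "te_bin_summary")
  expect_equal(nrow(bs), 120L)
  expect_true(all(bs$ks_D >= 0 & bs$ks_D <= 1, na.rm = TRUE))
  expect_true(all(bs$p_adj >= bs$p_raw - 1e-12, na.rm = TRUE))
  expect_equal(bs$neglog10_padj, -log10(bs$p_adj))
  # delta columns equal the group delta profile
  dp <- delta_profile(prof, labs)
  vivo_rows <- bs[bs$condition == "vivo", ]
  expect_equal(vivo_rows$delta_high,
               dp$delta[dp$te_class == "high"][vivo_rows$bin])
})

test_that("single-transcript report has 60 rows and a consistent delta", {
  tx <- make_toy_transcripts()
  tr <- make_constant_tracks(tx, 0.5)
  prof <- bin_profile(tr, tx)
  rep1 <- transcript_profile_report(prof, "t1")
  expect_equal(nrow(rep1), 60L)
  expect_equal(unique(rep1$delta[!is.na(rep1$delta)]), 0)

  vivo_only <- bin_profile(dplyr::filter(tr, condition == "vivo"), tx)
  rep2 <- transcript_profile_report(vivo_only, "t1")
  expect_true(all(is.na(rep2$delta)))
  expect_error(transcript_profile_report(prof, "nope"), "Unknown transcript")
})

test_that("plot functions return ggplot objects", {
  sim <- simulate_te_dataset(synthetic_config("mesc_like", n_transcripts = 40,
                                              seed = 29, missing_rate = 0))
  prof <- bin_profile(sim$tracks, sim$transcripts)
  labs <- tibble::tibble(transcript_id = sim$truth$transcript_id,
                         te_class = sim$truth$true_class)
  bs <- summarize_bins(prof, labs)
  expect_s3_class(plot_bin_reactivity(bs), "ggplot")
  expect_s3_class(plot_bin_significance(bs), "ggplot")
  expect_s3_class(autoplot(bs), "ggplot")
  expect_s3_class(plot_delta_profile(delta_profile(prof, labs)), "ggplot")
  expect_s3_class(plot_transcript_profile(
    transcript_profile_report(prof, sim$transcripts$transcript_id[1])), "ggplot")
})
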