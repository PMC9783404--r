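# per-bin group means, two-sample KS with exact small-sample p, BH
# adjustment, delta (vivo - vitro) profiles, single-transcript reports

#' Two-sample Kolmogorov-Smirnov test
#'
#' The statistic is `D = sup |ECDF_x - ECDF_y|`. The two-sided p-value is
#' exact — the permutation tail probability `P(D* >= D)` computed by lattice
#' path counting over all `C(n+m, n)` orderings — whenever
#' `|x| * |y| <= exact_limit`, and otherwise uses the asymptotic Kolmogorov
#' distribution `Q(sqrt(nm/(n+m)) * D)`. The exact count assumes no ties
#' across samples (reactivity values are continuous); with ties it is
#' conservative.
#'
#' @param x,y Numeric samples, each of length >= 2; `NA`s are dropped.
#' @param exact_limit Switch point between exact and asymptotic p, default
#'   10000 on `|x| * |y|`.
#' @return One-row tibble: `statistic` (D), `p.value`, `method` (`"exact"`
#'   or `"asymptotic"`), `n_x`, `n_y`.
#' @export
ks_two_sample <- function(x, y, exact_limit = 10000) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  n <- length(x)
  m <- length(y)
  if (n < 2L || m < 2L) abort("Both samples need at least 2 non-missing values.")
  pooled <- c(x, y)
  ord <- order(pooled)
  z <- ifelse(seq_along(pooled) <= n, 1 / n, -1 / m)[ord]
  steps <- cumsum(z)
  # with ties, the ECDF gap is read only after the last tied value
  last_of_run <- c(diff(pooled[ord]) != 0, TRUE)
  D <- max(abs(steps[last_of_run]))
  if (n * m <= exact_limit) {
    p <- ks_exact_p(n, m, D)
    method <- "exact"
  } else {
    p <- ks_asymptotic_p(n, m, D)
    method <- "asymptotic"
  }
  tibble(statistic = D, p.value = p, method = method, n_x = n, n_y = m)
}

# exact P(D* >= d): 1 - (#lattice paths from (0,0) to (n,m) with
# |i/n - j/m| < d at every step) / C(n+m, n); integer band test |im - jn| < K
ks_exact_p <- function(n, m, d) {
  K <- d * n * m - 1e-7 # |im - jn| must stay strictly below d*n*m
  u <- numeric(m + 1L)
  u[1L] <- 1
  for (j in seq_len(m)) u[j + 1L] <- if (abs(-j * n) < K) u[j] else 0
  for (i in seq_len(n)) {
    u[1L] <- if (abs(i * m) < K) u[1L] else 0
    for (j in seq_len(m)) {
      u[j + 1L] <- if (abs(i * m - j * n) < K) u[j + 1L] + u[j] else 0
    }
  }
  p <- 1 - u[m + 1L] / choose(n + m, n)
  # the permutation tail is never below 1/C(n+m, n); guards cancellation to 0
  min(max(p, 1 / choose(n + m, n)), 1)
}

# asymptotic two-sided Kolmogorov tail Q(lambda) = 2 sum (-1)^(k-1) exp(-2 k^2 lambda^2)
ks_asymptotic_p <- function(n, m, d) {
  lambda <- sqrt(n * m / (n + m)) * d
  if (lambda == 0) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(max(p, .Machine$double.xmin), 1) # keep p strictly positive
}

#' Adjust p-values for multiple testing
#'
#' Benjamini-Hochberg step-up false-discovery-rate adjustment (via
#' [stats::p.adjust()]), with input validation: all p-values must lie in
#' (0, 1]. The adjustment is order-preserving and never decreases a
#' p-value.
#'
#' @param p Numeric vector of raw p-values in (0, 1]; `NA`s pass through.
#' @param method Adjustment method, default `"BH"`.
#' @return Adjusted p-values in input order.
#' @export
adjust_pvalues <- function(p, method = "BH") {
  ok <- is.na(p) | (p > 0 & p <= 1)
  if (!all(ok)) abort("All p-values must lie in (0, 1].")
  p.adjust(p, method = method)
}

#' Per-bin group mean reactivities
#'
#' Mean of the per-transcript bin values within each TE class, per condition
#' and bin; a bin empty in a group (all transcripts missing) is `NA`.
#'
#' @param profiles Long bin-profile tibble from [bin_profile()].
#' @param labels Tibble `transcript_id`, `te_class` (`high`/`low`).
#' @return Tibble `condition`, `bin`, `region`, `te_class`, `mean_reactivity`,
#'   `n` (transcripts contributing).
#' @export
group_bin_means <- function(profiles, labels) {
  assert_columns(profiles, c("transcript_id", "condition", "bin", "region", "reactivity"),
                 "Bin profiles")
  dat <- inner_join(profiles, te_labels(labels), by = "transcript_id")
  summarise(
    group_by(dat, .data$condition, .data$bin, .data$region, .data$te_class),
    mean_reactivity = if (all(is.na(.data$reactivity))) NA_real_ else
      mean(.data$reactivity, na.rm = TRUE),
    n = sum(!is.na(.data$reactivity)),
    .groups = "drop"
  )
}

#' Per-bin differential reactivity between TE classes
#'
#' For every metagene bin and probing condition, compares the
#' per-transcript bin reactivities of the high-TE and low-TE groups with a
#' two-sample KS test; p-values are adjusted by Benjamini-Hochberg within
#' each condition across its bins. Also reports each group's delta
#' reactivity (in vivo minus in vitro bin mean), the measure of structural
#' rearrangement between conditions.
#'
#' Each observation entering a test is one transcript's bin mean — the
#' per-bin sample sizes are numbers of transcripts, not nucleotides.
#'
#' @param profiles Long bin-profile tibble covering (ideally) both
#'   conditions.
#' @param labels Tibble `transcript_id`, `te_class`.
#' @param alpha Nominal adjusted-p cutoff recorded in the `significant`
#'   column, default 0.05.
#' @param exact_limit Passed to [ks_two_sample()].
#' @return A tibble of class `te_bin_summary`, one row per condition x bin:
#'   `condition`, `bin`, `region`, `mean_high`, `mean_low`, `n_high`,
#'   `n_low`, `ks_D`, `p_raw`, `p_adj`, `neglog10_padj`, `significant`,
#'   `delta_high`, `delta_low`.
#' @export
summarize_bins <- function(profiles, labels, alpha = 0.05, exact_limit = 10000) {
  labs <- te_labels(labels)
  dat <- inner_join(profiles, labs, by = "transcript_id")
  per_bin <- summarise(
    group_by(dat, .data$condition, .data$bin, .data$region),
    mean_high = if (any(!is.na(.data$reactivity[.data$te_class == "high"])))
      mean(.data$reactivity[.data$te_class == "high"], na.rm = TRUE) else NA_real_,
    mean_low = if (any(!is.na(.data$reactivity[.data$te_class == "low"])))
      mean(.data$reactivity[.data$te_class == "low"], na.rm = TRUE) else NA_real_,
    n_high = sum(!is.na(.data$reactivity[.data$te_class == "high"])),
    n_low = sum(!is.na(.data$reactivity[.data$te_class == "low"])),
    ks = list(
      if (sum(!is.na(.data$reactivity[.data$te_class == "high"])) >= 2 &&
          sum(!is.na(.data$reactivity[.data$te_class == "low"])) >= 2) {
        ks_two_sample(.data$reactivity[.data$te_class == "high"],
                      .data$reactivity[.data$te_class == "low"],
                      exact_limit = exact_limit)
      } else {
        tibble(statistic = NA_real_, p.value = NA_real_,
               method = NA_character_, n_x = NA_integer_, n_y = NA_integer_)
      }
    ),
    .groups = "drop"
  )
  per_bin <- mutate(per_bin,
    ks_D = purrr::map_dbl(.data$ks, "statistic"),
    p_raw = purrr::map_dbl(.data$ks, "p.value")
  )
  per_bin$ks <- NULL
  per_bin <- mutate(group_by(per_bin, .data$condition),
                    p_adj = adjust_pvalues(.data$p_raw))
  per_bin <- ungroup(mutate(per_bin,
    neglog10_padj = -log10(.data$p_adj),
    significant = !is.na(.data$p_adj) & .data$p_adj < .env$alpha
  ))

  deltas <- delta_profile(profiles, labels)
  deltas <- tidyr::pivot_wider(deltas, id_cols = "bin", names_from = "te_class",
                               values_from = "delta", names_prefix = "delta_")
  out <- left_join(per_bin, deltas, by = "bin")
  out <- arrange(out, .data$condition, .data$bin)
  class(out) <- c("te_bin_summary", class(out))
  out
}

#' Delta reactivity profile per TE class
#'
#' Per bin and class: (group mean in vivo reactivity) minus (group mean in
#' vitro reactivity); `NA` when either side is missing. Positive values mean
#' the region is more accessible (more unfolded) inside cells than after
#' refolding in vitro.
#'
#' @inheritParams group_bin_means
#' @return Tibble `te_class`, `bin`, `region`, `delta`.
#' @export
delta_profile <- function(profiles, labels) {
  means <- group_bin_means(profiles, labels)
  wide <- tidyr::pivot_wider(means, id_cols = c("te_class", "bin", "region"),
                             names_from = "condition", values_from = "mean_reactivity")
  if (!all(c("vivo", "vitro") %in% names(wide))) {
    for (nm in setdiff(c("vivo", "vitro"), names(wide))) wide[[nm]] <- NA_real_
  }
  out <- mutate(wide, delta = .data$vivo - .data$vitro)
  arrange(out[, c("te_class", "bin", "region", "delta")], .data$te_class, .data$bin)
}

#' Per-bin profile report for a single transcript
#'
#' Extracts one transcript's binned in vivo and in vitro reactivities and
#' their difference — the single-gene counterpart of the group-level
#' metagene curves, suitable for plotting individual genes of interest.
#'
#' @param profiles Long bin-profile tibble.
#' @param transcript_id Transcript to report.
#' @return Tibble with one row per bin: `bin`, `region`, `vivo`, `vitro`,
#'   `delta` (vivo - vitro; `NA` where either condition is missing).
#' @export
transcript_profile_report <- function(profiles, transcript_id) {
  sel <- filter(profiles, .data$transcript_id == .env$transcript_id)
  if (nrow(sel) == 0L) abort(sprintf("Unknown transcript id: %s", transcript_id))
  wide <- tidyr::pivot_wider(sel, id_cols = c("bin", "region"),
                             names_from = "condition", values_from = "reactivity")
  for (nm in setdiff(c("vivo", "vitro"), names(wide))) wide[[nm]] <- NA_real_
  out <- mutate(wide, delta = .data$vivo - .data$vitro)
  arrange(out[, c("bin", "region", "vivo", "vitro", "delta")], .data$bin)
}
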