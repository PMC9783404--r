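# internal helpers shared across modules

# seed-scoped evaluation: run expr under a fixed seed, restore RNG state after
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# derive a child seed from a base seed and a stream offset, kept < 2^31
derive_seed <- function(base_seed, offset) {
  as.integer((as.numeric(base_seed) * 1103L + as.numeric(offset) * 12347) %% 2147483629)
}

assert_scalar_number <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (strict_min && x <= min) abort(sprintf("`%s` must be > %s.", name, min))
  if (!strict_min && x < min) abort(sprintf("`%s` must be >= %s.", name, min))
  invisible(x)
}

assert_columns <- function(df, cols, what) {
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "%s must have columns: %s (missing: %s).",
      what, paste(cols, collapse = ", "), paste(missing_cols, collapse = ", ")
    ))
  }
  invisible(df)
}

# message only when verbose; all record-level rejections go through here
log_msg <- function(verbose, fmt, ...) {
  if (isTRUE(verbose)) inform(sprintf(fmt, ...))
  invisible(NULL)
}

region_levels <- c("utr5", "cds", "utr3")

# substring of a transcript sequence for one region / scope
scope_sequence <- function(sequence, len_utr5, len_cds, len_utr3,
                           scope = c("whole", "utr5", "cds", "utr3", "cds_head"),
                           head_nt = 18L) {
  scope <- match.arg(scope)
  switch(scope,
    whole = sequence,
    utr5 = substr(sequence, 1L, len_utr5),
    cds = substr(sequence, len_utr5 + 1L, len_utr5 + len_cds),
    utr3 = substr(sequence, len_utr5 + len_cds + 1L, len_utr5 + len_cds + len_utr3),
    cds_head = if (len_cds >= head_nt) {
      substr(sequence, len_utr5 + 1L, len_utr5 + head_nt)
    } else {
      ""
    }
  )
}
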