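# Internal validation helpers ------------------------------------------------

assert_cols <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    rlang::abort(sprintf(
      "`%s` is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

assert_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                 strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    rlang::abort(sprintf("`%s` must be a single finite number", name))
  }
  if (strict_min && x <= min) {
    rlang::abort(sprintf("`%s` must be > %s", name, min))
  }
  if (!strict_min && x < min) {
    rlang::abort(sprintf("`%s` must be >= %s", name, min))
  }
  if (x > max) {
    rlang::abort(sprintf("`%s` must be <= %s", name, max))
  }
  invisible(x)
}

# Run code with a local, restored RNG state seeded from `seed` (+ offset).
# Keeps generator calls pure functions of (config, seed) without disturbing
# the caller's RNG stream.
with_local_seed <- function(seed, code) {
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
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Derive a sub-seed for an operation so the same reference can feed several
# independent simulators deterministically. Kept below 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}

revcomp_dna <- function(x) {
  comp <- chartr("ACGTacgt", "TGCAtgca", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}
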