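# shared internal helpers

# run an expression under a local, restored RNG state
with_seed <- function(seed, code) withr::with_seed(seed, code)

# roman numeral labels I, II, ... for aroma combinations
roman_labels <- function(n) as.character(utils::as.roman(seq_len(n)))

# uniform variate with mean 0, sd 1, bounded support (+-sqrt(3));
# used by the cohort generator so that log-scale latent factors cannot
# produce physically absurd order-of-magnitude outliers in single cultivars
runif_unit <- function(n) stats::runif(n, -sqrt(3), sqrt(3))

assert_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")),
          class = "vitisaroma_format_error")
  }
  invisible(df)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s]",
                  name, format(lower), format(upper)),
          class = "vitisaroma_validation_error")
  }
  invisible(x)
}

# split a pipe-separated descriptor field into a clean character vector
split_tokens <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(character(0))
    tolower(trimws(strsplit(s, "|", fixed = TRUE)[[1]]))
  })
}

join_tokens <- function(x) {
  vapply(x, function(v) paste(v, collapse = "|"), character(1))
}

# canonical descriptor form: case-folded, whitespace-trimmed
fold_descriptor <- function(x) tolower(trimws(x))
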