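#' Round half away from zero
#'
#' Reporting convention for metric tables: two decimals, ties rounded up
#' (0.945 -> 0.95), unlike base R's round-to-even.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Normalize a structured code for table lookup: trim, uppercase, collapse
# whitespace, underscores treated as spaces.
normalize_code <- function(x) {
  x <- str_to_upper(str_squish(gsub("_", " ", as.character(x))))
  x[is.na(x) | x == ""] <- NA_character_
  x
}

is_blank <- function(x) is.na(x) | !nzchar(trimws(as.character(x)))

sample1 <- function(x) if (length(x) == 1L) x else sample(x, 1L)

# low-overhead tibble constructor for hot paths: no name repair, explicit
# recycling of scalars
fast_tibble <- function(...) {
  l <- list(...)
  n <- if (length(l) == 0) 0L else max(lengths(l))
  l <- lapply(l, function(x) if (length(x) == n) x else
    rep(x, length.out = n))
  new_tibble(l, nrow = n)
}
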