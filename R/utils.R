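# Internal helpers shared across modules.

# Evaluate expr under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# round-half-away-from-zero (R's round() uses banker's rounding)
round_half_up <- function(x) trunc(x + sign(x) * 0.5)

# mean/sd/n summary that returns NAs (not zeros) for empty input
summarise_values <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L)
    return(list(mean = NA_real_, sd = NA_real_, n = 0L))
  list(mean = mean(x),
       sd = if (length(x) > 1L) stats::sd(x) else 0,
       n = length(x))
}

assert_classmap <- function(mask) {
  mask <- as.matrix(mask)
  bad <- setdiff(unique(as.vector(mask)), 0:4)
  if (length(bad) > 0)
    stop(sprintf("class map contains invalid label(s): %s",
                 paste(bad, collapse = ", ")))
  storage.mode(mask) <- "integer"
  mask
}
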