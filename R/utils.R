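## Internal helpers shared across modules.

## Round half away from zero (display convention for reported percentages;
## base round() rounds half to even).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## Fraction -> percentage rounded half-up to 2 decimals.
as_percent <- function(x, digits = 2) round_half_up(100 * x, digits)

## Per-row standard deviation with per-row NA handling; x is a numeric
## matrix. Rows with < 2 non-missing values get NA.
row_sds <- function(x) {
  k <- rowSums(!is.na(x))
  m <- rowMeans(x, na.rm = TRUE)
  ss <- rowSums(x * x, na.rm = TRUE)
  v <- (ss - k * m * m) / (k - 1)
  v[k < 2] <- NA_real_
  sqrt(pmax(v, 0))
}

## Per-row max/min across columns without apply(); na.rm per element.
row_max <- function(x) {
  out <- x[, 1]
  if (ncol(x) > 1) for (j in 2:ncol(x)) out <- pmax(out, x[, j], na.rm = TRUE)
  out
}
row_min <- function(x) {
  out <- x[, 1]
  if (ncol(x) > 1) for (j in 2:ncol(x)) out <- pmin(out, x[, j], na.rm = TRUE)
  out
}

## Deterministic seed derivation; keeps results < 2^31 - 1.
derive_seed <- function(master_seed, a, b = 0L) {
  (abs(as.integer(master_seed)) %% 2000000L) * 1000L +
    as.integer(a) * 100L + as.integer(b) * 10L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
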