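# Internal helpers shared across modules.

# Running mean with partial windows at the edges (no NA padding, unbiased at
# boundaries). `k` must be odd; k = 1 returns x unchanged.
.runmean <- function(x, k) {
  stopifnot(k >= 1, k %% 2 == 1)
  if (k == 1L || length(x) == 0L) return(as.numeric(x))
  n <- length(x)
  h <- (k - 1L) / 2L
  cs <- cumsum(c(0, as.numeric(x)))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Deterministic derived seeds: one top-level seed fans out to per-stage
# streams. Kept well below 2^31.
.deriveSeed <- function(seed, salt) {
  (abs(as.integer(seed)) %% 1000003L) * 2011L + as.integer(salt) %% 2011L
}

.assertScalarNumber <- function(x, name, min = -Inf, max = Inf,
                                strictMin = FALSE, strictMax = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  okMin <- if (strictMin) x > min else x >= min
  okMax <- if (strictMax) x < max else x <= max
  if (!okMin || !okMax)
    stop(sprintf("'%s' = %g is outside its allowed range", name, x),
         call. = FALSE)
  invisible(x)
}

# Population standard deviation (denominator N).
.popSd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

# Format doubles so that read.table()/strtod() reproduces them bit-exactly.
.fmtNum <- function(x) sprintf("%.17g", x)
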