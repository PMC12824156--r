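# Internal helpers: seeded RNG scoping, stable seed derivation, numerics.

# Deterministically derive a 31-bit seed from a base seed plus string tags,
# so every stochastic step in a pipeline gets its own reproducible stream.
derive_seed <- function(seed, ...) {
  key <- paste(c(format(seed), ...), collapse = "/")
  h <- 17
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483563
  as.integer(h + 1L)
}

# Row-wise sample standard deviation (n - 1 denominator) of a matrix.
row_sds <- function(x) {
  n <- ncol(x)
  if (n < 2L) return(rep(NA_real_, nrow(x)))
  m <- rowMeans(x)
  sqrt(pmax(rowSums((x - m)^2), 0) / (n - 1))
}

# clamp to the rating bounds, preserving dim attributes
clip1 <- function(x) {
  x[x > 1] <- 1
  x[x < -1] <- -1
  x
}

# Full-precision number formatting so CSV round-trips are bit exact.
fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  # shorten where fewer digits already round-trip (keeps files readable)
  short <- sprintf("%.15g", x)
  use <- as.numeric(short) == x
  out[use] <- short[use]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
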