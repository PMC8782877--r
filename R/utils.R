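# Shared internal helpers.

# Round half away from zero to `digits` decimals (table-style rounding, unlike
# base round()'s round-half-even).
roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

.gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) {
    r <- a %% b
    a <- b
    b <- r
  }
  a
}

# gcd of a numeric vector of (exactly representable) integers; gcd(0-vector) = 0
vecGCD <- function(v) {
  g <- 0
  for (x in v) {
    g <- .gcd2(g, x)
    if (g == 1) break
  }
  g
}

# Overflow guard for the exact integer engine: doubles represent integers
# exactly up to 2^53; abort well before that.
.INT_GUARD <- 2^49

.checkExact <- function(m) {
  if (any(abs(m) > .INT_GUARD)) {
    stop("integer overflow guard tripped in invariant computation; ",
         "net coefficients grew beyond the exactly-representable range")
  }
  invisible(m)
}

# condition helpers so the CLI can map error classes to exit codes
stopInput <- function(...) {
  stop(errorCondition(paste0(...), class = c("petrisig_input_error", "error")))
}

stopAnalysis <- function(...) {
  stop(errorCondition(paste0(...), class = c("petrisig_analysis_error", "error")))
}

# Deterministic 31-bit string/integer hash (multiplicative, minstd modulus);
# used to key per-(seed, parameter, run) random streams and config fingerprints.
.mix31 <- function(seed, ...) {
  M <- 2147483647
  h <- as.numeric(seed) %% M
  for (part in list(...)) {
    if (is.character(part)) part <- utf8ToInt(part)
    for (v in as.numeric(part)) {
      h <- (h * 48271 + (v %% M) + 1) %% M
    }
  }
  as.integer(h)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG stream afterwards.
withLocalSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# trapezoidal integral of y over t
trapz <- function(t, y) {
  n <- length(t)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(t)) / 2
}
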