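# Minimal exact rational arithmetic for model weights and transition
# probabilities, so distribution equalities need no floating tolerance.

gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b != 0) {
    t <- a %% b
    a <- b
    b <- t
  }
  a
}

lcm2 <- function(a, b) a / gcd2(a, b) * b

rat_reduce <- function(num, den) {
  if (den == 0) stop("zero denominator", call. = FALSE)
  if (den < 0) {
    num <- -num
    den <- -den
  }
  g <- max(gcd2(num, den), 1)
  c(num / g, den / g)
}

# parse "2/5", "1", 0.4, 1/3 (numeric, rationalized with small denominator)
rat_parse <- function(x) {
  if (is.character(x)) {
    parts <- strsplit(trimws(x), "/", fixed = TRUE)[[1L]]
    if (length(parts) == 1L) {
      v <- suppressWarnings(as.numeric(parts))
      if (is.na(v)) stop("cannot parse weight ", sQuote(x), call. = FALSE)
      return(rat_parse(v))
    }
    num <- suppressWarnings(as.numeric(parts[1L]))
    den <- suppressWarnings(as.numeric(parts[2L]))
    if (is.na(num) || is.na(den)) {
      stop("cannot parse weight ", sQuote(x), call. = FALSE)
    }
    return(rat_reduce(num, den))
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("weights must be numbers or fraction strings", call. = FALSE)
  }
  for (den in 1:100000) {
    num <- round(x * den)
    if (abs(x - num / den) < 1e-9) return(rat_reduce(num, den))
  }
  stop("cannot represent weight ", x, " as an exact fraction", call. = FALSE)
}
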