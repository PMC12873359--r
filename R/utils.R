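#' @keywords internal
"_PACKAGE"

#' @useDynLib restact, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats aggregate coef lm pf pt rgamma rnorm rpois rnbinom runif
#'   sd var setNames
#' @importFrom utils read.csv write.csv
NULL

# Parse "HH:MM" clock strings to minutes after midnight.
parse_clock <- function(x) {
  if (is.numeric(x)) {
    stopifnot(x >= 0, x < 1440)
    return(as.integer(x))
  }
  m <- regmatches(x, regexec("^([0-9]{1,2}):([0-9]{2})$", x))[[1]]
  if (length(m) != 3L) stop("clock time must be 'HH:MM', got: ", x)
  h <- as.integer(m[2]); mi <- as.integer(m[3])
  if (h > 23L || mi > 59L) stop("clock time out of range: ", x)
  h * 60L + mi
}

format_clock <- function(minutes) {
  sprintf("%02d:%02d", minutes %/% 60L, minutes %% 60L)
}

# Deterministic 32-bit seed for a subject substream. Doubles are exact below
# 2^53 so the modulus is computed without integer overflow.
mix_seed <- function(seed, k) {
  s <- (as.numeric(seed) %% 2147483647) * 1000003 + as.numeric(k) * 7919 + 12345
  as.integer(s %% 2147483647)
}

# Circular mean of angles (radians), mapped to [0, 2pi). NA if all inputs NA.
circular_mean <- function(phi) {
  phi <- phi[!is.na(phi)]
  if (length(phi) == 0L) return(NA_real_)
  ang <- atan2(mean(sin(phi)), mean(cos(phi)))
  ang %% (2 * pi)
}

# FNV-1a 32-bit hash of a character scalar, as 8 hex digits. Used only to
# fingerprint run configurations in the pipeline manifest.
fnv1a32 <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    # xor on the low 32 bits, kept as a double to avoid integer overflow
    lo <- bitwXor(as.integer(h %% 65536), b)
    h <- (h %/% 65536) * 65536 + lo
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Sample skewness (g1) and excess kurtosis (g2), moment estimators.
moment_skewness <- function(x) {
  n <- length(x); m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3)
  if (m2 == 0) return(NA_real_)
  m3 / m2^1.5
}

moment_kurtosis_excess <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2); m4 <- mean((x - m)^4)
  if (m2 == 0) return(NA_real_)
  m4 / m2^2 - 3
}
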