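# Internal helpers shared across modules.

#' Derive a reproducible child seed from a parent seed and a label
#'
#' A single experiment-level seed fans out to independent per-unit seeds so
#' that adding sharks (or grid points) does not perturb streams already
#' drawn. The derivation is a small multiplicative hash kept below 2^31 so
#' the result is always a valid R integer seed.
#'
#' @param seed parent integer seed.
#' @param ... labels (coerced to character) identifying the child stream.
#' @return an integer seed.
#' @export
child_seed <- function(seed, ...) {
  label <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  h <- as.double(seed %% 2147483647L)
  for (ch in utf8ToInt(label)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer((h * 48271) %% 2147483647)
}

#' Evaluate an expression under a local RNG state
#'
#' Seeds the generator, evaluates `expr`, and restores the caller's RNG
#' stream, so seeded draws never perturb surrounding randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Wilson score interval for a binomial proportion.
wilson_ci <- function(k, n, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

# Least-squares slope, intercept and R^2 of y on x without lm() overhead.
fast_slope <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  sxy <- sum((x - mx) * (y - my))
  slope <- sxy / sxx
  fitted <- my + slope * (x - mx)
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - my)^2)
  r2 <- if (ss_tot <= .Machine$double.eps * n) {
    if (ss_res <= .Machine$double.eps * n) 1 else 0
  } else 1 - ss_res / ss_tot
  list(slope = slope, intercept = my - slope * mx, r_squared = r2)
}

# Rolling least-squares slopes of y over windows of `width` consecutive
# samples (x assumed uniformly spaced), via cumulative sums. Returns one
# slope per window start; NA-free input required.
rolling_slopes <- function(x, y, width) {
  n <- length(x)
  if (n < width) return(numeric(0))
  cx <- cumsum(x); cy <- cumsum(y)
  cxx <- cumsum(x * x); cxy <- cumsum(x * y)
  idx <- seq_len(n - width + 1)
  hi <- idx + width - 1
  sx <- cx[hi] - c(0, cx)[idx]
  sy <- cy[hi] - c(0, cy)[idx]
  sxx <- cxx[hi] - c(0, cxx)[idx]
  sxy <- cxy[hi] - c(0, cxy)[idx]
  (width * sxy - sx * sy) / (width * sxx - sx^2)
}

# Centred running mean with shrinking windows at the edges (window `k`
# samples, k odd preferred). Used for static-acceleration estimation.
running_mean_centred <- function(x, k) {
  n <- length(x)
  half <- k %/% 2
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}
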