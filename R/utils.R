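# Internal numerical helpers shared across modules.

# Deterministic RNG substreams. Every stochastic routine draws from its own
# stream derived from (seed, label), so stages can be re-run independently
# without perturbing each other and the whole pipeline is reproducible from
# one top-level seed.
local_rng <- function(seed, label = "") {
  sub <- (as.numeric(seed) * 2654435761 + fnv1a32(label)) %% 2147483647
  env <- new.env(parent = emptyenv())
  env$state <- NULL
  draw <- function(fn, ...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    if (is.null(env$state)) set.seed(as.integer(sub))
    else assign(".Random.seed", env$state, envir = globalenv())
    fn(...)
  }
  list(
    rnorm = function(n, ...) draw(stats::rnorm, n, ...),
    runif = function(n, ...) draw(stats::runif, n, ...),
    rpois = function(n, lambda) draw(stats::rpois, n, lambda),
    sample = function(...) draw(base::sample, ...)
  )
}

# 31-bit polynomial string hash (all arithmetic stays below 2^53);
# also used for config hashes.
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\x01"))
  h <- 5381
  for (b in bytes) h <- (h * 127 + b) %% 2147483629
  h
}

config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = 10, force = TRUE)
  sprintf("%08x", fnv1a32(as.character(s)))
}

# Analytic signal via FFT (one-sided spectrum doubling); x must be gap-free.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Largest 5-smooth (2^a 3^b 5^c) integer <= m: FFT-friendly series length.
nice_length_floor <- function(m) {
  best <- 1
  p5 <- 1
  while (p5 <= m) {
    p35 <- p5
    while (p35 <= m) {
      p2 <- p35 * 2^floor(log2(m / p35))
      if (p2 > best) best <- p2
      p35 <- p35 * 3
    }
    p5 <- p5 * 5
  }
  as.integer(best)
}

# Smallest 5-smooth integer >= m.
nice_length_ceiling <- function(m) {
  n <- m
  while (TRUE) {
    k <- n
    for (p in c(2L, 3L, 5L)) while (k %% p == 0) k <- k %/% p
    if (k == 1) return(as.integer(n))
    n <- n + 1
  }
}

# Wrap angles to [-pi, pi).
wrap_phase <- function(theta) {
  w <- (theta + pi) %% (2 * pi) - pi
  w[w >= pi] <- -pi
  w
}

#' Circular (Fisher--Lee) correlation between two phase series
#'
#' Rotation-invariant association measure for paired angles; used to check
#' that a recovered cycle phase tracks a known ground-truth phase.
#'
#' @param a,b Numeric vectors of angles in radians (equal length).
#' @return Correlation in `[-1, 1]`.
#' @export
circular_correlation <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  am <- atan2(mean(sin(a)), mean(cos(a)))
  bm <- atan2(mean(sin(b)), mean(cos(b)))
  sa <- sin(a - am); sb <- sin(b - bm)
  sum(sa * sb) / sqrt(sum(sa^2) * sum(sb^2))
}

# Mean of the most recent `window` non-missing samples up to and including t
# (cumulative-sum implementation; NA where no sample is available).
running_mean_recent <- function(x, window) {
  n <- length(x)
  ok <- !is.na(x)
  xs <- ifelse(ok, x, 0)
  cs <- cumsum(xs)
  cn <- cumsum(as.numeric(ok))
  lag_cs <- c(rep(0, window), cs[seq_len(max(0, n - window))])[seq_len(n)]
  lag_cn <- c(rep(0, window), cn[seq_len(max(0, n - window))])[seq_len(n)]
  tot <- cs - lag_cs
  cnt <- cn - lag_cn
  out <- tot / cnt
  out[cnt == 0] <- NA_real_
  out
}

# Runs of TRUE in a logical vector -> data.frame(start, length).
true_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], length = r$lengths[r$values])
}
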