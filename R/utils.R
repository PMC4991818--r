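#' @keywords internal
"_PACKAGE"

#' @importFrom Rcpp sourceCpp
#' @useDynLib ecogcoupling, .registration = TRUE
#' @importFrom rlang abort warn .data
#' @importFrom stats fft sd var quantile median rnorm runif rbinom t.test
#'   complete.cases qbinom
#' @importFrom utils head tail
NULL

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards.  `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Deterministically derive a child seed (< 2^31) from a parent seed and a
# stage label, so independent pipeline stages draw from decoupled streams.
derive_seed <- function(seed, label) {
  h <- as.numeric(seed) %% 2147483647
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% 2147483647
  as.integer(h)
}

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s]",
                  name, format(lower), format(upper)),
          class = "ecog_config_error")
  }
  invisible(x)
}

# Analytic signal via the FFT half-spectrum construction: zero the negative
# frequencies, double the positive ones, keep DC (and Nyquist for even n).
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

# Kaiser-windowed-sinc polyphase (upfirdn) rational resampler.  Flat
# passband (error ~2e-5), >80 dB alias rejection, zero group delay.
resample_poly <- function(x, p, q) {
  p <- as.integer(p); q <- as.integer(q)
  g <- function(a, b) if (b == 0L) a else Recall(b, a %% b)
  d <- g(p, q); p <- p %/% d; q <- q %/% d
  if (p == 1L && q == 1L) return(x)
  m <- max(p, q)
  half <- 10L * m
  k <- seq(-half, half)
  fc <- 1 / (2 * m)
  h <- ifelse(k == 0, 2 * fc, sin(2 * pi * fc * k) / (pi * k))
  beta <- 7.8562
  w <- besselI(beta * sqrt(pmax(0, 1 - (k / half)^2)), 0) / besselI(beta, 0)
  h <- h * w * p
  nx <- length(x)
  up <- numeric(nx * p)
  up[seq(1, nx * p, by = p)] <- x
  len <- length(h)                      # 2 * half + 1 taps
  padded <- c(numeric(len - 1), up, numeric(len - 1))
  y <- stats::filter(padded, h, method = "convolution", sides = 1)
  # full convolution c[m] = y[m + len - 1]; take the zero-delay center
  y <- as.numeric(y[(len - 1) + half + seq_len(nx * p)])
  y[seq(1, length(y), by = q)]
}

# Truncated Gaussian smoothing kernel: `fwhm_ms` full width at half max,
# total width `width_ms`, unit sum.
gaussian_kernel <- function(fwhm_ms, width_ms, rate) {
  if (fwhm_ms <= 0) abort("`fwhm_ms` must be > 0", class = "ecog_config_error")
  if (fwhm_ms > width_ms) abort("`fwhm_ms` must not exceed `width_ms`",
                                class = "ecog_config_error")
  sigma <- fwhm_ms / 1000 / (2 * sqrt(2 * log(2)))   # FWHM -> SD in s
  half <- max(1L, round(width_ms / 1000 * rate / 2))
  t <- seq(-half, half) / rate
  k <- exp(-t^2 / (2 * sigma^2))
  k / sum(k)
}

# Convolve each row of `m` with kernel `k` using reflective edge padding.
smooth_rows <- function(m, k) {
  half <- (length(k) - 1L) %/% 2L
  n <- ncol(m)
  pad_idx <- c(rev(seq_len(half) + 1L), seq_len(n),
               n - seq_len(half))
  out <- t(apply(m[, pad_idx, drop = FALSE], 1L, function(x) {
    y <- stats::filter(x, k, method = "convolution", sides = 2)
    as.numeric(y[(half + 1L):(half + n)])
  }))
  dimnames(out) <- dimnames(m)
  out
}
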