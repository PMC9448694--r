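# Periodized orthogonal wavelet transform (Daubechies db4) and a 1-D
# nonlocal-means smoother. Written in-package: the denoiser operates on
# detail coefficients, so exact perfect reconstruction under circular
# extension is required.

# db4 decomposition low-pass filter (8 taps, orthonormal)
DB4_LO <- c(-0.010597401785069032, 0.0328830116668852,
            0.030841381835560764, -0.18703481171909309,
            -0.027983769416859854, 0.6308807679298589,
            0.7148465705529157, 0.2303778133088965)
# quadrature mirror high-pass: g[i] = (-1)^i h[L-1-i]  (0-based)
DB4_HI <- rev(DB4_LO) * (-1)^(seq_along(DB4_LO) - 1)

# one analysis step with circular extension; x must have even length
dwt_step <- function(x, lo = DB4_LO, hi = DB4_HI) {
  n <- length(x)
  stopifnot(n %% 2L == 0L, n >= length(lo))
  half <- n / 2L
  base <- (seq_len(half) - 1L) * 2L
  a <- numeric(half); d <- numeric(half)
  for (i in seq_along(lo)) {
    xi <- x[(base + (i - 1L)) %% n + 1L]
    a <- a + lo[i] * xi
    d <- d + hi[i] * xi
  }
  list(approx = a, detail = d)
}

# adjoint (= inverse, rows orthonormal under circular shifts by 2)
idwt_step <- function(a, d, lo = DB4_LO, hi = DB4_HI) {
  half <- length(a)
  stopifnot(length(d) == half)
  n <- 2L * half
  x <- numeric(n)
  base <- (seq_len(half) - 1L) * 2L
  for (i in seq_along(lo)) {
    # distinct positions: a constant circular shift of the even grid
    pos <- (base + (i - 1L)) %% n + 1L
    x[pos] <- x[pos] + lo[i] * a + hi[i] * d
  }
  x
}

# multi-level periodized DWT; odd-length levels padded by repeating the
# final sample (pad bookkeeping kept for exact-length inverse)
dwt_pyramid <- function(x, levels = 4, lo = DB4_LO, hi = DB4_HI) {
  details <- vector("list", levels)
  pads <- logical(levels)
  cur <- as.numeric(x)
  for (j in seq_len(levels)) {
    if (length(cur) %% 2L == 1L) {
      cur <- c(cur, cur[length(cur)])
      pads[j] <- TRUE
    }
    if (length(cur) < length(lo))
      stop("signal too short for the requested wavelet decomposition depth")
    st <- dwt_step(cur, lo, hi)
    details[[j]] <- st$detail
    cur <- st$approx
  }
  list(approx = cur, details = details, pads = pads, n = length(x))
}

idwt_pyramid <- function(dec, lo = DB4_LO, hi = DB4_HI) {
  cur <- dec$approx
  for (j in rev(seq_along(dec$details))) {
    cur <- idwt_step(cur, dec$details[[j]], lo, hi)
    if (dec$pads[j]) cur <- cur[-length(cur)]
  }
  cur[seq_len(dec$n)]
}

#' One-dimensional nonlocal-means smoothing
#'
#' Replaces each sample by a weighted average of samples inside a search
#' window, with weights decaying in the mean squared difference between
#' the local patches around the two samples:
#' `w(i, j) = exp(-msd(i, j) / (2 h^2))`. Used on wavelet detail
#' coefficients by [denoise_eeg()], but exported as a generic smoother.
#'
#' @param x Numeric vector.
#' @param h Bandwidth (same units as `x`); larger smooths more.
#' @param patch Patch half-width in samples (default 5).
#' @param search Search half-width in samples (default 50).
#' @return Smoothed numeric vector, same length as `x`.
#' @export
nlm_smooth <- function(x, h, patch = 5, search = 50) {
  n <- length(x)
  if (n == 0L) return(x)
  if (h <= 0) return(x)
  box <- rep(1 / (2 * patch + 1), 2 * patch + 1)
  num <- x            # shift 0: weight 1
  den <- rep(1, n)
  for (s in c(-(search:1), 1:search)) {
    if (abs(s) >= n) next
    xs <- rep(NA_real_, n)
    if (s > 0) xs[1:(n - s)] <- x[(1 + s):n] else xs[(1 - s):n] <- x[1:(n + s)]
    d2 <- (x - xs)^2
    msd <- stats::filter(d2, box, sides = 2)
    w <- exp(-as.numeric(msd) / (2 * h^2))
    ok <- !is.na(w) & !is.na(xs)
    num[ok] <- num[ok] + w[ok] * xs[ok]
    den[ok] <- den[ok] + w[ok]
  }
  num / den
}
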