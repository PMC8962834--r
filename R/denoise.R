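# Coiflet-5 orthonormal decomposition low-pass filter (30 taps, standard
# published coefficients). The high-pass filter is the quadrature mirror.
COIF5_LO <- c(
  -9.604010112767894e-08, -1.6237995172048338e-07, 2.0612203985788783e-06,
  3.7007277113394796e-06, -2.1270221672515614e-05, -4.12198619242655e-05,
  1.4035632812373243e-04, 3.018579416682448e-04, -6.375589261258812e-04,
  -1.6616273039298788e-03, 2.4315754425382886e-03, 6.761520220620417e-03,
  -9.159507338676163e-03, -1.9758391600965465e-02, 3.2674799467057355e-02,
  4.1287530472117834e-02, -1.0556315130733723e-01, -6.203775157498196e-02,
  4.379823066591634e-01, 7.742936228603274e-01, 4.2157126673075435e-01,
  -5.2046670253554764e-02, -9.192158806008609e-02, 2.8169744270532353e-02,
  2.3408322118927783e-02, -1.0131584846900276e-02, -4.15931262757864e-03,
  2.1782943778456947e-03, 3.585777411617577e-04, -2.12081862067494e-04
)

coif5_hi <- function() {
  h <- COIF5_LO
  n <- length(h)
  rev(h) * (-1)^(seq_len(n) - 1)
}

# One analysis step of the periodized orthonormal DWT. x must have even
# length; returns approximation and detail coefficient vectors of length n/2.
dwt_step <- function(x, lo, hi) {
  n <- length(x)
  L <- length(lo)
  half <- n / 2
  a <- numeric(half)
  d <- numeric(half)
  for (k in seq_len(half)) {
    idx <- ((2 * k - 2 + seq_len(L) - 1) %% n) + 1
    seg <- x[idx]
    a[k] <- sum(lo * seg)
    d[k] <- sum(hi * seg)
  }
  list(a = a, d = d)
}

idwt_step <- function(a, d, lo, hi) {
  half <- length(a)
  n <- 2 * half
  L <- length(lo)
  x <- numeric(n)
  for (k in seq_len(half)) {
    idx <- ((2 * k - 2 + seq_len(L) - 1) %% n) + 1
    x[idx] <- x[idx] + a[k] * lo + d[k] * hi
  }
  x
}

# Full periodized decomposition to `level` scales. Odd-length inputs at any
# scale are extended by repeating the last sample (the duplicate is dropped on
# reconstruction).
dwt_periodic <- function(x, level, lo = COIF5_LO, hi = coif5_hi()) {
  details <- vector("list", level)
  lengths <- integer(level)
  a <- x
  for (j in seq_len(level)) {
    lengths[j] <- length(a)
    if (length(a) %% 2 == 1) a <- c(a, a[length(a)])
    st <- dwt_step(a, lo, hi)
    a <- st$a
    details[[j]] <- st$d
  }
  list(approx = a, details = details, lengths = lengths)
}

idwt_periodic <- function(dec, lo = COIF5_LO, hi = coif5_hi()) {
  a <- dec$approx
  for (j in rev(seq_along(dec$details))) {
    a <- idwt_step(a, dec$details[[j]], lo, hi)
    a <- a[seq_len(dec$lengths[j])]
  }
  a
}

#' SURE-minimizing soft threshold
#'
#' Stein's Unbiased Risk Estimate for soft thresholding of `x ~ N(theta, 1)`:
#' the candidate thresholds are the absolute coefficient values, and the
#' returned threshold minimizes the estimated risk. Coefficients should be
#' normalized to unit noise scale before calling.
#'
#' @param x Numeric vector of (noise-normalized) coefficients.
#' @return The threshold value.
#' @export
sure_threshold <- function(x) {
  n <- length(x)
  if (n == 0) return(0)
  s <- sort(x^2)
  cs <- cumsum(s)
  k <- seq_len(n)
  # risk of thresholding at t = sqrt(s[k]): coefficients 1..k are shrunk to 0
  risk <- (n - 2 * k + cs + (n - k) * s) / n
  sqrt(s[which.min(risk)])
}

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

max_dwt_level <- function(n, filter_len = length(COIF5_LO), cap = 8L) {
  lev <- 0L
  while (n >= filter_len && lev < cap) {
    n <- ceiling(n / 2)
    lev <- lev + 1L
  }
  lev
}

#' Wavelet-denoise one voltage series
#'
#' Decomposes the series with the periodized coiflet-5 orthonormal wavelet
#' transform, soft-thresholds each detail level at its SURE-minimizing
#' threshold (noise scale estimated once from the finest detail level via the
#' median absolute deviation), leaves the approximation coefficients
#' untouched, and reconstructs. Series length is always preserved.
#'
#' @param x Numeric vector, length >= 2.
#' @param level Decomposition depth, or `NULL` (default) for the maximum depth
#'   the series length supports, capped at 8.
#' @return Denoised numeric vector of the same length.
#' @export
denoise_lead <- function(x, level = NULL) {
  n <- length(x)
  if (n < 2) abort("`x` must have length >= 2.")
  max_lev <- max_dwt_level(n)
  if (max_lev < 1L) {
    warn(sprintf(
      "Series of length %d is shorter than the coif5 filter support; returning it unchanged.",
      n
    ))
    return(x)
  }
  level <- if (is.null(level)) max_lev else min(as.integer(level), max_lev)
  dec <- dwt_periodic(x, level)
  sigma <- mad(dec$details[[1]], center = 0)
  if (sigma > 0) {
    for (j in seq_along(dec$details)) {
      t_j <- sigma * sure_threshold(dec$details[[j]] / sigma)
      dec$details[[j]] <- soft_threshold(dec$details[[j]], t_j)
    }
  }
  idwt_periodic(dec)
}

#' Denoise all 12 leads of a recording
#'
#' [denoise_lead()] applied independently to each lead; metadata unchanged.
#'
#' @param rec An [ecg_recording()].
#' @inheritParams denoise_lead
#' @return The denoised [ecg_recording()].
#' @export
denoise_recording <- function(rec, level = NULL) {
  stopifnot(inherits(rec, "ecg_recording"))
  rec$signal <- t(apply(rec$signal, 1, denoise_lead, level = level))
  rownames(rec$signal) <- ECG_LEADS
  rec
}
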