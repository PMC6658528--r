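# steady-state spectrum processing

#' Normalize a steady-state spectrum
#'
#' Scales the spectrum so that a reference value equals one: either the
#' absorbance at 280 nm (protein band) or the maximum within the chromophore
#' window (330-650 nm by default).
#'
#' @param spectrum data frame with increasing `wavelength_nm` and `absorbance`.
#' @param mode `"at_280"` or `"chromophore_max"`.
#' @param chromophore_window c(lo, hi) nm for `"chromophore_max"`.
#' @return tibble with the same columns, scaled.
#' @export
normalize_spectrum <- function(spectrum, mode = c("chromophore_max", "at_280"),
                               chromophore_window = c(330, 650)) {
  mode <- match.arg(mode)
  wl <- spectrum$wavelength_nm; a <- spectrum$absorbance
  ref <- if (mode == "at_280") {
    if (280 < min(wl) || 280 > max(wl)) abort_pc("280 nm outside the spectrum range")
    stats::approx(wl, a, xout = 280)$y
  } else {
    sel <- wl >= chromophore_window[1] & wl <= chromophore_window[2]
    if (!any(sel)) abort_pc("chromophore window outside the spectrum range")
    max(a[sel])
  }
  if (ref == 0) abort_pc("zero reference absorbance")
  tibble::tibble(wavelength_nm = wl, absorbance = a / ref)
}

#' Savitzky-Golay smoothing of a spectrum
#'
#' Standard symmetric Savitzky-Golay convolution; the window must be odd and
#' larger than the polynomial order, so the conventional even 10-point window
#' is widened to the next odd width (11). Polynomials up to the filter order
#' pass through unchanged.
#'
#' @param spectrum data frame with `wavelength_nm`, `absorbance` (>= 11 points).
#' @param window_points odd window width (default 11).
#' @param poly_order polynomial order (default 5).
#' @return smoothed tibble.
#' @export
smooth_sg <- function(spectrum, window_points = 11, poly_order = 5) {
  if (window_points %% 2 == 0) abort_pc("window_points must be odd")
  if (poly_order >= window_points) abort_pc("poly_order must be below window_points")
  a <- spectrum$absorbance
  if (length(a) < window_points) abort_pc("need at least ", window_points, " points")
  tibble::tibble(wavelength_nm = spectrum$wavelength_nm,
                 absorbance = as.numeric(
                   signal::sgolayfilt(a, p = poly_order, n = window_points)))
}

#' Pointwise difference of two spectra on identical grids
#'
#' @param a,b spectra (data frames with `wavelength_nm`, `absorbance`) on
#'   exactly the same wavelength grid; no resampling is performed.
#' @return tibble `a - b`.
#' @export
difference_spectrum <- function(a, b) {
  if (length(a$wavelength_nm) != length(b$wavelength_nm) ||
      any(a$wavelength_nm != b$wavelength_nm)) {
    abort_pc("wavelength grids differ; resample before subtracting")
  }
  tibble::tibble(wavelength_nm = a$wavelength_nm,
                 absorbance = a$absorbance - b$absorbance)
}

#' Locate sub-maxima of a (smoothed) spectrum
#'
#' Finds strict local maxima within a wavelength window and refines each by
#' the vertex of the parabola through the three neighbouring samples.
#'
#' @param spectrum data frame with `wavelength_nm`, `absorbance`.
#' @param window c(lo, hi) wavelength range to search (nm).
#' @return numeric vector of peak wavelengths (nm), possibly empty.
#' @export
find_submaxima <- function(spectrum, window = range(spectrum$wavelength_nm)) {
  wl <- spectrum$wavelength_nm; a <- spectrum$absorbance
  n <- length(a)
  if (n < 3) return(numeric())
  idx <- which(a[2:(n - 1)] > a[1:(n - 2)] & a[2:(n - 1)] > a[3:n]) + 1L
  idx <- idx[wl[idx] >= window[1] & wl[idx] <= window[2]]
  vapply(idx, function(i) {
    x <- wl[(i - 1):(i + 1)]; y <- a[(i - 1):(i + 1)]
    d2 <- y[1] - 2 * y[2] + y[3]
    if (d2 >= 0) return(x[2])
    # quadratic vertex on a possibly non-uniform grid
    co <- solve(cbind(1, x, x^2), y)
    -co[2] / (2 * co[3])
  }, numeric(1))
}
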