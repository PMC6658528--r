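# action-spectrum fitting

# Weibull density shape on wavelength: x = (lambda - lambda0)/beta, value
# x^(k-1) exp(-x^k) for x > 0, else 0 (amplitude absorbed separately)
weibull_shape <- function(lambda, lambda0, beta, k) {
  x <- (lambda - lambda0) / beta
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- x[pos]^(k - 1) * exp(-x[pos]^k)
  out
}

#' Analytic peak of the three-parameter Weibull shape
#' @param lambda0 location (nm), @param beta scale (nm), @param k shape (> 1).
#' @return wavelength of the maximum (nm): lambda0 + beta ((k-1)/k)^(1/k).
#' @export
weibull_lambda_max <- function(lambda0, beta, k) {
  lambda0 + beta * ((k - 1) / k)^(1 / k)
}

#' Fit a three-parameter Weibull to a normalized action spectrum
#'
#' Fits the peaked Weibull density shape (location lambda0, scale beta,
#' shape k > 1, free amplitude) to a max-normalized action spectrum and
#' returns the wavelength of maximal response analytically as
#' lambda0 + beta ((k-1)/k)^(1/k). Internal parameterisation keeps beta > 0
#' and k > 1 during optimisation; a fit degenerating to a monotone curve
#' (k -> 1) is flagged.
#'
#' @param spectrum data frame with increasing `wavelength_nm` and `response`
#'   (will be max-normalized); at least 6 points spanning the peak.
#' @return object of class `weibull_fit` with `lambda_max_nm`, `lambda0`,
#'   `beta`, `k`, `amplitude`, `residual_rms`, `converged`, `monotone_flag`.
#' @export
weibull_action_fit <- function(spectrum) {
  wl <- spectrum$wavelength_nm
  y <- spectrum$response
  if (length(wl) < 6) abort_pc("need at least 6 points spanning the peak")
  if (!is_strictly_increasing(wl)) abort_pc("wavelengths must be increasing")
  y <- y / max(y)
  peak_wl <- wl[which.max(y)]
  span <- diff(range(wl))
  # theta = (lambda0, log(beta), log(k - 1)); amplitude solved linearly
  resid_fun <- function(theta) {
    s <- weibull_shape(wl, theta[1], exp(theta[2]), 1 + exp(theta[3]))
    a <- if (sum(s^2) > 0) sum(s * y) / sum(s^2) else 0
    y - a * s
  }
  starts <- list(c(min(wl) - 0.2 * span, log(peak_wl - min(wl) + 0.3 * span), log(1)),
                 c(min(wl) - 1.0 * span, log(1.5 * span), log(1.5)),
                 c(peak_wl - 0.8 * span, log(span), log(0.5)))
  best <- NULL
  for (st in starts) {
    fit <- try(minpack.lm::nls.lm(par = st, fn = resid_fun,
                                  control = minpack.lm::nls.lm.control(
                                    maxiter = 400, ftol = 1e-15, ptol = 1e-15)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || sum(fit$fvec^2) < sum(best$fvec^2)) best <- fit
  }
  if (is.null(best)) abort_pc("Weibull fit failed from all starting points")
  theta <- best$par
  lambda0 <- theta[1]; beta <- exp(theta[2]); k <- 1 + exp(theta[3])
  s <- weibull_shape(wl, lambda0, beta, k)
  amplitude <- sum(s * y) / sum(s^2)
  structure(list(lambda_max_nm = weibull_lambda_max(lambda0, beta, k),
                 lambda0 = lambda0, beta = beta, k = k, amplitude = amplitude,
                 residual_rms = sqrt(sum(best$fvec^2) / length(y)),
                 converged = best$info %in% 1:4,
                 monotone_flag = k < 1 + 1e-6,
                 data = tibble::tibble(wavelength_nm = wl, response = y)),
            class = "weibull_fit")
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat("<weibull_fit> lambda_max:", signif(x$lambda_max_nm, 5), "nm",
      "(lambda0", signif(x$lambda0, 4), ", beta", signif(x$beta, 4),
      ", k", signif(x$k, 4), ")\n")
  invisible(x)
}

#' @rdname weibull_action_fit
#' @param x a `weibull_fit`.
#' @param ... unused.
#' @export
tidy.weibull_fit <- function(x, ...) {
  tibble::tibble(term = c("lambda_max_nm", "lambda0", "beta", "k", "amplitude"),
                 estimate = c(x$lambda_max_nm, x$lambda0, x$beta, x$k, x$amplitude))
}

#' @rdname weibull_action_fit
#' @export
glance.weibull_fit <- function(x, ...) {
  tibble::tibble(residual_rms = x$residual_rms, converged = x$converged,
                 monotone_flag = x$monotone_flag)
}
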