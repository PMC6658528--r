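# pH-titration analysis

boltzmann_curve <- function(pH, A1, A2, pK, h) {
  A1 + (A2 - A1) / (1 + 10^(h * (pK - pH)))
}

#' Boltzmann fit of a pH titration series
#'
#' Fits the base-10 Boltzmann (Hill-type logistic)
#' `A(pH) = A1 + (A2 - A1) / (1 + 10^(h (pK - pH)))` to amplitude-vs-pH data
#' and reports the transition pK. `A1` and `A2` are the acid- and base-side
#' plateaus; `h` is the Hill slope (1 for a single protonatable group). The
#' curve value at pK is the plateau midpoint; decreasing series fit equally
#' well (the sign of `A2 - A1` flips).
#'
#' @param titration data frame with `pH` and `amplitude` (>= 4 points
#'   spanning the transition).
#' @param hill_fixed optionally fix the Hill slope (e.g. 1); default free.
#' @return object of class `boltzmann_fit` with `pK`, `hill_slope`,
#'   `plateaus` (c(A1, A2)), `residual_rms`, `converged`, `pk_in_span`.
#' @export
boltzmann_pk_fit <- function(titration, hill_fixed = NULL) {
  pH <- titration$pH; A <- titration$amplitude
  if (length(pH) < 4) abort_pc("need at least 4 pH points")
  mid <- (max(A) + min(A)) / 2
  pk0 <- pH[which.min(abs(A - mid))]
  increasing <- stats::cor(pH, A) >= 0
  par0 <- if (is.null(hill_fixed)) c(pk0, 1) else pk0
  resid_fun <- function(par) {
    pK <- par[1]
    h0 <- if (is.null(hill_fixed)) par[2] else hill_fixed
    h <- if (increasing) abs(h0) else -abs(h0)
    # plateaus solved linearly at fixed (pK, h)
    f <- 1 / (1 + 10^(h * (pK - pH)))
    X <- cbind(1 - f, f)
    co <- qr.coef(qr(X), A)
    co[is.na(co)] <- 0
    A - X %*% co
  }
  fit <- minpack.lm::nls.lm(par = par0, fn = resid_fun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 300, ftol = 1e-15, ptol = 1e-15))
  pK <- fit$par[1]
  h0 <- if (is.null(hill_fixed)) fit$par[2] else hill_fixed
  h <- if (increasing) abs(h0) else -abs(h0)
  f <- 1 / (1 + 10^(h * (pK - pH)))
  X <- cbind(1 - f, f)
  co <- as.numeric(qr.coef(qr(X), A))
  in_span <- pK >= min(pH) && pK <= max(pH)
  structure(list(pK = pK, hill_slope = abs(h0), plateaus = co,
                 increasing = increasing,
                 residual_rms = sqrt(sum(fit$fvec^2) / length(A)),
                 converged = fit$info %in% 1:4 && in_span,
                 pk_in_span = in_span,
                 data = tibble::tibble(pH = pH, amplitude = A)),
            class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat("<boltzmann_fit> pK:", signif(x$pK, 4), "; Hill slope:",
      signif(x$hill_slope, 3), "\n")
  invisible(x)
}

#' @rdname boltzmann_pk_fit
#' @param x a `boltzmann_fit`.
#' @param ... unused.
#' @export
tidy.boltzmann_fit <- function(x, ...) {
  tibble::tibble(term = c("pK", "hill_slope", "plateau_1", "plateau_2"),
                 estimate = c(x$pK, x$hill_slope, x$plateaus))
}

#' @rdname boltzmann_pk_fit
#' @export
glance.boltzmann_fit <- function(x, ...) {
  tibble::tibble(residual_rms = x$residual_rms, converged = x$converged,
                 pk_in_span = x$pk_in_span)
}
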