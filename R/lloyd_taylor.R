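#' Lloyd-Taylor respiration function
#'
#' `R(T) = Rref * exp(E0 * (1/(Tref - T0) - 1/(T - T0)))` with the
#' conventional constants `Tref = 15` C and `T0 = -46.02` C.
#'
#' @param temp temperature, degrees C.
#' @param rref base respiration at `tref`, umol m-2 s-1.
#' @param e0 temperature sensitivity, K.
#' @param tref,t0 reference and zero temperature, degrees C.
#' @return respiration, umol m-2 s-1.
#' @export
lloyd_taylor <- function(temp, rref, e0, tref = 15, t0 = -46.02) {
  rref * exp(e0 * (1 / (tref - t0) - 1 / (temp - t0)))
}

#' Fit the Lloyd-Taylor model to nighttime flux/temperature pairs
#'
#' Nonlinear least squares via Levenberg-Marquardt with `E0` bounded to
#' `[30, 450]` K. When the temperature range is too narrow to identify `E0`
#' (< `min_range` C) or the nonlinear fit fails, `E0` is fixed (argument
#' `e0_fallback`) and only `Rref` is estimated, which is then linear:
#' `Rref = sum(R f) / sum(f^2)` with `f` the unit-Rref Lloyd-Taylor factor.
#'
#' @param temp nighttime temperature, C.
#' @param resp observed nighttime respiration (= -NEP), umol m-2 s-1.
#' @param e0_bounds numeric(2) bounds for `E0`, K.
#' @param e0_fallback fixed `E0` used on the degenerate path (`NULL` to
#'   signal failure instead).
#' @param min_pairs,min_range minimum number of pairs and temperature span
#'   (C) required for the two-parameter fit.
#' @param tref,t0 Lloyd-Taylor constants, degrees C.
#' @return object of class `lloyd_taylor_fit`: coefficients `rref`, `e0`,
#'   diagnostics `rmse`, `n`, standard errors, and `e0_fixed` flag; or
#'   `NULL` (window-skip signal) if fewer than `min_pairs` valid pairs and
#'   no fallback is possible.
#' @export
fit_lloyd_taylor <- function(temp, resp, e0_bounds = c(30, 450),
                             e0_fallback = NULL,
                             min_pairs = 10, min_range = 5,
                             tref = 15, t0 = -46.02) {
  ok <- is.finite(temp) & is.finite(resp)
  temp <- temp[ok]; resp <- resp[ok]
  n <- length(temp)
  if (n < max(2, min_pairs) && is.null(e0_fallback)) return(NULL)
  span <- if (n) diff(range(temp)) else 0

  fit_rref_only <- function(e0) {
    f <- lloyd_taylor(temp, 1, e0, tref, t0)
    rref <- sum(resp * f) / sum(f * f)
    res <- resp - rref * f
    se <- sqrt(sum(res^2) / max(n - 1, 1) / sum(f * f))
    new_ltfit(rref, e0, n, res, rref_se = se, e0_se = NA_real_,
              e0_fixed = TRUE, tref = tref, t0 = t0)
  }

  if (n >= min_pairs && span >= min_range) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        resp ~ rref * exp(e0 * (1 / (tref - t0) - 1 / (temp - t0))),
        start = list(rref = max(mean(resp), 0.1), e0 = 150),
        lower = c(0, e0_bounds[1]), upper = c(Inf, e0_bounds[2]),
        control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      cf <- stats::coef(fit)
      ses <- tryCatch(sqrt(diag(stats::vcov(fit))),
                      error = function(e) c(NA_real_, NA_real_))
      return(new_ltfit(cf[["rref"]], cf[["e0"]], n, stats::resid(fit),
                       rref_se = ses[1], e0_se = ses[2], e0_fixed = FALSE,
                       tref = tref, t0 = t0))
    }
  }
  if (is.null(e0_fallback)) return(NULL)
  fit_rref_only(e0_fallback)
}

new_ltfit <- function(rref, e0, n, res, rref_se, e0_se, e0_fixed, tref, t0) {
  structure(list(coefficients = c(rref = unname(rref), e0 = unname(e0)),
                 rmse = sqrt(mean(res^2)), n = n,
                 rref_se = unname(rref_se), e0_se = unname(e0_se),
                 e0_fixed = e0_fixed, tref = tref, t0 = t0),
            class = "lloyd_taylor_fit")
}

#' @export
coef.lloyd_taylor_fit <- function(object, ...) object$coefficients

#' @param object a `lloyd_taylor_fit`.
#' @param newdata numeric vector of temperatures (C); if missing, an error.
#' @rdname fit_lloyd_taylor
#' @export
predict.lloyd_taylor_fit <- function(object, newdata, ...) {
  cf <- object$coefficients
  lloyd_taylor(newdata, cf[["rref"]], cf[["e0"]], object$tref, object$t0)
}

#' @export
print.lloyd_taylor_fit <- function(x, ...) {
  cf <- x$coefficients
  cat("Lloyd-Taylor respiration fit\n")
  cat(sprintf("  Rref = %.3f umol m-2 s-1 (at %g C)   E0 = %.1f K%s\n",
              cf[["rref"]], x$tref, cf[["e0"]],
              if (x$e0_fixed) " [fixed]" else ""))
  cat(sprintf("  n = %d   RMSE = %.3f\n", x$n, x$rmse))
  invisible(x)
}
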