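#' Fit the log-linear SEC molecular-weight calibration
#'
#' Size-exclusion columns separate log-linearly over their working range:
#' ln(MW) falls linearly with elution (fraction index), larger assemblies
#' eluting earlier. The model is an ordinary least-squares fit of
#' ln(mw_kda) on apex fraction of a set of reference standards.
#'
#' @param standards `data.frame` with columns `std_weights_kda` and
#'   `std_elu_fractions` (one row per reference protein), or a two-column
#'   matrix/data.frame in that order.
#' @return A `calibration_model` with `slope` (ln(kDa)/fraction, < 0),
#'   `intercept` (ln(kDa)), `n_standards`, and `rmse` (ln(kDa)).
#' @export
fit_calibration <- function(standards) {
  standards <- as.data.frame(standards)
  if (!all(c("std_weights_kda", "std_elu_fractions") %in% names(standards))) {
    if (ncol(standards) < 2L) stop("standards needs two columns")
    names(standards)[1:2] <- c("std_weights_kda", "std_elu_fractions")
  }
  mw <- as.numeric(standards$std_weights_kda)
  fr <- as.numeric(standards$std_elu_fractions)
  if (length(mw) < 2L) stop("need at least 2 calibration standards")
  if (any(mw <= 0)) stop("calibration standard masses must be positive")
  if (sd(fr) == 0) stop("calibration standards have zero fraction variance")
  fit <- lm(log(mw) ~ fr)
  slope <- unname(coef(fit)[2L])
  if (slope >= 0)
    stop("non-physical calibration: fitted slope >= 0 ",
         "(larger species must elute earlier)")
  structure(list(slope = slope, intercept = unname(coef(fit)[1L]),
                 n_standards = length(mw),
                 rmse = sqrt(mean(resid(fit)^2))),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "<calibration_model> ln(kDa) = %.4f %+.4f * fraction (n = %d, rmse = %.3g)\n",
    x$intercept, x$slope, x$n_standards, x$rmse))
  invisible(x)
}

check_calibration <- function(model) {
  if (!inherits(model, "calibration_model"))
    stop("not a calibration_model")
  invisible(model)
}

#' Convert between fraction index and apparent molecular weight
#'
#' `fraction_to_mw` evaluates exp(slope * fraction + intercept);
#' `mw_to_fraction` inverts it. The two are mutual inverses to numerical
#' precision. Fractions outside the span of the calibration standards
#' extrapolate on the same line (apex fractions of very large or very
#' small species routinely fall outside the standards).
#'
#' @param model a `calibration_model`.
#' @param fraction numeric fraction index (may be non-integer).
#' @param mw_kda apparent molecular weight in kDa, > 0.
#' @return kDa for `fraction_to_mw`; fractional fraction index for
#'   `mw_to_fraction`.
#' @export
fraction_to_mw <- function(model, fraction) {
  check_calibration(model)
  exp(model$slope * as.numeric(fraction) + model$intercept)
}

#' @rdname fraction_to_mw
#' @export
mw_to_fraction <- function(model, mw_kda) {
  check_calibration(model)
  mw_kda <- as.numeric(mw_kda)
  if (any(mw_kda <= 0)) stop("molecular weight must be positive")
  (log(mw_kda) - model$intercept) / model$slope
}

#' Expected elution fraction of a complex under 1:1 stoichiometry
#'
#' The expected apex of a complex is the calibrated fraction of the
#' cumulative mass of one copy of each component.
#'
#' @param model a `calibration_model`.
#' @param monomer_mws_kda numeric vector of component monomer masses, kDa.
#' @return Expected (fractional) apex fraction.
#' @export
expected_complex_fraction <- function(model, monomer_mws_kda) {
  monomer_mws_kda <- as.numeric(monomer_mws_kda)
  if (length(monomer_mws_kda) == 0L) stop("empty monomer mass list")
  if (any(monomer_mws_kda <= 0)) stop("monomer masses must be positive")
  mw_to_fraction(model, sum(monomer_mws_kda))
}

#' Attach per-fraction apparent molecular weight to a trace matrix
#'
#' Evaluates the calibration at the integer fraction centers and stores the
#' result in the `fraction_mw` slot.
#'
#' @param tm a `sec_traces` object.
#' @param model a `calibration_model`.
#' @return `tm` with `fraction_mw` filled.
#' @export
annotate_fraction_mw <- function(tm, model) {
  stopifnot(inherits(tm, "sec_traces"))
  check_calibration(model)
  tm$fraction_mw <- fraction_to_mw(model, tm$fractions)
  tm
}
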