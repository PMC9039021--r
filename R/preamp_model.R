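#' Threshold-gated exponential preamplification model
#'
#' The detectable output of the assay is modelled as
#' `n = f(k) * k * A`, where `k` is the template copy number at the
#' start of preamplification, `n` the resulting number of positive
#' partitions, `A = exp(t*v)` the (dimensionless) amplification factor
#' absorbing reaction time and rate, and `f(k)` a hard gate: `f(k) = 0`
#' for `k < h` and `1` for `k >= h`, with `h` the detection threshold
#' in copies. Below the gate the reaction fails entirely; above it the
#' output is proportional to the input.
#'
#' @param amp_factor amplification factor `A` (at least 1).
#' @param threshold_h detection threshold `h` in copies (default 0:
#'   no gating).
#' @param r2 optional coefficient of determination of the fit that
#'   produced `amp_factor`.
#' @return a `preamp_model` object.
#' @seealso [fit_amp_factor()], [predict_output()],
#'   [censor_artifacts()].
#' @export
preamp_model <- function(amp_factor, threshold_h = 0, r2 = NA_real_) {
  if (!is.numeric(amp_factor) || length(amp_factor) != 1L ||
      !is.finite(amp_factor) || amp_factor < 1)
    stop_invalid("amp_factor must be a single number >= 1")
  check_nonneg_scalar(threshold_h, "threshold_h")
  if (!is.na(r2) && (r2 < 0 || r2 > 1))
    stop_invalid("r2 must lie in [0, 1]")
  structure(list(amp_factor = amp_factor, threshold_h = threshold_h,
                 r2 = r2),
            class = "preamp_model")
}

#' @export
print.preamp_model <- function(x, ...) {
  cat(sprintf("<preamp_model> A = %.4g, h = %g copies%s\n",
              x$amp_factor, x$threshold_h,
              if (is.na(x$r2)) "" else sprintf(", R2 = %.3f", x$r2)))
  invisible(x)
}

#' Fit the amplification factor from calibration observations
#'
#' Estimates `A` in `n = A * k` by least squares through the origin
#' over the supra-threshold observations (`k >= threshold_h`):
#' `A = sum(k * n) / sum(k^2)`. With a single observation this reduces
#' to the ratio `n / k`, e.g. 1574 positive droplets from 65 input
#' copies give `A = 24.2`.
#'
#' @param k template copies at the start of preamplification (vector).
#' @param n observed positive partitions (vector, same length).
#' @param threshold_h detection threshold; observations below it are
#'   excluded from the fit.
#' @return the fitted amplification factor (numeric scalar).
#' @examples
#' fit_amp_factor(65, 1574)  # 24.2
#' @export
fit_amp_factor <- function(k, n, threshold_h = 0) {
  if (length(k) != length(n) || length(k) < 1L)
    stop_invalid("k and n must be non-empty vectors of equal length")
  if (any(!is.finite(k)) || any(!is.finite(n)) || any(k < 1) || any(n <= 0))
    stop_invalid("each observation needs k >= 1 and n > 0")
  keep <- k >= threshold_h
  if (!any(keep))
    stop_invalid("all observations are below threshold_h; cannot fit")
  sum(k[keep] * n[keep]) / sum(k[keep]^2)
}

#' Predict the positive-partition output for a template input
#'
#' Applies the threshold-gated model: `round(A * k)` for `k >= h`, 0
#' otherwise. Predictions are rounded to whole partitions.
#'
#' @param model a [preamp_model()].
#' @param k template copies at the start of preamplification
#'   (vectorized, non-negative).
#' @return expected positive partitions (integer-valued numeric).
#' @examples
#' m <- preamp_model(24.2)
#' predict_output(m, c(50, 25, 12))  # 1210 605 290
#' @export
predict_output <- function(model, k) {
  stopifnot(inherits(model, "preamp_model"))
  if (any(!is.finite(k)) || any(k < 0)) stop_invalid("k must be >= 0")
  ifelse(k >= model$threshold_h, round(model$amp_factor * k), 0)
}

#' Censor artifact counts against the model prediction
#'
#' Solitary positive partitions far below the model's prediction arise
#' from probe degradation or non-specific binding rather than genuine
#' template, and are replaced with zero. An observation is censored
#' when it falls below `artifact_fraction` of the predicted output (or
#' when the input is below the detection threshold, where the model
#' predicts no output at all); otherwise it is returned unchanged.
#'
#' @param observed_n observed positive partitions (vectorized,
#'   non-negative).
#' @param model a [preamp_model()].
#' @param k template copies at the start of preamplification
#'   (vectorized).
#' @param artifact_fraction censoring cutoff as a fraction of the
#'   prediction (default 0.01).
#' @return corrected counts.
#' @examples
#' m <- preamp_model(24.2)
#' censor_artifacts(3, m, 50)     # 0: 3 << 1210 is an artifact
#' censor_artifacts(1574, m, 65)  # kept
#' @export
censor_artifacts <- function(observed_n, model, k,
                             artifact_fraction = 0.01) {
  stopifnot(inherits(model, "preamp_model"))
  if (any(observed_n < 0)) stop_invalid("observed_n must be >= 0")
  check_probability(artifact_fraction, "artifact_fraction")
  predicted <- ifelse(k >= model$threshold_h, model$amp_factor * k, 0)
  ifelse(k < model$threshold_h |
           observed_n < artifact_fraction * predicted,
         0, observed_n)
}

#' Fit the exponential cycle-number trend
#'
#' Fits the dependence of detectable output on preamplification cycle
#' number as an exponential trend, via linear regression of
#' `log(output)` on `cycles`. Returns the per-cycle growth multiplier
#' `exp(slope)` and the regression R². Non-positive outputs cannot
#' enter the log fit and are dropped with a warning; constant outputs
#' yield growth 1 (and R² 1, the degenerate trend fitting exactly).
#'
#' @param cycles cycle numbers (numeric vector).
#' @param output detectable outputs at each cycle number.
#' @return list with `growth` (per-cycle multiplier) and `r2`.
#' @examples
#' fit_cycle_trend(0:5, 2^(0:5))  # growth 2, r2 1
#' @export
fit_cycle_trend <- function(cycles, output) {
  if (length(cycles) != length(output))
    stop_invalid("cycles and output must have equal length")
  usable <- is.finite(cycles) & is.finite(output) & output > 0
  if (any(!usable & is.finite(output)))
    warning("dropping ", sum(!usable), " non-positive output value(s)",
            call. = FALSE)
  cycles <- cycles[usable]; output <- output[usable]
  if (length(cycles) < 3L)
    stop_invalid("need at least 3 usable (cycles, output) points")
  ly <- log(output)
  if (var(ly) == 0) return(list(growth = 1, r2 = 1))
  fit <- lm(ly ~ cycles)
  r2 <- 1 - sum(fit$residuals^2) / sum((ly - mean(ly))^2)
  list(growth = exp(unname(coef(fit)[2])), r2 = r2)
}
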