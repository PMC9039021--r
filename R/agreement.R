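#' Pair measurements across two platforms
#'
#' Matches measurements by key and applies the exclusion rules of a
#' method-comparison analysis: keys measured on only one platform are
#' dropped (no pairing possible), and pairs where either value is zero
#' are dropped (a zero cannot enter a log-scale comparison). Exclusion
#' counts and ids are attached as attributes.
#'
#' @param platform_a,platform_b data frames with columns `id` and
#'   `value`; `id` must be unique within each platform.
#' @return data frame with columns `id`, `a`, `b`; attributes
#'   `excluded_unpaired` and `excluded_zero` list the dropped ids.
#' @export
pair_measurements <- function(platform_a, platform_b) {
  for (nm in c("platform_a", "platform_b")) {
    df <- get(nm)
    if (!is.data.frame(df) || !all(c("id", "value") %in% names(df)))
      stop_invalid(nm, " must be a data frame with columns id and value")
    if (anyDuplicated(df$id))
      stop_invalid("duplicate ids in ", nm, ": ",
                   paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  }
  merged <- merge(platform_a, platform_b, by = "id",
                  suffixes = c("_a", "_b"), all = TRUE)
  unpaired <- is.na(merged$value_a) | is.na(merged$value_b)
  zero <- !unpaired & (merged$value_a == 0 | merged$value_b == 0)
  keep <- merged[!unpaired & !zero, ]
  out <- data.frame(id = keep$id, a = keep$value_a, b = keep$value_b,
                    stringsAsFactors = FALSE)
  attr(out, "excluded_unpaired") <- merged$id[unpaired]
  attr(out, "excluded_zero") <- merged$id[zero]
  out
}

#' Bland-Altman agreement between two measurement methods
#'
#' Computes the Bland-Altman statistics on paired concentration
#' measurements: per-pair differences (by default
#' `log10(b) - log10(a)`, i.e. second platform minus first on the
#' log10 copies/µl scale), their mean (the bias), sample standard
#' deviation (n - 1 denominator), and the limits of agreement
#' `bias ± 1.96 * sd`. Pairs whose difference deviates from the bias
#' by more than `1.96 * sd` are flagged as outliers.
#'
#' @param pairs data frame from [pair_measurements()] (columns `id`,
#'   `a`, `b`), or a two-column matrix/data frame of positive paired
#'   values.
#' @param log_transform compare on the log10 scale (default `TRUE`).
#'   Zero or negative values are a contract error here; exclude them
#'   upstream with [pair_measurements()].
#' @param conf_mult multiplier for the limits of agreement
#'   (default 1.96).
#' @return an `agreement_result` object: list with `bias`, `sd`,
#'   `loa_low`, `loa_high`, `n_pairs`, `n_outliers`, `outlier_ids`,
#'   plus the per-pair `differences` and `means` used for plotting.
#' @examples
#' pairs <- data.frame(id = 1:5, a = c(10, 20, 50, 100, 400))
#' pairs$b <- pairs$a * 10^0.2
#' bland_altman(pairs)$bias  # 0.2
#' @export
bland_altman <- function(pairs, log_transform = TRUE, conf_mult = 1.96) {
  if (!is.data.frame(pairs) && !is.matrix(pairs))
    stop_invalid("pairs must be a data frame or matrix")
  pairs <- as.data.frame(pairs)
  if (all(c("a", "b") %in% names(pairs))) {
    a <- pairs$a; b <- pairs$b
    ids <- if ("id" %in% names(pairs)) pairs$id else seq_along(a)
  } else if (ncol(pairs) >= 2L) {
    a <- pairs[[1]]; b <- pairs[[2]]; ids <- seq_along(a)
  } else stop_invalid("pairs needs columns a and b (or two columns)")
  if (length(a) < 2L) stop_invalid("need at least 2 pairs")
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop_invalid("pairs contain non-finite values")
  if (log_transform && (any(a <= 0) || any(b <= 0)))
    stop_invalid("log-scale comparison requires strictly positive values; ",
                 "exclude zeros with pair_measurements()")
  if (log_transform) { a <- log10(a); b <- log10(b) }
  d <- b - a
  bias <- mean(d)
  sdd <- sd(d)
  # epsilon guard: numerically constant differences are never outliers
  dev <- abs(d - bias)
  outlier <- dev > conf_mult * sdd & dev > sqrt(.Machine$double.eps)
  structure(
    list(bias = bias, sd = sdd,
         loa_low = bias - conf_mult * sdd,
         loa_high = bias + conf_mult * sdd,
         n_pairs = length(d),
         n_outliers = sum(outlier),
         outlier_ids = ids[outlier],
         differences = d,
         means = (a + b) / 2,
         conf_mult = conf_mult,
         log_transform = log_transform),
    class = "agreement_result")
}

#' Limits of agreement from summary statistics
#'
#' `bias ± conf_mult * sd`, for recovering the agreement band when only
#' the bias and standard deviation of the paired differences are
#' available.
#'
#' @param bias mean difference.
#' @param sd standard deviation of the differences (non-negative).
#' @param conf_mult multiplier (default 1.96).
#' @return named numeric vector `c(low, high)`.
#' @examples
#' round(limits_of_agreement(0.17, 0.15), 2)  # -0.12 0.46
#' @export
limits_of_agreement <- function(bias, sd, conf_mult = 1.96) {
  if (sd < 0) stop_invalid("sd must be non-negative")
  c(low = bias - conf_mult * sd, high = bias + conf_mult * sd)
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf(
    "<agreement_result> n = %d pairs: bias %.3f, SD %.3f, LoA (%.3f, %.3f), %d outlier(s)\n",
    x$n_pairs, x$bias, x$sd, x$loa_low, x$loa_high, x$n_outliers))
  invisible(x)
}

#' Bland-Altman plot
#'
#' Scatter of per-pair means against differences with the bias and the
#' limits of agreement drawn as horizontal lines; outliers are drawn
#' filled.
#'
#' @param x an `agreement_result`.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.agreement_result <- function(x, ...) {
  lab <- if (x$log_transform) "log10 copies/ul" else "copies/ul"
  plot(x$means, x$differences,
       xlab = paste("Mean of methods,", lab),
       ylab = paste("Difference between methods,", lab), ...)
  abline(h = x$bias, lty = 2, col = "blue")
  abline(h = c(x$loa_low, x$loa_high), lty = 2, col = "red")
  out <- abs(x$differences - x$bias) > x$conf_mult * x$sd
  if (any(out)) points(x$means[out], x$differences[out], pch = 19)
  invisible(x)
}
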