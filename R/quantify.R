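#' Poisson estimate of mean copies per partition
#'
#' In digital PCR the template is distributed over partitions with
#' Poisson occupancy, so the fraction of negative partitions estimates
#' `exp(-lambda)` and the mean copies per partition is
#' `lambda = -ln(1 - n_pos / n_total)`. The 95% confidence interval is
#' obtained by computing a Clopper-Pearson (exact binomial) interval on
#' the positive fraction and mapping both ends through the same
#' transform.
#'
#' A fully positive well is not quantifiable (the estimate diverges)
#' and raises a saturation error rather than returning infinity.
#'
#' @param n_pos positive partitions.
#' @param n_total total partitions (at least 1).
#' @param conf_level confidence level (default 0.95).
#' @return a `lambda_estimate` object: list with `lam`, `ci_low`,
#'   `ci_high` (copies/partition), `n_pos`, `n_total`.
#' @examples
#' estimate_lambda(10000, 20000)$lam  # ln 2
#' @export
estimate_lambda <- function(n_pos, n_total, conf_level = 0.95) {
  if (length(n_total) != 1L || !is.finite(n_total) || n_total < 1 ||
      n_total != round(n_total))
    stop_invalid("n_total must be a positive integer")
  if (length(n_pos) != 1L || !is.finite(n_pos) || n_pos < 0 ||
      n_pos > n_total || n_pos != round(n_pos))
    stop_invalid("n_pos must be an integer in [0, n_total]")
  if (n_pos == n_total)
    stop_invalid("saturated well (all partitions positive): ",
                 "concentration is not quantifiable")
  check_probability(conf_level, "conf_level")
  alpha <- 1 - conf_level
  p_low <- if (n_pos == 0) 0 else qbeta(alpha / 2, n_pos, n_total - n_pos + 1)
  p_high <- qbeta(1 - alpha / 2, n_pos + 1, n_total - n_pos)
  structure(list(lam = -log(1 - n_pos / n_total),
                 ci_low = -log(1 - p_low),
                 ci_high = -log(1 - p_high),
                 n_pos = n_pos, n_total = n_total,
                 conf_level = conf_level),
            class = "lambda_estimate")
}

#' Convert mean copies per partition to copies/µl in the reaction
#'
#' `conc = lambda / partition_volume * VPF`, with the partition volume
#' taken from the platform profile (nL, converted to µl) and the
#' profile's Volume Precision Factor applied multiplicatively.
#'
#' @param lam mean copies per partition (non-negative).
#' @param profile a [platform_profile()].
#' @return copies/µl in the dPCR reaction.
#' @examples
#' p <- platform_profile("x", 1, 1, partition_volume_nl = 1)
#' lambda_to_concentration(log(2), p)  # 693.1 copies/ul
#' @export
lambda_to_concentration <- function(lam, profile) {
  stopifnot(inherits(profile, "platform_profile"))
  if (any(!is.finite(lam)) || any(lam < 0))
    stop_invalid("lam must be non-negative and finite")
  lam / (profile$partition_volume_nl * 1e-3) * profile$vpf
}

#' Back-calculate the starting-sample concentration
#'
#' Undoes the wet-lab scale factors between the dPCR reaction and the
#' starting sample: multiply by the pre-dPCR dilution factor, divide by
#' the preamplification factor, and rescale by the ratio of reaction
#' volume to template volume loaded.
#'
#' @param conc_reaction copies/µl measured in the dPCR reaction.
#' @param dilution_factor fold-dilution of the (pre)amplified product
#'   before dPCR (e.g. 2 for a 1:1 dilution); at least 1.
#' @param preamp_factor mean preamplification factor `A` (see
#'   [fit_amp_factor()]); at least 1 (1 = no preamplification).
#' @param volume_ratio reaction volume / template volume loaded
#'   (default 1, i.e. report per µl of reaction-equivalent template).
#' @return copies/µl in the starting sample.
#' @examples
#' back_calculate(484, dilution_factor = 2, preamp_factor = 24.2)  # 40
#' @export
back_calculate <- function(conc_reaction, dilution_factor = 1,
                           preamp_factor = 1, volume_ratio = 1) {
  if (any(conc_reaction < 0)) stop_invalid("conc_reaction must be >= 0")
  if (dilution_factor < 1) stop_invalid("dilution_factor must be >= 1")
  if (preamp_factor < 1) stop_invalid("preamp_factor must be >= 1")
  if (volume_ratio <= 0) stop_invalid("volume_ratio must be > 0")
  conc_reaction * dilution_factor / preamp_factor * volume_ratio
}

#' Variant allele frequency
#'
#' VAF = mutant / (mutant + wild type), reported in percent.
#'
#' @param conc_mut,conc_wt mutant and wild-type concentrations on a
#'   common scale (both non-negative, not both zero).
#' @return VAF in percent.
#' @examples
#' vaf(37, 63)  # 37
#' @export
vaf <- function(conc_mut, conc_wt) {
  check_nonneg_scalar(conc_mut, "conc_mut")
  check_nonneg_scalar(conc_wt, "conc_wt")
  total <- conc_mut + conc_wt
  if (total == 0)
    stop_invalid("VAF undefined: both concentrations are zero")
  100 * conc_mut / total
}

#' Pool replicate wells before estimation
#'
#' Sums the partition counts of replicate wells into a single pooled
#' classification, so that the Poisson estimate is computed on the
#' pooled counts rather than averaged across per-well estimates.
#' Pooling is the correct merge under the Poisson model (partitions are
#' exchangeable across wells of the same platform) and narrows the
#' binomial confidence interval.
#'
#' @param classifications list of [well_classification()] objects made
#'   under the same platform profile.
#' @return a pooled `well_classification`.
#' @export
merge_replicates <- function(classifications) {
  if (!is.list(classifications) || length(classifications) < 1L ||
      !all(vapply(classifications, inherits, logical(1), "well_classification")))
    stop_invalid("classifications must be a non-empty list of well_classification objects")
  profiles <- unique(unlist(lapply(classifications, attr, "profile")))
  if (length(profiles) > 1L)
    stop_invalid("cannot pool wells classified under different platform ",
                 "profiles: ", paste(profiles, collapse = ", "))
  sum_field <- function(f) sum(vapply(classifications, `[[`, numeric(1), f))
  well_classification(
    n_total = sum_field("n_total"),
    n_fam_pos = sum_field("n_fam_pos"),
    n_hex_pos = sum_field("n_hex_pos"),
    n_double_pos = sum_field("n_double_pos"),
    n_double_neg = sum_field("n_double_neg"),
    profile = if (length(profiles)) profiles else NULL)
}

#' Per-channel concentration estimate for a well
#'
#' Convenience wrapper chaining [estimate_lambda()],
#' [lambda_to_concentration()] and [back_calculate()] for one channel
#' of a (possibly pooled) well classification.
#'
#' @param classification a [well_classification()], e.g. from
#'   [classify_droplets()] or [merge_replicates()].
#' @param profile the [platform_profile()] the counts were made under.
#' @param channel `"mutant"` (FAM counts) or `"wildtype"` (HEX counts).
#' @inheritParams back_calculate
#' @return a `concentration_estimate` object: list with `channel`,
#'   `lam`, `conc_reaction`, `ci_low`, `ci_high` (all reaction-scale
#'   copies/µl) and `conc_sample` (starting-sample copies/µl).
#' @export
estimate_concentration <- function(classification, profile,
                                   channel = c("mutant", "wildtype"),
                                   dilution_factor = 1, preamp_factor = 1,
                                   volume_ratio = 1) {
  stopifnot(inherits(classification, "well_classification"))
  channel <- match.arg(channel)
  n_pos <- switch(channel, mutant = classification$n_fam_pos,
                  wildtype = classification$n_hex_pos)
  est <- estimate_lambda(n_pos, classification$n_total)
  conc <- lambda_to_concentration(est$lam, profile)
  structure(
    list(channel = channel,
         lam = est$lam,
         conc_reaction = conc,
         ci_low = lambda_to_concentration(est$ci_low, profile),
         ci_high = lambda_to_concentration(est$ci_high, profile),
         conc_sample = back_calculate(conc, dilution_factor,
                                      preamp_factor, volume_ratio)),
    class = "concentration_estimate")
}

#' @export
print.concentration_estimate <- function(x, ...) {
  cat(sprintf(
    "<concentration_estimate> %s: %.3g copies/ul in reaction (95%% CI %.3g-%.3g); %.3g copies/ul in sample\n",
    x$channel, x$conc_reaction, x$ci_low, x$ci_high, x$conc_sample))
  invisible(x)
}
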