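#' Probability of capturing mutant template in a low-copy aliquot
#'
#' When a small number of cfDNA molecules is pipetted into a reaction,
#' the number of mutant copies captured follows a binomial law:
#' `X ~ Binomial(k_total, vaf_f)`. This function returns
#' `P(X >= min_mutant)`, the probability that the aliquot contains
#' enough mutant template to be detectable at all. Below 100 total
#' copies the exact binomial tail is used; from 100 copies upward the
#' default switches to the Gaussian (de Moivre-Laplace) approximation
#' with continuity correction, the regime where the normal limit is
#' conventionally invoked. `method = "exact"` forces the exact tail at
#' any copy number; the approximation degrades when the expected mutant
#' count `k_total * vaf_f` is small (see the package vignette).
#'
#' @param k_total total template copies entering the reaction
#'   (non-negative integer).
#' @param vaf_f mutant allele fraction in \[0, 1\].
#' @param min_mutant minimum mutant copies that count as "captured"
#'   (default 1).
#' @param method `"auto"` (exact below 100 copies, normal at or above),
#'   `"exact"`, or `"normal"`.
#' @return probability in \[0, 1\].
#' @examples
#' capture_probability(10, 0.1)  # 1 - 0.9^10
#' @export
capture_probability <- function(k_total, vaf_f, min_mutant = 1,
                                method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  if (length(k_total) != 1L || !is.finite(k_total) || k_total < 0 ||
      k_total != round(k_total))
    stop_invalid("k_total must be a single non-negative integer")
  check_probability(vaf_f, "vaf_f")
  if (length(min_mutant) != 1L || !is.finite(min_mutant) || min_mutant < 0 ||
      min_mutant != round(min_mutant))
    stop_invalid("min_mutant must be a single non-negative integer")
  if (min_mutant == 0) return(1)
  if (k_total == 0 || vaf_f == 0) return(0)
  use_normal <- switch(method,
                       exact = FALSE,
                       normal = TRUE,
                       auto = k_total >= 100)
  sigma2 <- k_total * vaf_f * (1 - vaf_f)
  if (use_normal && sigma2 > 0) {
    # continuity-corrected Gaussian tail
    p <- pnorm(min_mutant - 0.5, mean = k_total * vaf_f,
               sd = sqrt(sigma2), lower.tail = FALSE)
    return(min(max(p, 0), 1))
  }
  pbinom(min_mutant - 1, size = k_total, prob = vaf_f, lower.tail = FALSE)
}

#' Smallest template input achieving a target capture probability
#'
#' Scans total copy numbers upward (exact binomial tail) and returns
#' the smallest `k_total` for which
#' [capture_probability()] reaches `target_prob`. A design tool for
#' choosing input amounts when the mutant fraction is low.
#'
#' @param vaf_f mutant allele fraction (strictly positive).
#' @param target_prob required capture probability, in (0, 1).
#' @param min_mutant minimum mutant copies that count as captured.
#' @param max_k scan ceiling (error if reached).
#' @return smallest qualifying copy number (integer).
#' @examples
#' min_input_for_detection(0.1, 0.95)  # 29
#' @export
min_input_for_detection <- function(vaf_f, target_prob, min_mutant = 1,
                                    max_k = 1e6) {
  if (!is.numeric(vaf_f) || length(vaf_f) != 1L || vaf_f <= 0 || vaf_f > 1)
    stop_invalid("vaf_f must lie in (0, 1]: a zero mutant fraction can ",
                 "never reach the target")
  if (!is.numeric(target_prob) || length(target_prob) != 1L ||
      target_prob <= 0 || target_prob >= 1)
    stop_invalid("target_prob must lie in (0, 1)")
  k <- max(1, min_mutant)
  while (k <= max_k) {
    if (capture_probability(k, vaf_f, min_mutant, method = "exact") >=
        target_prob)
      return(as.integer(k))
    k <- k + 1
  }
  stop_invalid("no input up to ", max_k, " copies reaches the target")
}

#' Distribution of positive droplets after sampling and preamplification
#'
#' Propagates low-copy sampling noise through the threshold-gated
#' preamplification model: the mutant copy count entering
#' preamplification is `X ~ Binomial(k_total, vaf_f)`, and each
#' possible value `x` maps to `predict_output(model, x)` positive
#' droplets. Computed by exact enumeration over `x = 0..k_total`.
#' Reports the full distribution, its mean, and the probability that
#' the positivity rule (`>= min_count` FAM-positive droplets) would be
#' met.
#'
#' @param k_total total template copies entering the reaction.
#' @param vaf_f mutant allele fraction.
#' @param model a [preamp_model()].
#' @param min_count droplet-count threshold of the positivity rule
#'   (default 50).
#' @return list with `mean` (expected positive droplets),
#'   `p_positive_call` (probability the droplet count reaches
#'   `min_count`) and `distribution` (data frame `mut_copies`, `prob`,
#'   `droplets`).
#' @examples
#' m <- preamp_model(1574 / 65)
#' expected_positive_droplets_after_preamp(65, 1, m)$mean  # 1574
#' @export
expected_positive_droplets_after_preamp <- function(k_total, vaf_f, model,
                                                    min_count = 50) {
  stopifnot(inherits(model, "preamp_model"))
  if (length(k_total) != 1L || k_total < 0 || k_total != round(k_total))
    stop_invalid("k_total must be a single non-negative integer")
  check_probability(vaf_f, "vaf_f")
  x <- 0:k_total
  prob <- dbinom(x, size = k_total, prob = vaf_f)
  droplets <- predict_output(model, x)
  list(mean = sum(prob * droplets),
       p_positive_call = sum(prob[droplets >= min_count]),
       distribution = data.frame(mut_copies = x, prob = prob,
                                 droplets = droplets))
}
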