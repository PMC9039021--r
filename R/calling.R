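#' Construct a well classification
#'
#' Per-well counts of the four threshold classes of a duplex dPCR well.
#' Channel-positive counts include double positives, so the counts obey
#' `n_fam_pos + n_hex_pos - n_double_pos + n_double_neg = n_total`.
#'
#' @param n_total total partitions.
#' @param n_fam_pos partitions at or above the FAM threshold.
#' @param n_hex_pos partitions at or above the HEX threshold.
#' @param n_double_pos partitions positive in both channels.
#' @param n_double_neg partitions positive in neither.
#' @param profile optional platform profile name the counts were made
#'   under (used by [merge_replicates()] to refuse mixing platforms).
#' @return a `well_classification` object.
#' @export
well_classification <- function(n_total, n_fam_pos, n_hex_pos,
                                n_double_pos, n_double_neg,
                                profile = NULL) {
  counts <- c(n_total = n_total, n_fam_pos = n_fam_pos,
              n_hex_pos = n_hex_pos, n_double_pos = n_double_pos,
              n_double_neg = n_double_neg)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts)))
    stop_invalid("classification counts must be non-negative integers")
  if (any(counts[-1] > n_total))
    stop_invalid("no count may exceed n_total")
  if (n_double_pos > min(n_fam_pos, n_hex_pos))
    stop_invalid("n_double_pos cannot exceed either channel count")
  if (n_fam_pos + n_hex_pos - n_double_pos + n_double_neg != n_total)
    stop_invalid("counts violate the partition identity ",
                 "n_fam_pos + n_hex_pos - n_double_pos + n_double_neg = n_total")
  structure(as.list(counts), profile = profile,
            class = "well_classification")
}

#' @export
print.well_classification <- function(x, ...) {
  cat(sprintf(
    "<well_classification> %d partitions: FAM+ %d, HEX+ %d, double+ %d, double- %d\n",
    x$n_total, x$n_fam_pos, x$n_hex_pos, x$n_double_pos, x$n_double_neg))
  invisible(x)
}

#' Classify partitions against platform thresholds
#'
#' Scores every partition against the profile's manually set
#' fluorescence thresholds. The comparison is inclusive: an amplitude
#' exactly equal to the threshold counts as positive.
#'
#' @param droplets droplet-record data frame (columns `fam_rfu`,
#'   `hex_rfu`), e.g. from [read_amplitude_csv()] or
#'   [simulate_well()].
#' @param profile a [platform_profile()].
#' @return a [well_classification()] object.
#' @examples
#' d <- data.frame(well_id = "A01", replicate_id = "rep1",
#'                 fam_rfu = c(2000, 0), hex_rfu = c(0, 3000))
#' classify_droplets(d, load_platform_profile("qx200"))
#' @export
classify_droplets <- function(droplets, profile) {
  stopifnot(inherits(profile, "platform_profile"))
  if (!is.data.frame(droplets) ||
      !all(c("fam_rfu", "hex_rfu") %in% names(droplets)))
    stop_invalid("droplets must be a data frame with fam_rfu and hex_rfu")
  if (nrow(droplets) == 0L) stop_invalid("empty well: no partitions to classify")
  fam <- droplets$fam_rfu >= profile$fam_threshold_rfu
  hex <- droplets$hex_rfu >= profile$hex_threshold_rfu
  well_classification(
    n_total = nrow(droplets),
    n_fam_pos = sum(fam),
    n_hex_pos = sum(hex),
    n_double_pos = sum(fam & hex),
    n_double_neg = sum(!fam & !hex),
    profile = profile$name)
}

#' Call a sample from its technical duplicates
#'
#' Applies the duplicate-based decision rules to the FAM (mutant) and
#' HEX (wild-type) positive-partition counts of exactly two technical
#' replicates:
#'
#' * **positive** — at least `min_count` FAM-positive partitions in the
#'   duplicate total, reproducible in both replicates (each replicate
#'   contributes at least one FAM-positive partition). With
#'   `positive_rule = "per_replicate"` each replicate must reach
#'   `min_count` on its own.
#' * **ambiguous** — the FAM total reaches `min_count` but all FAM
#'   positivity is confined to one replicate; or FAM positives are
#'   present (1 to `min_count - 1`) without supporting wild-type signal
#'   (HEX total at or below `min_count`).
#' * **negative** — fewer than `min_count` FAM positives in the
#'   duplicate total with more than `min_count` HEX positives.
#' * **non_informative** — no FAM positives and HEX total at or below
#'   `min_count`: the well carries too little amplifiable template to
#'   support a negative call.
#'
#' Boundary conventions: "at least `min_count`" for the positive rule
#' (a total of exactly 50 qualifies) and strictly "more than
#' `min_count`" for the HEX evidence backing a negative call.
#'
#' @param duplicates list of exactly two [well_classification()]
#'   objects.
#' @param min_count partition-count threshold of the decision rules
#'   (default 50).
#' @param positive_rule whether the `min_count` criterion for
#'   positivity applies to the duplicate total (default) or to each
#'   replicate separately.
#' @return a `sample_call` object: list with `verdict` (one of
#'   `"positive"`, `"negative"`, `"ambiguous"`, `"non_informative"`),
#'   `fam_pos_total`, `hex_pos_total`, `replicate_fam_counts`.
#' @examples
#' w <- function(fam, hex) well_classification(20000, fam, hex, 0,
#'                                             20000 - fam - hex)
#' call_sample(list(w(30, 250), w(40, 250)))$verdict  # "positive"
#' @export
call_sample <- function(duplicates, min_count = 50,
                        positive_rule = c("total", "per_replicate")) {
  positive_rule <- match.arg(positive_rule)
  if (!is.list(duplicates) || length(duplicates) != 2L ||
      !all(vapply(duplicates, inherits, logical(1), "well_classification")))
    stop_invalid("duplicates must be a list of exactly two well_classification objects")
  check_nonneg_scalar(min_count, "min_count")
  fam <- vapply(duplicates, function(w) w$n_fam_pos, numeric(1))
  hex <- vapply(duplicates, function(w) w$n_hex_pos, numeric(1))
  fam_total <- sum(fam)
  hex_total <- sum(hex)
  reproducible <- all(fam >= 1)
  meets <- switch(positive_rule,
                  total = fam_total >= min_count,
                  per_replicate = all(fam >= min_count))
  verdict <-
    if (meets && reproducible) "positive"
    else if (fam_total >= min_count) "ambiguous"   # signal confined to one replicate
    else if (fam_total >= 1) {
      if (hex_total > min_count) "negative" else "ambiguous"
    } else {
      if (hex_total > min_count) "negative" else "non_informative"
    }
  structure(list(verdict = verdict,
                 fam_pos_total = fam_total,
                 hex_pos_total = hex_total,
                 replicate_fam_counts = fam),
            class = "sample_call")
}

#' @export
print.sample_call <- function(x, ...) {
  cat(sprintf("<sample_call> %s (FAM+ %d [%s], HEX+ %d)\n",
              x$verdict, x$fam_pos_total,
              paste(x$replicate_fam_counts, collapse = "+"),
              x$hex_pos_total))
  invisible(x)
}

#' Informativeness filter on cfDNA fragment content
#'
#' An isolate is analytically informative only if it contains
#' amplifiable DNA fragments of at least 150 bp; isolates whose 150 bp
#' fragment concentration is exactly zero are excluded from downstream
#' analysis as non-informative.
#'
#' @param records cohort data frame (see [read_cohort_table()]) or a
#'   numeric vector of 150 bp fragment concentrations.
#' @return logical vector, `TRUE` for informative isolates.
#' @examples
#' informativeness_filter(c(0, 3, 15170))  # FALSE TRUE TRUE
#' @export
informativeness_filter <- function(records) {
  conc_150 <- if (is.data.frame(records)) {
    if (!"conc_150" %in% names(records))
      stop_invalid("records must have a conc_150 column")
    records$conc_150
  } else records
  if (!is.numeric(conc_150))
    stop_invalid("conc_150 must be numeric")
  if (anyNA(conc_150))
    stop_invalid("conc_150 contains missing values; the filter needs a ",
                 "measured 150 bp concentration for every isolate")
  conc_150 > 0
}
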