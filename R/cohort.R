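# Route grouping used throughout: ventricular CSF reaches the analysis
# either intraoperatively or through a ventricular access device;
# lumbar puncture is its own group.
route_group <- function(route) {
  ifelse(route == "LP", "lumbar", "ventricular")
}

summary_stats <- function(x) {
  list(n = length(x), median = median(x), min = min(x), max = max(x))
}

#' Summarize cfDNA content of a CSF cohort
#'
#' Cohort-level summaries of the 150 bp amplifiable-fragment
#' concentration (the working measure of dPCR-suitable cfDNA): median
#' and range over all isolates or over informative isolates only
#' (see [informativeness_filter()]), plus per-route-group summaries.
#' Every isolate row counts as one observation, including repeat
#' isolates from the same patient. Even-sized groups use the midpoint
#' of the two central values as the median.
#'
#' @param records cohort data frame, e.g. [csf_cohort()] or
#'   [read_cohort_table()].
#' @param informative_only drop isolates with zero 150 bp fragment
#'   concentration before summarizing (default `FALSE`).
#' @return a `cohort_summary` object: list with `n_isolates`,
#'   `n_informative`, `median_150`, `range_150` and `by_route` (data
#'   frame with one row per route group).
#' @examples
#' summarize_cohort(csf_cohort())$median_150                           # 35
#' summarize_cohort(csf_cohort(), informative_only = TRUE)$median_150  # 81
#' @export
summarize_cohort <- function(records, informative_only = FALSE) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop_invalid("records must be a non-empty cohort data frame")
  if (!all(c("conc_150", "collection_route") %in% names(records)))
    stop_invalid("records must have conc_150 and collection_route columns")
  informative <- informativeness_filter(records)
  retained <- if (informative_only) records[informative, ] else records
  if (nrow(retained) == 0L)
    stop_invalid("no isolates left after the informativeness filter")
  conc <- retained$conc_150
  groups <- split(conc, route_group(retained$collection_route))
  by_route <- do.call(rbind, lapply(names(groups), function(g) {
    s <- summary_stats(groups[[g]])
    data.frame(group = g, n = s$n, median = s$median,
               min = s$min, max = s$max, stringsAsFactors = FALSE)
  }))
  structure(
    list(n_isolates = nrow(records),
         n_informative = sum(informative),
         median_150 = median(conc),
         range_150 = c(min(conc), max(conc)),
         by_route = by_route),
    class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf(
    "<cohort_summary> %d isolates (%d informative); 150 bp conc median %g copies/ul (range %g-%g)\n",
    x$n_isolates, x$n_informative, x$median_150,
    x$range_150[1], x$range_150[2]))
  for (i in seq_len(nrow(x$by_route)))
    cat(sprintf("  %-12s n = %2d, median %g (range %g-%g)\n",
                x$by_route$group[i], x$by_route$n[i], x$by_route$median[i],
                x$by_route$min[i], x$by_route$max[i]))
  invisible(x)
}

#' Compare cfDNA yield between CSF collection routes
#'
#' Summarizes the 150 bp fragment concentration separately for
#' ventricular isolates (intraoperative and ventricular-access-device
#' collections pooled) and lumbar-puncture isolates. All isolates enter,
#' including zeros and repeat isolates.
#'
#' @param records cohort data frame.
#' @return data frame with one row per route group: `group`, `n`,
#'   `median`, `min`, `max`.
#' @examples
#' route_comparison(csf_cohort())
#' @export
route_comparison <- function(records) {
  summarize_cohort(records, informative_only = FALSE)$by_route
}
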