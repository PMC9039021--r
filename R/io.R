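# Column dictionaries for the two amplitude CSV dialects. These are
# this package's documented approximations of the per-partition export
# tables of droplet (QX200-style) and nanoplate (QIAcuity-style)
# instruments; vendor exports can be adapted via col_map.
.amplitude_dialects <- list(
  droplet = c(well = "Well", replicate = "Sample",
              fam = "Ch1Amplitude", hex = "Ch2Amplitude"),
  nanoplate = c(well = "WellID", replicate = "Replicate",
                fam = "FAM", hex = "HEX"))

#' Read a per-partition amplitude table
#'
#' Reads a two-channel amplitude CSV in one of the two dialects the
#' package defines (see Details) and returns a validated droplet-record
#' data frame with columns `well_id`, `replicate_id`, `fam_rfu`,
#' `hex_rfu`.
#'
#' The `droplet` dialect has columns `Well`, `Sample`, `Ch1Amplitude`,
#' `Ch2Amplitude`; the `nanoplate` dialect has `WellID`, `Replicate`,
#' `FAM`, `HEX`. Use `col_map` to map differently named vendor columns
#' onto the dialect's roles, e.g.
#' `col_map = c(fam = "Ch1 Amplitude", hex = "Ch2 Amplitude")`.
#'
#' Parsing is all-or-nothing: a missing column raises a schema error
#' naming the missing columns, and any row with a non-numeric, missing,
#' or negative amplitude raises a validation error naming the offending
#' rows.
#'
#' @param path CSV file path.
#' @param dialect `"droplet"` or `"nanoplate"`.
#' @param col_map optional named character vector remapping the roles
#'   `well`, `replicate`, `fam`, `hex` to file column names.
#' @return data frame of droplet records (possibly 0 rows).
#' @export
read_amplitude_csv <- function(path, dialect = c("droplet", "nanoplate"),
                               col_map = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  cols <- .amplitude_dialects[[dialect]]
  if (!is.null(col_map)) {
    bad <- setdiff(names(col_map), names(cols))
    if (length(bad))
      stop_invalid("unknown col_map roles: ", paste(bad, collapse = ", "))
    cols[names(col_map)] <- col_map
  }
  raw <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(unname(cols), names(raw))
  if (length(missing))
    stop_invalid("schema error (", dialect, " dialect): missing column(s) ",
                 paste(missing, collapse = ", "))
  if (nrow(raw) == 0L)
    return(data.frame(well_id = character(), replicate_id = character(),
                      fam_rfu = numeric(), hex_rfu = numeric(),
                      stringsAsFactors = FALSE))
  fam <- suppressWarnings(as.numeric(raw[[cols[["fam"]]]]))
  hex <- suppressWarnings(as.numeric(raw[[cols[["hex"]]]]))
  bad_rows <- which(is.na(fam) | is.na(hex) | !is.finite(fam) |
                      !is.finite(hex) | fam < 0 | hex < 0)
  if (length(bad_rows))
    stop_invalid("invalid amplitude(s) in row(s): ",
                 paste(head(bad_rows, 10L), collapse = ", "),
                 if (length(bad_rows) > 10L) ", ..." else "")
  data.frame(well_id = as.character(raw[[cols[["well"]]]]),
             replicate_id = as.character(raw[[cols[["replicate"]]]]),
             fam_rfu = fam, hex_rfu = hex, stringsAsFactors = FALSE)
}

#' Write a per-partition amplitude table
#'
#' Inverse of [read_amplitude_csv()]: writes droplet records in the
#' requested dialect so that reading the file back yields the same
#' records.
#'
#' @param droplets data frame with columns `well_id`, `replicate_id`,
#'   `fam_rfu`, `hex_rfu`.
#' @param path output CSV path.
#' @inheritParams read_amplitude_csv
#' @return `path`, invisibly.
#' @export
write_amplitude_csv <- function(droplets, path,
                                dialect = c("droplet", "nanoplate")) {
  dialect <- match.arg(dialect)
  need <- c("well_id", "replicate_id", "fam_rfu", "hex_rfu")
  if (!all(need %in% names(droplets)))
    stop_invalid("droplets must have columns ", paste(need, collapse = ", "))
  cols <- .amplitude_dialects[[dialect]]
  out <- data.frame(droplets$well_id, droplets$replicate_id,
                    droplets$fam_rfu, droplets$hex_rfu,
                    stringsAsFactors = FALSE)
  names(out) <- unname(cols[c("well", "replicate", "fam", "hex")])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a simulated experiment to disk
#'
#' Writes one amplitude CSV per replicate well plus a `truth.json`
#' sidecar holding the simulation ground truth (true VAF, loaded and
#' post-preamplification copy numbers per replicate).
#'
#' @param experiment a `dpcr_experiment` from [simulate_experiment()].
#' @param dir output directory (created if absent).
#' @param dialect amplitude CSV dialect to write.
#' @return character vector of the CSV paths written, invisibly.
#' @export
write_experiment <- function(experiment, dir,
                             dialect = c("droplet", "nanoplate")) {
  stopifnot(inherits(experiment, "dpcr_experiment"))
  dialect <- match.arg(dialect)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(experiment$wells))
  for (i in seq_along(experiment$wells)) {
    paths[i] <- file.path(dir, sprintf("well_%02d.csv", i))
    write_amplitude_csv(experiment$wells[[i]], paths[i], dialect)
  }
  truth <- experiment$truth
  jsonlite::write_json(
    list(true_vaf = truth$true_vaf, replicates = truth$replicates),
    file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA, na = "null")
  invisible(paths)
}

.cohort_routes <- c("VAD", "IO", "LP")
.cohort_required <- c("patient_id", "collection_route", "csf_volume_ml",
                      "conc_37", "conc_150", "conc_300", "tissue_h3_status")

#' Read a CSF cfDNA cohort table
#'
#' Reads a tab-separated cohort table with one row per cfDNA isolate.
#' Required columns: `patient_id`, `collection_route` (one of `VAD` =
#' ventricular access device, `IO` = intraoperative, `LP` = lumbar
#' puncture), `csf_volume_ml`, the per-fragment-length amplifiable
#' cfDNA concentrations `conc_37`, `conc_150`, `conc_300` (copies/µl),
#' and `tissue_h3_status` (`positive`, `negative`, `unavailable`).
#' Zero concentrations are kept as zeros (they drive the
#' informativeness filter); missing values must be encoded as `NA`.
#'
#' @param path TSV file path.
#' @return data frame with one row per isolate.
#' @seealso [csf_cohort()] for the packaged example cohort,
#'   [summarize_cohort()].
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  missing <- setdiff(.cohort_required, names(tab))
  if (length(missing))
    stop_invalid("cohort table missing column(s): ",
                 paste(missing, collapse = ", "))
  bad_route <- setdiff(unique(tab$collection_route), .cohort_routes)
  if (length(bad_route))
    stop_invalid("unknown collection_route code(s): ",
                 paste(bad_route, collapse = ", "),
                 " (expected VAD, IO or LP)")
  bad_status <- setdiff(unique(tab$tissue_h3_status),
                        c("positive", "negative", "unavailable", NA))
  if (length(bad_status))
    stop_invalid("unknown tissue_h3_status value(s): ",
                 paste(bad_status, collapse = ", "))
  for (f in c("conc_37", "conc_150", "conc_300")) {
    v <- tab[[f]]
    if (!is.numeric(v)) stop_invalid(f, " must be numeric")
    if (any(v < 0, na.rm = TRUE))
      stop_invalid(f, " contains negative concentration(s)")
  }
  tab
}

#' Packaged example CSF cohort
#'
#' Returns the cohort table shipped with the package: 21 CSF cfDNA
#' isolates from 18 pediatric CNS tumor patients (two patients
#' contributed multiple isolates), with collection route and
#' amplifiable-fragment concentrations at 37, 150 and 300 bp. The
#' 150 bp concentration is the working measure of dPCR-suitable cfDNA
#' content.
#'
#' @return data frame of cohort records, see [read_cohort_table()].
#' @examples
#' summarize_cohort(csf_cohort())
#' @export
csf_cohort <- function() {
  read_cohort_table(system.file("extdata", "csf_cohort.tsv",
                                package = "raredrop", mustWork = TRUE))
}
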