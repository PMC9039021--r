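#' Built-in dPCR platform profiles
#'
#' A platform profile bundles the per-platform analysis settings: the
#' manually set fluorescence thresholds above which a partition is
#' scored positive in each channel, the partition volume used by the
#' Poisson quantification model, and the Volume Precision Factor (VPF),
#' a multiplicative correction for partition-volume variation on
#' nanoplate instruments (1.0 on droplet instruments).
#'
#' Two profiles ship with the package:
#' \describe{
#'   \item{`qx200`}{droplet platform; FAM threshold 2000 RFU, HEX
#'     threshold 1500 RFU, 0.85 nL droplets, VPF 1.0.}
#'   \item{`qiacuity`}{8.5k nanoplate platform; FAM threshold 40 RFU,
#'     HEX threshold 20 RFU, 1.34 nL chambers, VPF 1.0 unless
#'     overridden.}
#' }
#'
#' @param name profile name, e.g. `"qx200"`.
#' @param config optional named list of profile definitions (each a list
#'   with the fields of [platform_profile()]) overriding or extending
#'   the built-ins; unspecified fields are filled with defaults
#'   (`vpf = 1`).
#' @return a `platform_profile` object.
#' @seealso [platform_profile()] to build a profile from scratch.
#' @examples
#' load_platform_profile("qx200")$fam_threshold_rfu  # 2000
#' @export
load_platform_profile <- function(name, config = NULL) {
  registry <- .platform_defaults
  if (!is.null(config)) {
    if (is.null(names(config)) || any(names(config) == ""))
      stop_invalid("config must be a named list of profile definitions")
    registry[names(config)] <- config
  }
  if (!is.character(name) || length(name) != 1L || !name %in% names(registry))
    stop_invalid("unknown platform profile: ", name,
                 " (known: ", paste(names(registry), collapse = ", "), ")")
  spec <- registry[[name]]
  spec$name <- name
  if (is.null(spec$vpf)) spec$vpf <- 1.0
  do.call(platform_profile, spec)
}

#' Construct a dPCR platform profile
#'
#' @param name profile name.
#' @param fam_threshold_rfu fluorescence threshold (RFU) for the FAM
#'   (mutant) channel; a partition with amplitude at or above it is
#'   positive.
#' @param hex_threshold_rfu threshold (RFU) for the HEX (wild-type)
#'   channel.
#' @param partition_volume_nl partition (droplet or chamber) volume in
#'   nanolitres.
#' @param vpf Volume Precision Factor, a dimensionless multiplier
#'   applied to concentrations; default 1.
#' @param dialect amplitude CSV dialect this platform writes, see
#'   [read_amplitude_csv()].
#' @return a `platform_profile` object (a validated list).
#' @export
platform_profile <- function(name, fam_threshold_rfu, hex_threshold_rfu,
                             partition_volume_nl, vpf = 1.0,
                             dialect = c("droplet", "nanoplate")) {
  dialect <- match.arg(dialect)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop_invalid("name must be a non-empty string")
  for (f in c("fam_threshold_rfu", "hex_threshold_rfu",
              "partition_volume_nl", "vpf")) {
    v <- get(f)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
      stop_invalid(f, " must be a single positive number")
  }
  structure(
    list(name = name,
         fam_threshold_rfu = fam_threshold_rfu,
         hex_threshold_rfu = hex_threshold_rfu,
         partition_volume_nl = partition_volume_nl,
         vpf = vpf,
         dialect = dialect),
    class = "platform_profile")
}

#' @export
print.platform_profile <- function(x, ...) {
  cat(sprintf(
    "<platform_profile> %s: FAM >= %g RFU, HEX >= %g RFU, %g nL/partition, VPF %g\n",
    x$name, x$fam_threshold_rfu, x$hex_threshold_rfu,
    x$partition_volume_nl, x$vpf))
  invisible(x)
}

.platform_defaults <- list(
  qx200 = list(fam_threshold_rfu = 2000, hex_threshold_rfu = 1500,
               partition_volume_nl = 0.85, vpf = 1.0, dialect = "droplet"),
  qiacuity = list(fam_threshold_rfu = 40, hex_threshold_rfu = 20,
                  partition_volume_nl = 1.34, vpf = 1.0,
                  dialect = "nanoplate"))
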