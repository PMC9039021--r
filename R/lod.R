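#' Geometric dilution series of input masses
#'
#' Builds the input-mass ladder of a serial dilution experiment:
#' `n_dilutions` masses descending from `start_mass_pg` by `factor` at
#' each step. The defaults give the standard ten two-fold dilutions
#' from 600 pg down to about 1 pg.
#'
#' @param start_mass_pg starting DNA mass, pg (positive).
#' @param n_dilutions number of points (at least 1).
#' @param factor fold-dilution per step (strictly greater than 1).
#' @return numeric vector of masses, descending.
#' @examples
#' make_dilution_series()  # 600, 300, ..., ~1.17 pg
#' @export
make_dilution_series <- function(start_mass_pg = 600, n_dilutions = 10,
                                 factor = 2) {
  if (!is.numeric(start_mass_pg) || length(start_mass_pg) != 1L ||
      start_mass_pg <= 0)
    stop_invalid("start_mass_pg must be a single positive number")
  if (length(n_dilutions) != 1L || n_dilutions < 1 ||
      n_dilutions != round(n_dilutions))
    stop_invalid("n_dilutions must be an integer >= 1")
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 1)
    stop_invalid("factor must be > 1")
  start_mass_pg / factor^(0:(n_dilutions - 1))
}

#' One point of a dilution series
#'
#' Pairs an input mass with the duplicate well classifications measured
#' at that mass.
#'
#' @param input_mass_pg DNA mass at the start of preamplification, pg
#'   (positive).
#' @param duplicate_classifications list of exactly two
#'   [well_classification()] objects.
#' @return a `dilution_point` object.
#' @export
dilution_point <- function(input_mass_pg, duplicate_classifications) {
  if (!is.numeric(input_mass_pg) || length(input_mass_pg) != 1L ||
      !is.finite(input_mass_pg) || input_mass_pg <= 0)
    stop_invalid("input_mass_pg must be a single positive number")
  if (!is.list(duplicate_classifications) ||
      length(duplicate_classifications) != 2L ||
      !all(vapply(duplicate_classifications, inherits, logical(1),
                  "well_classification")))
    stop_invalid("duplicate_classifications must be a list of exactly two ",
                 "well_classification objects")
  structure(list(input_mass_pg = input_mass_pg,
                 duplicate_classifications = duplicate_classifications),
            class = "dilution_point")
}

#' Limit of detection of a dilution series
#'
#' The limit of detection is the smallest input mass affording at
#' least `min_count` positive partitions in at least one of the two
#' channels, counting the duplicate wells together. Returns `NA` (with
#' a message) when no dilution point qualifies.
#'
#' @param series list of [dilution_point()] objects.
#' @param min_count partition-count threshold (default 50, the same
#'   boundary-inclusive convention as [call_sample()]).
#' @return LoD mass in pg, or `NA_real_` if nothing is detected.
#' @export
call_lod <- function(series, min_count = 50) {
  if (!is.list(series) || length(series) < 1L ||
      !all(vapply(series, inherits, logical(1), "dilution_point")))
    stop_invalid("series must be a non-empty list of dilution_point objects")
  check_nonneg_scalar(min_count, "min_count")
  mass <- vapply(series, `[[`, numeric(1), "input_mass_pg")
  qualifies <- vapply(series, function(pt) {
    fam <- sum(vapply(pt$duplicate_classifications, `[[`, numeric(1),
                      "n_fam_pos"))
    hex <- sum(vapply(pt$duplicate_classifications, `[[`, numeric(1),
                      "n_hex_pos"))
    max(fam, hex) >= min_count
  }, logical(1))
  if (!any(qualifies)) {
    message("no dilution point reaches ", min_count,
            " positive partitions; nothing detected")
    return(NA_real_)
  }
  min(mass[qualifies])
}

#' Convert DNA mass to haploid genome equivalents
#'
#' Divides a DNA mass by the mass of one haploid human genome
#' (default 3.3 pg) and rounds to whole genomes, e.g. 9 pg is 3
#' haploid genomes.
#'
#' @param mass_pg DNA mass in pg (vectorized, non-negative).
#' @param pg_per_haploid_genome mass of one haploid genome, pg
#'   (positive).
#' @return integer genome equivalents.
#' @examples
#' mass_to_genome_equivalents(9)  # 3
#' @export
mass_to_genome_equivalents <- function(mass_pg,
                                       pg_per_haploid_genome = 3.3) {
  if (any(!is.finite(mass_pg)) || any(mass_pg < 0))
    stop_invalid("mass_pg must be non-negative")
  if (!is.numeric(pg_per_haploid_genome) ||
      length(pg_per_haploid_genome) != 1L || pg_per_haploid_genome <= 0)
    stop_invalid("pg_per_haploid_genome must be a single positive number")
  round(mass_pg / pg_per_haploid_genome)
}
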