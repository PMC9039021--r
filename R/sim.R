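#' Configure a synthetic two-channel dPCR experiment
#'
#' Builds the parameter set for the droplet-level simulator. The
#' simulated assay is a duplex reaction in which the FAM channel reports
#' the mutant allele and the HEX channel the wild-type allele. Template
#' molecules are sampled from the specimen into each replicate reaction
#' (Poisson, mean `conc * sample_volume_ul`), optionally preamplified by
#' a per-molecule branching process, partitioned with Poisson occupancy,
#' and rendered as fluorescence amplitudes drawn from configurable
#' negative and positive clouds, with sub-threshold "rain" and rare
#' artifact droplets.
#'
#' Defaults emulate a low-VAF cerebrospinal-fluid specimen: 65 template
#' copies/µl total at 14% variant allele frequency, 1 µl loaded per
#' replicate, 8 preamplification cycles at per-cycle duplication
#' probability 0.49 (so the mean amplification factor is
#' 1.49^8 = 24.3), duplicate reactions on a 20,000-partition droplet
#' platform.
#'
#' @param conc_mut,conc_wt mutant / wild-type concentration in the
#'   specimen, copies/µl.
#' @param sample_volume_ul specimen volume loaded per replicate, µl.
#' @param preamp_cycles number of preamplification cycles (0 = none).
#' @param preamp_efficiency probability that a molecule duplicates in
#'   one cycle, in \[0, 1\].
#' @param n_partitions partitions per well.
#' @param partition_volume_nl partition volume, nL.
#' @param neg_cloud,pos_cloud per-channel amplitude clouds: lists with
#'   elements `fam` and `hex`, each `c(mean, sd)` in RFU. Positive-cloud
#'   means must exceed negative-cloud means.
#' @param rain_fraction probability that a positive partition's
#'   amplitude is drawn uniformly between the clouds ("rain") instead of
#'   from the positive cloud.
#' @param fp_artifact_rate probability that a partition containing no
#'   mutant template nevertheless fires FAM (probe degradation
#'   artifact).
#' @param cross_hyb_rate probability that a wild-type-occupied partition
#'   also fires FAM (non-specific annealing of the mutant probe to the
#'   normal allele).
#' @param n_replicates technical replicates (wells) per experiment.
#' @param seed integer seed for [simulate_experiment()]; `NULL` uses the
#'   current RNG stream.
#' @return a validated `sim_config` object.
#' @examples
#' cfg <- sim_config(conc_mut = 0, conc_wt = 50, seed = 1)
#' @export
sim_config <- function(conc_mut = 9.1,
                       conc_wt = 55.9,
                       sample_volume_ul = 1,
                       preamp_cycles = 8,
                       preamp_efficiency = 0.49,
                       n_partitions = 20000,
                       partition_volume_nl = 0.85,
                       neg_cloud = list(fam = c(500, 150), hex = c(400, 120)),
                       pos_cloud = list(fam = c(5000, 400), hex = c(4000, 300)),
                       rain_fraction = 0.02,
                       fp_artifact_rate = 5e-5,
                       cross_hyb_rate = 0,
                       n_replicates = 2,
                       seed = NULL) {
  check_nonneg_scalar(conc_mut, "conc_mut")
  check_nonneg_scalar(conc_wt, "conc_wt")
  if (sample_volume_ul <= 0) stop_invalid("sample_volume_ul must be > 0")
  if (partition_volume_nl <= 0) stop_invalid("partition_volume_nl must be > 0")
  if (length(preamp_cycles) != 1L || is.na(preamp_cycles) ||
      preamp_cycles < 0 || preamp_cycles != round(preamp_cycles))
    stop_invalid("preamp_cycles must be a non-negative integer")
  check_probability(preamp_efficiency, "preamp_efficiency")
  check_probability(rain_fraction, "rain_fraction")
  check_probability(fp_artifact_rate, "fp_artifact_rate")
  check_probability(cross_hyb_rate, "cross_hyb_rate")
  if (length(n_partitions) != 1L || n_partitions < 1 ||
      n_partitions != round(n_partitions))
    stop_invalid("n_partitions must be an integer >= 1")
  if (length(n_replicates) != 1L || n_replicates < 1 ||
      n_replicates != round(n_replicates))
    stop_invalid("n_replicates must be an integer >= 1")
  for (ch in c("fam", "hex")) {
    ng <- neg_cloud[[ch]]; ps <- pos_cloud[[ch]]
    if (is.null(ng) || is.null(ps) || length(ng) != 2L || length(ps) != 2L)
      stop_invalid("neg_cloud and pos_cloud need 'fam' and 'hex' c(mean, sd) entries")
    if (any(c(ng, ps) < 0)) stop_invalid("cloud parameters must be non-negative")
    if (ps[1] <= ng[1])
      stop_invalid("positive cloud mean must exceed negative cloud mean (", ch, ")")
  }
  if (!is.null(seed) && (length(seed) != 1L || is.na(seed)))
    stop_invalid("seed must be a single integer or NULL")
  structure(
    list(conc_mut = conc_mut, conc_wt = conc_wt,
         sample_volume_ul = sample_volume_ul,
         preamp_cycles = as.integer(preamp_cycles),
         preamp_efficiency = preamp_efficiency,
         n_partitions = as.integer(n_partitions),
         partition_volume_nl = partition_volume_nl,
         neg_cloud = neg_cloud, pos_cloud = pos_cloud,
         rain_fraction = rain_fraction,
         fp_artifact_rate = fp_artifact_rate,
         cross_hyb_rate = cross_hyb_rate,
         n_replicates = as.integer(n_replicates),
         seed = seed),
    class = "sim_config")
}

#' Stochastic preamplification of a template pool
#'
#' Simulates limited-cycle PCR as a Bernoulli branching process: in each
#' cycle every molecule independently duplicates with probability
#' `efficiency`. After `cycles` cycles the expected copy number is
#' `k * (1 + efficiency)^cycles`; at `efficiency = 1` the process is
#' deterministic doubling. The stochastic formulation matters at the
#' low copy numbers typical of cell-free DNA, where per-molecule
#' duplication noise propagates into the partition counts.
#'
#' @param k starting copy number (non-negative integer).
#' @param cycles number of cycles (non-negative integer).
#' @param efficiency per-molecule per-cycle duplication probability.
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return final copy number (numeric scalar, always `>= k`).
#' @examples
#' simulate_preamp(50, 8, 1)  # 50 * 2^8 = 12800
#' @export
simulate_preamp <- function(k, cycles, efficiency, seed = NULL) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 0 ||
      k != round(k))
    stop_invalid("k must be a single non-negative integer")
  if (!is.numeric(cycles) || length(cycles) != 1L || is.na(cycles) ||
      cycles < 0 || cycles != round(cycles))
    stop_invalid("cycles must be a single non-negative integer")
  check_probability(efficiency, "efficiency")
  with_seed(seed, {
    n <- k
    for (i in seq_len(cycles)) {
      if (n == 0) break
      n <- n + rbinom(1L, size = n, prob = efficiency)
    }
    n
  })
}

# Amplitude draw for one channel: negatives from the negative cloud,
# positives from the positive cloud except a rain_fraction drawn
# uniformly between (neg mean + 2 sd) and (pos mean - 2 sd).
draw_channel_amplitudes <- function(positive, neg, pos, rain_fraction) {
  n <- length(positive)
  amp <- rnorm(n, neg[1], neg[2])
  npos <- sum(positive)
  if (npos > 0) {
    amp[positive] <- rnorm(npos, pos[1], pos[2])
    rain <- positive & (runif(n) < rain_fraction)
    nr <- sum(rain)
    if (nr > 0) {
      lo <- neg[1] + 2 * neg[2]
      hi <- max(lo, pos[1] - 2 * pos[2])
      amp[rain] <- runif(nr, lo, hi)
    }
  }
  pmax(amp, 0)
}

#' Simulate one dPCR well
#'
#' Samples template molecules into the reaction, preamplifies them with
#' [simulate_preamp()], assigns per-partition occupancy by Poisson
#' statistics (`lambda = post-preamplification copies / n_partitions`,
#' independently per allele), and draws two-channel fluorescence
#' amplitudes. FAM fires in partitions holding at least one mutant
#' molecule, plus (optionally) wild-type partitions affected by probe
#' cross-hybridization and empty-of-mutant partitions hit by spurious
#' probe-degradation artifacts. HEX fires in partitions holding at
#' least one wild-type molecule.
#'
#' @param config a [sim_config()] object.
#' @param seed optional seed; identical seed and config give identical
#'   output.
#' @param well_id,replicate_id identifiers stamped on the droplet
#'   records.
#' @return a list with elements `droplets` (data frame with columns
#'   `well_id`, `replicate_id`, `fam_rfu`, `hex_rfu`) and `truth`
#'   (loaded and post-preamplification copy numbers per allele).
#' @export
simulate_well <- function(config, seed = NULL, well_id = "A01",
                          replicate_id = "rep1") {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    loaded_mut <- rpois(1L, config$conc_mut * config$sample_volume_ul)
    loaded_wt <- rpois(1L, config$conc_wt * config$sample_volume_ul)
    post_mut <- simulate_preamp(loaded_mut, config$preamp_cycles,
                                config$preamp_efficiency)
    post_wt <- simulate_preamp(loaded_wt, config$preamp_cycles,
                               config$preamp_efficiency)
    n <- config$n_partitions
    occ_mut <- rpois(n, post_mut / n)
    occ_wt <- rpois(n, post_wt / n)

    fam_template <- occ_mut > 0
    cross <- !fam_template & occ_wt > 0 &
      runif(n) < config$cross_hyb_rate
    artifact <- !fam_template & !cross &
      runif(n) < config$fp_artifact_rate
    fam_pos <- fam_template | cross | artifact
    hex_pos <- occ_wt > 0

    droplets <- data.frame(
      well_id = well_id,
      replicate_id = replicate_id,
      fam_rfu = draw_channel_amplitudes(fam_pos, config$neg_cloud$fam,
                                        config$pos_cloud$fam,
                                        config$rain_fraction),
      hex_rfu = draw_channel_amplitudes(hex_pos, config$neg_cloud$hex,
                                        config$pos_cloud$hex,
                                        config$rain_fraction),
      stringsAsFactors = FALSE)
    list(droplets = droplets,
         truth = list(copies_mut_loaded = loaded_mut,
                      copies_wt_loaded = loaded_wt,
                      post_preamp_mut = post_mut,
                      post_preamp_wt = post_wt,
                      n_fam_template_partitions = sum(fam_template),
                      n_fam_positive_partitions = sum(fam_pos),
                      n_hex_positive_partitions = sum(hex_pos)))
  })
}

#' Simulate a replicated dPCR experiment with known ground truth
#'
#' Runs [simulate_well()] once per technical replicate. Each replicate
#' draws its own template load from the specimen, so low-concentration
#' configurations show realistic replicate-to-replicate dropout.
#'
#' @param config a [sim_config()] object; `config$seed` (if set) makes
#'   the whole experiment reproducible.
#' @return a `dpcr_experiment` object: list with `wells` (one droplet
#'   data frame per replicate), `truth` (list with `true_vaf` and a
#'   per-replicate data frame of loaded / post-preamplification copy
#'   numbers) and `config`.
#' @examples
#' exp <- simulate_experiment(sim_config(seed = 42, n_partitions = 2000))
#' exp$truth$true_vaf  # 0.14
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    wells <- vector("list", config$n_replicates)
    per_rep <- vector("list", config$n_replicates)
    for (r in seq_len(config$n_replicates)) {
      w <- simulate_well(config,
                         well_id = sprintf("A%02d", r),
                         replicate_id = sprintf("rep%d", r))
      wells[[r]] <- w$droplets
      per_rep[[r]] <- data.frame(replicate = sprintf("rep%d", r),
                                 as.data.frame(w$truth),
                                 stringsAsFactors = FALSE)
    }
    total <- config$conc_mut + config$conc_wt
    structure(
      list(wells = wells,
           truth = list(
             true_vaf = if (total > 0) config$conc_mut / total else NA_real_,
             replicates = do.call(rbind, per_rep)),
           config = config),
      class = "dpcr_experiment")
  })
}

#' @export
print.dpcr_experiment <- function(x, ...) {
  cat(sprintf(
    "<dpcr_experiment> %d replicate(s) x %d partitions; true VAF %s\n",
    length(x$wells), x$config$n_partitions,
    if (is.na(x$truth$true_vaf)) "undefined"
    else sprintf("%.1f%%", 100 * x$truth$true_vaf)))
  invisible(x)
}
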