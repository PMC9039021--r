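# Shared fixture builders for the test suite.

# Unique scratch path under the session tempdir (removed with it).
scratch_file <- function(name) {
  tempfile(pattern = paste0(sub("\\..*$", "", name), "_"),
           fileext = sub("^[^.]*", "", name))
}

# Well classification with given channel counts and no double positives.
make_wc <- function(fam, hex, n = 20000, profile = NULL) {
  well_classification(n_total = n, n_fam_pos = fam, n_hex_pos = hex,
                      n_double_pos = 0, n_double_neg = n - fam - hex,
                      profile = profile)
}

# Simulator configuration with artifact channels switched off.
clean_config <- function(...) {
  sim_config(fp_artifact_rate = 0, cross_hyb_rate = 0, rain_fraction = 0,
             ...)
}

qx200 <- load_platform_profile("qx200")

# Dilution point whose duplicate wells carry the given summed FAM/HEX
# counts (split evenly across the two wells).
make_dilution_point <- function(mass, fam_total, hex_total, n = 20000) {
  half <- function(x) c(floor(x / 2), ceiling(x / 2))
  fams <- half(fam_total); hexes <- half(hex_total)
  dilution_point(mass, list(make_wc(fams[1], hexes[1], n),
                            make_wc(fams[2], hexes[2], n)))
}
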