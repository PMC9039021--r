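test_that("amplitude CSVs round-trip in both dialects", {
  w <- simulate_well(sim_config(n_partitions = 200), seed = 21)
  for (dialect in c("droplet", "nanoplate")) {
    path <- scratch_file(sprintf("rt_%s.csv", dialect))
    write_amplitude_csv(w$droplets, path, dialect = dialect)
    back <- read_amplitude_csv(path, dialect = dialect)
    expect_equal(back, w$droplets, tolerance = 1e-12)
  }
})

test_that("empty data section yields an empty record set", {
  path <- scratch_file("empty.csv")
  writeLines("Well,Sample,Ch1Amplitude,Ch2Amplitude", path)
  rec <- read_amplitude_csv(path, dialect = "droplet")
  expect_identical(nrow(rec), 0L)
  expect_named(rec, c("well_id", "replicate_id", "fam_rfu", "hex_rfu"))
})

test_that("schema and validation errors are total and informative", {
  # header of the other dialect: schema error naming the missing columns
  path <- scratch_file("wrongdialect.csv")
  writeLines("WellID,Replicate,FAM,HEX", path)
  expect_error(read_amplitude_csv(path, dialect = "droplet"),
               "Ch1Amplitude")
  # negative amplitude: row-indexed validation error, nothing returned
  path2 <- scratch_file("neg.csv")
  writeLines(c("Well,Sample,Ch1Amplitude,Ch2Amplitude",
               "A01,r1,100,200", "A01,r1,-5,200"), path2)
  expect_error(read_amplitude_csv(path2, dialect = "droplet"), "row")
  # non-numeric amplitude likewise
  path3 <- scratch_file("txt.csv")
  writeLines(c("Well,Sample,Ch1Amplitude,Ch2Amplitude",
               "A01,r1,abc,200"), path3)
  expect_error(read_amplitude_csv(path3, dialect = "droplet"), "row")
})

test_that("col_map adapts vendor column names", {
  path <- scratch_file("vendor.csv")
  writeLines(c("Well,Sample,Ch1 Amplitude,Ch2 Amplitude",
               "A01,r1,1500,800"), path)
  rec <- read_amplitude_csv(path, dialect = "droplet",
                            col_map = c(fam = "Ch1 Amplitude",
                                        hex = "Ch2 Amplitude"))
  expect_equal(rec$fam_rfu, 1500)
  expect_error(read_amplitude_csv(path, dialect = "droplet",
                                  col_map = c(bogus = "x")),
               "unknown col_map roles")
})

test_that("write_experiment emits per-replicate wells plus a truth sidecar", {
  dir <- scratch_file("expdir")
  exp <- simulate_experiment(sim_config(n_partitions = 100, seed = 8))
  paths <- write_experiment(exp, dir)
  expect_length(paths, 2)
  expect_true(file.exists(file.path(dir, "truth.json")))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$true_vaf, exp$truth$true_vaf, tolerance = 1e-12)
  back <- read_amplitude_csv(paths[1], dialect = "droplet")
  expect_equal(back, exp$wells[[1]], tolerance = 1e-12)
})

test_that("platform profiles expose the documented thresholds and defaults", {
  qx <- load_platform_profile("qx200")
  expect_equal(qx$fam_threshold_rfu, 2000)
  expect_equal(qx$hex_threshold_rfu, 1500)
  expect_equal(qx$vpf, 1.0)
  qc <- load_platform_profile("qiacuity")
  expect_equal(qc$fam_threshold_rfu, 40)
  expect_equal(qc$hex_threshold_rfu, 20)
  # vpf omitted from a user profile defaults to 1.0
  custom <- load_platform_profile(
    "mine", config = list(mine = list(fam_threshold_rfu = 10,
                                      hex_threshold_rfu = 5,
                                      partition_volume_nl = 1)))
  expect_equal(custom$vpf, 1.0)
  expect_error(load_platform_profile("nope"), "unknown platform profile")
})

test_that("cohort tables are read with per-isolate rows and validated", {
  cohort <- csf_cohort()
  expect_identical(nrow(cohort), 21L)
  expect_true(all(cohort$collection_route %in% c("VAD", "IO", "LP")))
  # repeat isolates preserved as separate rows
  expect_identical(sum(cohort$patient_id == "P11"), 3L)
  expect_identical(sum(cohort$patient_id == "P12"), 2L)
  expect_true(any(cohort$collection_route == "LP"))

  bad <- scratch_file("badroute.tsv")
  writeLines(c(paste("patient_id", "collection_route", "csf_volume_ml",
                     "conc_37", "conc_150", "conc_300", "tissue_h3_status",
                     sep = "\t"),
               paste("X", "SHUNT", "2", "1", "1", "1", "negative",
                     sep = "\t")), bad)
  expect_error(read_cohort_table(bad), "collection_route")

  bad2 <- scratch_file("badconc.tsv")
  writeLines(c(paste("patient_id", "collection_route", "csf_volume_ml",
                     "conc_37", "conc_150", "conc_300", "tissue_h3_status",
                     sep = "\t"),
               paste("X", "LP", "2", "1", "-3", "1", "negative",
                     sep = "\t")), bad2)
  expect_error(read_cohort_table(bad2), "negative")
})
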