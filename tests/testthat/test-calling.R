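test_that("droplet classification respects the partition identity and boundaries", {
  # all-dark well: everything double negative
  dark <- data.frame(well_id = "A", replicate_id = "r",
                     fam_rfu = rep(0, 10), hex_rfu = rep(0, 10))
  cl <- classify_droplets(dark, qx200)
  expect_equal(cl$n_double_neg, cl$n_total)
  # amplitude exactly at threshold counts as positive
  edge <- data.frame(well_id = "A", replicate_id = "r",
                     fam_rfu = c(2000, 1999.99), hex_rfu = c(0, 0))
  expect_equal(classify_droplets(edge, qx200)$n_fam_pos, 1)
  expect_error(classify_droplets(dark[0, ], qx200), "empty well")
})

test_that("classification counts match simulator ground truth when clouds are clean", {
  # rain off and clouds far from the thresholds: threshold counts must
  # equal the injected occupancy truth exactly
  cfg <- clean_config(conc_mut = 30, conc_wt = 100, preamp_cycles = 0,
                      n_partitions = 5000)
  for (s in c(2, 17, 31)) {
    w <- simulate_well(cfg, seed = s)
    cl <- classify_droplets(w$droplets, qx200)
    expect_equal(cl$n_fam_pos, w$truth$n_fam_positive_partitions)
    expect_equal(cl$n_hex_pos, w$truth$n_hex_positive_partitions)
    # identity holds by construction
    expect_equal(cl$n_fam_pos + cl$n_hex_pos - cl$n_double_pos +
                   cl$n_double_neg, cl$n_total)
  }
})

test_that("sample calling follows the duplicate decision rules", {
  call <- function(fam1, fam2, hex_total, ...)
    call_sample(list(make_wc(fam1, floor(hex_total / 2)),
                     make_wc(fam2, ceiling(hex_total / 2))), ...)$verdict
  # 30 + 40 = 70 >= 50, both replicates fire: positive
  expect_identical(call(30, 40, 500), "positive")
  # 49 FAM in total with > 50 HEX: negative
  expect_identical(call(24, 25, 600), "negative")
  # 60 + 0: threshold met but not reproducible: ambiguous
  expect_identical(call(60, 0, 600), "ambiguous")
  # a few FAM positives without wild-type support: ambiguous
  expect_identical(call(2, 1, 30), "ambiguous")
  # no FAM and hardly any HEX: non-informative well
  expect_identical(call(0, 0, 40), "non_informative")
  # no FAM with solid HEX: negative
  expect_identical(call(0, 0, 600), "negative")
  # boundary: exactly 50 in total satisfies "at least 50"
  expect_identical(call(25, 25, 600), "positive")
  # hex exactly at 50 does not satisfy "more than 50"
  expect_identical(call(0, 0, 50), "non_informative")
  # stricter per-replicate reading of the positive rule
  expect_identical(call(60, 10, 600, positive_rule = "per_replicate"),
                   "ambiguous")
  expect_identical(call(60, 55, 600, positive_rule = "per_replicate"),
                   "positive")
})

test_that("sample calling is total: every count configuration gets one verdict", {
  verdicts <- c("positive", "negative", "ambiguous", "non_informative")
  for (fam1 in c(0, 1, 25, 60))
    for (fam2 in c(0, 1, 25, 60))
      for (hex in c(0, 40, 51, 500)) {
        v <- call_sample(list(make_wc(fam1, hex), make_wc(fam2, hex)))$verdict
        expect_true(v %in% verdicts)
      }
})

test_that("sample calling rejects anything but exactly two wells", {
  expect_error(call_sample(list(make_wc(10, 10))), "exactly two")
  expect_error(call_sample(list(make_wc(1, 1), make_wc(1, 1),
                                make_wc(1, 1))), "exactly two")
})

test_that("high mutant load is always called positive, absent mutant never", {
  hot <- clean_config(conc_mut = 500, conc_wt = 500, preamp_cycles = 0,
                      sample_volume_ul = 2, n_partitions = 5000)
  cold <- clean_config(conc_mut = 0, conc_wt = 100, preamp_cycles = 0,
                       sample_volume_ul = 2, n_partitions = 5000)
  for (s in 1:10) {
    hot$seed <- s; cold$seed <- s
    call_of <- function(cfg) {
      e <- simulate_experiment(cfg)
      call_sample(lapply(e$wells, classify_droplets, qx200))$verdict
    }
    expect_identical(call_of(hot), "positive")
    expect_identical(call_of(cold), "negative")
  }
})

test_that("informativeness filter excludes only zero 150 bp concentrations", {
  expect_identical(informativeness_filter(c(0, 3, 15170)),
                   c(FALSE, TRUE, TRUE))
  cohort <- csf_cohort()
  keep <- informativeness_filter(cohort)
  # exactly the four isolates with no >= 150 bp fragments drop out
  expect_identical(sum(!keep), 4L)
  expect_true(all(cohort$conc_150[!keep] == 0))
  expect_error(informativeness_filter(c(1, NA)), "missing")
})
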