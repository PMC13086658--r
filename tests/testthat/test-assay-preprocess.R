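test_that("reporter normalization divides by the per-replicate solvent-control ratio", {
  # treated identical to SC -> all fold inductions 1
  raw <- raw_plate(fold = c(1, 1, 1))
  d <- normalize_reporter(raw)
  expect_true(all(abs(d$response - 1) < 1e-12))
  # doubled firefly, unchanged renilla -> fold 2
  raw <- raw_plate(fold = c(2, 2, 2))
  d <- normalize_reporter(raw)
  expect_true(all(abs(d$response[d$concentration > 0] - 2) < 1e-12))
  # hand arithmetic: SC ratios (1.0, 1.2, 0.8) mean 1.0, treated ratio 1.5
  raw <- data.frame(compound_id = "c", concentration = c(0, 0, 0, 10),
                    bio_rep = 1, tech_rep = 1:4,
                    fluc = c(1.0, 1.2, 0.8, 1.5), rluc = 1)
  d <- normalize_reporter(raw)
  expect_equal(d$response[d$concentration == 10], 1.5)
})

test_that("solvent controls average to one within each biological replicate", {
  set.seed(4)
  raw <- raw_plate(bio = 3, tech = 3)
  raw$fluc <- raw$fluc * exp(rnorm(nrow(raw), 0, 0.2))
  raw$rluc <- raw$rluc * exp(rnorm(nrow(raw), 0, 0.1))
  d <- normalize_reporter(raw)
  sc_means <- tapply(d$response[d$concentration == 0],
                     d$bio_rep[d$concentration == 0], mean)
  expect_true(all(abs(sc_means - 1) < 1e-12))
})

test_that("normalization is idempotent and validates its input", {
  raw <- raw_plate()
  d <- normalize_reporter(raw)
  again <- normalize_reporter(data.frame(compound_id = d$compound_id,
                                         concentration = d$concentration,
                                         bio_rep = d$bio_rep,
                                         tech_rep = d$tech_rep,
                                         fluc = d$response, rluc = 1))
  expect_equal(again$response, d$response, tolerance = 1e-12)
  bad <- raw; bad$rluc[1] <- 0
  expect_error(normalize_reporter(bad), "RLuc")
  expect_error(normalize_reporter(raw[raw$concentration > 0, ]),
               "solvent-control")
})

test_that("cytotoxicity rule reproduces the worked viability examples", {
  expect_equal(highest_noncytotoxic(c(10, 50, 100), c(98, 95, 79)), 50)
  expect_equal(highest_noncytotoxic(c(10, 50, 100), c(100, 92, 81)), 50)
  expect_equal(highest_noncytotoxic(c(10, 50, 100), c(100, 100, 100)), 100)
  # lowest concentration already below threshold -> none
  expect_true(is.na(highest_noncytotoxic(c(10, 50), c(79, 70))))
  expect_error(highest_noncytotoxic(c(50, 10), c(90, 90)), "ascending")
})

test_that("drop rule switches between absolute points and relative percent", {
  # 95 -> 86: 9 points (not cytotoxic by points), 9.47% (not by relative)
  expect_equal(highest_noncytotoxic(c(1, 10), c(95, 86)), 10)
  # 95 -> 84: 11 points -> cytotoxic by points
  expect_equal(highest_noncytotoxic(c(1, 10), c(95, 84)), 1)
  # relative: 95 -> 85 is 10.5% -> cytotoxic, though 10 points would also flag;
  # use 90 -> 81 = 9 points but exactly 10% relative
  expect_equal(highest_noncytotoxic(c(1, 10), c(90, 81),
                                    drop_rule = "relative"), 1)
  expect_equal(highest_noncytotoxic(c(1, 10), c(90, 81),
                                    drop_rule = "points"), 10)
})

test_that("the cutoff is monotone in the absolute viability threshold", {
  set.seed(11)
  for (i in 1:50) {
    conc <- sort(10^runif(6, -1, 2.7))
    viab <- 100 - cumsum(runif(6, 0, 12))
    cuts <- vapply(c(70, 80, 90), function(th)
      highest_noncytotoxic(conc, viab, abs_threshold = th), numeric(1))
    # a stricter (higher) threshold can only lower the cutoff
    cuts[is.na(cuts)] <- 0
    expect_true(all(diff(cuts) <= 0))
  }
})

test_that("truncation removes only supra-cutoff records and warns on empty", {
  sp <- curve_spec(concentrations = c(0.1, 1, 10, 50, 100))
  d <- simulate_dose_response(sp, seed = 1)
  tr <- truncate_to_noncytotoxic(d, 50)
  expect_equal(sort(unique(tr$concentration)), c(0.1, 1, 10, 50))
  expect_equal(nrow(tr), sum(d$concentration <= 50))
  # cutoff at the top dose: identity
  expect_equal(nrow(truncate_to_noncytotoxic(d, 100)), nrow(d))
  expect_warning(empty <- truncate_to_noncytotoxic(d, NA_real_), "cytotoxic")
  expect_equal(nrow(empty), 0)
  expect_error(truncate_to_noncytotoxic(d, 50, compound_id = "other"),
               "mismatch")
})
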