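test_that("trend gate separates rising curves from flat ones", {
  sp <- curve_spec(family = "exponential", true_bmd = 5, noise_scale = 0,
                   max_effect = 30)
  expect_true(trend_gate(simulate_dose_response(sp, seed = 1)))
  flat <- simulate_dose_response(sp, seed = 1)
  set.seed(3)
  flat$response <- rnorm(nrow(flat), 1, 0.02)
  expect_false(trend_gate(dose_response_set(flat)))
  two <- flat[flat$concentration %in% c(0.1, 1), ]
  expect_error(trend_gate(dose_response_set(two)), "3 dose groups")
})

test_that("candidate fits are seeded, diagnosed, and recover noise-free truth", {
  sp <- curve_spec(family = "gamma", true_bmd = 10, noise_scale = 0,
                   max_effect = 30)
  d <- simulate_dose_response(sp, seed = 1)
  f1 <- fit_candidate(d, "gamma", "normal", draws = 3000, warmup = 1500,
                      seed = 4)
  f2 <- fit_candidate(d, "gamma", "normal", draws = 3000, warmup = 1500,
                      seed = 4)
  expect_identical(f1$draws, f2$draws)
  expect_equal(nrow(f1$draws), 1500)  # retained = draws - warmup
  expect_lt(abs(median(f1$bmd_draws, na.rm = TRUE) - 10) / 10, 0.01)
  expect_true(is.finite(f1$rhat))
  # log-normal error demands positive responses
  neg <- d; neg$response[1] <- -0.1
  expect_error(fit_candidate(dose_response_set(neg), "gamma", "lognormal"),
               "positive")
})

test_that("model averaging mixes candidate posteriors by weight", {
  mk <- function(bmds, lml) list(bmd_draws = bmds, log_ml = lml,
                                 divergent = FALSE)
  # degenerate mixture: one candidate with all the weight
  one <- model_average(list(mk(c(1, 2, 3, 4, 5), 0),
                            mk(c(100, 100), -1e6)))
  expect_equal(one$weights, c(1, 0), tolerance = 1e-12)
  expect_equal(one$bmd, 3)
  # two equally weighted symmetric candidates: mixture median between them
  sym <- model_average(list(mk(seq(0.5, 1.5, length.out = 101), 0),
                            mk(seq(2.5, 3.5, length.out = 101), 0)))
  expect_equal(sym$weights, c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(sym$bmd, 2, tolerance = 1e-9)  # midpoint of the mixture gap
  expect_equal(sum(sym$weights), 1, tolerance = 1e-12)
  # all candidates failed
  bad <- model_average(list(mk(1:5, -Inf)))
  expect_true(bad$failed)
})

test_that("a full fit enumerates all sixteen candidates and orders its bounds", {
  sp <- curve_spec(family = "hill", true_bmd = 10, noise_scale = 0.15,
                   max_effect = 30)
  d <- simulate_dose_response(sp, seed = 12)
  r <- bmd_fit(d, draws = 1500, warmup = 750, seed = 2)
  expect_s3_class(r, "bmd_fit")
  expect_equal(nrow(r$weights), 16)
  expect_equal(nrow(unique(r$weights[, c("family", "noise")])), 16)
  expect_equal(sum(r$weights$weight), 1, tolerance = 1e-12)
  expect_true(r$bmdl <= r$bmd && r$bmd <= r$bmdu)
  expect_gte(r$uncertainty_ratio, 1)
})

test_that("a failed trend gate yields an empty estimate", {
  sp <- curve_spec(true_bmd = 10, max_effect = 30)
  d <- simulate_dose_response(sp, seed = 1)
  set.seed(8)
  d$response <- rnorm(nrow(d), 1, 0.05)
  r <- bmd_fit(dose_response_set(d), seed = 1)
  expect_false(r$trend_ok)
  expect_true(is.na(r$bmd) && is.na(r$bmdl) && is.na(r$bmdu))
})

test_that("larger benchmark responses give larger benchmark doses", {
  cand <- list(family = "exponential", parameters = c(a = 1, b = 8, c = 25,
                                                      d = 1.3))
  bmds <- vapply(c(1.2, 1.5, 2, 3), function(r) bmd_from_params(cand, r),
                 numeric(1))
  expect_true(all(diff(bmds) > 0))
})

test_that("the posterior is equivariant under rescaling of the dose axis", {
  sp <- curve_spec(family = "hill", true_bmd = 10, noise_scale = 0.15,
                   max_effect = 30)
  d <- simulate_dose_response(sp, seed = 2)
  d2 <- d; d2$concentration <- d$concentration * 7
  d2 <- dose_response_set(d2)
  for (fam in c("exponential", "probit")) {
    f1 <- fit_candidate(d, fam, "normal", draws = 1200, warmup = 600, seed = 5)
    f2 <- fit_candidate(d2, fam, "normal", draws = 1200, warmup = 600, seed = 5)
    expect_equal(f2$bmd_draws, 7 * f1$bmd_draws, tolerance = 1e-8, info = fam)
  }
})
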