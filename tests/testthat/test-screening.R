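# train a small model on the featurized panel with a synthetic response
trained_panel_model <- function() {
  if (!is.null(.panel_cache$model)) return(.panel_cache$model)
  dm <- panel_descriptors()
  st <- standardize_descriptors(clean_descriptors(dm))
  set.seed(5)
  feats <- c(grep("^mordred:", st$feature_names, value = TRUE)[1:3],
             grep("^ecfp:", st$feature_names, value = TRUE)[1])
  X <- st$values[, feats]
  y <- exp(log(20) + 0.7 * X[, 1] - 0.4 * X[, 4] + rnorm(nrow(X), 0, 0.15))
  m <- qsar_fit(descriptor_matrix(X, ids = st$ids, feature_names = feats,
                                  feature_kind = st$feature_kind[
                                    match(feats, st$feature_names)],
                                  state = "standardized",
                                  scaler = st$scaler), y)
  .panel_cache$model <- m
  m
}

test_that("screening the training panel reproduces training predictions in-box", {
  m <- trained_panel_model()
  sr <- screen_compounds(panel_compounds(), m)
  expect_equal(nrow(sr$records), nrow(panel_compounds()))
  expect_true(all(sr$records$in_bbox))  # self-screen: box always passes
  expect_equal(sr$records$predicted_bmd, unname(predict(m)),
               tolerance = 1e-10)
})

test_that("every input id appears exactly once and failures are isolated", {
  m <- trained_panel_model()
  lst <- rbind(panel_compounds()[1:3, ],
               data.frame(id = "broken", smiles = "xx(("),
               panel_compounds()[4:5, ])
  sr <- suppressMessages(screen_compounds(lst, m))
  expect_equal(sr$records$id, lst$id)
  expect_equal(sum(nzchar(sr$records$failure_reason)), 1)
  expect_true(is.na(sr$records$predicted_bmd[sr$records$id == "broken"]))
  expect_equal(sr$summary$n_failed, 1)
})

test_that("batched screening equals all-at-once and is rerun-deterministic", {
  m <- trained_panel_model()
  lst <- rbind(panel_compounds(), make_pfas_like_series("FTS", c(4, 6, 8)))
  a <- screen_compounds(lst, m, batch_size = 4)
  b <- screen_compounds(lst, m, batch_size = 1000)
  expect_identical(a$records, b$records)
  expect_identical(a$summary, b$summary)
})

test_that("out-of-range congeners are counted out of domain", {
  m <- trained_panel_model()
  # much longer chains push descriptor values outside the training ranges
  lst <- rbind(panel_compounds()[1:3, ],
               make_pfas_like_series("PFCA", c(16, 18)))
  sr <- screen_compounds(lst, m)
  long <- grepl("C1[68]$", sr$records$id)
  expect_true(all(!sr$records$in_domain[long]))
  expect_equal(sr$summary$n_in_domain, sum(sr$records$in_domain, na.rm = TRUE))
})

test_that("an empty list yields an empty result with zero counts", {
  m <- trained_panel_model()
  sr <- screen_compounds(data.frame(id = character(0),
                                    smiles = character(0)), m)
  expect_equal(nrow(sr$records), 0)
  expect_equal(sr$summary$n, 0)
  expect_equal(sr$summary$n_in_domain, 0)
  expect_true(is.na(sr$summary$median_bmd_in_domain))
})

test_that("top-k ranks in-domain hits by ascending predicted BMD", {
  rec <- data.frame(id = c("c", "a", "b", "d", "e"),
                    smiles = "", predicted_bmd = c(3, 1, 2, 0.5, 1),
                    in_bbox = TRUE, h = 0.1, h_star = 1,
                    in_domain = c(TRUE, TRUE, TRUE, FALSE, TRUE),
                    collision_check = FALSE, failure_reason = "")
  top <- top_k(rec, 3)
  expect_equal(top$id, c("a", "e", "b"))  # tie at 1 broken by id
  expect_false("d" %in% top_k(rec, 10)$id)  # out-of-domain excluded
  expect_equal(nrow(top_k(rec, 10)), 4)     # k beyond the in-domain count
})

test_that("screening lists are read from CSV and plain SMILES dialects", {
  csv <- file.path(tempdir(), "list.csv")
  write.csv(data.frame(id = c("x1", "x2"), smiles = c("CCO", "CCC")), csv,
            row.names = FALSE)
  got <- read_screening_list(csv)
  expect_equal(got$smiles, c("CCO", "CCC"))
  smi <- file.path(tempdir(), "list.smi")
  writeLines(c("CCO\tx1", "CCC"), smi)
  got2 <- read_screening_list(smi)
  expect_equal(got2$smiles, c("CCO", "CCC"))
  expect_equal(got2$id[1], "x1")
})
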