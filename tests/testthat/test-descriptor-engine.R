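test_that("featurization yields the four blocks with a 166-key MACCS block", {
  dm <- panel_descriptors()
  expect_s3_class(dm, "descriptor_matrix")
  expect_equal(sum(grepl("^maccs:", dm$feature_names)), 166)
  expect_equal(sum(grepl("^ecfp:", dm$feature_names)), 2048)
  expect_true(all(c("mordred:AATS5dv", "mordred:ATSC5dv", "mordred:ATSC6c",
                    "mordred:GATS5p", "phys:TPSA") %in% dm$feature_names))
  bin <- dm$feature_kind == "binary"
  expect_true(all(dm$values[, bin] %in% c(0, 1)))
})

test_that("featurization is deterministic and flags unparseable SMILES", {
  cmp <- data.frame(id = c("a", "bad", "b"),
                    smiles = c("CCO", "not_a_smiles((", "OC(=O)C(F)(F)F"))
  dm <- suppressMessages(featurize(cmp))
  expect_equal(dm$ids, c("a", "b"))
  expect_equal(attr(dm, "failures"), "bad")
  dm2 <- suppressMessages(featurize(cmp))
  expect_identical(dm$values, dm2$values)
})

test_that("polar surface area behaves as a polarity measure", {
  dm <- suppressMessages(featurize(data.frame(id = c("ethane", "ethanol"),
                                              smiles = c("CC", "CCO"))))
  tpsa <- dm$values[, "phys:TPSA"]
  expect_equal(unname(tpsa["ethane"]), 0)
  expect_gt(tpsa["ethanol"], 0)
})

test_that("autocorrelation descriptors match a hand-computed molecule", {
  # propan-1-ol C-C-C-O: heavy-atom graph is a path; mass weights with
  # implicit hydrogens folded in: CH3 15.035, CH2 14.027, CH2 14.027, OH 17.007
  dm <- suppressMessages(featurize(data.frame(id = "p", smiles = "CCCO")))
  w <- c(12.011 + 3 * 1.008, 12.011 + 2 * 1.008, 12.011 + 2 * 1.008,
         15.999 + 1.008)
  ats1 <- w[1] * w[2] + w[2] * w[3] + w[3] * w[4]
  ats2 <- w[1] * w[3] + w[2] * w[4]
  expect_equal(unname(dm$values[, "mordred:ATS1m"]), ats1, tolerance = 1e-6)
  expect_equal(unname(dm$values[, "mordred:ATS2m"]), ats2, tolerance = 1e-6)
  expect_equal(unname(dm$values[, "mordred:AATS1m"]), ats1 / 3,
               tolerance = 1e-6)
  wc <- w - mean(w)
  expect_equal(unname(dm$values[, "mordred:ATSC1m"]),
               wc[1] * wc[2] + wc[2] * wc[3] + wc[3] * wc[4],
               tolerance = 1e-6)
  gats1 <- (((w[1] - w[2])^2 + (w[2] - w[3])^2 + (w[3] - w[4])^2) / (2 * 3)) /
    (sum(wc^2) / 3)
  expect_equal(unname(dm$values[, "mordred:GATS1m"]), gats1, tolerance = 1e-6)
})

test_that("cleaning drops non-finite, low-variance and correlated columns", {
  set.seed(2)
  n <- 30
  a <- rnorm(n); b <- a + rnorm(n, 0, 0.05)  # r > 0.99
  X <- cbind(nonfin = c(NaN, rnorm(n - 1)), const = rep(1, n),
             modal = c(rep(0, 29), 1), a = a, dup = a, b = b,
             ind = rnorm(n))
  dm <- descriptor_matrix(X, ids = sprintf("c%d", 1:n),
                          feature_names = colnames(X),
                          feature_kind = rep("continuous", ncol(X)),
                          state = "raw")
  cl <- clean_descriptors(dm)
  expect_equal(cl$feature_names, c("a", "ind"))
  expect_setequal(cl$manifest$reason[cl$manifest$feature == "nonfin"],
                  "non-finite")
  expect_setequal(cl$manifest$reason[cl$manifest$feature %in%
                                       c("const", "modal")], "low-variance")
  expect_setequal(cl$manifest$reason[cl$manifest$feature %in% c("dup", "b")],
                  "correlated")
})

test_that("correlation pruning is the first-kept greedy rule", {
  # chain: a-b and b-c above the 0.9 ceiling, a-c below it -> keep {a, c}
  set.seed(42)
  n <- 4000
  a <- rnorm(n)
  c_ <- 0.82 * a + sqrt(1 - 0.82^2) * rnorm(n)
  b <- (a + c_) / sqrt(2 + 2 * 0.82)  # r(a,b) = r(b,c) ~ 0.95
  X <- cbind(a = a, b = b, c = c_)
  stopifnot(abs(cor(a, b)) > 0.9, abs(cor(b, c_)) > 0.9,
            abs(cor(a, c_)) < 0.9)
  dm <- descriptor_matrix(X, ids = sprintf("r%d", 1:n),
                          feature_names = colnames(X),
                          feature_kind = rep("continuous", 3), state = "raw")
  cl <- clean_descriptors(dm)
  expect_equal(cl$feature_names, c("a", "c"))
  # a just-below-threshold pair survives intact
  set.seed(1)
  u <- rnorm(500); v <- 0.85 * u + sqrt(1 - 0.85^2) * rnorm(500)
  stopifnot(abs(cor(u, v)) < 0.9)
  dm2 <- descriptor_matrix(cbind(u = u, v = v), ids = sprintf("r%d", 1:500),
                           feature_names = c("u", "v"),
                           feature_kind = rep("continuous", 2), state = "raw")
  expect_equal(clean_descriptors(dm2)$feature_names, c("u", "v"))
})

test_that("cleaning is idempotent and leaves no pair above the threshold", {
  dm <- panel_descriptors()
  cl <- clean_descriptors(dm)
  R <- abs(cor(cl$values))
  expect_lte(max(R[upper.tri(R)]), 0.9 + 1e-12)
  cl2 <- clean_descriptors(cl)
  expect_identical(cl$values, cl2$values)
})

test_that("standardization z-scores continuous columns on training rows only", {
  dm <- clean_descriptors(panel_descriptors())
  st <- standardize_descriptors(dm)
  cont <- st$feature_kind == "continuous"
  expect_lt(max(abs(colMeans(st$values[, cont]))), 1e-9)
  expect_lt(max(abs(apply(st$values[, cont], 2, sd) - 1)), 1e-9)
  bin <- st$feature_kind == "binary"
  expect_true(all(st$values[, bin] %in% c(0, 1)))
  # projecting a training row through the stored scaler reproduces it
  proj <- bmdqsar:::.project_features(dm$values[3, , drop = FALSE], st$scaler)
  expect_equal(unname(proj[1, ]), unname(st$values[3, ]), tolerance = 1e-12)
  # a row at the training mean maps to zero on continuous features
  mu <- matrix(colMeans(dm$values), 1,
               dimnames = list(NULL, dm$feature_names))
  z <- bmdqsar:::.project_features(mu, st$scaler)
  expect_lt(max(abs(z[, cont])), 1e-9)
})

test_that("descriptor matrices round-trip through CSV with their sidecar", {
  dm <- standardize_descriptors(clean_descriptors(panel_descriptors()))
  path <- file.path(tempdir(), "dm.csv")
  write_descriptors(dm, path)
  back <- read_descriptors(path)
  expect_equal(back$values, dm$values, tolerance = 1e-12)
  expect_equal(unname(back$feature_kind), dm$feature_kind)
  expect_equal(back$state, "standardized")
  expect_equal(back$scaler$sd, dm$scaler$sd, tolerance = 1e-12)
})
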