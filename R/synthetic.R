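#' Specification of a synthetic dose-response curve
#'
#' Describes one compound's true concentration-response relationship in the
#' units the reporter assay produces (fold induction over solvent control).
#' The defaults mirror the design of a dual-luciferase transactivation
#' experiment: background close to 1, plateau around 30-fold, seven half-log
#' spaced concentrations from 0.1 uM, and three biological times three
#' technical replicates.
#'
#' @param compound_id label for the simulated compound.
#' @param family one of [drc_families()].
#' @param background fold induction at dose 0 (default 1).
#' @param true_bmd concentration (uM) at which the noise-free median response
#'   equals `bmr * background`.
#' @param bmr benchmark response ratio the curve is anchored at (default 1.5).
#' @param max_effect plateau fold induction (default 30); must exceed
#'   `bmr * background`.
#' @param steepness shape parameter `d` of the family (default 1).
#' @param noise_model `"normal"` (additive, response units) or `"lognormal"`
#'   (multiplicative, sd in log units).
#' @param noise_scale noise standard deviation (default 0.15).
#' @param concentrations ascending positive concentration grid (uM); default
#'   seven half-log steps from 0.1.
#' @param bio_replicates,tech_replicates replicate structure (default 3 x 3).
#' @return object of class `curve_spec`.
#' @export
curve_spec <- function(compound_id = "synth",
                       family = "hill",
                       background = 1,
                       true_bmd = 10,
                       bmr = 1.5,
                       max_effect = 30,
                       steepness = 1,
                       noise_model = c("normal", "lognormal"),
                       noise_scale = 0.15,
                       concentrations = 0.1 * 10^(seq(0, 3, by = 0.5)),
                       bio_replicates = 3,
                       tech_replicates = 3) {
  noise_model <- match.arg(noise_model)
  family <- match.arg(family, drc_families())
  stopifnot(true_bmd > 0, background > 0, steepness > 0,
            max_effect > bmr * background, bmr > 1,
            bio_replicates >= 1, tech_replicates >= 1,
            noise_scale >= 0)
  if (any(concentrations <= 0) || is.unsorted(concentrations, strictly = TRUE))
    stop("concentrations must be strictly ascending and positive")
  structure(list(compound_id = compound_id, family = family,
                 background = background, true_bmd = true_bmd, bmr = bmr,
                 max_effect = max_effect, steepness = steepness,
                 noise_model = noise_model, noise_scale = noise_scale,
                 concentrations = concentrations,
                 bio_replicates = bio_replicates,
                 tech_replicates = tech_replicates),
            class = "curve_spec")
}

#' Simulate reporter-assay dose-response data
#'
#' Draws one fold-induction value per (concentration, biological replicate,
#' technical replicate) cell from the curve described by `spec`. Normal noise
#' is added on the response scale; log-normal noise multiplies the median by
#' `exp(N(0, noise_scale))`, so in both cases the noise-free curve is the
#' median response and passes through `bmr * background` exactly at
#' `true_bmd`.
#'
#' @param spec a [curve_spec()].
#' @param seed integer seed; identical seeds give identical data.
#' @return a `dose_response_set`: data frame with columns `compound_id`,
#'   `concentration`, `bio_rep`, `tech_rep`, `response`, carrying the
#'   generating parameters as attributes.
#' @export
simulate_dose_response <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "curve_spec"))
  c_par <- spec$max_effect / spec$background
  t <- (spec$bmr - 1) / (c_par - 1)
  b <- .b_for_bmd(spec$family, spec$true_bmd, t, spec$steepness)
  mu <- drc_median(spec$family, spec$concentrations, spec$background, b,
                   c_par, spec$steepness)
  grid <- expand.grid(tech_rep = seq_len(spec$tech_replicates),
                      bio_rep = seq_len(spec$bio_replicates),
                      concentration = spec$concentrations,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("concentration", "bio_rep", "tech_rep")]
  mu_i <- mu[match(grid$concentration, spec$concentrations)]
  n <- nrow(grid)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  resp <- if (spec$noise_model == "normal") {
    mu_i + stats::rnorm(n, 0, spec$noise_scale)
  } else {
    mu_i * exp(stats::rnorm(n, 0, spec$noise_scale))
  }
  out <- data.frame(compound_id = spec$compound_id,
                    concentration = grid$concentration,
                    bio_rep = grid$bio_rep, tech_rep = grid$tech_rep,
                    response = resp)
  dose_response_set(out, top_concentration = max(spec$concentrations),
                    truth = list(family = spec$family, true_bmd = spec$true_bmd,
                                 bmr = spec$bmr, b = b, c = c_par,
                                 d = spec$steepness, a = spec$background))
}

# save/restore global RNG state so seeded generators do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Specification of a planted-signal descriptor matrix
#'
#' Emulates the shape of a cleaned QSAR design matrix: a few dozen compounds,
#' on the order of a hundred mixed binary/continuous features, and a sparse
#' linear signal on log-BMD planted on a known subset of columns.
#'
#' @param n_compounds,n_features matrix dimensions (defaults 34 x 141,
#'   the size of the modelling problem the pipeline targets).
#' @param n_binary number of 0/1 columns (default 70); the remainder are
#'   standard-normal continuous columns.
#' @param planted_mask column indices carrying true signal (default the first
#'   two continuous columns).
#' @param coefficients effect sizes on log-BMD, one per planted column.
#' @param intercept mean log-BMD (default `log(20)`, i.e. 20 uM).
#' @param noise_sd residual sd of log-BMD (default 0.05).
#' @param correlation_block optional `list(pairs = <k x 2 matrix>, r = <num>)`
#'   forcing the named continuous column pairs to the requested Pearson
#'   correlation.
#' @param seed integer seed.
#' @return object of class `planted_matrix_spec`.
#' @export
planted_matrix_spec <- function(n_compounds = 34, n_features = 141,
                                n_binary = 70,
                                planted_mask = n_binary + 1:2,
                                coefficients = c(1, -0.8),
                                intercept = log(20),
                                noise_sd = 0.05,
                                correlation_block = NULL,
                                seed = 1) {
  stopifnot(n_binary <= n_features,
            all(planted_mask >= 1), all(planted_mask <= n_features),
            length(coefficients) == length(planted_mask),
            noise_sd >= 0)
  if (!is.null(correlation_block)) {
    stopifnot(is.list(correlation_block),
              !is.null(correlation_block$pairs), !is.null(correlation_block$r))
    if (abs(correlation_block$r) >= 1)
      stop("singular requested correlation structure: |r| must be < 1")
  }
  structure(list(n_compounds = n_compounds, n_features = n_features,
                 n_binary = n_binary, planted_mask = planted_mask,
                 coefficients = coefficients, intercept = intercept,
                 noise_sd = noise_sd, correlation_block = correlation_block,
                 seed = seed),
            class = "planted_matrix_spec")
}

#' Simulate a descriptor matrix with a planted linear signal
#'
#' Binary columns are Bernoulli draws with column-specific prevalences in
#' (0.15, 0.5); continuous columns are standard normal. The response is
#' `log_bmd = intercept + X[, planted] %*% coefficients + N(0, noise_sd)`.
#'
#' @param spec a [planted_matrix_spec()].
#' @return list with `matrix` (a cleaned-state [descriptor_matrix]),
#'   `log_bmd`, `bmd` (`exp(log_bmd)`, uM) and the spec.
#' @export
simulate_descriptor_matrix <- function(spec) {
  stopifnot(inherits(spec, "planted_matrix_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  n <- spec$n_compounds; p <- spec$n_features; nb <- spec$n_binary
  X <- matrix(0, n, p)
  if (nb > 0) {
    prev <- stats::runif(nb, 0.15, 0.5)
    X[, seq_len(nb)] <- matrix(stats::rbinom(n * nb, 1, rep(prev, each = n)),
                               n, nb)
  }
  if (p > nb)
    X[, (nb + 1):p] <- matrix(stats::rnorm(n * (p - nb)), n, p - nb)
  if (!is.null(spec$correlation_block)) {
    pr <- spec$correlation_block$pairs
    if (is.null(dim(pr))) pr <- matrix(pr, ncol = 2)
    r <- spec$correlation_block$r
    for (k in seq_len(nrow(pr))) {
      i <- pr[k, 1]; j <- pr[k, 2]
      if (i <= nb || j <= nb)
        stop("singular requested correlation structure: ",
             "correlation blocks must use continuous columns")
      X[, j] <- r * X[, i] + sqrt(1 - r^2) * stats::rnorm(n)
    }
  }
  log_bmd <- spec$intercept +
    as.vector(X[, spec$planted_mask, drop = FALSE] %*% spec$coefficients) +
    stats::rnorm(n, 0, spec$noise_sd)
  kind <- rep(c("binary", "continuous"), c(nb, p - nb))
  fn <- sprintf("synth:%s%03d", ifelse(kind == "binary", "b", "x"), seq_len(p))
  dm <- descriptor_matrix(X, ids = sprintf("cmp%03d", seq_len(n)),
                          feature_names = fn, feature_kind = kind,
                          state = "cleaned")
  list(matrix = dm, log_bmd = log_bmd, bmd = exp(log_bmd), spec = spec)
}

#' Template SMILES for homologous perfluoroalkyl series
#'
#' Builds syntactically valid SMILES for five structural subgroups of
#' per/polyfluoroalkyl substances: perfluoroalkyl carboxylic (PFCA) and
#' sulfonic (PFSA) acids, their mono-ether analogues (PFECA, PFESA), and
#' fluorotelomer sulfonic acids (FTS, with a CH2CH2 spacer). Chain length
#' counts carbon atoms (for FTS, the perfluorinated carbons only).
#'
#' @param subgroup one of `"PFCA"`, `"PFSA"`, `"PFECA"`, `"PFESA"`, `"FTS"`.
#' @param chain_lengths integer vector of chain lengths (>= 2; ether
#'   subgroups need >= 3 carbons to place the ether oxygen).
#' @return data frame with columns `id` and `smiles`.
#' @export
make_pfas_like_series <- function(subgroup, chain_lengths) {
  subgroup <- match.arg(subgroup, c("PFCA", "PFSA", "PFECA", "PFESA", "FTS"))
  stopifnot(all(chain_lengths >= 2))
  if (subgroup %in% c("PFECA", "PFESA") && any(chain_lengths < 3))
    stop("ether subgroups need chain length >= 3")
  tail_cf <- function(k) paste0(strrep("C(F)(F)", k - 1), "C(F)(F)F")
  smi <- vapply(chain_lengths, function(n) {
    switch(subgroup,
      PFCA  = paste0("OC(=O)", tail_cf(n - 1)),
      PFSA  = paste0("OS(=O)(=O)", tail_cf(n)),
      PFECA = paste0("OC(=O)C(F)(F)O", tail_cf(n - 2)),
      PFESA = paste0("OS(=O)(=O)C(F)(F)O", tail_cf(n - 1)),
      FTS   = paste0("OS(=O)(=O)CC", tail_cf(n)))
  }, character(1))
  data.frame(id = sprintf("%s-C%d", subgroup, chain_lengths), smiles = smi)
}
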