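#' Genetic-algorithm configuration
#'
#' Defaults follow the strategy that proved optimal for this pipeline:
#' population 300, tournament selection of size 3, uniform crossover with
#' probability 0.75, bit-flip mutation applied to an individual with
#' probability 0.25 (each bit then flipping with probability `indpb`,
#' default 1/n_features), and elitism preserving the top three individuals
#' per generation. Two-point crossover, Gaussian mutation (perturb-and-
#' threshold on the bit vector) and roulette-wheel selection are available
#' behind the same interface.
#'
#' @param population population size.
#' @param tournament tournament size (used when `selection = "tournament"`).
#' @param selection `"tournament"` or `"roulette"`.
#' @param crossover `"uniform"` or `"two_point"`.
#' @param p_crossover per-pair crossover probability.
#' @param mutation `"bitflip"` or `"gaussian"`.
#' @param p_mutation per-individual mutation probability.
#' @param indpb per-bit flip probability inside a mutation event
#'   (`NULL` = 1/n_features).
#' @param elitism individuals copied unchanged into the next generation.
#' @param cv_folds folds of the internal cross-validation.
#' @param lambda parsimony penalty, in MAPE percentage points per selected
#'   feature (default 0.5).
#' @param max_generations generation cap.
#' @param convergence_window stop early when the best fitness has not
#'   improved for this many generations.
#' @param init_prob per-bit activation probability in the initial population
#'   (sparse initialisation keeps early chromosomes smaller than the number
#'   of training compounds).
#' @param seed master seed; all fold re-randomization derives from it.
#' @return object of class `ga_config`.
#' @export
ga_config <- function(population = 300, tournament = 3,
                      selection = c("tournament", "roulette"),
                      crossover = c("uniform", "two_point"),
                      p_crossover = 0.75,
                      mutation = c("bitflip", "gaussian"),
                      p_mutation = 0.25, indpb = NULL, elitism = 3,
                      cv_folds = 5, lambda = 0.5, max_generations = 50,
                      convergence_window = 10, init_prob = 0.05, seed = 1) {
  selection <- match.arg(selection)
  crossover <- match.arg(crossover)
  mutation <- match.arg(mutation)
  stopifnot(p_crossover >= 0, p_crossover <= 1, p_mutation >= 0,
            p_mutation <= 1, population > elitism, elitism >= 0,
            cv_folds >= 2, lambda >= 0)
  structure(list(population = population, tournament = tournament,
                 selection = selection, crossover = crossover,
                 p_crossover = p_crossover, mutation = mutation,
                 p_mutation = p_mutation, indpb = indpb, elitism = elitism,
                 cv_folds = cv_folds, lambda = lambda,
                 max_generations = max_generations,
                 convergence_window = convergence_window,
                 init_prob = init_prob, seed = seed),
            class = "ga_config")
}

# deterministic child seed stream: independent of evaluation order, so
# serial and parallel evaluation agree (kept below 2^31)
.child_seed <- function(master, generation, index) {
  as.integer((as.numeric(master) + 97003 * generation + 193 * index) %%
               2147483647)
}

# cross-validated MAPE (%) of an OLS model on log(y), errors measured on the
# back-transformed uM scale
.cv_mape <- function(X, logy, y, cols, folds, seed) {
  n <- length(y)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fold <- sample(rep(seq_len(folds), length.out = n))
  ape <- numeric(n)
  for (f in seq_len(folds)) {
    te <- fold == f
    A <- cbind(1, X[!te, cols, drop = FALSE])
    fit <- stats::lm.fit(A, logy[!te])
    beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
    pred <- exp(cbind(1, X[te, cols, drop = FALSE]) %*% beta)
    ape[te] <- abs(pred - y[te]) / y[te]
  }
  100 * mean(ape)
}

#' Fitness of a feature mask
#'
#' `-MAPE_cv - lambda * k`: the negative cross-validated mean absolute
#' percentage error (computed on back-transformed BMD predictions against
#' observed BMDs in uM) minus a parsimony penalty proportional to the number
#' of selected features. Folds are re-randomized on every call via `seed`.
#' An empty mask scores `-Inf`.
#'
#' @param mask logical/0-1 vector over the feature columns of `X`.
#' @param X standardized feature matrix (or [descriptor_matrix()]).
#' @param y observed BMD values (uM, positive).
#' @param cfg a [ga_config()].
#' @param seed fold-randomization seed for this evaluation.
#' @return scalar fitness (higher is better).
#' @export
ga_fitness <- function(mask, X, y, cfg = ga_config(), seed = 1) {
  if (inherits(X, "descriptor_matrix")) X <- X$values
  mask <- as.logical(mask)
  if (!any(mask)) return(-Inf)
  stopifnot(length(y) == nrow(X), all(y > 0), nrow(X) >= cfg$cv_folds)
  mape <- .cv_mape(X, log(y), y, which(mask), cfg$cv_folds, seed)
  -mape - cfg$lambda * sum(mask)
}

#' Run the genetic algorithm for feature selection
#'
#' Evolves a population of binary chromosomes over the feature columns of
#' `X`, maximizing [ga_fitness()]. Elitism guarantees the best-so-far
#' fitness never decreases. Fully reproducible under a fixed
#' `cfg$seed`; each individual's cross-validation folds use a child seed
#' derived from (master seed, generation, individual index), so evaluations
#' are order-independent.
#'
#' @inheritParams ga_fitness
#' @return object of class `ga_result`: `best_mask` (logical),
#'   `best_fitness`, `features` (selected column names), and `history`
#'   (per-generation best/mean fitness and selected-feature count).
#' @export
run_ga <- function(X, y, cfg = ga_config()) {
  dm_names <- if (inherits(X, "descriptor_matrix")) X$feature_names else
    colnames(X)
  if (inherits(X, "descriptor_matrix")) X <- X$values
  L <- ncol(X)
  indpb <- if (is.null(cfg$indpb)) 1 / L else cfg$indpb
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  pop <- matrix(stats::runif(cfg$population * L) < cfg$init_prob,
                cfg$population, L)
  empty <- rowSums(pop) == 0
  pop[cbind(which(empty), sample.int(L, sum(empty), replace = TRUE))] <- TRUE
  logy <- log(y)
  eval_pop <- function(pop, gen) {
    vapply(seq_len(nrow(pop)), function(i) {
      if (!any(pop[i, ])) return(-Inf)
      -.cv_mape(X, logy, y, which(pop[i, ]), cfg$cv_folds,
                .child_seed(cfg$seed, gen, i)) - cfg$lambda * sum(pop[i, ])
    }, numeric(1))
  }
  fit <- eval_pop(pop, 0L)
  best_i <- which.max(fit)
  best_mask <- pop[best_i, ]; best_fit <- fit[best_i]
  hist <- data.frame(generation = 0L, best = best_fit,
                     mean = mean(fit[is.finite(fit)]),
                     n_selected = sum(best_mask))
  stall <- 0L
  for (gen in seq_len(cfg$max_generations)) {
    ord <- order(fit, decreasing = TRUE)
    elites <- pop[ord[seq_len(cfg$elitism)], , drop = FALSE]
    n_off <- cfg$population - cfg$elitism
    parents <- if (cfg$selection == "tournament") {
      vapply(seq_len(2 * n_off), function(i) {
        cand <- sample.int(cfg$population, cfg$tournament)
        cand[which.max(fit[cand])]
      }, integer(1))
    } else {
      w <- fit - min(fit[is.finite(fit)]) + 1e-9
      w[!is.finite(w)] <- 0
      sample.int(cfg$population, 2 * n_off, replace = TRUE, prob = w)
    }
    off <- matrix(FALSE, n_off, L)
    for (i in seq_len(n_off)) {
      p1 <- pop[parents[2 * i - 1], ]; p2 <- pop[parents[2 * i], ]
      ch <- p1
      if (stats::runif(1) < cfg$p_crossover) {
        if (cfg$crossover == "uniform") {
          sw <- stats::runif(L) < 0.5
          ch[sw] <- p2[sw]
        } else {
          pts <- sort(sample.int(L, 2))
          idx <- pts[1]:pts[2]
          ch[idx] <- p2[idx]
        }
      }
      if (stats::runif(1) < cfg$p_mutation) {
        if (cfg$mutation == "bitflip") {
          fl <- stats::runif(L) < indpb
          ch[fl] <- !ch[fl]
        } else {
          # gaussian: perturb the 0/1 vector and re-threshold at 0.5
          ch <- (as.numeric(ch) + stats::rnorm(L, 0, 0.5)) > 0.5
        }
      }
      off[i, ] <- ch
    }
    pop <- rbind(elites, off)
    fit <- eval_pop(pop, gen)
    gi <- which.max(fit)
    if (fit[gi] > best_fit) {
      best_fit <- fit[gi]; best_mask <- pop[gi, ]; stall <- 0L
    } else stall <- stall + 1L
    hist <- rbind(hist, data.frame(generation = gen, best = best_fit,
                                   mean = mean(fit[is.finite(fit)]),
                                   n_selected = sum(best_mask)))
    if (stall >= cfg$convergence_window) break
  }
  structure(list(best_mask = best_mask, best_fitness = best_fit,
                 features = dm_names[best_mask], history = hist, cfg = cfg),
            class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("<ga_result> %d features selected, fitness %.3f after %d generations\n",
              sum(x$best_mask), x$best_fitness, max(x$history$generation)))
  cat("  features:", paste(x$features, collapse = ", "), "\n")
  invisible(x)
}

#' Exhaustive small-subset search (reference for the GA)
#'
#' Evaluates every 1- and 2-feature mask with the same fitness definition
#' and fold seed, returning the best. Tractable only for modest feature
#' counts; used to verify that the GA's selection is the cross-validation
#' optimum among small subsets.
#'
#' @inheritParams ga_fitness
#' @param max_size largest subset size to enumerate (default 2).
#' @return list with `best_cols`, `best_fitness`.
#' @export
exhaustive_subset_search <- function(X, y, cfg = ga_config(), max_size = 2,
                                     seed = 1) {
  if (inherits(X, "descriptor_matrix")) X <- X$values
  L <- ncol(X); logy <- log(y)
  best <- -Inf; best_cols <- integer(0)
  score <- function(cols)
    -.cv_mape(X, logy, y, cols, cfg$cv_folds, seed) - cfg$lambda * length(cols)
  for (j in seq_len(L)) {
    s <- score(j)
    if (s > best) { best <- s; best_cols <- j }
  }
  if (max_size >= 2) {
    for (j in seq_len(L - 1)) for (k in (j + 1):L) {
      s <- score(c(j, k))
      if (s > best) { best <- s; best_cols <- c(j, k) }
    }
  }
  list(best_cols = best_cols, best_fitness = best)
}
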