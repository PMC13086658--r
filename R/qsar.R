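#' Fit the linear BMD model on log scale
#'
#' Ordinary least squares of `log(BMD)` on the selected standardized
#' descriptors. The natural logarithm compresses the response range and
#' keeps back-transformed predictions strictly positive; all reported
#' performance metrics are computed on the original uM scale after
#' exponentiating predictions. The fitted object stores everything needed
#' for screening: coefficients, the feature scaler, and a snapshot of the
#' training design matrix for applicability-domain assessment.
#'
#' @param X standardized [descriptor_matrix()] (or plain matrix) restricted
#'   to the selected features, rows = training compounds.
#' @param y observed BMD values (uM, positive).
#' @param scaler optional per-feature (feature, mean, sd) table; taken from
#'   `X` when it is a [descriptor_matrix()].
#' @param feature_kind optional per-feature kind vector (binary/continuous).
#' @param ecfp_bits circular-fingerprint length the features were computed
#'   with (stored so screening featurizes identically).
#' @return object of class `qsar_model`.
#' @export
qsar_fit <- function(X, y, scaler = NULL, feature_kind = NULL,
                     ecfp_bits = 2048) {
  if (inherits(X, "descriptor_matrix")) {
    if (is.null(scaler) && !is.null(X$scaler))
      scaler <- X$scaler[X$scaler$feature %in% X$feature_names, ]
    if (is.null(feature_kind)) feature_kind <- X$feature_kind
    X <- X$values
  }
  stopifnot(is.matrix(X), all(y > 0), length(y) == nrow(X),
            nrow(X) >= ncol(X) + 2)
  A <- cbind(`(Intercept)` = 1, X)
  fit <- stats::lm.fit(A, log(y))
  if (fit$rank < ncol(A)) stop("rank-deficient design matrix")
  beta <- fit$coefficients
  structure(list(feature_names = colnames(X),
                 coefficients = beta[-1], intercept = unname(beta[1]),
                 scaler = scaler, feature_kind = feature_kind,
                 X_train = X, y_train = y, ecfp_bits = ecfp_bits,
                 residuals_log = fit$residuals),
            class = "qsar_model")
}

#' @export
coef.qsar_model <- function(object, ...) {
  c(`(Intercept)` = object$intercept, object$coefficients)
}

#' @export
residuals.qsar_model <- function(object, ...) object$residuals_log

#' Predict benchmark doses for new standardized feature rows
#'
#' @param object a [qsar_model()].
#' @param newdata matrix (or [descriptor_matrix()]) with the model's feature
#'   columns, already on the training standardization scale; default the
#'   training snapshot.
#' @param ... unused.
#' @return predicted BMD vector (uM, strictly positive).
#' @export
predict.qsar_model <- function(object, newdata = NULL, ...) {
  X <- if (is.null(newdata)) object$X_train else
    if (inherits(newdata, "descriptor_matrix")) newdata$values else newdata
  if (is.null(dim(X))) X <- matrix(X, nrow = 1,
                                   dimnames = list(NULL, names(X)))
  if (!is.null(colnames(X))) {
    miss <- setdiff(object$feature_names, colnames(X))
    if (length(miss))
      stop("feature mismatch: missing ", paste(miss, collapse = ", "))
    X <- X[, object$feature_names, drop = FALSE]
  } else if (ncol(X) != length(object$feature_names)) {
    stop("feature mismatch: expected ", length(object$feature_names),
         " columns")
  }
  # row-wise accumulation: results do not depend on how rows are batched
  eta <- object$intercept + rowSums(sweep(X, 2, object$coefficients, "*"))
  as.vector(exp(eta))
}

.fit_metrics <- function(obs, pred, context) {
  err <- pred - obs
  data.frame(context = context,
             r2 = 1 - sum(err^2) / sum((obs - mean(obs))^2),
             mae = mean(abs(err)), rmse = sqrt(mean(err^2)))
}

#' Goodness-of-fit metrics on the original scale
#'
#' R squared (1 - SS_res/SS_tot, may be negative), mean absolute error and
#' root mean squared error, all in uM on back-transformed predictions.
#'
#' @param model a [qsar_model()].
#' @return one-row data frame (context `"training"`).
#' @export
training_metrics <- function(model) {
  .fit_metrics(model$y_train, predict(model), "training")
}

#' Cross-validated evaluation of the linear BMD model
#'
#' Each compound is predicted exactly once, from the fold model that did not
#' train on it; metrics are computed on the back-transformed uM scale. The
#' fold assignment is drawn once from `seed` (distinct, by convention, from
#' the re-randomized folds inside the genetic algorithm).
#'
#' @param X standardized feature matrix or [descriptor_matrix()] (selected
#'   features).
#' @param y observed BMD values (uM).
#' @param folds number of folds (default 5).
#' @param seed fold-assignment seed.
#' @return list with `metrics` (context `"cv"`) and `details`
#'   (per-compound observed, predicted, fold).
#' @export
evaluate_cv <- function(X, y, folds = 5, seed = 1) {
  if (inherits(X, "descriptor_matrix")) X <- X$values
  n <- length(y)
  stopifnot(n >= folds, all(y > 0))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fold <- sample(rep(seq_len(folds), length.out = n))
  pred <- numeric(n)
  logy <- log(y)
  for (f in seq_len(folds)) {
    te <- fold == f
    if (sum(!te) < 2) stop("fold with fewer than 2 training rows")
    A <- cbind(1, X[!te, , drop = FALSE])
    b <- stats::lm.fit(A, logy[!te])$coefficients
    b[is.na(b)] <- 0
    pred[te] <- exp(cbind(1, X[te, , drop = FALSE]) %*% b)
  }
  list(metrics = .fit_metrics(y, pred, "cv"),
       details = data.frame(observed = y, predicted = pred, fold = fold))
}

#' y-randomization test
#'
#' Refits and cross-validates the model `repeats` times after randomly
#' permuting the response, establishing the chance-correlation baseline: a
#' real structure-activity relationship should collapse (cross-validated R
#' squared far below the unpermuted value, typically negative) when the
#' link between structure and response is destroyed. Each permutation
#' preserves the multiset of observed BMDs.
#'
#' @inheritParams evaluate_cv
#' @param repeats number of permutations (default 20).
#' @return list with `mean_metrics` (context `"y_randomization"`),
#'   `per_repeat`, and the unpermuted `reference` cv metrics.
#' @export
y_randomize <- function(X, y, repeats = 20, folds = 5, seed = 1) {
  if (inherits(X, "descriptor_matrix")) X <- X$values
  stopifnot(repeats >= 1)
  ref <- evaluate_cv(X, y, folds, seed)$metrics
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  per <- vector("list", repeats)
  perms <- matrix(NA_real_, repeats, length(y))
  for (r in seq_len(repeats)) {
    set.seed(seed + 1000 * r)
    yp <- sample(y)
    perms[r, ] <- yp
    m <- evaluate_cv(X, yp, folds, seed + r)$metrics
    m$context <- "y_randomization"
    per[[r]] <- m
  }
  per <- do.call(rbind, per)
  mean_m <- data.frame(context = "y_randomization", r2 = mean(per$r2),
                       mae = mean(per$mae), rmse = mean(per$rmse))
  list(mean_metrics = mean_m, per_repeat = per, reference = ref,
       permutations = perms)
}

#' @export
print.qsar_model <- function(x, ...) {
  cat(sprintf("<qsar_model> %d features, n = %d training compounds\n",
              length(x$feature_names), nrow(x$X_train)))
  m <- training_metrics(x)
  cat(sprintf("  training R2 %.3f, MAE %.3g uM, RMSE %.3g uM\n",
              m$r2, m$mae, m$rmse))
  invisible(x)
}

#' @export
summary.qsar_model <- function(object, ...) {
  print(object)
  co <- coef(object)
  cat("  coefficients (standardized log-uM scale):\n")
  for (i in seq_along(co))
    cat(sprintf("    %-24s %+8.4f\n", names(co)[i], co[i]))
  invisible(object)
}

#' @export
plot.qsar_model <- function(x, ...) {
  obs <- x$y_train; pred <- predict(x)
  lim <- range(c(obs, pred))
  plot(obs, pred, xlim = lim, ylim = lim, xlab = "observed BMD (uM)",
       ylab = "predicted BMD (uM)", ...)
  abline(0, 1, lty = 2)
  invisible(x)
}

#' Serialize / restore a fitted model as a single JSON artifact
#'
#' @param model a [qsar_model()].
#' @param path JSON file path.
#' @export
write_qsar_model <- function(model, path) {
  obj <- list(feature_names = model$feature_names,
              coefficients = as.list(model$coefficients),
              intercept = model$intercept,
              scaler = model$scaler,
              feature_kind = as.list(stats::setNames(
                model$feature_kind %||% rep("continuous",
                                            length(model$feature_names)),
                model$feature_names)),
              ecfp_bits = model$ecfp_bits,
              X_train = unname(model$X_train),
              y_train = model$y_train)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname write_qsar_model
#' @export
read_qsar_model <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  Xt <- as.matrix(o$X_train)
  colnames(Xt) <- o$feature_names
  structure(list(feature_names = o$feature_names,
                 coefficients = stats::setNames(unlist(o$coefficients),
                                                o$feature_names),
                 intercept = o$intercept,
                 scaler = as.data.frame(o$scaler),
                 feature_kind = unlist(o$feature_kind),
                 X_train = Xt, y_train = o$y_train,
                 ecfp_bits = o$ecfp_bits,
                 residuals_log = NULL),
            class = "qsar_model")
}
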