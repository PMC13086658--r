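#' Bounding-box applicability check
#'
#' A query row is inside the bounding box when every feature value lies
#' within the closed interval `[min, max]` observed for that feature in the
#' training design matrix. Checked on the standardized selected features —
#' under affine z-scoring this is equivalent to raw-scale bounds.
#'
#' @param x_row numeric vector (one compound) or matrix (one row per
#'   compound), same columns as `X_train`.
#' @param X_train training design matrix (selected features).
#' @return logical vector, one verdict per query row.
#' @export
bounding_box <- function(x_row, X_train) {
  X <- if (is.null(dim(x_row))) matrix(x_row, nrow = 1) else x_row
  if (ncol(X) != ncol(X_train)) stop("feature mismatch")
  lo <- apply(X_train, 2, min); hi <- apply(X_train, 2, max)
  apply(X, 1, function(r) all(is.finite(r)) && all(r >= lo) && all(r <= hi))
}

#' Leverage of query rows with respect to a training design
#'
#' `h_i = x_i' (X'X)^{-1} x_i`, the diagonal of the hat matrix extended to
#' query points: the squared Mahalanobis-type distance of a compound from
#' the training centroid in descriptor space. Computed on the standardized
#' selected features without an intercept column. When `X'X` is singular the
#' Moore-Penrose pseudo-inverse is used with a warning.
#'
#' @inheritParams bounding_box
#' @return numeric leverage vector (`>= 0`).
#' @export
leverage <- function(x_row, X_train) {
  X <- if (is.null(dim(x_row))) matrix(x_row, nrow = 1) else x_row
  if (ncol(X) != ncol(X_train)) stop("feature mismatch")
  G <- crossprod(X_train)
  Gi <- tryCatch(chol2inv(chol(G)), error = function(e) {
    warning("singular X'X; using pseudo-inverse")
    MASS::ginv(G)
  })
  # per-row quadratic form (independent of how query rows are batched)
  apply(X, 1, function(r) sum(as.vector(Gi %*% r) * r))
}

#' Critical leverage threshold
#'
#' `h* = 3 (p + 1) / n`, with `p` the number of descriptors in the design
#' matrix and `n` the number of training compounds.
#'
#' @param p selected-feature count.
#' @param n training-set size.
#' @return scalar threshold.
#' @export
critical_leverage <- function(p, n) {
  stopifnot(n > 0, p >= 0)
  3 * (p + 1) / n
}

#' Composite applicability-domain assessment
#'
#' A compound is inside the applicability domain only when it passes both
#' the bounding-box and the leverage criterion (`h <= h*`); the verdict
#' carries all intermediate values for audit. Rows with non-finite feature
#' values are out of domain with a reason code.
#'
#' @param x_rows matrix of standardized selected-feature rows (or a single
#'   row vector).
#' @param model a [qsar_model()].
#' @param ids optional compound labels.
#' @return data frame: `compound_id`, `in_bbox`, `h`, `h_star`,
#'   `in_leverage`, `in_domain`, `reason`.
#' @export
ad_assess <- function(x_rows, model, ids = NULL) {
  X <- if (is.null(dim(x_rows))) matrix(x_rows, nrow = 1,
                                        dimnames = list(NULL, names(x_rows)))
       else x_rows
  if (!is.null(colnames(X))) X <- X[, model$feature_names, drop = FALSE]
  if (is.null(ids)) ids <- rownames(X) %||% sprintf("q%d", seq_len(nrow(X)))
  hstar <- critical_leverage(ncol(model$X_train), nrow(model$X_train))
  finite <- apply(X, 1, function(r) all(is.finite(r)))
  Xf <- X; Xf[!finite, ] <- 0  # placeholder; overridden below
  bb <- bounding_box(Xf, model$X_train)
  h <- leverage(Xf, model$X_train)
  bb[!finite] <- FALSE
  h[!finite] <- NA_real_
  in_lev <- !is.na(h) & h <= hstar
  data.frame(compound_id = ids, in_bbox = bb, h = h, h_star = hstar,
             in_leverage = in_lev, in_domain = bb & in_lev,
             reason = ifelse(!finite, "non-finite descriptor",
                        ifelse(!bb & !in_lev, "bbox+leverage",
                          ifelse(!bb, "bbox",
                            ifelse(!in_lev, "leverage", "")))))
}
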