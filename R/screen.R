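#' Batch screening of a compound list with a trained QSAR model
#'
#' For every compound: featurize the SMILES with the same descriptor
#' pipeline the model was trained with, project the selected features onto
#' the stored training standardization, predict the BMD, and assess the
#' composite applicability domain. Unparseable SMILES yield a record with a
#' failure reason instead of halting the screen; out-of-domain compounds
#' retain their prediction but are flagged. Because hashed
#' extended-connectivity bits can collide (two substructures activating the
#' same bit), records whose prediction is lowered by a set fingerprint bit
#' with a negative coefficient carry a `collision_check` flag prompting
#' substructure verification before a low BMD is trusted.
#'
#' @param compounds data frame with columns `id` and `smiles`.
#' @param model a [qsar_model()] whose scaler covers the selected features.
#' @param batch_size compounds featurized per chunk (memory stays bounded in
#'   the batch size; results are identical to all-at-once processing).
#' @return object of class `screen_result`: `records` (one row per input
#'   id, in input order) and `summary` (counts and the median in-domain
#'   predicted BMD).
#' @export
screen_compounds <- function(compounds, model, batch_size = 500) {
  stopifnot(all(c("id", "smiles") %in% names(compounds)),
            inherits(model, "qsar_model"), !is.null(model$scaler))
  n <- nrow(compounds)
  recs <- vector("list", max(1, ceiling(n / batch_size)))
  if (n > 0) {
    starts <- seq(1, n, by = batch_size)
    for (bi in seq_along(starts)) {
      idx <- starts[bi]:min(starts[bi] + batch_size - 1, n)
      recs[[bi]] <- .screen_batch(compounds[idx, , drop = FALSE], model)
    }
  }
  records <- do.call(rbind, recs)
  if (is.null(records))
    records <- data.frame(id = character(0), smiles = character(0),
                          predicted_bmd = numeric(0), in_bbox = logical(0),
                          h = numeric(0), h_star = numeric(0),
                          in_domain = logical(0),
                          collision_check = logical(0),
                          failure_reason = character(0))
  ind <- records$in_domain %in% TRUE
  summary <- list(n = nrow(records),
                  n_failed = sum(!is.na(records$failure_reason) &
                                   records$failure_reason != ""),
                  n_in_domain = sum(ind),
                  median_bmd_in_domain = if (any(ind))
                    stats::median(records$predicted_bmd[ind]) else NA_real_)
  structure(list(records = records, summary = summary, model = model),
            class = "screen_result")
}

.screen_batch <- function(compounds, model) {
  dm <- suppressMessages(featurize(compounds, ecfp_bits = model$ecfp_bits))
  ok_ids <- dm$ids
  Xs <- .project_features(dm$values, model$scaler)
  pred <- predict(model, Xs)
  ad <- ad_assess(Xs, model, ids = ok_ids)
  # collision audit: prediction pulled down by a set fingerprint bit
  fp <- grepl("^(ecfp|maccs):", model$feature_names) &
    model$coefficients < 0
  coll <- if (any(fp)) {
    rowSums(Xs[, model$feature_names[fp], drop = FALSE] > 0) > 0
  } else rep(FALSE, length(ok_ids))
  found <- match(compounds$id, ok_ids)
  data.frame(id = compounds$id, smiles = compounds$smiles,
             predicted_bmd = pred[found],
             in_bbox = ad$in_bbox[found], h = ad$h[found],
             h_star = if (nrow(ad)) ad$h_star[1] else NA_real_,
             in_domain = ad$in_domain[found],
             collision_check = coll[found] & ad$in_domain[found],
             failure_reason = ifelse(is.na(found), "unparseable SMILES", ""),
             row.names = NULL)
}

#' Top-ranked screening hits
#'
#' The `k` in-domain records with the lowest predicted BMD (highest
#' predicted potency), ties broken deterministically by id; out-of-domain
#' and failed records are excluded.
#'
#' @param x a `screen_result` or its `records` data frame.
#' @param k number of hits (default 10).
#' @return data frame of at most `k` rows, most potent first.
#' @export
top_k <- function(x, k = 10) {
  records <- if (inherits(x, "screen_result")) x$records else x
  ind <- records[records$in_domain %in% TRUE, , drop = FALSE]
  ind <- ind[order(ind$predicted_bmd, ind$id), , drop = FALSE]
  utils::head(ind, k)
}

#' @export
print.screen_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<screen_result> %d compounds: %d in domain (%.1f%%), %d failed\n",
              s$n, s$n_in_domain,
              if (s$n > 0) 100 * s$n_in_domain / s$n else 0, s$n_failed))
  if (!is.na(s$median_bmd_in_domain))
    cat(sprintf("  median in-domain predicted BMD: %.3g uM\n",
                s$median_bmd_in_domain))
  invisible(x)
}

#' Read a screening list
#'
#' Accepts a CSV with `id` and `smiles` columns, or a plain SMILES file (one
#' SMILES per line, optional tab-separated id).
#'
#' @param path input file.
#' @return data frame with columns `id`, `smiles`.
#' @export
read_screening_list <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl(",", first) && grepl("smiles", tolower(first))) {
    df <- utils::read.csv(path)
    names(df) <- tolower(names(df))
    data.frame(id = as.character(df$id), smiles = df$smiles)
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "\t")
    data.frame(id = vapply(seq_along(parts), function(i)
                 if (length(parts[[i]]) > 1) parts[[i]][2] else
                   sprintf("s%d", i), character(1)),
               smiles = vapply(parts, `[[`, character(1), 1))
  }
}
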