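#' Dose-response set container
#'
#' A light data-frame subclass holding one compound's fold-induction records.
#' Concentration 0 is reserved for solvent-control wells; all other
#' concentrations are positive and expressed in uM.
#'
#' @param records data frame with columns `compound_id`, `concentration`,
#'   `bio_rep`, `tech_rep`, `response`.
#' @param top_concentration highest tested concentration (defaults to the
#'   maximum present).
#' @param truth optional list of generating parameters (set by the simulator).
#' @return object of classes `dose_response_set` and `data.frame`.
#' @export
dose_response_set <- function(records, top_concentration = NULL, truth = NULL) {
  need <- c("compound_id", "concentration", "bio_rep", "tech_rep", "response")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  stopifnot(all(records$concentration >= 0))
  if (is.null(top_concentration))
    top_concentration <- suppressWarnings(max(records$concentration))
  out <- as.data.frame(records)[, need]
  attr(out, "top_concentration") <- top_concentration
  attr(out, "truth") <- truth
  class(out) <- c("dose_response_set", "data.frame")
  out
}

#' @export
print.dose_response_set <- function(x, ...) {
  nd <- length(unique(x$concentration[x$concentration > 0]))
  cat(sprintf("<dose_response_set> %s: %d records, %d dose levels, top %g uM\n",
              x$compound_id[1], nrow(x), nd, attr(x, "top_concentration")))
  invisible(x)
}

#' Normalize dual-luciferase readings to fold induction
#'
#' Divides each well's firefly/renilla luminescence ratio by the mean
#' solvent-control ratio of the same biological replicate (each plate carries
#' its own solvent controls), so solvent-control wells average to 1 within
#' each replicate and treated wells are expressed as fold induction over
#' control.
#'
#' @param raw data frame with columns `concentration` (0 for solvent-control
#'   wells), `bio_rep`, `tech_rep`, `fluc`, `rluc`, and optionally
#'   `compound_id`.
#' @return a [dose_response_set()] including the solvent-control rows.
#' @export
normalize_reporter <- function(raw) {
  need <- c("concentration", "bio_rep", "tech_rep", "fluc", "rluc")
  if (!all(need %in% names(raw)))
    stop("raw table must have columns: ", paste(need, collapse = ", "))
  if (any(raw$rluc <= 0)) stop("non-positive renilla (RLuc) luminescence")
  if (!any(raw$concentration == 0))
    stop("no solvent-control wells (concentration == 0)")
  id <- if ("compound_id" %in% names(raw)) raw$compound_id[1] else "compound"
  ratio <- raw$fluc / raw$rluc
  sc <- raw$concentration == 0
  sc_mean <- tapply(ratio[sc], raw$bio_rep[sc], mean)
  missing_rep <- setdiff(unique(raw$bio_rep), names(sc_mean))
  if (length(missing_rep))
    stop("biological replicate(s) without solvent-control wells: ",
         paste(missing_rep, collapse = ", "))
  resp <- ratio / as.numeric(sc_mean[as.character(raw$bio_rep)])
  dose_response_set(data.frame(
    compound_id = id, concentration = raw$concentration,
    bio_rep = raw$bio_rep, tech_rep = raw$tech_rep, response = resp),
    top_concentration = max(raw$concentration))
}

#' Highest non-cytotoxic concentration
#'
#' Applies the two-part cytotoxicity rule to a viability profile: a tested
#' concentration is cytotoxic when its mean viability is below
#' `abs_threshold` percent of the untreated control, or when it falls at
#' least `drop_threshold` below the viability at the next smaller tested
#' concentration. The drop is measured in absolute percentage points by
#' default (`drop_rule = "points"`); `"relative"` measures it as a percentage
#' of the preceding value. Once any concentration is cytotoxic, all higher
#' concentrations are treated as cytotoxic, so the returned value is the
#' largest concentration below the first cytotoxic one, or `NA` if already
#' the lowest tested concentration is cytotoxic.
#'
#' @param concentrations ascending tested concentrations (uM).
#' @param viability mean viability (percent of control) per concentration.
#' @param abs_threshold absolute viability threshold (default 80).
#' @param drop_threshold drop threshold (default 10).
#' @param drop_rule `"points"` (default) or `"relative"`.
#' @return highest non-cytotoxic concentration, or `NA_real_`.
#' @export
highest_noncytotoxic <- function(concentrations, viability,
                                 abs_threshold = 80, drop_threshold = 10,
                                 drop_rule = c("points", "relative")) {
  drop_rule <- match.arg(drop_rule)
  stopifnot(length(concentrations) == length(viability),
            length(concentrations) >= 1, all(viability >= 0))
  if (is.unsorted(concentrations, strictly = TRUE))
    stop("concentrations must be strictly ascending")
  drop <- c(0, -diff(viability))
  rel <- if (drop_rule == "points") drop else
    100 * drop / c(Inf, viability[-length(viability)])
  cyto <- viability < abs_threshold | rel >= drop_threshold
  if (!any(cyto)) return(concentrations[length(concentrations)])
  first <- which(cyto)[1]
  if (first == 1) NA_real_ else concentrations[first - 1]
}

#' Truncate a dose-response set at the highest non-cytotoxic concentration
#'
#' Removes all records above the cytotoxicity cutoff; solvent-control rows
#' (concentration 0) are always retained. If the cutoff is `NA` (already the
#' lowest tested concentration was cytotoxic) an empty set is returned with
#' a warning.
#'
#' @param drs a [dose_response_set()].
#' @param cutoff concentration in uM (e.g. from [highest_noncytotoxic()]),
#'   or `NA`.
#' @param compound_id optional label to check against `drs` (error on
#'   mismatch).
#' @return truncated [dose_response_set()].
#' @export
truncate_to_noncytotoxic <- function(drs, cutoff, compound_id = NULL) {
  stopifnot(inherits(drs, "dose_response_set"))
  if (!is.null(compound_id) && !identical(compound_id, drs$compound_id[1]))
    stop("compound mismatch: viability profile is for ", compound_id,
         ", dose-response set for ", drs$compound_id[1])
  if (is.na(cutoff)) {
    warning("lowest tested concentration already cytotoxic; returning empty set")
    keep <- drs$concentration < 0  # none
  } else {
    keep <- drs$concentration <= cutoff
  }
  dose_response_set(drs[keep, , drop = FALSE],
                    top_concentration = if (is.na(cutoff)) NA_real_ else
                      min(cutoff, attr(drs, "top_concentration")),
                    truth = attr(drs, "truth"))
}

#' Read / write normalized dose-response tables
#'
#' Long CSV dialect: columns `compound_id, concentration, bio_rep, tech_rep,
#' response`.
#'
#' @param path CSV file path.
#' @return `read_dose_response()` returns a named list of
#'   [dose_response_set()] objects, one per compound.
#' @export
read_dose_response <- function(path) {
  df <- utils::read.csv(path)
  lapply(split(df, df$compound_id), dose_response_set)
}

#' @rdname read_dose_response
#' @param sets list of [dose_response_set()] objects (or a single one).
#' @export
write_dose_response <- function(sets, path) {
  if (inherits(sets, "dose_response_set")) sets <- list(sets)
  df <- do.call(rbind, lapply(sets, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
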