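#' Descriptor matrix container
#'
#' Compounds-by-features numeric matrix with per-feature provenance. Feature
#' names carry a block prefix: `maccs:` (166 substructure keys), `ecfp:`
#' (hashed circular fingerprint bits), `mordred:` (topological
#' autocorrelation descriptors) and `phys:` (physicochemical descriptors).
#' The `state` tracks the cleaning cascade: `raw` -> `cleaned` ->
#' `standardized`; once standardized, the per-feature training mean/sd are
#' stored in `scaler` so screening compounds can be projected consistently.
#'
#' @param values numeric matrix (compounds x features).
#' @param ids compound labels (rownames).
#' @param feature_names feature labels with block prefix (colnames).
#' @param feature_kind per-feature `"binary"` or `"continuous"`.
#' @param state `"raw"`, `"cleaned"` or `"standardized"`.
#' @param scaler optional data frame (feature, mean, sd).
#' @param manifest optional removal manifest (feature, reason).
#' @return object of class `descriptor_matrix`.
#' @export
descriptor_matrix <- function(values, ids, feature_names, feature_kind,
                              state = c("raw", "cleaned", "standardized"),
                              scaler = NULL, manifest = NULL) {
  state <- match.arg(state)
  stopifnot(nrow(values) == length(ids),
            ncol(values) == length(feature_names),
            ncol(values) == length(feature_kind),
            all(feature_kind %in% c("binary", "continuous")))
  dimnames(values) <- list(ids, feature_names)
  structure(list(values = values, ids = ids, feature_names = feature_names,
                 feature_kind = feature_kind, state = state,
                 scaler = scaler, manifest = manifest),
            class = "descriptor_matrix")
}

#' @export
print.descriptor_matrix <- function(x, ...) {
  blocks <- table(sub(":.*", "", x$feature_names))
  cat(sprintf("<descriptor_matrix> %d compounds x %d features (%s)\n",
              nrow(x$values), ncol(x$values), x$state))
  cat("  blocks:", paste(sprintf("%s=%d", names(blocks), blocks),
                         collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.descriptor_matrix <- function(x) dim(x$values)

# ---- molecular graph utilities -------------------------------------------

# principal quantum valence electrons per element
.VALENCE_E <- c(H = 1, B = 3, C = 4, N = 5, O = 6, F = 7, Si = 4, P = 5,
                S = 6, Cl = 7, Br = 7, I = 7, Na = 1, K = 1, Li = 1, Ca = 2,
                Mg = 2)
# atomic polarizabilities (A^3), standard tabulated values
.POLARIZ <- c(H = 0.666793, B = 3.03, C = 1.76, N = 1.10, O = 0.802,
              F = 0.557, Si = 5.38, P = 3.63, S = 2.90, Cl = 2.18,
              Br = 3.05, I = 5.35, Na = 24.08, K = 43.4, Li = 24.33,
              Ca = 22.8, Mg = 10.6)
.ATMASS <- c(H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
             F = 18.998, Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45,
             Br = 79.904, I = 126.904, Na = 22.99, K = 39.098, Li = 6.94,
             Ca = 40.078, Mg = 24.305)
.ATNUM <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15,
            S = 16, Cl = 17, Br = 35, I = 53, Na = 11, K = 19, Li = 3,
            Ca = 20, Mg = 12)

# Parse one SMILES into the heavy-atom graph with per-atom weights.
# Gasteiger partial charges come from an OpenBabel MOL2 conversion of the
# same SMILES (atom order is preserved by OpenBabel).
.mol_graph <- function(smiles) {
  sdf <- ChemmineR::smiles2sdf(smiles)[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elem <- gsub("_.*", "", rownames(ab))
  n <- length(elem)
  edges <- if (n > 1 && nrow(bb) > 0) cbind(bb[, 1], bb[, 2]) else
    matrix(0L, 0, 2)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  D <- igraph::distances(g)
  deg <- igraph::degree(g)
  # implicit hydrogen count from standard valences
  std_val <- c(C = 4, N = 3, O = 2, S = 2, F = 1, Cl = 1, Br = 1, I = 1,
               P = 3, B = 3, Si = 4)
  bond_order <- if (nrow(edges)) as.numeric(bb[, 3]) else numeric(0)
  valsum <- numeric(n)
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      bo <- min(bond_order[k], 3)
      valsum[edges[k, 1]] <- valsum[edges[k, 1]] + bo
      valsum[edges[k, 2]] <- valsum[edges[k, 2]] + bo
    }
  }
  nH <- pmax(ifelse(elem %in% names(std_val), std_val[elem] - valsum, 0), 0)
  # Gasteiger charges via MOL2 (heavy atoms, same order)
  chg <- rep(0, n)
  m2 <- try(ChemmineOB::convertFormat("SMI", "MOL2",
                                      paste0(smiles, "\tmol\n")),
            silent = TRUE)
  if (!inherits(m2, "try-error")) {
    lines <- strsplit(m2, "\n")[[1]]
    a0 <- which(lines == "@<TRIPOS>ATOM")
    if (length(a0) == 1) {
      rows <- lines[(a0 + 1):length(lines)]
      rows <- rows[seq_len(min(n, sum(!grepl("^@", rows))))]
      rows <- rows[!grepl("^@", rows)]
      ch <- suppressWarnings(as.numeric(vapply(strsplit(trimws(rows), "\\s+"),
                                               function(f) f[length(f)],
                                               character(1))))
      if (length(ch) == n && all(is.finite(ch))) chg <- ch
    }
  }
  lk <- function(tab, el) ifelse(el %in% names(tab), tab[el], mean(tab))
  list(n = n, elem = elem, D = D, nH = nH,
       weights = list(
         dv = as.numeric(lk(.VALENCE_E, elem)) - nH,  # valence electrons less bonded H
         c  = chg,
         p  = as.numeric(lk(.POLARIZ, elem)) + nH * .POLARIZ[["H"]],
         m  = as.numeric(lk(.ATMASS, elem)) + nH * .ATMASS[["H"]],
         Z  = as.numeric(lk(.ATNUM, elem))))
}

# Topological autocorrelation descriptors on the heavy-atom graph.
# For property vector w and topological distance k:
#   ATS_k  = sum over unordered pairs at distance k of w_i * w_j
#   AATS_k = ATS_k / (number of such pairs)
#   ATSC_k = ATS_k computed on the centred property (w - mean(w))
#   GATS_k = Geary coefficient:
#            [sum_{d(i,j)=k} (w_i - w_j)^2 / (2 n_k)] / [var(w) * (n-1)/(n-1)]
# Lags 1..8; undefined values (no pair at that lag, zero variance) are NaN
# and are removed later by the cleaning cascade.
.autocorr_block <- function(gr, lags = 1:8) {
  out <- c(); nm <- c()
  n <- gr$n
  for (wname in names(gr$weights)) {
    w <- gr$weights[[wname]]
    wc <- w - mean(w)
    varw <- sum(wc^2) / max(n - 1, 1)
    for (k in lags) {
      pair <- which(gr$D == k & upper.tri(gr$D), arr.ind = TRUE)
      nk <- nrow(pair)
      ats <- if (nk) sum(w[pair[, 1]] * w[pair[, 2]]) else NaN
      aats <- if (nk) ats / nk else NaN
      atsc <- if (nk) sum(wc[pair[, 1]] * wc[pair[, 2]]) else NaN
      gats <- if (nk && varw > 0)
        (sum((w[pair[, 1]] - w[pair[, 2]])^2) / (2 * nk)) / varw else NaN
      out <- c(out, ats, aats, atsc, gats)
      nm <- c(nm, sprintf(c("ATS%d%s", "AATS%d%s", "ATSC%d%s", "GATS%d%s"),
                          k, wname))
    }
  }
  names(out) <- nm
  out
}

#' Compute the four descriptor blocks from SMILES
#'
#' Per compound: the 166 MACCS substructure keys, hashed extended-connectivity
#' fingerprint bits at atomic neighbourhood radius 3 (4096 native bits folded
#' by OR to `ecfp_bits`), topological autocorrelation descriptors
#' (Broto-Moreau ATS/AATS/ATSC and Geary GATS at lags 1-8, weighted by
#' valence electrons, Gasteiger partial charge, polarizability, mass and
#' atomic number), and a physicochemical block (TPSA, logP, molar
#' refractivity, molecular weight, H-bond donor/acceptor counts, fluorine
#' count). SMILES are used exactly as supplied (salt forms are not
#' neutralized). Unparseable SMILES are excluded and reported in the
#' `failures` attribute.
#'
#' @param compounds data frame with columns `id` and `smiles`.
#' @param ecfp_bits folded circular-fingerprint length (default 2048).
#' @return a raw-state [descriptor_matrix()]; attribute `failures` lists
#'   excluded compounds.
#' @export
featurize <- function(compounds, ecfp_bits = 2048) {
  stopifnot(all(c("id", "smiles") %in% names(compounds)))
  n_in <- nrow(compounds)
  rows <- vector("list", n_in)
  failures <- character(0)
  for (i in seq_len(n_in)) {
    smi <- compounds$smiles[i]
    row <- try(.featurize_one(smi, ecfp_bits), silent = TRUE)
    if (inherits(row, "try-error") || anyNA(row[["maccs"]])) {
      failures <- c(failures, compounds$id[i])
      message("featurize: skipping unparseable SMILES for ", compounds$id[i])
    } else rows[[i]] <- row
  }
  keep <- !vapply(rows, is.null, logical(1))
  if (!any(keep)) stop("no parseable SMILES")
  rows <- rows[keep]
  vals <- do.call(rbind, lapply(rows, function(r)
    c(r$maccs, r$ecfp, r$mordred, r$phys)))
  r1 <- rows[[1]]
  fn <- c(sprintf("maccs:K%d", seq_along(r1$maccs)),
          sprintf("ecfp:B%04d", seq_along(r1$ecfp)),
          paste0("mordred:", names(r1$mordred)),
          paste0("phys:", names(r1$phys)))
  kind <- rep(c("binary", "binary", "continuous", "continuous"),
              c(length(r1$maccs), length(r1$ecfp), length(r1$mordred),
                length(r1$phys)))
  dm <- descriptor_matrix(vals, ids = compounds$id[keep], feature_names = fn,
                          feature_kind = kind, state = "raw")
  attr(dm, "failures") <- failures
  dm
}

.featurize_one <- function(smiles, ecfp_bits) {
  sdf <- ChemmineR::smiles2sdf(smiles)
  maccs <- as.numeric(ChemmineR::as.matrix(
    ChemmineR::fingerprintOB(sdf, "MACCS"))[1, 1:166])
  e6 <- as.numeric(ChemmineR::as.matrix(
    ChemmineR::fingerprintOB(sdf, "ECFP6"))[1, ])
  fold <- length(e6) / ecfp_bits
  ecfp <- if (fold > 1) {
    m <- matrix(e6, nrow = ecfp_bits)
    as.numeric(rowSums(m) > 0)
  } else e6
  gr <- .mol_graph(smiles)
  mord <- .autocorr_block(gr)
  pr <- ChemmineR::propOB(sdf)
  phys <- c(TPSA = pr$TPSA[1], logP = pr$logP[1], MR = pr$MR[1],
            MW = pr$MW[1], HBA = pr$HBA2[1], HBD = pr$HBD[1], nF = pr$nF[1])
  list(maccs = maccs, ecfp = ecfp, mordred = mord, phys = phys)
}

#' Cleaning cascade for a raw descriptor matrix
#'
#' Applied in order: (1) drop columns containing any non-finite value;
#' (2) low-variance filter — drop columns whose variance is below `min_var`
#' or whose most frequent value covers at least `max_modal` of the rows;
#' (3) greedy correlation pruning — walk the remaining columns left to
#' right, keeping a column only if its absolute Pearson correlation with
#' every already-kept column is at most `corr_threshold` (the later member of
#' an offending pair is discarded). A removal manifest (feature, reason) is
#' recorded. Deterministic for a fixed input column order, and idempotent.
#'
#' @param dm a raw [descriptor_matrix()].
#' @param corr_threshold pairwise absolute-correlation ceiling (default 0.9).
#' @param min_var minimum variance (default 1e-8).
#' @param max_modal maximal modal-value frequency (default 0.95).
#' @return cleaned [descriptor_matrix()] with `manifest` filled.
#' @export
clean_descriptors <- function(dm, corr_threshold = 0.9, min_var = 1e-8,
                              max_modal = 0.95) {
  stopifnot(inherits(dm, "descriptor_matrix"), nrow(dm$values) >= 2)
  X <- dm$values
  reason <- character(0); feat <- character(0)
  note <- function(f, why) {
    feat <<- c(feat, f); reason <<- c(reason, why)
  }
  fin <- apply(X, 2, function(v) all(is.finite(v)))
  for (f in colnames(X)[!fin]) note(f, "non-finite")
  X <- X[, fin, drop = FALSE]
  v <- apply(X, 2, stats::var)
  modal <- apply(X, 2, function(col) max(table(col)) / length(col))
  lowvar <- v < min_var | modal >= max_modal
  for (f in colnames(X)[lowvar]) note(f, "low-variance")
  X <- X[, !lowvar, drop = FALSE]
  if (ncol(X) == 0) stop("all columns removed by cleaning")
  R <- abs(stats::cor(X))
  keep <- logical(ncol(X))
  for (j in seq_len(ncol(X))) {
    if (j == 1 || all(R[j, keep] <= corr_threshold, na.rm = TRUE)) {
      keep[j] <- TRUE
    } else note(colnames(X)[j], "correlated")
  }
  X <- X[, keep, drop = FALSE]
  kind <- dm$feature_kind[match(colnames(X), dm$feature_names)]
  manifest <- data.frame(feature = feat, reason = reason)
  descriptor_matrix(X, ids = dm$ids, feature_names = colnames(X),
                    feature_kind = kind, state = "cleaned",
                    manifest = manifest)
}

#' Standardize a cleaned descriptor matrix
#'
#' Continuous columns are z-scored with means and standard deviations
#' computed on the training rows; binary fingerprint bits are left on their
#' native 0/1 scale (recorded in the scaler with mean 0, sd 1). The scaler is
#' stored so screening compounds can be projected onto the training scale.
#'
#' @param dm a cleaned [descriptor_matrix()].
#' @param training_rows row indices used to estimate the scaler (default all).
#' @return standardized [descriptor_matrix()] with `scaler` filled.
#' @export
standardize_descriptors <- function(dm, training_rows = NULL) {
  stopifnot(inherits(dm, "descriptor_matrix"), dm$state == "cleaned")
  X <- dm$values
  tr <- if (is.null(training_rows)) seq_len(nrow(X)) else training_rows
  mu <- colMeans(X[tr, , drop = FALSE])
  sd <- apply(X[tr, , drop = FALSE], 2, stats::sd)
  cont <- dm$feature_kind == "continuous"
  if (any(cont & sd == 0))
    stop("zero-variance continuous column reached standardization: ",
         paste(colnames(X)[cont & sd == 0], collapse = ", "))
  mu[!cont] <- 0; sd[!cont] <- 1
  Xs <- sweep(sweep(X, 2, mu, "-"), 2, sd, "/")
  scaler <- data.frame(feature = colnames(X), mean = mu, sd = sd,
                       row.names = NULL)
  descriptor_matrix(Xs, ids = dm$ids, feature_names = dm$feature_names,
                    feature_kind = dm$feature_kind, state = "standardized",
                    scaler = scaler, manifest = dm$manifest)
}

# project new raw feature rows onto a stored scaler (selected features only)
.project_features <- function(raw_values, scaler) {
  miss <- setdiff(scaler$feature, colnames(raw_values))
  if (length(miss))
    stop("feature mismatch: missing ", paste(miss, collapse = ", "))
  X <- raw_values[, scaler$feature, drop = FALSE]
  sweep(sweep(X, 2, scaler$mean, "-"), 2, scaler$sd, "/")
}

#' Read / write descriptor matrices as CSV with a JSON sidecar
#'
#' The CSV holds ids in the first column and block-prefixed feature names in
#' the header; the sidecar (same path with extension `.json`) records the
#' feature kinds, state, scaler and removal manifest.
#'
#' @param dm a [descriptor_matrix()].
#' @param path CSV file path.
#' @export
write_descriptors <- function(dm, path) {
  df <- data.frame(id = dm$ids, dm$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  side <- list(feature_kind = as.list(stats::setNames(dm$feature_kind,
                                                      dm$feature_names)),
               state = dm$state, scaler = dm$scaler, manifest = dm$manifest)
  jsonlite::write_json(side, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_descriptors
#' @export
read_descriptors <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  side <- jsonlite::read_json(sub("\\.csv$", ".json", path),
                              simplifyVector = TRUE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  descriptor_matrix(vals, ids = df[[1]], feature_names = colnames(vals),
                    feature_kind = unlist(side$feature_kind)[colnames(vals)],
                    state = side$state,
                    scaler = if (!is.null(side$scaler))
                      as.data.frame(side$scaler) else NULL,
                    manifest = if (!is.null(side$manifest))
                      as.data.frame(side$manifest) else NULL)
}
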