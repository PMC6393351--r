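#' Fit a GC-MS calibration curve on internal-standard response ratios
#'
#' Ordinary least squares of the response ratio (analyte peak area divided by
#' internal-standard peak area) on the standard's known amount. The intercept
#' is free by default: forcing the line through the origin is stricter than
#' the data usually supports, and the choice is surfaced as an argument.
#'
#' @param standards Data frame with columns `concentration` (amount of
#'   analyte in the calibration vial, micrograms), `area` (analyte peak
#'   area) and `is_area` (internal-standard peak area, > 0).
#' @param compound Optional compound name to record on the curve.
#' @param through_origin Force a zero intercept (default `FALSE`).
#' @return Object of class `calibration_curve`: list with `compound`,
#'   `slope`, `intercept`, `r2`, `range` (concentration range fitted), `n`.
#' @export
fit_calibration <- function(standards, compound = NULL,
                            through_origin = FALSE) {
  .assert(is.data.frame(standards) &&
            all(c("concentration", "area", "is_area") %in% names(standards)),
          "standards needs columns concentration, area, is_area")
  .assert(nrow(standards) >= 2, "need at least 2 calibration points")
  .assert(all(standards$is_area > 0), "internal-standard areas must be > 0")
  .assert(all(standards$concentration >= 0), "concentrations must be >= 0")
  .assert(length(unique(standards$concentration)) >= 2,
          "all calibration concentrations are identical")

  ratio <- standards$area / standards$is_area
  conc <- standards$concentration
  fit <- if (through_origin) lm(ratio ~ 0 + conc) else lm(ratio ~ conc)
  cf <- coef(fit)
  slope <- unname(cf[["conc"]])
  intercept <- if (through_origin) 0 else unname(cf[["(Intercept)"]])
  ss_tot <- sum((ratio - mean(ratio))^2)
  r2 <- if (ss_tot == 0) NA_real_ else
    1 - sum(stats::resid(fit)^2) / ss_tot
  if (slope <= 0) {
    warning("calibration slope is not positive; curve is unusable for quantification")
  }
  structure(list(compound = compound, slope = slope, intercept = intercept,
                 r2 = r2, range = range(conc), n = nrow(standards)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("calibration_curve%s: ratio = %.4g * conc + %.4g (r2 = %.4f, n = %d, range %.3g-%.3g ug)\n",
              if (is.null(x$compound)) "" else paste0(" [", x$compound, "]"),
              x$slope, x$intercept, x$r2, x$n, x$range[1], x$range[2]))
  invisible(x)
}

#' Convert GC-MS peak areas to tissue concentrations
#'
#' Each peak area is normalized to the internal-standard area of its sample,
#' back-calculated through the compound's calibration curve (amount in the
#' extraction vial, micrograms) and divided by the tissue fresh weight to
#' give micrograms per gram fresh weight. Compounds without a dedicated
#' authentic-standard curve fall back to `fallback` (classically the
#' (+)-valencene curve) and are flagged `semi-quantitative`. Negative
#' back-calculated amounts (response ratio below the intercept) are clamped
#' to zero and flagged.
#'
#' @param peaks Data frame with columns `sample_id`, `compound`, `peak_area`,
#'   `is_area`, `tissue_mass` (grams fresh weight); any of `cultivar`,
#'   `stage`, `replicate` are carried through.
#' @param curves Named list of [fit_calibration()] curves, keyed by compound
#'   (matched case-insensitively).
#' @param fallback Optional `calibration_curve` used for compounds without a
#'   dedicated curve.
#' @return A tibble (the concentration table): sample metadata plus
#'   `compound`, `concentration` (ug/g FW), `mode`
#'   (`"standard"`/`"semi-quantitative"`) and `clamped`.
#' @export
quantify <- function(peaks, curves, fallback = NULL) {
  req <- c("sample_id", "compound", "peak_area", "is_area", "tissue_mass")
  .assert(is.data.frame(peaks) && all(req %in% names(peaks)),
          "peaks needs columns %s", paste(req, collapse = ", "))
  bad_is <- unique(peaks$sample_id[peaks$is_area <= 0])
  .assert(length(bad_is) == 0,
          "internal-standard area is not positive in sample(s): %s",
          paste(bad_is, collapse = ", "))
  .assert(all(peaks$peak_area >= 0), "peak areas must be >= 0")
  .assert(all(peaks$tissue_mass > 0), "tissue masses must be > 0")
  if (!is.null(fallback)) stopifnot(inherits(fallback, "calibration_curve"))
  stopifnot(is.list(curves))
  .assert(!is.null(names(curves)) || length(curves) == 0,
          "curves must be a named list keyed by compound")

  curve_key <- tolower(names(curves))
  lookup <- function(cmp) {
    i <- match(tolower(cmp), curve_key)
    if (!is.na(i)) return(list(curve = curves[[i]], mode = "standard"))
    .assert(!is.null(fallback),
            "no calibration curve for '%s' and no fallback given", cmp)
    list(curve = fallback, mode = "semi-quantitative")
  }

  n <- nrow(peaks)
  concentration <- numeric(n)
  mode <- character(n)
  clamped <- logical(n)
  for (i in seq_len(n)) {
    cv <- lookup(peaks$compound[i])
    ratio <- peaks$peak_area[i] / peaks$is_area[i]
    amt <- (ratio - cv$curve$intercept) / cv$curve$slope
    clamped[i] <- amt < 0
    concentration[i] <- max(0, amt) / peaks$tissue_mass[i]
    mode[i] <- cv$mode
  }
  meta <- intersect(c("sample_id", "cultivar", "stage", "replicate"),
                    names(peaks))
  out <- tibble::as_tibble(peaks[, c(meta, "compound")])
  out$concentration <- concentration
  out$mode <- mode
  out$clamped <- clamped
  out
}

#' Per-sample percentage composition over a compound class
#'
#' Expresses each sample's concentrations as percentages of that sample's
#' total over the given compound class (e.g. the sesquiterpenes only,
#' excluding green-leaf aldehydes and alkanes). Samples with a zero class
#' total have no defined composition; they are excluded and recorded in the
#' `excluded_samples` attribute.
#'
#' @param conc A concentration table from [quantify()] (long form: one row
#'   per sample x compound).
#' @param compounds Compound class to normalize over (default: every
#'   compound present).
#' @return Tibble with sample metadata, `compound` and `percentage`;
#'   per-sample percentages sum to 100. Attribute `excluded_samples` lists
#'   all-zero samples.
#' @export
composition <- function(conc, compounds = unique(conc$compound)) {
  .assert(length(compounds) > 0, "compound class is empty")
  .assert(all(c("sample_id", "compound", "concentration") %in% names(conc)),
          "conc needs sample_id, compound, concentration columns")
  d <- conc[conc$compound %in% compounds, , drop = FALSE]
  totals <- tapply(d$concentration, d$sample_id, sum)
  excluded <- names(totals)[totals == 0]
  d <- d[!(d$sample_id %in% excluded), , drop = FALSE]
  d$percentage <- 100 * d$concentration /
    as.numeric(totals[as.character(d$sample_id)])
  keep <- intersect(c("sample_id", "cultivar", "stage", "replicate",
                      "compound", "percentage"), names(d))
  out <- tibble::as_tibble(d[, keep])
  attr(out, "excluded_samples") <- excluded
  out
}

#' Percent difference of group means for one compound
#'
#' Computes `100 * (mean_a - mean_b) / mean_b`, i.e. how much higher (or
#' lower) group A's mean concentration is *relative to* group B's. Groups
#' are (cultivar, stage) cells; means are arithmetic means over replicates.
#'
#' @param conc Concentration table with `cultivar`, `stage`, `compound`,
#'   `concentration` columns.
#' @param compound Compound to compare.
#' @param group_a,group_b Character vectors `c(cultivar, stage)` (or named
#'   `c(cultivar = , stage = )`).
#' @return Percent difference (scalar).
#' @export
relative_change <- function(conc, compound, group_a, group_b) {
  .assert(all(c("cultivar", "stage", "compound", "concentration") %in%
                names(conc)),
          "conc needs cultivar, stage, compound, concentration columns")
  pick <- function(grp) {
    grp <- unname(grp)
    rows <- conc$compound == compound & conc$cultivar == grp[1] &
      conc$stage == grp[2]
    .assert(any(rows), "no replicates for compound '%s' in group (%s, %s)",
            compound, grp[1], grp[2])
    mean(conc$concentration[rows])
  }
  mean_a <- pick(group_a)
  mean_b <- pick(group_b)
  .assert(mean_b > 0, "reference group mean is zero")
  100 * (mean_a - mean_b) / mean_b
}

#' Principal component analysis of a chemotype matrix
#'
#' Eigen-decomposition of the covariance (optionally correlation) matrix of
#' the centered sample-by-compound data. Component signs are fixed by making
#' the largest-magnitude entry of each loading vector positive, so results
#' are reproducible across platforms.
#'
#' @param x Numeric matrix, samples in rows, compounds in columns.
#' @param center Center the columns (default `TRUE`).
#' @param scale Scale the columns to unit variance (default `FALSE`;
#'   zero-variance compounds are rejected by name when scaling).
#' @return Object of class `chemotype_pca`: list with `scores` (samples x
#'   components), `loadings` (compounds x components), `percent_variance`
#'   (sums to 100), `sdev`, `center`, `scale`.
#' @export
pca_chemotype <- function(x, center = TRUE, scale = FALSE) {
  stopifnot(is.matrix(x), is.numeric(x))
  .assert(nrow(x) >= 2 && ncol(x) >= 2,
          "need at least 2 samples and 2 compounds")
  if (scale) {
    v <- apply(x, 2, sd)
    zv <- colnames(x)[v == 0]
    if (is.null(colnames(x))) zv <- which(v == 0)
    .assert(length(zv) == 0, "zero-variance compound(s) under scaling: %s",
            paste(zv, collapse = ", "))
  }
  xc <- scale(x, center = center, scale = scale)
  S <- crossprod(xc) / (nrow(xc) - 1)
  ee <- eigen(S, symmetric = TRUE)
  vals <- pmax(ee$values, 0)
  loadings <- ee$vectors
  # deterministic sign convention
  for (j in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) loadings[, j] <- -loadings[, j]
  }
  scores <- xc %*% loadings
  comp <- paste0("PC", seq_along(vals))
  dimnames(loadings) <- list(colnames(x), comp)
  dimnames(scores) <- list(rownames(x), comp)
  structure(list(scores = scores, loadings = loadings,
                 percent_variance = setNames(100 * vals / sum(vals), comp),
                 sdev = sqrt(vals), center = center, scale = scale),
            class = "chemotype_pca")
}

#' @export
print.chemotype_pca <- function(x, ...) {
  pv <- x$percent_variance
  cat(sprintf("chemotype_pca: %d component(s); PC1 %.1f%%, PC2 %.1f%%\n",
              length(pv), pv[1], if (length(pv) > 1) pv[2] else NA))
  invisible(x)
}
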