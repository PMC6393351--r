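#' Summarize probe-level expression to gene level from unique probes
#'
#' Gene-level expression is the arithmetic mean, per sample, of the probes
#' that bind uniquely to that gene. The values are assumed to be on a log2
#' (RMA-like) scale, so the plain mean — not the median, not an anti-logged
#' mean — is the appropriate summary. Genes represented only by ambiguously
#' binding probes cannot be summarized and are reported as dropped.
#'
#' @param expr Numeric matrix of probe-level expression, probes in rows
#'   (rownames are probe ids), samples in columns.
#' @param classification A [classify_probes()] result.
#' @param map The matching [build_probe_gene_map()] result.
#' @return An object of class `gene_expression`: list with `matrix` (genes x
#'   samples), `provenance` (named list: gene -> unique probe ids averaged)
#'   and `dropped_genes` (genes with zero unique probes).
#' @export
summarize_by_gene <- function(expr, classification, map) {
  stopifnot(is.matrix(expr), inherits(classification, "probe_classification"),
            inherits(map, "probe_gene_map"))
  .assert(!is.null(rownames(expr)), "expr must have probe ids as rownames")
  universe <- c(classification$unique, names(classification$ambiguous),
                classification$unmapped)
  missing <- setdiff(rownames(expr), universe)
  .assert(length(missing) == 0,
          "probes absent from the classification: %s",
          paste(missing, collapse = ", "))

  uhits <- map$hits[map$hits$probe_id %in% classification$unique, ,
                    drop = FALSE]
  uhits <- uhits[uhits$probe_id %in% rownames(expr), , drop = FALSE]
  provenance <- split(uhits$probe_id, uhits$gene_id)
  retained <- sort(names(provenance))
  dropped <- setdiff(map$gene_ids, retained)

  gmat <- matrix(NA_real_, nrow = length(retained), ncol = ncol(expr),
                 dimnames = list(retained, colnames(expr)))
  for (g in retained) {
    gmat[g, ] <- colMeans(expr[provenance[[g]], , drop = FALSE])
  }

  structure(list(matrix = gmat, provenance = provenance[retained],
                 dropped_genes = sort(dropped)),
            class = "gene_expression")
}

#' @export
print.gene_expression <- function(x, ...) {
  cat(sprintf("gene_expression: %d gene(s) x %d sample(s); %d gene(s) dropped (no unique probe)\n",
              nrow(x$matrix), ncol(x$matrix), length(x$dropped_genes)))
  invisible(x)
}

#' Hierarchical clustering of an expression matrix
#'
#' Deterministic agglomerative clustering of rows and/or columns, the way a
#' clustered heatmap orders its axes. The correlation metric uses
#' `1 - Pearson r` as the distance; constant rows have no defined correlation
#' and are rejected by name.
#'
#' @param mat Numeric matrix with row and column names; no missing values.
#' @param axis Which axes to cluster: `"both"` (default), `"rows"`,
#'   `"columns"`.
#' @param metric `"euclidean"` (default) or `"correlation"`.
#' @param linkage `"average"` (default) or `"complete"`.
#' @return List of class `expression_clustering` with `row_hclust`,
#'   `col_hclust` (either may be `NULL`), `matrix` (input reordered by the
#'   dendrogram leaf orders) and `params`.
#' @export
cluster_expression <- function(mat, axis = c("both", "rows", "columns"),
                               metric = c("euclidean", "correlation"),
                               linkage = c("average", "complete")) {
  axis <- match.arg(axis)
  metric <- match.arg(metric)
  linkage <- match.arg(linkage)
  stopifnot(is.matrix(mat), is.numeric(mat))
  .assert(!anyNA(mat), "matrix contains missing values; impute upstream")

  dfun <- function(m, what) {
    if (metric == "euclidean") return(dist(m))
    sds <- apply(m, 1, sd)
    if (any(sds == 0)) {
      .validation_error("constant %s under correlation metric: %s", what,
                        paste(rownames(m)[sds == 0], collapse = ", "))
    }
    as.dist(1 - cor(t(m)))
  }

  row_h <- col_h <- NULL
  if (axis %in% c("both", "rows")) {
    .assert(nrow(mat) >= 2, "need >= 2 rows to cluster rows")
    row_h <- hclust(dfun(mat, "row(s)"), method = linkage)
  }
  if (axis %in% c("both", "columns")) {
    .assert(ncol(mat) >= 2, "need >= 2 columns to cluster columns")
    col_h <- hclust(dfun(t(mat), "column(s)"), method = linkage)
  }
  ord <- mat[if (is.null(row_h)) seq_len(nrow(mat)) else row_h$order,
             if (is.null(col_h)) seq_len(ncol(mat)) else col_h$order,
             drop = FALSE]
  structure(list(row_hclust = row_h, col_hclust = col_h, matrix = ord,
                 params = list(axis = axis, metric = metric,
                               linkage = linkage)),
            class = "expression_clustering")
}

# robust row z-score: rows are median-centered and scaled by a pooled
# robust sigma (the median of the per-row scaled MADs). A plain per-row
# mean/sd z-score has an algebraic ceiling below typical thresholds when
# the elevated cells are a sizeable minority of the row, and even a per-row
# MAD is inflated by the hotspot cells themselves; pooling the scale over
# all rows works because most rows are pure background. Degenerate cases
# fall back to the sd of the centered matrix; a fully constant matrix gets
# z = 0 everywhere.
.robust_row_z <- function(mat) {
  ctr <- apply(mat, 1, median)
  centered <- mat - ctr
  sigma <- median(apply(mat, 1, mad))
  if (is.na(sigma) || sigma == 0) sigma <- sd(centered)
  if (is.na(sigma) || sigma == 0) return(centered * 0)
  centered / sigma
}

# cut a dendrogram at the largest gap between consecutive merge heights
.gap_cut <- function(h, tol = 1e-10) {
  heights <- sort(h$height)
  n_leaf <- length(h$order)
  if (length(heights) == 1) {
    k <- if (heights > tol) 2L else 1L
    return(cutree(h, k = k))
  }
  gaps <- diff(heights)
  i <- which.max(gaps)
  if (gaps[i] <= tol) return(setNames(rep(1L, n_leaf), h$labels))
  cutree(h, h = (heights[i] + heights[i + 1]) / 2)
}

# optimal two-group split of 1-D scores (minimum within-group sum of
# squares); returns the names of the high group
.ss_top <- function(score) {
  s <- sort(score)
  n <- length(s)
  if (n < 2) return(names(s))
  best <- Inf
  cut <- 1L
  for (k in seq_len(n - 1)) {
    lo <- s[1:k]
    hi <- s[(k + 1):n]
    ss <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (ss < best) {
      best <- ss
      cut <- k
    }
  }
  names(s)[(cut + 1):n]
}

# refine a candidate block by alternating optimal splits of in-block vs
# out-of-block contrast scores on each axis
.refine_block <- function(z, genes, samples, max_iter = 4) {
  for (it in seq_len(max_iter)) {
    oth_s <- setdiff(colnames(z), samples)
    gscore <- rowMeans(z[, samples, drop = FALSE]) -
      (if (length(oth_s)) rowMeans(z[, oth_s, drop = FALSE]) else 0)
    genes2 <- .ss_top(gscore)
    oth_g <- setdiff(rownames(z), genes2)
    sscore <- colMeans(z[genes2, , drop = FALSE]) -
      (if (length(oth_g)) colMeans(z[oth_g, , drop = FALSE]) else 0)
    samples2 <- .ss_top(sscore)
    done <- setequal(genes2, genes) && setequal(samples2, samples)
    genes <- genes2
    samples <- samples2
    if (done) break
  }
  list(genes = sort(genes), samples = sort(samples))
}

#' Detect expression hotspots as high-z gene-by-sample blocks
#'
#' Operationalizes the "draw a square on the heatmap" reading of an
#' expression hotspot. Gene rows are z-scored robustly (median-centered,
#' pooled-MAD scaled), rows and columns of the z matrix are clustered
#' (euclidean, average linkage) and each dendrogram is cut at the largest
#' gap in its merge heights. Each resulting (gene cluster x sample cluster)
#' candidate is then refined by alternating optimal two-group splits of the
#' in-block versus out-of-block contrast on each axis until the block is
#' stable — a raw dendrogram cut routinely clips or pads a block by one
#' member, and the refinement step is what makes recovered block boundaries
#' exact. Refined blocks whose mean z-score reaches `z_threshold` and that
#' meet the size minima are reported, deduplicated, sorted by mean z
#' descending.
#'
#' @param mat Gene x sample numeric matrix (e.g. from [summarize_by_gene()]).
#' @param z_threshold Minimum mean robust z-score of a block (default 1.5).
#' @param min_genes,min_samples Minimum block dimensions (default 2 each).
#' @return Object of class `hotspot_report`: list with `blocks` (each a list
#'   of `genes`, `samples`, `mean_z`) and `params`.
#' @export
detect_hotspots <- function(mat, z_threshold = 1.5, min_genes = 2,
                            min_samples = 2) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  .assert(nrow(mat) >= min_genes && ncol(mat) >= min_samples,
          "matrix smaller than the requested block minima")
  .assert(!anyNA(mat), "matrix contains missing values")
  if (is.null(rownames(mat))) rownames(mat) <- paste0("g", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- paste0("s", seq_len(ncol(mat)))

  z <- .robust_row_z(mat)
  dimnames(z) <- dimnames(mat)

  row_cl <- if (nrow(z) >= 2) .gap_cut(hclust(dist(z), "average")) else
    setNames(1L, rownames(z))
  col_cl <- if (ncol(z) >= 2) .gap_cut(hclust(dist(t(z)), "average")) else
    setNames(1L, colnames(z))

  blocks <- list()
  for (rc in unique(row_cl)) {
    for (cc in unique(col_cl)) {
      cand <- .refine_block(z, names(row_cl)[row_cl == rc],
                            names(col_cl)[col_cl == cc])
      if (length(cand$genes) < min_genes ||
          length(cand$samples) < min_samples) next
      mz <- mean(z[cand$genes, cand$samples])
      if (mz >= z_threshold) {
        blocks[[length(blocks) + 1]] <-
          list(genes = cand$genes, samples = cand$samples, mean_z = mz)
      }
    }
  }
  if (length(blocks) > 1) {
    key <- vapply(blocks, function(b)
      paste(c(b$genes, "|", b$samples), collapse = ","), character(1))
    blocks <- blocks[!duplicated(key)]
    blocks <- blocks[order(vapply(blocks, `[[`, numeric(1), "mean_z"),
                           decreasing = TRUE)]
  }
  structure(list(blocks = blocks,
                 params = list(z_threshold = z_threshold,
                               min_genes = min_genes,
                               min_samples = min_samples)),
            class = "hotspot_report")
}

#' @export
print.hotspot_report <- function(x, ...) {
  cat(sprintf("hotspot_report: %d block(s) at mean z >= %.2f\n",
              length(x$blocks), x$params$z_threshold))
  for (b in x$blocks) {
    cat(sprintf("  %d gene(s) x %d sample(s), mean z = %.2f\n",
                length(b$genes), length(b$samples), b$mean_z))
  }
  invisible(x)
}
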