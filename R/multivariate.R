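#' Principal component analysis of standardized spectra
#'
#' Column-centered, unscaled (covariance) PCA of the nine sum-to-one band
#' proportions. Because the inputs are commensurable proportions, no
#' rescaling to unit variance is applied by default; correlation PCA is
#' available via `scale.`. The sign of PC1 is fixed so that the 676 nm
#' loading is positive: high PC1 means more red/far-red reflectance relative
#' to green, i.e. redder/browner (dormant-looking) leaves. Remaining
#' components get a deterministic sign (largest-magnitude loading positive)
#' so results are platform-stable.
#'
#' @param spectra Numeric matrix or data frame, rows = plants, columns = the
#'   nine band proportions (`p445` ... `p800`), at least 3 rows.
#' @param scale. Use correlation PCA instead of covariance PCA (default
#'   `FALSE`).
#' @return An object of class `pca_result`: `loadings` (bands x K),
#'   `scores` (N x K), `explained_variance_ratio` (sums to 1), `center`.
#' @export
run_pca <- function(spectra, scale. = FALSE) {
  x <- as.matrix(spectra)
  if (nrow(x) < 3L) stop("PCA needs at least 3 spectra")
  if (all(apply(x, 2, stats::var) < .Machine$double.eps))
    stop("constant matrix: no variance to decompose")
  fit <- stats::prcomp(x, center = TRUE, scale. = scale.)
  load <- fit$rotation
  scores <- fit$x
  sign_col <- function(k) {
    ref <- if (k == 1L && "p676" %in% rownames(load)) load["p676", 1L]
           else load[which.max(abs(load[, k])), k]
    if (ref < 0) -1 else 1
  }
  s <- vapply(seq_len(ncol(load)), sign_col, numeric(1))
  load <- sweep(load, 2, s, "*")
  scores <- sweep(scores, 2, s, "*")
  evr <- fit$sdev^2 / sum(fit$sdev^2)
  structure(list(loadings = load, scores = scores,
                 explained_variance_ratio = evr, center = fit$center),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result> ", nrow(x$scores), " plants; variance explained: ",
      paste0(sprintf("%.1f%%", 100 * x$explained_variance_ratio[1:min(3, length(x$explained_variance_ratio))]),
             collapse = ", "), " ...\n", sep = "")
  invisible(x)
}

trait_matrix <- function(tab, traits = TRAIT_NAMES) {
  tab <- as.data.frame(tab)
  miss <- setdiff(traits, names(tab))
  if (length(miss))
    stop("phenotype table lacks trait column(s): ", paste(miss, collapse = ", "))
  m <- as.matrix(tab[, traits, drop = FALSE])
  rownames(m) <- tab$plant_id
  m
}

#' Interannual trait correlation matrix
#'
#' Pearson correlation of every trait measured in year 1 against every trait
#' measured in year 2, over the plants present in both tables (inner join on
#' `plant_id`). The diagonal of the matched-trait sub-block is each trait's
#' interannual repeatability.
#'
#' @param tableY1,tableY2 Phenotype tables (data frames with a `plant_id`
#'   column and the columns in `traits`).
#' @param traits Trait columns to correlate (default the 27-trait set).
#' @return `length(traits) x length(traits)` matrix; rows = year-1 traits,
#'   columns = year-2 traits. Zero-variance traits give `NA` entries with a
#'   warning.
#' @export
annual_correlations <- function(tableY1, tableY2, traits = TRAIT_NAMES) {
  m1 <- trait_matrix(tableY1, traits)
  m2 <- trait_matrix(tableY2, traits)
  shared <- intersect(rownames(m1), rownames(m2))
  if (length(shared) < 3L) stop("fewer than 3 shared plants")
  m1 <- m1[shared, , drop = FALSE]
  m2 <- m2[shared, , drop = FALSE]
  degenerate <- apply(m1, 2, stats::sd) == 0 | apply(m2, 2, stats::sd) == 0
  if (any(degenerate))
    warning("zero-variance trait(s): ",
            paste(traits[degenerate], collapse = ", "))
  suppressWarnings(stats::cor(m1, m2))
}

#' Correlation between two trait vectors
#'
#' Pearson (default) or Spearman correlation with its two-sided test.
#'
#' @param x,y Equal-length numeric vectors.
#' @param method `"pearson"` or `"spearman"`.
#' @return List with `R`, `R2` and two-sided `p`.
#' @export
correlate_traits <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("length mismatch")
  ct <- suppressWarnings(stats::cor.test(x, y, method = method))
  list(R = unname(ct$estimate), R2 = unname(ct$estimate)^2, p = ct$p.value)
}

#' Quantile-representative plants
#'
#' For each requested quantile of a trait (default the quartiles 0, 25, 50,
#' 75, 100%), the plant whose trait value is nearest the empirical (type-7)
#' quantile. Ties break to the lower plant id, so the selection is
#' deterministic.
#'
#' @param values Numeric trait vector.
#' @param ids Plant ids aligned with `values`.
#' @param q Quantile probabilities.
#' @return Data frame with `q`, `quantile_value`, `plant_id`, `value`.
#' @export
quantile_representatives <- function(values, ids, q = c(0, .25, .5, .75, 1)) {
  if (length(values) == 0L) stop("empty input")
  if (length(values) != length(ids)) stop("ids and values differ in length")
  qv <- stats::quantile(values, probs = q, type = 7, names = FALSE)
  pick <- vapply(qv, function(target) {
    d <- abs(values - target)
    order(d, as.character(ids))[1]
  }, integer(1))
  data.frame(q = q, quantile_value = qv, plant_id = as.character(ids)[pick],
             value = values[pick], row.names = NULL)
}
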