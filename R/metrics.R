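.STRATEGIES <- c("drug", "drug_dose", "cov_drug", "cov_drug_dose", "per_sample")

#' Coefficient of determination
#'
#' `1 - sum((y_true - y_pred)^2) / sum((y_true - m)^2)` where `m` is the
#' mean of `y_true` (standard definition, default) or of `y_pred`
#' (`center = "pred"`, the strict printed-formula variant; see the methods
#' vignette for why the default differs).
#'
#' @param y_true,y_pred equal-length numeric vectors (length >= 2).
#' @param center `"true"` or `"pred"`.
#' @return a real `<= 1`, or `NA` with a warning when the centring vector
#'   is constant.
#' @export
rSquared <- function(y_true, y_pred, center = c("true", "pred")) {
  center <- match.arg(center)
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (length(y_true) < 2L) stop("need at least two genes")
  m <- mean(if (center == "true") y_true else y_pred)
  denom <- sum((y_true - m)^2)
  if (denom == 0) {
    warning("constant centring vector: R^2 undefined")
    return(NA_real_)
  }
  1 - sum((y_true - y_pred)^2) / denom
}

#' Log fold change against the paired control
#'
#' Elementwise difference of log-normalized expression; in log space the
#' difference is the log fold change.
#'
#' @param y,x_control equal-length log-normalized vectors.
#' @return numeric vector `y - x_control`.
#' @export
lnFoldChange <- function(y, x_control) {
  if (length(y) != length(x_control)) stop("length mismatch")
  y - x_control
}

#' Pearson correlation of true and predicted log fold changes
#'
#' @param y_true,y_pred,x_control equal-length log-normalized vectors.
#' @return correlation in `[-1, 1]`, or `NA` with a warning when either
#'   fold-change vector has zero variance.
#' @export
pccLnFC <- function(y_true, y_pred, x_control) {
  lt <- lnFoldChange(y_true, x_control)
  lp <- lnFoldChange(y_pred, x_control)
  if (stats::sd(lt) == 0 || stats::sd(lp) == 0) {
    warning("zero-variance log fold change: PCC undefined")
    return(NA_real_)
  }
  stats::cor(lt, lp)
}

## Group keys per strategy; doses compared after rounding to 6 significant
## digits so float noise cannot split a dose level.
.group_keys <- function(pe, strategy) {
  cd <- SummarizedExperiment::colData(pe)
  dose <- signif(cd$dose_um, 6)
  switch(strategy,
    drug = as.character(cd$drug_id),
    drug_dose = paste(cd$drug_id, dose, sep = "|"),
    cov_drug = paste(cd$drug_id, cd$cell_line, sep = "|"),
    cov_drug_dose = paste(cd$drug_id, cd$cell_line, dose, sep = "|"),
    per_sample = as.character(seq_len(ncol(pe))),
    stop("unknown strategy: ", strategy))
}

#' Group-averaged evaluation metric
#'
#' Records are grouped by the chosen granularity; within each group the
#' true, predicted and control profiles are averaged, the metric is
#' computed on the group means, and the unweighted mean over groups is
#' returned. Groups where the metric is undefined are excluded (their
#' count is reported in the attributes).
#'
#' @param pe a [PerturbationExperiment-class].
#' @param predictions matrix `n_gene x n_record` aligned 1:1 with records.
#' @param strategy one of `"drug"`, `"drug_dose"`, `"cov_drug"`,
#'   `"cov_drug_dose"`, `"per_sample"`.
#' @param metric `"R2"` or `"PCC_lnFC"`.
#' @param center passed to [rSquared()].
#' @return scalar with attributes `n_groups` (evaluated) and `n_excluded`.
#' @export
groupedMetric <- function(pe, predictions, strategy, metric = c("R2", "PCC_lnFC"),
                          center = "true") {
  metric <- match.arg(metric)
  if (!identical(dim(predictions), dim(perturbedMatrix(pe)))) {
    stop("predictions must align 1:1 with records")
  }
  keys <- .group_keys(pe, strategy)
  y_true <- perturbedMatrix(pe)
  x_ctl <- controlMatrix(pe)
  vals <- vapply(split(seq_along(keys), keys), function(idx) {
    yt <- rowMeans(y_true[, idx, drop = FALSE])
    yp <- rowMeans(predictions[, idx, drop = FALSE])
    suppressWarnings(
      if (metric == "R2") rSquared(yt, yp, center = center)
      else pccLnFC(yt, yp, rowMeans(x_ctl[, idx, drop = FALSE])))
  }, numeric(1))
  ok <- !is.na(vals)
  if (!any(ok)) stop("no evaluable group for strategy ", strategy)
  structure(mean(vals[ok]), n_groups = sum(ok), n_excluded = sum(!ok))
}

#' Evaluate the full 2 x 5 metric grid
#'
#' R-squared and PCC(lnFC) at all five grouping granularities: ten
#' measures per evaluated split.
#'
#' @inheritParams groupedMetric
#' @return a [MetricReport-class].
#' @export
evaluateAll <- function(pe, predictions, center = "true") {
  vals <- matrix(NA_real_, 2L, length(.STRATEGIES),
                 dimnames = list(c("R2", "PCC_lnFC"), .STRATEGIES))
  ng <- integer(length(.STRATEGIES)); nx <- integer(length(.STRATEGIES))
  for (s in seq_along(.STRATEGIES)) {
    for (m in rownames(vals)) {
      v <- tryCatch(
        groupedMetric(pe, predictions, .STRATEGIES[s], m, center = center),
        error = function(e) stop("strategy ", .STRATEGIES[s], ": ",
                                 conditionMessage(e)))
      vals[m, s] <- as.numeric(v)
      ng[s] <- attr(v, "n_groups"); nx[s] <- attr(v, "n_excluded")
    }
  }
  new("MetricReport", values = vals, n_groups = ng, n_excluded = nx)
}

#' Per-gene fold-change correlation on differentially expressed genes
#'
#' For each DEG set and each of its genes, the Pearson correlation across
#' that drug's samples between true and predicted per-sample log fold
#' changes of the gene; the per-set value is the mean over its DEGs.
#' Genes with zero variance within a drug are skipped with a warning.
#'
#' @param pe a [PerturbationExperiment-class].
#' @param predictions aligned prediction matrix.
#' @param deg_sets list from [computeDEGs()].
#' @param min_samples minimum samples per drug (default 3).
#' @return named numeric vector, one mean per DEG set.
#' @export
degGenePCC <- function(pe, predictions, deg_sets, min_samples = 3L) {
  cd <- SummarizedExperiment::colData(pe)
  lt <- perturbedMatrix(pe) - controlMatrix(pe)
  lp <- predictions - controlMatrix(pe)
  out <- numeric(length(deg_sets))
  names(out) <- vapply(deg_sets, function(s) {
    if (is.na(s$cell_line)) s$drug_id else paste(s$drug_id, s$cell_line, sep = "|")
  }, character(1))
  for (i in seq_along(deg_sets)) {
    s <- deg_sets[[i]]
    idx <- which(cd$drug_id == s$drug_id &
                   (is.na(s$cell_line) | cd$cell_line == s$cell_line))
    if (length(idx) < min_samples) {
      stop("drug ", s$drug_id, " has fewer than ", min_samples, " samples")
    }
    genes <- c(s$up_genes, s$down_genes)
    genes <- genes[genes %in% rownames(pe)]
    vals <- vapply(genes, function(g) {
      a <- lt[g, idx]; b <- lp[g, idx]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) {
        warning("zero-variance gene ", g, " within drug ", s$drug_id, "; skipped")
        return(NA_real_)
      }
      stats::cor(a, b)
    }, numeric(1))
    out[i] <- mean(vals, na.rm = TRUE)
  }
  out
}

#' Tidy form and serialization of a metric report
#'
#' @param report a [MetricReport-class].
#' @return `reportAsDataFrame`: data.frame with columns `metric`,
#'   `strategy`, `value`, `n_groups`, `n_excluded`.
#' @export
reportAsDataFrame <- function(report) {
  v <- report@values
  data.frame(
    metric = rep(rownames(v), times = ncol(v)),
    strategy = rep(colnames(v), each = nrow(v)),
    value = as.numeric(v),
    n_groups = rep(report@n_groups, each = nrow(v)),
    n_excluded = rep(report@n_excluded, each = nrow(v)))
}

#' @rdname reportAsDataFrame
#' @param path_json,path_csv output paths (either may be `NULL`).
#' @export
writeMetricReport <- function(report, path_json = NULL, path_csv = NULL) {
  df <- reportAsDataFrame(report)
  if (!is.null(path_json)) {
    jsonlite::write_json(df, path_json, dataframe = "rows", digits = NA)
  }
  if (!is.null(path_csv)) utils::write.csv(df, path_csv, row.names = FALSE)
  invisible(df)
}
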