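#' Construct a PerturbationExperiment
#'
#' @param control,perturbed numeric matrices, genes x records, log-normalized;
#'   column `j` of `control` is the paired pre-perturbation profile of record
#'   `j`. Gene order must be identical (rownames checked when present).
#' @param smiles,dose_um,cell_line per-record annotations.
#' @param organ optional per-record organ label.
#' @param drug_id optional; computed as the canonical SMILES when missing
#'   (`NA` for invalid SMILES; see [filterRecords()]).
#' @param metadata optional list stored as experiment metadata.
#' @return a [PerturbationExperiment-class].
#' @export
PerturbationExperiment <- function(control, perturbed, smiles, dose_um,
                                   cell_line, organ = NULL, drug_id = NULL,
                                   metadata = list()) {
  control <- as.matrix(control)
  perturbed <- as.matrix(perturbed)
  if (!identical(dim(control), dim(perturbed))) {
    stop("control and perturbed matrices must share dimensions")
  }
  if (!is.null(rownames(control)) && !is.null(rownames(perturbed)) &&
      !identical(rownames(control), rownames(perturbed))) {
    stop("control and perturbed gene panels differ; records with mismatched ",
         "panels are rejected rather than intersected")
  }
  if (is.null(rownames(perturbed))) {
    rownames(perturbed) <- rownames(control) <-
      sprintf("g%03d", seq_len(nrow(perturbed)))
  } else {
    rownames(control) <- rownames(perturbed)
  }
  colnames(control) <- colnames(perturbed) <- NULL
  if (is.null(drug_id)) drug_id <- canonicalizeSmiles(smiles)
  cd <- S4Vectors::DataFrame(smiles = smiles, dose_um = dose_um,
                             cell_line = cell_line, drug_id = drug_id)
  if (!is.null(organ)) cd$organ <- organ
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(control = control, perturbed = perturbed),
    colData = cd, metadata = metadata)
  colnames(se) <- sprintf("r%05d", seq_len(ncol(se)))
  new("PerturbationExperiment", se)
}

#' @rdname PerturbationExperiment
#' @param pe a `PerturbationExperiment`.
#' @export
controlMatrix <- function(pe) SummarizedExperiment::assay(pe, "control")

#' @rdname PerturbationExperiment
#' @export
perturbedMatrix <- function(pe) SummarizedExperiment::assay(pe, "perturbed")

#' @rdname PerturbationExperiment
#' @export
drugIds <- function(pe) SummarizedExperiment::colData(pe)$drug_id

#' @rdname PerturbationExperiment
#' @export
cellLines <- function(pe) SummarizedExperiment::colData(pe)$cell_line

#' @rdname PerturbationExperiment
#' @export
doseUm <- function(pe) SummarizedExperiment::colData(pe)$dose_um

#' Log-normalize a count matrix
#'
#' Scales every sample (row) to the common total `scale`, then applies
#' `log(1 + x)`. This is the standard library-size normalization of
#' expression workflows; within-sample gene ranking is preserved.
#'
#' @param counts non-negative matrix, samples x genes.
#' @param scale positive target total per sample (default `1e4`).
#' @return matrix of the same shape, log-normalized.
#' @export
logNormalize <- function(counts, scale = 1e4) {
  counts <- as.matrix(counts)
  if (!all(is.finite(counts))) stop("counts must be finite")
  if (any(counts < 0)) {
    bad <- which(apply(counts, 1L, function(r) any(r < 0)))[1L]
    stop("negative entry in sample ", rownames(counts)[bad] %||% bad)
  }
  stopifnot(is.finite(scale), scale > 0)
  tot <- rowSums(counts)
  if (any(tot == 0)) {
    bad <- which(tot == 0)
    stop("all-zero sample(s): ",
         paste(rownames(counts)[bad] %||% bad, collapse = ", "))
  }
  log1p(counts / tot * scale)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assign a paired control to every perturbed sample
#'
#' Each perturbed sample receives one control sample sharing its matching
#' keys (by default the cell line, plus batch when such a column is
#' present in both tables). When several controls match, one is drawn
#' seeded-uniformly, so the pairing is reproducible.
#'
#' @param perturbed,controls numeric matrices, genes x samples,
#'   log-normalized, same gene panel.
#' @param perturbed_meta data.frame with columns `smiles`, `dose_um`,
#'   `cell_line` (+ optional `batch`, `organ`), one row per perturbed column.
#' @param control_meta data.frame with `cell_line` (+ optional `batch`), one
#'   row per control column.
#' @param match_keys columns that must agree between a record and its control.
#' @param seed integer; fixes the draw among multiple matching controls.
#' @return a [PerturbationExperiment-class].
#' @export
pairControls <- function(perturbed, controls, perturbed_meta, control_meta,
                         match_keys = NULL, seed = 1L) {
  perturbed <- as.matrix(perturbed)
  controls <- as.matrix(controls)
  if (nrow(perturbed) != nrow(controls)) stop("gene panels differ")
  if (is.null(match_keys)) {
    match_keys <- c("cell_line",
                    if ("batch" %in% colnames(perturbed_meta) &&
                        "batch" %in% colnames(control_meta)) "batch")
  }
  key_of <- function(meta) {
    do.call(paste, c(lapply(match_keys, function(k) meta[[k]]), sep = "\r"))
  }
  pk <- key_of(perturbed_meta)
  ck <- key_of(control_meta)
  pool <- split(seq_along(ck), ck)
  unmatched <- unique(pk[!pk %in% names(pool)])
  if (length(unmatched)) {
    stop("no matching control for key(s): ",
         paste(gsub("\r", "/", unmatched), collapse = ", "))
  }
  idx <- with_seed(seed, vapply(pk, function(k) {
    cand <- pool[[k]]
    if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1L)]
  }, integer(1)))
  PerturbationExperiment(
    control = controls[, idx, drop = FALSE], perturbed = perturbed,
    smiles = perturbed_meta$smiles, dose_um = perturbed_meta$dose_um,
    cell_line = perturbed_meta$cell_line, organ = perturbed_meta$organ)
}

#' Filter records by SMILES validity and compound sample count
#'
#' Removes records whose SMILES fails canonicalization, then compounds
#' with fewer than `min_obs_per_compound` remaining observations (default
#' 5). Idempotent.
#'
#' @param pe a [PerturbationExperiment-class].
#' @param min_obs_per_compound minimum observations a compound must retain.
#' @return the filtered `PerturbationExperiment`.
#' @export
filterRecords <- function(pe, min_obs_per_compound = 5L) {
  keep <- !is.na(drugIds(pe))
  cnt <- table(drugIds(pe)[keep])
  good <- names(cnt)[cnt >= min_obs_per_compound]
  keep <- keep & drugIds(pe) %in% good
  if (!any(keep)) stop("no records remain after filtering")
  pe[, keep]
}

#' Compute differentially expressed gene sets
#'
#' Within each group (per drug, or per drug-cell combination), genes are
#' scored by the mean log fold change of perturbed versus paired control
#' profiles (`method = "mean_lnfc"`), or by a signed log10 p-value from a
#' paired Wilcoxon signed-rank test (`method = "wilcoxon"`). The top
#' `n_up` and `n_down` genes are reported, ties broken by absolute score
#' and then gene-panel order, so the output is deterministic and invariant
#' to record order. Groups with fewer than `min_group` records are skipped
#' with a warning.
#'
#' @param pe a [PerturbationExperiment-class].
#' @param n_up,n_down genes per direction (default 25 each).
#' @param group_by `"drug"` or `"drug_cell"`.
#' @param method scoring statistic.
#' @param min_group minimum records per group (default 2).
#' @return a list of DEG sets: `list(drug_id, cell_line, up_genes, down_genes)`.
#' @export
computeDEGs <- function(pe, n_up = 25L, n_down = 25L,
                        group_by = c("drug", "drug_cell"),
                        method = c("mean_lnfc", "wilcoxon"),
                        min_group = 2L) {
  group_by <- match.arg(group_by)
  method <- match.arg(method)
  cd <- SummarizedExperiment::colData(pe)
  gkey <- if (group_by == "drug") cd$drug_id else paste(cd$drug_id, cd$cell_line, sep = "\r")
  lfc <- perturbedMatrix(pe) - controlMatrix(pe)
  genes <- rownames(pe)
  out <- list()
  for (g in unique(gkey)) {
    idx <- which(gkey == g)
    if (length(idx) < min_group) {
      warning("group ", gsub("\r", "/", g), " has fewer than ", min_group,
              " records; skipped")
      next
    }
    score <- if (method == "mean_lnfc") {
      rowMeans(lfc[, idx, drop = FALSE])
    } else {
      m <- rowMeans(lfc[, idx, drop = FALSE])
      p <- apply(lfc[, idx, drop = FALSE], 1L, function(v) {
        if (all(v == 0)) 1 else
          suppressWarnings(stats::wilcox.test(v, mu = 0)$p.value)
      })
      sign(m) * -log10(pmax(p, .Machine$double.xmin))
    }
    ord_up <- order(-score, -abs(score), seq_along(score))
    up <- if (n_up > 0L) genes[ord_up[seq_len(min(n_up, length(genes)))]] else character()
    remaining <- setdiff(seq_along(genes), match(up, genes))
    sc_d <- score[remaining]
    ord_dn <- remaining[order(sc_d, -abs(sc_d), seq_along(sc_d))]
    dn <- if (n_down > 0L) genes[ord_dn[seq_len(min(n_down, length(ord_dn)))]] else character()
    parts <- strsplit(g, "\r", fixed = TRUE)[[1L]]
    out[[length(out) + 1L]] <- list(
      drug_id = parts[1L],
      cell_line = if (group_by == "drug_cell") parts[2L] else NA_character_,
      up_genes = up, down_genes = dn)
  }
  out
}

#' Serialize DEG sets to and from JSON
#'
#' @param degs result of [computeDEGs()].
#' @param path JSON file path.
#' @export
writeDEGSets <- function(degs, path) {
  jsonlite::write_json(degs, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname writeDEGSets
#' @export
readDEGSets <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(nrow(raw)), function(i) list(
    drug_id = raw$drug_id[i],
    cell_line = raw$cell_line[i],
    up_genes = unlist(raw$up_genes[i]),
    down_genes = unlist(raw$down_genes[i])))
}

#' Read and write the CSV dataset container
#'
#' The on-disk form is a trio of CSV files: an expression matrix (first
#' column `gene`, one column per sample, controls included), a metadata
#' table (`sample_id`, `smiles`, `dose_um`, `cell_line`,
#' `pert_type` in `control`/`treated`, optional `organ`), and a pairing
#' table (`sample_id`, `control_id`) assigning a control column to every
#' treated column.
#'
#' @param expr_file,meta_file,pairing_file paths to the three CSVs.
#' @return a [PerturbationExperiment-class].
#' @export
readPerturbationCSV <- function(expr_file, meta_file, pairing_file) {
  ex <- utils::read.csv(expr_file, check.names = FALSE)
  genes <- ex[[1L]]
  mat <- as.matrix(ex[, -1L, drop = FALSE])
  rownames(mat) <- genes
  meta <- utils::read.csv(meta_file)
  pairing <- utils::read.csv(pairing_file)
  treated <- meta[meta$pert_type == "treated", , drop = FALSE]
  ci <- pairing$control_id[match(treated$sample_id, pairing$sample_id)]
  if (any(is.na(ci))) stop("pairing table lacks entries for some treated samples")
  PerturbationExperiment(
    control = mat[, ci, drop = FALSE],
    perturbed = mat[, treated$sample_id, drop = FALSE],
    smiles = treated$smiles, dose_um = treated$dose_um,
    cell_line = treated$cell_line,
    organ = if ("organ" %in% colnames(treated)) treated$organ else NULL)
}

#' @rdname readPerturbationCSV
#' @param pe a `PerturbationExperiment` to write.
#' @param dir output directory; files `expression.csv`, `metadata.csv`,
#'   `pairing.csv` are created.
#' @export
writePerturbationCSV <- function(pe, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- ncol(pe)
  tid <- sprintf("t%05d", seq_len(n))
  cid <- sprintf("c%05d", seq_len(n))
  mat <- cbind(perturbedMatrix(pe), controlMatrix(pe))
  colnames(mat) <- c(tid, cid)
  utils::write.csv(data.frame(gene = rownames(pe), mat, check.names = FALSE),
                   file.path(dir, "expression.csv"), row.names = FALSE)
  cd <- SummarizedExperiment::colData(pe)
  meta <- data.frame(
    sample_id = c(tid, cid),
    smiles = c(cd$smiles, rep(NA, n)),
    dose_um = c(cd$dose_um, rep(NA, n)),
    cell_line = c(cd$cell_line, cd$cell_line),
    pert_type = rep(c("treated", "control"), each = n))
  if ("organ" %in% colnames(cd)) meta$organ <- c(cd$organ, cd$organ)
  utils::write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  utils::write.csv(data.frame(sample_id = tid, control_id = cid),
                   file.path(dir, "pairing.csv"), row.names = FALSE)
  invisible(dir)
}
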