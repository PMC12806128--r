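#' Five-way out-of-distribution benchmark split
#'
#' Drugs (canonical SMILES) and cell lines are sampled independently into
#' held-out sets; every record is then routed by the cross-classification:
#' both held out -> `test_both_unseen`, drug only -> `test_drug_unseen`,
#' cell only -> `test_cell_unseen`, neither -> `train` / `val` (split at
#' record level by `val_frac`). A drug held out at one dose is held out at
#' every dose, since the holdout unit is the canonical SMILES.
#'
#' @param pe a [PerturbationExperiment-class].
#' @param drug_holdout_frac,cell_holdout_frac fractions of drugs / cell
#'   lines to hold out (in (0,1); at least one unit each).
#' @param val_frac fraction of the remaining records labelled `val`.
#' @param seed integer seed; assignments are reproducible.
#' @return a [SplitAssignment-class].
#' @export
splitBenchmark <- function(pe, drug_holdout_frac = 0.2, cell_holdout_frac = 0.2,
                           val_frac = 0.25, seed = 1L) {
  stopifnot(drug_holdout_frac > 0, drug_holdout_frac < 1,
            cell_holdout_frac > 0, cell_holdout_frac < 1,
            val_frac > 0, val_frac < 1)
  drugs <- unique(drugIds(pe))
  cells <- unique(cellLines(pe))
  n_hd <- max(1L, round(drug_holdout_frac * length(drugs)))
  n_hc <- max(1L, round(cell_holdout_frac * length(cells)))
  if (n_hd >= length(drugs)) stop("not enough drugs to hold some out")
  if (n_hc >= length(cells)) stop("not enough cell lines to hold some out")
  held <- with_seed(seed, {
    labels <- character(ncol(pe))
    hd <- sample(drugs, n_hd)
    hc <- sample(cells, n_hc)
    d_in <- drugIds(pe) %in% hd
    c_in <- cellLines(pe) %in% hc
    labels[d_in & c_in] <- "test_both_unseen"
    labels[d_in & !c_in] <- "test_drug_unseen"
    labels[!d_in & c_in] <- "test_cell_unseen"
    rest <- which(!d_in & !c_in)
    n_val <- round(val_frac * length(rest))
    val_idx <- if (n_val > 0L) sample(rest, n_val) else integer()
    labels[rest] <- "train"
    labels[val_idx] <- "val"
    list(hd = hd, hc = hc, labels = labels)
  })
  labels <- held$labels
  parts <- c("train", "val", "test_drug_unseen", "test_cell_unseen",
             "test_both_unseen")
  empty <- parts[!parts %in% labels]
  if (length(empty)) {
    stop("empty split part(s): ", paste(empty, collapse = ", "))
  }
  new("SplitAssignment", labels = labels, mode = "benchmark",
      fold = NA_integer_, held_out_drugs = held$hd, held_out_cells = held$hc,
      seed = as.integer(seed))
}

#' k-fold cross-validation splits (random / drug / cell modes)
#'
#' `mode = "random"` partitions records into `n_folds` groups; per fold the
#' test set is one group, the validation set the next group (cyclically),
#' and the rest trains — at five folds this is the approximate 6:2:2
#' proportion. Unit modes partition drugs (canonical SMILES) or cell lines
#' instead, so test units never occur in training; the validation set is
#' then drawn at record level from the training side.
#'
#' @param pe a [PerturbationExperiment-class].
#' @param mode `"random"`, `"drug"` or `"cell"`.
#' @param n_folds number of folds (>= 2).
#' @param val_frac record-level validation fraction for unit modes.
#' @param seed integer seed.
#' @return list of [SplitAssignment-class], one per fold.
#' @export
splitCrossValidation <- function(pe, mode = c("random", "drug", "cell"),
                                 n_folds = 5L, val_frac = 0.25, seed = 1L) {
  mode <- match.arg(mode)
  n_folds <- as.integer(n_folds)
  stopifnot(n_folds >= 2L)
  n <- ncol(pe)
  units <- switch(mode,
    random = as.character(seq_len(n)),
    drug = drugIds(pe),
    cell = cellLines(pe))
  u <- unique(units)
  if (length(u) < n_folds) {
    stop("only ", length(u), " ", mode, " unit(s) for ", n_folds, " folds")
  }
  out <- with_seed(seed, {
    fold_of <- sample(rep_len(seq_len(n_folds), length(u)))
    names(fold_of) <- u
    lapply(seq_len(n_folds), function(f) {
      test_units <- u[fold_of == f]
      is_test <- units %in% test_units
      labels <- character(n)
      labels[is_test] <- "test"
      if (mode == "random") {
        val_units <- u[fold_of == (f %% n_folds) + 1L]
        labels[units %in% val_units] <- "val"
        labels[labels == ""] <- "train"
      } else {
        rest <- which(!is_test)
        n_val <- round(val_frac * length(rest))
        val_idx <- if (n_val > 0L) sample(rest, n_val) else integer()
        labels[rest] <- "train"
        labels[val_idx] <- "val"
      }
      new("SplitAssignment", labels = labels, mode = mode,
          fold = f,
          held_out_drugs = if (mode == "drug") test_units else character(),
          held_out_cells = if (mode == "cell") test_units else character(),
          seed = as.integer(seed))
    })
  })
  out
}

#' Serialize a split assignment to CSV plus a JSON manifest
#'
#' @param sa a [SplitAssignment-class].
#' @param dir output directory (`assignment.csv`, `manifest.json`).
#' @export
writeSplitAssignment <- function(sa, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(record_id = seq_along(sa@labels), part = sa@labels),
                   file.path(dir, "assignment.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(mode = sa@mode, fold = sa@fold, seed = sa@seed,
         held_out_drugs = sa@held_out_drugs,
         held_out_cells = sa@held_out_cells),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, null = "null",
    na = "null")
  invisible(dir)
}

#' @rdname writeSplitAssignment
#' @export
readSplitAssignment <- function(dir) {
  df <- utils::read.csv(file.path(dir, "assignment.csv"))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  fold <- suppressWarnings(as.integer(man$fold))
  new("SplitAssignment", labels = as.character(df$part[order(df$record_id)]),
      mode = man$mode, fold = if (length(fold) != 1L || is.na(fold)) NA_integer_ else fold,
      held_out_drugs = as.character(man$held_out_drugs %||% character()),
      held_out_cells = as.character(man$held_out_cells %||% character()),
      seed = as.integer(man$seed))
}
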