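#' End-to-end training entry point
#'
#' Builds (or reuses) the perturbation-embedding cache, initialises the
#' denoiser and trains it on the requested records, returning a
#' self-contained checkpoint (config, schedule, weights, loss curve and
#' embedding settings) that [runPredict()] can consume.
#'
#' @param pe a [PerturbationExperiment-class].
#' @param config a [DenoiserConfig-class].
#' @param sched a [NoiseSchedule-class]. The default is the desk-scale
#'   50-step schedule with endpoints rescaled so that almost no signal
#'   survives at `t = T` (`alpha_bar[T] ~ 1e-3`); ancestral sampling starts
#'   from pure noise, so a schedule whose terminal distribution is far from
#'   N(0, I) cannot sample correctly.
#' @param train_idx record indices to train on.
#' @param epochs,batch_size,lr,weight_decay,ema_decay,restarts see
#'   [trainDenoiser()].
#' @param seeds named list with integer elements `model` (initialisation),
#'   `train` (batching/noise) and `embed` (stub embedder hash).
#' @param embeddings optional prebuilt cache ([perturbationEmbeddings()]).
#' @param verbose print per-epoch loss.
#' @return checkpoint: list with elements `model`, `raw_model`, `config`,
#'   `sched`, `losses`, `embed_seed`, `gene_names`.
#' @export
runTrain <- function(pe, config,
                     sched = makeSchedule(50L, beta_start = 1e-3,
                                          beta_end = 0.25),
                     train_idx = seq_len(ncol(pe)), epochs = 30L,
                     batch_size = 32L, lr = 1e-3, weight_decay = 1e-4,
                     ema_decay = 0.995, restarts = 1L,
                     seeds = list(model = 1L, train = 2L, embed = 3L),
                     embeddings = NULL, verbose = FALSE) {
  if (is.null(embeddings)) {
    embeddings <- perturbationEmbeddings(pe, config, seed = seeds$embed)
  }
  model <- initDenoiser(config, seed = seeds$model)
  fit <- trainDenoiser(model, pe, sched, embeddings, records = train_idx,
                       epochs = epochs, batch_size = batch_size, lr = lr,
                       weight_decay = weight_decay, ema_decay = ema_decay,
                       restarts = restarts, seed = seeds$train,
                       verbose = verbose)
  list(model = fit$model, raw_model = fit$raw_model, config = config,
       sched = sched, losses = fit$losses, embed_seed = seeds$embed,
       gene_names = rownames(pe))
}

#' Save / load a training checkpoint
#'
#' Checkpoints bundle weights, config and schedule in one archive so a
#' reload reproduces predictions bit for bit.
#'
#' @param checkpoint list from [runTrain()].
#' @param path file path.
#' @export
saveCheckpoint <- function(checkpoint, path) {
  saveRDS(checkpoint, path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) readRDS(path)

#' Predict post-perturbation profiles from a checkpoint
#'
#' @param checkpoint list from [runTrain()] or [loadCheckpoint()].
#' @param pe dataset to predict on; its gene panel must match the
#'   checkpoint's.
#' @param records record indices (default: all).
#' @param sampling_seed integer base seed for the reverse chains.
#' @param embeddings optional prebuilt cache.
#' @return matrix `n_gene x length(records)`.
#' @export
runPredict <- function(checkpoint, pe, records = seq_len(ncol(pe)),
                       sampling_seed = 1L, embeddings = NULL) {
  if (!identical(rownames(pe), checkpoint$gene_names)) {
    stop("gene panel does not match the checkpoint")
  }
  if (is.null(embeddings)) {
    embeddings <- perturbationEmbeddings(pe, checkpoint$config,
                                         seed = checkpoint$embed_seed)
  }
  predictPerturbed(checkpoint$model, pe, checkpoint$sched, embeddings,
                   records = records, seed = sampling_seed)
}

#' Evaluate predictions, optionally per split part
#'
#' Runs the ten-metric grid on the whole dataset, or once per non-empty
#' part of a [SplitAssignment-class].
#'
#' @param pe a [PerturbationExperiment-class].
#' @param predictions aligned prediction matrix (all records).
#' @param split optional `SplitAssignment`.
#' @param center passed to [rSquared()].
#' @return a [MetricReport-class], or a named list of them (one per part).
#' @export
runEvaluate <- function(pe, predictions, split = NULL, center = "true") {
  if (is.null(split)) return(evaluateAll(pe, predictions, center = center))
  parts <- unique(split@labels)
  out <- lapply(parts, function(p) {
    idx <- which(split@labels == p)
    evaluateAll(pe[, idx], predictions[, idx, drop = FALSE], center = center)
  })
  names(out) <- parts
  out
}

#' Mean-perturbed-profile baseline predictor
#'
#' Predicts, for every record, the mean perturbed profile of the training
#' records — the natural no-conditioning reference for R-squared
#' comparisons.
#'
#' @param pe a [PerturbationExperiment-class].
#' @param train_idx records whose mean defines the baseline.
#' @return matrix `n_gene x n_record`.
#' @export
baselineMeanPerturbed <- function(pe, train_idx = seq_len(ncol(pe))) {
  m <- rowMeans(perturbedMatrix(pe)[, train_idx, drop = FALSE])
  matrix(m, nrow(pe), ncol(pe), dimnames = list(rownames(pe), colnames(pe)))
}

#' Read a YAML run configuration
#'
#' Configuration files carry the paths, architecture, schedule, optimiser,
#' split and seed settings of a pipeline run; every stochastic component's
#' seed is recorded so runs are reproducible.
#'
#' @param path YAML file.
#' @return named list.
#' @export
readRunConfig <- function(path) yaml::read_yaml(path)

#' @rdname readRunConfig
#' @param config named list to write.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
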