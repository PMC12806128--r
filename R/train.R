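#' Train the denoiser on a paired perturbation dataset
#'
#' Standard diffusion training: per record a timestep is drawn uniformly in
#' `1..T`, Gaussian noise is drawn, the noisy profile is formed by the
#' closed-form forward marginal, and the squared-error noise-prediction
#' loss (summed over genes, averaged over the batch) is minimised with
#' AdamW under a cosine learning-rate decay. An exponential moving average
#' (EMA) of the weights is kept and returned as the model to sample from,
#' the usual stabiliser for diffusion models.
#'
#' @param model an initialised [DenoiserModel-class].
#' @param pe a [PerturbationExperiment-class]; `perturbed` is the clean
#'   target `x0`, `control` the conditioning profile.
#' @param sched a [NoiseSchedule-class].
#' @param embeddings environment from [perturbationEmbeddings()] keyed by
#'   `drug_id|dose`.
#' @param records indices of records to train on (default: all).
#' @param epochs,batch_size,lr,weight_decay optimisation settings.
#' @param ema_decay EMA decay per step; `NULL` disables EMA.
#' @param restarts number of cosine cycles: the learning-rate schedule and
#'   the optimiser moments restart at each cycle boundary (warm restarts).
#'   Restarts help the weak conditional-signal pathways escape the early
#'   reconstruction-only plateau; see the methods vignette.
#' @param seed integer seed governing batch order, timesteps and noise.
#' @param backend `"cpp"` (compiled fast path, default) or `"r"` (reference
#'   implementation); both compute identical mathematics.
#' @param verbose print per-epoch loss.
#' @return list with `model` (EMA weights), `raw_model` (final optimiser
#'   iterate) and `losses` (mean per-record loss per epoch).
#' @export
trainDenoiser <- function(model, pe, sched, embeddings,
                          records = seq_len(ncol(pe)), epochs = 30L,
                          batch_size = 32L, lr = 1e-3, weight_decay = 1e-4,
                          ema_decay = 0.995, restarts = 1L, seed = 1L,
                          backend = c("cpp", "r"), verbose = FALSE) {
  backend <- match.arg(backend)
  cfg <- model@config
  par <- model@params
  stopifnot(nrow(pe) == cfg@n_gene)
  x0_all <- perturbedMatrix(pe)
  cpre_all <- controlMatrix(pe)
  keys <- embeddingKey(drugIds(pe), doseUm(pe))
  for (k in unique(keys[records])) {
    if (is.null(embeddings[[k]])) stop("missing embedding for key ", k)
  }
  m1 <- lapply(par, function(p) p * 0)
  m2 <- lapply(par, function(p) p * 0)
  ema <- par
  pnames <- names(par)
  b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8
  step <- 0L
  cycle_len <- ceiling(epochs / restarts)
  total_steps <- cycle_len * ceiling(length(records) / batch_size)
  losses <- numeric(epochs)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      if (restarts > 1L && ep > 1L && (ep - 1L) %% cycle_len == 0L) {
        m1 <- lapply(par, function(p) p * 0)
        m2 <- lapply(par, function(p) p * 0)
        step <- 0L
      }
      perm <- sample(records)
      ep_loss <- 0
      n_seen <- 0L
      for (bstart in seq(1L, length(perm), by = batch_size)) {
        batch <- perm[bstart:min(bstart + batch_size - 1L, length(perm))]
        nb <- length(batch)
        tvec <- integer(nb)
        EPS <- matrix(NA_real_, cfg@n_gene, nb)
        XT <- matrix(NA_real_, cfg@n_gene, nb)
        for (b in seq_len(nb)) {
          tvec[b] <- sample.int(sched@steps, 1L)
          EPS[, b] <- stats::rnorm(cfg@n_gene)
          XT[, b] <- forwardDiffuse(x0_all[, batch[b]], tvec[b], EPS[, b], sched)
        }
        res <- .loss_grad_batch(par, cfg, XT,
                                cpre_all[, batch, drop = FALSE],
                                lapply(keys[batch], function(k) embeddings[[k]]),
                                tvec, EPS, backend = backend)
        gsum <- res$grads
        ep_loss <- ep_loss + res$loss
        n_seen <- n_seen + nb
        step <- step + 1L
        lr_t <- lr * (0.1 + 0.45 * (1 + cos(pi * step / total_steps)))
        bc1 <- 1 - b1^step
        bc2 <- 1 - b2^step
        for (n in pnames) {
          g <- gsum[[n]] / nb
          m1[[n]] <- b1 * m1[[n]] + (1 - b1) * g
          m2[[n]] <- b2 * m2[[n]] + (1 - b2) * g * g
          par[[n]] <- par[[n]] - lr_t *
            ((m1[[n]] / bc1) / (sqrt(m2[[n]] / bc2) + adam_eps) +
               weight_decay * par[[n]])
          if (!is.null(ema_decay)) {
            ema[[n]] <- ema_decay * ema[[n]] + (1 - ema_decay) * par[[n]]
          }
        }
      }
      losses[ep] <- ep_loss / n_seen
      if (verbose) message(sprintf("epoch %d/%d: loss %.4f", ep, epochs, losses[ep]))
    }
  })
  out_par <- if (is.null(ema_decay)) par else ema
  list(model = new("DenoiserModel", config = cfg, params = out_par),
       raw_model = new("DenoiserModel", config = cfg, params = par),
       losses = losses)
}

#' Predict post-perturbation profiles by ancestral sampling
#'
#' For each requested record, runs the reverse diffusion chain conditioned
#' on its control profile and perturbation embedding. Per-record sampling
#' seeds are derived from `seed`, so results are reproducible and
#' independent of which records are requested together.
#'
#' @param model a trained [DenoiserModel-class].
#' @param pe a [PerturbationExperiment-class] with matching gene panel.
#' @param sched the [NoiseSchedule-class] used in training.
#' @param embeddings environment from [perturbationEmbeddings()].
#' @param records record indices to predict (default: all).
#' @param seed integer base sampling seed.
#' @param backend `"cpp"` (default) or `"r"`; per-record noise draws are
#'   identical between the two, so they produce the same chains up to
#'   floating-point rounding.
#' @return matrix `n_gene x length(records)` of predicted profiles, with
#'   record names as column names.
#' @export
predictPerturbed <- function(model, pe, sched, embeddings,
                             records = seq_len(ncol(pe)), seed = 1L,
                             backend = c("cpp", "r")) {
  backend <- match.arg(backend)
  cfg <- model@config
  if (nrow(pe) != cfg@n_gene) stop("gene panel does not match model config")
  cpre_all <- controlMatrix(pe)
  keys <- embeddingKey(drugIds(pe), doseUm(pe))
  rec_seed <- function(j) (seed * 1009L + j) %% .Machine$integer.max
  for (k in unique(keys[records])) {
    if (is.null(embeddings[[k]])) stop("missing embedding for key ", k)
  }
  if (backend == "r") {
    out <- matrix(NA_real_, cfg@n_gene, length(records))
    for (i in seq_along(records)) {
      j <- records[i]
      pert <- embeddings[[keys[j]]]
      cpre <- cpre_all[, j]
      predictor <- function(x, t) {
        denoiser_forward(model@params, cfg, x, cpre, pert, t)$eps_hat
      }
      out[, i] <- sampleDiffusion(predictor, cfg@n_gene, sched,
                                  seed = rec_seed(j))
    }
  } else {
    # One synchronous reverse chain over all records; each record's noise
    # sequence is drawn under its own derived seed in the same order as the
    # per-record reference path (x_T first, then z for t = T..2).
    B <- length(records)
    steps <- sched@steps
    noise <- lapply(records, function(j) {
      with_seed(rec_seed(j), matrix(stats::rnorm(cfg@n_gene * steps),
                                    cfg@n_gene, steps))
    })
    X <- vapply(noise, function(nz) nz[, 1L], numeric(cfg@n_gene))
    X <- matrix(X, cfg@n_gene, B)
    CPRE <- cpre_all[, records, drop = FALSE]
    perts <- lapply(keys[records], function(k) embeddings[[k]])
    payloads <- lapply(perts, .pert_payload)
    cfgl <- .cfg_as_list(cfg)
    for (t in seq(steps, 1L)) {
      EH <- cpp_forward_batch(model@params, cfgl, X, CPRE, payloads,
                              rep(as.integer(t), B))
      X <- (X - sched@beta[t] / sqrt(1 - sched@alpha_bar[t]) * EH) /
        sqrt(sched@alpha[t])
      if (t > 1L) {
        Z <- vapply(noise, function(nz) nz[, steps - t + 2L],
                    numeric(cfg@n_gene))
        X <- X + sched@sigma[t] * matrix(Z, cfg@n_gene, B)
      }
    }
    out <- X
  }
  colnames(out) <- colnames(pe)[records]
  rownames(out) <- rownames(pe)
  out
}
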