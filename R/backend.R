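# Glue between the R reference implementation of the denoiser and the
# compiled fast path. Both backends implement identical mathematics; the
# test suite asserts their agreement, and training/sampling default to the
# compiled one.

.cfg_as_list <- function(cfg) {
  list(variant = cfg@variant, n_gene = cfg@n_gene, d_model = cfg@d_model,
       n_layers = cfg@n_layers, n_heads = cfg@n_heads, d_ff = cfg@d_ff)
}

## Payload the compiled backend consumes for one perturbation: valid token
## rows for cross-attention variants, a 1 x d row matrix for adadit.
.pert_payload <- function(pert) {
  if (is(pert, "TextEmbedding")) pert@tokens[pert@mask, , drop = FALSE]
  else matrix(as.numeric(pert), nrow = 1L)
}

## Loss + summed gradients for a batch, R reference backend.
.loss_grad_batch_r <- function(par, cfg, XT, CPRE, perts, tvec, EPS) {
  gsum <- NULL
  loss <- 0
  for (b in seq_len(ncol(XT))) {
    lg <- denoiser_loss_grad(par, cfg, XT[, b], CPRE[, b], perts[[b]],
                             tvec[b], EPS[, b])
    loss <- loss + lg$loss
    if (is.null(gsum)) gsum <- lg$grads
    else for (n in names(gsum)) gsum[[n]] <- gsum[[n]] + lg$grads[[n]]
  }
  list(loss = loss, grads = gsum)
}

.loss_grad_batch <- function(par, cfg, XT, CPRE, perts, tvec, EPS,
                             backend = "cpp") {
  if (backend == "cpp") {
    cpp_loss_grad_batch(par, .cfg_as_list(cfg), XT, CPRE,
                        lapply(perts, .pert_payload), as.integer(tvec), EPS)
  } else {
    .loss_grad_batch_r(par, cfg, XT, CPRE, perts, tvec, EPS)
  }
}

.forward_batch <- function(par, cfg, XT, CPRE, perts, tvec, backend = "cpp") {
  if (backend == "cpp") {
    cpp_forward_batch(par, .cfg_as_list(cfg), XT, CPRE,
                      lapply(perts, .pert_payload), as.integer(tvec))
  } else {
    out <- matrix(NA_real_, cfg@n_gene, ncol(XT))
    for (b in seq_len(ncol(XT))) {
      out[, b] <- denoiser_forward(par, cfg, XT[, b], CPRE[, b], perts[[b]],
                                   tvec[b])$eps_hat
    }
    out
  }
}
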