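#' Create a denoiser configuration
#'
#' @param variant one of `"crossdit"`, `"catcrossdit"`, `"adadit"`,
#'   `"catonlycrossdit"`.
#' @param n_gene gene-panel size.
#' @param d_model token width (default 128).
#' @param n_layers stacked transformer layers (default 4).
#' @param n_heads attention heads (default 4; must divide `d_model`).
#' @param d_text perturbation embedding width (stub default 64; for
#'   `pert_input = "fingerprint"` this is the folded fingerprint length).
#' @param max_tokens pad/truncate length for token embeddings.
#' @param d_ff feed-forward hidden width (default `4 * d_model`).
#' @param pert_input `"text_tokens"` (cross-attention variants),
#'   `"text_pooled"` or `"fingerprint"` (adadit).
#' @return a [DenoiserConfig-class].
#' @export
denoiserConfig <- function(variant, n_gene, d_model = 128L, n_layers = 4L,
                           n_heads = 4L, d_text = 64L, max_tokens = 32L,
                           d_ff = 4L * d_model,
                           pert_input = if (variant == "adadit") "text_pooled" else "text_tokens") {
  new("DenoiserConfig", variant = variant, n_gene = as.integer(n_gene),
      d_model = as.integer(d_model), n_layers = as.integer(n_layers),
      n_heads = as.integer(n_heads), d_text = as.integer(d_text),
      max_tokens = as.integer(max_tokens), d_ff = as.integer(d_ff),
      pert_input = pert_input)
}

add_rowvec <- function(M, v) M + rep(v, each = nrow(M))
scale_rowvec <- function(M, v) M * rep(v, each = nrow(M))

pk <- function(...) paste(..., sep = ".")

.attn_param_names <- function(pre) {
  as.vector(outer(c("Wq", "Wk", "Wv", "Wo", "bq", "bk", "bv", "bo"), pre,
                  function(a, b) pk(b, a)))
}

## Block layout per variant: which sublayer parameter groups each layer owns.
.layer_blocks <- function(variant) {
  switch(variant,
    crossdit = c("ca1", "ca2", "ffn"),
    catcrossdit = c("sa", "ca", "ffn"),
    catonlycrossdit = c("ca", "ffn"),
    adadit = c("sa", "ffn", "ada"))
}

#' Initialise a denoiser model
#'
#' Weights are seeded Gaussian with 1/sqrt(fan-in) scale; the AdaLN
#' modulation map is zero-initialised (so modulation starts at the identity
#' scale with closed gates) and the output head starts small, following
#' common diffusion-transformer practice. The gene-positional table starts
#' at sd 0.3 — large enough that attention can tell genes apart from the
#' first step, which matters when per-gene information must be retrieved
#' from a condition stream by cross-attention.
#'
#' @param config a [DenoiserConfig-class].
#' @param seed integer initialisation seed.
#' @return a [DenoiserModel-class].
#' @export
initDenoiser <- function(config, seed = 1L) {
  d <- config@d_model
  ng <- config@n_gene
  par <- list()
  with_seed(seed, {
    gmat <- function(nr, nc, fan = nr) {
      matrix(stats::rnorm(nr * nc, sd = 1 / sqrt(fan)), nr, nc)
    }
    par[["pos"]] <- matrix(stats::rnorm(ng * d, sd = 0.3), ng, d)
    par[["t.W1"]] <- gmat(d, d); par[["t.b1"]] <- numeric(d)
    par[["t.W2"]] <- gmat(d, d); par[["t.b2"]] <- numeric(d)
    if (config@variant == "crossdit") {
      par[["ax.W"]] <- gmat(1L, d, fan = 1L); par[["ax.b"]] <- numeric(d)
      par[["ac.W"]] <- gmat(1L, d, fan = 1L); par[["ac.b"]] <- numeric(d)
    } else {
      par[["ax.W"]] <- gmat(2L, d, fan = 2L); par[["ax.b"]] <- numeric(d)
    }
    if (config@variant == "adadit") {
      par[["ap.W1"]] <- gmat(config@d_text, d); par[["ap.b1"]] <- numeric(d)
      par[["ap.W2"]] <- gmat(d, d); par[["ap.b2"]] <- numeric(d)
    } else {
      par[["ap.W"]] <- gmat(config@d_text, d); par[["ap.b"]] <- numeric(d)
    }
    for (l in seq_len(config@n_layers)) {
      for (blk in .layer_blocks(config@variant)) {
        pre <- pk(paste0("L", l), blk)
        if (blk %in% c("ca1", "ca2", "ca", "sa")) {
          for (w in c("Wq", "Wk", "Wv", "Wo")) par[[pk(pre, w)]] <- gmat(d, d)
          for (b in c("bq", "bk", "bv", "bo")) par[[pk(pre, b)]] <- numeric(d)
        } else if (blk == "ffn") {
          par[[pk(pre, "W1")]] <- gmat(d, config@d_ff); par[[pk(pre, "b1")]] <- numeric(config@d_ff)
          par[[pk(pre, "W2")]] <- gmat(config@d_ff, d); par[[pk(pre, "b2")]] <- numeric(d)
        } else { # ada: zero-init -> identity scale, closed gates
          par[[pk(pre, "W")]] <- matrix(0, d, 6L * d)
          par[[pk(pre, "b")]] <- numeric(6L * d)
        }
      }
    }
    par[["head.w"]] <- stats::rnorm(d, sd = 0.02)
    par[["head.b"]] <- 0
  })
  new("DenoiserModel", config = config, params = par)
}

#' Fill every weight array with independent Gaussian noise
#'
#' Used by oracle-style tests (gradient checks, permutation properties)
#' that need a generic position in weight space.
#'
#' @param model a [DenoiserModel-class].
#' @param sd Gaussian standard deviation.
#' @param seed integer seed.
#' @return the model with randomised parameters.
#' @export
randomizeParams <- function(model, sd = 0.2, seed = 1L) {
  with_seed(seed, {
    model@params <- lapply(model@params, function(p) {
      q <- stats::rnorm(length(p), sd = sd)
      if (is.matrix(p)) matrix(q, nrow(p), ncol(p)) else q
    })
  })
  model
}

#' Set all attention and feed-forward weights to zero
#'
#' Leaves adapters, positional table, timestep MLP and head untouched, so
#' each layer reduces to the residual identity.
#'
#' @param model a [DenoiserModel-class].
#' @return the modified model.
#' @export
zeroSublayerParams <- function(model) {
  idx <- grep("^L[0-9]+\\.", names(model@params))
  for (i in idx) model@params[[i]][] <- 0
  model
}

#' Sinusoidal timestep embedding through the T-adapter
#'
#' Fixed interleaved sine/cosine encoding of the timestep followed by the
#' learnable two-layer MLP of the model's T-adapter.
#'
#' @param t timestep (>= 0).
#' @param par parameter list (needs `t.W1`, `t.b1`, `t.W2`, `t.b2`).
#' @param d_model encoding width.
#' @return list with `sinusoid`, the pre-activation `a1`, hidden `h`, and
#'   the final `emb` (numeric vector of length `d_model`).
#' @export
timestepEmbed <- function(t, par, d_model) {
  ts <- matrix(timestep_sinusoid(t, d_model), 1L)
  a1 <- add_rowvec(ts %*% par[["t.W1"]], par[["t.b1"]])
  h <- silu(a1)
  emb <- add_rowvec(h %*% par[["t.W2"]], par[["t.b2"]])
  list(sinusoid = ts, a1 = a1, h = h, emb = as.numeric(emb))
}

## Multi-head scaled-dot-product attention. Queries from `Qin`, keys/values
## from `Cin`; `mask` (logical over Cin rows) excludes padding keys.
mha_forward <- function(par, pre, Qin, Cin, n_heads, mask = NULL) {
  d <- ncol(Qin)
  dh <- d %/% n_heads
  if (!is.null(mask) && !any(mask)) stop("attention mask excludes every context token")
  Q <- add_rowvec(Qin %*% par[[pk(pre, "Wq")]], par[[pk(pre, "bq")]])
  K <- add_rowvec(Cin %*% par[[pk(pre, "Wk")]], par[[pk(pre, "bk")]])
  V <- add_rowvec(Cin %*% par[[pk(pre, "Wv")]], par[[pk(pre, "bv")]])
  O <- matrix(0, nrow(Qin), d)
  P_list <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1L) * dh + 1L):(h * dh)
    S <- tcrossprod(Q[, idx, drop = FALSE], K[, idx, drop = FALSE]) / sqrt(dh)
    if (!is.null(mask)) S[, !mask] <- -Inf
    P <- softmax_rows(S)
    P_list[[h]] <- P
    O[, idx] <- P %*% V[, idx, drop = FALSE]
  }
  out <- add_rowvec(O %*% par[[pk(pre, "Wo")]], par[[pk(pre, "bo")]])
  list(out = out, Q = Q, K = K, V = V, P = P_list, O = O, Qin = Qin, Cin = Cin)
}

ffn_forward <- function(par, pre, X) {
  A1 <- add_rowvec(X %*% par[[pk(pre, "W1")]], par[[pk(pre, "b1")]])
  H <- silu(A1)
  out <- add_rowvec(H %*% par[[pk(pre, "W2")]], par[[pk(pre, "b2")]])
  list(out = out, X = X, A1 = A1, H = H)
}

## Adapt raw inputs into token sets: transcriptome tokens receive the gene
## positional table and the broadcast time embedding; perturbation tokens
## receive the time embedding only.
adaptInputs <- function(par, cfg, x_t, c_pre, pert, t_emb) {
  d <- cfg@d_model
  out <- list()
  if (cfg@variant == "crossdit") {
    Hx <- matrix(x_t, ncol = 1L) %*% par[["ax.W"]]
    Hx <- add_rowvec(add_rowvec(Hx, par[["ax.b"]]) + par[["pos"]], t_emb)
    Hc <- matrix(c_pre, ncol = 1L) %*% par[["ac.W"]]
    Hc <- add_rowvec(add_rowvec(Hc, par[["ac.b"]]) + par[["pos"]], t_emb)
    out$H0 <- Hx
    out$Hc0 <- Hc
  } else {
    XC <- cbind(x_t, c_pre)
    H <- XC %*% par[["ax.W"]]
    out$H0 <- add_rowvec(add_rowvec(H, par[["ax.b"]]) + par[["pos"]], t_emb)
    out$XC <- XC
  }
  if (cfg@variant == "adadit") {
    pv <- matrix(as.numeric(pert), 1L)
    a1 <- add_rowvec(pv %*% par[["ap.W1"]], par[["ap.b1"]])
    h <- silu(a1)
    cvec <- add_rowvec(h %*% par[["ap.W2"]], par[["ap.b2"]])
    out$pv <- pv; out$p_a1 <- a1; out$p_h <- h
    out$cond <- matrix(t_emb + as.numeric(cvec), 1L)
  } else {
    stopifnot(is(pert, "TextEmbedding"))
    P0 <- add_rowvec(add_rowvec(pert@tokens %*% par[["ap.W"]], par[["ap.b"]]), t_emb)
    out$P0 <- P0
    out$ptokens <- pert@tokens
    out$mask <- pert@mask
  }
  out
}

## Split the 6*d AdaLN modulation row into its two (gamma, beta, alpha)
## sets; gamma is parameterised as 1 + raw so a zero map is the identity.
.ada_split <- function(raw, d) {
  r <- as.numeric(raw)
  list(g1 = 1 + r[1:d], b1 = r[(d + 1):(2 * d)], a1 = r[(2 * d + 1):(3 * d)],
       g2 = 1 + r[(3 * d + 1):(4 * d)], b2 = r[(4 * d + 1):(5 * d)],
       a2 = r[(5 * d + 1):(6 * d)])
}

#' Adaptive layer-normalization modulation
#'
#' `stage = "scale_shift"` applies `gamma * x + beta` (broadcast over
#' positions); `stage = "gate"` applies `alpha * x`.
#'
#' @param x token matrix (`positions x d_model`).
#' @param params list with `gamma`, `beta`, `alpha` vectors of width
#'   `d_model` (as produced from the perturbation vector).
#' @param stage `"scale_shift"` or `"gate"`.
#' @return modulated token matrix.
#' @export
adalnModulate <- function(x, params, stage = c("scale_shift", "gate")) {
  stage <- match.arg(stage)
  if (stage == "scale_shift") {
    if (length(params$gamma) != ncol(x)) stop("modulation width mismatch")
    add_rowvec(scale_rowvec(x, params$gamma), params$beta)
  } else {
    if (length(params$alpha) != ncol(x)) stop("modulation width mismatch")
    scale_rowvec(x, params$alpha)
  }
}

## Full forward pass of the epsilon-predictor. Returns eps_hat and, when
## keep_cache, every intermediate needed by the backward pass.
denoiser_forward <- function(par, cfg, x_t, c_pre, pert, t, keep_cache = FALSE) {
  d <- cfg@d_model
  ng <- cfg@n_gene
  if (length(x_t) != ng || length(c_pre) != ng) stop("gene-panel length mismatch")
  te <- timestepEmbed(t, par, d)
  ad <- adaptInputs(par, cfg, x_t, c_pre, pert, te$emb)
  H <- ad$H0
  layers <- vector("list", cfg@n_layers)
  for (l in seq_len(cfg@n_layers)) {
    Lp <- paste0("L", l)
    lc <- list()
    if (cfg@variant == "crossdit") {
      lc$ln1 <- ln_forward(H)
      lc$at1 <- mha_forward(par, pk(Lp, "ca1"), lc$ln1$y, ad$Hc0, cfg@n_heads)
      H <- H + lc$at1$out
      lc$ln2 <- ln_forward(H)
      lc$at2 <- mha_forward(par, pk(Lp, "ca2"), lc$ln2$y, ad$P0, cfg@n_heads, ad$mask)
      H <- H + lc$at2$out
      lc$ln3 <- ln_forward(H)
      lc$ff <- ffn_forward(par, pk(Lp, "ffn"), lc$ln3$y)
      H <- H + lc$ff$out
    } else if (cfg@variant == "catcrossdit") {
      lc$ln1 <- ln_forward(H)
      lc$at1 <- mha_forward(par, pk(Lp, "sa"), lc$ln1$y, lc$ln1$y, cfg@n_heads)
      H <- H + lc$at1$out
      lc$ln2 <- ln_forward(H)
      lc$at2 <- mha_forward(par, pk(Lp, "ca"), lc$ln2$y, ad$P0, cfg@n_heads, ad$mask)
      H <- H + lc$at2$out
      lc$ln3 <- ln_forward(H)
      lc$ff <- ffn_forward(par, pk(Lp, "ffn"), lc$ln3$y)
      H <- H + lc$ff$out
    } else if (cfg@variant == "catonlycrossdit") {
      lc$ln2 <- ln_forward(H)
      lc$at2 <- mha_forward(par, pk(Lp, "ca"), lc$ln2$y, ad$P0, cfg@n_heads, ad$mask)
      H <- H + lc$at2$out
      lc$ln3 <- ln_forward(H)
      lc$ff <- ffn_forward(par, pk(Lp, "ffn"), lc$ln3$y)
      H <- H + lc$ff$out
    } else { # adadit
      lc$raw <- add_rowvec(ad$cond %*% par[[pk(Lp, "ada.W")]], par[[pk(Lp, "ada.b")]])
      md <- .ada_split(lc$raw, d)
      lc$md <- md
      lc$ln1 <- ln_forward(H)
      M1 <- add_rowvec(scale_rowvec(lc$ln1$y, md$g1), md$b1)
      lc$M1 <- M1
      lc$at1 <- mha_forward(par, pk(Lp, "sa"), M1, M1, cfg@n_heads)
      H <- H + scale_rowvec(lc$at1$out, md$a1)
      lc$ln2 <- ln_forward(H)
      M2 <- add_rowvec(scale_rowvec(lc$ln2$y, md$g2), md$b2)
      lc$M2 <- M2
      lc$ff <- ffn_forward(par, pk(Lp, "ffn"), M2)
      H <- H + scale_rowvec(lc$ff$out, md$a2)
    }
    layers[[l]] <- lc
  }
  lnf <- ln_forward(H)
  eps_hat <- as.numeric(lnf$y %*% par[["head.w"]]) + par[["head.b"]]
  if (!keep_cache) return(list(eps_hat = eps_hat))
  list(eps_hat = eps_hat, te = te, ad = ad, layers = layers, lnf = lnf,
       x_t = x_t, c_pre = c_pre)
}

#' Predict the noise component of a noisy profile
#'
#' Runs the configured transformer denoiser
#' `eps_theta(x_t, t | c_pre, c_pert)`.
#'
#' @param model a [DenoiserModel-class].
#' @param x_t noisy profile vector (length `n_gene`).
#' @param t timestep.
#' @param c_pre paired control profile vector.
#' @param pert perturbation input: a [TextEmbedding-class] for token
#'   variants, or a numeric vector (pooled text or fingerprint) for adadit.
#' @return numeric vector `eps_hat` of length `n_gene`.
#' @export
predictNoise <- function(model, x_t, t, c_pre, pert) {
  denoiser_forward(model@params, model@config, x_t, c_pre, pert, t)$eps_hat
}
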