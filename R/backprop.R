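# Reverse-mode gradients for the transformer denoiser. Each function here
# mirrors a forward function in denoiser.R and consumes its cache; the full
# pass is validated against central finite differences in the test suite.

mha_backward <- function(par, pre, cache, dout, n_heads) {
  d <- ncol(cache$O)
  dh <- d %/% n_heads
  dbo <- colSums(dout)
  dWo <- crossprod(cache$O, dout)
  dO <- tcrossprod(dout, par[[pk(pre, "Wo")]])
  dQ <- matrix(0, nrow(cache$Q), d)
  dK <- matrix(0, nrow(cache$K), d)
  dV <- matrix(0, nrow(cache$V), d)
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1L) * dh + 1L):(h * dh)
    P <- cache$P[[h]]
    dO_h <- dO[, idx, drop = FALSE]
    dP <- tcrossprod(dO_h, cache$V[, idx, drop = FALSE])
    dV[, idx] <- crossprod(P, dO_h)
    dS <- softmax_rows_backward(P, dP) / sqrt(dh)
    dQ[, idx] <- dS %*% cache$K[, idx, drop = FALSE]
    dK[, idx] <- crossprod(dS, cache$Q[, idx, drop = FALSE])
  }
  grads <- list()
  grads[[pk(pre, "Wq")]] <- crossprod(cache$Qin, dQ)
  grads[[pk(pre, "bq")]] <- colSums(dQ)
  grads[[pk(pre, "Wk")]] <- crossprod(cache$Cin, dK)
  grads[[pk(pre, "bk")]] <- colSums(dK)
  grads[[pk(pre, "Wv")]] <- crossprod(cache$Cin, dV)
  grads[[pk(pre, "bv")]] <- colSums(dV)
  grads[[pk(pre, "Wo")]] <- dWo
  grads[[pk(pre, "bo")]] <- dbo
  dQin <- tcrossprod(dQ, par[[pk(pre, "Wq")]])
  dCin <- tcrossprod(dK, par[[pk(pre, "Wk")]]) + tcrossprod(dV, par[[pk(pre, "Wv")]])
  list(dQin = dQin, dCin = dCin, grads = grads)
}

ffn_backward <- function(par, pre, cache, dout) {
  dH <- tcrossprod(dout, par[[pk(pre, "W2")]])
  dA1 <- dH * silu_grad(cache$A1)
  grads <- list()
  grads[[pk(pre, "W2")]] <- crossprod(cache$H, dout)
  grads[[pk(pre, "b2")]] <- colSums(dout)
  grads[[pk(pre, "W1")]] <- crossprod(cache$X, dA1)
  grads[[pk(pre, "b1")]] <- colSums(dA1)
  list(dX = tcrossprod(dA1, par[[pk(pre, "W1")]]), grads = grads)
}

## Gradient of a scalar loss w.r.t. every parameter array, given the
## gradient d_eps of the loss w.r.t. the predicted noise vector.
denoiser_backward <- function(par, cfg, cache, d_eps) {
  d <- cfg@d_model
  gz <- lapply(par, function(p) p * 0)
  acc <- function(lst) for (n in names(lst)) gz[[n]] <<- gz[[n]] + lst[[n]]

  Hn <- cache$lnf$y
  gz[["head.w"]] <- gz[["head.w"]] + as.numeric(crossprod(Hn, d_eps))
  gz[["head.b"]] <- gz[["head.b"]] + sum(d_eps)
  dH <- ln_backward(cache$lnf, outer(d_eps, par[["head.w"]]))

  ad <- cache$ad
  dHc0 <- if (cfg@variant == "crossdit") ad$Hc0 * 0 else NULL
  dP0 <- if (cfg@variant != "adadit") ad$P0 * 0 else NULL
  dcond <- if (cfg@variant == "adadit") matrix(0, 1L, d) else NULL

  for (l in rev(seq_len(cfg@n_layers))) {
    Lp <- paste0("L", l)
    lc <- cache$layers[[l]]
    if (cfg@variant %in% c("crossdit", "catcrossdit", "catonlycrossdit")) {
      fb <- ffn_backward(par, pk(Lp, "ffn"), lc$ff, dH)
      acc(fb$grads)
      dH <- dH + ln_backward(lc$ln3, fb$dX)
      ca_pre <- pk(Lp, if (cfg@variant == "crossdit") "ca2" else "ca")
      ab <- mha_backward(par, ca_pre, lc$at2, dH, cfg@n_heads)
      acc(ab$grads)
      dH <- dH + ln_backward(lc$ln2, ab$dQin)
      dP0 <- dP0 + ab$dCin
      if (cfg@variant == "crossdit") {
        ab1 <- mha_backward(par, pk(Lp, "ca1"), lc$at1, dH, cfg@n_heads)
        acc(ab1$grads)
        dH <- dH + ln_backward(lc$ln1, ab1$dQin)
        dHc0 <- dHc0 + ab1$dCin
      } else if (cfg@variant == "catcrossdit") {
        ab1 <- mha_backward(par, pk(Lp, "sa"), lc$at1, dH, cfg@n_heads)
        acc(ab1$grads)
        dH <- dH + ln_backward(lc$ln1, ab1$dQin + ab1$dCin)
      }
    } else { # adadit
      md <- lc$md
      dG2 <- dH
      d_a2 <- colSums(dG2 * lc$ff$out)
      fb <- ffn_backward(par, pk(Lp, "ffn"), lc$ff, scale_rowvec(dG2, md$a2))
      acc(fb$grads)
      d_g2 <- colSums(fb$dX * lc$ln2$y)
      d_b2 <- colSums(fb$dX)
      dH <- dH + ln_backward(lc$ln2, scale_rowvec(fb$dX, md$g2))
      dG1 <- dH
      d_a1 <- colSums(dG1 * lc$at1$out)
      ab <- mha_backward(par, pk(Lp, "sa"), lc$at1, scale_rowvec(dG1, md$a1),
                         cfg@n_heads)
      acc(ab$grads)
      dM1 <- ab$dQin + ab$dCin
      d_g1 <- colSums(dM1 * lc$ln1$y)
      d_b1 <- colSums(dM1)
      dH <- dH + ln_backward(lc$ln1, scale_rowvec(dM1, md$g1))
      draw <- matrix(c(d_g1, d_b1, d_a1, d_g2, d_b2, d_a2), 1L)
      gz[[pk(Lp, "ada.W")]] <- gz[[pk(Lp, "ada.W")]] + crossprod(ad$cond, draw)
      gz[[pk(Lp, "ada.b")]] <- gz[[pk(Lp, "ada.b")]] + as.numeric(draw)
      dcond <- dcond + tcrossprod(draw, par[[pk(Lp, "ada.W")]])
    }
  }

  d_t_emb <- numeric(d)
  if (cfg@variant == "crossdit") {
    gz[["ax.W"]] <- gz[["ax.W"]] + crossprod(matrix(cache$x_t, ncol = 1L), dH)
    gz[["ax.b"]] <- gz[["ax.b"]] + colSums(dH)
    gz[["ac.W"]] <- gz[["ac.W"]] + crossprod(matrix(cache$c_pre, ncol = 1L), dHc0)
    gz[["ac.b"]] <- gz[["ac.b"]] + colSums(dHc0)
    gz[["pos"]] <- gz[["pos"]] + dH + dHc0
    d_t_emb <- d_t_emb + colSums(dH) + colSums(dHc0)
  } else {
    gz[["ax.W"]] <- gz[["ax.W"]] + crossprod(ad$XC, dH)
    gz[["ax.b"]] <- gz[["ax.b"]] + colSums(dH)
    gz[["pos"]] <- gz[["pos"]] + dH
    d_t_emb <- d_t_emb + colSums(dH)
  }
  if (cfg@variant == "adadit") {
    d_t_emb <- d_t_emb + as.numeric(dcond)
    gz[["ap.W2"]] <- gz[["ap.W2"]] + crossprod(ad$p_h, dcond)
    gz[["ap.b2"]] <- gz[["ap.b2"]] + as.numeric(dcond)
    dh_ <- tcrossprod(dcond, par[["ap.W2"]])
    da1 <- dh_ * silu_grad(ad$p_a1)
    gz[["ap.W1"]] <- gz[["ap.W1"]] + crossprod(ad$pv, da1)
    gz[["ap.b1"]] <- gz[["ap.b1"]] + as.numeric(da1)
  } else {
    gz[["ap.W"]] <- gz[["ap.W"]] + crossprod(ad$ptokens, dP0)
    gz[["ap.b"]] <- gz[["ap.b"]] + colSums(dP0)
    d_t_emb <- d_t_emb + colSums(dP0)
  }
  dm <- matrix(d_t_emb, 1L)
  gz[["t.b2"]] <- gz[["t.b2"]] + d_t_emb
  gz[["t.W2"]] <- gz[["t.W2"]] + crossprod(cache$te$h, dm)
  dth <- tcrossprod(dm, par[["t.W2"]])
  dta1 <- dth * silu_grad(cache$te$a1)
  gz[["t.W1"]] <- gz[["t.W1"]] + crossprod(cache$te$sinusoid, dta1)
  gz[["t.b1"]] <- gz[["t.b1"]] + as.numeric(dta1)
  gz
}

## Loss and gradients for one training example.
denoiser_loss_grad <- function(par, cfg, x_t, c_pre, pert, t, eps_true) {
  fw <- denoiser_forward(par, cfg, x_t, c_pre, pert, t, keep_cache = TRUE)
  diff <- fw$eps_hat - eps_true
  loss <- sum(diff * diff)
  grads <- denoiser_backward(par, cfg, fw, 2 * diff)
  list(loss = loss, grads = grads)
}
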