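test_that("denoiser configs validate their invariants", {
  expect_error(denoiserConfig("adadit", 10L, pert_input = "text_tokens"),
               "vector-like")
  expect_error(denoiserConfig("crossdit", 10L, pert_input = "fingerprint"),
               "text_tokens")
  expect_error(denoiserConfig("crossdit", 10L, d_model = 10L, n_heads = 4L),
               "divisible")
  expect_error(denoiserConfig("nope", 10L), "unknown variant")
})

test_that("timestep embedding follows the sinusoidal convention", {
  cfg <- tiny_config()
  m <- initDenoiser(cfg, seed = 1)
  sin0 <- DiffPert:::timestep_sinusoid(0, cfg@d_model)
  expect_equal(sin0[seq_len(cfg@d_model / 2)], rep(0, cfg@d_model / 2))
  expect_equal(sin0[-seq_len(cfg@d_model / 2)], rep(1, cfg@d_model / 2))
  e1 <- timestepEmbed(1, m@params, cfg@d_model)
  e1b <- timestepEmbed(1, m@params, cfg@d_model)
  e2 <- timestepEmbed(2, m@params, cfg@d_model)
  expect_identical(e1$emb, e1b$emb)
  expect_false(identical(e1$emb, e2$emb))
  expect_length(e1$emb, cfg@d_model)
})

test_that("single-context-token cross-attention returns the value projection", {
  cfg <- tiny_config()
  m <- randomizeParams(initDenoiser(cfg), sd = 0.4, seed = 2)
  d <- cfg@d_model
  Qin <- matrix(rnorm(3 * d), 3, d)
  Cin <- matrix(rnorm(d), 1, d)
  out <- DiffPert:::mha_forward(m@params, "L1.sa", Qin, Cin, cfg@n_heads)$out
  vproj <- (Cin %*% m@params[["L1.sa.Wv"]] + rep(m@params[["L1.sa.bv"]], each = 1)) %*%
    m@params[["L1.sa.Wo"]] + rep(m@params[["L1.sa.bo"]], each = 1)
  for (i in 1:3) expect_equal(out[i, ], vproj[1, ], tolerance = 1e-12)
})

test_that("identical key projections average the value projections", {
  cfg <- tiny_config()
  m <- randomizeParams(initDenoiser(cfg), sd = 0.4, seed = 3)
  m@params[["L1.sa.Wk"]][] <- 0  # all keys identical -> uniform attention
  d <- cfg@d_model
  Qin <- matrix(rnorm(2 * d), 2, d)
  Cin <- matrix(rnorm(2 * d), 2, d)
  out <- DiffPert:::mha_forward(m@params, "L1.sa", Qin, Cin, cfg@n_heads)$out
  V <- Cin %*% m@params[["L1.sa.Wv"]] + rep(m@params[["L1.sa.bv"]], each = 2)
  expected <- (colMeans(V) %*% m@params[["L1.sa.Wo"]])[1, ] + m@params[["L1.sa.bo"]]
  expect_equal(out[1, ], expected, tolerance = 1e-12)
  expect_equal(out[2, ], expected, tolerance = 1e-12)
})

test_that("hand-computed toy attention matches", {
  # 1 head, d_model = 2, 1 query, 2 keys, hand-set weights, no biases
  par <- list(`A.Wq` = diag(2), `A.Wk` = diag(2), `A.Wv` = diag(2),
              `A.Wo` = diag(2), `A.bq` = c(0, 0), `A.bk` = c(0, 0),
              `A.bv` = c(0, 0), `A.bo` = c(0, 0))
  Qin <- matrix(c(1, 0), 1, 2)
  Cin <- rbind(c(1, 0), c(0, 1))
  out <- DiffPert:::mha_forward(par, "A", Qin, Cin, 1L)$out
  # scores = (1, 0)/sqrt(2); softmax = (w, 1-w)
  w <- exp(1 / sqrt(2)) / (exp(1 / sqrt(2)) + exp(0))
  expect_equal(out[1, ], w * c(1, 0) + (1 - w) * c(0, 1), tolerance = 1e-12)
})

test_that("a fully masked context errors", {
  cfg <- tiny_config()
  m <- initDenoiser(cfg, seed = 1)
  Qin <- matrix(rnorm(2 * cfg@d_model), 2, cfg@d_model)
  expect_error(
    DiffPert:::mha_forward(m@params, "L1.sa", Qin, Qin, cfg@n_heads,
                           mask = c(FALSE, FALSE)),
    "mask excludes every context token")
})

test_that("AdaLN modulation follows scale-shift and gate formulas", {
  x <- matrix(0.5, 1, 4)
  p <- list(gamma = rep(1, 4), beta = rep(0, 4), alpha = rep(0, 4))
  expect_equal(adalnModulate(x, p, "scale_shift"), x)
  expect_equal(adalnModulate(x, p, "gate"), x * 0)
  p2 <- list(gamma = rep(2, 4), beta = rep(1, 4), alpha = rep(3, 4))
  expect_equal(adalnModulate(x, p2, "scale_shift"), matrix(2, 1, 4))
  expect_equal(adalnModulate(x, p2, "gate"), matrix(1.5, 1, 4))
  expect_error(adalnModulate(x, list(gamma = 1:2, beta = 1:2, alpha = 1:2)),
               "width mismatch")
})

test_that("zero attention/FFN weights reduce every variant to the residual identity head", {
  for (v in all_variants) {
    cfg <- tiny_config(v)
    m <- randomizeParams(initDenoiser(cfg), sd = 0.3, seed = 5)
    m <- zeroSublayerParams(m)
    pert <- tiny_pert(cfg)
    x_t <- withr::with_seed(1, rnorm(cfg@n_gene))
    c_pre <- withr::with_seed(2, rnorm(cfg@n_gene))
    out <- predictNoise(m, x_t, 3L, c_pre, pert)
    # expected: output head applied to the adapted (unchanged) input tokens
    te <- timestepEmbed(3, m@params, cfg@d_model)
    ad <- DiffPert:::adaptInputs(m@params, cfg, x_t, c_pre, pert, te$emb)
    hn <- DiffPert:::ln_forward(ad$H0)$y
    expected <- as.numeric(hn %*% m@params[["head.w"]]) + m@params[["head.b"]]
    expect_equal(out, expected, tolerance = 1e-12, label = v)
  }
})

test_that("every variant consumes its perturbation input", {
  for (v in all_variants) {
    cfg <- tiny_config(v)
    m <- randomizeParams(initDenoiser(cfg), sd = 0.3, seed = 6)
    x_t <- withr::with_seed(1, rnorm(cfg@n_gene))
    c_pre <- withr::with_seed(2, rnorm(cfg@n_gene))
    p1 <- tiny_pert(cfg)
    p2 <- if (is(p1, "TextEmbedding")) {
      embedText("different words here", d_text = cfg@d_text,
                max_tokens = cfg@max_tokens)
    } else p1 + 1
    o1 <- predictNoise(m, x_t, 2L, c_pre, p1)
    o2 <- predictNoise(m, x_t, 2L, c_pre, p2)
    expect_false(isTRUE(all.equal(o1, o2)), label = v)
    # and the control profile
    o3 <- predictNoise(m, x_t, 2L, c_pre + 0.5, p1)
    expect_false(isTRUE(all.equal(o1, o3)), label = v)
  }
})

test_that("the denoiser is deterministic and shape-correct", {
  for (v in all_variants) {
    cfg <- tiny_config(v)
    m <- initDenoiser(cfg, seed = 8)
    pert <- tiny_pert(cfg)
    x_t <- withr::with_seed(3, rnorm(cfg@n_gene))
    c_pre <- withr::with_seed(4, rnorm(cfg@n_gene))
    o1 <- predictNoise(m, x_t, 5L, c_pre, pert)
    o2 <- predictNoise(m, x_t, 5L, c_pre, pert)
    expect_identical(o1, o2)
    expect_length(o1, cfg@n_gene)
    expect_error(predictNoise(m, x_t[-1], 5L, c_pre, pert), "length mismatch")
  }
})

test_that("permuting genes together with the positional table permutes the output", {
  cfg <- tiny_config("catcrossdit", n_gene = 7L)
  m <- randomizeParams(initDenoiser(cfg), sd = 0.3, seed = 9)
  pert <- tiny_pert(cfg)
  x_t <- withr::with_seed(5, rnorm(7))
  c_pre <- withr::with_seed(6, rnorm(7))
  perm <- c(3, 1, 7, 2, 6, 4, 5)
  out <- predictNoise(m, x_t, 2L, c_pre, pert)
  m2 <- m
  m2@params[["pos"]] <- m@params[["pos"]][perm, ]
  out_p <- predictNoise(m2, x_t[perm], 2L, c_pre[perm], pert)
  expect_equal(out_p, out[perm], tolerance = 1e-10)
})

test_that("R and compiled backends agree on loss, gradients and forward", {
  for (v in all_variants) {
    cfg <- tiny_config(v)
    m <- randomizeParams(initDenoiser(cfg), sd = 0.3, seed = 10)
    pert <- tiny_pert(cfg)
    B <- 3L
    XT <- withr::with_seed(1, matrix(rnorm(cfg@n_gene * B), cfg@n_gene, B))
    CP <- withr::with_seed(2, matrix(rnorm(cfg@n_gene * B), cfg@n_gene, B))
    EPS <- withr::with_seed(3, matrix(rnorm(cfg@n_gene * B), cfg@n_gene, B))
    tv <- c(1L, 2L, 4L)
    perts <- list(pert, pert, pert)
    a <- DiffPert:::.loss_grad_batch(m@params, cfg, XT, CP, perts, tv, EPS,
                                     backend = "r")
    b <- DiffPert:::.loss_grad_batch(m@params, cfg, XT, CP, perts, tv, EPS,
                                     backend = "cpp")
    expect_equal(b$loss, a$loss, tolerance = 1e-10, label = v)
    for (n in names(a$grads)) {
      expect_equal(as.numeric(b$grads[[n]]), as.numeric(a$grads[[n]]),
                   tolerance = 1e-9, label = paste(v, n))
    }
    fa <- DiffPert:::.forward_batch(m@params, cfg, XT, CP, perts, tv,
                                    backend = "r")
    fb <- DiffPert:::.forward_batch(m@params, cfg, XT, CP, perts, tv,
                                    backend = "cpp")
    expect_equal(fb, fa, tolerance = 1e-10, label = v)
  }
})

test_that("a tiny network overfits a fixed pair (loss driven toward zero)", {
  cfg <- denoiserConfig("catcrossdit", n_gene = 8L, d_model = 16L,
                        n_layers = 2L, n_heads = 2L, d_text = 8L,
                        max_tokens = 4L, d_ff = 32L)
  ctl <- matrix(rnorm(8 * 2, 5), 8, 2)
  prt <- ctl + 0.5
  pe <- PerturbationExperiment(ctl, prt, c("CCO", "CCO"), c(10, 10), c("A", "A"))
  sched <- makeSchedule(5L, beta_start = 0.05, beta_end = 0.2)
  emb <- perturbationEmbeddings(pe, cfg, seed = 1)
  m <- initDenoiser(cfg, seed = 1)
  fit <- trainDenoiser(m, pe, sched, emb, epochs = 150L, batch_size = 2L,
                       lr = 3e-3, ema_decay = NULL, seed = 2)
  expect_lt(mean(tail(fit$losses, 10)), 0.2 * fit$losses[1])
})
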