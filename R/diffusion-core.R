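#' Build a diffusion noise schedule
#'
#' Linearly spaced variances `beta` between `beta_start` and `beta_end`,
#' with `alpha = 1 - beta`, cumulative `alpha_bar`, and the reverse-process
#' posterior standard deviation
#' `sigma[t] = sqrt((1 - alpha_bar[t-1]) / (1 - alpha_bar[t]) * beta[t])`
#' under the convention `alpha_bar[0] = 1`, which forces `sigma[1] = 0`.
#'
#' @param steps number of diffusion steps T (>= 1).
#' @param beta_start,beta_end endpoints with `0 < beta_start < beta_end < 1`
#'   (standard defaults `1e-4` and `0.02`). With `steps = 1` the single
#'   beta equals `beta_start`.
#' @param kind schedule family; only `"linear"` is provided.
#' @return a [NoiseSchedule-class].
#' @export
makeSchedule <- function(steps = 1000L, beta_start = 1e-4, beta_end = 0.02,
                         kind = c("linear")) {
  kind <- match.arg(kind)
  steps <- as.integer(steps)
  stopifnot(steps >= 1L)
  if (!(beta_start > 0 && beta_start <= beta_end && beta_end < 1)) {
    stop("need 0 < beta_start <= beta_end < 1")
  }
  if (steps > 1L && beta_start == beta_end) {
    stop("beta must be strictly increasing; raise beta_end")
  }
  beta <- if (steps == 1L) beta_start else seq(beta_start, beta_end, length.out = steps)
  alpha <- 1 - beta
  alpha_bar <- cumprod(alpha)
  alpha_bar_prev <- c(1, alpha_bar[-steps])
  sigma <- sqrt((1 - alpha_bar_prev) / (1 - alpha_bar) * beta)
  new("NoiseSchedule", steps = steps, beta = beta, alpha = alpha,
      alpha_bar = alpha_bar, sigma = sigma)
}

#' Forward diffusion (closed-form marginal)
#'
#' `x_t = sqrt(alpha_bar[t]) * x0 + sqrt(1 - alpha_bar[t]) * eps`.
#'
#' @param x0 clean profile (numeric vector).
#' @param t timestep in `1..steps`.
#' @param eps noise vector, same length as `x0`.
#' @param sched a [NoiseSchedule-class].
#' @return the noisy vector `x_t`.
#' @export
forwardDiffuse <- function(x0, t, eps, sched) {
  stopifnot(is(sched, "NoiseSchedule"), t >= 1L, t <= sched@steps)
  if (length(eps) != length(x0)) stop("eps and x0 lengths differ")
  ab <- sched@alpha_bar[t]
  sqrt(ab) * x0 + sqrt(1 - ab) * eps
}

#' Diffusion training loss
#'
#' Squared L2 norm of the difference between true and predicted noise
#' (`reduction = "sum"`, the norm of the training objective), or its
#' per-element mean (`reduction = "mean"`).
#'
#' @param eps_pred,eps_true equal-length numeric vectors.
#' @param reduction `"sum"` or `"mean"`.
#' @return non-negative scalar.
#' @export
diffusionLoss <- function(eps_pred, eps_true, reduction = c("sum", "mean")) {
  reduction <- match.arg(reduction)
  if (length(eps_pred) != length(eps_true)) stop("length mismatch")
  d <- eps_pred - eps_true
  if (reduction == "sum") sum(d * d) else mean(d * d)
}

#' One reverse diffusion step
#'
#' `x_{t-1} = (x_t - beta[t] / sqrt(1 - alpha_bar[t]) * eps_hat) /
#' sqrt(alpha[t]) + sigma[t] * z`. At `t = 1`, `sigma[1] = 0`, so the
#' output is independent of `z`.
#'
#' @param x_t current noisy vector.
#' @param t timestep in `1..steps`.
#' @param eps_hat predicted noise, same length as `x_t`.
#' @param sched a [NoiseSchedule-class].
#' @param z standard-normal vector (ignored at `t = 1`); defaults to zeros.
#' @return the vector `x_{t-1}`.
#' @export
reverseStep <- function(x_t, t, eps_hat, sched, z = NULL) {
  stopifnot(is(sched, "NoiseSchedule"), t >= 1L, t <= sched@steps)
  if (length(eps_hat) != length(x_t)) stop("eps_hat and x_t lengths differ")
  if (is.null(z)) z <- numeric(length(x_t))
  if (length(z) != length(x_t)) stop("z and x_t lengths differ")
  mu <- (x_t - sched@beta[t] / sqrt(1 - sched@alpha_bar[t]) * eps_hat) /
    sqrt(sched@alpha[t])
  mu + sched@sigma[t] * z
}

#' Ancestral sampling of a clean profile
#'
#' Starts from seeded `x_T ~ N(0, I)` and applies [reverseStep()] for
#' `t = T..1` using the supplied noise predictor. Deterministic given the
#' seed.
#'
#' @param predictor `function(x_t, t) -> eps_hat`; conditions (control
#'   profile, perturbation embedding) are typically bound into the closure.
#' @param n_gene output length.
#' @param sched a [NoiseSchedule-class].
#' @param seed integer seed for `x_T` and the per-step noise `z`.
#' @return the sampled clean vector `x0`.
#' @export
sampleDiffusion <- function(predictor, n_gene, sched, seed = 1L) {
  stopifnot(is(sched, "NoiseSchedule"))
  with_seed(seed, {
    x <- stats::rnorm(n_gene)
    for (t in seq(sched@steps, 1L)) {
      eps_hat <- tryCatch(predictor(x, t), error = function(e) {
        stop("noise predictor failed at timestep ", t, ": ",
             conditionMessage(e))
      })
      z <- if (t > 1L) stats::rnorm(n_gene) else numeric(n_gene)
      x <- reverseStep(x, t, eps_hat, sched, z)
    }
    x
  })
}

#' Serialize a noise schedule to and from JSON
#'
#' @param sched a [NoiseSchedule-class].
#' @param path JSON file path.
#' @export
writeSchedule <- function(sched, path) {
  jsonlite::write_json(
    list(steps = sched@steps, beta = sched@beta), path,
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeSchedule
#' @export
readSchedule <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  beta <- x$beta
  sched <- makeSchedule(x$steps, beta_start = beta[1L],
                        beta_end = beta[length(beta)])
  stopifnot(max(abs(sched@beta - beta)) < 1e-12)
  sched
}
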