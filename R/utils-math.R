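# Shared numerical primitives for the transformer denoiser and embedders.
# All of these are pure functions; the backward passes live in backprop.R.

.LN_EPS <- 1e-5

sigmoid <- function(x) 1 / (1 + exp(-x))

## SiLU (swish) activation; smooth, so finite-difference gradient checks are
## well behaved everywhere.
silu <- function(x) x * sigmoid(x)

silu_grad <- function(x) {
  s <- sigmoid(x)
  s * (1 + x * (1 - s))
}

## Row-wise layer normalization without learnable affine terms (the adaptive
## scale/shift of AdaLN, where used, supplies the affine part).
ln_forward <- function(x) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv_std <- 1 / sqrt(v + .LN_EPS)
  xhat <- xc * inv_std
  list(y = xhat, xhat = xhat, inv_std = inv_std)
}

ln_backward <- function(cache, dy) {
  xhat <- cache$xhat
  m1 <- rowMeans(dy)
  m2 <- rowMeans(dy * xhat)
  cache$inv_std * (dy - m1 - xhat * m2)
}

## Row-wise softmax, numerically stabilised (max.col gives the row maxima
## without the overhead of apply(); ties.method "first" keeps it exact).
softmax_rows <- function(s) {
  mx <- s[cbind(seq_len(nrow(s)), max.col(s, ties.method = "first"))]
  e <- exp(s - mx)
  e / rowSums(e)
}

softmax_rows_backward <- function(p, dp) {
  p * (dp - rowSums(dp * p))
}

## Deterministic pseudo-random unit-scale vector from an integer hash.
## Trigonometric counter-based construction: touches no RNG state, so text
## embedding is a pure function of its inputs.
hash_to_vec <- function(h, d) {
  h <- (h %% 100003) + 1
  k <- seq_len(d)
  u <- sin(h * 0.738912 + k * 2.399963) * 43758.5453
  2 * (u - floor(u)) - 1
}

## Stable 32-bit-range string hash (polynomial rolling hash).
string_hash <- function(s, seed = 0L) {
  bytes <- as.integer(charToRaw(s))
  h <- as.numeric(seed) %% 2147483647
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  h
}

## Sinusoidal timestep encoding of dimension d (d even): interleaved
## sin/cos at geometrically spaced frequencies, as used in transformer
## position encodings. t = 0 gives all sines 0 and cosines 1.
timestep_sinusoid <- function(t, d) {
  stopifnot(d %% 2L == 0L, t >= 0)
  half <- d %/% 2L
  freqs <- exp(-log(10000) * (seq_len(half) - 1L) / half)
  c(sin(t * freqs), cos(t * freqs))
}

## Run an expression under a fixed RNG seed without disturbing the caller's
## RNG stream.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

## Relative error used by gradient checks.
rel_err <- function(a, b) {
  abs(a - b) / pmax(1e-8, abs(a) + abs(b))
}
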