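# Synthetic paired-perturbation data with known ground truth, emulating the
# structure of large drug-perturbation compendia: paired controls,
# log-normalized values, dose-dependent drug effects modulated per cell line,
# and valid SMILES so the cheminformatics path is exercised end to end.

.SMILES_POOL <- c(
  "CCO", "CCC", "CCCC", "CCCCC", "CC(C)O", "CC(C)C", "CCN", "CCCN",
  "CCOC", "CCCO", "CCCCO", "CC(C)CO", "CCOCC", "CCCCN", "CC(C)N", "CCCCCC")

#' Synthetic dataset specification
#'
#' Study conditions of the synthetic generator. Defaults give a desk-scale
#' dataset of 50 genes, 12 drugs x 6 cell lines x 3 doses x 4 replicates
#' (864 records). Doses are half-decade spaced over 1-10 micromolar, a
#' typical screening range. `effect_scale` is the per-gene standard
#' deviation of drug signatures on the log-expression scale,
#' `cell_modulation_scale` the spread of the multiplicative cell-line
#' modulation around 1, `cell_baseline_sd` the per-cell-line baseline
#' offset (what lets a model infer the cell line from the control), and
#' `noise_sd` the i.i.d. measurement noise added independently to control
#' and perturbed profiles.
#'
#' @param n_gene,n_drug,n_cell,n_dose_levels,samples_per_condition counts.
#' @param effect_scale,cell_modulation_scale,cell_baseline_sd,noise_sd reals.
#' @param seed integer generator seed.
#' @return a list with class `"SyntheticSpec"`.
#' @export
syntheticSpec <- function(n_gene = 50L, n_drug = 12L, n_cell = 6L,
                          n_dose_levels = 3L, samples_per_condition = 4L,
                          effect_scale = 0.5, cell_modulation_scale = 0.3,
                          cell_baseline_sd = 0.5, noise_sd = 0.05, seed = 1L) {
  spec <- list(n_gene = as.integer(n_gene), n_drug = as.integer(n_drug),
               n_cell = as.integer(n_cell),
               n_dose_levels = as.integer(n_dose_levels),
               samples_per_condition = as.integer(samples_per_condition),
               effect_scale = effect_scale,
               cell_modulation_scale = cell_modulation_scale,
               cell_baseline_sd = cell_baseline_sd, noise_sd = noise_sd,
               seed = as.integer(seed))
  stopifnot(all(vapply(spec[1:5], function(x) x >= 1L, logical(1))),
            noise_sd >= 0, effect_scale >= 0, cell_baseline_sd >= 0)
  class(spec) <- "SyntheticSpec"
  spec
}

.synthetic_smiles <- function(n_drug) {
  if (n_drug <= length(.SMILES_POOL)) return(.SMILES_POOL[seq_len(n_drug)])
  extra <- paste0("OC", vapply(seq_len(n_drug - length(.SMILES_POOL)),
                               function(i) strrep("C", 6L + i), character(1)))
  c(.SMILES_POOL, extra)
}

.dose_key <- function(dose) format(signif(dose, 6), scientific = FALSE,
                                   trim = TRUE, drop0trailing = TRUE)

#' Generate a synthetic paired-perturbation dataset with ground truth
#'
#' Controls are drawn around cell-line-specific baselines; perturbed
#' profiles are the same baseline plus
#' `dose_response(dose) * drug_signature * cell_modulator` plus independent
#' noise, so the per-record true effect is known exactly. The dose response
#' is the monotone saturating curve `log10(1 + dose) / log10(1 + dose_max)`.
#' Drugs receive valid SMILES from a fixed small-molecule pool.
#'
#' @param spec a [syntheticSpec()].
#' @return list with `pe` (a [PerturbationExperiment-class]) and `truth`
#'   (class `"GroundTruthEffect"`: `drug_signatures`, `cell_modulators`,
#'   `dose_response`, `cell_baselines`, `spec`).
#' @export
generateDataset <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  smiles <- .synthetic_smiles(spec$n_drug)
  drug_ids <- canonicalizeSmiles(smiles)
  if (anyNA(drug_ids) || anyDuplicated(drug_ids)) {
    stop("synthetic SMILES pool failed to canonicalize to distinct drugs")
  }
  cells <- sprintf("cell%02d", seq_len(spec$n_cell))
  genes <- sprintf("g%03d", seq_len(spec$n_gene))
  doses <- 10^seq(0, 1, length.out = spec$n_dose_levels)
  with_seed(spec$seed, {
    base <- stats::rnorm(spec$n_gene, mean = 5, sd = 1)
    cell_base <- matrix(base, spec$n_cell, spec$n_gene, byrow = TRUE) +
      matrix(stats::rnorm(spec$n_cell * spec$n_gene, sd = spec$cell_baseline_sd),
             spec$n_cell, spec$n_gene)
    sig <- matrix(stats::rnorm(spec$n_drug * spec$n_gene, sd = spec$effect_scale),
                  spec$n_drug, spec$n_gene, dimnames = list(drug_ids, genes))
    mod <- 1 + matrix(stats::rnorm(spec$n_cell * spec$n_gene,
                                   sd = spec$cell_modulation_scale),
                      spec$n_cell, spec$n_gene, dimnames = list(cells, genes))
    resp <- log10(1 + doses) / log10(1 + max(doses))
    names(resp) <- .dose_key(doses)
    n_rec <- spec$n_drug * spec$n_cell * spec$n_dose_levels *
      spec$samples_per_condition
    ctl <- matrix(NA_real_, spec$n_gene, n_rec)
    prt <- matrix(NA_real_, spec$n_gene, n_rec)
    rec_smiles <- character(n_rec); rec_cell <- character(n_rec)
    rec_dose <- numeric(n_rec)
    k <- 0L
    for (d in seq_len(spec$n_drug)) {
      for (cl in seq_len(spec$n_cell)) {
        for (dz in seq_along(doses)) {
          eff <- resp[dz] * sig[d, ] * mod[cl, ]
          for (r in seq_len(spec$samples_per_condition)) {
            k <- k + 1L
            ctl[, k] <- cell_base[cl, ] +
              stats::rnorm(spec$n_gene, sd = spec$noise_sd)
            prt[, k] <- cell_base[cl, ] + eff +
              stats::rnorm(spec$n_gene, sd = spec$noise_sd)
            rec_smiles[k] <- smiles[d]
            rec_cell[k] <- cells[cl]
            rec_dose[k] <- doses[dz]
          }
        }
      }
    }
    rownames(ctl) <- rownames(prt) <- genes
    pe <- PerturbationExperiment(
      control = ctl, perturbed = prt, smiles = rec_smiles,
      dose_um = rec_dose, cell_line = rec_cell,
      drug_id = drug_ids[match(rec_smiles, smiles)],
      metadata = list(synthetic_seed = spec$seed))
    truth <- structure(
      list(drug_signatures = sig, cell_modulators = mod, dose_response = resp,
           cell_baselines = cell_base, spec = spec),
      class = "GroundTruthEffect")
    list(pe = pe, truth = truth)
  })
}

## Per-record noiseless true effect matrix (genes x records).
trueEffects <- function(pe, truth) {
  if (!identical(S4Vectors::metadata(pe)$synthetic_seed, truth$spec$seed)) {
    stop("dataset and ground truth were generated with different seeds")
  }
  sig <- truth$drug_signatures
  mod <- truth$cell_modulators
  resp <- truth$dose_response
  dk <- .dose_key(doseUm(pe))
  if (!all(dk %in% names(resp))) stop("dose level absent from ground truth")
  eff <- t(sig[drugIds(pe), , drop = FALSE] *
             mod[cellLines(pe), , drop = FALSE]) *
    rep(resp[dk], each = nrow(pe))
  rownames(eff) <- rownames(pe)
  eff
}

#' Bayes-optimal oracle predictions on synthetic data
#'
#' Returns `control + true effect` per record — the best possible
#' predictor under the generative model (it lacks only the irreducible
#' measurement noise).
#'
#' @param pe synthetic [PerturbationExperiment-class] from
#'   [generateDataset()].
#' @param truth the matching `"GroundTruthEffect"`.
#' @return matrix `n_gene x n_record` of predictions.
#' @export
oraclePredict <- function(pe, truth) {
  controlMatrix(pe) + trueEffects(pe, truth)
}

#' Analytic attenuation of the oracle's per-sample fold-change correlation
#'
#' With independent control and perturbed noise of standard deviation
#' `noise_sd`, the observed log fold change is `effect + noise_p - noise_c`,
#' so the expected per-record correlation between oracle-predicted and
#' observed fold changes is `s / sqrt(s^2 + 2 * noise_sd^2)` where `s^2` is
#' the per-record variance of the true effect across genes. Returns the
#' mean over records — the value the measured oracle PCC(lnFC)_per_sample
#' converges to.
#'
#' @inheritParams oraclePredict
#' @return scalar expected per-sample PCC(lnFC) of the oracle.
#' @export
analyticOraclePcc <- function(pe, truth) {
  eff <- trueEffects(pe, truth)
  s2 <- apply(eff, 2L, function(e) mean((e - mean(e))^2))
  mean(sqrt(s2 / (s2 + 2 * truth$spec$noise_sd^2)))
}
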