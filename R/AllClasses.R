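#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
NULL

#' Paired control/perturbed expression experiment
#'
#' A `PerturbationExperiment` extends
#' [SummarizedExperiment::SummarizedExperiment] with exactly two assays,
#' `control` and `perturbed` (genes x samples, log-normalized), where column
#' `j` of `control` is the paired pre-perturbation profile assigned to the
#' perturbed sample in column `j`. Column metadata must carry `smiles`,
#' `dose_um`, `cell_line` and `drug_id` (the canonical SMILES, a pure
#' function of `smiles`); `organ` is optional.
#'
#' @slot .. inherited from `SummarizedExperiment`.
#' @export
setClass("PerturbationExperiment", contains = "SummarizedExperiment")

.validPerturbationExperiment <- function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("control", "perturbed") %in% an)) {
    msg <- c(msg, "assays must include 'control' and 'perturbed'")
  } else {
    ctl <- SummarizedExperiment::assay(object, "control")
    prt <- SummarizedExperiment::assay(object, "perturbed")
    if (!all(is.finite(ctl)) || !all(is.finite(prt))) {
      msg <- c(msg, "expression values must be finite")
    }
  }
  cd <- SummarizedExperiment::colData(object)
  need <- c("smiles", "dose_um", "cell_line", "drug_id")
  miss <- setdiff(need, colnames(cd))
  if (length(miss)) {
    msg <- c(msg, paste0("colData lacks column(s): ", paste(miss, collapse = ", ")))
  } else {
    if (any(!is.finite(cd$dose_um)) || any(cd$dose_um <= 0)) {
      msg <- c(msg, "dose_um must be positive and finite")
    }
  }
  if (ncol(object) == 0L) msg <- c(msg, "dataset must contain at least one record")
  if (is.null(rownames(object))) msg <- c(msg, "gene names (rownames) are required")
  if (length(msg)) msg else TRUE
}

setValidity("PerturbationExperiment", .validPerturbationExperiment)

#' Diffusion noise schedule
#'
#' Per-timestep variance tables of the forward noising chain: strictly
#' increasing `beta` in (0,1), `alpha = 1 - beta`, cumulative products
#' `alpha_bar`, and posterior standard deviations
#' `sigma[t] = sqrt((1 - alpha_bar[t-1]) / (1 - alpha_bar[t]) * beta[t])`
#' under the convention `alpha_bar[0] = 1` (so `sigma[1] = 0`).
#'
#' @slot steps integer number of diffusion steps T.
#' @slot beta,alpha,alpha_bar,sigma numeric vectors of length `steps`.
#' @export
setClass("NoiseSchedule",
  representation(steps = "integer", beta = "numeric", alpha = "numeric",
                 alpha_bar = "numeric", sigma = "numeric"))

setValidity("NoiseSchedule", function(object) {
  msg <- character()
  b <- object@beta
  if (length(b) != object@steps) msg <- c(msg, "beta length must equal steps")
  if (any(b <= 0) || any(b >= 1)) msg <- c(msg, "beta must lie in (0, 1)")
  if (object@steps > 1L && any(diff(b) <= 0)) msg <- c(msg, "beta must be strictly increasing")
  if (object@steps >= 1L && any(diff(c(1, object@alpha_bar)) >= 0)) {
    msg <- c(msg, "alpha_bar must be strictly decreasing from 1")
  }
  if (any(object@sigma < 0)) msg <- c(msg, "sigma must be non-negative")
  if (abs(object@sigma[1L]) > 1e-12) msg <- c(msg, "sigma[1] must be 0 (alpha_bar[0] = 1)")
  if (length(msg)) msg else TRUE
})

#' Token-level text embedding of a perturbation
#'
#' Token matrix (`max_tokens x d_text`) for the rendered molecule + dose
#' prompt, with a logical mask flagging real (non-padding) tokens and the
#' mean-pooled vector over real tokens.
#'
#' @slot tokens numeric matrix, `max_tokens x d_text`.
#' @slot mask logical vector of length `max_tokens`; `TRUE` = real token.
#' @slot pooled numeric vector of length `d_text` (token mean).
#' @export
setClass("TextEmbedding",
  representation(tokens = "matrix", mask = "logical", pooled = "numeric"))

setValidity("TextEmbedding", function(object) {
  msg <- character()
  if (!sum(object@mask)) msg <- c(msg, "at least one real token is required")
  if (length(object@mask) != nrow(object@tokens)) msg <- c(msg, "mask length must match token rows")
  if (!all(is.finite(object@tokens))) msg <- c(msg, "token entries must be finite")
  if (length(object@pooled) != ncol(object@tokens)) msg <- c(msg, "pooled length must equal d_text")
  pm <- colMeans(object@tokens[object@mask, , drop = FALSE])
  if (max(abs(pm - object@pooled)) > 1e-8) msg <- c(msg, "pooled must equal the token mean")
  if (length(msg)) msg else TRUE
})

#' Denoiser architecture configuration
#'
#' Selects one of the four transformer-layer variants and its dimensions.
#' `crossdit` fuses the control transcriptome and the perturbation each by
#' cross-attention; `catcrossdit` concatenates noisy and control profiles
#' per gene, then self-attention plus perturbation cross-attention;
#' `catonlycrossdit` drops the self-attention; `adadit` replaces
#' perturbation cross-attention by adaptive layer normalization and hence
#' needs a vector-like perturbation input (`text_pooled` or `fingerprint`).
#'
#' @slot variant one of `"crossdit"`, `"catcrossdit"`, `"adadit"`,
#'   `"catonlycrossdit"`.
#' @slot n_gene,d_model,n_layers,n_heads,d_text,max_tokens,d_ff integers.
#' @slot pert_input one of `"text_tokens"`, `"text_pooled"`, `"fingerprint"`.
#' @export
setClass("DenoiserConfig",
  representation(variant = "character", n_gene = "integer", d_model = "integer",
                 n_layers = "integer", n_heads = "integer", d_text = "integer",
                 max_tokens = "integer", d_ff = "integer", pert_input = "character"))

setValidity("DenoiserConfig", function(object) {
  msg <- character()
  if (!object@variant %in% c("crossdit", "catcrossdit", "adadit", "catonlycrossdit")) {
    msg <- c(msg, "unknown variant")
  }
  if (!object@pert_input %in% c("text_tokens", "text_pooled", "fingerprint")) {
    msg <- c(msg, "unknown pert_input")
  }
  if (object@d_model %% object@n_heads != 0L) msg <- c(msg, "d_model must be divisible by n_heads")
  if (object@variant == "adadit" && object@pert_input == "text_tokens") {
    msg <- c(msg, "adadit requires a vector-like pert_input (text_pooled or fingerprint)")
  }
  if (object@variant != "adadit" && object@pert_input != "text_tokens") {
    msg <- c(msg, "cross-attention variants require pert_input = 'text_tokens'")
  }
  if (any(c(object@n_gene, object@d_model, object@n_layers, object@n_heads,
            object@d_text, object@max_tokens, object@d_ff) < 1L)) {
    msg <- c(msg, "all dimensions must be >= 1")
  }
  if (length(msg)) msg else TRUE
})

#' Trained (or initialised) noise-predictor model
#'
#' Bundles a [DenoiserConfig-class] with the flat named list of weight
#' arrays of the epsilon-predictor.
#'
#' @slot config a `DenoiserConfig`.
#' @slot params named list of numeric arrays.
#' @export
setClass("DenoiserModel",
  representation(config = "DenoiserConfig", params = "list"))

#' Ten-metric evaluation report
#'
#' Holds R-squared and PCC(lnFC) at the five grouping granularities
#' (`drug`, `drug_dose`, `cov_drug`, `cov_drug_dose`, `per_sample`), with
#' group counts and the number of groups excluded as undefined.
#'
#' @slot values numeric matrix `2 x 5` (rows `R2`, `PCC_lnFC`).
#' @slot n_groups,n_excluded integer vectors, one entry per strategy.
#' @export
setClass("MetricReport",
  representation(values = "matrix", n_groups = "integer", n_excluded = "integer"))

#' Dataset split assignment
#'
#' Record-level part labels from either the five-way benchmark split
#' (train / val / test_drug_unseen / test_cell_unseen / test_both_unseen)
#' or one fold of cross-validation (train / val / test).
#'
#' @slot labels character vector, one label per record.
#' @slot mode `"benchmark"` or one of the CV modes `"random"`, `"drug"`, `"cell"`.
#' @slot fold fold index (`NA` for benchmark mode).
#' @slot held_out_drugs,held_out_cells character vectors of held-out units.
#' @slot seed integer seed the assignment was drawn with.
#' @export
setClass("SplitAssignment",
  representation(labels = "character", mode = "character", fold = "integer",
                 held_out_drugs = "character", held_out_cells = "character",
                 seed = "integer"))

setMethod("show", "NoiseSchedule", function(object) {
  cat(sprintf("NoiseSchedule: T = %d, beta in [%.3g, %.3g], alpha_bar[T] = %.4g\n",
              object@steps, object@beta[1L], object@beta[object@steps],
              object@alpha_bar[object@steps]))
})

setMethod("show", "DenoiserConfig", function(object) {
  cat(sprintf(
    "DenoiserConfig: %s | n_gene=%d d_model=%d layers=%d heads=%d | pert=%s (d_text=%d, max_tokens=%d)\n",
    object@variant, object@n_gene, object@d_model, object@n_layers,
    object@n_heads, object@pert_input, object@d_text, object@max_tokens))
})

setMethod("show", "DenoiserModel", function(object) {
  n_par <- sum(vapply(object@params, length, integer(1)))
  show(object@config)
  cat(sprintf("  %d weight arrays, %d parameters\n", length(object@params), n_par))
})

setMethod("show", "MetricReport", function(object) {
  cat("MetricReport (2 metrics x 5 grouping strategies):\n")
  print(round(object@values, 4))
  cat("n_groups: ", paste(sprintf("%s=%d", colnames(object@values), object@n_groups),
                          collapse = ", "), "\n")
})

setMethod("show", "SplitAssignment", function(object) {
  tab <- table(object@labels)
  cat(sprintf("SplitAssignment (%s%s, seed %d): %s\n", object@mode,
              if (is.na(object@fold)) "" else paste0(", fold ", object@fold),
              object@seed,
              paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = " ")))
})
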