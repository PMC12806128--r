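#' Canonicalize SMILES strings
#'
#' Validity of a SMILES string is defined as successful canonicalization by
#' Open Babel (via \pkg{ChemmineOB}); the canonical form serves as the drug
#' identifier, so two spellings of one molecule collapse to one drug.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES; `NA` where invalid.
#' @export
canonicalizeSmiles <- function(smiles) {
  u <- unique(smiles)
  canon <- vapply(u, function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_character_)
    out <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", source = s)),
      error = function(e) "")
    out <- sub("[ \t\n].*$", "", out)
    if (!nzchar(out)) NA_character_ else out
  }, character(1))
  unname(canon[match(smiles, u)])
}

#' Describe a molecule as text
#'
#' Delegates to a pluggable describer (e.g. an adapter around an external
#' molecule-captioning model). The built-in stub emits a deterministic
#' sentence derived from the canonical SMILES, so any two spellings of the
#' same molecule yield identical text and no model weights are required.
#'
#' @param smiles a single SMILES string.
#' @param describer optional `function(canonical_smiles) -> character`.
#' @return a non-empty description string.
#' @export
describeMolecule <- function(smiles, describer = NULL) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  canon <- canonicalizeSmiles(smiles)
  if (is.na(canon)) stop("invalid SMILES: ", smiles)
  if (!is.null(describer)) {
    txt <- describer(canon)
    stopifnot(is.character(txt), length(txt) == 1L, nzchar(txt))
    return(txt)
  }
  sprintf("The molecule with canonical SMILES %s is a small-molecule compound.",
          canon)
}

#' Append the dose prompt to a molecule description
#'
#' Renders the dose sentence `"The dosage is <dose> micromoles"` after the
#' description. Doses are printed as plain decimals with trailing zeros
#' stripped.
#'
#' @param description non-empty molecule description.
#' @param dose_um positive dose in micromoles.
#' @return the full prompt string.
#' @export
buildDosePrompt <- function(description, dose_um) {
  stopifnot(is.character(description), length(description) == 1L)
  if (!nzchar(description)) stop("description must be non-empty")
  if (!is.finite(dose_um) || dose_um <= 0) stop("dose_um must be positive")
  dose_txt <- format(dose_um, scientific = FALSE, trim = TRUE, drop0trailing = TRUE)
  paste0(description, " The dosage is ", dose_txt, " micromoles")
}

#' Embed a text prompt as a token matrix
#'
#' Delegates to a pluggable encoder; the built-in stub maps each whitespace
#' token to a `d_text`-dimensional vector through a seeded deterministic
#' hash (no downloads, no RNG state touched). Token sequences are truncated
#' or zero-padded to `max_tokens`, with a padding mask carried alongside.
#'
#' @param prompt non-empty text.
#' @param d_text embedding width (stub default 64).
#' @param max_tokens pad/truncate length.
#' @param seed integer mixed into the token hash.
#' @param encoder optional `function(prompt) -> TextEmbedding` replacing the
#'   stub (e.g. an adapter around an external language-model encoder).
#' @return a [TextEmbedding-class].
#' @export
embedText <- function(prompt, d_text = 64L, max_tokens = 32L, seed = 1L,
                      encoder = NULL) {
  stopifnot(is.character(prompt), length(prompt) == 1L)
  if (!nzchar(trimws(prompt))) stop("prompt must be non-empty")
  if (!is.null(encoder)) {
    emb <- encoder(prompt)
    stopifnot(is(emb, "TextEmbedding"))
    return(emb)
  }
  toks <- strsplit(trimws(prompt), "\\s+")[[1L]]
  n_real <- min(length(toks), max_tokens)
  mat <- matrix(0, nrow = max_tokens, ncol = d_text)
  for (i in seq_len(n_real)) {
    mat[i, ] <- hash_to_vec(string_hash(toks[i], seed = seed), d_text)
  }
  mask <- c(rep(TRUE, n_real), rep(FALSE, max_tokens - n_real))
  new("TextEmbedding", tokens = mat, mask = mask,
      pooled = colMeans(mat[mask, , drop = FALSE]))
}

#' Average-pool a token embedding
#'
#' Arithmetic mean over real (unmasked) tokens; the vector form of the
#' perturbation representation used by the AdaLN variant.
#'
#' @param emb a [TextEmbedding-class].
#' @return numeric vector of length `d_text`.
#' @export
poolEmbedding <- function(emb) {
  stopifnot(is(emb, "TextEmbedding"))
  colMeans(emb@tokens[emb@mask, , drop = FALSE])
}

#' Dose-weighted circular fingerprint of a molecule
#'
#' Circular (ECFP4-class, radius 2) fingerprint bits computed by Open
#' Babel, folded by OR to `n_bits`, then multiplied elementwise by the
#' log10-scaled dose. Note that a dose of exactly 1 micromole has
#' log10 weight 0 and therefore yields the zero vector; this is the stated
#' baseline representation and is kept as-is, with a warning.
#'
#' @param smiles a single valid SMILES string.
#' @param dose_um positive dose in micromoles.
#' @param n_bits folded fingerprint length (must divide 4096).
#' @return numeric vector of length `n_bits`.
#' @export
fingerprintEmbedding <- function(smiles, dose_um, n_bits = 1024L) {
  canon <- canonicalizeSmiles(smiles)
  if (is.na(canon)) stop("invalid SMILES: ", smiles)
  if (!is.finite(dose_um) || dose_um <= 0) stop("dose_um must be positive")
  stopifnot(4096L %% n_bits == 0L)
  mol <- ChemmineOB::forEachMol("SMILES", canon, identity)
  raw_fp <- ChemmineOB::fingerprint_OB(mol, "ECFP4")
  bits <- as.numeric(rowSums(matrix(as.numeric(raw_fp), nrow = n_bits)) > 0)
  w <- log10(dose_um)
  if (w == 0) {
    warning("dose_um = 1 gives log10 weight 0: fingerprint embedding is the zero vector")
  }
  bits * w
}

## Build the perturbation input the denoiser consumes for one (smiles, dose)
## pair, according to the configured representation.
.pert_input_for <- function(config, smiles, dose_um, seed = 1L,
                            describer = NULL, encoder = NULL) {
  if (config@pert_input == "fingerprint") {
    return(suppressWarnings(
      fingerprintEmbedding(smiles, dose_um, n_bits = config@d_text)))
  }
  desc <- describeMolecule(smiles, describer = describer)
  prompt <- buildDosePrompt(desc, dose_um)
  emb <- embedText(prompt, d_text = config@d_text,
                   max_tokens = config@max_tokens, seed = seed,
                   encoder = encoder)
  if (config@pert_input == "text_pooled") poolEmbedding(emb) else emb
}

#' Precompute perturbation embeddings for a dataset
#'
#' Builds (or extends) a cache keyed by `canonical SMILES|dose` holding the
#' perturbation representation each record needs under `config`. Backends:
#' the deterministic stub (default), an external `encoder`/`describer`
#' adapter, or a precomputed cache read with [readEmbeddingCache()].
#'
#' @param pe a [PerturbationExperiment-class].
#' @param config a [DenoiserConfig-class].
#' @param seed stub-embedder hash seed.
#' @param describer,encoder optional external backends (see
#'   [describeMolecule()], [embedText()]).
#' @param cache optional environment from a previous call; missing keys are
#'   added.
#' @return an environment mapping keys to embeddings.
#' @export
perturbationEmbeddings <- function(pe, config, seed = 1L, describer = NULL,
                                   encoder = NULL, cache = NULL) {
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  cd <- SummarizedExperiment::colData(pe)
  keys <- embeddingKey(cd$drug_id, cd$dose_um)
  for (i in which(!duplicated(keys))) {
    k <- keys[i]
    if (!is.null(cache[[k]])) next
    cache[[k]] <- .pert_input_for(config, cd$drug_id[i], cd$dose_um[i],
                                  seed = seed, describer = describer,
                                  encoder = encoder)
  }
  cache
}

#' @rdname perturbationEmbeddings
#' @param drug_id,dose_um vectors defining cache keys.
#' @export
embeddingKey <- function(drug_id, dose_um) {
  paste0(drug_id, "|", format(dose_um, scientific = FALSE, trim = TRUE,
                              drop0trailing = TRUE))
}

#' Write / read an embedding cache as CSV matrices plus a JSON manifest
#'
#' One CSV per key (token matrices keep their mask as an extra column);
#' `manifest.json` records keys, file names and the representation kind.
#'
#' @param cache environment from [perturbationEmbeddings()].
#' @param dir directory to write to / read from.
#' @return `dir` (write) or a cache environment (read).
#' @export
writeEmbeddingCache <- function(cache, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  keys <- ls(cache)
  files <- sprintf("emb_%04d.csv", seq_along(keys))
  kinds <- character(length(keys))
  for (i in seq_along(keys)) {
    obj <- cache[[keys[i]]]
    if (is(obj, "TextEmbedding")) {
      kinds[i] <- "tokens"
      utils::write.csv(cbind(as.data.frame(obj@tokens), mask = as.integer(obj@mask)),
                       file.path(dir, files[i]), row.names = FALSE)
    } else {
      kinds[i] <- "vector"
      utils::write.csv(data.frame(value = as.numeric(obj)),
                       file.path(dir, files[i]), row.names = FALSE)
    }
  }
  jsonlite::write_json(list(keys = keys, files = files, kinds = kinds),
                       file.path(dir, "manifest.json"))
  invisible(dir)
}

#' @rdname writeEmbeddingCache
#' @export
readEmbeddingCache <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  cache <- new.env(parent = emptyenv())
  for (i in seq_along(man$keys)) {
    df <- utils::read.csv(file.path(dir, man$files[i]))
    if (man$kinds[i] == "tokens") {
      mask <- as.logical(df$mask)
      tok <- as.matrix(df[, setdiff(colnames(df), "mask"), drop = FALSE])
      dimnames(tok) <- NULL
      cache[[man$keys[i]]] <- new("TextEmbedding", tokens = tok, mask = mask,
                                  pooled = colMeans(tok[mask, , drop = FALSE]))
    } else {
      cache[[man$keys[i]]] <- df$value
    }
  }
  cache
}
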