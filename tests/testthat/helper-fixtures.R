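# Shared in-code fixtures. Everything is generated programmatically; no
# data files.

# A minimal paired experiment with explicit values: n records over a fixed
# gene panel, deterministic from the arguments.
make_tiny_pe <- function(n_gene = 6L, smiles = c("CCO", "CCO", "CCC", "CCC"),
                         dose = c(1, 10, 1, 10),
                         cell = c("A", "A", "B", "B"), seed = 42L) {
  n <- length(smiles)
  withr::with_seed(seed, {
    ctl <- matrix(rnorm(n_gene * n, mean = 5), n_gene, n,
                  dimnames = list(sprintf("g%02d", seq_len(n_gene)), NULL))
    prt <- ctl + matrix(rnorm(n_gene * n, sd = 0.5), n_gene, n)
  })
  PerturbationExperiment(control = ctl, perturbed = prt, smiles = smiles,
                         dose_um = dose, cell_line = cell)
}

# Small denoiser config for architecture tests.
tiny_config <- function(variant = "catcrossdit", n_gene = 6L,
                        pert_input = if (variant == "adadit") "text_pooled" else "text_tokens") {
  denoiserConfig(variant, n_gene = n_gene, d_model = 16L, n_layers = 2L,
                 n_heads = 2L, d_text = 8L, max_tokens = 4L, d_ff = 24L,
                 pert_input = pert_input)
}

tiny_pert <- function(cfg) {
  if (cfg@pert_input == "text_tokens") {
    embedText("one two three", d_text = cfg@d_text, max_tokens = cfg@max_tokens)
  } else {
    withr::with_seed(7L, rnorm(cfg@d_text))
  }
}

all_variants <- c("crossdit", "catcrossdit", "catonlycrossdit", "adadit")
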