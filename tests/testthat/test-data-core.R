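test_that("logNormalize rescales rows and applies log1p", {
  m <- rbind(s1 = c(0, 0, 3), s2 = c(1, 1, 2))
  out <- logNormalize(m, scale = 1e4)
  expect_equal(out["s1", ], c(0, 0, log1p(1e4)), ignore_attr = TRUE)
  # scalar-multiple rows normalize identically
  m2 <- rbind(a = c(1, 2, 3), b = c(10, 20, 30))
  out2 <- logNormalize(m2)
  expect_equal(out2["a", ], out2["b", ])
  # within-sample ranking preserved
  m3 <- matrix(runif(50, 1, 100), 5, 10)
  out3 <- logNormalize(m3)
  for (i in 1:5) expect_equal(order(out3[i, ]), order(m3[i, ]))
})

test_that("logNormalize rejects degenerate input", {
  expect_error(logNormalize(rbind(a = c(0, 0, 0), b = c(1, 2, 3))), "all-zero")
  expect_error(logNormalize(rbind(a = c(-1, 2, 3))), "negative")
  expect_error(logNormalize(matrix(c(1, NA, 3, 4), 2)), "finite")
})

test_that("pairControls matches on keys and is seeded-deterministic", {
  genes <- 4L
  prt <- matrix(rnorm(genes * 2, 5), genes, 2)
  ctl <- matrix(rnorm(genes * 3, 5), genes, 3)
  pmeta <- data.frame(smiles = c("CCO", "CCO"), dose_um = c(1, 1),
                      cell_line = c("A", "B"))
  cmeta <- data.frame(cell_line = c("A", "A", "B"))
  pe <- pairControls(prt, ctl, pmeta, cmeta, seed = 5)
  expect_s4_class(pe, "PerturbationExperiment")
  # record 2 (cell B) must get the unique cell-B control
  expect_equal(controlMatrix(pe)[, 2], ctl[, 3], ignore_attr = TRUE)
  # record 1 gets one of the two cell-A controls, same one on re-run
  pe2 <- pairControls(prt, ctl, pmeta, cmeta, seed = 5)
  expect_identical(controlMatrix(pe), controlMatrix(pe2))
  # control metadata always matches perturbed metadata on the match keys
  expect_true(all(cellLines(pe) == pmeta$cell_line))
})

test_that("pairControls errors when a record has no matching control", {
  prt <- matrix(rnorm(4), 4, 1)
  ctl <- matrix(rnorm(4), 4, 1)
  expect_error(
    pairControls(prt, ctl, data.frame(smiles = "CCO", dose_um = 1, cell_line = "A"),
                 data.frame(cell_line = "B")),
    "no matching control.*A")
})

test_that("filterRecords drops invalid SMILES then sparse compounds", {
  smiles <- c(rep("CCO", 5), rep("CCC", 4), rep("CCCC", 7), "not_a_molecule")
  n <- length(smiles)
  ctl <- matrix(rnorm(3 * n, 5), 3, n)
  pe <- PerturbationExperiment(ctl, ctl + 0.1, smiles, rep(1, n), rep("A", n))
  out <- filterRecords(pe, min_obs_per_compound = 5L)
  expect_equal(ncol(out), 12L)  # compounds with 5 and 7 records survive
  expect_setequal(unique(drugIds(out)), canonicalizeSmiles(c("CCO", "CCCC")))
  # idempotent
  expect_identical(colnames(filterRecords(out, 5L)), colnames(out))
  # threshold 1 with valid SMILES only: no-op
  pe2 <- pe[, seq_len(16)]
  expect_equal(ncol(filterRecords(pe2, 1L)), 16L)
  expect_error(filterRecords(pe, 100L), "no records remain")
})

test_that("computeDEGs ranks by mean lnFC with deterministic tie-breaking", {
  n_gene <- 8L
  ctl <- matrix(5, n_gene, 4, dimnames = list(sprintf("g%02d", 1:n_gene), NULL))
  prt <- ctl
  prt[3, ] <- prt[3, ] + 2   # g03 strongly up
  prt[5, ] <- prt[5, ] - 1.5 # g05 strongly down
  pe <- PerturbationExperiment(ctl, prt, rep("CCO", 4), rep(1, 4), rep("A", 4))
  degs <- computeDEGs(pe, n_up = 2L, n_down = 2L, group_by = "drug")
  expect_length(degs, 1L)
  expect_equal(degs[[1]]$up_genes[1], "g03")
  expect_equal(degs[[1]]$down_genes[1], "g05")
  expect_length(intersect(degs[[1]]$up_genes, degs[[1]]$down_genes), 0L)
  # degenerate request
  empty <- computeDEGs(pe, n_up = 0L, n_down = 0L)
  expect_length(empty[[1]]$up_genes, 0L)
  # null case: perturbed == control ties everywhere; panel order decides
  pe0 <- PerturbationExperiment(ctl, ctl, rep("CCO", 4), rep(1, 4), rep("A", 4))
  d0 <- computeDEGs(pe0, n_up = 3L, n_down = 3L)
  expect_equal(d0[[1]]$up_genes, c("g01", "g02", "g03"))
  expect_equal(d0[[1]]$down_genes, c("g04", "g05", "g06"))
})

test_that("computeDEGs is invariant to record order and warns on small groups", {
  pe <- make_tiny_pe(n_gene = 10L)
  a <- computeDEGs(pe, n_up = 3L, n_down = 3L, group_by = "drug")
  perm <- c(3, 1, 4, 2)
  b <- computeDEGs(pe[, perm], n_up = 3L, n_down = 3L, group_by = "drug")
  key <- function(x) vapply(x, function(s) s$drug_id, character(1))
  b <- b[match(key(a), key(b))]
  expect_equal(a, b)
  # group below min size is skipped with a warning
  pe1 <- make_tiny_pe(smiles = c("CCO", "CCO", "CCC"), dose = c(1, 1, 1),
                      cell = c("A", "A", "A"))
  expect_warning(computeDEGs(pe1, group_by = "drug"), "skipped")
})

test_that("DEG sets round-trip through JSON", {
  pe <- make_tiny_pe(n_gene = 10L)
  degs <- computeDEGs(pe, n_up = 3L, n_down = 2L, group_by = "drug_cell")
  path <- tempfile(fileext = ".json")
  writeDEGSets(degs, path)
  back <- readDEGSets(path)
  expect_equal(degs, back)
})

test_that("the CSV trio round-trips a dataset", {
  pe <- make_tiny_pe(n_gene = 5L)
  dir <- tempfile()
  writePerturbationCSV(pe, dir)
  back <- readPerturbationCSV(file.path(dir, "expression.csv"),
                              file.path(dir, "metadata.csv"),
                              file.path(dir, "pairing.csv"))
  expect_equal(unname(perturbedMatrix(back)), unname(perturbedMatrix(pe)),
               tolerance = 1e-12)
  expect_equal(unname(controlMatrix(back)), unname(controlMatrix(pe)),
               tolerance = 1e-12)
  expect_equal(drugIds(back), drugIds(pe))
  expect_equal(doseUm(back), doseUm(pe))
})

test_that("mismatched gene panels are rejected", {
  ctl <- matrix(rnorm(8, 5), 4, 2, dimnames = list(paste0("g", 1:4), NULL))
  prt <- ctl + 0.1
  rownames(prt) <- paste0("h", 1:4)
  expect_error(
    PerturbationExperiment(ctl, prt, c("CCO", "CCO"), c(1, 1), c("A", "A")),
    "panels differ")
})
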