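test_that("the generator is deterministic and honours null settings", {
  spec0 <- syntheticSpec(n_gene = 12L, n_drug = 2L, n_cell = 2L,
                         samples_per_condition = 2L, effect_scale = 0,
                         noise_sd = 0, seed = 5L)
  gd <- generateDataset(spec0)
  expect_equal(perturbedMatrix(gd$pe), controlMatrix(gd$pe))
  # same seed -> identical dataset; different seed -> different
  spec <- syntheticSpec(n_gene = 12L, n_drug = 2L, n_cell = 2L,
                        samples_per_condition = 2L, seed = 9L)
  a <- generateDataset(spec)
  b <- generateDataset(spec)
  expect_identical(perturbedMatrix(a$pe), perturbedMatrix(b$pe))
  spec2 <- syntheticSpec(n_gene = 12L, n_drug = 2L, n_cell = 2L,
                         samples_per_condition = 2L, seed = 10L)
  expect_false(identical(perturbedMatrix(a$pe),
                         perturbedMatrix(generateDataset(spec2)$pe)))
})

test_that("noiseless records carry exactly the constructed effect", {
  spec <- syntheticSpec(n_gene = 15L, n_drug = 3L, n_cell = 2L,
                        samples_per_condition = 1L, noise_sd = 0, seed = 2L)
  gd <- generateDataset(spec)
  lfc <- perturbedMatrix(gd$pe) - controlMatrix(gd$pe)
  eff <- DiffPert:::trueEffects(gd$pe, gd$truth)
  expect_equal(unname(lfc), unname(eff), tolerance = 1e-12)
  # oracle on noiseless data: all ten measures equal 1
  rep1 <- evaluateAll(gd$pe, oraclePredict(gd$pe, gd$truth))
  expect_true(all(abs(rep1@values - 1) < 1e-10))
})

test_that("dose response is monotone saturating with unit max", {
  gd <- generateDataset(syntheticSpec(n_gene = 10L, n_drug = 2L, n_cell = 2L,
                                      samples_per_condition = 1L, seed = 1L))
  resp <- gd$truth$dose_response
  expect_true(all(diff(resp) > 0))
  expect_equal(unname(resp[length(resp)]), 1)
})

test_that("oracle predictions refuse a mismatched ground truth", {
  a <- generateDataset(syntheticSpec(n_gene = 10L, n_drug = 2L, n_cell = 2L,
                                     samples_per_condition = 1L, seed = 1L))
  b <- generateDataset(syntheticSpec(n_gene = 10L, n_drug = 2L, n_cell = 2L,
                                     samples_per_condition = 1L, seed = 2L))
  expect_error(oraclePredict(a$pe, b$truth), "different seeds")
})

test_that("replicate averaging recovers control plus true effect", {
  # law of large numbers at one condition with many replicates
  spec <- syntheticSpec(n_gene = 10L, n_drug = 1L, n_cell = 1L,
                        n_dose_levels = 1L, samples_per_condition = 400L,
                        noise_sd = 0.2, seed = 6L)
  gd <- generateDataset(spec)
  lfc_mean <- rowMeans(perturbedMatrix(gd$pe) - controlMatrix(gd$pe))
  eff <- DiffPert:::trueEffects(gd$pe, gd$truth)[, 1]
  # mean lnFC has sd noise_sd*sqrt(2/n) per gene
  expect_lt(max(abs(lfc_mean - eff)), 0.2 * sqrt(2 / 400) * 4)
})

test_that("effect matrices are recoverable by regression on condition indicators", {
  spec <- syntheticSpec(n_gene = 8L, n_drug = 3L, n_cell = 2L,
                        n_dose_levels = 2L, samples_per_condition = 3L,
                        noise_sd = 0, seed = 7L)
  gd <- generateDataset(spec)
  pe <- gd$pe
  lfc <- perturbedMatrix(pe) - controlMatrix(pe)
  cond <- paste(drugIds(pe), cellLines(pe), doseUm(pe))
  eff <- DiffPert:::trueEffects(pe, gd$truth)
  for (cn in unique(cond)) {
    i <- cond == cn
    expect_equal(rowMeans(lfc[, i, drop = FALSE]),
                 eff[, which(i)[1]], tolerance = 1e-10)
  }
})

test_that("measured oracle attenuation matches the analytic value", {
  spec <- syntheticSpec(n_gene = 40L, n_drug = 6L, n_cell = 4L,
                        samples_per_condition = 4L, noise_sd = 0.1, seed = 8L)
  gd <- generateDataset(spec)  # 1152 records
  measured <- as.numeric(groupedMetric(gd$pe, oraclePredict(gd$pe, gd$truth),
                                       "per_sample", "PCC_lnFC"))
  expect_equal(measured, analyticOraclePcc(gd$pe, gd$truth), tolerance = 0.02)
})

test_that("synthetic datasets flow through the CSV container unchanged", {
  gd <- generateDataset(syntheticSpec(n_gene = 8L, n_drug = 2L, n_cell = 2L,
                                      samples_per_condition = 1L, seed = 4L))
  dir <- tempfile()
  writePerturbationCSV(gd$pe, dir)
  back <- readPerturbationCSV(file.path(dir, "expression.csv"),
                              file.path(dir, "metadata.csv"),
                              file.path(dir, "pairing.csv"))
  expect_equal(unname(perturbedMatrix(back)), unname(perturbedMatrix(gd$pe)),
               tolerance = 1e-12)
  expect_equal(drugIds(back), drugIds(gd$pe))
})
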