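test_that("rSquared matches hand-computed values", {
  expect_equal(rSquared(c(1, 2, 3), c(1, 2, 3)), 1)
  y <- c(1, 2, 3, 4)
  expect_equal(rSquared(y, rep(mean(y), 4)), 0)
  expect_equal(rSquared(c(1, 2, 3), c(1, 2, 4)), 1 - 1 / 2)
  # strict printed-formula variant centres on the prediction mean
  expect_equal(rSquared(c(1, 2, 3), c(1, 2, 4), center = "pred"),
               1 - 1 / sum((c(1, 2, 3) - 7 / 3)^2))
  expect_warning(v <- rSquared(c(2, 2, 2), c(1, 2, 3)), "undefined")
  expect_true(is.na(v))
  expect_error(rSquared(1:3, 1:2), "mismatch")
})

test_that("lnFoldChange is the log-space difference", {
  expect_equal(lnFoldChange(c(2, 3), c(1, 1)), c(1, 2))
  x <- rnorm(5)
  expect_equal(lnFoldChange(x, x), rep(0, 5))
  expect_equal(lnFoldChange(x + 3, x), rep(3, 5))
  expect_error(lnFoldChange(1:3, 1:2), "mismatch")
})

test_that("pccLnFC matches hand-computed correlations", {
  x <- c(0, 0, 0)
  expect_equal(pccLnFC(c(1, 2, 3), c(1, 2, 3), x), 1)
  expect_equal(pccLnFC(c(1, 2, 3), -c(1, 2, 3), x), -1)
  expect_equal(pccLnFC(c(1, 2, 3), c(1, 2, 2), x), cor(c(1, 2, 3), c(1, 2, 2)))
  expect_equal(pccLnFC(c(1, 2, 3), c(1, 2, 2), x), 0.8660254, tolerance = 1e-7)
  expect_warning(v <- pccLnFC(c(1, 1, 1), c(1, 2, 3), x), "undefined")
  expect_true(is.na(v))
  # invariant to adding any constant vector to both true and predicted
  ctl <- rnorm(6)
  yt <- rnorm(6); yp <- rnorm(6); shift <- rnorm(6)
  expect_equal(pccLnFC(yt + shift, yp + shift, ctl + shift),
               pccLnFC(yt, yp, ctl), tolerance = 1e-12)
})

test_that("metrics are invariant to consistent gene permutation", {
  yt <- rnorm(8); yp <- rnorm(8); ctl <- rnorm(8)
  perm <- sample(8)
  expect_equal(rSquared(yt[perm], yp[perm]), rSquared(yt, yp))
  expect_equal(pccLnFC(yt[perm], yp[perm], ctl[perm]), pccLnFC(yt, yp, ctl))
})

test_that("grouped metrics average group means per the grid definition", {
  # hand-built: 2 drugs x 2 records, 3 genes
  ctl <- matrix(c(1, 1, 1,  2, 2, 2,  0, 0, 0,  1, 1, 1), 3, 4)
  prt <- matrix(c(2, 3, 1,  3, 4, 2,  1, 0, 2,  2, 1, 3), 3, 4)
  pred <- matrix(c(2, 2.5, 1.5,  3, 3.5, 2,  1, 0.5, 1.5,  2, 1.5, 2.5), 3, 4)
  pe <- PerturbationExperiment(ctl, prt, c("CCO", "CCO", "CCC", "CCC"),
                               rep(1, 4), rep("A", 4))
  # independent computation: average profiles per drug, then metric, then mean
  ids <- drugIds(pe)
  manual <- function(metric) {
    vals <- vapply(unique(ids), function(d) {
      i <- ids == d
      yt <- rowMeans(prt[, i]); yp <- rowMeans(pred[, i]); xc <- rowMeans(ctl[, i])
      if (metric == "R2") 1 - sum((yt - yp)^2) / sum((yt - mean(yt))^2)
      else cor(yt - xc, yp - xc)
    }, numeric(1))
    mean(vals)
  }
  expect_equal(as.numeric(groupedMetric(pe, pred, "drug", "R2")), manual("R2"))
  expect_equal(as.numeric(groupedMetric(pe, pred, "drug", "PCC_lnFC")),
               manual("PCC_lnFC"))
})

test_that("per-sample grouping equals the mean of record-level metrics", {
  pe <- make_tiny_pe(n_gene = 9L)
  pred <- perturbedMatrix(pe) + matrix(rnorm(9 * 4, sd = 0.2), 9, 4)
  g <- groupedMetric(pe, pred, "per_sample", "R2")
  direct <- mean(vapply(1:4, function(j) {
    rSquared(perturbedMatrix(pe)[, j], pred[, j])
  }, numeric(1)))
  expect_equal(as.numeric(g), direct, tolerance = 1e-12)
  expect_equal(attr(g, "n_groups"), 4L)
})

test_that("evaluateAll returns the full ten-measure grid", {
  pe <- make_tiny_pe(n_gene = 9L)
  pred <- perturbedMatrix(pe)
  rep1 <- evaluateAll(pe, pred)
  expect_equal(dim(rep1@values), c(2L, 5L))
  expect_equal(sum(!is.na(rep1@values)), 10L)
  # perfect predictions: every measure is 1
  expect_true(all(abs(rep1@values - 1) < 1e-12))
  # record order invariance
  noisy <- pred + matrix(rnorm(9 * 4, sd = 0.3), 9, 4)
  perm <- c(4, 2, 1, 3)
  a <- evaluateAll(pe, noisy)
  b <- evaluateAll(pe[, perm], noisy[, perm])
  expect_equal(a@values, b@values, tolerance = 1e-12)
})

test_that("increasing prediction noise degrades per-sample R-squared", {
  pe <- make_tiny_pe(n_gene = 30L)
  truth <- perturbedMatrix(pe)
  vals <- withr::with_seed(11, vapply(c(0.05, 0.3, 1), function(s) {
    mean(replicate(20, {
      as.numeric(groupedMetric(pe, truth + matrix(rnorm(length(truth), sd = s),
                                                  nrow(truth)),
                               "per_sample", "R2"))
    }))
  }, numeric(1)))
  expect_true(all(diff(vals) < 0))
})

test_that("degGenePCC computes per-drug means of per-gene correlations", {
  # 1 drug, 4 samples, 3 genes; hand-set fold changes for gene g01
  ctl <- matrix(5, 3, 4, dimnames = list(c("g01", "g02", "g03"), NULL))
  lt <- rbind(c(1, 2, 3, 4), c(0.5, 0.4, 0.3, 0.2), c(1, 1, 2, 2))
  lp <- rbind(c(1.2, 1.8, 3.1, 3.9), c(0.4, 0.5, 0.2, 0.3), c(1, 2, 1, 2))
  pe <- PerturbationExperiment(ctl, ctl + lt, rep("CCO", 4), rep(1, 4),
                               rep("A", 4))
  degs <- list(list(drug_id = drugIds(pe)[1], cell_line = NA_character_,
                    up_genes = c("g01", "g03"), down_genes = "g02"))
  out <- degGenePCC(pe, ctl + lp, degs)
  expected <- mean(c(cor(lt[1, ], lp[1, ]), cor(lt[3, ], lp[3, ]),
                     cor(lt[2, ], lp[2, ])))
  expect_equal(as.numeric(out), expected, tolerance = 1e-12)
  # perfect predictions give 1; sign-flipped fold changes give -1
  expect_equal(as.numeric(degGenePCC(pe, ctl + lt, degs)), 1)
  expect_equal(as.numeric(degGenePCC(pe, ctl - lt, degs)), -1)
})

test_that("metric reports serialize to tidy JSON and CSV", {
  pe <- make_tiny_pe(n_gene = 9L)
  noisy <- perturbedMatrix(pe) + matrix(rnorm(36, sd = 0.2), 9, 4)
  rep1 <- evaluateAll(pe, noisy)
  df <- reportAsDataFrame(rep1)
  expect_equal(nrow(df), 10L)
  pj <- tempfile(fileext = ".json"); pc <- tempfile(fileext = ".csv")
  writeMetricReport(rep1, pj, pc)
  back <- utils::read.csv(pc)
  expect_equal(back$value, df$value, tolerance = 1e-12)
  expect_equal(nrow(jsonlite::read_json(pj, simplifyVector = TRUE)), 10L)
})
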