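test_that("fold assignment partitions candidates into near-equal folds", {
  f <- makeFolds(sprintf("L%02d", 1:10), k = 5, seed = 1)
  expect_equal(as.vector(table(f$folds)), rep(2L, 5))
  expect_setequal(names(f$folds), sprintf("L%02d", 1:10))

  f2 <- makeFolds(sprintf("L%02d", 1:23), k = 5, seed = 9)
  sizes <- table(f2$folds)
  expect_lte(max(sizes) - min(sizes), 1)
  expect_error(makeFolds(c("a", "b"), k = 5), "fewer lines")

  # stratified: every cycle present in every fold
  cyc <- setNames(rep(c("2021", "2022"), each = 20), sprintf("L%02d", 1:40))
  f3 <- makeFolds(names(cyc), k = 5, seed = 3, cycles = cyc)
  tab <- table(f3$folds, cyc[names(f3$folds)])
  expect_true(all(tab > 0))
})

test_that("LBCO assigns lines to their first tested cycle", {
  ph <- data.frame(line_id = c("A", "A", "B", "C"),
                   year = c(2021, 2022, 2022, 2021))
  sch <- makeLbco(ph)
  expect_identical(sch$kind, "lbco")
  expect_equal(unname(sch$folds[c("A", "B", "C")]), c(1L, 2L, 1L))
  expect_error(makeLbco(data.frame(line_id = "A", year = 2021)), "2 breeding cycles")
})

test_that("corrected phenotypes remove fixed effects and equal the two-step oracle", {
  set.seed(15)
  df <- data.frame(y = rnorm(24), line_id = rep(LETTERS[1:6], 4),
                   year = 2021, location = "L",
                   trial = rep(c("T1", "T2"), each = 12),
                   plot_id = paste0("p", 1:24))
  des <- buildDesign(df, modelSpec("y", random = list(randomTerm("l", "line_id"))))
  vc <- remlFit(des)
  sol <- blupSolve(des, vc)
  yc <- correctedPhenotypes(des, sol)
  # oracle: subtract X b_hat observation-wise, average per line
  resid <- df$y - drop(des$X %*% fixedEffects(sol))
  oracle <- c(tapply(resid, df$line_id, mean))
  expect_equal(yc[names(oracle)], oracle, tolerance = 1e-12)

  # adding a constant to one trial's phenotypes is absorbed
  df2 <- df
  df2$y[df2$trial == "T2"] <- df2$y[df2$trial == "T2"] + 5
  des2 <- buildDesign(df2, modelSpec("y", random = list(randomTerm("l", "line_id"))))
  sol2 <- blupSolve(des2, vc)
  expect_equal(correctedPhenotypes(des2, sol2), yc, tolerance = 1e-8)
})

test_that("dispersion slope is cov/var with its closed-form special cases", {
  set.seed(16)
  x <- rnorm(30)
  expect_equal(dispersionSlope(x, x), 1.0)
  expect_equal(dispersionSlope(0.5 * x, x), 0.5)
  y <- rnorm(30)
  expect_equal(dispersionSlope(y, x), coef(lm(y ~ x))[[2]], tolerance = 1e-12)
  expect_error(dispersionSlope(x, rep(1, 30)), "zero-variance")
})

test_that("bootstrap SE matches the analytic SE of a mean and is seed-stable", {
  set.seed(17)
  d <- data.frame(x = rnorm(200))
  se <- bootstrapSE(function(d) mean(d$x), d, nRep = 10000, seed = 1)
  expect_equal(as.numeric(se), 1 / sqrt(200), tolerance = 0.1)
  se2 <- bootstrapSE(function(d) mean(d$x), d, nRep = 5000, seed = 99)
  expect_equal(as.numeric(se), as.numeric(se2), tolerance = 0.15)
  # constant statistic
  expect_equal(as.numeric(bootstrapSE(function(d) 1, d, nRep = 100, seed = 1)), 0)
})

test_that("percent change matches hand arithmetic", {
  expect_equal(percentChange(0.30, 0.25), 20.0)
  expect_equal(percentChange(0.4, 0.4), 0.0)
  expect_error(percentChange(0.3, 0), "zero reference")
})

test_that("paired model comparison separates different models and letters equal ones", {
  pa <- c(0.5, 0.6, 0.55, 0.58, 0.52)
  # spec-style case: a model against itself shifted by +0.2 must separate
  shift <- compareModels(cbind(A = pa, B = pa + 0.2), alpha = 0.01)
  expect_lt(shift$p["A", "B"], 0.01)
  expect_false(shift$letters[["A"]] == shift$letters[["B"]])

  set.seed(20)
  paMat <- cbind(A = pa, B = pa + 0.2 + rnorm(5, sd = 0.002),
                 C = pa + 0.201 + rnorm(5, sd = 0.002))
  res <- compareModels(paMat, alpha = 0.01)
  # paired t oracle for A vs B
  tt <- t.test(paMat[, "A"], paMat[, "B"], paired = TRUE)$p.value
  expect_equal(res$p["A", "B"], tt, tolerance = 1e-12)
  expect_lt(res$p["A", "B"], 0.01)
  expect_identical(res$letters[["B"]], res$letters[["C"]])
  expect_false(res$letters[["A"]] == res$letters[["B"]])

  # identical per-fold values share a letter
  same <- cbind(A = pa, B = pa)
  resSame <- compareModels(same, alpha = 0.01)
  expect_identical(resSame$letters[["A"]], resSame$letters[["B"]])

  # A = B >> C gives letters (a, a, b)
  paABC <- cbind(A = pa + 0.3, B = pa + 0.3 + rnorm(5, sd = 0.005), C = pa)
  resABC <- compareModels(paABC, alpha = 0.01)
  expect_identical(resABC$letters[["A"]], "a")
  expect_identical(resABC$letters[["B"]], "a")
  expect_identical(resABC$letters[["C"]], "b")

  # single paired unit: not applicable
  one <- matrix(c(0.5, 0.6), 1, dimnames = list(NULL, c("A", "B")))
  resNA <- compareModels(one)
  expect_identical(resNA$status, "not-applicable")
})

test_that("cross-validation masks cleanly, recovers sensible accuracy, and reports LR ratios", {
  tr <- smallTrial(seed = 31, nLines = 80, nMi = 250, trialsPerEnv = 2)
  ph <- tr$ph
  cands <- setdiff(unique(ph$line_id), tr$ds$truth$controls)
  sch <- makeFolds(cands, k = 5, seed = 2, cycles = tr$ds$truth$cycleOf)
  cv <- runCV(sch, "GBLUP", "GY", ph, tr$G, tr$S, nBoot = 300, seed = 4)
  expect_s4_class(cv, "CVResult")
  expect_lte(abs(predictiveAbility(cv)), 1)
  # masking audit: no masked plot or line ever enters a training design
  aud <- cv@info$audit
  expect_false(any(aud$trainHasMaskedPlots))
  expect_false(any(aud$trainHasMaskedLines))
  expect_true(all(lrRatios(cv) <= 1 + 1e-12))
  expect_equal(nrow(cv@perFold), 5L)

  # GEBV == corrected phenotype would give PA = 1: check the correlation
  # machinery on a constructed pooled table
  pool <- cv@info$pooled
  expect_equal(cor(pool$yc, pool$yc), 1)
})

test_that("GOBLUP cross-validation with a negligible omics path matches GBLUP closely", {
  cfg <- simConfig(nLines = 60, nSnps = 300, nCycles = 2, locations = "LocA",
                   trialsPerEnv = 2, plotsGrid = c(6, 8), nMiFeatures = 150,
                   seed = 33,
                   varianceComponents = list(
                     GY = list(g = 0.05, l = 0.01, i_g = 0.01, i_l = 0.01,
                               s = 0.01, m = 0, e = 0.05, omics = 0.02)))
  ds <- generateDataset(cfg)
  geno <- imputeMeanDosage(snpQC(ds$genotypes))
  G <- vanRadenG(geno)
  ph <- ds$phenotypes
  S <- spatialKernel(data.frame(plot_id = ph$plot_id,
                                trial = paste(ph$year, ph$location, ph$trial),
                                row = ph$row, col = ph$col))
  Q <- miKernel(normalizeColumns(ds$mi))
  cands <- setdiff(unique(ph$line_id), ds$truth$controls)
  sch <- makeFolds(cands, k = 3, seed = 5, cycles = ds$truth$cycleOf)
  cvG <- runCV(sch, "GBLUP", "GY", ph, G, S, nBoot = 100, seed = 6)
  cvM <- runCV(sch, "GOBLUP-MI", "GY", ph, G, S, omicsKernel = Q,
               nBoot = 100, seed = 6)
  expect_false(any(cvM@info$audit$omicsHasMaskedPlots))
  expect_lt(abs(predictiveAbility(cvM) - predictiveAbility(cvG)), 0.05)
})
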