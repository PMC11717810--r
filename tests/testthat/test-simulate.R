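test_that("generator handles the empty case and is fully seed-deterministic", {
  ds0 <- generateDataset(simConfig(nLines = 0, nMiFeatures = 10))
  expect_equal(nrow(ds0$phenotypes), 0L)

  cfg <- simConfig(nLines = 30, nSnps = 100, nCycles = 2, locations = "LocA",
                   trialsPerEnv = 1, plotsGrid = c(5, 6), nMiFeatures = 40,
                   seed = 7)
  a <- generateDataset(cfg)
  b <- generateDataset(cfg)
  expect_identical(dosages(a$genotypes), dosages(b$genotypes))
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(spectraValues(a$mi), spectraValues(b$mi))
  expect_identical(spectraValues(a$nir), spectraValues(b$nir))
  expect_identical(a$truth$g, b$truth$g)
})

test_that("infeasible layouts raise a sizing error", {
  expect_error(generateDataset(
    simConfig(nLines = 500, nCycles = 1, locations = "LocA", trialsPerEnv = 1,
              plotsGrid = c(5, 6), nMiFeatures = 5)),
    "infeasible layout")
})

test_that("layout is a valid incomplete block design with replicated controls and <= 8 neighbours", {
  cfg <- simConfig(nLines = 40, nSnps = 100, nCycles = 2,
                   locations = c("A", "B"), trialsPerEnv = 2,
                   plotsGrid = c(5, 6), nMiFeatures = 20, seed = 9)
  ds <- generateDataset(cfg)
  ph <- ds$phenotypes
  # every plot references an existing line
  expect_true(all(ph$line_id %in% lineIds(ds$genotypes)))
  # controls appear repsControls times in each trial
  perTrial <- table(ph$line_id, paste(ph$year, ph$location, ph$trial))
  for (ctrl in ds$truth$controls) {
    expect_true(all(perTrial[ctrl, ] == cfg$repsControls))
  }
  # neighbour counts from the spatial kernel construction
  S <- ds$truth$spatialKernel
  lay <- data.frame(plot_id = ph$plot_id,
                    trial = paste(ph$year, ph$location, ph$trial),
                    row = ph$row, col = ph$col)
  for (tr in unique(lay$trial)) {
    sub <- lay[lay$trial == tr, ]
    nb <- vapply(seq_len(nrow(sub)), function(i) {
      sum(pmax(abs(sub$row - sub$row[i]), abs(sub$col - sub$col[i])) == 1)
    }, numeric(1))
    expect_true(all(nb <= 8))
  }
})

test_that("simulated variance components are calibrated to the configuration", {
  # realized additive variance matches exactly by construction; the other
  # components match within Monte-Carlo tolerance across seeds
  vcs <- list(Y = list(g = 0.3, l = 0.1, i_g = 0, i_l = 0, s = 0.05, m = 0,
                       e = 0.7, omics = 0))
  devs <- sapply(1:8, function(sd) {
    ds <- generateDataset(simConfig(
      nLines = 100, nSnps = 150, nCycles = 1, locations = "LocA",
      trialsPerEnv = 2, plotsGrid = c(6, 10), nMiFeatures = 5,
      varianceComponents = vcs, traitMeans = c(Y = 0), seed = sd))
    unlist(ds$truth$varianceComponents$Y[c("g", "l", "s", "e")])
  })
  expect_equal(unname(devs["g", ]), rep(0.3, 8), tolerance = 1e-10)
  expect_equal(unname(devs["s", ]), rep(0.05, 8), tolerance = 1e-10)
  # l and e are drawn, not rescaled: mean over seeds within 3 SE
  seL <- sqrt(2 * 0.1^2 / (100 - 1) / 8)
  expect_lt(abs(mean(devs["l", ]) - 0.1), 3 * seL)

  # zero-variance case
  ds0 <- generateDataset(simConfig(
    nLines = 50, nSnps = 100, nCycles = 1, locations = "LocA",
    trialsPerEnv = 1, plotsGrid = c(6, 10), nMiFeatures = 5,
    varianceComponents = list(Y = list(g = 0, l = 0, i_g = 0, i_l = 0, s = 0,
                                       m = 0, e = 1, omics = 0)),
    traitMeans = c(Y = 0), seed = 3))
  expect_equal(ds0$truth$varianceComponents$Y[["g"]], 0)
})

test_that("balanced two-rep design: line means regress on true g with slope 1 and expected heritability", {
  # closed form for a balanced design: h2(line mean) = g / (g + e/2)
  slopes <- c(); h2s <- c()
  for (sd in 1:20) {
    ds <- generateDataset(simConfig(
      nLines = 200, nSnps = 200, nCycles = 1, locations = "LocA",
      trialsPerEnv = 4, plotsGrid = c(10, 11), nControls = 2,
      repsControls = 5, nMiFeatures = 2,
      varianceComponents = list(Y = list(g = 0.3, l = 0, i_g = 0, i_l = 0,
                                         s = 0, m = 0, e = 0.7, omics = 0)),
      traitMeans = c(Y = 0), trialEffectSd = 0, seed = 100 + sd))
    ph <- ds$phenotypes
    cand <- setdiff(unique(ph$line_id), ds$truth$controls)
    mu <- tapply(ph$Y, ph$line_id, mean)[cand]
    g <- ds$truth$g[cand, "Y"]
    slopes <- c(slopes, coef(lm(mu ~ g))[[2]])
    h2s <- c(h2s, var(g) / var(mu))
  }
  expect_equal(mean(slopes), 1, tolerance = 0.05)
  expect_equal(mean(h2s), 0.3 / (0.3 + 0.7 / 2), tolerance = 0.05)
})

test_that("truth report covers traits and features and reflects the heritability mixture", {
  cfg <- simConfig(nLines = 60, nSnps = 100, nCycles = 1, locations = "LocA",
                   trialsPerEnv = 2, plotsGrid = c(6, 8), nMiFeatures = 400,
                   seed = 13,
                   varianceComponents = defaultTraitVariances()["GY"])
  ds <- generateDataset(cfg)
  rep <- truthReport(ds)
  expect_equal(sum(rep$type == "mi_feature"), 400L)
  expect_setequal(unique(rep$id[rep$type == "trait"]), "GY")
  # about 40% of features are pure noise (binomial tolerance at n = 400)
  zeroFrac <- mean(rep$value[rep$type == "mi_feature"] < 0.01)
  expect_lt(abs(zeroFrac - 0.40), 3 * sqrt(0.4 * 0.6 / 400) + 0.01)
})
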