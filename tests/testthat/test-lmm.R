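test_that("design assembly: fixed factor, incidence tabulations, missing-response handling", {
  df <- data.frame(y = c(1, 2, 3), line_id = c("A", "B", "A"),
                   year = 2021, location = "L", trial = "T1",
                   plot_id = c("p1", "p2", "p3"))
  des <- buildDesign(df, modelSpec("y", random = list(randomTerm("l", "line_id"))))
  expect_equal(ncol(des$X), 1L) # single trial level -> intercept-like column

  # same line in two environments maps to two distinct i_g columns
  G <- kernelMatrix(matrix(c(1, 0.5, 0.5, 1), 2,
                           dimnames = list(c("A", "B"), c("A", "B"))), "G")
  df2 <- data.frame(y = rnorm(4), line_id = c("A", "A", "B", "B"),
                    year = c(2021, 2022, 2021, 2022), location = "L",
                    trial = "T1", plot_id = paste0("p", 1:4))
  des2 <- buildDesign(df2, modelSpec("y", random = list(
    randomTerm("i_g", c("line_id", "year", "location"), kernel = G, gxe = TRUE))))
  tm <- des2$terms$i_g
  expect_equal(ncol(tm$Z), 4L)
  # block-diagonal covariance: same-env pairs carry G, cross-env pairs zero
  expect_equal(tm$K["A|2021:L", "B|2021:L"], 0.5)
  expect_equal(tm$K["A|2021:L", "B|2022:L"], 0)

  # X'X and Z'Z equal brute-force tabulations on a random small table
  set.seed(8)
  df3 <- data.frame(y = rnorm(30),
                    line_id = sample(LETTERS[1:6], 30, TRUE),
                    year = sample(2021:2022, 30, TRUE),
                    location = sample(c("N", "S"), 30, TRUE),
                    trial = sample(c("T1", "T2"), 30, TRUE),
                    plot_id = paste0("p", 1:30))
  des3 <- buildDesign(df3, modelSpec("y", random = list(randomTerm("l", "line_id"))))
  ZtZ <- crossprod(des3$terms$l$Z)
  counts <- table(df3$line_id)
  expect_equal(unname(diag(ZtZ)), as.numeric(counts[colnames(ZtZ)]))
  f <- factor(paste(df3$year, df3$location, df3$trial, sep = ":"))
  expect_equal(unname(crossprod(des3$X)),
               unname(crossprod(model.matrix(~f))))

  # missing responses dropped and logged; unknown kernel level is an error
  df4 <- df2
  df4$y[2] <- NA
  des4 <- buildDesign(df4, modelSpec("y", random = list(randomTerm("g", "line_id", G))))
  expect_equal(des4$n, 3L)
  expect_equal(des4$nDropped, 1L)
  df5 <- df2
  df5$line_id[1] <- "UNKNOWN"
  expect_error(buildDesign(df5, modelSpec("y", random = list(
    randomTerm("g", "line_id", G)))), "not in kernel")
})

test_that("REML: fixed-effects-only residual, balanced one-way ANOVA closed form, SEs", {
  set.seed(10)
  df <- data.frame(y = rnorm(40), year = rep(2021:2022, each = 20),
                   location = "L", trial = rep(c("T1", "T2"), 20),
                   line_id = "x", plot_id = paste0("p", 1:40))
  des <- buildDesign(df, modelSpec("y"))
  fit <- remlFit(des)
  X <- des$X
  rss <- sum(stats::lm.fit(X, df$y)$residuals^2)
  expect_equal(unname(vcEstimates(fit)[["e"]]), rss / (40 - qr(X)$rank),
               tolerance = 1e-6)

  ng <- 10; r <- 5
  set.seed(11)
  df2 <- data.frame(y = rnorm(ng * r) + rep(rnorm(ng, sd = 1.2), each = r),
                    grp = rep(sprintf("g%02d", 1:ng), each = r),
                    year = 2021, location = "L", trial = "T1")
  des2 <- buildDesign(df2, modelSpec("y", random = list(randomTerm("a", "grp"))))
  fit2 <- remlFit(des2)
  MSW <- sum((df2$y - ave(df2$y, df2$grp))^2) / (ng * (r - 1))
  MSB <- r * sum((tapply(df2$y, df2$grp, mean) - mean(df2$y))^2) / (ng - 1)
  expect_equal(unname(vcEstimates(fit2)), c((MSB - MSW) / r, MSW),
               tolerance = 1e-6)
  expect_true(isConverged(fit2))
  expect_true(all(is.finite(vcStandardErrors(fit2))))
})

test_that("REML is invariant to observation order and scales correctly with the response", {
  tr <- smallTrial(seed = 13, nLines = 40, nMi = 20)
  ph <- tr$ph
  spec <- modelSpec("GY", random = list(randomTerm("g", "line_id", tr$G),
                                        randomTerm("l", "line_id")))
  f1 <- remlFit(buildDesign(ph, spec))
  set.seed(1)
  f2 <- remlFit(buildDesign(ph[sample(nrow(ph)), ], spec))
  expect_equal(vcEstimates(f1), vcEstimates(f2), tolerance = 1e-5)

  ph3 <- ph
  ph3$GY <- 3 * ph3$GY
  f3 <- remlFit(buildDesign(ph3, spec))
  expect_equal(vcEstimates(f3), 9 * vcEstimates(f1), tolerance = 1e-4)
})

test_that("restricted log-likelihood is nondecreasing over accepted iterations", {
  tr <- smallTrial(seed = 17, nLines = 40, nMi = 20)
  spec <- modelSpec("GY", random = list(randomTerm("g", "line_id", tr$G),
                                        randomTerm("s", "plot_id", tr$S)))
  des <- buildDesign(tr$ph, spec)
  lls <- c()
  trace <- capture.output(remlFit(des, verbose = TRUE), type = "message")
  lls <- as.numeric(sub(".*logL +(-?[0-9.]+).*", "\\1", trace))
  expect_true(all(diff(lls) >= -1e-8))
})

test_that("BLUP solves the mixed-model equations and shows kernel-regression limits", {
  # identity kernel, one observation per entity: ridge shrinkage closed form
  set.seed(14)
  n <- 30
  df <- data.frame(y = rnorm(n), line_id = sprintf("L%02d", 1:n),
                   year = 2021, location = "L", trial = "T1")
  des <- buildDesign(df, modelSpec("y", random = list(randomTerm("a", "line_id"))))
  vc <- c(a = 0.6, e = 0.4)
  sol <- blupSolve(des, vc)
  shrunk <- 0.6 / (0.6 + 0.4) * (df$y - mean(df$y)) * (1 - 0) # approx; exact below
  # exact: u = sigma_a^2/(sigma_a^2+sigma_e^2) * (y - GLS mean); GLS mean = mean(y)
  expect_equal(unname(randomEffects(sol, "a")[df$line_id]),
               0.6 / (0.6 + 0.4) * (df$y - mean(df$y)), tolerance = 1e-8)

  # sigma2 -> 0 shrinks all effects to zero
  sol0 <- blupSolve(des, c(a = 1e-12, e = 1))
  expect_lt(max(abs(randomEffects(sol0, "a"))), 1e-9)

  # Henderson MME residual check with a dense nonsingular kernel
  m <- 8
  K <- crossprod(matrix(rnorm(m * m), m)) / m + diag(0.5, m)
  dimnames(K) <- list(LETTERS[1:m], LETTERS[1:m])
  KM <- kernelMatrix(K, "G")
  df2 <- data.frame(y = rnorm(24), line_id = rep(LETTERS[1:m], 3),
                    year = 2021, location = "L", trial = rep(c("T1", "T2"), 12))
  des2 <- buildDesign(df2, modelSpec("y", random = list(randomTerm("g", "line_id", KM))))
  vc2 <- c(g = 0.7, e = 0.9)
  s2 <- blupSolve(des2, vc2)
  X <- des2$X; Z <- des2$terms$g$Z
  lhs <- rbind(cbind(crossprod(X), crossprod(X, Z)),
               cbind(crossprod(Z, X), crossprod(Z) + (0.9 / 0.7) * solve(K)))
  rhs <- c(crossprod(X, df2$y), crossprod(Z, df2$y))
  solVec <- c(fixedEffects(s2), randomEffects(s2, "g"))
  expect_lt(max(abs(lhs %*% solVec - rhs)) / max(abs(rhs)), 1e-8)

  # masked entity with kernel covariance gets a nonzero prediction;
  # zero covariance predicts zero
  K3 <- diag(3); K3[1, 2] <- K3[2, 1] <- 0.8
  dimnames(K3) <- list(c("obs", "rel", "stranger"), c("obs", "rel", "stranger"))
  df3 <- data.frame(y = c(2.5, 2.1), line_id = "obs", year = 2021,
                    location = "L", trial = "T1")
  des3 <- buildDesign(df3, modelSpec("y", random = list(
    randomTerm("g", "line_id", kernelMatrix(K3, "G")))))
  s3 <- blupSolve(des3, c(g = 1, e = 0.5))
  u3 <- randomEffects(s3, "g")
  expect_gt(abs(u3[["rel"]]), 0)
  expect_equal(u3[["stranger"]], 0)
})

test_that("full model with extra variances fixed at zero equals the plain two-variance GBLUP fit", {
  tr <- smallTrial(seed = 19, nLines = 40, nMi = 20)
  ph <- tr$ph
  simple <- modelSpec("GY", random = list(randomTerm("g", "line_id", tr$G)))
  desS <- buildDesign(ph, simple)
  fitS <- remlFit(desS)

  full <- modelSpec("GY", random = list(
    randomTerm("g", "line_id", tr$G),
    randomTerm("i_g", c("line_id", "year", "location"), tr$G, gxe = TRUE),
    randomTerm("s", "plot_id", tr$S)))
  desF <- buildDesign(ph, full)
  fitF <- remlFit(desF, fixed = c(i_g = 0, s = 0))
  expect_equal(vcEstimates(fitF)[c("g", "e")], vcEstimates(fitS)[c("g", "e")],
               tolerance = 1e-3)
  sS <- blupSolve(desS, fitS)
  sF <- blupSolve(desF, fitF)
  expect_equal(randomEffects(sF, "g"), randomEffects(sS, "g"),
               tolerance = 1e-3)
})

test_that("non-convergence is reported explicitly and boundary collapse is flagged", {
  tr <- smallTrial(seed = 23, nLines = 40, nMi = 20)
  spec <- modelSpec("GY", random = list(randomTerm("g", "line_id", tr$G),
                                        randomTerm("l", "line_id")))
  des <- buildDesign(tr$ph, spec)
  lame <- remlFit(des, maxit = 1L, tolParam = 1e-14, tolLogl = 1e-14)
  expect_false(isConverged(lame))

  # response with no line structure: line variance collapses to the boundary
  set.seed(30)
  ph0 <- tr$ph
  ph0$GY <- rnorm(nrow(ph0))
  f0 <- remlFit(buildDesign(ph0, spec))
  expect_true(all(vcEstimates(f0) >= 0))
  expect_true(length(boundaryTerms(f0)) >= 1)
})
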