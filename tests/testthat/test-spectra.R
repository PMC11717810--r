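test_that("column normalization centers, scales, drops zero-variance columns, and is idempotent", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 4, 4), c = rnorm(3))
  sp <- spectraMatrix(m, kind = "MI")
  out <- normalizeColumns(sp)
  v <- spectraValues(out)
  expect_equal(unname(v[, "a"]), c(-1, 0, 1))
  expect_false("b" %in% colnames(v))
  expect_equal(out@info$droppedZeroVar, 1L)

  set.seed(2)
  sp2 <- normalizeColumns(spectraMatrix(matrix(rnorm(200), 20), kind = "MI"))
  v2 <- spectraValues(sp2)
  expect_lt(max(abs(colMeans(v2))), 1e-12)
  expect_equal(unname(apply(v2, 2, var)), rep(1, 10), tolerance = 1e-12)
  again <- normalizeColumns(sp2)
  expect_equal(spectraValues(again), v2, tolerance = 1e-12)

  expect_error(normalizeColumns(spectraMatrix(matrix(1, 5, 3), kind = "MI")),
               "zero variance")
})

test_that("Savitzky-Golay first derivative reproduces polynomial derivatives exactly, edges included", {
  k <- 0:40
  lin <- matrix(3 + 2 * k, 1)
  quad <- matrix(k^2, 1)
  cons <- matrix(rep(5, 41), 1)
  for (w in c(5, 11)) {
    spLin <- spectraMatrix(lin, kind = "NIR")
    dLin <- spectraValues(savgolFirstDerivative(spLin, window = w, polyorder = 2))
    expect_equal(unname(dLin[1, ]), rep(2, 41), tolerance = 1e-10)
    dCons <- spectraValues(savgolFirstDerivative(spectraMatrix(cons, kind = "NIR"),
                                                 window = w, polyorder = 2))
    expect_equal(unname(dCons[1, ]), rep(0, 41), tolerance = 1e-10)
    dQuad <- spectraValues(savgolFirstDerivative(spectraMatrix(quad, kind = "NIR"),
                                                 window = w, polyorder = 2))
    expect_equal(unname(dQuad[1, ]), 2 * k, tolerance = 1e-9)
  }
  sp <- spectraMatrix(lin, kind = "NIR")
  expect_error(savgolFirstDerivative(sp, window = 10), "odd")
  expect_error(savgolFirstDerivative(sp, window = 5, polyorder = 5), "smaller")
  expect_error(savgolFirstDerivative(sp, window = 43), "larger")
  expect_error(savgolFirstDerivative(spectraMatrix(lin, kind = "MI")), "NIR")
})

test_that("Q_MI kernel: single-feature outer product, trace identity, brute-force oracle", {
  sp1 <- spectraMatrix(matrix(c(1, 2, 3), 3, dimnames = list(c("p1", "p2", "p3"), NULL)),
                       kind = "MI")
  Q1 <- miKernel(normalizeColumns(sp1))
  expect_equal(unname(kernelValues(Q1)),
               matrix(c(1, 0, -1, 0, 0, 0, -1, 0, 1), 3), tolerance = 1e-12)

  set.seed(9)
  sp <- normalizeColumns(spectraMatrix(matrix(rnorm(600), 15), kind = "MI"))
  Q <- miKernel(sp)
  n <- nrow(spectraValues(sp))
  expect_equal(sum(diag(kernelValues(Q))), n - 1, tolerance = 1e-10)
  M <- spectraValues(sp)
  expect_equal(kernelValues(Q), M %*% t(M) / ncol(M), tolerance = 1e-12)

  expect_error(miKernel(spectraMatrix(matrix(rnorm(20), 5), kind = "MI")),
               "normalized")
})

test_that("Q_NIR kernel: component choice and eigendecomposition oracle", {
  set.seed(4)
  # rank-1 spectra: all plots are scalar multiples of one curve
  base <- sin(seq(0, 3, length.out = 30))
  m <- outer(rnorm(12, 1, 0.2), base)
  sp <- normalizeColumns(spectraMatrix(m, kind = "NIR"))
  Q1 <- nirKernel(sp, varTarget = 0.99)
  expect_identical(Q1@info$t, 1L)
  expect_equal(Q1@info$cumExplained[1], 1.0, tolerance = 1e-8)

  # low-rank-8 + tiny noise: t = 8 at the 99% target and the kernel matches
  # a from-scratch eigendecomposition truncated at 8
  scores <- matrix(rnorm(25 * 8), 25)
  load <- matrix(rnorm(8 * 40), 8)
  m2 <- scores %*% load + matrix(rnorm(25 * 40, sd = 0.01), 25)
  sp2 <- normalizeColumns(spectraMatrix(m2, kind = "NIR"))
  Q8 <- nirKernel(sp2, varTarget = 0.99)
  expect_identical(Q8@info$t, 8L)
  M <- spectraValues(sp2)
  eg <- eigen(crossprod(M) / (nrow(M) - 1), symmetric = TRUE)
  sc <- M %*% eg$vectors[, 1:8]
  expect_equal(kernelValues(Q8), sc %*% t(sc) / 8, tolerance = 1e-8)

  # varTarget = 1 retains the full rank
  Qfull <- nirKernel(sp2, varTarget = 1)
  expect_identical(Qfull@info$t, Qfull@info$rank)

  expect_error(nirKernel(sp2, varTarget = 0), "varTarget")
  expect_error(nirKernel(sp2, varTarget = 1.5), "varTarget")
})

test_that("kernels are equivariant to plot order and Q_NIR converges to the all-wavelength kernel", {
  set.seed(6)
  m <- matrix(rnorm(20 * 30), 20,
              dimnames = list(sprintf("p%02d", 1:20), NULL))
  sp <- normalizeColumns(spectraMatrix(m, kind = "MI"))
  Q <- kernelValues(miKernel(sp))
  perm <- sample(20)
  Qp <- kernelValues(miKernel(normalizeColumns(
    spectraMatrix(m[perm, ], kind = "MI"))))
  expect_equal(Qp, Q[perm, perm], tolerance = 1e-12)

  spN <- normalizeColumns(spectraMatrix(m, kind = "NIR"))
  Mfull <- spectraValues(spN)
  eg <- eigen(crossprod(Mfull) / (nrow(Mfull) - 1), symmetric = TRUE)
  cum <- cumsum(eg$values) / sum(eg$values)
  full <- Mfull %*% t(Mfull) / ncol(Mfull)
  dist <- vapply(c(0.5, 0.8, 0.95, 0.999999), function(vt) {
    Qt <- kernelValues(nirKernel(spN, varTarget = vt))
    sqrt(sum((Qt - full)^2))
  }, numeric(1))
  expect_true(all(diff(dist) <= 1e-8))
})
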