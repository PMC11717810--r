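#' Kernel scalars used by the heritability formulas
#'
#' Collects d(G) (mean diagonal of the genomic kernel), d(S) and mean(S)
#' for the spatial kernel (d(S) = 1 exactly by trace normalization), and
#' d(Q) for an omics kernel when present.
#'
#' @param G,S,Q [KernelMatrix-class] objects (Q optional).
#' @return named list `dG`, `dS`, `meanS`, and optionally `dQ`.
#' @export
kernelScalars <- function(G, S, Q = NULL) {
  out <- list(dG = meanDiag(G), dS = meanDiag(S), meanS = meanAll(S))
  if (!is.null(Q)) out$dQ <- meanDiag(Q)
  out
}

#' Assemble the plot-level phenotypic variance
#'
#' Weighted sum of the fitted variance components:
#' `sigma2_P = d(G) sigma2_g + sigma2_l + w_ig sigma2_ig + sigma2_il +
#' (d(S) - mean(S)) sigma2_s [+ sigma2_m] [+ d(Q) sigma2_u] + sigma2_e`,
#' where the malting-batch and omics contributions enter whenever the fit
#' contains those components.  The genomic-by-environment weight `w_ig` is
#' d(G) by default; `gxeDiagWeight = "one"` reproduces the alternative
#' reading in which the interaction term enters with weight 1.
#'
#' @param vc a [VCEstimates-class] or named variance vector.
#' @param scalars output of [kernelScalars()].
#' @param gxeDiagWeight `"dG"` (default) or `"one"`.
#' @return the phenotypic variance, with the per-component weights attached
#'   as attribute `"weights"`.
#' @export
assembleSigmaP <- function(vc, scalars, gxeDiagWeight = c("dG", "one")) {
  gxeDiagWeight <- match.arg(gxeDiagWeight)
  est <- if (is(vc, "VCEstimates")) vcEstimates(vc) else vc
  need <- c("dG", "dS", "meanS")
  if (any(c("u", "v") %in% names(est))) need <- c(need, "dQ")
  missing <- setdiff(need, names(scalars))
  if (length(missing)) {
    stop("missing kernel scalar(s): ", paste(missing, collapse = ", "))
  }
  w <- vapply(names(est), function(nm) {
    switch(nm,
      g = scalars$dG,
      l = 1,
      i_g = if (gxeDiagWeight == "dG") scalars$dG else 1,
      i_l = 1,
      s = scalars$dS - scalars$meanS,
      m = 1,
      u = scalars$dQ,
      v = scalars$dQ,
      e = 1,
      1)
  }, numeric(1))
  structure(sum(w * est), weights = w)
}

#' Plot-level narrow-sense heritability
#'
#' `h2 = d(G) sigma2_g / sigma2_P`, with the phenotypic variance assembled
#' by [assembleSigmaP()].  Values are returned unrounded; rounding to the
#' 2-decimal presentation convention is left to [presentationRound()].
#'
#' @param vc a [VCEstimates-class] or named variance vector containing `g`.
#' @param scalars output of [kernelScalars()].
#' @param ... passed to [assembleSigmaP()].
#' @return list with `h2`, `sigmaP2`, `addVar` (= d(G) sigma2_g).
#' @export
h2PlotLevel <- function(vc, scalars, ...) {
  est <- if (is(vc, "VCEstimates")) vcEstimates(vc) else vc
  if (!"g" %in% names(est)) stop("no genomic component 'g' in the estimates")
  sigmaP <- assembleSigmaP(est, scalars, ...)
  if (sigmaP <= 0) stop("undefined heritability: sigma2_P = 0")
  addVar <- scalars$dG * est[["g"]]
  list(h2 = addVar / as.numeric(sigmaP), sigmaP2 = as.numeric(sigmaP),
       addVar = addVar)
}

#' GOBLUP heritability decomposition
#'
#' Total narrow-sense heritability of the two-step GOBLUP model:
#' `h2 = h2_d + c_m2 * h2_M`, the direct heritability plus the omics
#' variance ratio times the heritability of the omics-predicted component.
#'
#' @param h2d direct heritability (step 1).
#' @param cm2 omics variance ratio (step 1).
#' @param h2M omics heritability (step 2).
#' @return the combined heritability.
#' @examples
#' goblupDecomposition(0.11, 0.21, 0.14)
#' @export
goblupDecomposition <- function(h2d, cm2, h2M) {
  stopifnot(is.numeric(h2d), is.numeric(cm2), is.numeric(h2M))
  h2d + cm2 * h2M
}

#' Presentation rounding (half away from zero)
#'
#' Rounds half away from zero, the convention used in the reported tables
#' (unlike base `round`, which rounds half to even).
#'
#' @param x numeric.
#' @param digits decimal places (default 2).
#' @export
presentationRound <- function(x, digits = 2L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Heritability report for fitted models
#'
#' One row per fit, mirroring the layout of the genetic-parameter tables:
#' direct heritability, omics variance ratio, omics heritability and the
#' combined h2 (for GBLUP fits only h2 is populated).
#'
#' @param fits list of [GblupFit-class] / [GoblupFit-class] objects.
#' @param gxeDiagWeight passed to [assembleSigmaP()].
#' @return data.frame with columns `trait`, `model`, `h2_d`, `c_m2`, `h2_M`,
#'   `h2`, `sigma_P2`, `status`.
#' @export
h2Report <- function(fits, gxeDiagWeight = "dG") {
  if (is(fits, "GblupFit") || is(fits, "GoblupFit")) fits <- list(fits)
  rows <- lapply(fits, function(fit) {
    if (is(fit, "GblupFit")) {
      h <- h2PlotLevel(fit@vc, fit@info$scalars, gxeDiagWeight = gxeDiagWeight)
      data.frame(trait = fit@trait, model = "GBLUP", h2_d = NA_real_,
                 c_m2 = NA_real_, h2_M = NA_real_, h2 = h$h2,
                 sigma_P2 = h$sigmaP2, status = "ok")
    } else {
      model <- paste0("GOBLUP-", fit@omicsKind)
      if (fit@status != "ok") {
        return(data.frame(trait = fit@info$trait, model = model,
                          h2_d = NA_real_, c_m2 = NA_real_, h2_M = NA_real_,
                          h2 = NA_real_, sigma_P2 = NA_real_,
                          status = "failed"))
      }
      sc <- fit@info$scalars
      est1 <- vcEstimates(fit@step1$vc)
      h1 <- h2PlotLevel(est1, sc, gxeDiagWeight = gxeDiagWeight)
      omicsName <- fit@info$omicsName
      cm2 <- sc$dQ * est1[[omicsName]] / h1$sigmaP2
      est2 <- vcEstimates(fit@step2$vc)
      h2M <- h2PlotLevel(est2, sc, gxeDiagWeight = gxeDiagWeight)$h2
      data.frame(trait = fit@info$trait, model = model, h2_d = h1$h2,
                 c_m2 = cm2, h2_M = h2M,
                 h2 = goblupDecomposition(h1$h2, cm2, h2M),
                 sigma_P2 = h1$sigmaP2, status = "ok")
    }
  })
  do.call(rbind, rows)
}

#' Simulation-based significance threshold for feature heritabilities
#'
#' Determines the null distribution of the plot-level heritability estimate
#' under the specific statistical design: phenotype vectors are simulated
#' from the fitted null model (all non-genomic components at their
#' estimated variances, additive genomic variance zero), the full model is
#' refitted to each, and the empirical `(1 - alpha)` quantile of the
#' resulting h2 estimates is the significance threshold.  A feature is
#' declared significantly heritable when its estimated h2 exceeds the
#' threshold.
#'
#' @param design output of [buildDesign()] for the full model (including
#'   the genomic term `g`).
#' @param vcNull named variances of the null model: the fitted components
#'   with `g` forced to 0 (a `g` entry, if present, is ignored).
#' @param scalars output of [kernelScalars()].
#' @param alpha significance level (default 0.01).
#' @param nSim number of null simulations (default 1000, minimum 100 for a
#'   stable quantile; smaller values error).
#' @param seed RNG seed.
#' @param ... passed to [remlFit()] for the refits.
#' @return list with `threshold`, the vector `h2Null`, `nFail` (refit
#'   failures) and `status` (`"ok"`, or `"unreliable"` when more than 10%
#'   of refits failed).
#' @export
h2SignificanceThreshold <- function(design, vcNull, scalars, alpha = 0.01,
                                    nSim = 1000L, seed = 1L, ...) {
  if (nSim < 100L) stop("nSim must be at least 100")
  stopifnot(alpha > 0, alpha <= 1)
  est <- if (is(vcNull, "VCEstimates")) vcEstimates(vcNull) else vcNull
  est <- est[setdiff(names(est), "g")]
  need <- c(setdiff(names(design$terms), "g"), "e")
  if (!all(need %in% names(est))) {
    stop("vcNull must provide variances for: ", paste(need, collapse = ", "))
  }
  n <- design$n
  Sigma <- diag(est[["e"]], n)
  for (nm in setdiff(names(design$terms), "g")) {
    Sigma <- Sigma + est[[nm]] * design$terms[[nm]]$V
  }
  L <- chol(Sigma + diag(1e-10 * mean(diag(Sigma)), n))
  set.seed(seed)
  h2null <- rep(NA_real_, nSim)
  for (i in seq_len(nSim)) {
    ysim <- drop(crossprod(L, stats::rnorm(n)))
    dsim <- design
    dsim$y <- ysim
    fit <- tryCatch(remlFit(dsim, ...), error = function(e) NULL)
    if (is.null(fit)) next
    h2null[i] <- tryCatch(
      h2PlotLevel(fit, scalars)$h2, error = function(e) NA_real_)
  }
  nFail <- sum(is.na(h2null))
  ok <- h2null[!is.na(h2null)]
  if (!length(ok)) stop("all null refits failed")
  threshold <- as.numeric(stats::quantile(ok, probs = 1 - alpha, type = 1))
  list(threshold = threshold, h2Null = ok, nFail = nFail,
       status = if (nFail > 0.1 * nSim) "unreliable" else "ok")
}
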