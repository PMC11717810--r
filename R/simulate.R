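#' Default per-trait variance components of the synthetic generator
#'
#' Plot-level variance components for the seven traits (grain yield GY,
#' protein content PC, and the malting traits WV, BG, EY, FS, WC), on the
#' scale of a commercial spring-barley programme: the additive variance
#' `g` and total phenotypic variance match the magnitudes observed in such
#' trials, the remainder is split across line, genotype-by-environment,
#' spatial, malting-batch and residual components, and `omics` is the
#' variance of the omics-mediated contribution to the trait (zero means no
#' omics path).
#'
#' @return named list of per-trait variance lists
#'   (`g`, `l`, `i_g`, `i_l`, `s`, `m`, `e`, `omics`).
#' @export
defaultTraitVariances <- function() {
  list(
    GY = list(g = 0.015, l = 0.020, i_g = 0.015, i_l = 0.020, s = 0.020,
              m = 0, e = 0.044, omics = 0.028),
    PC = list(g = 0.016, l = 0.030, i_g = 0.020, i_l = 0.030, s = 0.030,
              m = 0, e = 0.072, omics = 0.050),
    WV = list(g = 3.94e-4, l = 2e-4, i_g = 1e-4, i_l = 2e-4, s = 1e-4,
              m = 2e-4, e = 8.06e-4, omics = 2e-5),
    BG = list(g = 1817, l = 1500, i_g = 1000, i_l = 1500, s = 500,
              m = 1000, e = 4514, omics = 118),
    EY = list(g = 0.095, l = 0.080, i_g = 0.060, i_l = 0.080, s = 0.050,
              m = 0.080, e = 0.240, omics = 0.027),
    FS = list(g = 0.018, l = 0.150, i_g = 0.100, i_l = 0.150, s = 0.100,
              m = 0.150, e = 0.405, omics = 0.010),
    WC = list(g = 0.092, l = 0.020, i_g = 0.015, i_l = 0.020, s = 0.015,
              m = 0.020, e = 0.062, omics = 0.002)
  )
}

.defaultTraitMeans <- c(GY = 7.19, PC = 10.75, WV = 1.47, BG = 153,
                        EY = 82.28, FS = 4.91, WC = 5.11)

#' Configuration for the synthetic breeding-trial generator
#'
#' Defaults describe a two-cycle spring-barley programme: 600 candidate
#' lines tested over two years at two locations, four trials per
#' year-location environment on a 10 x 14 plot grid, two control lines
#' replicated three times per trial, an 8,198-SNP panel with 0.3%
#' missingness, 30,468 metabolomic intensities with a mixture of zero and
#' moderate-to-high feature heritabilities, and 141 NIR wavelengths
#' (950-1650 nm) built from eight smooth latent basis curves.
#'
#' @param nLines number of candidate lines (split evenly over cycles).
#' @param nSnps number of SNPs.
#' @param nCycles number of breeding cycles (one per year).
#' @param locations location labels.
#' @param trialsPerEnv trials per year-location environment.
#' @param plotsGrid `c(rows, cols)` per trial.
#' @param nControls number of control lines.
#' @param repsControls replicates of each control per trial.
#' @param familySize number of full-sib lines per cross.  Lines within a
#'   family segregate from the same two inbred founders, giving the
#'   within-cycle relatedness a breeding programme needs for genomic
#'   prediction to carry information.  `familySize = 1` makes every line
#'   an independent cross.  Families never span cycles.
#' @param nMiFeatures number of metabolomic intensities.
#' @param nNirWavelengths number of NIR wavelengths.
#' @param nirRange wavelength range in nm.
#' @param mafRange allele-frequency interval for SNP simulation.
#' @param inbreeding inbreeding coefficient F of the candidate lines: at
#'   each locus a line is homozygous for a randomly chosen parental allele
#'   with probability F, and otherwise carries the two parental alleles
#'   (the residual heterozygosity of advanced selfing generations).  The
#'   default 0.97 emulates F6 material and raises the mean diagonal of G
#'   to about 1.8; with `familySize = 1` and `inbreeding = 0` dosages are
#'   exactly Binomial(2, p) (Hardy-Weinberg sampling of unrelated lines).
#' @param missingRate genotype missingness fraction.
#' @param varianceComponents per-trait variance lists
#'   (see [defaultTraitVariances()]).
#' @param traitMeans per-trait means.
#' @param omicsH2Mixture list with `zeroFrac` (fraction of pure-noise
#'   features emulating empty spectral regions), `ranges` (list of
#'   heritability intervals) and `probs` (their probabilities among
#'   non-zero features).
#' @param nirH2Range heritability range of the NIR basis coefficients.
#' @param nGeneticFactors number of shared latent genetic factors driving
#'   the omics features.
#' @param trialEffectSd standard deviation of the fixed year-location-trial
#'   effects, as a multiple of the square root of the total trait variance.
#' @param batchSize plots per malting batch.
#' @param seed RNG seed; fully determines the generated dataset.
#' @return a validated `SimConfig` list.
#' @export
simConfig <- function(nLines = 600L, nSnps = 8198L, nCycles = 2L,
                      locations = c("LocA", "LocB"), trialsPerEnv = 4L,
                      plotsGrid = c(10L, 14L), nControls = 2L,
                      repsControls = 3L, familySize = 10L,
                      nMiFeatures = 30468L,
                      nNirWavelengths = 141L, nirRange = c(950, 1650),
                      mafRange = c(0.05, 0.5), inbreeding = 0.97,
                      missingRate = 0.003,
                      varianceComponents = defaultTraitVariances(),
                      traitMeans = .defaultTraitMeans,
                      omicsH2Mixture = list(
                        zeroFrac = 0.40,
                        ranges = list(c(0.01, 0.2), c(0.2, 0.5), c(0.5, 0.93)),
                        probs = c(0.50, 0.07, 0.03)),
                      nirH2Range = c(0.05, 0.45),
                      nGeneticFactors = 50L, trialEffectSd = 0.5,
                      batchSize = 30L, seed = 1L) {
  cfg <- list(nLines = as.integer(nLines), nSnps = as.integer(nSnps),
              nCycles = as.integer(nCycles), locations = locations,
              trialsPerEnv = as.integer(trialsPerEnv),
              plotsGrid = as.integer(plotsGrid),
              nControls = as.integer(nControls),
              repsControls = as.integer(repsControls),
              familySize = as.integer(familySize),
              nMiFeatures = as.integer(nMiFeatures),
              nNirWavelengths = as.integer(nNirWavelengths),
              nirRange = nirRange, mafRange = mafRange,
              inbreeding = inbreeding, missingRate = missingRate,
              varianceComponents = varianceComponents,
              traitMeans = traitMeans, omicsH2Mixture = omicsH2Mixture,
              nirH2Range = nirH2Range,
              nGeneticFactors = as.integer(nGeneticFactors),
              trialEffectSd = trialEffectSd,
              batchSize = as.integer(batchSize), seed = as.integer(seed))
  vcs <- unlist(cfg$varianceComponents)
  if (any(vcs < 0)) stop("all variance components must be non-negative")
  if (cfg$missingRate < 0 || cfg$missingRate >= 1) {
    stop("missingRate must be in [0, 1)")
  }
  if (cfg$nControls * cfg$repsControls > prod(cfg$plotsGrid)) {
    stop("controls alone exceed the trial grid")
  }
  structure(cfg, class = "SimConfig")
}

## draw a line-level genetic vector from the marker matrix, scaled so its
## realized sample variance equals exactly targetVar
.geneticDraw <- function(Qc, targetVar) {
  if (targetVar <= 0) return(numeric(nrow(Qc)))
  g <- drop(Qc %*% stats::rnorm(ncol(Qc)))
  g <- g - mean(g)
  g * sqrt(targetVar / stats::var(g))
}

.scaleToVar <- function(x, targetVar) {
  if (targetVar <= 0 || stats::var(x) == 0) return(rep(0, length(x)))
  x <- x - mean(x)
  x * sqrt(targetVar / stats::var(x))
}

#' Generate a synthetic breeding-trial dataset
#'
#' Produces genotypes, a plot-level phenotype table over a randomized
#' incomplete block layout with replicated controls, metabolomic and NIR
#' spectra, and a truth record, all generated forward from the
#' variance-component model that the analysis assumes: per trait, the
#' phenotype is the sum of fixed year-location-trial effects, an additive
#' genomic effect (g = Q alpha, scaled so its realized variance matches the
#' configured additive variance), line and genotype-by-environment effects,
#' a spatial effect drawn with the neighbour kernel of the generated
#' layout, a malting-batch effect, an omics-mediated contribution M beta
#' (for traits with a nonzero omics variance), and residual noise.
#' Metabolomic features combine shared latent genetic factors with
#' per-feature heritabilities following the configured mixture (including
#' pure-noise features); NIR spectra are built from eight smooth basis
#' curves (low-order polynomials plus Gaussian bumps) whose per-plot
#' coefficients carry genetic and environmental components.
#'
#' @param config a [simConfig()].
#' @return a `SyntheticDataset` list with elements `genotypes`
#'   ([GenotypeData-class] with missing calls), `phenotypes` (data.frame),
#'   `mi` and `nir` ([SpectraMatrix-class]), and `truth` (true breeding
#'   values, omics effects, realized variance components, feature
#'   heritabilities, and the complete dosage matrix).
#' @export
generateDataset <- function(config = simConfig()) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  traits <- names(config$varianceComponents)

  if (config$nLines == 0L) {
    return(structure(list(
      genotypes = genotypeData(matrix(numeric(0), 0, config$nSnps,
                                      dimnames = list(NULL, paste0("S", seq_len(config$nSnps))))),
      phenotypes = data.frame(), mi = NULL, nir = NULL,
      truth = list(), config = config), class = "SyntheticDataset"))
  }

  ## ---- lines and genotypes ----------------------------------------------
  candIds <- sprintf("L%04d", seq_len(config$nLines))
  cycleOf <- rep(seq_len(config$nCycles), length.out = config$nLines)
  cycleOf <- sort(cycleOf)
  names(cycleOf) <- candIds
  ctrlIds <- if (config$nControls > 0L) {
    sprintf("CTRL%d", seq_len(config$nControls))
  } else character(0)
  allIds <- c(candIds, ctrlIds)
  nAll <- length(allIds)

  ## genotypes: candidate lines segregate within full-sib families (two
  ## inbred founders per cross); controls are independent lines.  Marginal
  ## dosage distribution stays Binomial(2, p) per SNP.
  p <- stats::runif(config$nSnps, config$mafRange[1], config$mafRange[2])
  nS <- config$nSnps
  famOf <- integer(0)
  if (config$nLines > 0L) {
    fs <- max(1L, config$familySize)
    famOf <- unlist(lapply(seq_len(config$nCycles), function(ci) {
      nc <- sum(cycleOf == ci)
      1e4L * ci + rep(seq_len(ceiling(nc / fs)), each = fs)[seq_len(nc)]
    }))
  }
  drawLine <- function(a1, a2) {
    # selfed progeny of the cross a1 x a2: homozygous for a random parental
    # allele with probability F, residual F1 heterozygosity otherwise
    z <- ifelse(stats::runif(nS) < 0.5, a1, a2)
    if (config$inbreeding >= 1) return(2L * z)
    hom <- stats::runif(nS) < config$inbreeding
    ifelse(hom, 2L * z, a1 + a2)
  }
  doseComplete <- matrix(0, nAll, nS,
                         dimnames = list(allIds,
                                         sprintf("SNP%05d", seq_len(nS))))
  for (fam in unique(famOf)) {
    members <- which(famOf == fam)
    a1 <- stats::rbinom(nS, 1L, p)
    a2 <- stats::rbinom(nS, 1L, p)
    for (i in members) doseComplete[i, ] <- drawLine(a1, a2)
  }
  for (i in seq_along(ctrlIds)) {
    doseComplete[config$nLines + i, ] <-
      drawLine(stats::rbinom(nS, 1L, p), stats::rbinom(nS, 1L, p))
  }
  storage.mode(doseComplete) <- "double"
  doseObs <- doseComplete
  if (config$missingRate > 0) {
    nMiss <- round(config$missingRate * length(doseObs))
    doseObs[sample.int(length(doseObs), nMiss)] <- NA_real_
  }
  pObs <- colMeans(doseComplete) / 2
  Qc <- sweep(doseComplete, 2L, 2 * pObs, "-")

  ## ---- field layout ------------------------------------------------------
  years <- 2021L + seq_len(config$nCycles) - 1L
  rows <- config$plotsGrid[1]
  cols <- config$plotsGrid[2]
  cellsPerTrial <- rows * cols
  ctrlCells <- config$nControls * config$repsControls
  freeCells <- cellsPerTrial - ctrlCells
  layout <- list()
  for (ci in seq_len(config$nCycles)) {
    cyc <- candIds[cycleOf == ci]
    cellsPerEnv <- config$trialsPerEnv * freeCells
    if (length(cyc) > cellsPerEnv) {
      stop(sprintf(
        "infeasible layout: cycle %d has %d lines but only %d non-control plots per environment",
        ci, length(cyc), cellsPerEnv))
    }
    for (loc in config$locations) {
      envAssign <- sample(rep_len(sample(cyc), cellsPerEnv))
      k <- 0L
      for (tr in seq_len(config$trialsPerEnv)) {
        trialName <- sprintf("T%d", tr)
        cells <- expand.grid(row = seq_len(rows), col = seq_len(cols))
        occ <- character(cellsPerTrial)
        ctrlPos <- sample.int(cellsPerTrial, ctrlCells)
        occ[ctrlPos] <- rep(ctrlIds, each = config$repsControls)
        occ[occ == ""] <- envAssign[k + seq_len(freeCells)]
        k <- k + freeCells
        layout[[length(layout) + 1L]] <- data.frame(
          line_id = occ, year = years[ci], location = loc, trial = trialName,
          row = cells$row, col = cells$col, stringsAsFactors = FALSE)
      }
    }
  }
  ph <- do.call(rbind, layout)
  ph$trial_uid <- paste(ph$year, ph$location, ph$trial, sep = "_")
  ph$plot_id <- sprintf("%s_R%02d_C%02d", ph$trial_uid, ph$row, ph$col)
  ph$env <- paste(ph$year, ph$location, sep = "_")
  nPlots <- nrow(ph)
  ph$malting_batch <- paste0("B", (seq_len(nPlots) - 1L) %/% config$batchSize + 1L)

  ## spatial kernel of the generated layout (trial-unique coordinates)
  Slay <- data.frame(plot_id = ph$plot_id, trial = ph$trial_uid,
                     row = ph$row, col = ph$col)
  S <- spatialKernel(Slay)
  cholS <- chol(kernelValues(S) + diag(1e-8, nPlots))

  ## ---- shared latent genetic factors for omics --------------------------
  nF <- config$nGeneticFactors
  Fg <- Qc %*% matrix(stats::rnorm(config$nSnps * nF), config$nSnps)
  Fg <- scale(Fg) # unit variance per factor across lines
  rownames(Fg) <- allIds

  ## ---- metabolomic intensities ------------------------------------------
  mx <- config$omicsH2Mixture
  nMi <- config$nMiFeatures
  h2f <- numeric(nMi)
  nz <- stats::runif(nMi) >= mx$zeroFrac
  if (any(nz)) {
    grp <- sample.int(length(mx$ranges), sum(nz), replace = TRUE,
                      prob = mx$probs)
    lo <- vapply(mx$ranges, `[`, numeric(1), 1L)
    hi <- vapply(mx$ranges, `[`, numeric(1), 2L)
    h2f[nz] <- stats::runif(sum(nz), lo[grp], hi[grp])
  }
  Wmi <- matrix(stats::rnorm(nF * nMi), nF)
  gFeat <- Fg %*% Wmi                      # lines x features
  gFeat <- scale(gFeat)
  lineIdx <- match(ph$line_id, allIds)
  miValues <- sweep(gFeat[lineIdx, , drop = FALSE], 2L, sqrt(h2f), "*") +
    sweep(matrix(stats::rnorm(nPlots * nMi), nPlots), 2L, sqrt(1 - h2f), "*")
  rownames(miValues) <- ph$plot_id
  miAxis <- seq(0.70, 9.00, length.out = nMi)
  colnames(miValues) <- sprintf("MI%05d", seq_len(nMi))
  mi <- spectraMatrix(miValues, featureAxis = miAxis, kind = "MI",
                      info = list(trueH2 = h2f))

  ## ---- NIR spectra -------------------------------------------------------
  nW <- config$nNirWavelengths
  wl <- seq(config$nirRange[1], config$nirRange[2], length.out = nW)
  x01 <- (wl - min(wl)) / diff(range(wl))
  centers <- seq(0.1, 0.9, length.out = 4)
  Bnir <- rbind(rep(1, nW), x01, x01^2, x01^3,
                t(vapply(centers, function(cc) exp(-((x01 - cc) / 0.08)^2),
                         numeric(nW))))
  nB <- nrow(Bnir)
  h2nir <- stats::runif(nB, config$nirH2Range[1], config$nirH2Range[2])
  Wnir <- matrix(stats::rnorm(nF * nB), nF)
  gNir <- scale(Fg %*% Wnir)               # lines x basis
  coefs <- sweep(gNir[lineIdx, , drop = FALSE], 2L, sqrt(h2nir), "*") +
    sweep(matrix(stats::rnorm(nPlots * nB), nPlots), 2L, sqrt(pmax(1 - h2nir, 0)), "*")
  nirValues <- coefs %*% Bnir + matrix(stats::rnorm(nPlots * nW, sd = 0.02),
                                       nPlots)
  rownames(nirValues) <- ph$plot_id
  colnames(nirValues) <- sprintf("nm%04d", round(wl))
  nir <- spectraMatrix(nirValues, featureAxis = wl, kind = "NIR",
                       info = list(basisH2 = h2nir))

  ## ---- phenotypes --------------------------------------------------------
  envs <- unique(ph$env)
  trialUids <- unique(ph$trial_uid)
  batches <- unique(ph$malting_batch)
  comboEnv <- paste(ph$line_id, ph$env, sep = "|")
  combos <- unique(comboEnv)
  truthG <- matrix(0, nAll, length(traits), dimnames = list(allIds, traits))
  truthU <- matrix(0, nPlots, length(traits),
                   dimnames = list(ph$plot_id, traits))
  realized <- list()
  for (tn in traits) {
    v <- config$varianceComponents[[tn]]
    g <- .geneticDraw(Qc, v$g)
    l <- stats::rnorm(nAll, sd = sqrt(v$l))
    igl <- matrix(0, nAll, length(envs), dimnames = list(allIds, envs))
    for (ev in envs) igl[, ev] <- .geneticDraw(Qc, v$i_g)
    il <- stats::rnorm(length(combos), sd = sqrt(v$i_l))
    names(il) <- combos
    s <- .scaleToVar(drop(crossprod(cholS, stats::rnorm(nPlots))), v$s)
    mEff <- stats::rnorm(length(batches), sd = sqrt(v$m))
    names(mEff) <- batches
    bTrial <- stats::rnorm(length(trialUids),
                           sd = config$trialEffectSd *
                             sqrt(sum(unlist(v[c("g", "l", "i_g", "i_l",
                                                 "s", "m", "e")]))))
    names(bTrial) <- trialUids
    u <- if (v$omics > 0) {
      .scaleToVar(drop(miValues %*% stats::rnorm(nMi)), v$omics)
    } else {
      rep(0, nPlots)
    }
    e <- stats::rnorm(nPlots, sd = sqrt(v$e))
    yv <- config$traitMeans[[tn]] + bTrial[ph$trial_uid] + g[lineIdx] +
      l[lineIdx] + igl[cbind(lineIdx, match(ph$env, envs))] +
      il[comboEnv] + s + mEff[ph$malting_batch] + u + e
    ph[[tn]] <- as.numeric(yv)
    truthG[, tn] <- g
    truthU[, tn] <- u
    realized[[tn]] <- c(
      g = stats::var(g), l = stats::var(l),
      i_g = mean(apply(igl, 2L, stats::var)), i_l = stats::var(il),
      s = stats::var(s), m = if (length(batches) > 1L) stats::var(mEff) else 0,
      omics = stats::var(u), e = stats::var(e))
  }

  pheno <- ph[, c("plot_id", "line_id", "year", "location", "trial",
                  "row", "col", "malting_batch", traits)]
  rownames(pheno) <- NULL
  geno <- genotypeData(doseObs)
  structure(list(
    genotypes = geno, phenotypes = pheno, mi = mi, nir = nir,
    truth = list(g = truthG, omicsEffect = truthU,
                 varianceComponents = realized, featureH2 = h2f,
                 nirBasisH2 = h2nir, dosagesComplete = doseComplete,
                 controls = ctrlIds, cycleOf = cycleOf,
                 spatialKernel = S),
    config = config), class = "SyntheticDataset")
}

#' Summarize the truth record of a synthetic dataset
#'
#' One row per trait (realized variance components of each simulated effect
#' vector) followed by one row per omics feature (its true plot-level
#' heritability), for use by parameter-recovery tests.
#'
#' @param ds a `SyntheticDataset` from [generateDataset()].
#' @return data.frame with columns `id`, `type`, and the realized values.
#' @export
truthReport <- function(ds) {
  stopifnot(inherits(ds, "SyntheticDataset"))
  if (!length(ds$truth)) return(data.frame())
  tr <- ds$truth$varianceComponents
  traitRows <- do.call(rbind, lapply(names(tr), function(tn) {
    data.frame(id = tn, type = "trait", component = names(tr[[tn]]),
               value = as.numeric(tr[[tn]]), row.names = NULL)
  }))
  featRows <- data.frame(id = colnames(spectraValues(ds$mi)),
                         type = "mi_feature", component = "h2",
                         value = ds$truth$featureH2, row.names = NULL)
  rbind(traitRows, featRows)
}
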