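#' Cross-validation fold assignment
#'
#' `makeFolds` assigns candidate lines to `k` near-equal random folds
#' (sizes differ by at most one).  When breeding cycles are supplied the
#' assignment is stratified so every cycle contributes to every fold
#' (preventing accidental confounding with leave-one-cycle-out masking).
#' `makeLbco` builds the leave-one-breeding-cycle-out scheme: one run per
#' cycle, each masking all lines whose first tested year is that cycle.
#' Control lines are excluded from validation sets by passing candidate
#' lines only.
#'
#' @param lines character vector of candidate line ids (no controls).
#' @param k number of folds (default 5).
#' @param seed RNG seed.
#' @param cycles optional named vector (by line id) of breeding-cycle
#'   labels for stratification.
#' @return a `CVScheme` list with `kind`, `folds` (named integer vector,
#'   line -> fold), `k`, `seed`.
#' @export
makeFolds <- function(lines, k = 5L, seed = 1L, cycles = NULL) {
  stopifnot(k >= 2L)
  if (length(lines) < k) stop("fewer lines than folds")
  if (anyDuplicated(lines)) stop("duplicate line ids")
  set.seed(seed)
  if (is.null(cycles)) {
    ord <- sample(lines)
  } else {
    cyc <- cycles[lines]
    ord <- unlist(lapply(split(lines, cyc), sample), use.names = FALSE)
  }
  folds <- rep_len(seq_len(k), length(ord))
  names(folds) <- ord
  structure(list(kind = "fivefold", folds = folds[lines], k = k, seed = seed),
            class = "CVScheme")
}

#' @rdname makeFolds
#' @param pheno plot-level phenotype data.frame with `line_id` and `year`.
#' @param candidates candidate line ids (controls excluded).
#' @export
makeLbco <- function(pheno, candidates = unique(as.character(pheno$line_id))) {
  ph <- pheno[as.character(pheno$line_id) %in% candidates, ]
  firstYear <- tapply(as.character(ph$year), as.character(ph$line_id),
                      function(y) sort(y)[1L])
  cyc <- sort(unique(firstYear))
  if (length(cyc) < 2L) stop("LBCO needs at least 2 breeding cycles")
  folds <- match(firstYear, cyc)
  names(folds) <- names(firstYear)
  structure(list(kind = "lbco", folds = folds[candidates], k = length(cyc),
                 cycles = cyc, seed = NA_integer_),
            class = "CVScheme")
}

#' Fixed-effect-corrected phenotypes
#'
#' `y_c(plot) = y - X b_hat` using the fixed-effect solutions of the
#' whole-data fit, averaged per line.
#'
#' @param design output of [buildDesign()] for the whole-data model.
#' @param blup [BlupSolution-class] of the whole-data fit.
#' @return named numeric vector of per-line mean corrected phenotypes.
#' @export
correctedPhenotypes <- function(design, blup) {
  yc <- design$y - drop(design$X %*% fixedEffects(blup))
  mu <- tapply(yc, as.character(design$pheno$line_id), mean)
  out <- as.numeric(mu)
  names(out) <- names(mu)
  out
}

#' Dispersion slope of whole on partial GEBVs
#'
#' `b_w,p = cov(ghat_w, ghat_p) / var(ghat_p)` over the validation lines;
#' 1 indicates no inflation, values below 1 over-dispersion of the
#' partial-information GEBVs.
#'
#' @param gebvWhole,gebvPartial numeric vectors over the same lines.
#' @return the regression slope.
#' @export
dispersionSlope <- function(gebvWhole, gebvPartial) {
  stopifnot(length(gebvWhole) == length(gebvPartial))
  v <- stats::var(gebvPartial)
  if (!is.finite(v) || v == 0) stop("zero-variance partial GEBVs: slope undefined")
  stats::cov(gebvWhole, gebvPartial) / v
}

#' Bootstrap standard error of a statistic over validation lines
#'
#' Ordinary non-parametric bootstrap: validation lines are resampled with
#' replacement at full sample size, the statistic recomputed per replicate,
#' and the standard deviation across replicates reported.  Degenerate
#' replicates (statistic `NA`, e.g. zero variance) are dropped and counted.
#'
#' @param statistic function taking the resampled `data` and returning a
#'   scalar.
#' @param data data.frame (rows = validation lines).
#' @param nRep bootstrap replicates (default 10000).
#' @param seed RNG seed.
#' @return the SE, with attributes `nDropped` and `nRep`.
#' @export
bootstrapSE <- function(statistic, data, nRep = 10000L, seed = 1L) {
  n <- nrow(data)
  if (n < 2L) stop("bootstrap needs at least 2 validation lines")
  set.seed(seed)
  reps <- vapply(seq_len(nRep), function(i) {
    idx <- sample.int(n, n, replace = TRUE)
    tryCatch(as.numeric(statistic(data[idx, , drop = FALSE])),
             error = function(e) NA_real_)
  }, numeric(1))
  ok <- reps[is.finite(reps)]
  structure(stats::sd(ok), nDropped = nRep - length(ok), nRep = nRep)
}

#' Percent change in predictive ability
#'
#' `100 * (paNew - paRef) / paRef` with 1-decimal presentation rounding.
#'
#' @param paNew,paRef predictive abilities; `paRef` must be nonzero.
#' @param digits presentation digits (default 1; `NA` for unrounded).
#' @export
percentChange <- function(paNew, paRef, digits = 1L) {
  if (any(paRef == 0)) stop("zero reference: percent change undefined")
  pc <- 100 * (paNew - paRef) / paRef
  if (is.na(digits)) pc else presentationRound(pc, digits)
}

#' Pairwise paired model comparison with compact letter display
#'
#' Two-tailed paired t-tests on per-fold predictive abilities at the given
#' significance level; models sharing a letter are not significantly
#' different.  Identical per-fold values (t statistic undefined) are
#' treated as not different.  With fewer than 2 paired units the t-test is
#' not applicable and is reported as such (all models share a letter and
#' `status = "not-applicable"`); when per-line GEBV/phenotype pairs are
#' supplied via `lineStats`, a bootstrap interval for each pairwise PA
#' difference is substituted.
#'
#' @param paMatrix numeric matrix, folds x models (column names = model
#'   labels).
#' @param alpha critical p-value (default 0.01).
#' @param lineStats optional list, per model, of data.frames with columns
#'   `gebv` and `yc` over the pooled validation lines (rows aligned across
#'   models), used for the bootstrap substitute.
#' @param nBoot bootstrap replicates for the substitute test.
#' @param seed RNG seed for the substitute test.
#' @return list with `letters` (named character), `p` (pairwise p-value
#'   matrix), `status`, and for the bootstrap substitute `intervals`.
#' @export
compareModels <- function(paMatrix, alpha = 0.01, lineStats = NULL,
                          nBoot = 2000L, seed = 1L) {
  paMatrix <- as.matrix(paMatrix)
  m <- ncol(paMatrix)
  models <- colnames(paMatrix)
  if (is.null(models)) models <- colnames(paMatrix) <- paste0("M", seq_len(m))
  p <- matrix(NA_real_, m, m, dimnames = list(models, models))
  status <- "ok"
  intervals <- NULL
  if (nrow(paMatrix) < 2L) {
    status <- "not-applicable"
    if (!is.null(lineStats)) {
      intervals <- list()
      set.seed(seed)
      for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
        a <- lineStats[[models[i]]]
        b <- lineStats[[models[j]]]
        n <- nrow(a)
        d <- vapply(seq_len(nBoot), function(r) {
          idx <- sample.int(n, n, replace = TRUE)
          stats::cor(a$gebv[idx], a$yc[idx]) - stats::cor(b$gebv[idx], b$yc[idx])
        }, numeric(1))
        ci <- stats::quantile(d, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE)
        p[i, j] <- p[j, i] <- if (prod(sign(ci)) > 0) 0 else 1
        intervals[[paste(models[i], models[j], sep = "/")]] <- ci
      }
    }
  } else {
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      d <- paMatrix[, i] - paMatrix[, j]
      if (all(abs(d - mean(d)) < 1e-12)) {
        # zero-variance differences: identical folds share a letter, a
        # constant nonzero shift is an (infinitely) clear separation
        p[i, j] <- p[j, i] <- if (abs(mean(d)) < 1e-12) 1 else 0
      } else {
        p[i, j] <- p[j, i] <- stats::t.test(paMatrix[, i], paMatrix[, j],
                                            paired = TRUE)$p.value
      }
      if (is.na(p[i, j])) p[i, j] <- p[j, i] <- 1
    }
  }
  nonsig <- !is.na(p) & p >= alpha
  diag(nonsig) <- TRUE
  if (status == "not-applicable" && is.null(intervals)) nonsig[] <- TRUE
  letters <- .compactLetters(nonsig, order(-colMeans(paMatrix)))
  names(letters) <- models
  list(letters = letters, p = p, status = status, intervals = intervals)
}

## Compact letter display: maximal cliques of the non-significance graph,
## lettered in decreasing order of model mean.
.compactLetters <- function(nonsig, ord) {
  m <- nrow(nonsig)
  cliques <- list()
  grow <- function(set, candidates) {
    extendable <- FALSE
    for (v in candidates) {
      if (all(nonsig[v, set])) {
        extendable <- TRUE
        grow(c(set, v), candidates[candidates > v])
      }
    }
    if (!extendable) {
      maximal <- !any(vapply(setdiff(seq_len(m), set), function(v)
        all(nonsig[v, set]), logical(1)))
      if (maximal) cliques[[length(cliques) + 1L]] <<- sort(set)
    }
  }
  for (v in seq_len(m)) grow(v, seq_len(m)[seq_len(m) > v])
  cliques <- unique(cliques)
  # order cliques by the best (highest-mean) member
  rank <- match(seq_len(m), ord)
  cliques <- cliques[order(vapply(cliques, function(cl) min(rank[cl]),
                                  numeric(1)))]
  out <- rep("", m)
  for (i in seq_along(cliques)) {
    out[cliques[[i]]] <- paste0(out[cliques[[i]]], letters[i])
  }
  out
}

#' Run cross-validation for one trait and model family
#'
#' For each fold (or breeding-cycle run) the variance components and BLUPs
#' are refitted on the training observations only; the masked lines'
#' phenotypes never enter a training design, and for GOBLUP validation the
#' omics kernel is restricted to training plots, so masked plots contribute
#' neither phenotype nor omics rows.  GEBVs of masked lines are predicted
#' through the genomic kernel.  The headline predictive ability is the
#' Pearson correlation between the pooled masked-line GEBVs and their
#' line-mean fixed-effect-corrected phenotypes (per-fold values are also
#' reported).  LR-method accuracy ratios are computed from the nested
#' information states: genomic only (g), genomic + omics (gm), genomic +
#' phenotypes (gp, GBLUP), and whole information (gmp).
#'
#' A training fit whose omics variance collapses to the boundary is
#' refitted with that variance fixed at zero (the degenerate model it
#' converged to) and flagged in the audit table; a whole-data collapse is
#' an error, mirroring the exclusion of such trait/model combinations from
#' the validation tables.
#'
#' @param scheme a `CVScheme` from [makeFolds()] or [makeLbco()].
#' @param family `"GBLUP"`, `"GOBLUP-MI"` or `"GOBLUP-NIR"`.
#' @param trait trait column name.
#' @param pheno plot-level phenotype data.frame.
#' @param G,S kernels as in [fitGblup()].
#' @param omicsKernel plot-level omics kernel (required for GOBLUP
#'   families).
#' @param nBoot bootstrap replicates for the standard errors.
#' @param seed RNG seed for the bootstrap.
#' @param allowDegenerate when `TRUE`, a whole-data omics collapse is
#'   handled like a fold-level one (refit with the omics variance fixed at
#'   zero, flagged in `info$degenerateWhole`) instead of raising an error.
#' @param ... passed to the model-fitting functions.
#' @return a [CVResult-class].
#' @export
runCV <- function(scheme, family = c("GBLUP", "GOBLUP-MI", "GOBLUP-NIR"),
                  trait, pheno, G, S, omicsKernel = NULL, nBoot = 1000L,
                  seed = 1L, allowDegenerate = FALSE, ...) {
  family <- match.arg(family)
  stopifnot(inherits(scheme, "CVScheme"))
  isGoblup <- family != "GBLUP"
  if (isGoblup && is.null(omicsKernel)) {
    stop(family, " cross-validation requires the omics kernel")
  }
  candidates <- names(scheme$folds)
  pheno$line_id <- as.character(pheno$line_id)
  pheno$plot_id <- as.character(pheno$plot_id)

  ## whole-data fit: source of ghat_w (gmp/gp state) and of y_c
  fitW <- if (isGoblup) {
    fitGoblup(trait, pheno, G, S, omicsKernel, ...)
  } else {
    fitGblup(trait, pheno, G, S, ...)
  }
  degenerateWhole <- FALSE
  if (isGoblup && fitW@status != "ok") {
    if (!allowDegenerate) {
      stop("whole-data GOBLUP fit failed for trait ", trait, ": ",
           fitW@info$reason)
    }
    degenerateWhole <- TRUE
    fitW <- fitGoblup(trait, pheno, G, S, omicsKernel, omicsVariance = 0, ...)
  }
  gW <- gebv(fitW)
  blupW <- if (isGoblup) fitW@step1$blup else fitW@blup
  designW <- if (isGoblup) fitW@step1$design else fitW@info$design
  yc <- correctedPhenotypes(designW, blupW)

  nf <- max(scheme$folds)
  perFold <- vector("list", nf)
  pooled <- list()
  audit <- vector("list", nf)
  for (f in seq_len(nf)) {
    masked <- candidates[scheme$folds == f]
    isVal <- pheno$line_id %in% masked
    trainPh <- pheno[!isVal, , drop = FALSE]
    valPlots <- pheno$plot_id[isVal]
    if (isGoblup) {
      # a training fit whose omics variance collapses to the boundary is
      # refitted with that variance fixed at zero (the degenerate model it
      # converged to) and flagged
      fallback <- FALSE
      refit <- function(Q, step2Pheno = NULL) {
        fit <- fitGoblup(trait, trainPh, G, S, Q, step2Pheno = step2Pheno, ...)
        if (fit@status != "ok") {
          fallback <<- TRUE
          fit <- fitGoblup(trait, trainPh, G, S, Q, step2Pheno = step2Pheno,
                           omicsVariance = 0, ...)
        }
        fit
      }
      Qtrain <- omicsKernel[trainPh$plot_id]
      fit_g <- refit(Qtrain)
      fit_gm <- refit(omicsKernel, step2Pheno = pheno)
      st <- list(g = gebv(fit_g), gm = gebv(fit_gm))
      omicsEntitiesG <- entityIds(Qtrain)
      trainDesign <- fit_g@step1$design
    } else {
      fitT <- fitGblup(trait, trainPh, G, S, ...)
      st <- list(g = gebv(fitT))
      fallback <- FALSE
      omicsEntitiesG <- character(0)
      trainDesign <- fitT@info$design
    }
    audit[[f]] <- data.frame(
      fold = f, nMaskedLines = length(masked), nMaskedPlots = length(valPlots),
      trainHasMaskedPlots =
        length(intersect(trainDesign$pheno$plot_id, valPlots)) > 0,
      trainHasMaskedLines =
        length(intersect(trainDesign$pheno$line_id, masked)) > 0,
      omicsHasMaskedPlots = length(intersect(omicsEntitiesG, valPlots)) > 0,
      omicsBoundaryFallback = fallback
    )
    mlines <- intersect(masked, names(yc))
    paFold <- stats::cor(st$g[mlines], yc[mlines])
    perFold[[f]] <- data.frame(fold = f, n = length(mlines), pa = paFold)
    pooled[[f]] <- data.frame(
      line = mlines, fold = f,
      g = st$g[mlines],
      gm = if (isGoblup) st$gm[mlines] else NA_real_,
      whole = gW[mlines], yc = yc[mlines], row.names = NULL)
  }
  pooled <- do.call(rbind, pooled)
  perFold <- do.call(rbind, perFold)

  pa <- stats::cor(pooled$g, pooled$yc)
  slope <- dispersionSlope(pooled$whole, pooled$g)
  paSe <- bootstrapSE(function(d) stats::cor(d$g, d$yc), pooled,
                      nRep = nBoot, seed = seed)
  slopeSe <- bootstrapSE(function(d) dispersionSlope(d$whole, d$g), pooled,
                         nRep = nBoot, seed = seed + 1L)
  lr <- if (isGoblup) {
    c(g_gm = stats::cor(pooled$g, pooled$gm),
      gm_gmp = stats::cor(pooled$gm, pooled$whole),
      g_gmp = stats::cor(pooled$g, pooled$whole))
  } else {
    c(g_gp = stats::cor(pooled$g, pooled$whole))
  }
  new("CVResult", scheme = scheme$kind, family = family, trait = trait,
      pa = pa, paSe = as.numeric(paSe), slope = slope,
      slopeSe = as.numeric(slopeSe), perFold = perFold, lr = lr,
      info = list(pooled = pooled, audit = do.call(rbind, audit),
                  wholeFit = fitW, degenerateWhole = degenerateWhole))
}

#' Accessors for CVResult
#'
#' @param x a [CVResult-class].
#' @name cvAccessors
#' @aliases predictiveAbility lrRatios
NULL

#' @rdname cvAccessors
#' @export
setMethod("predictiveAbility", "CVResult", function(x) x@pa)

#' @rdname cvAccessors
#' @export
setMethod("lrRatios", "CVResult", function(x) x@lr)

setMethod("show", "CVResult", function(object) {
  cat(sprintf("CVResult: %s, %s, trait %s\n", object@scheme, object@family,
              object@trait))
  cat(sprintf("  PA = %.3f (SE %.3f), b_w,p = %.3f (SE %.3f)\n",
              object@pa, object@paSe, object@slope, object@slopeSe))
  cat("  LR ratios:", paste(sprintf("%s = %.3f", names(object@lr), object@lr),
                            collapse = ", "), "\n")
  invisible(object)
})
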