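#' Fitted GBLUP model (single-step genomic BLUP)
#'
#' @slot trait trait name.
#' @slot vc [VCEstimates-class] from AI-REML.
#' @slot blup [BlupSolution-class] at the fitted variances.
#' @slot info model metadata (terms, scalars, batch flag).
#' @exportClass GblupFit
setClass("GblupFit",
  representation(trait = "character", vc = "VCEstimates",
                 blup = "BlupSolution", info = "list")
)

setMethod("show", "GblupFit", function(object) {
  cat(sprintf("GblupFit for trait '%s' (%s)\n", object@trait,
              if (isConverged(object@vc)) "converged" else "NOT converged"))
  print(round(vcEstimates(object@vc), 6))
  invisible(object)
})

#' Traits measured after micro-malting (fitted with a malting-batch effect)
#' @export
maltingTraits <- function() c("WV", "BG", "EY", "FS", "WC")

## Standard random-term list of the field-trial model:
## g (genomic), l (line), i_g (genomic x env), i_l (line x env), s (spatial),
## optionally m (malting batch).
.gblupTerms <- function(G, S, maltingBatch) {
  terms <- list(
    randomTerm("g", "line_id", kernel = G),
    randomTerm("l", "line_id"),
    randomTerm("i_g", c("line_id", "year", "location"), kernel = G, gxe = TRUE),
    randomTerm("i_l", c("line_id", "year", "location")),
    randomTerm("s", "plot_id", kernel = S)
  )
  if (maltingBatch) {
    terms <- c(terms, list(randomTerm("m", "malting_batch")))
  }
  terms
}

#' Fit the GBLUP field-trial model for one trait
#'
#' Model terms: fixed year-location-trial combination; random additive
#' genomic effect (kernel G), genetic line effect, genomic-by-environment
#' and line-by-environment interactions (environment = year-location),
#' spatial neighbour effect (kernel S) and residual.  Malting traits add a
#' random malting-batch effect.
#'
#' @param trait trait column name (GY, PC, WV, BG, EY, FS, WC or any other
#'   numeric column of `pheno`).
#' @param pheno plot-level phenotype data.frame (columns `plot_id`,
#'   `line_id`, `year`, `location`, `trial`, and `malting_batch` when the
#'   batch effect is requested).
#' @param G genomic [KernelMatrix-class] over lines.
#' @param S spatial [KernelMatrix-class] over plots.
#' @param maltingBatch include the malting-batch random effect; default:
#'   `trait` is one of [maltingTraits()].
#' @param ... passed to [remlFit()].
#' @return a [GblupFit-class].
#' @export
fitGblup <- function(trait, pheno, G, S,
                     maltingBatch = trait %in% maltingTraits(), ...) {
  if (maltingBatch && !"malting_batch" %in% names(pheno)) {
    stop("malting_batch column required for the batch effect of trait ", trait)
  }
  spec <- modelSpec(trait, random = .gblupTerms(G, S, maltingBatch))
  design <- buildDesign(pheno, spec)
  vc <- remlFit(design, ...)
  blup <- blupSolve(design, vc)
  new("GblupFit", trait = trait, vc = vc, blup = blup,
      info = list(maltingBatch = maltingBatch,
                  scalars = kernelScalars(G = G, S = S),
                  design = design))
}

#' Fit the two-step GOBLUP model for one trait
#'
#' Step 1 fits the trait with the GBLUP terms plus a plot-level omics effect
#' whose covariance is the omics similarity kernel (Q_MI or Q_NIR).  Step 2
#' regresses the predicted omics effect from step 1 on the same genetic
#' design (without the omics term).  The combined breeding value of a line
#' is ghat1 + ghat2: the direct genomic effect plus the omics-mediated
#' genomic effect.
#'
#' When the omics variance collapses to the boundary in step 1 the fit is
#' reported as failed for the trait (status `"failed"`); step 2 is not run.
#'
#' @param trait trait column name.  GOBLUP-NIR is refused for `PC` (protein
#'   content is itself predicted from NIR spectra) unless `force = TRUE`.
#' @param pheno plot-level phenotype data.frame.
#' @param G,S kernels as in [fitGblup()].
#' @param omicsKernel [KernelMatrix-class] of kind `Q_MI` or `Q_NIR` over
#'   plots; must cover all phenotyped plots in `pheno`.
#' @param maltingBatch include the malting-batch effect (default by trait).
#' @param step2Pheno observations used in step 2.  Default: the step-1 rows.
#'   Supplying a larger table (e.g. including plots whose phenotypes are
#'   masked but whose omics records are available) adds their predicted
#'   omics effects as step-2 records.
#' @param step2Level `"plot"` (default: one step-2 record per observation)
#'   or `"line"` (records carry the per-line mean predicted omics effect).
#' @param omicsVariance optional value at which the omics variance is held
#'   fixed (not estimated).  Fixing it at 0 removes the omics path: the
#'   combined GEBVs then reproduce the plain GBLUP breeding values.
#' @param force override the PC/NIR refusal.
#' @param ... passed to [remlFit()].
#' @return a [GoblupFit-class].
#' @export
fitGoblup <- function(trait, pheno, G, S, omicsKernel,
                      maltingBatch = trait %in% maltingTraits(),
                      step2Pheno = NULL, step2Level = c("plot", "line"),
                      omicsVariance = NULL, force = FALSE, ...) {
  step2Level <- match.arg(step2Level)
  kind <- switch(kernelKind(omicsKernel), Q_MI = "MI", Q_NIR = "NIR",
                 stop("omicsKernel must be of kind Q_MI or Q_NIR"))
  if (kind == "NIR" && trait == "PC" && !force) {
    stop("GOBLUP-NIR is not offered for PC: protein content is directly ",
         "predicted from NIR spectra. Use force = TRUE to override.")
  }
  if (maltingBatch && !"malting_batch" %in% names(pheno)) {
    stop("malting_batch column required for the batch effect of trait ", trait)
  }
  omicsName <- if (kind == "MI") "u" else "v"
  terms1 <- c(.gblupTerms(G, S, maltingBatch),
              list(randomTerm(omicsName, "plot_id", kernel = omicsKernel)))
  spec1 <- modelSpec(trait, random = terms1)
  design1 <- buildDesign(pheno, spec1)
  vc1 <- if (is.null(omicsVariance)) {
    remlFit(design1, ...)
  } else {
    remlFit(design1, fixed = stats::setNames(omicsVariance, omicsName), ...)
  }
  blup1 <- blupSolve(design1, vc1)
  scalars <- kernelScalars(G = G, S = S, Q = omicsKernel)
  step1 <- list(vc = vc1, blup = blup1, design = design1)

  if (omicsName %in% boundaryTerms(vc1)) {
    return(new("GoblupFit", omicsKind = kind, step1 = step1, step2 = list(),
               gebvCombined = numeric(0), status = "failed",
               info = list(trait = trait, scalars = scalars,
                           reason = sprintf(
                             "omics variance (sigma2_%s) converged towards zero",
                             omicsName))))
  }

  uhat <- randomEffects(blup1, omicsName)
  ph2 <- if (is.null(step2Pheno)) design1$pheno else step2Pheno
  idx <- match(as.character(ph2$plot_id), names(uhat))
  if (anyNA(idx)) stop("step-2 plots missing from the omics kernel")
  ph2$.uhat <- uhat[idx]
  if (step2Level == "line") {
    mu <- tapply(ph2$.uhat, as.character(ph2$line_id), mean)
    ph2$.uhat <- as.numeric(mu[as.character(ph2$line_id)])
  }
  spec2 <- modelSpec(".uhat", random = .gblupTerms(G, S, maltingBatch))
  design2 <- buildDesign(ph2, spec2)
  vc2 <- remlFit(design2, ...)
  blup2 <- blupSolve(design2, vc2)
  g1 <- randomEffects(blup1, "g")
  g2 <- randomEffects(blup2, "g")
  stopifnot(identical(names(g1), names(g2)))
  new("GoblupFit", omicsKind = kind, step1 = step1,
      step2 = list(vc = vc2, blup = blup2, design = design2),
      gebvCombined = g1 + g2, status = "ok",
      info = list(trait = trait, scalars = scalars,
                  omicsName = omicsName, step2Level = step2Level))
}

#' @rdname gebv
#' @export
setMethod("gebv", "GblupFit", function(fit, ...) {
  randomEffects(fit@blup, "g")
})

#' @rdname gebv
#' @export
setMethod("gebv", "GoblupFit", function(fit, ...) {
  if (fit@status != "ok") {
    stop("GOBLUP fit failed (", fit@info$reason, "); no combined GEBVs")
  }
  fit@gebvCombined
})

setMethod("show", "GoblupFit", function(object) {
  cat(sprintf("GoblupFit (GOBLUP-%s) for trait '%s': %s\n",
              object@omicsKind, object@info$trait, object@status))
  if (object@status == "ok") {
    cat(sprintf("  combined GEBVs for %d lines\n", length(object@gebvCombined)))
  } else {
    cat("  ", object@info$reason, "\n")
  }
  invisible(object)
})
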