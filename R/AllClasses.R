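#' @import methods
NULL

#' Labelled similarity kernel for mixed-model covariance structures
#'
#' A `KernelMatrix` holds a symmetric positive semi-definite similarity
#' matrix over named entities (breeding lines or field plots) together with
#' the scalar summaries used by the heritability formulas: the mean diagonal
#' d(K) and the overall mean of the matrix.  Recognised kinds are `"G"`
#' (VanRaden genomic relationship), `"S"` (spatial neighbour kernel),
#' `"Q_MI"` (metabolomic similarity), `"Q_NIR"` (NIR similarity) and
#' `"identity"`.
#'
#' @slot values symmetric numeric matrix with entity ids as dimnames.
#' @slot kind character scalar, one of G, S, Q_MI, Q_NIR, identity.
#' @slot meanDiag mean of the diagonal, d(K).
#' @slot meanAll mean of all entries.
#' @slot info provenance metadata (construction parameters, logs).
#'
#' @seealso [kernelMatrix()], [vanRadenG()], [spatialKernel()],
#'   [miKernel()], [nirKernel()]
#' @exportClass KernelMatrix
setClass("KernelMatrix",
  representation(
    values = "matrix",
    kind = "character",
    meanDiag = "numeric",
    meanAll = "numeric",
    info = "list"
  )
)

setValidity("KernelMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) {
    return("kernel matrix must be square")
  }
  if (nrow(v) > 0L) {
    if (is.null(rownames(v)) || is.null(colnames(v))) {
      return("kernel matrix must carry entity ids as dimnames")
    }
    if (!identical(rownames(v), colnames(v))) {
      return("row and column entity ids differ")
    }
    if (anyDuplicated(rownames(v))) {
      return("duplicate entity ids")
    }
    asym <- max(abs(v - t(v)))
    if (asym > 1e-10) {
      return(sprintf("kernel not symmetric (max |K - K'| = %g)", asym))
    }
  }
  if (!object@kind %in% c("G", "S", "Q_MI", "Q_NIR", "identity")) {
    return(sprintf("unknown kernel kind '%s'", object@kind))
  }
  TRUE
})

#' SNP dosage matrix with quality-control history
#'
#' Dosages are coded 0/1/2 (count of the reference allele), `NA` for missing
#' calls.  Rows are lines, columns SNPs.
#'
#' @slot dosages numeric matrix, lines x SNPs, values in \[0, 2\] or NA
#'   (imputed dosages may be fractional).
#' @slot qcLog list recording QC and imputation steps applied.
#' @exportClass GenotypeData
setClass("GenotypeData",
  representation(dosages = "matrix", qcLog = "list")
)

setValidity("GenotypeData", function(object) {
  d <- object@dosages
  if (nrow(d) > 0L && (is.null(rownames(d)) || anyDuplicated(rownames(d)))) {
    return("line ids missing or duplicated")
  }
  if (ncol(d) > 0L && (is.null(colnames(d)) || anyDuplicated(colnames(d)))) {
    return("SNP ids missing or duplicated")
  }
  rng <- suppressWarnings(range(d, na.rm = TRUE))
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2)) {
    return("dosages outside [0, 2]")
  }
  TRUE
})

#' Plot-level spectra matrix (metabolomic intensities or NIR absorbances)
#'
#' @slot values numeric matrix, plots x features, plot ids as rownames.
#' @slot featureAxis strictly increasing numeric axis: chemical shift (ppm)
#'   for metabolomic intensities, wavelength (nm) for NIR.
#' @slot kind `"MI"` or `"NIR"`.
#' @slot history ordered character vector of preprocessing steps applied
#'   (append-only).
#' @slot info list of preprocessing metadata (dropped columns, filter
#'   parameters, PCA logs).
#' @exportClass SpectraMatrix
setClass("SpectraMatrix",
  representation(
    values = "matrix",
    featureAxis = "numeric",
    kind = "character",
    history = "character",
    info = "list"
  )
)

setValidity("SpectraMatrix", function(object) {
  if (!object@kind %in% c("MI", "NIR")) {
    return("kind must be 'MI' or 'NIR'")
  }
  if (length(object@featureAxis) != ncol(object@values)) {
    return("feature axis length does not match number of columns")
  }
  if (length(object@featureAxis) > 1L && any(diff(object@featureAxis) <= 0)) {
    return("feature axis must be strictly increasing")
  }
  if (nrow(object@values) > 0L && is.null(rownames(object@values))) {
    return("plot ids (rownames) required")
  }
  TRUE
})

#' REML variance-component estimates
#'
#' @slot estimates named numeric vector of variance components (term names
#'   plus `"e"` for the residual).
#' @slot se asymptotic standard errors from the inverse average-information
#'   matrix at the optimum.
#' @slot logLik restricted log-likelihood (up to an additive constant).
#' @slot converged logical.
#' @slot boundary names of components pinned at the lower boundary.
#' @slot iterations iterations used.
#' @slot info fitting metadata (algorithm trace, problem size).
#' @exportClass VCEstimates
setClass("VCEstimates",
  representation(
    estimates = "numeric",
    se = "numeric",
    logLik = "numeric",
    converged = "logical",
    boundary = "character",
    iterations = "integer",
    info = "list"
  )
)

setValidity("VCEstimates", function(object) {
  if (is.null(names(object@estimates))) {
    return("estimates must be named")
  }
  if (any(object@estimates < 0)) {
    return("variance estimates must be non-negative")
  }
  if (!all(object@boundary %in% names(object@estimates))) {
    return("boundary flags name unknown components")
  }
  TRUE
})

#' Solution of the mixed-model equations at fixed variance components
#'
#' @slot fixef named fixed-effect solutions.
#' @slot ranef named list of per-term effect solutions; kernel terms carry
#'   one entry per kernel entity (so unphenotyped lines obtain predictions
#'   through the kernel covariance).
#' @slot info solver metadata.
#' @exportClass BlupSolution
setClass("BlupSolution",
  representation(fixef = "numeric", ranef = "list", info = "list")
)

#' Two-step GOBLUP fit
#'
#' Bundles the step-1 fit (trait regressed on design plus the plot-level
#' omics term) and the step-2 fit (predicted omics effect regressed on the
#' same genetic design) together with the combined breeding values
#' ghat1 + ghat2.
#'
#' @slot omicsKind `"MI"` or `"NIR"`.
#' @slot step1 list with elements `vc` (VCEstimates) and `blup`
#'   (BlupSolution).
#' @slot step2 as `step1`, or empty when the fit failed.
#' @slot gebvCombined named per-line combined breeding values.
#' @slot status `"ok"` or `"failed"` (omics variance collapsed to the
#'   boundary in step 1).
#' @slot info variance ratios and scalars used.
#' @exportClass GoblupFit
setClass("GoblupFit",
  representation(
    omicsKind = "character",
    step1 = "list",
    step2 = "list",
    gebvCombined = "numeric",
    status = "character",
    info = "list"
  )
)

setValidity("GoblupFit", function(object) {
  if (!object@omicsKind %in% c("MI", "NIR")) {
    return("omicsKind must be 'MI' or 'NIR'")
  }
  if (!object@status %in% c("ok", "failed")) {
    return("status must be 'ok' or 'failed'")
  }
  TRUE
})

#' Cross-validation result for one trait / model family / scheme
#'
#' @slot scheme `"fivefold"` or `"lbco"`.
#' @slot family model family label (GBLUP, GOBLUP-MI, GOBLUP-NIR).
#' @slot trait trait name.
#' @slot pa pooled predictive ability (correlation of masked lines' GEBVs
#'   with fixed-effect-corrected phenotypes).
#' @slot paSe bootstrap standard error of `pa`.
#' @slot slope dispersion slope b_w,p = cov(ghat_w, ghat_p)/var(ghat_p).
#' @slot slopeSe bootstrap standard error of `slope`.
#' @slot perFold data.frame of per-fold predictive abilities and sizes.
#' @slot lr named LR-method accuracy ratios (g_gp or g_gm, gm_gmp, g_gmp).
#' @slot info per-line vectors and audit records.
#' @exportClass CVResult
setClass("CVResult",
  representation(
    scheme = "character",
    family = "character",
    trait = "character",
    pa = "numeric",
    paSe = "numeric",
    slope = "numeric",
    slopeSe = "numeric",
    perFold = "data.frame",
    lr = "numeric",
    info = "list"
  )
)
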