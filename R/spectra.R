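#' Construct a SpectraMatrix
#'
#' @param values numeric matrix, plots x features, plot ids as rownames.
#' @param featureAxis strictly increasing numeric feature axis (chemical
#'   shift in ppm for MI, wavelength in nm for NIR); defaults to the column
#'   index.
#' @param kind `"MI"` (metabolomic intensities) or `"NIR"` (near-infrared
#'   absorbances).
#' @param history preprocessing history (normally left empty).
#' @param info metadata list.
#' @return a [SpectraMatrix-class].
#' @export
spectraMatrix <- function(values, featureAxis = seq_len(ncol(values)),
                          kind = c("MI", "NIR"), history = character(),
                          info = list()) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(values))
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) && nrow(values) > 0L) {
    rownames(values) <- paste0("P", seq_len(nrow(values)))
  }
  new("SpectraMatrix", values = values, featureAxis = as.numeric(featureAxis),
      kind = kind, history = history, info = info)
}

#' Accessors for SpectraMatrix
#'
#' @param x a [SpectraMatrix-class].
#' @name spectraValues
#' @aliases featureAxis preprocessingHistory
NULL

#' @rdname spectraValues
#' @export
setMethod("spectraValues", "SpectraMatrix", function(x) x@values)

#' @rdname spectraValues
#' @export
setMethod("featureAxis", "SpectraMatrix", function(x) x@featureAxis)

#' @rdname spectraValues
#' @export
setMethod("preprocessingHistory", "SpectraMatrix", function(x) x@history)

setMethod("dim", "SpectraMatrix", function(x) dim(x@values))

setMethod("show", "SpectraMatrix", function(object) {
  cat(sprintf("SpectraMatrix (%s): %d plots x %d features\n",
              object@kind, nrow(object@values), ncol(object@values)))
  if (length(object@history)) {
    cat("  preprocessing:", paste(object@history, collapse = " -> "), "\n")
  }
  invisible(object)
})

#' Column-wise normalization of spectra
#'
#' Centers every feature column to mean zero and scales it to sample
#' variance one (denominator n - 1).  Zero-variance columns carry no
#' information and are dropped; the count is logged in the object's info.
#'
#' @param sp a [SpectraMatrix-class] with at least two plots.
#' @return normalized [SpectraMatrix-class]; history gains `"normalize"`.
#' @export
normalizeColumns <- function(sp) {
  v <- spectraValues(sp)
  if (nrow(v) < 2L) stop("normalization needs at least 2 plots")
  mu <- colMeans(v)
  sdv <- apply(v, 2L, stats::sd)
  keep <- sdv > 0
  if (!any(keep)) stop("all feature columns have zero variance")
  v <- sweep(v[, keep, drop = FALSE], 2L, mu[keep], "-")
  v <- sweep(v, 2L, sdv[keep], "/")
  spectraMatrix(v, featureAxis = sp@featureAxis[keep], kind = sp@kind,
                history = c(sp@history, "normalize"),
                info = c(sp@info, list(droppedZeroVar = sum(!keep))))
}

#' Savitzky-Golay first derivative of NIR spectra
#'
#' Computes, per plot, the first derivative of the spectrum with respect to
#' the feature index (unit spacing; the uniform 5 nm wavelength step makes
#' this proportional to d/dnm) by local least-squares polynomial fitting.
#' Edge points are handled by fitting the boundary window and evaluating its
#' derivative at the edge, so the output has the same length as the input
#' and derivatives of polynomials up to `polyorder` are exact everywhere.
#'
#' @param sp a [SpectraMatrix-class] of kind `"NIR"`.
#' @param window odd filter window length (default 11 points).
#' @param polyorder local polynomial order, `< window` (default 2).
#' @return derivative-transformed [SpectraMatrix-class]; history gains
#'   `"savgol_d1"`.
#' @export
savgolFirstDerivative <- function(sp, window = 11L, polyorder = 2L) {
  if (sp@kind != "NIR") stop("Savitzky-Golay derivative is defined for NIR spectra")
  v <- spectraValues(sp)
  if (window %% 2L == 0L) stop("window must be odd")
  if (polyorder >= window) stop("polyorder must be smaller than window")
  if (window > ncol(v)) stop("window larger than the number of features")
  out <- t(apply(v, 1L, signal::sgolayfilt,
                 p = polyorder, n = window, m = 1L, ts = 1))
  dimnames(out) <- dimnames(v)
  spectraMatrix(out, featureAxis = sp@featureAxis, kind = "NIR",
                history = c(sp@history, "savgol_d1"),
                info = c(sp@info, list(savgol = list(window = window,
                                                     polyorder = polyorder))))
}

#' Metabolomic similarity kernel
#'
#' Q_MI = M M' / q over plots, where M is the centered and scaled
#' (plots x q) matrix of metabolomic intensities.  With sample-variance
#' scaling, tr(Q_MI) = n - 1 exactly.
#'
#' @param sp normalized [SpectraMatrix-class] of kind `"MI"`.
#' @return a [KernelMatrix-class] of kind `"Q_MI"` over plots.
#' @export
miKernel <- function(sp) {
  if (!"normalize" %in% sp@history) {
    stop("miKernel requires normalized spectra (run normalizeColumns first)")
  }
  M <- spectraValues(sp)
  q <- ncol(M)
  kernelMatrix(tcrossprod(M) / q, "Q_MI", info = list(nFeatures = q),
               checkPSD = FALSE) # Gram matrix, PSD by construction
}

#' NIR similarity kernel via principal components
#'
#' Performs PCA (eigendecomposition of the feature correlation matrix; the
#' columns are already scaled) on the preprocessed wavelength matrix,
#' retains the smallest number of components `t` whose cumulative explained
#' variance reaches `varTarget`, and builds
#' Q_NIR = M M' / t from the plots x t score matrix.  Scores are not
#' re-standardized.
#'
#' @param sp normalized (and typically derivative-transformed)
#'   [SpectraMatrix-class] of kind `"NIR"`.
#' @param varTarget cumulative explained-variance target in (0, 1\];
#'   default 0.99.
#' @return a [KernelMatrix-class] of kind `"Q_NIR"`; `info` records the
#'   chosen `t` and the explained-variance curve.
#' @export
nirKernel <- function(sp, varTarget = 0.99) {
  if (!(is.numeric(varTarget) && varTarget > 0 && varTarget <= 1)) {
    stop("varTarget must lie in (0, 1]")
  }
  if (!"normalize" %in% sp@history) {
    stop("nirKernel requires normalized spectra (run normalizeColumns first)")
  }
  M0 <- spectraValues(sp)
  R <- crossprod(M0) / (nrow(M0) - 1)
  eg <- eigen(R, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  cumvar <- cumsum(ev) / sum(ev)
  tol <- max(ev) * 1e-10
  rk <- sum(ev > tol)
  t <- min(which(cumvar >= varTarget - 1e-12))
  t <- min(t, rk)
  scores <- M0 %*% eg$vectors[, seq_len(t), drop = FALSE]
  kernelMatrix(tcrossprod(scores) / t, "Q_NIR",
               info = list(t = t, cumExplained = cumvar, rank = rk,
                           varTarget = varTarget),
               checkPSD = FALSE)
}
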