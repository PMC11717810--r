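#' Construct a GenotypeData object
#'
#' @param dosages numeric matrix, lines x SNPs, entries 0/1/2 or NA (allowing
#'   fractional values after mean-dosage imputation); line ids as rownames,
#'   SNP ids as colnames.  Unnamed matrices are labelled `L1..` / `S1..`.
#' @param qcLog list of QC records (normally left to [snpQC()]).
#' @return a [GenotypeData-class].
#' @export
genotypeData <- function(dosages, qcLog = list()) {
  stopifnot(is.matrix(dosages))
  storage.mode(dosages) <- "double"
  if (is.null(rownames(dosages)) && nrow(dosages) > 0L) {
    rownames(dosages) <- paste0("L", seq_len(nrow(dosages)))
  }
  if (is.null(colnames(dosages)) && ncol(dosages) > 0L) {
    colnames(dosages) <- paste0("S", seq_len(ncol(dosages)))
  }
  new("GenotypeData", dosages = dosages, qcLog = qcLog)
}

#' @rdname dosages
#' @export
setMethod("dosages", "GenotypeData", function(x) x@dosages)

#' Accessors for GenotypeData
#'
#' @param x a [GenotypeData-class].
#' @name dosages
#' @aliases lineIds snpIds qcLog
NULL

#' @rdname dosages
#' @export
setMethod("lineIds", "GenotypeData", function(x) rownames(x@dosages))

#' @rdname dosages
#' @export
setMethod("snpIds", "GenotypeData", function(x) colnames(x@dosages))

#' @rdname dosages
#' @export
setMethod("qcLog", "GenotypeData", function(x) x@qcLog)

setMethod("dim", "GenotypeData", function(x) dim(x@dosages))

setMethod("show", "GenotypeData", function(object) {
  d <- object@dosages
  cat(sprintf("GenotypeData: %d lines x %d SNPs, %.2f%% missing\n",
              nrow(d), ncol(d), 100 * mean(is.na(d))))
  if (length(object@qcLog)) {
    cat(sprintf("  QC steps applied: %s\n",
                paste(names(object@qcLog), collapse = ", ")))
  }
  invisible(object)
})

#' Observed allele frequencies
#'
#' Reference-allele frequency per SNP computed on non-missing calls,
#' p_i = mean(dosage_i)/2.
#'
#' @param geno a [GenotypeData-class].
#' @return named numeric vector of per-SNP frequencies.
#' @export
alleleFrequencies <- function(geno) {
  colMeans(dosages(geno), na.rm = TRUE) / 2
}

#' SNP quality control
#'
#' Removes SNPs whose minor allele frequency (computed on observed calls)
#' falls below `mafMin` or whose call rate falls below `callrateMin`.
#' Column order of the survivors is preserved and the removals per rule are
#' recorded in the QC log.
#'
#' @param geno a [GenotypeData-class] with dosages in \{0, 1, 2, NA\}.
#' @param mafMin minimum minor allele frequency (default 0.05).
#' @param callrateMin minimum call rate (default 0.90).
#' @return filtered [GenotypeData-class]; `qcLog(x)$snpQC` lists the SNPs
#'   removed by each rule.
#' @examples
#' g <- genotypeData(matrix(c(0, 0, 0, 2, 1, 1), nrow = 3))
#' snpQC(g, mafMin = 0.05)
#' @export
snpQC <- function(geno, mafMin = 0.05, callrateMin = 0.90) {
  d <- dosages(geno)
  callrate <- colMeans(!is.na(d))
  p <- colMeans(d, na.rm = TRUE) / 2
  p[is.nan(p)] <- 0
  maf <- pmin(p, 1 - p)
  dropMaf <- maf < mafMin
  dropCall <- callrate < callrateMin
  keep <- !(dropMaf | dropCall)
  if (!any(keep)) {
    stop("SNP QC removed every SNP (empty panel)")
  }
  log <- list(
    mafMin = mafMin, callrateMin = callrateMin,
    removedMAF = colnames(d)[dropMaf],
    removedCallRate = colnames(d)[dropCall],
    kept = sum(keep)
  )
  genotypeData(d[, keep, drop = FALSE],
               qcLog = c(geno@qcLog, list(snpQC = log)))
}

#' Mean-dosage imputation of missing genotypes
#'
#' Each missing entry is replaced by twice the observed allele frequency of
#' its SNP (the SNP's mean dosage), leaving column means unchanged.
#'
#' @param geno a [GenotypeData-class]; QC should already have been applied.
#' @return [GenotypeData-class] with no missing entries.
#' @export
imputeMeanDosage <- function(geno) {
  d <- dosages(geno)
  miss <- is.na(d)
  nImp <- sum(miss)
  if (nImp) {
    obs <- colSums(!miss)
    if (any(obs == 0L)) {
      stop("SNP(s) with zero observed calls cannot be imputed: ",
           paste(colnames(d)[obs == 0L], collapse = ", "))
    }
    mu <- colMeans(d, na.rm = TRUE)
    idx <- which(miss, arr.ind = TRUE)
    d[idx] <- mu[idx[, 2L]]
  }
  genotypeData(d, qcLog = c(geno@qcLog, list(impute = list(nImputed = nImp))))
}

#' VanRaden genomic relationship matrix
#'
#' Centers the dosage matrix by twice the allele frequencies,
#' Q = dosages - 2p, and scales the cross-product by the sum of binomial
#' variances: G = QQ' / (2 * sum p_i (1 - p_i)).
#'
#' @param geno imputed [GenotypeData-class] (no missing entries, every SNP
#'   polymorphic).
#' @param freqs `"observed"` (default: frequencies computed from `geno`) or
#'   a numeric vector of external reference frequencies, one per SNP, e.g.
#'   from a training population when building G for a prediction set.
#' @return a [KernelMatrix-class] of kind `"G"` over the lines;
#'   `meanDiag(G)` is the d(G) scalar of the heritability formulas.
#' @examples
#' g <- genotypeData(matrix(c(0, 2), nrow = 2, dimnames = list(c("A", "B"), "s1")))
#' kernelValues(vanRadenG(g))
#' @export
vanRadenG <- function(geno, freqs = "observed") {
  d <- dosages(geno)
  if (anyNA(d)) stop("missing dosages: impute before computing G")
  if (identical(freqs, "observed")) {
    p <- colMeans(d) / 2
  } else {
    stopifnot(is.numeric(freqs), length(freqs) == ncol(d))
    p <- freqs
  }
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) {
    stop("degenerate panel: all SNPs monomorphic (2*sum p(1-p) = 0)")
  }
  Q <- sweep(d, 2L, 2 * p, "-")
  G <- tcrossprod(Q) / denom
  kernelMatrix(G, "G",
               info = list(nSNP = ncol(d), freqs = if (identical(freqs, "observed"))
                 "observed" else "external"))
}

#' Spatial neighbour similarity kernel for field-trial plots
#'
#' Builds the indicator matrix W in which `W[i, j] = 1` when plot j is one of
#' the (at most eight) row/column-adjacent plots of plot i within the same
#' trial (Chebyshev distance 1 on the row/column grid; the plot itself is
#' excluded and trials never share neighbours), then
#' S = WW' / (tr(WW')/n), so that tr(S) = n exactly.
#'
#' @param layout data.frame with columns `plot_id`, `trial`, `row`, `col`;
#'   plot coordinates must be unique within a trial.
#' @return a [KernelMatrix-class] of kind `"S"` over the plots; `meanAll(S)`
#'   is the mean(S) scalar of the heritability formulas.
#' @export
spatialKernel <- function(layout) {
  stopifnot(all(c("plot_id", "trial", "row", "col") %in% names(layout)))
  n <- nrow(layout)
  ids <- as.character(layout$plot_id)
  if (anyDuplicated(ids)) stop("duplicate plot_id in layout")
  W <- matrix(0, n, n, dimnames = list(ids, ids))
  for (tr in unique(layout$trial)) {
    ii <- which(layout$trial == tr)
    if (anyDuplicated(layout[ii, c("row", "col")])) {
      stop(sprintf("duplicate plot coordinates within trial '%s'", tr))
    }
    dr <- abs(outer(layout$row[ii], layout$row[ii], "-"))
    dc <- abs(outer(layout$col[ii], layout$col[ii], "-"))
    adj <- (pmax(dr, dc) == 1)
    W[ii, ii] <- adj + 0
  }
  WWt <- tcrossprod(W)
  trWWt <- sum(diag(WWt))
  if (trWWt == 0) {
    stop("degenerate spatial kernel: no plot has any neighbour")
  }
  S <- WWt / (trWWt / n)
  kernelMatrix(S, "S", info = list(nPlots = n,
                                   isolated = ids[rowSums(W) == 0]),
               checkPSD = FALSE) # WW' is a Gram matrix, PSD by construction
}
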