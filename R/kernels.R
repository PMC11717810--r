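#' Construct a KernelMatrix
#'
#' Validates symmetry, optionally checks positive semi-definiteness, and
#' records the scalar summaries d(K) (mean diagonal) and mean(K) used by the
#' plot-level heritability formulas.
#'
#' @param values square numeric matrix with entity ids as dimnames (a plain
#'   unnamed matrix is accepted and labelled `E1..En`).
#' @param kind one of `"G"`, `"S"`, `"Q_MI"`, `"Q_NIR"`, `"identity"`.
#' @param info list of provenance metadata.
#' @param checkPSD check the smallest eigenvalue against
#'   `-1e-8 * max(eigenvalue)`.  Default `NA` checks matrices up to
#'   600 x 600 (an O(n^3) eigendecomposition); pass `TRUE`/`FALSE` to force.
#' @return a [KernelMatrix-class].
#' @examples
#' K <- kernelMatrix(diag(3), kind = "identity")
#' meanDiag(K)
#' @export
kernelMatrix <- function(values, kind, info = list(), checkPSD = NA) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) && nrow(values) > 0L) {
    rownames(values) <- colnames(values) <- paste0("E", seq_len(nrow(values)))
  }
  values <- (values + t(values)) / 2
  if (is.na(checkPSD)) checkPSD <- nrow(values) <= 600L
  if (checkPSD && nrow(values) > 0L) {
    ev <- eigen(values, symmetric = TRUE, only.values = TRUE)$values
    lo <- min(ev)
    hi <- max(ev, 0)
    if (lo < -1e-8 * max(hi, 1)) {
      stop(sprintf("kernel '%s' is not PSD (min eigenvalue %g)", kind, lo))
    }
    info$minEigenvalue <- lo
  }
  n <- nrow(values)
  new("KernelMatrix",
    values = values, kind = kind,
    meanDiag = if (n) mean(diag(values)) else NA_real_,
    meanAll = if (n) mean(values) else NA_real_,
    info = info
  )
}

#' Identity kernel over a set of entities
#'
#' @param ids entity labels.
#' @return a [KernelMatrix-class] of kind `"identity"`.
#' @export
identityKernel <- function(ids) {
  v <- diag(length(ids))
  dimnames(v) <- list(ids, ids)
  kernelMatrix(v, "identity", checkPSD = FALSE)
}

#' Accessors for KernelMatrix
#'
#' `kernelValues` returns the similarity matrix, `kernelKind` its kind label,
#' `entityIds` the entity labels, `meanDiag` the mean diagonal d(K), and
#' `meanAll` the mean of all entries.
#'
#' @param x a [KernelMatrix-class].
#' @name kernelValues
#' @aliases kernelKind entityIds meanDiag meanAll
NULL

#' @rdname kernelValues
#' @export
setMethod("kernelValues", "KernelMatrix", function(x) x@values)

#' @rdname kernelValues
#' @export
setMethod("kernelKind", "KernelMatrix", function(x) x@kind)

#' @rdname kernelValues
#' @export
setMethod("entityIds", "KernelMatrix", function(x) rownames(x@values))

#' @rdname kernelValues
#' @export
setMethod("meanDiag", "KernelMatrix", function(x) x@meanDiag)

#' @rdname kernelValues
#' @export
setMethod("meanAll", "KernelMatrix", function(x) x@meanAll)

#' Subset a kernel to a set of entities
#'
#' @param x a [KernelMatrix-class].
#' @param i,j entity ids or indices; must be identical (principal submatrix).
#' @param ... unused.
#' @param drop ignored.
#' @export
setMethod("[", "KernelMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(j)) j <- i
  v <- x@values[i, j, drop = FALSE]
  if (!identical(rownames(v), colnames(v))) {
    stop("kernel subsets must be principal (same rows and columns)")
  }
  kernelMatrix(v, x@kind, info = c(x@info, list(subsetOf = nrow(x@values))),
               checkPSD = FALSE)
})

setMethod("dim", "KernelMatrix", function(x) dim(x@values))

setMethod("show", "KernelMatrix", function(object) {
  n <- nrow(object@values)
  cat(sprintf("KernelMatrix (kind '%s') over %d entities\n", object@kind, n))
  if (n) {
    cat(sprintf("  mean diagonal d(K) = %.4f, mean(K) = %.4f\n",
                object@meanDiag, object@meanAll))
  }
  invisible(object)
})
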