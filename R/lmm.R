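#' Declare a random model term
#'
#' A random term binds an observation-to-entity incidence (one or more
#' phenotype-table columns) to a covariance kernel.  With `kernel = NULL`
#' the term has identity covariance over its observed levels (line effects,
#' interaction deviations, malting batch).  With `gxe = TRUE` the term is a
#' genotype-by-environment interaction: `by[1]` names the column keyed to
#' the kernel (lines) and the remaining columns define the environment; the
#' covariance is block-diagonal, one copy of the kernel per environment
#' (zero covariance across environments).
#'
#' @param name term label; its variance component is reported under this
#'   name.
#' @param by character vector of phenotype-table column names.
#' @param kernel a [KernelMatrix-class] or `NULL` for identity covariance.
#' @param gxe logical; environment-block-diagonal kernel expansion.
#' @return an object of class `RandomTerm`.
#' @export
randomTerm <- function(name, by, kernel = NULL, gxe = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, is.character(by))
  if (gxe && (is.null(kernel) || length(by) < 2L)) {
    stop("gxe terms need a kernel and at least one environment column")
  }
  structure(list(name = name, by = by, kernel = kernel, gxe = gxe),
            class = "RandomTerm")
}

#' Declare a linear mixed model
#'
#' @param response name of the trait (or feature) column.
#' @param fixed character vector of columns whose interaction forms the
#'   single fixed factor (default the year-location-trial combination).
#' @param random list of [randomTerm()] objects.
#' @return an object of class `ModelSpec`.
#' @export
modelSpec <- function(response, fixed = c("year", "location", "trial"),
                      random = list()) {
  stopifnot(is.character(response), length(response) == 1L)
  if (!all(vapply(random, inherits, logical(1), "RandomTerm"))) {
    stop("random must be a list of randomTerm() objects")
  }
  structure(list(response = response, fixed = fixed, random = random),
            class = "ModelSpec")
}

.interactionLabel <- function(df, cols) {
  if (length(cols) == 1L) return(as.character(df[[cols]]))
  do.call(paste, c(lapply(cols, function(cl) as.character(df[[cl]])),
                   sep = ":"))
}

#' Assemble design matrices for a mixed model
#'
#' Builds the reference-level fixed-effect design X from the interaction of
#' the fixed columns, an incidence matrix Z and covariance kernel K per
#' random term (kernel terms carry a column for every kernel entity, so
#' entities without observations are predicted through the kernel
#' covariance), and the per-term marginal covariance contributions
#' V_k = Z K Z'.  Rows with a missing response are dropped and logged.
#'
#' @param pheno plot-level phenotype data.frame.
#' @param spec a [modelSpec()].
#' @return a list with elements `y`, `X`, `terms` (each with `name`, `Z`,
#'   `K`, `entities`, `V`), `n`, `nDropped`, and the retained `pheno` rows.
#' @export
buildDesign <- function(pheno, spec) {
  stopifnot(inherits(spec, "ModelSpec"))
  miss <- setdiff(c(spec$response, spec$fixed,
                    unique(unlist(lapply(spec$random, `[[`, "by")))),
                  names(pheno))
  if (length(miss)) {
    stop("column(s) absent from phenotype table: ", paste(miss, collapse = ", "))
  }
  keep <- !is.na(pheno[[spec$response]])
  nDropped <- sum(!keep)
  ph <- pheno[keep, , drop = FALSE]
  n <- nrow(ph)
  if (n == 0L) stop("no non-missing observations for response ", spec$response)
  y <- as.numeric(ph[[spec$response]])

  f <- factor(.interactionLabel(ph, spec$fixed))
  X <- if (nlevels(f) > 1L) {
    stats::model.matrix(~f)
  } else {
    matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  }

  terms <- lapply(spec$random, function(tm) {
    if (tm$gxe) {
      key <- as.character(ph[[tm$by[1L]]])
      env <- .interactionLabel(ph, tm$by[-1L])
      kid <- entityIds(tm$kernel)
      unknown <- setdiff(key, kid)
      if (length(unknown)) {
        stop(sprintf("term '%s': %d level(s) not in kernel (e.g. %s)",
                     tm$name, length(unknown), unknown[1L]))
      }
      combo <- paste(key, env, sep = "|")
      ents <- unique(combo)
      entKey <- key[match(ents, combo)]
      entEnv <- env[match(ents, combo)]
      Kbase <- kernelValues(tm$kernel)
      K <- Kbase[entKey, entKey, drop = FALSE] *
        outer(entEnv, entEnv, "==")
      dimnames(K) <- list(ents, ents)
      Z <- matrix(0, n, length(ents), dimnames = list(NULL, ents))
      Z[cbind(seq_len(n), match(combo, ents))] <- 1
    } else if (!is.null(tm$kernel)) {
      key <- .interactionLabel(ph, tm$by)
      ents <- entityIds(tm$kernel)
      unknown <- setdiff(key, ents)
      if (length(unknown)) {
        stop(sprintf("term '%s': %d level(s) not in kernel (e.g. %s)",
                     tm$name, length(unknown), unknown[1L]))
      }
      K <- kernelValues(tm$kernel)
      Z <- matrix(0, n, length(ents), dimnames = list(NULL, ents))
      Z[cbind(seq_len(n), match(key, ents))] <- 1
    } else {
      key <- .interactionLabel(ph, tm$by)
      ents <- sort(unique(key))
      K <- NULL
      Z <- matrix(0, n, length(ents), dimnames = list(NULL, ents))
      Z[cbind(seq_len(n), match(key, ents))] <- 1
    }
    V <- if (is.null(K)) tcrossprod(Z) else Z %*% K %*% t(Z)
    list(name = tm$name, Z = Z, K = K, entities = colnames(Z), V = V)
  })
  names(terms) <- vapply(spec$random, `[[`, character(1), "name")

  list(y = y, X = X, terms = terms, n = n, nDropped = nDropped, pheno = ph,
       response = spec$response)
}

## Restricted log-likelihood and projection pieces at variances theta.
## theta is c(<term variances>, e = residual variance).
.remlPieces <- function(design, theta) {
  n <- design$n
  m <- length(design$terms)
  V <- diag(theta[m + 1L], n)
  for (k in seq_len(m)) V <- V + theta[k] * design$terms[[k]]$V
  cholV <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(cholV)) return(NULL)
  Vinv <- chol2inv(cholV)
  X <- design$X
  VinvX <- Vinv %*% X
  XtVinvX <- crossprod(X, VinvX)
  cholC <- tryCatch(chol(XtVinvX), error = function(e) NULL)
  if (is.null(cholC)) return(NULL)
  P <- Vinv - VinvX %*% chol2inv(cholC) %*% t(VinvX)
  Py <- drop(P %*% design$y)
  ll <- -0.5 * (2 * sum(log(diag(cholV))) + 2 * sum(log(diag(cholC))) +
                  sum(design$y * Py))
  list(P = P, Py = Py, ll = ll)
}

.remlDerivs <- function(design, theta, pieces) {
  m <- length(design$terms)
  n <- design$n
  P <- pieces$P
  Py <- pieces$Py
  nc <- m + 1L
  trPV <- numeric(nc)
  yPVPy <- numeric(nc)
  W <- matrix(0, n, nc)
  for (k in seq_len(m)) {
    Vk <- design$terms[[k]]$V
    trPV[k] <- sum(P * Vk)
    w <- drop(Vk %*% Py)
    W[, k] <- w
    yPVPy[k] <- sum(Py * w)
  }
  trPV[nc] <- sum(diag(P))
  W[, nc] <- Py
  yPVPy[nc] <- sum(Py * Py)
  score <- -0.5 * (trPV - yPVPy)
  PW <- P %*% W
  AI <- 0.5 * crossprod(W, PW)
  qk <- c(vapply(design$terms, function(tm) ncol(tm$Z), numeric(1)), n)
  emTheta <- theta + theta^2 / qk * (yPVPy - trPV)
  list(score = score, AI = AI, em = emTheta)
}

#' REML variance-component estimation (average information with EM fallback)
#'
#' Maximizes the restricted likelihood of a Gaussian mixed model over all
#' variance components by Newton-type average-information (AI) updates with
#' step-halving.  When an AI step would leave the feasible region or
#' decrease the restricted log-likelihood, the expectation-maximization
#' update is substituted for that iteration.  Components whose estimates
#' collapse are pinned at a small boundary value
#' (`boundaryFactor * var(y)`) and flagged.  Convergence is declared when
#' the maximum relative parameter change falls below `tolParam` or the
#' restricted log-likelihood change falls below `tolLogl`.  Asymptotic
#' standard errors come from the inverse AI matrix at the optimum.
#'
#' @param design output of [buildDesign()].
#' @param init optional named starting values (term names plus `"e"`).
#' @param fixed optional named vector of components held fixed at the given
#'   values (excluded from the updates; zero is allowed and removes the
#'   term's covariance contribution).
#' @param maxit maximum iterations (default 200).
#' @param tolParam relative parameter-change tolerance (default 1e-8).
#' @param tolLogl restricted log-likelihood change tolerance (default 1e-6).
#' @param boundaryFactor lower boundary as a fraction of the phenotypic
#'   variance (default 1e-6).
#' @param verbose print the iteration trace.
#' @return a [VCEstimates-class]; non-convergence is reported explicitly in
#'   the `converged` slot, never silently.
#' @export
remlFit <- function(design, init = NULL, fixed = NULL, maxit = 200L,
                    tolParam = 1e-8, tolLogl = 1e-6, boundaryFactor = 1e-6,
                    verbose = FALSE) {
  m <- length(design$terms)
  nms <- c(names(design$terms), "e")
  n <- design$n
  p <- ncol(design$X)
  if (n <= p) stop("more fixed-effect parameters than observations")
  vary <- stats::var(design$y)
  if (!is.finite(vary) || vary <= 0) vary <- 1
  bound <- boundaryFactor * vary
  theta <- rep(vary / (m + 1L), m + 1L)
  names(theta) <- nms
  if (!is.null(init)) {
    stopifnot(all(names(init) %in% nms))
    theta[names(init)] <- pmax(init, bound)
  }
  pinned <- rep(FALSE, m + 1L)
  isFixed <- rep(FALSE, m + 1L)
  if (!is.null(fixed)) {
    stopifnot(all(names(fixed) %in% nms), all(fixed >= 0))
    if ("e" %in% names(fixed) && fixed[["e"]] == 0) {
      stop("the residual variance cannot be fixed at zero")
    }
    theta[names(fixed)] <- fixed
    isFixed[match(names(fixed), nms)] <- TRUE
    pinned <- pinned | isFixed
  }

  pieces <- .remlPieces(design, theta)
  if (is.null(pieces)) stop("initial covariance matrix is singular")
  ll <- pieces$ll
  converged <- FALSE
  iter <- 0L
  AI <- NULL
  for (iter in seq_len(maxit)) {
    d <- .remlDerivs(design, theta, pieces)
    AI <- d$AI
    free <- which(!pinned)
    delta <- rep(0, m + 1L)
    Afree <- d$AI[free, free, drop = FALSE]
    # mild ridge stabilizes near-singular AI matrices (flat directions)
    ridge <- 1e-8 * mean(diag(Afree))
    sol <- tryCatch(solve(Afree + diag(ridge, nrow(Afree)), d$score[free]),
                    error = function(e) NULL)
    accepted <- FALSE
    newTheta <- theta
    newPieces <- NULL
    if (!is.null(sol)) {
      # cap the initial step so no component moves by more than 10x its size
      cap <- max(abs(sol) / pmax(theta[free], bound))
      step <- if (cap > 10) 10 / cap else 1
      for (h in 1:30) {
        cand <- theta
        cand[free] <- theta[free] + step * sol
        if (all(cand[free] > 0)) {
          cp <- .remlPieces(design, cand)
          if (!is.null(cp) && cp$ll >= ll - 1e-10) {
            newTheta <- cand
            newPieces <- cp
            accepted <- TRUE
            break
          }
        }
        step <- step / 2
      }
    }
    if (!accepted) {
      # EM update: guaranteed uphill, always feasible after clamping
      cand <- theta
      cand[free] <- pmax(d$em[free], bound)
      cp <- .remlPieces(design, cand)
      if (is.null(cp)) break
      newTheta <- cand
      newPieces <- cp
    }
    hitting <- which(!pinned & newTheta < bound)
    if (length(hitting)) {
      newTheta[hitting] <- bound
      pinned[hitting] <- TRUE
      newPieces <- .remlPieces(design, newTheta)
      if (is.null(newPieces)) break
    }
    relChange <- max(abs(newTheta - theta) / pmax(abs(theta), bound))
    dll <- newPieces$ll - ll
    if (verbose) {
      message(sprintf("it %3d  logL %.6f  dll %.2e  max rel %.2e  [%s]",
                      iter, newPieces$ll, dll, relChange,
                      paste(signif(newTheta, 4), collapse = " ")))
    }
    theta <- newTheta
    pieces <- newPieces
    ll <- pieces$ll
    if (relChange < tolParam || abs(dll) < tolLogl) {
      converged <- TRUE
      break
    }
  }
  d <- .remlDerivs(design, theta, pieces)
  AI <- d$AI
  se <- rep(NA_real_, m + 1L)
  names(se) <- nms
  covm <- tryCatch(solve(AI), error = function(e) NULL)
  if (!is.null(covm)) {
    dg <- diag(covm)
    se[dg > 0] <- sqrt(dg[dg > 0])
  }
  new("VCEstimates",
      estimates = theta, se = se, logLik = ll, converged = converged,
      boundary = nms[pinned & !isFixed], iterations = iter,
      info = list(n = n, rankX = p, bound = bound, varY = vary,
                  fixed = nms[isFixed]))
}

#' Accessors for VCEstimates
#'
#' @param x a [VCEstimates-class].
#' @name vcEstimates
#' @aliases vcStandardErrors isConverged boundaryTerms
NULL

#' @rdname vcEstimates
#' @export
setMethod("vcEstimates", "VCEstimates", function(x) x@estimates)

#' @rdname vcEstimates
#' @export
setMethod("vcStandardErrors", "VCEstimates", function(x) x@se)

#' @rdname vcEstimates
#' @export
setMethod("isConverged", "VCEstimates", function(x) x@converged)

#' @rdname vcEstimates
#' @export
setMethod("boundaryTerms", "VCEstimates", function(x) x@boundary)

setMethod("logLik", "VCEstimates", function(object, ...) object@logLik)

setMethod("show", "VCEstimates", function(object) {
  cat(sprintf("VCEstimates: %d components, restricted logL = %.4f (%s, %d it)\n",
              length(object@estimates), object@logLik,
              if (object@converged) "converged" else "NOT converged",
              object@iterations))
  df <- data.frame(estimate = object@estimates, se = object@se,
                   boundary = names(object@estimates) %in% object@boundary)
  print(df)
  invisible(object)
})

#' Solve the mixed-model equations at given variance components
#'
#' Computes GLS fixed-effect solutions and per-term BLUPs at the supplied
#' variances via the equivalent V-inverse form
#' `u_k = sigma2_k K_k Z_k' P y`, which requires no kernel inversion and
#' therefore yields predictions for every kernel entity, including lines
#' without phenotypic records (through the kernel covariance).
#'
#' @param design output of [buildDesign()].
#' @param vc a [VCEstimates-class] (or named variance vector) whose names
#'   match the design terms plus `"e"`.
#' @return a [BlupSolution-class].
#' @export
blupSolve <- function(design, vc) {
  theta <- if (is(vc, "VCEstimates")) vcEstimates(vc) else vc
  nms <- c(names(design$terms), "e")
  stopifnot(all(nms %in% names(theta)))
  theta <- theta[nms]
  n <- design$n
  m <- length(design$terms)
  V <- diag(theta[["e"]], n)
  for (k in seq_len(m)) V <- V + theta[k] * design$terms[[k]]$V
  cholV <- tryCatch(chol(V), error = function(e)
    stop("covariance matrix singular at the given variances"))
  Vinv <- chol2inv(cholV)
  X <- design$X
  VinvX <- Vinv %*% X
  XtVinvX <- crossprod(X, VinvX)
  beta <- tryCatch(solve(XtVinvX, crossprod(VinvX, design$y)),
                   error = function(e)
                     stop("regularization failure: X'V^{-1}X is singular"))
  beta <- drop(beta)
  names(beta) <- colnames(X)
  Py <- drop(Vinv %*% (design$y - X %*% beta))
  ranef <- lapply(seq_len(m), function(k) {
    tm <- design$terms[[k]]
    u <- if (is.null(tm$K)) {
      theta[k] * drop(crossprod(tm$Z, Py))
    } else {
      theta[k] * drop(tm$K %*% crossprod(tm$Z, Py))
    }
    names(u) <- tm$entities
    u
  })
  names(ranef) <- names(design$terms)
  resid <- theta[["e"]] * Py
  new("BlupSolution", fixef = beta, ranef = ranef,
      info = list(residuals = resid, Py = Py, theta = theta,
                  n = n))
}

#' Accessors for BlupSolution
#'
#' @param x a [BlupSolution-class].
#' @param term random-term name.
#' @name blupAccessors
#' @aliases fixedEffects randomEffects
NULL

#' @rdname blupAccessors
#' @export
setMethod("fixedEffects", "BlupSolution", function(x) x@fixef)

#' @rdname blupAccessors
#' @export
setMethod("randomEffects", "BlupSolution", function(x, term) {
  if (missing(term)) return(x@ranef)
  if (!term %in% names(x@ranef)) {
    stop(sprintf("no random term '%s' in this solution", term))
  }
  x@ranef[[term]]
})

setMethod("show", "BlupSolution", function(object) {
  cat(sprintf("BlupSolution: %d fixed effects, random terms: %s\n",
              length(object@fixef),
              paste(sprintf("%s[%d]", names(object@ranef),
                            lengths(object@ranef)), collapse = ", ")))
  invisible(object)
})
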