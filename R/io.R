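## TSV formats: tab-separated, "." decimal point, "NA" for missing, numeric
## payloads written with 15 significant digits so write-then-read
## round-trips to 1e-12 relative.

.writeTsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  for (j in which(num)) {
    out[[j]] <- ifelse(is.na(df[[j]]), "NA", sprintf("%.15g", df[[j]]))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
}

#' Read / write genotype TSV files
#'
#' Lines in rows, SNPs in columns; first column `line_id`; `NA` marks a
#' missing call.  On read, raw dosage files are validated to contain only
#' 0/1/2/NA tokens (`allowImputed = TRUE` accepts fractional dosages in
#' \[0, 2\], e.g. after mean-dosage imputation) and offending entries are
#' named.
#'
#' @param path file path.
#' @param allowImputed accept fractional dosages.
#' @return a [GenotypeData-class].
#' @export
readGenotypes <- function(path, allowImputed = FALSE) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (names(df)[1] != "line_id") {
    stop("genotype file must start with a 'line_id' column, found '",
         names(df)[1], "'")
  }
  ids <- df$line_id
  if (anyDuplicated(ids)) stop("duplicate line_id in genotype file")
  m <- as.matrix(df[, -1, drop = FALSE])
  vals <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m),
                                  dimnames = list(ids, colnames(m))))
  bad <- which((is.na(vals) & m != "NA") |
                 (!allowImputed & !is.na(vals) & !vals %in% c(0, 1, 2)),
               arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("invalid genotype token '%s' at line '%s', SNP '%s'",
                 m[bad[1, 1], bad[1, 2]], ids[bad[1, 1]],
                 colnames(m)[bad[1, 2]]))
  }
  genotypeData(vals)
}

#' @rdname readGenotypes
#' @param geno a [GenotypeData-class].
#' @export
writeGenotypes <- function(geno, path) {
  d <- dosages(geno)
  df <- data.frame(line_id = rownames(d), as.data.frame(d),
                   check.names = FALSE)
  .writeTsv(df, path)
  invisible(path)
}

#' Read / write plot-level phenotype TSV files
#'
#' Required columns: `plot_id`, `line_id`, `year`, `location`, `trial`,
#' `row`, `col`; optional `malting_batch`; remaining columns are trait
#' values.  `plot_id` must be unique and row/column positions unique within
#' a trial.
#'
#' @param path file path.
#' @return data.frame.
#' @export
readPhenotypes <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("plot_id", "line_id", "year", "location", "trial", "row", "col")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("phenotype file lacks required column(s): ",
         paste(miss, collapse = ", "))
  }
  if (anyDuplicated(df$plot_id)) {
    stop("duplicate plot_id in phenotype file: ",
         df$plot_id[anyDuplicated(df$plot_id)][1])
  }
  uid <- paste(df$year, df$location, df$trial, df$row, df$col)
  if (anyDuplicated(uid)) stop("duplicate row/col position within a trial")
  df
}

#' @rdname readPhenotypes
#' @param pheno phenotype data.frame.
#' @export
writePhenotypes <- function(pheno, path) {
  .writeTsv(pheno, path)
  invisible(path)
}

#' Read / write spectra TSV files
#'
#' Plot ids in the first column (`plot_id`); the remaining column headers
#' are the numeric feature axis (chemical shift in ppm, wavelength in nm).
#'
#' @param path file path.
#' @param kind `"MI"` or `"NIR"`.
#' @return a [SpectraMatrix-class].
#' @export
readSpectra <- function(path, kind = c("MI", "NIR")) {
  kind <- match.arg(kind)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  if (names(df)[1] != "plot_id") stop("spectra file must start with 'plot_id'")
  if (anyDuplicated(df$plot_id)) stop("duplicate plot_id in spectra file")
  axis <- suppressWarnings(as.numeric(names(df)[-1]))
  if (anyNA(axis)) stop("spectra header must be the numeric feature axis")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$plot_id
  spectraMatrix(m, featureAxis = axis, kind = kind)
}

#' @rdname readSpectra
#' @param sp a [SpectraMatrix-class].
#' @export
writeSpectra <- function(sp, path) {
  v <- spectraValues(sp)
  df <- data.frame(plot_id = rownames(v), as.data.frame(v),
                   check.names = FALSE)
  names(df)[-1] <- sprintf("%.15g", featureAxis(sp))
  .writeTsv(df, path)
  invisible(path)
}

#' Read / write kernel TSV files
#'
#' Symmetric matrix with entity ids in both the header and the first
#' column (`id`).
#'
#' @param path file path.
#' @param kind kernel kind for the reconstructed object.
#' @return a [KernelMatrix-class].
#' @export
readKernel <- function(path, kind) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  if (names(df)[1] != "id") stop("kernel file must start with an 'id' column")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$id
  kernelMatrix(m, kind, checkPSD = FALSE)
}

#' @rdname readKernel
#' @param kernel a [KernelMatrix-class].
#' @export
writeKernel <- function(kernel, path) {
  v <- kernelValues(kernel)
  df <- data.frame(id = rownames(v), as.data.frame(v), check.names = FALSE)
  .writeTsv(df, path)
  invisible(path)
}

#' Descriptive statistics for trait columns
#'
#' Minimum, mean, maximum, sample standard deviation and coefficient of
#' variation (CV% = 100 * SD / mean) per trait.
#'
#' @param pheno phenotype data.frame.
#' @param traits trait column names (default: all numeric columns other
#'   than the layout columns).
#' @return data.frame with one row per trait.
#' @export
descriptiveStats <- function(pheno, traits = NULL) {
  if (is.null(traits)) {
    layoutCols <- c("plot_id", "line_id", "year", "location", "trial",
                    "row", "col", "malting_batch")
    traits <- setdiff(names(pheno)[vapply(pheno, is.numeric, logical(1))],
                      layoutCols)
  }
  rows <- lapply(traits, function(tn) {
    x <- pheno[[tn]]
    x <- x[!is.na(x)]
    if (length(x) < 2L) stop("trait ", tn, " has fewer than 2 values")
    mu <- mean(x)
    sdv <- stats::sd(x)
    data.frame(trait = tn, min = min(x), mean = mu, max = max(x), sd = sdv,
               cv = if (mu == 0) NA_real_ else 100 * sdv / mu)
  })
  do.call(rbind, rows)
}

#' Read a pipeline run configuration
#'
#' YAML file whose keys mirror the [runPipeline()] arguments: either a
#' `simulate:` block of [simConfig()] overrides or input `paths:`
#' (genotypes/phenotypes/mi/nir), plus QC thresholds, Savitzky-Golay
#' parameters, the PCA variance target, trait/model selection, CV settings
#' and seeds.
#'
#' @param path YAML file path.
#' @return named list.
#' @examples
#' cfg <- readRunConfig(system.file("extdata", "example_run.yaml",
#'                                  package = "goblup"))
#' names(cfg)
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

#' Run the full analysis pipeline
#'
#' Chains the stages: (simulate or load) -> SNP QC and imputation ->
#' kernels (G, S, Q_MI, Q_NIR) -> per-trait model fits (GBLUP, GOBLUP-MI,
#' GOBLUP-NIR) -> heritability report -> cross-validation -> model
#' comparison, writing TSV reports and a manifest (seeds, package version,
#' every design switch in effect) to `outDir`.  Any stage failure halts
#' with a stage-named error; outputs of completed stages are retained.
#'
#' @param config list from [readRunConfig()] or [simConfig()]-style
#'   overrides under `simulate`.
#' @param outDir output directory (created if needed).
#' @return invisibly, a list with the fitted objects and report paths.
#' @export
runPipeline <- function(config = list(), outDir = tempfile("goblup_run_")) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  manifest <- list(package = "goblup",
                   version = as.character(utils::packageVersion("goblup")),
                   date = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                   config = config)

  ## stage: data
  ds <- stage("data", {
    if (!is.null(config$paths)) {
      list(genotypes = readGenotypes(config$paths$genotypes),
           phenotypes = readPhenotypes(config$paths$phenotypes),
           mi = if (!is.null(config$paths$mi)) readSpectra(config$paths$mi, "MI"),
           nir = if (!is.null(config$paths$nir)) readSpectra(config$paths$nir, "NIR"),
           truth = NULL, controls = config$controls)
    } else {
      sc <- do.call(simConfig, config$simulate %||% list())
      d <- generateDataset(sc)
      d$controls <- d$truth$controls
      d
    }
  })
  ph <- ds$phenotypes
  traits <- config$traits %||%
    intersect(c("GY", "PC", "WV", "BG", "EY", "FS", "WC"), names(ph))

  ## stage: genotype QC
  geno <- stage("qc", {
    g <- snpQC(ds$genotypes, mafMin = config$mafMin %||% 0.05,
               callrateMin = config$callrateMin %||% 0.90)
    imputeMeanDosage(g)
  })

  ## stage: kernels
  kernels <- stage("kernels", {
    G <- vanRadenG(geno)
    S <- spatialKernel(data.frame(plot_id = ph$plot_id,
                                  trial = paste(ph$year, ph$location,
                                                ph$trial, sep = "_"),
                                  row = ph$row, col = ph$col))
    Qmi <- if (!is.null(ds$mi)) miKernel(normalizeColumns(ds$mi))
    Qnir <- if (!is.null(ds$nir)) {
      nirKernel(savgolFirstDerivative(
        normalizeColumns(ds$nir),
        window = config$savgolWindow %||% 11L,
        polyorder = config$savgolPolyorder %||% 2L),
        varTarget = config$pcaVarTarget %||% 0.99)
    }
    list(G = G, S = S, Qmi = Qmi, Qnir = Qnir)
  })
  writeKernel(kernels$G, file.path(outDir, "kernel_G.tsv"))

  models <- config$models %||% c("GBLUP", "GOBLUP-MI", "GOBLUP-NIR")
  if ("GOBLUP-NIR" %in% models && "PC" %in% traits &&
      !isTRUE(config$forceNirPc)) {
    message("note: GOBLUP-NIR is skipped for PC ",
            "(protein content is directly predicted from NIR spectra)")
  }

  ## stage: fits
  fits <- stage("fit", {
    out <- list()
    for (tn in traits) {
      if ("GBLUP" %in% models) {
        out[[paste0(tn, ".GBLUP")]] <- fitGblup(tn, ph, kernels$G, kernels$S)
      }
      if ("GOBLUP-MI" %in% models && !is.null(kernels$Qmi)) {
        out[[paste0(tn, ".GOBLUP-MI")]] <-
          fitGoblup(tn, ph, kernels$G, kernels$S, kernels$Qmi)
      }
      if ("GOBLUP-NIR" %in% models && !is.null(kernels$Qnir) &&
          (tn != "PC" || isTRUE(config$forceNirPc))) {
        out[[paste0(tn, ".GOBLUP-NIR")]] <-
          fitGoblup(tn, ph, kernels$G, kernels$S, kernels$Qnir,
                    force = isTRUE(config$forceNirPc))
      }
    }
    out
  })

  ## stage: heritability report
  h2 <- stage("h2", h2Report(fits,
                             gxeDiagWeight = config$gxeDiagWeight %||% "dG"))
  h2Path <- file.path(outDir, "heritability.tsv")
  .writeTsv(h2, h2Path)

  dsPath <- file.path(outDir, "descriptive_stats.tsv")
  .writeTsv(descriptiveStats(ph, traits), dsPath)

  ## stage: cross-validation (optional)
  cv <- NULL
  if (isTRUE(config$cv$run %||% FALSE)) {
    cv <- stage("cv", {
      controls <- ds$controls %||% character(0)
      candidates <- setdiff(unique(as.character(ph$line_id)), controls)
      cycles <- tapply(as.character(ph$year), as.character(ph$line_id),
                       function(y) sort(y)[1])
      schemes <- list()
      if ("fivefold" %in% (config$cv$schemes %||% "fivefold")) {
        schemes$fivefold <- makeFolds(candidates, k = config$cv$k %||% 5L,
                                      seed = config$cv$seed %||% 1L,
                                      cycles = cycles)
      }
      if ("lbco" %in% (config$cv$schemes %||% "fivefold")) {
        schemes$lbco <- makeLbco(ph, candidates)
      }
      res <- list()
      for (sn in names(schemes)) for (tn in config$cv$traits %||% traits[1]) {
        for (fam in models) {
          if (fam == "GOBLUP-NIR" && tn == "PC") next
          Q <- switch(fam, `GOBLUP-MI` = kernels$Qmi,
                      `GOBLUP-NIR` = kernels$Qnir, NULL)
          res[[paste(sn, tn, fam, sep = ".")]] <-
            runCV(schemes[[sn]], fam, tn, ph, kernels$G, kernels$S,
                  omicsKernel = Q, nBoot = config$cv$nBoot %||% 1000L,
                  seed = config$cv$seed %||% 1L)
        }
      }
      res
    })
    cvTab <- do.call(rbind, lapply(cv, function(r)
      data.frame(scheme = r@scheme, trait = r@trait, family = r@family,
                 pa = r@pa, paSe = r@paSe, slope = r@slope,
                 slopeSe = r@slopeSe)))
    .writeTsv(cvTab, file.path(outDir, "cv_results.tsv"))
  }

  manifest$stagesCompleted <- c("data", "qc", "kernels", "fit", "h2",
                                if (!is.null(cv)) "cv")
  manifest$switches <- list(gxeDiagWeight = config$gxeDiagWeight %||% "dG",
                            savgolWindow = config$savgolWindow %||% 11L,
                            savgolPolyorder = config$savgolPolyorder %||% 2L,
                            pcaVarTarget = config$pcaVarTarget %||% 0.99,
                            mafMin = config$mafMin %||% 0.05,
                            callrateMin = config$callrateMin %||% 0.90)
  yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))
  invisible(list(dataset = ds, geno = geno, kernels = kernels, fits = fits,
                 h2 = h2, cv = cv, outDir = outDir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
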