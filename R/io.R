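# Readers and writers: dense CSV/TSV matrices, MatrixMarket sparse
# matrices with plain-text id sidecars, label/covariate/batch tables.

.readTable <- function(path, sep) {
  utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                    check.names = FALSE, stringsAsFactors = FALSE,
                    comment.char = "")
}

#' Load a labeled expression matrix
#'
#' Reads a samples x features matrix (dense CSV/TSV, or sparse
#' MatrixMarket MTX with row/column id sidecar files), a two-column label
#' file and optional covariate and batch tables, and assembles a
#' [LabeledDataset-class]. Empty cells and the configured missing tokens
#' map to missing values; for MTX, structural zeros become missing when
#' \code{zerosAsMissing} is set (scRNA-seq dropout convention), observed
#' zeros otherwise.
#'
#' Orientation: dense files default to samples in rows, MTX to features
#' in rows (the scRNA-seq convention); both are overridable since a
#' transposed matrix is the most common loading error.
#'
#' @param matrixPath path to the matrix file (.csv, .tsv/.txt or .mtx).
#' @param labelsPath path to a header-bearing CSV whose first column is
#'   the sample id and second column the class label.
#' @param covariatesPath optional CSV: sample id column, then numeric
#'   covariate columns.
#' @param batchesPath optional CSV: sample id column, then a batch id
#'   column.
#' @param orientation "auto" (default; by format as above), "samples"
#'   (samples in rows) or "features".
#' @param missingTokens character tokens parsed as missing in dense files.
#' @param zerosAsMissing for MTX: treat structural zeros as missing.
#' @param rowNamesPath,colNamesPath id sidecars for MTX (defaults:
#'   \code{<matrix>.rownames.txt} / \code{<matrix>.colnames.txt}).
#' @return a [LabeledDataset-class].
#' @export
loadLabeledMatrix <- function(matrixPath, labelsPath,
                              covariatesPath = NULL, batchesPath = NULL,
                              orientation = c("auto", "samples", "features"),
                              missingTokens = c("", "NA", "NaN", "nan"),
                              zerosAsMissing = FALSE,
                              rowNamesPath = NULL, colNamesPath = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(matrixPath))
    stop(sprintf("matrix file not found: %s", matrixPath), call. = FALSE)
  ext <- tolower(tools::file_ext(matrixPath))
  if (ext == "mtx") {
    m <- Matrix::readMM(matrixPath)
    stem <- sub("\\.mtx$", "", matrixPath, ignore.case = TRUE)
    if (is.null(rowNamesPath)) rowNamesPath <- paste0(stem, ".rownames.txt")
    if (is.null(colNamesPath)) colNamesPath <- paste0(stem, ".colnames.txt")
    if (!file.exists(rowNamesPath) || !file.exists(colNamesPath))
      stop("MTX matrices need row/column id sidecar files", call. = FALSE)
    rn <- readLines(rowNamesPath); cn <- readLines(colNamesPath)
    if (length(rn) != nrow(m) || length(cn) != ncol(m))
      stop("id sidecar lengths do not match the MTX dimensions", call. = FALSE)
    dense <- as.matrix(m)
    if (zerosAsMissing) dense[dense == 0] <- NA_real_
    dimnames(dense) <- list(rn, cn)
    if (orientation %in% c("auto", "features")) dense <- t(dense)
  } else {
    sep <- if (ext %in% c("tsv", "txt")) "\t" else ","
    df <- .readTable(matrixPath, sep)
    dense <- as.matrix(df)
    suppressWarnings(storage.mode(dense) <- "double")
    chr <- as.matrix(df)
    dense[chr %in% missingTokens] <- NA_real_
    stillBad <- which(is.na(dense) & !(chr %in% missingTokens) & !is.na(chr))
    if (length(stillBad))
      stop(sprintf("non-numeric cell(s) in %s, e.g. value '%s'",
                   matrixPath, chr[stillBad[1]]), call. = FALSE)
    if (orientation == "features") dense <- t(dense)
  }
  if (anyDuplicated(rownames(dense)))
    stop(sprintf("duplicated sample id: %s",
                 rownames(dense)[duplicated(rownames(dense))][1]), call. = FALSE)

  labTab <- utils::read.csv(labelsPath, stringsAsFactors = FALSE)
  if (ncol(labTab) < 2) stop("label file needs two columns (sample, label)",
                             call. = FALSE)
  if (anyDuplicated(labTab[[1]]))
    stop(sprintf("duplicated sample id in label file: %s",
                 labTab[[1]][duplicated(labTab[[1]])][1]), call. = FALSE)
  missing <- setdiff(rownames(dense), labTab[[1]])
  if (length(missing))
    stop(sprintf("label file is missing sample(s): %s",
                 paste(utils::head(missing, 5), collapse = ", ")), call. = FALSE)
  extra <- setdiff(labTab[[1]], rownames(dense))
  if (length(extra))
    stop(sprintf("label file has unknown sample(s): %s",
                 paste(utils::head(extra, 5), collapse = ", ")), call. = FALSE)
  lab <- stats::setNames(labTab[[2]], labTab[[1]])[rownames(dense)]
  labels <- stats::setNames(factor(lab), rownames(dense))

  cov <- NULL
  if (!is.null(covariatesPath)) {
    covTab <- utils::read.csv(covariatesPath, row.names = 1,
                              stringsAsFactors = FALSE)
    miss <- setdiff(rownames(dense), rownames(covTab))
    if (length(miss))
      stop(sprintf("covariate file is missing sample(s): %s",
                   paste(utils::head(miss, 5), collapse = ", ")), call. = FALSE)
    cov <- covTab[rownames(dense), , drop = FALSE]
  }
  batches <- NULL
  if (!is.null(batchesPath)) {
    bt <- utils::read.csv(batchesPath, stringsAsFactors = FALSE)
    miss <- setdiff(rownames(dense), bt[[1]])
    if (length(miss))
      stop(sprintf("batch file is missing sample(s): %s",
                   paste(utils::head(miss, 5), collapse = ", ")), call. = FALSE)
    batches <- as.character(stats::setNames(bt[[2]], bt[[1]])[rownames(dense)])
  }
  new("LabeledDataset", data = omicsMatrix(dense), labels = labels,
      covariates = cov, batches = batches)
}

#' Write a dataset as plain-text files
#'
#' Serializes a [SimulatedDataset-class] or [LabeledDataset-class] as
#' \code{matrix.csv} (samples x features, missing entries empty),
#' \code{labels.csv}, optional \code{covariates.csv} and, for simulated
#' data, a \code{config.yaml} echo of the generating parameters. The
#' write/read round trip is lossless, including the missingness pattern.
#'
#' @param dataset a [SimulatedDataset-class] or [LabeledDataset-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of file paths written.
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is(dataset, "SimulatedDataset")) {
    om <- dataset@data; labels <- dataset@labels
    cov <- if (is.null(dataset@covariate)) NULL else
      data.frame(covariate = dataset@covariate,
                 row.names = names(dataset@covariate))
    cfg <- dataset@config
  } else if (is(dataset, "LabeledDataset")) {
    om <- dataset@data; labels <- dataset@labels
    cov <- dataset@covariates; cfg <- NULL
  } else stop("unsupported dataset type", call. = FALSE)
  paths <- character(0)
  mPath <- file.path(dir, "matrix.csv")
  utils::write.csv(as.data.frame(values(om)), mPath, na = "")
  paths <- c(paths, mPath)
  lPath <- file.path(dir, "labels.csv")
  utils::write.csv(data.frame(sample = names(labels),
                              label = as.character(labels)),
                   lPath, row.names = FALSE)
  paths <- c(paths, lPath)
  if (!is.null(cov)) {
    cPath <- file.path(dir, "covariates.csv")
    utils::write.csv(cov, cPath)
    paths <- c(paths, cPath)
  }
  if (!is.null(cfg)) {
    yPath <- file.path(dir, "config.yaml")
    yaml::write_yaml(.configToList(cfg), yPath)
    paths <- c(paths, yPath)
  }
  invisible(paths)
}

.configToList <- function(cfg) {
  list(n_features = cfg@nFeatures,
       c_centers = lapply(seq_len(nrow(cfg@cCenters)),
                          function(i) as.numeric(cfg@cCenters[i, ])),
       class_names = names(cfg@classSizes),
       sigma_feature = cfg@sigmaFeature,
       class_sizes = as.integer(cfg@classSizes),
       missing_fraction = cfg@missingFraction,
       covariate = if (is.null(cfg@covariate)) NULL else
         list(centers = as.numeric(cfg@covariate$centers),
              sd = cfg@covariate$sd),
       seed = cfg@seed)
}

#' Read a simulation configuration from YAML
#'
#' Field names mirror [simulationConfig()] in snake_case:
#' \code{n_features}, \code{c_centers} (list of rows), \code{class_names},
#' \code{sigma_feature}, \code{class_sizes}, \code{missing_fraction} (or
#' \code{target_sigma_rel} to calibrate it), \code{covariate}
#' (\code{centers}, \code{sd}), \code{seed} (mandatory).
#'
#' @param path YAML file path.
#' @return list with elements \code{config} (a [SimulationConfig-class])
#'   and \code{targetSigmaRel} (numeric or NULL).
#' @export
readSimulationConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) stop("config field 'seed' is mandatory", call. = FALSE)
  cC <- if (is.null(y$c_centers)) defaultCenters() else
    do.call(rbind, lapply(y$c_centers, as.numeric))
  nm <- if (!is.null(y$class_names)) y$class_names else
    if (!is.null(rownames(cC))) rownames(cC) else LETTERS[seq_len(nrow(cC))]
  dimnames(cC) <- list(nm, nm)
  sizes <- if (is.null(y$class_sizes)) c(70L, 30L, 50L) else
    as.integer(y$class_sizes)
  names(sizes) <- nm
  cov <- if (is.null(y$covariate)) NULL else
    list(centers = stats::setNames(as.numeric(y$covariate$centers), nm),
         sd = as.numeric(y$covariate$sd))
  cfg <- simulationConfig(
    nFeatures = if (is.null(y$n_features)) 10000L else y$n_features,
    cCenters = cC,
    sigmaFeature = if (is.null(y$sigma_feature)) 2.0 else y$sigma_feature,
    classSizes = sizes,
    missingFraction = if (is.null(y$missing_fraction)) 0 else
      y$missing_fraction,
    covariate = cov, seed = y$seed)
  list(config = cfg,
       targetSigmaRel = if (is.null(y$target_sigma_rel)) NULL else
         as.numeric(y$target_sigma_rel))
}
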