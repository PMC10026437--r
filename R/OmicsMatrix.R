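#' Construct an OmicsMatrix
#'
#' Wraps a samples x features numeric matrix. Any non-finite value
#' (\code{NA}, \code{NaN}, \code{Inf}) is treated as missing and stored as
#' \code{NA}. Row and column names become the sample and feature ids; if
#' absent, \code{S1..Sn} / \code{F1..Fp} are generated.
#'
#' @param values numeric matrix, samples in rows.
#' @param sampleIDs optional character vector of sample identifiers.
#' @param featureIDs optional character vector of feature identifiers.
#' @return an [OmicsMatrix-class].
#' @examples
#' m <- matrix(rnorm(20), 4, 5)
#' m[2, 3] <- NA
#' om <- omicsMatrix(m)
#' dim(om)
#' @export
omicsMatrix <- function(values, sampleIDs = NULL, featureIDs = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  values[!is.finite(values)] <- NA_real_
  if (!is.null(sampleIDs)) rownames(values) <- sampleIDs
  if (!is.null(featureIDs)) colnames(values) <- featureIDs
  if (is.null(rownames(values))) rownames(values) <- paste0("S", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- paste0("F", seq_len(ncol(values)))
  new("OmicsMatrix", values = values)
}

#' @describeIn omicsMatrix dimensions (samples, features)
#' @param x an OmicsMatrix.
#' @export
setMethod("dim", "OmicsMatrix", function(x) dim(x@values))

#' Accessors for OmicsMatrix
#'
#' \code{values()} returns the underlying matrix (with \code{NA} for
#' missing entries), \code{sampleIDs()} and \code{featureIDs()} the
#' identifiers, and \code{missingFraction()} the observed fraction of
#' missing entries.
#'
#' @param x an [OmicsMatrix-class].
#' @return matrix, character vector or numeric scalar respectively.
#' @name OmicsMatrix-accessors
NULL

#' @rdname OmicsMatrix-accessors
#' @export
setGeneric("values", function(x) standardGeneric("values"))

#' @rdname OmicsMatrix-accessors
#' @export
setMethod("values", "OmicsMatrix", function(x) x@values)

#' @rdname OmicsMatrix-accessors
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))

#' @rdname OmicsMatrix-accessors
#' @export
setMethod("sampleIDs", "OmicsMatrix", function(x) rownames(x@values))

#' @rdname OmicsMatrix-accessors
#' @export
setGeneric("featureIDs", function(x) standardGeneric("featureIDs"))

#' @rdname OmicsMatrix-accessors
#' @export
setMethod("featureIDs", "OmicsMatrix", function(x) colnames(x@values))

#' @rdname OmicsMatrix-accessors
#' @export
setGeneric("missingFraction", function(x) standardGeneric("missingFraction"))

#' @rdname OmicsMatrix-accessors
#' @export
setMethod("missingFraction", "OmicsMatrix", function(x) mean(is.na(x@values)))

#' Subset an OmicsMatrix by samples
#'
#' @param x an [OmicsMatrix-class].
#' @param i sample indices or ids.
#' @param j feature indices or ids.
#' @param ... ignored.
#' @param drop ignored; the result is always an OmicsMatrix.
#' @export
setMethod("[", "OmicsMatrix", function(x, i, j, ..., drop = FALSE) {
  v <- x@values
  if (!missing(i)) v <- v[i, , drop = FALSE]
  if (!missing(j)) v <- v[, j, drop = FALSE]
  new("OmicsMatrix", values = v)
})

setMethod("show", "OmicsMatrix", function(object) {
  d <- dim(object@values)
  cat(sprintf("OmicsMatrix: %d samples x %d features, %.1f%% missing\n",
              d[1], d[2], 100 * mean(is.na(object@values))))
})

setMethod("show", "CorrelationMatrix", function(object) {
  d <- dim(object@entries)
  cat(sprintf("CorrelationMatrix (%s, minOverlap=%d): %d x %d, %d undefined entries\n",
              object@method, object@minOverlap, d[1], d[2], sum(!object@defined)))
})

#' Accessors for CorrelationMatrix
#'
#' \code{corValues()} returns the correlation entries (\code{NA} where
#' undefined); \code{definedMask()} the logical mask of defined entries.
#'
#' @param x a [CorrelationMatrix-class].
#' @name CorrelationMatrix-accessors
NULL

#' @rdname CorrelationMatrix-accessors
#' @export
setGeneric("corValues", function(x) standardGeneric("corValues"))

#' @rdname CorrelationMatrix-accessors
#' @export
setMethod("corValues", "CorrelationMatrix", function(x) x@entries)

#' @rdname CorrelationMatrix-accessors
#' @export
setGeneric("definedMask", function(x) standardGeneric("definedMask"))

#' @rdname CorrelationMatrix-accessors
#' @export
setMethod("definedMask", "CorrelationMatrix", function(x) x@defined)

#' @describeIn CorrelationMatrix-accessors dimensions
#' @export
setMethod("dim", "CorrelationMatrix", function(x) dim(x@entries))

#' Feature table accessors
#'
#' @param x a [ClasswiseFeatureTable-class].
#' @param row.names,optional,... passed conventions of as.data.frame.
#' @name ClasswiseFeatureTable-accessors
NULL

#' @rdname ClasswiseFeatureTable-accessors
#' @export
setMethod("as.data.frame", "ClasswiseFeatureTable",
          function(x, row.names = NULL, optional = FALSE, ...) {
  df <- as.data.frame(x@features)
  if (!is.null(x@covariates)) df <- cbind(df, x@covariates)
  df
})

setMethod("show", "ClasswiseFeatureTable", function(object) {
  cat(sprintf("ClasswiseFeatureTable: %d samples, classes [%s]%s\n",
              nrow(object@features), paste(object@classOrder, collapse = ", "),
              if (is.null(object@covariates)) "" else
                sprintf(", %d covariate(s)", ncol(object@covariates))))
})
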