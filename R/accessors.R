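# Accessors and show methods for the S4 containers.

#' @describeIn VariantDataset-class Number of variants (rows).
#' @param x,object A `VariantDataset`.
#' @export
setMethod("nrow", "VariantDataset", function(x) nrow(x@scores))

#' Accessor generics
#'
#' @param x An object of one of the package's S4 classes.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("scoreMatrix", function(x) standardGeneric("scoreMatrix"))

#' @rdname accessors
#' @export
setMethod("scoreMatrix", "VariantDataset", function(x) x@scores)

#' @rdname accessors
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))

#' @rdname accessors
#' @export
setMethod("featureNames", "VariantDataset", function(x) colnames(x@scores))

#' @rdname accessors
#' @export
setMethod("featureNames", "PosteriorDraws", function(x) x@features)

#' @rdname accessors
#' @export
setGeneric("variantId", function(x) standardGeneric("variantId"))

#' @rdname accessors
#' @export
setMethod("variantId", "VariantDataset", function(x) x@variantId)

#' @rdname accessors
#' @export
setMethod("variantId", "ClassificationResult", function(x) x@variantId)

#' @rdname accessors
#' @export
setGeneric("clinicalLabels", function(x) standardGeneric("clinicalLabels"))

#' @rdname accessors
#' @export
setMethod("clinicalLabels", "VariantDataset", function(x) x@label)

#' @rdname accessors
#' @export
setGeneric("classVector", function(x) standardGeneric("classVector"))

#' @describeIn accessors Harmonized binary class (0 benign, 1 pathogenic,
#'   NA unlabelled); see [harmonizeLabels()].
#' @export
setMethod("classVector", "VariantDataset", function(x) x@yClass)

#' @rdname accessors
#' @export
setGeneric("nDraws", function(x) standardGeneric("nDraws"))

#' @rdname accessors
#' @export
setMethod("nDraws", "PosteriorDraws", function(x) nrow(x@omega))

#' @rdname accessors
#' @export
setGeneric("drawWeights", function(x) standardGeneric("drawWeights"))

#' @describeIn accessors M x K matrix of cluster weight draws.
#' @export
setMethod("drawWeights", "PosteriorDraws", function(x) x@omega)

#' @rdname accessors
#' @export
setGeneric("drawMeans", function(x) standardGeneric("drawMeans"))

#' @describeIn accessors M x K x p array of cluster mean draws.
#' @export
setMethod("drawMeans", "PosteriorDraws", function(x) x@mu)

#' @rdname accessors
#' @export
setGeneric("drawCovariances", function(x) standardGeneric("drawCovariances"))

#' @describeIn accessors M x K x p x p array of covariance draws.
#' @export
setMethod("drawCovariances", "PosteriorDraws", function(x) x@sigma)

#' @rdname accessors
#' @export
setGeneric("pathogenicProbability", function(x) standardGeneric("pathogenicProbability"))

#' @describeIn accessors Mean posterior-predictive pathogenic probability.
#' @export
setMethod("pathogenicProbability", "ClassificationResult", function(x) x@probPathogenic)

#' @rdname accessors
#' @export
setGeneric("predictedLabels", function(x) standardGeneric("predictedLabels"))

#' @rdname accessors
#' @export
setMethod("predictedLabels", "ClassificationResult", function(x) x@label)

#' Subset a VariantDataset by row
#'
#' @param x A `VariantDataset`.
#' @param i Row index vector.
#' @param j,...,drop Ignored (column subsetting is done via features at
#'   read/model time).
#' @export
setMethod("[", "VariantDataset", function(x, i, j, ..., drop = FALSE) {
  new("VariantDataset",
      variantId = x@variantId[i],
      gene = x@gene[i],
      label = x@label[i],
      scores = x@scores[i, , drop = FALSE],
      yClass = x@yClass[i],
      harmonized = x@harmonized)
})

setMethod("show", "VariantDataset", function(object) {
  n <- nrow(object@scores)
  cat(sprintf("VariantDataset with %d variants x %d features\n",
              n, ncol(object@scores)))
  cat("  features:", paste(colnames(object@scores), collapse = ", "), "\n")
  if (object@harmonized) {
    tab <- table(factor(object@yClass, levels = c(0, 1)), useNA = "always")
    cat(sprintf("  classes: %d benign, %d pathogenic, %d unlabelled\n",
                tab[1], tab[2], tab[3]))
  } else {
    cat("  labels not harmonized yet (see harmonizeLabels())\n")
  }
  nm <- sum(is.na(object@scores))
  cat(sprintf("  missing score cells: %d (%.1f%%)\n",
              nm, 100 * nm / max(1, length(object@scores))))
})

setMethod("show", "PriorSpec", function(object) {
  cat(sprintf("PriorSpec over %d feature(s)\n", length(object@eta)))
  cat("  alpha:", paste(format(object@alpha), collapse = ", "), "\n")
  cat("  nu:", format(object@nu), "\n")
})

setMethod("show", "GibbsConfig", function(object) {
  cat(sprintf("GibbsConfig: %d sweeps (burn-in %d, thin %d) -> %d retained; seed %d; init '%s'\n",
              object@nIter, object@burnIn, object@thin,
              (object@nIter - object@burnIn) %/% object@thin,
              object@seed, object@init))
})

setMethod("show", "PosteriorDraws", function(object) {
  cat(sprintf("PosteriorDraws: %d retained draws, K = 2, p = %d%s\n",
              nrow(object@omega), length(object@features),
              if (object@ordered) " (weight-ordered: benign = cluster 1)" else ""))
  cat("  features:", paste(object@features, collapse = ", "), "\n")
})

setMethod("show", "ClassificationResult", function(object) {
  n <- length(object@label)
  cat(sprintf("ClassificationResult for %d variants (%d draws)\n", n, object@nDraws))
  cat(sprintf("  pathogenic: %d, benign: %d, ties: %d\n",
              sum(object@label == "pathogenic"),
              sum(object@label == "benign"), sum(object@tie)))
})

setMethod("show", "DICResult", function(object) {
  cat(sprintf("DIC = %.2f (mean deviance %.2f, pD %.2f) on {%s}\n",
              object@dic, object@meanDeviance, object@pD,
              paste(object@features, collapse = ", ")))
})
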