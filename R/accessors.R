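#' Accessors for GenotypeData
#'
#' \code{dosages} returns the n x m dosage matrix; \code{markerMap} the marker
#' map; \code{sampleIds} the sample labels; \code{nSamples} / \code{nMarkers}
#' the dimensions. \code{markerMAF}, \code{markerCallRate} and
#' \code{sampleCallRate} are computed on the current matrix (so they reflect
#' any sample/marker subsetting already applied), using non-missing entries
#' only.
#'
#' @param x a \code{\linkS4class{GenotypeData}} object.
#' @return See individual descriptions.
#' @name GenotypeData-accessors
NULL

#' @rdname GenotypeData-accessors
setMethod("dosages", "GenotypeData", function(x) x@dosages)

#' @rdname GenotypeData-accessors
setMethod("markerMap", "GenotypeData", function(x) x@map)

#' @rdname GenotypeData-accessors
setMethod("sampleIds", "GenotypeData", function(x) x@sampleIds)

#' @rdname GenotypeData-accessors
setMethod("nSamples", "GenotypeData", function(x) nrow(x@dosages))

#' @rdname GenotypeData-accessors
setMethod("nMarkers", "GenotypeData", function(x) ncol(x@dosages))

#' @rdname GenotypeData-accessors
setMethod("markerMAF", "GenotypeData", function(x) {
  f <- colMeans(x@dosages, na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  maf[is.nan(maf)] <- NA_real_
  maf
})

#' @rdname GenotypeData-accessors
setMethod("markerCallRate", "GenotypeData", function(x) {
  colMeans(!is.na(x@dosages))
})

#' @rdname GenotypeData-accessors
setMethod("sampleCallRate", "GenotypeData", function(x) {
  rowMeans(!is.na(x@dosages))
})

setMethod("show", "GenotypeData", function(object) {
  cat("GenotypeData:", nSamples(object), "samples x", nMarkers(object),
      "markers on", length(unique(object@map$chrom)), "chromosome(s)\n")
  miss <- mean(is.na(object@dosages))
  cat(sprintf("  missing rate: %.4f\n", miss))
})

#' Accessors for TraitData
#'
#' @param x a \code{\linkS4class{TraitData}} object.
#' @return \code{traitId}: the trait label; \code{records}: the record
#'   data.frame (animal_id, debv, reliability, d, w); \code{heritability}:
#'   the trait h2.
#' @name TraitData-accessors
NULL

#' @rdname TraitData-accessors
setMethod("traitId", "TraitData", function(x) x@traitId)

#' @rdname TraitData-accessors
setMethod("records", "TraitData", function(x) x@records)

#' @rdname TraitData-accessors
setMethod("heritability", "TraitData", function(x) x@h2)

setMethod("show", "TraitData", function(object) {
  cat("TraitData:", object@traitId, "-", nrow(object@records), "records,",
      sprintf("h2 = %.2f, c = %.2f\n", object@h2, object@c))
})

#' Accessors for Grm
#'
#' @param x a \code{\linkS4class{Grm}} object.
#' @return \code{grmMatrix}: the n x n relationship matrix;
#'   \code{excludedChrom}: the excluded chromosome label or NA.
#' @name Grm-accessors
NULL

#' @rdname Grm-accessors
setMethod("grmMatrix", "Grm", function(x) x@K)

#' @rdname Grm-accessors
setMethod("excludedChrom", "Grm", function(x) x@excludedChrom)

setMethod("show", "Grm", function(object) {
  cat("Grm:", nrow(object@K), "x", ncol(object@K),
      "from", object@nMarkersUsed, "markers")
  if (!is.na(object@excludedChrom))
    cat(" (excluding chromosome", object@excludedChrom, ")")
  cat("\n")
})

#' Accessors for NullModelFit
#'
#' @param x a \code{\linkS4class{NullModelFit}} object.
#' @return \code{varianceComponents}: named vector with \code{sigma2g},
#'   \code{sigma2e}, \code{mu} and the marker-based heritability
#'   \code{h2_marker} = sigma2g / (sigma2g + sigma2e).
#' @name NullModelFit-accessors
NULL

#' @rdname NullModelFit-accessors
setMethod("varianceComponents", "NullModelFit", function(x) {
  c(sigma2g = x@sigma2g, sigma2e = x@sigma2e, mu = x@mu,
    h2_marker = x@sigma2g / (x@sigma2g + x@sigma2e))
})

setMethod("show", "NullModelFit", function(object) {
  cat("NullModelFit:", object@traitId)
  if (!is.na(object@excludedChrom))
    cat(" (LOCO, chromosome", object@excludedChrom, "excluded)")
  cat(sprintf("\n  n = %d, sigma2g = %.4g, sigma2e = %.4g, h2_marker = %.3f\n",
              length(object@yStar), object@sigma2g, object@sigma2e,
              object@sigma2g / (object@sigma2g + object@sigma2e)))
})
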