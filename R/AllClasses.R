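#' GenotypeData: dosage matrix with marker map
#'
#' Holds an n x m matrix of minor-allele dosages (0, 1, 2 or NA for missing)
#' together with the marker map (chromosome, base-pair position, marker id,
#' alleles) and sample identifiers. Markers are kept sorted by chromosome and
#' strictly increasing position within chromosome.
#'
#' @slot dosages numeric matrix, n samples x m markers, values in
#'   \{0, 1, 2, NA\}; columns named by marker id, rows by sample id.
#' @slot map data.frame with columns \code{chrom}, \code{bp} (1-based),
#'   \code{marker_id}, \code{allele1} (counted allele), \code{allele2}.
#' @slot sampleIds character vector of length n.
#'
#' @exportClass GenotypeData
setClass("GenotypeData",
  representation(
    dosages   = "matrix",
    map       = "data.frame",
    sampleIds = "character"
  )
)

setValidity("GenotypeData", function(object) {
  msg <- character()
  d <- object@dosages
  if (nrow(d) != length(object@sampleIds))
    msg <- c(msg, "nrow(dosages) must equal length(sampleIds)")
  if (ncol(d) != nrow(object@map))
    msg <- c(msg, "ncol(dosages) must equal nrow(map)")
  need <- c("chrom", "bp", "marker_id", "allele1", "allele2")
  if (!all(need %in% names(object@map)))
    msg <- c(msg, paste("map must have columns:", paste(need, collapse = ", ")))
  v <- d[!is.na(d)]
  if (length(v) && !all(v %in% c(0, 1, 2)))
    msg <- c(msg, "dosage codes must be 0, 1, 2 or NA")
  if (all(need %in% names(object@map)) && nrow(object@map) > 1) {
    bych <- split(object@map$bp, object@map$chrom)
    if (any(vapply(bych, function(x) any(diff(x) <= 0), logical(1))))
      msg <- c(msg, "bp must be strictly increasing within chromosome")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeData object
#'
#' @param dosages numeric matrix of dosages in \{0, 1, 2, NA\}.
#' @param map data.frame with columns \code{chrom}, \code{bp},
#'   \code{marker_id}, \code{allele1}, \code{allele2}.
#' @param sampleIds character vector of sample identifiers.
#' @return A \code{\linkS4class{GenotypeData}} object with markers sorted by
#'   chromosome then position.
#' @export
genotypeData <- function(dosages, map, sampleIds) {
  map$chrom <- as.character(map$chrom)
  ord <- order(map$chrom, map$bp)
  map <- map[ord, , drop = FALSE]
  rownames(map) <- NULL
  dosages <- dosages[, ord, drop = FALSE]
  dimnames(dosages) <- list(sampleIds, map$marker_id)
  new("GenotypeData", dosages = dosages, map = map,
      sampleIds = as.character(sampleIds))
}

#' TraitData: dEBV records with reliabilities and residual weights
#'
#' Per-trait pseudo-phenotypes: deregressed breeding values with their
#' reliabilities r2 (squared accuracies), the derived deregression weights
#' d = (1 - r2)/r2, and the residual weights w = (d + c)/lambda with
#' lambda = (1 - h2)/h2.
#'
#' @slot traitId character scalar.
#' @slot h2 heritability of the trait before deregression, in (0, 1).
#' @slot c blending constant in [0, 1] controlling the contribution of
#'   low-reliability records.
#' @slot records data.frame with columns \code{animal_id}, \code{debv},
#'   \code{reliability}, \code{d}, \code{w}.
#'
#' @exportClass TraitData
setClass("TraitData",
  representation(
    traitId = "character",
    h2      = "numeric",
    c       = "numeric",
    records = "data.frame"
  )
)

setValidity("TraitData", function(object) {
  msg <- character()
  if (length(object@h2) != 1 || object@h2 <= 0 || object@h2 >= 1)
    msg <- c(msg, "h2 must be a scalar in (0, 1)")
  if (length(object@c) != 1 || object@c < 0 || object@c > 1)
    msg <- c(msg, "c must be a scalar in [0, 1]")
  r <- object@records
  need <- c("animal_id", "debv", "reliability", "d", "w")
  if (!all(need %in% names(r)))
    msg <- c(msg, paste("records must have columns:", paste(need, collapse = ", ")))
  else {
    if (any(r$reliability <= 0 | r$reliability > 1))
      msg <- c(msg, "reliability must be in (0, 1]")
    if (any(r$w <= 0))
      msg <- c(msg, "weights w must be strictly positive")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a TraitData object
#'
#' Computes deregression weights d = (1 - r2)/r2 and residual weights
#' w = (d + c)/lambda from the supplied reliabilities and heritability.
#'
#' @param traitId trait label.
#' @param records data.frame with columns \code{animal_id}, \code{debv},
#'   \code{reliability}.
#' @param h2 heritability in (0, 1).
#' @param c blending constant in [0, 1]; default 0.5.
#' @return A \code{\linkS4class{TraitData}} object.
#' @export
traitData <- function(traitId, records, h2, c = 0.5) {
  stopifnot(is.data.frame(records),
            all(c("animal_id", "debv", "reliability") %in% names(records)))
  if (any(records$reliability <= 0))
    stop("reliability must be > 0 (d = (1 - r2)/r2 is undefined at 0)")
  records$animal_id <- as.character(records$animal_id)
  records$d <- (1 - records$reliability) / records$reliability
  records$w <- residualWeight(records$reliability, h2, c)
  rownames(records) <- NULL
  new("TraitData", traitId = as.character(traitId), h2 = h2, c = c,
      records = records)
}

#' Grm: genomic relationship matrix
#'
#' Realized additive relationship matrix K built from marker dosages,
#' optionally excluding one chromosome (leave-one-chromosome-out).
#'
#' @slot K symmetric n x n matrix, dimnames = sample ids.
#' @slot excludedChrom chromosome excluded from the build, or NA.
#' @slot nMarkersUsed number of markers entering the build.
#'
#' @exportClass Grm
setClass("Grm",
  representation(
    K             = "matrix",
    excludedChrom = "character",
    nMarkersUsed  = "integer"
  )
)

setValidity("Grm", function(object) {
  msg <- character()
  K <- object@K
  if (nrow(K) != ncol(K)) msg <- c(msg, "K must be square")
  else {
    if (max(abs(K - t(K))) > 1e-8) msg <- c(msg, "K must be symmetric")
    if (any(diag(K) <= 0)) msg <- c(msg, "diagonal of K must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' NullModelFit: fitted weighted polygenic null model
#'
#' REML fit of y = 1 mu + g + e with g ~ N(0, K sigma2_g) and
#' e ~ N(0, diag(w) sigma2_e), for one trait and one (possibly
#' chromosome-excluded) relationship matrix. Stores the fitted covariance
#' V = K sigma2_g + diag(w) sigma2_e, its inverse, and the centered
#' phenotype y* = y - 1 mu used by the score test.
#'
#' @slot traitId trait label.
#' @slot excludedChrom chromosome excluded from K, or NA.
#' @slot mu GLS estimate of the overall mean.
#' @slot sigma2g genetic variance (>= 0).
#' @slot sigma2e residual variance (> 0).
#' @slot weights diagonal residual weight vector w.
#' @slot V fitted covariance matrix.
#' @slot Vinv inverse of V.
#' @slot yStar centered phenotype y - 1 mu.
#' @slot sampleIds sample ids in fit order.
#' @slot remlLogLik restricted log-likelihood at the optimum.
#'
#' @exportClass NullModelFit
setClass("NullModelFit",
  representation(
    traitId       = "character",
    excludedChrom = "character",
    mu            = "numeric",
    sigma2g       = "numeric",
    sigma2e       = "numeric",
    weights       = "numeric",
    V             = "matrix",
    Vinv          = "matrix",
    yStar         = "numeric",
    sampleIds     = "character",
    remlLogLik    = "numeric"
  )
)

setValidity("NullModelFit", function(object) {
  msg <- character()
  if (object@sigma2g < 0) msg <- c(msg, "sigma2g must be >= 0")
  if (object@sigma2e <= 0) msg <- c(msg, "sigma2e must be > 0")
  if (length(object@yStar) != nrow(object@V))
    msg <- c(msg, "yStar length must match dim(V)")
  if (length(msg)) msg else TRUE
})
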