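#' Filter samples on genotype call rate
#'
#' Keeps samples whose call rate is strictly greater than
#' \code{minSampleCall} (samples at exactly the threshold are removed).
#' Sample order is preserved.
#'
#' @param gm a \code{\linkS4class{GenotypeData}} object.
#' @param minSampleCall call-rate threshold (default 0.90).
#' @return filtered \code{\linkS4class{GenotypeData}}.
#' @export
filterSamples <- function(gm, minSampleCall = 0.90) {
  cr <- sampleCallRate(gm)
  keep <- cr > minSampleCall
  if (!any(keep))
    stop("sample call-rate filter removed all samples (threshold ",
         minSampleCall, ")")
  genotypeData(dosages(gm)[keep, , drop = FALSE], markerMap(gm),
               sampleIds(gm)[keep])
}

#' Filter markers on chromosome, call rate and MAF
#'
#' Retains markers that are autosomal (chromosome label in
#' \code{autosomes}), have call rate >= \code{minMarkerCall} and minor
#' allele frequency >= \code{minMaf}; both thresholds inclusive. Call rates
#' and MAFs are computed on the samples currently in \code{gm}, so apply
#' \code{\link{filterSamples}} first.
#'
#' @param gm a \code{\linkS4class{GenotypeData}} object.
#' @param autosomes character vector of autosome labels; default the
#'   chromosome labels that parse as integers.
#' @param minMarkerCall call-rate threshold (default 0.95, inclusive).
#' @param minMaf MAF threshold (default 0.02, inclusive).
#' @return filtered \code{\linkS4class{GenotypeData}}.
#' @export
filterMarkers <- function(gm, autosomes = NULL, minMarkerCall = 0.95,
                          minMaf = 0.02) {
  map <- markerMap(gm)
  if (is.null(autosomes))
    autosomes <- unique(map$chrom[!is.na(suppressWarnings(as.integer(map$chrom)))])
  cr <- markerCallRate(gm)
  maf <- markerMAF(gm)
  keep <- map$chrom %in% autosomes & cr >= minMarkerCall &
    !is.na(maf) & maf >= minMaf
  if (!any(keep))
    stop("marker filters removed all markers")
  genotypeData(dosages(gm)[, keep, drop = FALSE], map[keep, , drop = FALSE],
               sampleIds(gm))
}

#' Mean and median gap between consecutive markers
#'
#' Gaps are computed between consecutive markers on the same chromosome
#' only; chromosome boundaries contribute no gap.
#'
#' @param markerMap data.frame with columns \code{chrom}, \code{bp}.
#' @return named numeric vector \code{c(mean_gap_bp, median_gap_bp)}.
#' @export
gapSummary <- function(markerMap) {
  gaps <- unlist(lapply(split(markerMap$bp, markerMap$chrom), function(x)
    if (length(x) >= 2) diff(sort(x)) else numeric(0)), use.names = FALSE)
  if (!length(gaps))
    stop("need at least 2 markers on some chromosome to compute gaps")
  c(mean_gap_bp = mean(gaps), median_gap_bp = median(gaps))
}

#' Run the full genotype QC (samples first, then markers)
#'
#' @inheritParams filterSamples
#' @inheritParams filterMarkers
#' @return list with the filtered \code{\linkS4class{GenotypeData}} and a
#'   \code{report} data.frame of counts at each step.
#' @export
genotypeQc <- function(gm, minSampleCall = 0.90, autosomes = NULL,
                       minMarkerCall = 0.95, minMaf = 0.02) {
  n0 <- nSamples(gm); m0 <- nMarkers(gm)
  gm1 <- filterSamples(gm, minSampleCall)
  gm2 <- filterMarkers(gm1, autosomes, minMarkerCall, minMaf)
  report <- data.frame(
    step = c("input", "sample_call_rate", "marker_filters"),
    threshold = c(NA, minSampleCall,
                  sprintf("call>=%g,maf>=%g,autosomes", minMarkerCall, minMaf)),
    n_samples = c(n0, nSamples(gm1), nSamples(gm2)),
    n_markers = c(m0, nMarkers(gm1), nMarkers(gm2)),
    stringsAsFactors = FALSE)
  list(genotypes = gm2, report = report)
}
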