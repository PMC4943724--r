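#' Compute a genomic relationship matrix (VanRaden method 1)
#'
#' K = ZZ' / (2 sum p(1-p)) where Z is the dosage matrix mean-imputed per
#' marker and centered by twice the allele frequency. Optionally excludes
#' all markers on one chromosome (leave-one-chromosome-out).
#'
#' @param gm a \code{\linkS4class{GenotypeData}} object.
#' @param excludeChrom chromosome label to exclude, or NA (default).
#' @param method \code{"vanraden1"} (default) or \code{"standardized"}
#'   (markers scaled to unit variance before the cross-product).
#' @return A \code{\linkS4class{Grm}} object.
#' @export
computeGrm <- function(gm, excludeChrom = NA_character_,
                       method = c("vanraden1", "standardized")) {
  method <- match.arg(method)
  map <- markerMap(gm)
  keep <- if (is.na(excludeChrom)) rep(TRUE, nrow(map)) else
    map$chrom != excludeChrom
  if (sum(keep) < 2)
    stop("fewer than 2 markers remain after excluding chromosome ",
         excludeChrom)
  X <- dosages(gm)[, keep, drop = FALSE]
  Z <- imputeCenter(X)
  p <- attr(Z, "freq")
  if (method == "vanraden1") {
    denom <- 2 * sum(p * (1 - p))
    if (denom <= 0)
      stop("all included markers are monomorphic; GRM denominator is zero")
    K <- tcrossprod(Z) / denom
  } else {
    sdz <- sqrt(2 * p * (1 - p))
    poly <- sdz > 0
    if (!any(poly))
      stop("all included markers are monomorphic; GRM denominator is zero")
    Zs <- sweep(Z[, poly, drop = FALSE], 2, sdz[poly], "/")
    K <- tcrossprod(Zs) / sum(poly)
  }
  K <- (K + t(K)) / 2
  dimnames(K) <- list(sampleIds(gm), sampleIds(gm))
  new("Grm", K = K, excludedChrom = as.character(excludeChrom),
      nMarkersUsed = as.integer(sum(keep)))
}

# mean-impute NA per column, center by 2*freq; attaches allele freqs
imputeCenter <- function(X) {
  mu <- colMeans(X, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  na <- which(is.na(X), arr.ind = TRUE)
  if (nrow(na)) X[na] <- mu[na[, 2]]
  Z <- sweep(X, 2, mu)
  attr(Z, "freq") <- mu / 2
  Z
}

#' Compute all leave-one-chromosome-out GRMs at once
#'
#' Builds the per-chromosome numerators of the VanRaden cross-product once
#' and assembles each LOCO matrix by subtraction, so the total cost is one
#' genome-wide pass.
#'
#' @param gm a \code{\linkS4class{GenotypeData}} object.
#' @return named list of \code{\linkS4class{Grm}}, one per chromosome,
#'   each excluding that chromosome.
#' @export
computeLocoGrms <- function(gm) {
  map <- markerMap(gm)
  chroms <- unique(map$chrom)
  if (length(chroms) < 2)
    stop("LOCO requires at least 2 chromosomes")
  nums <- list(); dens <- numeric(0); counts <- integer(0)
  for (ch in chroms) {
    X <- dosages(gm)[, map$chrom == ch, drop = FALSE]
    Z <- imputeCenter(X)
    p <- attr(Z, "freq")
    nums[[ch]] <- tcrossprod(Z)
    dens[ch] <- 2 * sum(p * (1 - p))
    counts[ch] <- ncol(X)
  }
  Ntot <- Reduce(`+`, nums)
  dtot <- sum(dens)
  out <- list()
  for (ch in chroms) {
    denom <- dtot - dens[ch]
    if (denom <= 0)
      stop("no polymorphic markers remain when excluding chromosome ", ch)
    K <- (Ntot - nums[[ch]]) / denom
    K <- (K + t(K)) / 2
    dimnames(K) <- list(sampleIds(gm), sampleIds(gm))
    out[[ch]] <- new("Grm", K = K, excludedChrom = ch,
                     nMarkersUsed = as.integer(sum(counts) - counts[ch]))
  }
  out
}

#' Fit the weighted polygenic null model by REML
#'
#' Fits y = 1 mu + g + e with g ~ N(0, K sigma2_g),
#' e ~ N(0, diag(w) sigma2_e) by restricted maximum likelihood. The data
#' are transformed by diag(w)^(-1/2), the transformed K is
#' eigendecomposed once, and the variance ratio delta = sigma2_g/sigma2_e
#' is optimised in one dimension on the log scale; the residual variance
#' and mean then have closed-form GLS solutions.
#'
#' @param trait a \code{\linkS4class{TraitData}} object; all of its animals
#'   must appear in the GRM.
#' @param grm a \code{\linkS4class{Grm}} object.
#' @param logRatioBounds search interval for log(delta); default c(-12, 12).
#' @param tol optimisation tolerance on log(delta); default 1e-8.
#' @return A \code{\linkS4class{NullModelFit}} object.
#' @export
fitNull <- function(trait, grm, logRatioBounds = c(-12, 12), tol = 1e-8) {
  rec <- records(trait)
  K <- grmMatrix(grm)
  ids <- rec$animal_id
  miss <- setdiff(ids, rownames(K))
  if (length(miss))
    stop("trait ", traitId(trait), ": animals absent from GRM: ",
         paste(head(miss, 5), collapse = ", "))
  K <- K[ids, ids, drop = FALSE]
  y <- rec$debv
  w <- rec$w
  n <- length(y)
  s <- 1 / sqrt(w)
  Kt <- K * tcrossprod(s)              # diag(s) K diag(s)
  eg <- eigen(Kt, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  yr <- drop(crossprod(eg$vectors, s * y))
  xr <- drop(crossprod(eg$vectors, s))

  profile <- function(logDelta) {
    delta <- exp(logDelta)
    dvec <- delta * lam + 1
    xtx <- sum(xr^2 / dvec)
    mu <- sum(xr * yr / dvec) / xtx
    rss <- sum((yr - xr * mu)^2 / dvec)
    s2e <- rss / (n - 1)
    ll <- -0.5 * ((n - 1) * (log(2 * pi * s2e) + 1) + sum(log(dvec)) +
                    log(xtx) + sum(log(w)))
    list(ll = ll, mu = mu, s2e = s2e, delta = delta)
  }
  opt <- optimize(function(ld) profile(ld)$ll, interval = logRatioBounds,
                  maximum = TRUE, tol = tol)
  # compare with the no-genetic-variance boundary
  best <- profile(opt$maximum)
  lower <- profile(logRatioBounds[1])
  atBoundary <- lower$ll > best$ll
  if (atBoundary) best <- lower
  if (!is.finite(best$ll))
    stop("REML optimisation failed for trait ", traitId(trait))

  delta <- if (atBoundary) 0 else best$delta
  s2e <- best$s2e
  s2g <- delta * s2e
  dvec <- delta * lam + 1
  # Vinv = diag(s) U diag(1/(s2e * dvec)) U' diag(s)
  Ui <- eg$vectors * s
  Vinv <- Ui %*% (t(Ui) / (s2e * dvec))
  Vinv <- (Vinv + t(Vinv)) / 2
  V <- K * s2g + diag(w * s2e, n)
  one <- rep(1, n)
  mu <- sum(Vinv %*% y) / sum(Vinv %*% one)
  new("NullModelFit", traitId = traitId(trait),
      excludedChrom = excludedChrom(grm), mu = mu, sigma2g = s2g,
      sigma2e = s2e, weights = w, V = V, Vinv = Vinv, yStar = y - mu,
      sampleIds = ids, remlLogLik = best$ll)
}

# build a NullModelFit from fixed variance components (for the option of
# reusing genome-wide estimates across LOCO folds)
fitFromComponents <- function(trait, grm, sigma2g, sigma2e) {
  rec <- records(trait)
  K <- grmMatrix(grm)[rec$animal_id, rec$animal_id, drop = FALSE]
  w <- rec$w
  n <- nrow(rec)
  V <- K * sigma2g + diag(w * sigma2e, n)
  Vinv <- chol2inv(chol(V))
  y <- rec$debv
  mu <- sum(Vinv %*% y) / sum(Vinv)
  new("NullModelFit", traitId = traitId(trait),
      excludedChrom = excludedChrom(grm), mu = mu, sigma2g = sigma2g,
      sigma2e = sigma2e, weights = w, V = V, Vinv = Vinv, yStar = y - mu,
      sampleIds = rec$animal_id, remlLogLik = NA_real_)
}

#' Single-marker mmscore-type test
#'
#' Computes b = (x'V^-1 x)^-1 x'V^-1 y*, SE(b) = sqrt((x'V^-1 x)^-1),
#' t = b/SE and a two-sided normal p-value, against a pre-fitted null
#' covariance. Missing dosages are mean-imputed and x is mean-centered
#' before testing. A constant x yields a flagged result with b = 0, p = 1.
#'
#' @param x dosage vector aligned to the fit's sample order.
#' @param fit a \code{\linkS4class{NullModelFit}} object.
#' @return one-row data.frame: \code{b}, \code{se}, \code{t}, \code{p},
#'   \code{flag} (NA or a reason code).
#' @export
scoreTest <- function(x, fit) {
  res <- scoreTestMatrix(matrix(x, ncol = 1), fit)
  res
}

# vectorised score test over the columns of X
scoreTestMatrix <- function(X, fit) {
  stopifnot(nrow(X) == length(fit@yStar))
  mu <- colMeans(X, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  na <- which(is.na(X), arr.ind = TRUE)
  if (nrow(na)) X[na] <- mu[na[, 2]]
  X <- sweep(X, 2, colMeans(X))
  VX <- fit@Vinv %*% X
  xvx <- colSums(X * VX)
  xvy <- drop(crossprod(VX, fit@yStar))
  const <- xvx <= 1e-12
  b <- ifelse(const, 0, xvy / xvx)
  se <- ifelse(const, NA_real_, sqrt(1 / xvx))
  t <- ifelse(const, 0, b / se)
  p <- ifelse(const, 1, 2 * pnorm(-abs(t)))
  data.frame(b = b, se = se, t = t, p = p,
             flag = ifelse(const, "constant_dosage", NA_character_),
             stringsAsFactors = FALSE)
}

#' Leave-one-chromosome-out genome-wide association scan for one trait
#'
#' For each chromosome j, fits (or reuses) the null model whose relationship
#' matrix excludes j, then score-tests every marker on j, so the null model
#' never contains the tested marker or markers in LD with it.
#'
#' @param gm a \code{\linkS4class{GenotypeData}} object (QC-passed).
#' @param trait a \code{\linkS4class{TraitData}} object (accuracy-filtered,
#'   weighted).
#' @param grms named list of LOCO \code{\linkS4class{Grm}}s from
#'   \code{\link{computeLocoGrms}}.
#' @param perLocoReml if TRUE (default) variance components are re-estimated
#'   for every fold; if FALSE they are estimated once on the genome-wide GRM
#'   and reused, only the mean and V being rebuilt per fold.
#' @return data.frame (one row per marker): \code{marker_id}, \code{chrom},
#'   \code{bp}, \code{allele}, \code{b}, \code{se}, \code{t}, \code{p},
#'   \code{flag}.
#' @export
gwaLoco <- function(gm, trait, grms, perLocoReml = TRUE) {
  map <- markerMap(gm)
  chroms <- unique(map$chrom)
  missing <- setdiff(chroms, names(grms))
  if (length(missing))
    stop("no LOCO GRM supplied for chromosome(s): ",
         paste(missing, collapse = ", "))
  comp <- NULL
  if (!perLocoReml) {
    gwFit <- fitNull(trait, computeGrm(gm))
    comp <- c(gwFit@sigma2g, gwFit@sigma2e)
  }
  ids <- records(trait)$animal_id
  rows <- vector("list", length(chroms))
  for (i in seq_along(chroms)) {
    ch <- chroms[i]
    grm <- grms[[ch]]
    if (is.na(excludedChrom(grm)) || excludedChrom(grm) != ch)
      stop("GRM supplied for chromosome ", ch, " does not exclude it")
    fit <- if (perLocoReml) fitNull(trait, grm) else
      fitFromComponents(trait, grm, comp[1], comp[2])
    sel <- which(map$chrom == ch)
    X <- dosages(gm)[ids, sel, drop = FALSE]
    res <- scoreTestMatrix(X, fit)
    rows[[i]] <- cbind(map[sel, c("marker_id", "chrom", "bp")],
                       allele = map$allele1[sel], res,
                       stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Conditional LOCO scan fixing selected markers
#'
#' Re-runs the scan with the dosages of \code{fixedMarkerIds} included as
#' fixed covariates: both the phenotype and the tested dosage are projected,
#' in the V inner product, onto the orthogonal complement of the intercept
#' and the fixed dosages before the score test. The fixed markers themselves
#' are reported with p = 1 and a flag; collinear fixed markers are dropped
#' with a warning.
#'
#' @inheritParams gwaLoco
#' @param fixedMarkerIds character vector of marker ids to condition on.
#' @return data.frame as in \code{\link{gwaLoco}}.
#' @export
conditionalScan <- function(gm, trait, grms, fixedMarkerIds,
                            perLocoReml = TRUE) {
  map <- markerMap(gm)
  fixedIdx <- match(fixedMarkerIds, map$marker_id)
  if (anyNA(fixedIdx))
    stop("fixed marker(s) not found: ",
         paste(fixedMarkerIds[is.na(fixedIdx)], collapse = ", "))
  ids <- records(trait)$animal_id
  Fmat <- dosages(gm)[ids, fixedIdx, drop = FALSE]
  Fmat <- imputeCenter(Fmat)
  if (any(apply(Fmat, 2, var) == 0))
    stop("fixed marker(s) with constant dosage cannot be conditioned on")
  qrF <- qr(cbind(1, Fmat))
  if (qrF$rank < ncol(Fmat) + 1) {
    dropCols <- qrF$pivot[seq(qrF$rank + 1, ncol(Fmat) + 1)] - 1
    warning("dropping collinear fixed marker(s): ",
            paste(fixedMarkerIds[dropCols], collapse = ", "))
    keepF <- setdiff(seq_len(ncol(Fmat)), dropCols)
    Fmat <- Fmat[, keepF, drop = FALSE]
    fixedIdx <- fixedIdx[keepF]
    fixedMarkerIds <- fixedMarkerIds[keepF]
  }
  comp <- NULL
  if (!perLocoReml) {
    gwFit <- fitNull(trait, computeGrm(gm))
    comp <- c(gwFit@sigma2g, gwFit@sigma2e)
  }
  y <- records(trait)$debv
  chroms <- unique(map$chrom)
  rows <- vector("list", length(chroms))
  for (i in seq_along(chroms)) {
    ch <- chroms[i]
    grm <- grms[[ch]]
    if (is.null(grm)) stop("no LOCO GRM supplied for chromosome ", ch)
    fit <- if (perLocoReml) fitNull(trait, grm) else
      fitFromComponents(trait, grm, comp[1], comp[2])
    C <- cbind(1, Fmat)
    VC <- fit@Vinv %*% C
    M <- solve(crossprod(C, VC))
    beta <- M %*% crossprod(VC, y)
    yAdj <- y - drop(C %*% beta)
    sel <- which(map$chrom == ch)
    X <- dosages(gm)[ids, sel, drop = FALSE]
    X <- imputeCenter(X)
    # project each tested dosage off the covariates (V inner product)
    G <- M %*% crossprod(VC, X)
    Xadj <- X - C %*% G
    VX <- fit@Vinv %*% Xadj
    xvx <- colSums(Xadj * VX)
    xvy <- drop(crossprod(VX, yAdj))
    const <- xvx <= 1e-12
    b <- ifelse(const, 0, xvy / xvx)
    se <- ifelse(const, NA_real_, sqrt(1 / xvx))
    tt <- ifelse(const, 0, b / se)
    p <- ifelse(const, 1, 2 * pnorm(-abs(tt)))
    flag <- ifelse(const, "constant_after_projection", NA_character_)
    isFixed <- sel %in% fixedIdx
    b[isFixed] <- 0; se[isFixed] <- NA_real_; tt[isFixed] <- 0
    p[isFixed] <- 1; flag[isFixed] <- "fixed_covariate"
    rows[[i]] <- cbind(map[sel, c("marker_id", "chrom", "bp")],
                       allele = map$allele1[sel],
                       data.frame(b = b, se = se, t = tt, p = p, flag = flag,
                                  stringsAsFactors = FALSE),
                       stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
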