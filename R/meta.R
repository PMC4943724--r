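#' Correlation matrix of signed t-values across traits
#'
#' Computes the q x q Pearson correlation matrix of signed t-values across
#' genome-wide markers, and the diagonal-corrected version used by the
#' multi-trait statistic: each diagonal element becomes
#' 1 + mean of that trait's off-diagonal correlations (off-diagonals are
#' unchanged). The correction guards against inflated composite scores when
#' some traits are, on average, more correlated than others.
#'
#' @param assocTables named list of per-trait association tables (as from
#'   \code{\link{gwaLoco}}); all must share the same marker set and order.
#'   Markers flagged in any trait are dropped (complete-case).
#' @param diagMode \code{"signed"} (default: signed mean of the off-diagonal
#'   row) or \code{"absolute"} (mean of absolute values).
#' @return list of class \code{"TraitCorrMatrix"}: \code{C_raw},
#'   \code{C_adj}, \code{row_means}, \code{markers_used}.
#' @export
tvalueCorrelation <- function(assocTables, diagMode = c("signed", "absolute")) {
  diagMode <- match.arg(diagMode)
  q <- length(assocTables)
  if (q < 2) stop("need at least 2 traits")
  ref <- assocTables[[1]]$marker_id
  for (i in seq_along(assocTables)) {
    mi <- assocTables[[i]]$marker_id
    if (!identical(mi, ref)) {
      diffm <- union(setdiff(mi, ref), setdiff(ref, mi))
      stop("association tables disagree on the marker set; e.g.: ",
           paste(head(c(diffm, "(same markers, different order)"), 5),
                 collapse = ", "))
    }
  }
  tmat <- vapply(assocTables, function(a) a$t, numeric(nrow(assocTables[[1]])))
  flagged <- Reduce(`|`, lapply(assocTables, function(a) !is.na(a$flag)))
  tmat <- tmat[!flagged, , drop = FALSE]
  if (is.null(names(assocTables)))
    colnames(tmat) <- paste0("trait", seq_len(q))
  C <- cor(tmat)
  M <- if (diagMode == "signed") C else abs(C)
  rowm <- (rowSums(M) - diag(M)) / (q - 1)
  Cadj <- C
  diag(Cadj) <- 1 + rowm
  structure(list(C_raw = C, C_adj = Cadj, row_means = rowm,
                 markers_used = sum(!flagged)),
            class = "TraitCorrMatrix")
}

#' Multi-trait chi-square meta-analysis statistic
#'
#' For each marker, combines the q signed t-values into
#' stat = t' C_adj^-1 t, referred to the upper tail of a chi-square
#' distribution with q degrees of freedom.
#'
#' @param tvec numeric q-vector of signed t-values, or an (m x q) matrix for
#'   many markers at once.
#' @param C a \code{"TraitCorrMatrix"} (from \code{\link{tvalueCorrelation}})
#'   or a plain q x q matrix used directly as C_adj.
#' @return for a vector input, a list with \code{stat} and \code{p}; for a
#'   matrix input, a data.frame with columns \code{stat}, \code{p}.
#' @export
metaStatistic <- function(tvec, C) {
  Cadj <- if (inherits(C, "TraitCorrMatrix")) C$C_adj else C
  ev <- eigen(Cadj, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10)
    stop("C_adj is singular or near-singular; consider the diagonal ",
         "adjustment or a pseudo-inverse")
  Cinv <- solve(Cadj)
  q <- ncol(Cadj)
  if (is.matrix(tvec)) {
    stopifnot(ncol(tvec) == q)
    stat <- rowSums((tvec %*% Cinv) * tvec)
    return(data.frame(stat = stat, p = pchisq(stat, df = q, lower.tail = FALSE)))
  }
  stopifnot(length(tvec) == q)
  stat <- drop(crossprod(tvec, Cinv %*% tvec))
  list(stat = stat, p = pchisq(stat, df = q, lower.tail = FALSE))
}

#' Empirical FDR threshold selection
#'
#' Sorts the p-values ascending and finds s, the largest rank i with
#' p_(i) <= f i / m; the significance threshold is alpha = f s / m and the
#' significant set is \{p < alpha\} (strict). This is the step-up rule that
#' controls the expected false-discovery proportion at level f.
#'
#' @param pValues numeric vector of p-values in [0, 1].
#' @param f target FDR level (default 0.05).
#' @return list of class \code{"FdrSelection"}: \code{f}, \code{m},
#'   \code{s}, \code{alpha}, \code{significant} (logical vector aligned to
#'   the input).
#' @export
selectFdrThreshold <- function(pValues, f = 0.05) {
  if (!length(pValues)) stop("pValues must be non-empty")
  if (any(pValues < 0 | pValues > 1, na.rm = TRUE))
    stop("pValues must lie in [0, 1]")
  m <- length(pValues)
  ps <- sort(pValues)
  ok <- which(ps <= f * seq_len(m) / m)
  s <- if (length(ok)) max(ok) else 0L
  alpha <- f * s / m
  structure(list(f = f, m = m, s = as.integer(s), alpha = alpha,
                 significant = pValues < alpha),
            class = "FdrSelection")
}

#' Mean of the off-diagonal entries of a correlation matrix
#'
#' Arithmetic mean of the q(q-1)/2 upper-triangle off-diagonal entries.
#'
#' @param corr square numeric matrix.
#' @return scalar mean.
#' @export
meanOffdiagonal <- function(corr) {
  corr <- as.matrix(corr)
  if (nrow(corr) != ncol(corr)) stop("matrix must be square")
  if (nrow(corr) < 2) stop("need at least a 2 x 2 matrix")
  mean(corr[upper.tri(corr)])
}
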