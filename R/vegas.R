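#' Expand gene windows and assign markers
#'
#' Widens each gene interval by \code{expandBp} on both sides (floored at
#' position 1) and lists the markers whose position falls inside the
#' expanded window (both ends inclusive) on the gene's chromosome.
#'
#' @param genes data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{start}, \code{end} (1-based inclusive); a \code{biotype} column
#'   is carried through if present.
#' @param markerMap data.frame with columns \code{chrom}, \code{bp},
#'   \code{marker_id}, sorted by position within chromosome.
#' @param expandBp window expansion in bp (default 100000).
#' @return the \code{genes} data.frame with added columns
#'   \code{expanded_start}, \code{expanded_end}, \code{n_members}, and a
#'   list-column \code{members} of marker-index vectors into
#'   \code{markerMap}.
#' @export
assignMarkers <- function(genes, markerMap, expandBp = 100000) {
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(genes)))
  genes$expanded_start <- pmax(1, genes$start - expandBp)
  genes$expanded_end <- genes$end + expandBp
  members <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    members[[i]] <- which(markerMap$chrom == genes$chrom[i] &
                            markerMap$bp >= genes$expanded_start[i] &
                            markerMap$bp <= genes$expanded_end[i])
  }
  genes$members <- members
  genes$n_members <- lengths(members)
  genes
}

#' Select a maximal marker subset with pairwise r2 <= threshold
#'
#' Finds a large subset of markers whose pairwise squared dosage
#' correlations are all at most \code{maxR2}, so the resulting correlation
#' matrix is well-conditioned for the Monte Carlo null. Monomorphic markers
#' are dropped first. For at most \code{exactLimit} candidates an exact
#' maximum subset is found by exhaustive search (ties broken towards lower
#' marker indices); larger sets use a deterministic greedy rule: order
#' markers by ascending number of r2 violations (ties by lower index) and
#' add each if compatible with everything already kept.
#'
#' @param X n x m dosage matrix of the candidate markers (columns).
#' @param maxR2 squared-correlation ceiling (default 0.5).
#' @param exactLimit maximum candidate count for exhaustive search
#'   (default 15).
#' @return integer vector of retained column indices of \code{X}
#'   (increasing).
#' @export
pruneR2 <- function(X, maxR2 = 0.5, exactLimit = 15) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1)
  m <- ncol(X)
  if (m == 0) return(integer(0))
  Z <- imputeCenter(X)
  poly <- apply(Z, 2, function(z) var(z) > 0)
  idx <- which(poly)
  if (!length(idx)) return(integer(0))
  if (length(idx) == 1) return(idx)
  R2 <- cor(Z[, idx, drop = FALSE])^2
  conflict <- R2 > maxR2
  diag(conflict) <- FALSE
  k <- length(idx)
  if (!any(conflict)) return(idx)
  if (k <= exactLimit) {
    # exhaustive: largest feasible subset, lexicographically smallest
    for (size in seq(k, 1)) {
      combs <- utils::combn(k, size)
      for (j in seq_len(ncol(combs))) {
        ss <- combs[, j]
        if (!any(conflict[ss, ss])) return(idx[ss])
      }
    }
  }
  viol <- rowSums(conflict)
  ord <- order(viol, seq_len(k))
  kept <- integer(0)
  for (cand in ord) {
    if (!any(conflict[cand, kept])) kept <- c(kept, cand)
  }
  idx[sort(kept)]
}

#' Gene-based statistic: sum of squared t-values
#'
#' @param tValues signed t-values of the gene's (pruned) markers.
#' @return sum of squares.
#' @export
vegasStatistic <- function(tValues) {
  if (!length(tValues)) stop("empty marker set; the caller handles p = 1")
  sum(tValues^2)
}

#' Adaptive Monte Carlo p-value for the gene statistic
#'
#' Draws z ~ MVN(0, D) and compares x2 = sum(z^2) against the observed
#' statistic; p is the fraction of draws at or above it. The simulation
#' count starts at \code{kInit} and is escalated tenfold (reusing all
#' previous draws and topping up) whenever the current p falls below 1/k,
#' up to \code{kMax}. If no draw reaches the statistic at the final stage,
#' p is reported at the bound 1/kMax with \code{censored = TRUE}.
#'
#' @param stat observed sum of squared t-values (>= 0).
#' @param D signed correlation matrix among the gene's pruned markers;
#'   repaired to positive definite by eigenvalue clipping at 1e-8 if
#'   needed.
#' @param seed integer seed for the draws.
#' @param kInit first-stage simulation count (default 1000).
#' @param kMax simulation cap (default 1e6).
#' @return list: \code{p}, \code{k} (simulations used), \code{censored}.
#' @export
mcPvalue <- function(stat, D, seed = 1L, kInit = 1000, kMax = 1e6) {
  stopifnot(stat >= 0)
  D <- as.matrix(D)
  L <- tryCatch(chol(D), error = function(e) NULL)
  if (is.null(L)) {
    eg <- eigen((D + t(D)) / 2, symmetric = TRUE)
    vals <- pmax(eg$values, 1e-8)
    Dr <- eg$vectors %*% (t(eg$vectors) * vals)
    # restore unit diagonal after clipping
    sc <- 1 / sqrt(diag(Dr))
    Dr <- Dr * tcrossprod(sc)
    L <- tryCatch(chol(Dr), error = function(e) NULL)
    if (is.null(L))
      stop("correlation matrix D is not positive definite after repair")
  }
  m <- ncol(D)
  set.seed(seed)
  draw <- function(nd) mcNullDraws(L, nd)
  x2 <- draw(kInit)
  k <- kInit
  p <- sum(x2 >= stat) / k
  while (p < 1 / k && k < kMax) {
    k <- min(10^(log10(k) + 1), kMax)
    x2 <- c(x2, draw(k - length(x2)))
    p <- sum(x2 >= stat) / k
  }
  censored <- p < 1 / kMax
  if (censored) p <- 1 / kMax
  list(p = p, k = as.integer(k), censored = censored)
}

# one batch of null draws: sum of squared components of z ~ MVN(0, L'L)
mcNullDraws <- function(L, nd) {
  m <- ncol(L)
  Z <- matrix(rnorm(nd * m), nd, m) %*% L
  rowSums(Z^2)
}

# deterministic 32-bit sub-seed from (seed, gene, trait) so per-gene
# simulations are reproducible regardless of scan order
subSeed <- function(seed, geneId, traitId = "") {
  h <- 5381
  for (ch in utf8ToInt(paste0(geneId, "|", traitId)))
    h <- (h * 33 + ch) %% 2147483647
  as.integer((h + as.numeric(seed)) %% 2147483647)
}

#' Gene-based scan for one trait
#'
#' For every gene: assign markers in the expanded window, prune to pairwise
#' r2 <= \code{maxR2}, sum the squared t-values, and compute the adaptive
#' Monte Carlo p-value from the pruned markers' signed correlation matrix.
#' Genes sheltering no markers get p = 1.
#'
#' @param assoc association table for the trait (from \code{\link{gwaLoco}}),
#'   aligned to the marker map of \code{gm}.
#' @param genes gene table (see \code{\link{assignMarkers}}); if it lacks a
#'   \code{members} column, markers are assigned here with \code{expandBp}.
#' @param gm a \code{\linkS4class{GenotypeData}} object supplying the
#'   dosages for LD.
#' @param seed global seed; each gene uses a sub-seed derived from
#'   (seed, gene id, trait id).
#' @param expandBp window expansion (default 100000).
#' @param maxR2 pruning threshold (default 0.5).
#' @param kInit,kMax Monte Carlo schedule (defaults 1000 and 1e6).
#' @return data.frame: \code{gene_id}, \code{trait_id}, \code{chrom},
#'   \code{n_members}, \code{n_markers} (pruned), \code{stat}, \code{p},
#'   \code{k}, \code{censored}.
#' @export
geneScan <- function(assoc, genes, gm, seed = 1L, expandBp = 100000,
                     maxR2 = 0.5, kInit = 1000, kMax = 1e6) {
  map <- markerMap(gm)
  if (!identical(assoc$marker_id, map$marker_id))
    stop("association table and genotype marker map are not aligned")
  if (!"flag" %in% names(assoc)) assoc$flag <- NA_character_
  if (!"members" %in% names(genes))
    genes <- assignMarkers(genes, map, expandBp)
  trait <- if (length(assoc$trait_id)) assoc$trait_id[1] else ""
  n <- nrow(genes)
  out <- data.frame(gene_id = genes$gene_id,
                    trait_id = rep(trait, n),
                    chrom = genes$chrom,
                    n_members = genes$n_members,
                    n_markers = 0L, stat = NA_real_, p = 1,
                    k = 0L, censored = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    mem <- genes$members[[i]]
    if (!length(mem)) next
    ok <- is.na(assoc$flag[mem])
    mem <- mem[ok]
    if (!length(mem)) next
    X <- dosages(gm)[, mem, drop = FALSE]
    keep <- tryCatch(pruneR2(X, maxR2 = maxR2), error = function(e) {
      warning("pruning failed for gene ", genes$gene_id[i], ": ",
              conditionMessage(e))
      integer(0)
    })
    if (!length(keep)) next
    mem <- mem[keep]
    tv <- assoc$t[mem]
    stat <- vegasStatistic(tv)
    D <- if (length(mem) == 1) matrix(1, 1, 1) else
      cor(imputeCenter(dosages(gm)[, mem, drop = FALSE]))
    mc <- tryCatch(
      mcPvalue(stat, D, seed = subSeed(seed, genes$gene_id[i], trait),
               kInit = kInit, kMax = kMax),
      error = function(e) {
        warning("Monte Carlo failed for gene ", genes$gene_id[i], ": ",
                conditionMessage(e))
        NULL
      })
    if (is.null(mc)) next
    out$n_markers[i] <- length(mem)
    out$stat[i] <- stat
    out$p[i] <- mc$p
    out$k[i] <- mc$k
    out$censored[i] <- mc$censored
  }
  out
}

#' Call pleiotropic genes across traits
#'
#' A gene is listed for a trait when its gene-based p-value is below
#' \code{listAlpha} (strict); genes listed for at least \code{minTraits}
#' traits are pleiotropy candidates, unless excluded. Exclusions support
#' explicit gene ids and whole chromosomes with named exceptions (for
#' dominant LD blocks where only the lead gene should be kept).
#'
#' @param geneResults named list of per-trait gene tables (from
#'   \code{\link{geneScan}}).
#' @param minTraits minimum number of listing traits (default 4).
#' @param listAlpha per-trait listing threshold (default 0.01).
#' @param excludeGenes character vector of gene ids to exclude.
#' @param excludeChroms character vector of chromosomes to exclude wholesale.
#' @param exceptGenes gene ids retained despite an excluded chromosome.
#' @return data.frame: \code{gene_id}, \code{n_traits}, \code{traits}
#'   (comma-separated), \code{is_candidate}, \code{excluded},
#'   \code{exclusion_reason}.
#' @export
callPleiotropic <- function(geneResults, minTraits = 4, listAlpha = 0.01,
                            excludeGenes = character(0),
                            excludeChroms = character(0),
                            exceptGenes = character(0)) {
  stopifnot(length(geneResults) >= 1)
  ids <- geneResults[[1]]$gene_id
  chrom <- geneResults[[1]]$chrom
  listed <- vapply(geneResults, function(g) {
    stopifnot(identical(g$gene_id, ids))
    g$p < listAlpha
  }, logical(length(ids)))
  listed <- matrix(listed, nrow = length(ids))
  nTraits <- rowSums(listed)
  traitNames <- names(geneResults)
  if (is.null(traitNames)) traitNames <- paste0("trait", seq_along(geneResults))
  traits <- apply(listed, 1, function(r) paste(traitNames[r], collapse = ","))
  reason <- rep(NA_character_, length(ids))
  excl <- ids %in% excludeGenes
  reason[excl] <- "excluded_gene"
  chrExcl <- chrom %in% excludeChroms & !(ids %in% exceptGenes)
  reason[chrExcl & !excl] <- "excluded_chromosome"
  excluded <- excl | chrExcl
  data.frame(gene_id = ids, chrom = chrom, n_traits = nTraits,
             traits = traits,
             is_candidate = nTraits >= minTraits & !excluded,
             excluded = excluded, exclusion_reason = reason,
             stringsAsFactors = FALSE)
}
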