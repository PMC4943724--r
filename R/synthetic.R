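#' Configuration for the synthetic-data generator
#'
#' Builds and validates the configuration controlling the synthetic
#' genotype/trait generator. Defaults mirror, at desk scale, the study
#' design the pipeline targets: a Nellore-like reference population with
#' 29 autosomes, nine traits with heritabilities between 0.25 and 0.37,
#' a handful of shared (pleiotropic) QTLs with mixed-sign effects, and
#' dEBVs of heterogeneous reliability, some below the 0.50 accuracy filter.
#'
#' @param nIndividuals number of individuals.
#' @param nMarkers total marker count, split evenly across chromosomes.
#' @param nChromosomes number of autosomes.
#' @param blockSize markers per LD block; blocks never span chromosomes.
#' @param withinBlockR target correlation between adjacent within-block
#'   dosages, in [0, 1). Implemented as a haplotype-copy probability, so the
#'   expected adjacent-marker dosage correlation equals this value exactly.
#' @param mafRange length-2 numeric, allele-frequency range (0, 0.5].
#' @param nGenes number of annotated genes.
#' @param nQtl number of pleiotropic QTLs.
#' @param qtlPleiotropy q x nQtl effect-size matrix (rows = traits); zeros
#'   mean the QTL does not affect that trait. Units: trait standard
#'   deviations of the QTL's per-allele substitution effect before
#'   normalisation of the genetic variance.
#' @param traitH2 q-vector of heritabilities in (0, 1).
#' @param reliabilityRange length-2 numeric in (0, 1]; per-record
#'   reliabilities are drawn uniformly from this range.
#' @param qtlVarFrac fraction of each affected trait's genetic variance
#'   explained jointly by the QTLs (remainder is polygenic background).
#' @param bgCorr cross-trait correlation of the polygenic backgrounds in
#'   [0, 1); together with the shared QTLs this induces the moderate
#'   cross-trait genetic correlations the pipeline expects.
#' @param missingRate genotype missing rate in [0, 1).
#' @param seed integer seed fixing every downstream draw.
#' @return A validated list of class \code{"SyntheticConfig"}.
#' @export
syntheticConfig <- function(nIndividuals = 1000,
                            nMarkers = 20000,
                            nChromosomes = 29,
                            blockSize = 20,
                            withinBlockR = 0.7,
                            mafRange = c(0.05, 0.5),
                            nGenes = 250,
                            nQtl = 3,
                            qtlPleiotropy = NULL,
                            traitH2 = c(0.37, 0.26, 0.25, 0.25, 0.26,
                                        0.33, 0.31, 0.31, 0.30),
                            reliabilityRange = c(0.15, 0.95),
                            qtlVarFrac = 0.3,
                            bgCorr = 0.75,
                            missingRate = 0.01,
                            seed = 1L) {
  if (is.null(qtlPleiotropy))
    qtlPleiotropy <- defaultPleiotropy(length(traitH2), nQtl)
  cfg <- list(nIndividuals = nIndividuals, nMarkers = nMarkers,
              nChromosomes = nChromosomes, blockSize = blockSize,
              withinBlockR = withinBlockR, mafRange = mafRange,
              nGenes = nGenes, nQtl = nQtl, qtlPleiotropy = qtlPleiotropy,
              traitH2 = traitH2, reliabilityRange = reliabilityRange,
              qtlVarFrac = qtlVarFrac, bgCorr = bgCorr,
              missingRate = missingRate,
              seed = as.integer(seed))
  validateSyntheticConfig(cfg)
  class(cfg) <- "SyntheticConfig"
  cfg
}

# Three QTLs, each affecting >= 5 of the q traits with mixed signs:
# negative on the "carcass" half, positive on the "weight/conformation" half.
defaultPleiotropy <- function(q, nQtl) {
  E <- matrix(0, q, nQtl)
  for (k in seq_len(nQtl)) {
    affected <- ((seq_len(q) + k) %% q) < max(5, ceiling(q / 2) + 1)
    sgn <- ifelse(seq_len(q) <= ceiling(q / 2), 1, -1)
    E[, k] <- ifelse(affected, sgn * (0.8 + 0.2 * k / nQtl), 0)
  }
  E
}

validateSyntheticConfig <- function(cfg) {
  chk <- function(ok, field, why)
    if (!ok) stop(sprintf("invalid synthetic config field '%s': %s", field, why),
                  call. = FALSE)
  chk(cfg$nIndividuals >= 2, "nIndividuals", "need >= 2")
  chk(cfg$nMarkers >= 1, "nMarkers", "need >= 1")
  chk(cfg$nChromosomes >= 1 && cfg$nChromosomes <= cfg$nMarkers,
      "nChromosomes", "need 1 <= nChromosomes <= nMarkers")
  chk(cfg$blockSize >= 1, "blockSize", "need >= 1")
  chk(cfg$withinBlockR >= 0 && cfg$withinBlockR < 1,
      "withinBlockR", "must be in [0, 1)")
  chk(length(cfg$mafRange) == 2 && cfg$mafRange[1] > 0 &&
        cfg$mafRange[2] <= 0.5 && cfg$mafRange[1] <= cfg$mafRange[2],
      "mafRange", "must be (low, high) within (0, 0.5]")
  chk(cfg$nGenes >= 1, "nGenes", "need >= 1")
  chk(cfg$nQtl >= 0, "nQtl", "must be >= 0")
  chk(is.matrix(cfg$qtlPleiotropy) &&
        ncol(cfg$qtlPleiotropy) == cfg$nQtl &&
        nrow(cfg$qtlPleiotropy) == length(cfg$traitH2),
      "qtlPleiotropy", "must be a q x nQtl matrix matching traitH2")
  chk(all(cfg$traitH2 > 0 & cfg$traitH2 < 1), "traitH2",
      "heritabilities must be in (0, 1)")
  chk(length(cfg$reliabilityRange) == 2 && cfg$reliabilityRange[1] > 0 &&
        cfg$reliabilityRange[2] <= 1 &&
        cfg$reliabilityRange[1] <= cfg$reliabilityRange[2],
      "reliabilityRange", "must be (low, high) within (0, 1]")
  chk(cfg$qtlVarFrac >= 0 && cfg$qtlVarFrac < 1, "qtlVarFrac",
      "must be in [0, 1)")
  chk(is.null(cfg$bgCorr) || (cfg$bgCorr >= 0 && cfg$bgCorr < 1), "bgCorr",
      "must be in [0, 1)")
  chk(cfg$missingRate >= 0 && cfg$missingRate < 1, "missingRate",
      "must be in [0, 1)")
  chk(length(cfg$seed) == 1 && is.finite(cfg$seed), "seed", "must be a scalar")
  invisible(cfg)
}

#' Generate LD-blocked biallelic genotypes
#'
#' Simulates two haplotypes per individual under a haplotype-copy LD model:
#' within a block, each marker allele copies the previous marker's allele on
#' the same haplotype with probability \code{withinBlockR}, otherwise it is
#' a fresh Bernoulli draw at the block's allele frequency. Because margins
#' are preserved, the expected correlation between adjacent within-block
#' dosages equals \code{withinBlockR}; blocks are mutually independent.
#' Block allele frequencies are drawn uniformly from \code{mafRange}.
#' Missing entries are masked at \code{missingRate}.
#'
#' @param config a \code{\link{syntheticConfig}} object.
#' @return A \code{\linkS4class{GenotypeData}} object. Positions are laid
#'   out with gaps of 1-10 kb so multi-marker genes and 100 kb windows are
#'   meaningful.
#' @export
generateGenotypes <- function(config) {
  validateSyntheticConfig(config)
  set.seed(config$seed)
  n <- config$nIndividuals
  m <- config$nMarkers
  perChrom <- tabulate(rep(seq_len(config$nChromosomes), length.out = m),
                       nbins = config$nChromosomes)
  chrom <- rep(as.character(seq_len(config$nChromosomes)), perChrom)
  bp <- unlist(lapply(perChrom, function(k)
    cumsum(sample(1000:10000, k, replace = TRUE))), use.names = FALSE)

  # block index: restart numbering at chromosome boundaries
  within <- unlist(lapply(perChrom, seq_len), use.names = FALSE)
  block <- cumsum(within == 1 |
                    (within - 1) %% config$blockSize == 0)

  dos <- matrix(0L, n, m)
  rho <- config$withinBlockR
  for (b in unique(block)) {
    idx <- which(block == b)
    p <- runif(1, config$mafRange[1], config$mafRange[2])
    h1 <- matrix(0L, n, length(idx))
    h2 <- matrix(0L, n, length(idx))
    h1[, 1] <- rbinom(n, 1, p)
    h2[, 1] <- rbinom(n, 1, p)
    if (length(idx) > 1) {
      for (j in 2:length(idx)) {
        copy1 <- runif(n) < rho
        copy2 <- runif(n) < rho
        h1[, j] <- ifelse(copy1, h1[, j - 1], rbinom(n, 1, p))
        h2[, j] <- ifelse(copy2, h2[, j - 1], rbinom(n, 1, p))
      }
    }
    dos[, idx] <- h1 + h2
  }
  storage.mode(dos) <- "double"
  if (config$missingRate > 0)
    dos[runif(n * m) < config$missingRate] <- NA_real_

  map <- data.frame(chrom = chrom, bp = bp,
                    marker_id = sprintf("snp%06d", seq_len(m)),
                    allele1 = "A", allele2 = "B",
                    stringsAsFactors = FALSE)
  genotypeData(dos, map, sprintf("ind%05d", seq_len(n)))
}

#' Generate a non-overlapping gene annotation
#'
#' Places \code{nGenes} disjoint gene intervals across the chromosomes of a
#' marker map. Most genes land inside the genotyped span; a fraction
#' (\code{desertFrac}) is deliberately placed beyond the last marker plus
#' the VEGAS window, so those genes contain no markers even after the
#' +/- 100 kb expansion and exercise the p = 1 path downstream.
#'
#' @param markerMap data.frame with columns \code{chrom}, \code{bp}.
#' @param config a \code{\link{syntheticConfig}} object.
#' @param geneLength gene length in bp (default 20000).
#' @param desertFrac fraction of genes placed in marker deserts.
#' @return data.frame with columns \code{gene_id}, \code{biotype},
#'   \code{chrom}, \code{start}, \code{end} (1-based inclusive).
#' @export
generateGeneAnnotation <- function(markerMap, config, geneLength = 20000,
                                   desertFrac = 0.1) {
  stopifnot(nrow(markerMap) > 0)
  set.seed(config$seed + 1L)
  chroms <- unique(as.character(markerMap$chrom))
  nGenes <- config$nGenes
  nDesert <- floor(nGenes * desertFrac)
  nIn <- nGenes - nDesert
  perChrom <- tabulate(rep(seq_along(chroms), length.out = nIn),
                       nbins = length(chroms))
  out <- list()
  biotypes <- c("protein_coding", "pseudogene", "snoRNA", "miRNA", "misc_RNA")
  gid <- 0L
  for (ci in seq_along(chroms)) {
    k <- perChrom[ci]
    if (k == 0) next
    span <- range(markerMap$bp[markerMap$chrom == chroms[ci]])
    # slots: non-overlapping starts spaced at least geneLength apart
    capacity <- floor((span[2] - span[1]) / geneLength)
    if (capacity < k)
      stop(sprintf("cannot place %d genes of length %d on chromosome %s", k,
                   geneLength, chroms[ci]))
    slots <- sort(sample(seq_len(capacity), k))
    start <- span[1] + (slots - 1) * geneLength
    for (s in start) {
      gid <- gid + 1L
      out[[gid]] <- data.frame(
        gene_id = sprintf("gene%04d", gid),
        biotype = sample(biotypes, 1, prob = c(0.8, 0.05, 0.05, 0.05, 0.05)),
        chrom = chroms[ci], start = s, end = s + geneLength - 1L,
        stringsAsFactors = FALSE)
    }
  }
  # marker-desert genes: beyond the last marker + expansion window
  for (d in seq_len(nDesert)) {
    ci <- ((d - 1) %% length(chroms)) + 1
    maxbp <- max(markerMap$bp[markerMap$chrom == chroms[ci]])
    s <- maxbp + 150000 + (d - 1) * (geneLength + 10000)
    gid <- gid + 1L
    out[[gid]] <- data.frame(
      gene_id = sprintf("gene%04d", gid), biotype = "protein_coding",
      chrom = chroms[ci], start = s, end = s + geneLength - 1L,
      stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, out)
  rownames(genes) <- NULL
  genes
}

#' Generate per-trait dEBV tables with known architecture
#'
#' True breeding values are the sum of the shared-QTL contribution (dosage
#' submatrix times the pleiotropy effect matrix) and an independent
#' polygenic background spread over all markers; the QTL share of the
#' genetic variance is \code{qtlVarFrac} for affected traits. Per-record
#' dEBVs add noise according to a drawn reliability r2:
#' dEBV_i = TBV_i + e_i with var(e_i) = var(TBV) (1 - r2_i)/r2_i, so
#' cor(dEBV, TBV)^2 converges to r2.
#'
#' @param genotypes a \code{\linkS4class{GenotypeData}} object.
#' @param config a \code{\link{syntheticConfig}} object.
#' @param qtlMarkerIndices optional integer vector (length \code{nQtl})
#'   fixing which markers carry the QTLs; by default they are drawn at
#'   random.
#' @param polygenicBackground if FALSE, omit the polygenic background so
#'   the true breeding values are the QTL contribution alone.
#' @return list with \code{traits} (list of \code{\linkS4class{TraitData}})
#'   and \code{truth} (list: \code{qtlMarkerIndices}, \code{effectMatrix},
#'   \code{trueBreedingValues}, \code{reliability} matrix).
#' @export
generateTraitData <- function(genotypes, config, qtlMarkerIndices = NULL,
                              polygenicBackground = TRUE) {
  validateSyntheticConfig(config)
  q <- length(config$traitH2)
  stopifnot(q >= 1)
  set.seed(config$seed + 2L)
  X <- dosages(genotypes)
  X[is.na(X)] <- 0  # truth uses complete dosages; missingness only masks calls
  n <- nrow(X); m <- ncol(X)

  nQtl <- config$nQtl
  qtlIdx <- if (!is.null(qtlMarkerIndices)) {
    stopifnot(length(qtlMarkerIndices) == nQtl)
    sort(as.integer(qtlMarkerIndices))
  } else if (nQtl > 0) sort(sample(m, nQtl)) else integer(0)
  E <- config$qtlPleiotropy  # q x nQtl

  # per-trait genetic variance normalised to 1
  TBV <- matrix(0, n, q)
  if (nQtl > 0) {
    Gq <- X[, qtlIdx, drop = FALSE] %*% t(E)  # n x q raw QTL contribution
    for (tr in seq_len(q)) {
      vq <- var(Gq[, tr])
      if (vq > 0)
        Gq[, tr] <- Gq[, tr] * sqrt(config$qtlVarFrac / vq)
    }
    TBV <- TBV + Gq
  }
  # polygenic background: a shared component across traits (weight
  # bgCorr) plus a trait-specific one, so backgrounds correlate at bgCorr
  if (polygenicBackground) {
    rho <- if (is.null(config$bgCorr)) 0 else config$bgCorr
    b0 <- rnorm(m, 0, 1)
    for (tr in seq_len(q)) {
      hasQtl <- nQtl > 0 && var(TBV[, tr]) > 0
      bgVar <- if (hasQtl) 1 - config$qtlVarFrac else 1
      b <- sqrt(rho) * b0 + sqrt(1 - rho) * rnorm(m, 0, 1)
      u <- X %*% b
      TBV[, tr] <- TBV[, tr] + drop(u) * sqrt(bgVar / var(drop(u)))
    }
  }

  rel <- matrix(runif(n * q, config$reliabilityRange[1],
                      config$reliabilityRange[2]), n, q)
  traits <- vector("list", q)
  for (tr in seq_len(q)) {
    vt <- var(TBV[, tr])
    noiseSd <- sqrt(vt * (1 - rel[, tr]) / rel[, tr])
    debv <- unname(TBV[, tr]) + rnorm(n, 0, noiseSd)
    rec <- data.frame(animal_id = sampleIds(genotypes), debv = debv,
                      reliability = rel[, tr], stringsAsFactors = FALSE)
    traits[[tr]] <- traitData(sprintf("trait%02d", tr), rec,
                              h2 = config$traitH2[tr])
  }
  names(traits) <- vapply(traits, traitId, character(1))
  list(traits = traits,
       truth = list(qtlMarkerIndices = qtlIdx, effectMatrix = E,
                    trueBreedingValues = TBV, reliability = rel))
}

#' Write a synthetic dataset to disk in the pipeline's input formats
#'
#' Writes PLINK bed/bim/fam genotypes, one TSV per trait
#' (animal_id, debv, reliability), a BED-like gene annotation TSV
#' (1-based inclusive coordinates) and ground-truth TSVs.
#'
#' @param dir output directory (created if needed).
#' @param config a \code{\link{syntheticConfig}} object.
#' @return invisibly, a list with the generated objects and file paths.
#' @export
writeSyntheticDataset <- function(dir, config = syntheticConfig()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gm <- generateGenotypes(config)
  genes <- generateGeneAnnotation(markerMap(gm), config)
  td <- generateTraitData(gm, config)
  prefix <- file.path(dir, "genotypes")
  writePlink(gm, prefix)
  write.table(genes, file.path(dir, "genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  traitPaths <- character(0)
  for (tr in td$traits) {
    p <- file.path(dir, paste0(traitId(tr), ".tsv"))
    write.table(records(tr)[, c("animal_id", "debv", "reliability")], p,
                sep = "\t", quote = FALSE, row.names = FALSE)
    traitPaths[traitId(tr)] <- p
  }
  tbv <- as.data.frame(td$truth$trueBreedingValues)
  names(tbv) <- names(td$traits)
  tbv <- cbind(animal_id = sampleIds(gm), tbv)
  write.table(tbv, file.path(dir, "truth_tbv.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  truthQtl <- data.frame(marker_id = markerMap(gm)$marker_id[td$truth$qtlMarkerIndices],
                         t(td$truth$effectMatrix))
  write.table(truthQtl, file.path(dir, "truth_qtl.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(list(genotypes = gm, genes = genes, traits = td$traits,
                 truth = td$truth, plinkPrefix = prefix,
                 genePath = file.path(dir, "genes.tsv"),
                 traitPaths = traitPaths))
}
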