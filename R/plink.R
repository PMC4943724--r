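#' Read PLINK bed/bim/fam genotypes
#'
#' Reads a variant-major PLINK 1 binary fileset. Dosages are oriented so
#' that the counted allele is the minor allele in the loaded sample: if the
#' frequency of A1 exceeds 0.5 at a marker, the dosages are flipped
#' (2 - dosage) and the allele columns swapped. Ties at frequency 0.5 keep
#' A1 as the counted allele.
#'
#' @param prefix path prefix; \code{<prefix>.bed}, \code{.bim}, \code{.fam}
#'   must all exist.
#' @return A \code{\linkS4class{GenotypeData}} object.
#' @export
readPlink <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  for (p in paths)
    if (!file.exists(p)) stop("PLINK file not found: ", p)

  bim <- read.table(paths[2], header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("chrom", "marker_id", "cm", "bp",
                                  "allele1", "allele2"))
  fam <- read.table(paths[3], header = FALSE, stringsAsFactors = FALSE)
  n <- nrow(fam); m <- nrow(bim)

  raw <- readBin(paths[1], "raw", n = file.size(paths[1]))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("malformed PLINK bed magic number in ", paths[1])
  if (raw[3] != as.raw(0x01))
    stop("only variant-major (SNP-major) bed files are supported: ", paths[1])
  bytesPerSnp <- ceiling(n / 4)
  if (length(raw) - 3 != bytesPerSnp * m)
    stop(sprintf("bed size mismatch in %s: expected %d genotype bytes for %d samples x %d markers, found %d",
                 paths[1], bytesPerSnp * m, n, m, length(raw) - 3))

  body <- as.integer(raw[-(1:3)])
  # unpack 2-bit codes, sample-fastest within each SNP's byte block
  codes <- matrix(0L, 4 * bytesPerSnp, m)
  blk <- matrix(body, bytesPerSnp, m)
  for (shift in 0:3)
    codes[seq(shift + 1, by = 4, length.out = bytesPerSnp), ] <-
      bitwAnd(bitwShiftR(blk, 2L * shift), 3L)
  codes <- codes[seq_len(n), , drop = FALSE]
  # PLINK codes: 00 hom A1, 01 missing, 10 het, 11 hom A2 -> A1 dosage
  lookup <- c(`0` = 2, `1` = NA, `2` = 1, `3` = 0)
  dos <- matrix(lookup[codes + 1L], n, m)

  # orient to minor allele in this sample
  f <- colMeans(dos, na.rm = TRUE) / 2
  flip <- !is.na(f) & f > 0.5
  if (any(flip)) {
    dos[, flip] <- 2 - dos[, flip]
    a1 <- bim$allele1[flip]
    bim$allele1[flip] <- bim$allele2[flip]
    bim$allele2[flip] <- a1
  }
  map <- bim[, c("chrom", "bp", "marker_id", "allele1", "allele2")]
  genotypeData(dos, map, as.character(fam[[2]]))
}

#' Write PLINK bed/bim/fam genotypes
#'
#' Writes a variant-major PLINK 1 binary fileset. A1 is the counted
#' (minor) allele; the bim cM column is 0 and the fam family id equals the
#' sample id with unknown parents/sex/phenotype.
#'
#' @param gm a \code{\linkS4class{GenotypeData}} object.
#' @param prefix output path prefix.
#' @return invisibly, the prefix.
#' @export
writePlink <- function(gm, prefix) {
  dos <- dosages(gm)
  map <- markerMap(gm)
  n <- nrow(dos); m <- ncol(dos)
  bim <- data.frame(map$chrom, map$marker_id, 0L, map$bp,
                    map$allele1, map$allele2)
  write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  fam <- data.frame(sampleIds(gm), sampleIds(gm), 0L, 0L, 0L, -9L)
  write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)

  # dosage of A1 -> PLINK 2-bit codes
  code <- matrix(1L, n, m)  # default missing (01)
  code[!is.na(dos) & dos == 2] <- 0L
  code[!is.na(dos) & dos == 1] <- 2L
  code[!is.na(dos) & dos == 0] <- 3L
  bytesPerSnp <- ceiling(n / 4)
  padded <- matrix(0L, 4 * bytesPerSnp, m)  # pad bits are zero
  padded[seq_len(n), ] <- code
  b <- matrix(0L, bytesPerSnp, m)
  for (shift in 0:3)
    b <- b + bitwShiftL(padded[seq(shift + 1, by = 4,
                                   length.out = bytesPerSnp), , drop = FALSE],
                        2L * shift)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(b), con)
  invisible(prefix)
}

#' Read a per-trait dEBV table
#'
#' @param path TSV with header columns \code{animal_id}, \code{debv},
#'   \code{reliability}.
#' @param traitId trait label; defaults to the file name without extension.
#' @param h2 heritability for weight computation.
#' @param c blending constant (default 0.5).
#' @return A \code{\linkS4class{TraitData}} object.
#' @export
readTraitTable <- function(path, traitId = NULL, h2, c = 0.5) {
  if (!file.exists(path)) stop("trait table not found: ", path)
  if (is.null(traitId)) traitId <- sub("\\.[^.]*$", "", basename(path))
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  traitData(traitId, df, h2 = h2, c = c)
}

#' Read a BED-like gene annotation table
#'
#' @param path delimited text with columns chromosome, start, end, gene id,
#'   biotype (header optional; detected from the first line).
#' @param dialect \code{"1-based"} (default; inclusive start/end) or
#'   \code{"bed"} (0-based half-open start, converted on read).
#' @return data.frame with columns \code{gene_id}, \code{biotype},
#'   \code{chrom}, \code{start}, \code{end}, 1-based inclusive.
#' @export
readGeneAnnotation <- function(path, dialect = c("1-based", "bed")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("gene annotation not found: ", path)
  first <- readLines(path, n = 1)
  hasHeader <- grepl("gene_id|chrom|start", first)
  df <- read.table(path, header = hasHeader, sep = "\t",
                   stringsAsFactors = FALSE)
  if (!hasHeader)
    names(df) <- c("chrom", "start", "end", "gene_id", "biotype")[seq_len(ncol(df))]
  if (!"biotype" %in% names(df)) df$biotype <- "unknown"
  if (dialect == "bed") df$start <- df$start + 1L
  df$chrom <- as.character(df$chrom)
  df[, c("gene_id", "biotype", "chrom", "start", "end")]
}
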