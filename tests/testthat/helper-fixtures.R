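# shared helpers: small in-code fixtures and independent oracles

# GenotypeData from a plain dosage matrix (one chromosome unless given)
makeGm <- function(dos, chrom = NULL, bp = NULL) {
  n <- nrow(dos); m <- ncol(dos)
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(bp)) bp <- ave(seq_len(m), chrom, FUN = function(i)
    seq(1000, by = 1000, length.out = length(i)))
  map <- data.frame(chrom = as.character(chrom), bp = bp,
                    marker_id = sprintf("m%03d", seq_len(m)),
                    allele1 = "A", allele2 = "B", stringsAsFactors = FALSE)
  genotypeData(dos, map, sprintf("s%03d", seq_len(n)))
}

# TraitData with unit weights (reliability 1, c chosen so w = 1)
makeUnitTrait <- function(y, ids = sprintf("s%03d", seq_along(y)), h2 = 0.5) {
  # w = (d + c)/lambda; with r2 = 1, d = 0 -> w = c/lambda; pick c = lambda
  lambda <- (1 - h2) / h2
  traitData("t", data.frame(animal_id = ids, debv = y, reliability = 1),
            h2 = h2, c = min(1, lambda))
}

# NullModelFit built directly from a chosen V (oracle harness)
makeFit <- function(V, yStar, w = rep(1, nrow(V))) {
  methods::new("NullModelFit", traitId = "t", excludedChrom = NA_character_,
               mu = 0, sigma2g = 1, sigma2e = 1, weights = w, V = V,
               Vinv = solve(V), yStar = yStar,
               sampleIds = sprintf("s%03d", seq_len(nrow(V))),
               remlLogLik = NA_real_)
}

# brute-force GLS oracle for the single-marker test
glsOracle <- function(x, V, yStar) {
  x <- x - mean(x)
  Vi <- solve(V)
  xvx <- drop(t(x) %*% Vi %*% x)
  b <- drop(t(x) %*% Vi %*% yStar) / xvx
  se <- sqrt(1 / xvx)
  list(b = b, se = se, t = b / se)
}

# random positive-definite covariance
randomPd <- function(n) {
  A <- matrix(rnorm(n * n), n)
  crossprod(A) / n + diag(n) * 0.5
}

# simulate y = mu + g + e with g ~ N(0, K s2g), e ~ N(0, diag(w) s2e)
simPhenotype <- function(K, s2g, s2e, w = rep(1, nrow(K)), mu = 0) {
  eg <- eigen(K, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  g <- eg$vectors %*% (sqrt(lam * s2g) * rnorm(nrow(K)))
  mu + drop(g) + rnorm(nrow(K), 0, sqrt(w * s2e))
}

# brute-force maximum feasible subset under pairwise conflicts
bruteMaxSubset <- function(conflict) {
  k <- nrow(conflict)
  best <- integer(0)
  for (size in seq(k, 1)) {
    combs <- utils::combn(k, size)
    for (j in seq_len(ncol(combs))) {
      ss <- combs[, j]
      if (!any(conflict[ss, ss])) return(ss)
    }
  }
  best
}
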