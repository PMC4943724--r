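test_that("gene windows expand 100 kb with inclusive, floored bounds", {
  map <- data.frame(chrom = "1",
                    bp = c(100000, 250000, 350000, 350001),
                    marker_id = paste0("m", 1:4),
                    stringsAsFactors = FALSE)
  genes <- data.frame(gene_id = "g1", chrom = "1",
                      start = 200000, end = 250000,
                      stringsAsFactors = FALSE)
  g <- assignMarkers(genes, map)
  expect_equal(g$expanded_start, 100000)
  expect_equal(g$expanded_end, 350000)
  expect_equal(g$members[[1]], 1:3)  # 100000 in, 350001 out

  near <- data.frame(gene_id = "g2", chrom = "1", start = 50000, end = 60000,
                     stringsAsFactors = FALSE)
  expect_equal(assignMarkers(near, map)$expanded_start, 1)
})

test_that("r2 pruning finds the maximum compatible subset", {
  set.seed(61)
  n <- 200
  base <- rnorm(n)
  x1 <- base + rnorm(n, 0, 0.2)          # r2(1,2) high
  x2 <- base + rnorm(n, 0, 0.2)
  x3 <- rnorm(n)                          # independent
  keep <- pruneR2(cbind(x1, x2, x3))
  expect_equal(unname(keep), c(1, 3))             # size 2, lower index preferred

  # all compatible: identity
  X <- matrix(rnorm(n * 4), n, 4)
  expect_equal(unname(pruneR2(X)), 1:4)

  # exact duplicates: keep the lower-index copy
  expect_equal(unname(pruneR2(cbind(x3, x3))), 1)

  # monomorphic members are dropped first
  expect_equal(unname(pruneR2(cbind(rep(1, n), x3))), 2)
})

test_that("greedy pruning is feasible and near the brute-force optimum", {
  set.seed(62)
  for (i in 1:20) {
    m <- sample(4:12, 1)
    n <- 80
    # correlated blocks to create conflicts
    X <- matrix(rnorm(n * m), n, m)
    shared <- rnorm(n)
    pick <- sample(m, ceiling(m / 2))
    X[, pick] <- X[, pick] * 0.5 + shared
    R2 <- cor(X)^2
    conflict <- R2 > 0.5; diag(conflict) <- FALSE
    best <- bruteMaxSubset(conflict)

    exact <- pruneR2(X)
    r2e <- cor(X[, exact, drop = FALSE])^2
    expect_true(all(r2e[upper.tri(r2e)] <= 0.5))
    expect_equal(length(exact), length(best))

    greedy <- pruneR2(X, exactLimit = 0)
    r2g <- cor(X[, greedy, drop = FALSE])^2
    expect_true(all(r2g[upper.tri(r2g)] <= 0.5))
    expect_lte(length(best) - length(greedy), 1)
  }
})

test_that("the gene statistic is the sum of squared t-values", {
  expect_equal(vegasStatistic(2), 4)
  expect_equal(vegasStatistic(c(1, -1, 2)), 6)
  expect_error(vegasStatistic(numeric(0)), "empty")
})

test_that("Monte Carlo p-values match chi-square tails", {
  # single marker, stat 4: P(chisq_1 >= 4) = 0.0455
  p1 <- mcPvalue(4, matrix(1, 1, 1), seed = 63, kInit = 1e4)
  truth1 <- pchisq(4, 1, lower.tail = FALSE)
  expect_lt(abs(p1$p - truth1), 3 * sqrt(truth1 * (1 - truth1) / 1e4))

  # two independent markers, stat 5.99: P(chisq_2 >= 5.99) = 0.05
  p2 <- mcPvalue(5.99, diag(2), seed = 64, kInit = 1e4)
  truth2 <- pchisq(5.99, 2, lower.tail = FALSE)
  expect_lt(abs(p2$p - truth2), 3 * sqrt(truth2 * (1 - truth2) / 1e4))

  # zero statistic: every draw is at least as large
  expect_equal(mcPvalue(0, diag(3), seed = 65)$p, 1)

  # unattainable statistic: escalates to the cap and censors at 1e-6
  pc <- mcPvalue(500, matrix(1, 1, 1), seed = 66)
  expect_equal(pc$p, 1e-6)
  expect_true(pc$censored)
  expect_equal(pc$k, 1000000L)

  # p non-increasing in the statistic for fixed seed and D
  stats <- c(0.5, 2, 4, 8, 16)
  ps <- vapply(stats, function(s) mcPvalue(s, diag(2), seed = 67)$p,
               numeric(1))
  expect_true(all(diff(ps) <= 0))

  # non-positive-definite D is repaired to a usable correlation
  Dbad <- matrix(c(1, 0.9, 0.9, 1, 0.9, 0.9, 0.9, 0.9, 1), 3)
  Dbad[1, 2] <- Dbad[2, 1] <- -0.9  # indefinite
  pr <- mcPvalue(3, Dbad, seed = 68, kInit = 1000)
  expect_true(pr$p > 0 && pr$p <= 1)
})

test_that("gene scan handles deserts, determinism and null calibration", {
  cfg <- syntheticConfig(nIndividuals = 200, nMarkers = 2000,
                         nChromosomes = 4, nGenes = 200, blockSize = 10,
                         withinBlockR = 0.5, nQtl = 0,
                         qtlPleiotropy = matrix(0, 9, 0),
                         missingRate = 0, seed = 69)
  gm <- generateGenotypes(cfg)
  genes <- generateGeneAnnotation(markerMap(gm), cfg, geneLength = 5000)
  # null trait: pure noise dEBVs, independent of the genotypes
  set.seed(690)
  tr <- traitData("null", data.frame(animal_id = sampleIds(gm),
                                     debv = rnorm(nSamples(gm)),
                                     reliability = runif(nSamples(gm), 0.5, 0.9)),
                  h2 = 0.3)
  grms <- computeLocoGrms(gm)
  assoc <- gwaLoco(gm, tr, grms)
  assoc$trait_id <- traitId(tr)
  v1 <- geneScan(assoc, genes, gm, seed = 70)
  v2 <- geneScan(assoc, genes, gm, seed = 70)
  expect_identical(v1$p, v2$p)

  deserts <- v1$n_members == 0
  expect_gte(sum(deserts), 1)
  expect_true(all(v1$p[deserts] == 1))

  frac <- mean(v1$p < 0.01)
  expect_gte(frac, 0.002 - 0.002)  # lower edge of the calibration band
  expect_lte(frac, 0.03)
})

test_that("pleiotropy calls apply the >=4-trait rule and exclusions", {
  mk <- function(ps) data.frame(gene_id = c("g1", "g2", "g3"),
                                chrom = c("1", "14", "14"),
                                p = ps, stringsAsFactors = FALSE)
  res <- list(t1 = mk(c(0.001, 0.001, 0.5)),
              t2 = mk(c(0.002, 0.001, 0.5)),
              t3 = mk(c(0.003, 0.001, 0.001)),
              t4 = mk(c(0.004, 0.001, 0.001)),
              t5 = mk(c(0.5,   0.5,   0.001)))
  calls <- callPleiotropic(res, minTraits = 4)
  # g1 listed for 4 traits -> candidate; g3 for 3 -> not
  expect_true(calls$is_candidate[calls$gene_id == "g1"])
  expect_false(calls$is_candidate[calls$gene_id == "g3"])

  # whole-chromosome exclusion with a named exception
  calls2 <- callPleiotropic(res, minTraits = 4, excludeChroms = "14",
                            exceptGenes = "g2")
  expect_true(calls2$is_candidate[calls2$gene_id == "g2"])
  expect_true(calls2$excluded[calls2$gene_id == "g3"])

  # listing threshold is strict: p exactly 0.01 does not list
  resb <- list(t1 = mk(c(0.01, 1, 1)), t2 = mk(c(0.005, 1, 1)))
  callsb <- callPleiotropic(resb, minTraits = 2)
  expect_equal(callsb$n_traits[callsb$gene_id == "g1"], 1)
})
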