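test_that("VanRaden GRM matches a hand-computed cross-product", {
  dos <- matrix(c(0, 1, 2, 1,
                  2, 2, 0, 0,
                  1, 0, 1, 2), 4, 3)
  gm <- makeGm(dos, chrom = c("1", "1", "2"))
  K <- grmMatrix(computeGrm(gm))
  p <- colMeans(dos) / 2
  Z <- sweep(dos, 2, 2 * p)
  Kexp <- Z %*% t(Z) / (2 * sum(p * (1 - p)))
  expect_equal(unname(K), unname(Kexp), tolerance = 1e-12)

  # identical genomes: off-diagonal equals the shared diagonal
  dup <- rbind(dos, dos[1, ])
  Kd <- grmMatrix(computeGrm(makeGm(dup, chrom = c("1", "1", "2"))))
  expect_equal(Kd[1, 5], Kd[1, 1], tolerance = 1e-12)

  # excluding the only chromosome -> error
  gm1 <- makeGm(dos, chrom = rep("1", 3))
  expect_error(computeGrm(gm1, excludeChrom = "1"), "fewer than 2")
  # monomorphic-only -> zero denominator error
  mono <- makeGm(matrix(1, 4, 2) * 0)
  expect_error(computeGrm(mono), "monomorphic")
})

test_that("LOCO GRMs equal per-chromosome exclusion builds", {
  set.seed(41)
  dos <- matrix(sample(0:2, 50 * 60, replace = TRUE), 50, 60)
  gm <- makeGm(dos, chrom = rep(c("1", "2", "3"), each = 20))
  grms <- computeLocoGrms(gm)
  for (ch in c("1", "2", "3"))
    expect_equal(grmMatrix(grms[[ch]]),
                 grmMatrix(computeGrm(gm, excludeChrom = ch)),
                 tolerance = 1e-10)
})

test_that("REML degenerates to OLS when K = I and weights are 1", {
  set.seed(42)
  n <- 80
  y <- rnorm(n, mean = 3, sd = 2)
  tr <- makeUnitTrait(y)
  K <- diag(n)
  dimnames(K) <- list(records(tr)$animal_id, records(tr)$animal_id)
  grm <- methods::new("Grm", K = K, excludedChrom = NA_character_,
                      nMarkersUsed = 1L)
  # scale w to exactly 1
  tr@records$w <- rep(1, n)
  fit <- fitNull(tr, grm)
  vc <- varianceComponents(fit)
  expect_equal(unname(vc["mu"]), mean(y), tolerance = 1e-6)
  expect_equal(unname(vc["sigma2g"] + vc["sigma2e"]), var(y),
               tolerance = 1e-4)
})

test_that("V is invariant when weights double and sigma2e halves", {
  set.seed(43)
  cfg <- syntheticConfig(nIndividuals = 60, nMarkers = 150, nChromosomes = 2,
                         missingRate = 0, seed = 43)
  gm <- generateGenotypes(cfg)
  td <- generateTraitData(gm, cfg)
  tr <- td$traits[[1]]
  grm <- computeGrm(gm)
  fit1 <- fitNull(tr, grm)
  tr2 <- tr
  tr2@records$w <- tr@records$w * 2
  fit2 <- fitNull(tr2, grm)
  expect_equal(fit2@sigma2e, fit1@sigma2e / 2, tolerance = 1e-4)
  expect_equal(fit2@sigma2g, fit1@sigma2g, tolerance = 1e-4)
  expect_equal(fit2@V, fit1@V, tolerance = 1e-4)
})

test_that("score test matches the dense GLS oracle", {
  set.seed(44)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    V <- randomPd(n)
    yStar <- rnorm(n)
    x <- sample(0:2, n, replace = TRUE)
    if (var(x) == 0) next
    fit <- makeFit(V, yStar)
    got <- scoreTest(x, fit)
    want <- glsOracle(x, V, yStar)
    expect_equal(got$b, want$b, tolerance = 1e-10)
    expect_equal(got$se, want$se, tolerance = 1e-10)
    expect_equal(got$t, want$t, tolerance = 1e-10)
    expect_equal(got$p, 2 * pnorm(-abs(want$t)), tolerance = 1e-10)
  }
})

test_that("score test reduces to OLS under V = I and flags edge cases", {
  set.seed(45)
  n <- 40
  yStar <- rnorm(n); yStar <- yStar - mean(yStar)
  x <- sample(0:2, n, replace = TRUE)
  fit <- makeFit(diag(n), yStar)
  got <- scoreTest(x, fit)
  xc <- x - mean(x)
  expect_equal(got$b, sum(xc * yStar) / sum(xc^2), tolerance = 1e-12)

  # V-orthogonal marker: b = 0, t = 0
  xo <- residuals(lm(rnorm(n) ~ yStar))
  gotO <- scoreTest(xo, fit)
  expect_equal(gotO$b, 0, tolerance = 1e-10)
  expect_equal(gotO$t, 0, tolerance = 1e-10)

  # constant marker: flagged with p = 1
  gotC <- scoreTest(rep(2, n), fit)
  expect_equal(gotC$p, 1)
  expect_equal(gotC$flag, "constant_dosage")

  # missing dosages are mean-imputed (same result as explicit imputation)
  xm <- as.numeric(x); xm[1:3] <- NA
  xi <- xm; xi[1:3] <- mean(xm, na.rm = TRUE)
  expect_equal(scoreTest(xm, fit)$b, scoreTest(xi, fit)$b, tolerance = 1e-12)
})

test_that("REML recovers the variance ratio on simulated data", {
  set.seed(46)
  cfg <- syntheticConfig(nIndividuals = 500, nMarkers = 800, nChromosomes = 2,
                         missingRate = 0, seed = 46)
  gm <- generateGenotypes(cfg)
  grm <- computeGrm(gm)
  K <- grmMatrix(grm)
  h2hat <- replicate(8, {
    y <- simPhenotype(K, s2g = 0.4, s2e = 0.6)
    tr <- makeUnitTrait(y, ids = rownames(K))
    tr@records$w <- rep(1, nrow(K))
    vc <- varianceComponents(fitNull(tr, grm))
    unname(vc["h2_marker"])
  })
  expect_equal(mean(h2hat), 0.4, tolerance = 0.08 / 0.4)
})

test_that("LOCO statistics ignore the excluded chromosome's content", {
  set.seed(47)
  cfg <- syntheticConfig(nIndividuals = 80, nMarkers = 300, nChromosomes = 3,
                         missingRate = 0, seed = 47)
  gm <- generateGenotypes(cfg)
  td <- generateTraitData(gm, cfg)
  tr <- td$traits[[1]]
  mkGrms <- function(g) {
    out <- lapply(c("1", "2", "3"), function(ch)
      computeGrm(g, excludeChrom = ch))
    names(out) <- c("1", "2", "3")
    out
  }
  grms <- mkGrms(gm)
  a1 <- gwaLoco(gm, tr, grms)

  # scramble chromosome 2's dosages (row permutation) before GRM building
  dos <- dosages(gm)
  sel <- markerMap(gm)$chrom == "2"
  dos[, sel] <- dos[sample(nrow(dos)), sel]
  gm2 <- genotypeData(dos, markerMap(gm), sampleIds(gm))
  a2 <- gwaLoco(gm, tr, mkGrms(gm2))
  expect_identical(a1$t[a1$chrom == "2"], a2$t[a2$chrom == "2"])

  # the one-pass LOCO builder agrees with direct exclusion builds
  fast <- computeLocoGrms(gm)
  expect_equal(grmMatrix(fast[["2"]]), grmMatrix(grms[["2"]]),
               tolerance = 1e-10)
  # missing LOCO fit -> error
  expect_error(gwaLoco(gm, tr, grms[c("1", "2")]), "chromosome")
})

test_that("LOCO avoids proximal contamination for a causal marker", {
  wins <- 0
  for (rep in 1:10) {
    cfg <- syntheticConfig(nIndividuals = 250, nMarkers = 400,
                           nChromosomes = 4, nQtl = 1,
                           qtlPleiotropy = matrix(2, 1, 1), traitH2 = 0.3,
                           qtlVarFrac = 0.35, withinBlockR = 0.4,
                           reliabilityRange = c(0.9, 0.9),
                           missingRate = 0, seed = 400 + rep)
    gm <- generateGenotypes(cfg)
    td <- generateTraitData(gm, cfg, qtlMarkerIndices = 50)
    tr <- td$traits[[1]]
    x <- dosages(gm)[, 50]
    ch <- markerMap(gm)$chrom[50]
    fitLoco <- fitNull(tr, computeGrm(gm, excludeChrom = ch))
    fitFull <- fitNull(tr, computeGrm(gm))
    tLoco <- abs(scoreTest(x, fitLoco)$t)
    tFull <- abs(scoreTest(x, fitFull)$t)
    if (tLoco >= tFull) wins <- wins + 1
  }
  expect_gte(wins, 8)
})

test_that("conditioning behaves as a V-orthogonal projection", {
  # with K = I the fitted V is proportional to I, so ordinary orthogonality
  # of centered dosages makes conditioning a no-op for the tested marker
  n <- 8
  x <- rep(c(0, 2), 4)            # centered: (-1, 1, ...)
  fvec <- rep(c(0, 0, 2, 2), 2)   # centered orthogonal to x
  other <- c(0, 1, 2, 0, 1, 2, 0, 1)
  dos <- cbind(x, other, fvec)
  gm <- makeGm(dos, chrom = c("1", "1", "2"))
  set.seed(48)
  y <- rnorm(n)
  tr <- makeUnitTrait(y, ids = sampleIds(gm))
  tr@records$w <- rep(1, n)
  mkGrm <- function(ch) {
    K <- diag(n); dimnames(K) <- list(sampleIds(gm), sampleIds(gm))
    methods::new("Grm", K = K, excludedChrom = ch, nMarkersUsed = 1L)
  }
  grms <- list("1" = mkGrm("1"), "2" = mkGrm("2"))
  plain <- gwaLoco(gm, tr, grms)
  cond <- conditionalScan(gm, tr, grms, fixedMarkerIds = "m003")
  expect_equal(cond$t[cond$marker_id == "m001"],
               plain$t[plain$marker_id == "m001"], tolerance = 1e-8)

  # the fixed marker itself is flagged with p = 1
  expect_equal(cond$p[cond$marker_id == "m003"], 1)
  expect_equal(cond$flag[cond$marker_id == "m003"], "fixed_covariate")

  # conditioning on a duplicate of the tested marker kills its signal
  dup <- cbind(x, x, other)
  gmd <- makeGm(dup, chrom = c("1", "1", "2"))
  condd <- conditionalScan(gmd, tr, grms, fixedMarkerIds = "m002")
  expect_equal(condd$p[condd$marker_id == "m001"], 1)

  # collinear fixed markers are dropped with a warning
  expect_warning(conditionalScan(gmd, tr, grms,
                                 fixedMarkerIds = c("m001", "m002")),
                 "collinear")
})

test_that("conditioning on the causal marker removes the regional signal", {
  cfg <- syntheticConfig(nIndividuals = 300, nMarkers = 400, nChromosomes = 2,
                         nQtl = 1, qtlPleiotropy = matrix(2, 1, 1),
                         traitH2 = 0.3, qtlVarFrac = 0.5,
                         reliabilityRange = c(0.9, 0.9),
                         missingRate = 0, seed = 49)
  gm <- generateGenotypes(cfg)
  td <- generateTraitData(gm, cfg, qtlMarkerIndices = 100)
  tr <- td$traits[[1]]
  grms <- computeLocoGrms(gm)
  plain <- gwaLoco(gm, tr, grms)
  qtlId <- markerMap(gm)$marker_id[100]
  region <- markerMap(gm)$chrom == markerMap(gm)$chrom[100] &
    abs(markerMap(gm)$bp - markerMap(gm)$bp[100]) < 100000
  expect_lt(min(plain$p[region]), 1e-6)
  cond <- conditionalScan(gm, tr, grms, fixedMarkerIds = qtlId)
  expect_equal(sum(cond$p[region & cond$flag %in% NA] < 1e-4), 0)
})
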