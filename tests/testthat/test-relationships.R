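test_that("A-inverse reproduces the textbook trio pattern", {
  ped <- data.frame(id = 1:3, sire = c(0L, 0L, 1L), dam = c(0L, 0L, 2L))
  A <- buildAInverse(ped)
  expect_equal(as.matrix(A$Ainv),
               matrix(c(1.5, 0.5, -1, 0.5, 1.5, -1, -1, -1, 2), 3),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(A$inbreeding, c(0, 0, 0))
  # diagonal of A itself is 1 for the non-inbred child
  expect_equal(solve(as.matrix(A$Ainv))[3, 3], 1, tolerance = 1e-12)
})

test_that("full-sib mating gives inbreeding 0.25", {
  ped <- data.frame(id = 1:5, sire = c(0L, 0L, 1L, 1L, 3L),
                    dam = c(0L, 0L, 2L, 2L, 4L))
  A <- buildAInverse(ped)
  expect_equal(A$inbreeding[5], 0.25, tolerance = 1e-12)
})

test_that("sparse A-inverse matches the dense tabular oracle", {
  ped <- randomPedigree(50, nFounders = 8, seed = 21)
  A <- buildAInverse(ped[, c("id", "sire", "dam")])
  Adense <- oracleTabularA(ped$sire, ped$dam)
  expect_lt(max(abs(as.matrix(A$Ainv) - solve(Adense))), 1e-8)
  expect_equal(A$inbreeding, diag(Adense) - 1, tolerance = 1e-10)
})

test_that("grouped A-inverse solves the unknown-parent-group model", {
  # oracle route: explicit Q and covariance of u* in the transformed system
  ped <- randomPedigree(40, nFounders = 6, seed = 4)
  groups <- rep(c("G1", "G2"), length.out = 40)
  A <- buildAInverse(ped, groups = groups)
  expect_equal(dim(A$Ainv), c(42L, 42L))
  # the animal block of the grouped inverse, reduced by absorbing the group
  # equations, must equal the classic A-inverse (QP-transform consistency)
  M <- as.matrix(A$Ainv)
  Ann <- M[1:40, 1:40]; Ang <- M[1:40, 41:42]; Agg <- M[41:42, 41:42]
  red <- Ann - Ang %*% solve(Agg) %*% t(Ang)
  # absorbing groups recovers the classic inverse up to the founder-level
  # indeterminacy: compare against classic A-inverse on the same pedigree
  classic <- as.matrix(buildAInverse(ped[, c("id", "sire", "dam")])$Ainv)
  # rows/cols for non-founders agree exactly; founder block differs by the
  # absorbed group uncertainty
  nf <- which(ped$sire > 0)
  expect_lt(max(abs(red[nf, nf] - classic[nf, nf])), 1e-8)
})

test_that("Q fractions recurse to 1 and follow parental averaging", {
  ped <- data.frame(id = 1:4, sire = c(0L, 0L, 1L, 3L),
                    dam = c(0L, 0L, 2L, 0L))
  Q <- upgContributions(ped, groups = c("X", "Y", "X", "Y"))
  expect_equal(rowSums(Q), rep(1, 4))
  expect_equal(Q[3, ], c(X = 0.5, Y = 0.5))
  expect_equal(Q[4, ], c(X = 0.25, Y = 0.75))
})

test_that("Gamma estimation matches hand computation and its invariances", {
  # single column with variance 0.03125 -> gamma = 8 * 0.03125 = 0.25
  P1 <- matrix(c(0.5, 0.75), ncol = 1)
  expect_equal(as.numeric(estimateGamma(P1)), 0.25)
  # constant frequencies give a zero matrix
  P0 <- matrix(0.5, nrow = 6, ncol = 3)
  expect_true(all(estimateGamma(P0) == 0))
  # allele relabelling p -> 1 - p leaves Gamma unchanged
  set.seed(2)
  P <- matrix(runif(8), 4, 2)
  expect_equal(estimateGamma(P), estimateGamma(1 - P), ignore_attr = TRUE)
  expect_error(estimateGamma(P[1, , drop = FALSE]), "2 markers")
  # 4-marker 2-breed hand computation: Gamma = 8 * cov(P)
  P2 <- matrix(c(0.1, 0.3, 0.6, 0.8, 0.2, 0.2, 0.7, 0.5), 4, 2)
  expect_equal(estimateGamma(P2), 8 * cov(P2), ignore_attr = TRUE)
})

test_that("gamma-augmented A reduces to classic A when Gamma is zero", {
  ped <- randomPedigree(20, nFounders = 4, seed = 7)
  pedMF <- ped[, c("id", "sire", "dam")]
  pedMF$sire[pedMF$sire == 0] <- -1L
  pedMF$dam[pedMF$dam == 0] <- -1L
  mf <- data.frame(id = -1L, breed = "A")
  AG <- buildAGamma(pedMF, matrix(0, 1, 1), mf)
  Adense <- oracleTabularA(ped$sire, ped$dam)
  expect_lt(max(abs(AG[-1, -1] - Adense)), 1e-12)
})

test_that("metafounder self-offspring diagonal follows the tabular rule", {
  ped <- data.frame(id = 1L, sire = -1L, dam = -1L)
  mf <- data.frame(id = -1L, breed = "A")
  G <- matrix(0.5, 1, 1)
  AG <- buildAGamma(ped, G, mf)
  expect_equal(AG[2, 2], 1.25) # 1 + gamma / 2
  inv <- buildAGammaInverse(ped, G, mf)
  expect_equal(inv$diag[2], 1.25)
  expect_lt(max(abs(as.matrix(inv$Ainv) - solve(AG))), 1e-10)
})

test_that("sparse gamma-pedigree inverse matches the dense oracle", {
  ped <- randomPedigree(30, nFounders = 5, seed = 13)
  Gamma <- randomGamma(3, seed = 5)
  # founders assigned round-robin to the three metafounders
  mfAssign <- rep(1:3, length.out = 5)
  pedMF <- ped[, c("id", "sire", "dam")]
  for (i in which(ped$sire == 0)) {
    pedMF$sire[i] <- -mfAssign[i]
    pedMF$dam[i] <- -mfAssign[i]
  }
  mf <- data.frame(id = -(1:3), breed = c("A", "B", "C"))
  inv <- buildAGammaInverse(pedMF, Gamma, mf)
  # oracle: dense tabular with the metafounder block set to Gamma
  cmb <- ifelse(pedMF$sire < 0, -pedMF$sire, pedMF$sire + 3L)
  cmbD <- ifelse(pedMF$dam < 0, -pedMF$dam, pedMF$dam + 3L)
  AG <- oracleTabularAGamma(cmb, cmbD, Gamma)
  expect_lt(max(abs(as.matrix(inv$Ainv) - solve(AG))), 1e-8)
  expect_equal(inv$diag, diag(AG), tolerance = 1e-10)
})

test_that("relationshipSubset extracts the exact dense block", {
  ped <- randomPedigree(25, nFounders = 5, seed = 3)
  pedMF <- ped[, c("id", "sire", "dam")]
  pedMF$sire[pedMF$sire == 0] <- -1L
  pedMF$dam[pedMF$dam == 0] <- -1L
  mf <- data.frame(id = -1L, breed = "A")
  Gamma <- matrix(0.4, 1, 1)
  inv <- buildAGammaInverse(pedMF, Gamma, mf)
  AG <- oracleTabularAGamma(ifelse(pedMF$sire < 0, 1L, pedMF$sire + 1L),
                            ifelse(pedMF$dam < 0, 1L, pedMF$dam + 1L), Gamma)
  idx <- c(3, 10, 22) + 1L
  expect_lt(max(abs(relationshipSubset(inv$Ainv, idx) - AG[idx, idx])), 1e-8)
})

test_that("genomic relationship follows the incidence coding", {
  # fully heterozygous animal: w = 0, so zero self-relationship
  M <- matrix(1L, 1, 10)
  expect_equal(buildGGamma(M)[1, 1], 0)
  # two markers AA and aa: w = (1, -1), s = 1 -> self-relationship 2
  M2 <- matrix(c(2L, 0L), 1, 2)
  expect_equal(buildGGamma(M2)[1, 1], 2)
  # identical twins: off-diagonal equals both diagonals
  M3 <- rbind(c(2L, 1L, 0L, 2L), c(2L, 1L, 0L, 2L))
  G3 <- buildGGamma(M3)
  expect_equal(G3[1, 2], G3[1, 1])
  expect_equal(G3[1, 2], G3[2, 2])
  expect_error(buildGGamma(matrix(3L, 1, 2)), "dosages")
  expect_error(buildGGamma(matrix(NA_integer_, 1, 2)), "missing")
})

test_that("single-step H-inverse matches the dense formula on a toy", {
  set.seed(31)
  ped <- randomPedigree(40, nFounders = 6, seed = 31)
  pedMF <- ped[, c("id", "sire", "dam")]
  mfAssign <- rep(1:2, length.out = 6)
  for (i in which(ped$sire == 0)) {
    pedMF$sire[i] <- -mfAssign[i]; pedMF$dam[i] <- -mfAssign[i]
  }
  mf <- data.frame(id = -(1:2), breed = c("A", "B"))
  Gamma <- randomGamma(2, seed = 8)
  inv <- buildAGammaInverse(pedMF, Gamma, mf)
  geno <- sort(sample(10:40, 12))
  # a valid positive-definite "genomic" matrix near the pedigree block
  A22 <- relationshipSubset(inv$Ainv, geno + 2L)
  G <- A22 + crossprod(matrix(rnorm(12 * 12, sd = 0.05), 12))
  H <- buildHGammaInverse(inv$Ainv, geno + 2L, G, A22)
  # dense oracle
  cmbS <- ifelse(pedMF$sire < 0, -pedMF$sire, pedMF$sire + 2L)
  cmbD <- ifelse(pedMF$dam < 0, -pedMF$dam, pedMF$dam + 2L)
  AG <- oracleTabularAGamma(cmbS, cmbD, Gamma)
  Hd <- solve(AG)
  gi <- geno + 2L
  Hd[gi, gi] <- Hd[gi, gi] + solve(G) - solve(AG[gi, gi])
  expect_lt(max(abs(as.matrix(H) - Hd)), 1e-8)
})

test_that("H-inverse reduction identities hold", {
  ped <- data.frame(id = 1:4, sire = c(-1L, -1L, 1L, 1L),
                    dam = c(-1L, -1L, 2L, 2L))
  mf <- data.frame(id = -1L, breed = "A")
  Gamma <- matrix(0.3, 1, 1)
  inv <- buildAGammaInverse(ped, Gamma, mf)
  # no genotyped animals: H-inverse equals the gamma pedigree inverse
  H0 <- buildHGammaInverse(inv$Ainv, integer(), matrix(0, 0, 0),
                           matrix(0, 0, 0))
  expect_lt(max(abs(as.matrix(H0) - as.matrix(inv$Ainv))), 1e-12)
  # G numerically equal to A22: correction vanishes
  A22 <- relationshipSubset(inv$Ainv, c(4L, 5L))
  H1 <- buildHGammaInverse(inv$Ainv, c(4L, 5L), A22, A22)
  expect_lt(max(abs(as.matrix(H1) - as.matrix(inv$Ainv))), 1e-10)
})

test_that("G tracks the gamma pedigree block under complete genotyping", {
  # pure-drift two-breed population, 2000 markers on the desk genome; the
  # genotyped cohort is the last three formation generations
  map <- uniformGenomeMap(5, 80, 4500)
  pool <- simulateHistorical(map, 40, 60, 10, 60, mutationRate = 2.5e-5,
                             seed = 77)
  sel <- selectSegregatingLoci(pool, 2000, 10, 0.1, seed = 78)
  pop <- expandPopulation(sel, 10, 20, 2, 3, mutationRate = 0, seed = 79)
  pop <- formBreeds(pop, 2, 12, 12, 10, 2, mutationRate = 0, seed = 80)
  ped <- pedigree(pop)
  mk <- markerLoci(genomeMap(pop))
  bf <- which(!is.na(ped$breed) & ped$step == 2) # breed founders
  P <- cbind(
    A = alleleFrequencies(pop, loci = mk, individuals = bf[ped$breed[bf] == "A"]),
    B = alleleFrequencies(pop, loci = mk, individuals = bf[ped$breed[bf] == "B"]))
  Gamma <- estimateGamma(P)
  # truncate to the breed populations, breed founders -> metafounders
  s3 <- which(ped$step == 3 | (!is.na(ped$breed) & ped$step == 2))
  sub <- ped[s3, ]
  remap <- integer(nrow(ped)); remap[sub$id] <- seq_along(s3)
  toMF <- function(p) ifelse(p > 0 & p %in% sub$id, remap[pmax(p, 1)],
                             ifelse(sub$breed == "A", -1L, -2L))
  pedMF <- data.frame(id = seq_along(s3), sire = toMF(sub$sire),
                      dam = toMF(sub$dam))
  inv <- buildAGammaInverse(pedMF, Gamma,
                            data.frame(id = -(1:2), breed = c("A", "B")))
  late <- which(sub$generation >= 8 & sub$step == 3)
  G <- buildGGamma(dosages(pop, loci = mk, individuals = s3[late]))
  A22 <- relationshipSubset(inv$Ainv, late + 2L)
  ut <- upper.tri(G)
  expect_gt(cor(G[ut], A22[ut]), 0.8)
  expect_lt(abs(mean(G[ut]) - mean(A22[ut])), 0.1)
  expect_lt(abs(mean(diag(G)) - mean(diag(A22))), 0.15)
})
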