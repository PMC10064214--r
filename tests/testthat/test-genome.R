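test_that("uniformGenomeMap lays out a valid evenly spaced pool", {
  map <- uniformGenomeMap(5, 80, 1000)
  expect_equal(nChromosomes(map), 5)
  expect_equal(sum(chromLengthsCM(map)), 400)
  expect_equal(nLoci(map), 1000)
  lp <- locusPositions(map)
  expect_true(all(tapply(lp$posCM, lp$chrom, function(p) all(diff(p) > 0))))
  # unequal lengths apportion loci proportionally
  map2 <- uniformGenomeMap(2, c(30, 90), 100)
  expect_equal(as.integer(table(locusPositions(map2)$chrom)), c(25, 75))
})

test_that("invalid genome maps are rejected", {
  expect_error(new("GenomeMap", chrom = c(1L, 1L), posCM = c(5, 5),
                   role = c("candidate", "candidate"), chromLengthsCM = 10),
               "strictly increasing")
  expect_error(new("GenomeMap", chrom = 1L, posCM = 5, role = "gene",
                   chromLengthsCM = 10), "role")
})

test_that("fixed monomorphic founders stay monomorphic without mutation", {
  map <- uniformGenomeMap(1, 50, 40)
  expect_warning(
    pool <- simulateHistorical(map, 5, 10, 3, 12, mutationRate = 0,
                               initFreq = 0, seed = 1),
    "no segregating loci")
  expect_true(all(alleleFrequencies(pool) == 0))
  expect_error(simulateHistorical(map, 5, 10, 3, 12, mutationRate = 0,
                                  initFreq = 0, seed = 1,
                                  requireSegregating = TRUE),
               "mutation rate")
})

test_that("without recombination every output haplotype copies a founder", {
  map <- uniformGenomeMap(1, 0, 30) # single 0-cM chromosome
  set.seed(5)
  hap <- matrix(as.raw(rbinom(30 * 20, 1, 0.5)), 30, 20)
  par <- sample.int(10, 50, replace = TRUE)
  gm <- metaGSim:::.dropGametes(hap, par, map, 0)
  founders <- apply(hap, 2, paste, collapse = "")
  out <- apply(gm, 2, paste, collapse = "")
  expect_true(all(out %in% founders))
})

test_that("history builds linkage disequilibrium that decays with distance", {
  map <- uniformGenomeMap(1, 100, 300)
  pool <- simulateHistorical(map, 80, 60, 20, 60, mutationRate = 2.5e-5,
                             seed = 42)
  f <- alleleFrequencies(pool)
  keep <- which(pmin(f, 1 - f) > 0.1)
  D <- dosages(pool, loci = keep)
  pos <- pool@map@posCM[keep]
  r2 <- cor(D)^2
  dm <- abs(outer(pos, pos, "-"))
  ut <- upper.tri(r2)
  near <- r2[ut & dm < 1]
  far <- r2[ut & dm > 10]
  expect_gt(mean(near), mean(far))
})

test_that("neutral drift conserves expected allele frequency across seeds", {
  map <- uniformGenomeMap(1, 50, 60)
  fin <- sapply(1:12, function(s)
    mean(alleleFrequencies(simulateHistorical(map, 15, 40, 5, 40,
                                              mutationRate = 0, seed = s,
                                              initFreq = 0.5))))
  # mean over replicates returns to the initial frequency within MC error
  se <- sd(fin) / sqrt(length(fin))
  expect_lt(abs(mean(fin) - 0.5), 4 * se + 0.01)
})

test_that("r2 decays monotonically over binned distance (averaged seeds)", {
  map <- uniformGenomeMap(1, 100, 200)
  bins <- c(0, 2, 10, 40, 100)
  acc <- matrix(0, 10, length(bins) - 1)
  for (s in 1:10) {
    pool <- simulateHistorical(map, 40, 50, 10, 50, mutationRate = 2.5e-5,
                               seed = 100 + s)
    f <- alleleFrequencies(pool)
    keep <- which(pmin(f, 1 - f) > 0.1)
    D <- dosages(pool, loci = keep)
    r2 <- cor(D)^2
    dm <- abs(outer(pool@map@posCM[keep], pool@map@posCM[keep], "-"))
    ut <- upper.tri(r2)
    acc[s, ] <- sapply(seq_len(length(bins) - 1), function(b)
      mean(r2[ut & dm >= bins[b] & dm < bins[b + 1]]))
  }
  m <- colMeans(acc)
  expect_true(all(diff(m) < 0))
})

test_that("marker selection filters MAF and hits the even-spacing grid", {
  # engineered pool: 10 loci at known positions, controllable frequencies
  pos <- c(5, 15, 28, 40, 52, 61, 77, 83, 91, 99)
  map <- new("GenomeMap", chrom = rep(1L, 10), posCM = pos,
             role = rep("candidate", 10), chromLengthsCM = 100)
  nInd <- 20
  hap <- matrix(as.raw(0), 10, 2 * nInd)
  hap[, seq_len(nInd)] <- as.raw(1) # every locus at frequency 0.5
  pool <- new("HaplotypePool", map = map, haplotypes = hap)
  sel <- selectSegregatingLoci(pool, nMarkers = 4, nQtl = 3, seed = 9)
  mk <- genomeMap(sel)@posCM[markerLoci(genomeMap(sel))]
  # brute-force oracle: greedy nearest eligible locus per equidistant target
  targets <- (1:4 - 0.5) / 4 * 100
  used <- logical(10); expect_mk <- numeric(4)
  for (i in 1:4) {
    d <- abs(pos - targets[i]); d[used] <- Inf
    j <- which.min(d); used[j] <- TRUE; expect_mk[i] <- pos[j]
  }
  expect_equal(sort(mk), sort(expect_mk))
  expect_length(qtlLoci(genomeMap(sel)), 3)
  expect_length(intersect(markerLoci(genomeMap(sel)),
                          qtlLoci(genomeMap(sel))), 0)
})

test_that("loci outside the MAF threshold are excluded and shortfalls error", {
  map <- new("GenomeMap", chrom = rep(1L, 3), posCM = c(10, 50, 90),
             role = rep("candidate", 3), chromLengthsCM = 100)
  hap <- matrix(as.raw(0), 3, 40)
  hap[1, seq_len(20)] <- as.raw(1)           # freq 0.50, eligible
  hap[2, seq_len(38)] <- as.raw(1)           # freq 0.95, MAF 0.05 -> excluded
  hap[3, seq_len(16)] <- as.raw(1)           # freq 0.40, eligible
  pool <- new("HaplotypePool", map = map, haplotypes = hap)
  sel <- selectSegregatingLoci(pool, nMarkers = 2, nQtl = 0, mafMin = 0.1)
  expect_equal(genomeMap(sel)@posCM, c(10, 90))
  expect_error(selectSegregatingLoci(pool, nMarkers = 3, nQtl = 0),
               "only 2 loci segregate")
  # fully monomorphic pool
  hap0 <- matrix(as.raw(0), 3, 40)
  pool0 <- new("HaplotypePool", map = map, haplotypes = hap0)
  expect_error(selectSegregatingLoci(pool0, nMarkers = 1, nQtl = 1),
               "only 0 loci")
})

test_that("meiosis copies homozygous parents and respects crossover model", {
  map <- uniformGenomeMap(1, 100, 500)
  hp <- matrix(as.raw(rbinom(500, 1, 0.5)), 500, 2)
  hp[, 2] <- hp[, 1] # homozygous parent
  set.seed(2)
  g <- meiosis(hp, map, mutationRate = 0)
  expect_identical(g, as.vector(hp[, 1]))
  # crossover count: parent heterozygous everywhere, transitions = crossovers
  hp2 <- matrix(as.raw(0), 500, 2)
  hp2[, 2] <- as.raw(1)
  set.seed(3)
  nG <- 20000
  gm <- metaGSim:::.dropGametes(hp2, rep(1L, nG), map, 0)
  trans <- colSums(matrix(as.integer(gm[-1, ] != gm[-500, ]), 499))
  se <- sd(trans) / sqrt(nG)
  expect_lt(abs(mean(trans) - 1.0), 3 * se + 0.01) # 1 Morgan chromosome
})

test_that("recurrent mutation flips alleles at the requested rate", {
  map <- uniformGenomeMap(1, 0, 1)
  hp <- matrix(as.raw(0), 1, 2)
  set.seed(4)
  gm <- metaGSim:::.dropGametes(hp, rep(1L, 100000), map, 0.5)
  frac <- mean(as.integer(gm))
  se <- sqrt(0.25 / 100000)
  expect_lt(abs(frac - 0.5), 3 * se)
})

test_that("gene dropping conserves founder alleles without mutation", {
  # 3-generation toy: every offspring allele must occur in its parent
  map <- uniformGenomeMap(2, 60, 100)
  set.seed(8)
  pool <- new("HaplotypePool", map = map,
              haplotypes = matrix(as.raw(rbinom(100 * 24, 1, 0.5)), 100, 24))
  pop <- expandPopulation(pool, 4, 8, 2, 3, mutationRate = 0, seed = 5)
  ped <- pedigree(pop)
  for (i in which(ped$sire > 0)) {
    hpS <- haplotypePair(pop, ped$sire[i])
    hpD <- haplotypePair(pop, ped$dam[i])
    hp <- haplotypePair(pop, i)
    expect_true(all(hp[, 1] == hpS[, 1] | hp[, 1] == hpS[, 2]))
    expect_true(all(hp[, 2] == hpD[, 1] | hp[, 2] == hpD[, 2]))
  }
})
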