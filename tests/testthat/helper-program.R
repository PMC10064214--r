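# Shared small simulation fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# a miniature full programme: same structure as the desk preset, scaled for
# unit tests (seconds per run)
tinyPreset <- function() {
  p <- deskPreset()
  p$name <- "tiny"
  p$genome <- list(nChrom = 2L, chromLengthCM = 50, nPoolLoci = 1200L,
                   nMarkers = 300L, nQtl = 60L, mafMin = 0.1,
                   mutationRate = 2.5e-5)
  p$history <- list(nGenPhase1 = 30L, sizePhase1 = 80L, nGenPhase2 = 10L,
                    sizeEnd = 100L)
  p$expansion <- list(nFounderMales = 20L, nFounderFemales = 20L,
                      nGenerations = 4L, offspringPerDam = 5L, maxSize = 400L)
  p$breedFormation <- list(nBreeds = 5L, malesPerBreed = 20L,
                           femalesPerBreed = 20L, nGenerations = 8L,
                           offspringPerDam = 2L)
  scale <- c(A = 11, B = 8, C = 7, D = 6, E = 5)
  fem <- c(A = 90, B = 55, C = 60, D = 30, E = 25)
  for (i in seq_along(p$breeds)) {
    nm <- p$breeds[[i]]$name
    p$breeds[[i]]$nMales0 <- as.integer(scale[[nm]])
    p$breeds[[i]]$nFemales0 <- as.integer(fem[[nm]])
  }
  p$step4$nGenerations <- 8L
  p$genotyping <- list(budget = 60L, minGeneration = 3L,
                       minProgenySires = 3L)
  p
}

tinyProgram <- function(seed = 11, selection = "ebv") {
  key <- paste0("prog_", seed, "_", selection)
  if (is.null(.fixtures[[key]])) {
    p <- tinyPreset()
    p$step4$selection <- selection
    .fixtures[[key]] <- suppressMessages(simulateProgram(p, seed = seed))
  }
  .fixtures[[key]]
}

# a synthetic evaluation-population skeleton for scenario tests: pedigree
# fields set directly, haplotypes all zero (never used by scenario sampling)
syntheticPopulation <- function(nPerGen = 40, nGen = 10, seed = 3) {
  set.seed(seed)
  n <- nPerGen * (nGen + 1)
  gen <- rep(0:nGen, each = nPerGen)
  sex <- rep(c("M", "F"), length.out = n)
  breed <- rep(LETTERS[1:5], length.out = n)
  sire <- dam <- integer(n)
  nProg <- integer(n)
  for (i in which(gen > 0)) {
    prev <- which(gen == gen[i] - 1)
    s <- sample(prev[sex[prev] == "M"], 1)
    d <- sample(prev[sex[prev] == "F"], 1)
    sire[i] <- s; dam[i] <- d
    nProg[s] <- nProg[s] + 1L; nProg[d] <- nProg[d] + 1L
  }
  ped <- data.frame(id = seq_len(n), sire = sire, dam = dam, sex = sex,
                    breed = breed, generation = gen, step = 4L,
                    nProgeny = nProg)
  map <- uniformGenomeMap(1, 10, 5)
  new("Population", pedigree = ped,
      haplotypes = matrix(as.raw(0), 5, 2 * n), map = map)
}
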