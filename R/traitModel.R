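#' Sample additive QTL allele-substitution effects
#'
#' Effect magnitudes are gamma distributed; each effect receives a random
#' sign with equal probability (symmetrized effects). Effects are typically
#' rescaled afterwards so that the true-breeding-value variance of a
#' reference cohort matches the additive variance; see [traitArchitecture()].
#'
#' @param nQtl number of QTL.
#' @param shape gamma shape parameter of the magnitudes.
#' @param scale gamma scale parameter.
#' @param seed optional integer seed.
#' @return numeric vector of signed effects.
#' @export
sampleQtlEffects <- function(nQtl, shape = 0.4, scale = 1, seed = NULL) {
  stopifnot(nQtl > 0)
  if (!is.null(seed)) set.seed(seed)
  mag <- rgamma(nQtl, shape = shape, scale = scale)
  sgn <- ifelse(runif(nQtl) < 0.5, -1, 1)
  mag * sgn
}

# TBV from a raw haplotype buffer (loci x 2n), for the given animal columns
.tbvFromHap <- function(hap, qtl, beta, individuals) {
  d <- .dosagesFromHaps(hap, qtl, individuals)
  as.numeric(d %*% beta)
}

#' Build a trait architecture calibrated on a reference cohort
#'
#' Samples signed gamma effects for the QTL of the population's genome map
#' and rescales them so that the variance of true breeding values among the
#' reference individuals equals \code{h2 * varP} exactly. Residual variance
#' is \code{varP - h2 * varP}.
#'
#' @param pop a [Population-class] (or [HaplotypePool-class]) whose map
#'   carries QTL roles.
#' @param referenceIndividuals indices of the cohort used for calibration
#'   (typically the selected-breeding base generation).
#' @param h2 narrow-sense heritability.
#' @param varP phenotypic variance.
#' @param shape gamma shape of effect magnitudes.
#' @param mu overall phenotypic mean.
#' @param sexEffects named numeric (M, F) additive fixed sex effects.
#' @param seed optional integer seed.
#' @return a [TraitArchitecture-class].
#' @export
traitArchitecture <- function(pop, referenceIndividuals, h2 = 0.3, varP = 1,
                              shape = 0.4, mu = 0,
                              sexEffects = c(M = 0.25, F = -0.25),
                              seed = NULL) {
  map <- genomeMap(pop)
  qtl <- qtlLoci(map)
  if (length(qtl) == 0) stop("genome map has no QTL loci")
  beta <- sampleQtlEffects(length(qtl), shape = shape, seed = seed)
  varA <- h2 * varP
  hap <- if (is(pop, "Population")) pop@haplotypes else pop@haplotypes
  tbv <- .tbvFromHap(hap, qtl, beta, referenceIndividuals)
  v <- var(tbv)
  if (v <= 0) stop("reference cohort has zero genetic variance at the QTL")
  beta <- beta * sqrt(varA / v)
  new("TraitArchitecture", qtl = as.integer(qtl), beta = beta, h2 = h2,
      varP = varP, varA = varA, varE = varP - varA, mu = mu,
      sexEffects = sexEffects)
}

#' True breeding values
#'
#' Sum over QTL of the additive effect times the allele-1 dosage (0, 1 or 2).
#'
#' @param pop a [Population-class] or [HaplotypePool-class].
#' @param arch a [TraitArchitecture-class].
#' @param individuals indices (default: all).
#' @return numeric vector of TBVs.
#' @export
trueBreedingValues <- function(pop, arch, individuals = NULL) {
  if (is.null(individuals)) individuals <- seq_len(nIndividuals(pop))
  .tbvFromHap(pop@haplotypes, arch@qtl, arch@beta, individuals)
}

# phenotypes for the given animal rows of a pedigree + haplotype buffer
.phenotypesFromBuffers <- function(hap, ped, ids, arch) {
  tbv <- .tbvFromHap(hap, arch@qtl, arch@beta, ids)
  sex <- ped$sex[ids]
  y <- arch@mu + arch@sexEffects[sex] + tbv +
    rnorm(length(ids), sd = sqrt(arch@varE))
  data.frame(id = ids, sex = sex, breed = ped$breed[ids],
             generation = ped$generation[ids], tbv = tbv, y = as.numeric(y))
}

#' Simulate phenotypes
#'
#' Phenotype = mean + sex effect + true breeding value + normal residual with
#' variance \code{varE}. Breed fixed effects are zero by construction: breed
#' differences arise genetically through drift and selection.
#'
#' @param pop a [Population-class].
#' @param arch a [TraitArchitecture-class].
#' @param individuals indices (default: all).
#' @param seed optional integer seed.
#' @return data.frame with columns id, sex, breed, generation, tbv, y.
#' @export
simulatePhenotypes <- function(pop, arch, individuals = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(individuals)) individuals <- seq_len(nIndividuals(pop))
  .phenotypesFromBuffers(pop@haplotypes, pop@pedigree, individuals, arch)
}
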