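#' @import methods
#' @importFrom stats rnorm runif rbinom rgamma var cor sd setNames
#' @importFrom utils head tail write.csv read.csv modifyList
#' @useDynLib metaGSim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' GenomeMap: chromosome and locus layout
#'
#' Describes a simulated genome: chromosome genetic lengths (cM) and, per
#' locus, its chromosome, genetic position (cM) and role. Loci start out in
#' the \code{"candidate"} pool; [selectSegregatingLoci()] promotes a subset to
#' \code{"marker"} (evenly spaced) and \code{"qtl"} (random) roles. Marker and
#' QTL sets are disjoint by construction.
#'
#' @slot chrom integer vector, chromosome index per locus (1-based).
#' @slot posCM numeric vector, genetic position per locus in cM, strictly
#'   increasing within chromosome.
#' @slot role character vector, one of \code{"candidate"}, \code{"marker"},
#'   \code{"qtl"} per locus.
#' @slot chromLengthsCM numeric vector of per-chromosome lengths in cM.
#' @export
setClass("GenomeMap",
  representation(chrom = "integer", posCM = "numeric", role = "character",
                 chromLengthsCM = "numeric"))

setValidity("GenomeMap", function(object) {
  L <- length(object@chrom)
  if (length(object@posCM) != L || length(object@role) != L)
    return("chrom, posCM and role must have equal length")
  if (!all(object@role %in% c("candidate", "marker", "qtl")))
    return("role must be candidate, marker or qtl")
  nc <- length(object@chromLengthsCM)
  if (L > 0 && (min(object@chrom) < 1 || max(object@chrom) > nc))
    return("chromosome indices out of range")
  for (c in unique(object@chrom)) {
    p <- object@posCM[object@chrom == c]
    # strictly increasing, except on a zero-length (no-recombination) chromosome
    if (object@chromLengthsCM[c] > 0 && any(diff(p) <= 0))
      return("positions must be strictly increasing within chromosome")
    if (any(diff(p) < 0))
      return("positions must be non-decreasing within chromosome")
    if (any(p < 0) || any(p > object@chromLengthsCM[c]))
      return("locus position outside chromosome length")
  }
  if (is.unsorted(object@chrom)) return("loci must be ordered by chromosome")
  TRUE
})

#' HaplotypePool: a cohort of haplotypes over a GenomeMap
#'
#' Carrier for the haplotypes of one (unpedigreed) cohort, e.g. the final
#' generation of the historical population. Haplotypes are stored as a raw
#' 0/1 matrix with loci in rows and \code{2 * nIndividuals} columns; columns
#' \code{2i - 1} and \code{2i} are the two haplotypes of individual \code{i}.
#'
#' @slot map a [GenomeMap-class].
#' @slot haplotypes raw matrix, loci x (2 * individuals), values 0/1.
#' @export
setClass("HaplotypePool",
  representation(map = "GenomeMap", haplotypes = "matrix"))

setValidity("HaplotypePool", function(object) {
  if (!is.raw(object@haplotypes)) return("haplotypes must be a raw matrix")
  if (nrow(object@haplotypes) != length(object@map@chrom))
    return("haplotype rows must match number of loci")
  if (ncol(object@haplotypes) %% 2 != 0)
    return("haplotype columns must come in pairs")
  TRUE
})

#' Population: pedigree plus per-individual haplotypes
#'
#' The central container for simulated populations. The pedigree is a
#' data.frame with one row per individual, topologically ordered (parents
#' before offspring) and with \code{id} equal to the row number. Missing
#' parents are coded 0; after [assignMetafounders()] the missing parents of
#' step-4 base animals are replaced by negative metafounder ids listed in the
#' \code{metafounders} slot.
#'
#' @slot pedigree data.frame with columns \code{id}, \code{sire}, \code{dam},
#'   \code{sex} ("M"/"F"), \code{breed} (character or NA), \code{generation},
#'   \code{step} (2 expansion, 3 breed formation, 4 selected breeding),
#'   \code{nProgeny}.
#' @slot haplotypes raw matrix, loci x (2 * nrow(pedigree)).
#' @slot map a [GenomeMap-class].
#' @slot metafounders data.frame with columns \code{id} (negative) and
#'   \code{breed}; zero rows until metafounders are assigned.
#' @export
setClass("Population",
  representation(pedigree = "data.frame", haplotypes = "matrix",
                 map = "GenomeMap", metafounders = "data.frame"),
  prototype(metafounders = data.frame(id = integer(), breed = character())))

setValidity("Population", function(object) {
  ped <- object@pedigree
  need <- c("id", "sire", "dam", "sex", "breed", "generation", "step", "nProgeny")
  if (!all(need %in% names(ped))) return("pedigree is missing required columns")
  n <- nrow(ped)
  if (n > 0 && !identical(ped$id, seq_len(n))) return("ids must be dense 1..n")
  known <- ped$sire > 0
  if (any(ped$sire[known] >= ped$id[known]) ||
      any(ped$dam[ped$dam > 0] >= ped$id[ped$dam > 0]))
    return("pedigree must be topologically ordered (parents precede offspring)")
  if (any(ped$sex[ped$sire[known]] != "M")) return("sires must be male")
  kd <- ped$dam > 0
  if (any(ped$sex[ped$dam[kd]] != "F")) return("dams must be female")
  if (!is.raw(object@haplotypes)) return("haplotypes must be a raw matrix")
  if (ncol(object@haplotypes) != 2 * n) return("haplotype columns must be 2 * n")
  if (nrow(object@haplotypes) != length(object@map@chrom))
    return("haplotype rows must match map loci")
  mf <- object@metafounders
  if (nrow(mf) > 0 && any(mf$id >= 0)) return("metafounder ids must be negative")
  neg <- ped$sire < 0 | ped$dam < 0
  if (any(neg) && nrow(mf) == 0) return("negative parent ids but no metafounder table")
  TRUE
})

#' TraitArchitecture: QTL effects and variance components
#'
#' Additive single-trait architecture: QTL loci, additive allele substitution
#' effects (gamma-distributed magnitudes, random sign, rescaled so that the
#' true-breeding-value variance in the reference cohort equals the additive
#' variance), and the variance decomposition implied by the heritability.
#'
#' @slot qtl integer vector of QTL locus indices into the [GenomeMap-class].
#' @slot beta numeric vector of additive effects, one per QTL.
#' @slot h2 numeric, narrow-sense heritability.
#' @slot varP numeric, phenotypic variance.
#' @slot varA numeric, additive genetic variance (= h2 * varP).
#' @slot varE numeric, residual variance (= varP - varA).
#' @slot mu numeric, overall phenotypic mean.
#' @slot sexEffects named numeric of length 2 (M, F) additive fixed effects.
#' @export
setClass("TraitArchitecture",
  representation(qtl = "integer", beta = "numeric", h2 = "numeric",
                 varP = "numeric", varA = "numeric", varE = "numeric",
                 mu = "numeric", sexEffects = "numeric"))

setValidity("TraitArchitecture", function(object) {
  if (length(object@qtl) != length(object@beta)) return("qtl and beta lengths differ")
  if (!all(is.finite(object@beta))) return("beta must be finite")
  if (abs(object@varA - object@h2 * object@varP) > 1e-8) return("varA must equal h2 * varP")
  if (abs(object@varE - (object@varP - object@varA)) > 1e-8)
    return("varE must equal varP - varA")
  if (!all(c("M", "F") %in% names(object@sexEffects)))
    return("sexEffects must be named M and F")
  TRUE
})

#' GenotypingScenario: a selective-genotyping design
#'
#' Defines which animals receive genotypes. A scenario has a total budget and
#' a set of strata, each a pair of an eligibility rule and a target count
#' drawn uniformly at random without replacement from the pooled multi-breed
#' population. Stratum types: \code{"none"} (reference scenario, budget 0),
#' \code{"candidate_male"}, \code{"candidate_both"} (latest-generation
#' selection candidates), \code{"ancestral_sire"}, \code{"ancestral_dam"}
#' (parents from the genotyping-eligible ancestral generations). Ancestral
#' sire strata may require a minimum progeny count.
#'
#' @slot name character scenario label.
#' @slot budget integer, total number of genotyped animals.
#' @slot strata data.frame with columns \code{type}, \code{count},
#'   \code{minProgeny}.
#' @export
setClass("GenotypingScenario",
  representation(name = "character", budget = "integer", strata = "data.frame"))

setValidity("GenotypingScenario", function(object) {
  st <- object@strata
  if (nrow(st) > 0 && sum(st$count) != object@budget)
    return("stratum counts must sum to the budget")
  ok <- c("none", "candidate_male", "candidate_both", "ancestral_sire", "ancestral_dam")
  if (!all(st$type %in% ok)) return("unknown stratum type")
  TRUE
})

#' PhenotypingCase: which animals carry phenotypic records
#'
#' A phenotyping case is a recording fraction (0.2, 0.6 or 1.0) applied to one
#' or both sexes; a sex-limited trait is expressed by restricting the
#' recorded sex. Sampling is uniform without replacement so realized counts
#' are exact.
#'
#' @slot name character label such as "100 MF" or "20 F".
#' @slot fraction numeric recording fraction in (0, 1].
#' @slot sexes character, "MF", "M" or "F".
#' @export
setClass("PhenotypingCase",
  representation(name = "character", fraction = "numeric", sexes = "character"))

setValidity("PhenotypingCase", function(object) {
  if (!object@sexes %in% c("MF", "M", "F")) return("sexes must be MF, M or F")
  if (object@fraction <= 0 || object@fraction > 1) return("fraction must be in (0, 1]")
  TRUE
})

# ---- show methods -----------------------------------------------------------

setMethod("show", "GenomeMap", function(object) {
  cat("GenomeMap:", length(object@chromLengthsCM), "chromosomes,",
      sprintf("%.0f cM,", sum(object@chromLengthsCM)),
      length(object@chrom), "loci (",
      sum(object@role == "marker"), "markers,",
      sum(object@role == "qtl"), "QTL )\n")
})

setMethod("show", "HaplotypePool", function(object) {
  cat("HaplotypePool:", ncol(object@haplotypes) / 2, "individuals,",
      nrow(object@haplotypes), "loci\n")
})

setMethod("show", "Population", function(object) {
  ped <- object@pedigree
  cat("Population:", nrow(ped), "individuals")
  if (nrow(ped) > 0) {
    br <- unique(ped$breed[!is.na(ped$breed)])
    cat(",", length(br), "breeds, steps", paste(sort(unique(ped$step)), collapse = "/"))
  }
  if (nrow(object@metafounders) > 0)
    cat(",", nrow(object@metafounders), "metafounders")
  cat("\n")
})

setMethod("show", "TraitArchitecture", function(object) {
  cat("TraitArchitecture:", length(object@qtl), "QTL, h2 =", object@h2,
      ", varP =", object@varP, "\n")
})

setMethod("show", "GenotypingScenario", function(object) {
  cat("GenotypingScenario", object@name, ": budget", object@budget, "\n")
  if (nrow(object@strata) > 0)
    for (i in seq_len(nrow(object@strata)))
      cat("  ", object@strata$type[i], object@strata$count[i],
          if (object@strata$minProgeny[i] > 0)
            paste0("(>= ", object@strata$minProgeny[i], " progeny)") else "", "\n")
})

setMethod("show", "PhenotypingCase", function(object) {
  cat("PhenotypingCase", object@name, ": fraction", object@fraction,
      "of sex(es)", object@sexes, "\n")
})
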