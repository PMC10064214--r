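#' @name accessors
#' @title Accessors for metaGSim classes
#' @description Small accessor generics; slots should not be reached into
#'   directly.
#' @param x an object.
#' @return The requested component.
NULL

#' @rdname accessors
#' @export
setGeneric("nLoci", function(x) standardGeneric("nLoci"))
#' @rdname accessors
#' @export
setMethod("nLoci", "GenomeMap", function(x) length(x@chrom))
#' @rdname accessors
#' @export
setMethod("nLoci", "HaplotypePool", function(x) nrow(x@haplotypes))
#' @rdname accessors
#' @export
setMethod("nLoci", "Population", function(x) nrow(x@haplotypes))

#' @rdname accessors
#' @export
setGeneric("nChromosomes", function(x) standardGeneric("nChromosomes"))
#' @rdname accessors
#' @export
setMethod("nChromosomes", "GenomeMap", function(x) length(x@chromLengthsCM))

#' @rdname accessors
#' @export
setGeneric("chromLengthsCM", function(x) standardGeneric("chromLengthsCM"))
#' @rdname accessors
#' @export
setMethod("chromLengthsCM", "GenomeMap", function(x) x@chromLengthsCM)

#' @rdname accessors
#' @export
setGeneric("locusPositions", function(x) standardGeneric("locusPositions"))
#' @rdname accessors
#' @export
setMethod("locusPositions", "GenomeMap", function(x)
  data.frame(chrom = x@chrom, posCM = x@posCM, role = x@role))

#' @rdname accessors
#' @export
setGeneric("markerLoci", function(x) standardGeneric("markerLoci"))
#' @rdname accessors
#' @export
setMethod("markerLoci", "GenomeMap", function(x) which(x@role == "marker"))

#' @rdname accessors
#' @export
setGeneric("qtlLoci", function(x) standardGeneric("qtlLoci"))
#' @rdname accessors
#' @export
setMethod("qtlLoci", "GenomeMap", function(x) which(x@role == "qtl"))

#' @rdname accessors
#' @export
setGeneric("genomeMap", function(x) standardGeneric("genomeMap"))
#' @rdname accessors
#' @export
setMethod("genomeMap", "HaplotypePool", function(x) x@map)
#' @rdname accessors
#' @export
setMethod("genomeMap", "Population", function(x) x@map)

#' @rdname accessors
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))
#' @rdname accessors
#' @export
setMethod("nIndividuals", "HaplotypePool", function(x) ncol(x@haplotypes) / 2L)
#' @rdname accessors
#' @export
setMethod("nIndividuals", "Population", function(x) nrow(x@pedigree))

#' @rdname accessors
#' @export
setGeneric("pedigree", function(x) standardGeneric("pedigree"))
#' @rdname accessors
#' @export
setMethod("pedigree", "Population", function(x) x@pedigree)

#' @rdname accessors
#' @export
setGeneric("metafounders", function(x) standardGeneric("metafounders"))
#' @rdname accessors
#' @export
setMethod("metafounders", "Population", function(x) x@metafounders)

#' @rdname accessors
#' @export
setGeneric("qtlEffects", function(x) standardGeneric("qtlEffects"))
#' @rdname accessors
#' @export
setMethod("qtlEffects", "TraitArchitecture", function(x)
  setNames(x@beta, x@qtl))

#' Allele dosages at selected loci
#'
#' Counts of the "1" allele (0, 1 or 2) per individual at the requested loci.
#'
#' @param x a [Population-class] or [HaplotypePool-class].
#' @param loci integer locus indices (default: all loci).
#' @param individuals integer indices of individuals (default: all).
#' @return integer matrix, individuals x loci.
#' @export
setGeneric("dosages", function(x, loci = NULL, individuals = NULL)
  standardGeneric("dosages"))

.dosagesFromHaps <- function(hap, loci, individuals) {
  if (is.null(loci)) loci <- seq_len(nrow(hap))
  if (is.null(individuals)) individuals <- seq_len(ncol(hap) / 2L)
  a <- hap[loci, 2L * individuals - 1L, drop = FALSE]
  b <- hap[loci, 2L * individuals, drop = FALSE]
  d <- matrix(as.integer(a), nrow = length(loci)) +
       matrix(as.integer(b), nrow = length(loci))
  dimnames(d) <- NULL
  t(d)
}

#' @rdname dosages
#' @export
setMethod("dosages", "Population", function(x, loci = NULL, individuals = NULL)
  .dosagesFromHaps(x@haplotypes, loci, individuals))
#' @rdname dosages
#' @export
setMethod("dosages", "HaplotypePool", function(x, loci = NULL, individuals = NULL)
  .dosagesFromHaps(x@haplotypes, loci, individuals))

#' Haplotype pair of one individual
#'
#' @param x a [Population-class] or [HaplotypePool-class].
#' @param individual integer index.
#' @return raw matrix, loci x 2 (maternal, paternal haplotype).
#' @export
setGeneric("haplotypePair", function(x, individual)
  standardGeneric("haplotypePair"))
#' @rdname haplotypePair
#' @export
setMethod("haplotypePair", "Population", function(x, individual)
  x@haplotypes[, c(2L * individual - 1L, 2L * individual), drop = FALSE])
#' @rdname haplotypePair
#' @export
setMethod("haplotypePair", "HaplotypePool", function(x, individual)
  x@haplotypes[, c(2L * individual - 1L, 2L * individual), drop = FALSE])

#' Allele frequencies (frequency of the "1" allele)
#'
#' @param x a [Population-class] or [HaplotypePool-class].
#' @param loci integer locus indices (default all).
#' @param individuals integer individual indices (default all).
#' @return numeric vector of per-locus allele-1 frequencies.
#' @export
setGeneric("alleleFrequencies", function(x, loci = NULL, individuals = NULL)
  standardGeneric("alleleFrequencies"))

.freqFromHaps <- function(hap, loci, individuals) {
  if (is.null(loci)) loci <- seq_len(nrow(hap))
  if (is.null(individuals)) individuals <- seq_len(ncol(hap) / 2L)
  cols <- sort(c(2L * individuals - 1L, 2L * individuals))
  h <- hap[loci, cols, drop = FALSE]
  rowMeans(matrix(as.integer(h), nrow = length(loci)))
}

#' @rdname alleleFrequencies
#' @export
setMethod("alleleFrequencies", "Population",
  function(x, loci = NULL, individuals = NULL)
    .freqFromHaps(x@haplotypes, loci, individuals))
#' @rdname alleleFrequencies
#' @export
setMethod("alleleFrequencies", "HaplotypePool",
  function(x, loci = NULL, individuals = NULL)
    .freqFromHaps(x@haplotypes, loci, individuals))
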