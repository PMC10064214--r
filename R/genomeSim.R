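#' Construct a genome map with an evenly spaced candidate-locus pool
#'
#' Builds a [GenomeMap-class] whose candidate loci are laid out evenly along
#' the genome, with per-chromosome locus counts proportional to chromosome
#' length. All loci start in the \code{"candidate"} role; marker and QTL
#' roles are assigned later from the segregating loci
#' (see [selectSegregatingLoci()]).
#'
#' @param nChrom number of chromosome pairs.
#' @param chromLengthCM genetic length per chromosome in cM (scalar recycled,
#'   or vector of length \code{nChrom}).
#' @param nLoci total number of candidate loci in the pool.
#' @return a [GenomeMap-class].
#' @examples
#' uniformGenomeMap(5, 80, 1000)
#' @export
uniformGenomeMap <- function(nChrom, chromLengthCM, nLoci) {
  len <- rep_len(chromLengthCM, nChrom)
  if (any(len < 0)) stop("chromosome lengths must be non-negative")
  total <- sum(len)
  # apportion loci to chromosomes proportionally to length (largest remainder)
  if (total > 0) {
    raw <- nLoci * len / total
  } else {
    raw <- rep(nLoci / nChrom, nChrom)
  }
  cnt <- floor(raw)
  rem <- nLoci - sum(cnt)
  if (rem > 0) {
    extra <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[extra] <- cnt[extra] + 1
  }
  chrom <- rep(seq_len(nChrom), cnt)
  pos <- unlist(lapply(seq_len(nChrom), function(c) {
    if (cnt[c] == 0) return(numeric())
    (seq_len(cnt[c]) - 0.5) / cnt[c] * len[c]
  }), use.names = FALSE)
  new("GenomeMap", chrom = as.integer(chrom), posCM = as.numeric(pos),
      role = rep("candidate", length(chrom)), chromLengthsCM = as.numeric(len))
}

# per-chromosome index ranges and Morgan lengths/positions
.chrRanges <- function(map) {
  nC <- nChromosomes(map)
  start <- integer(nC); end <- integer(nC)
  for (c in seq_len(nC)) {
    idx <- which(map@chrom == c)
    start[c] <- if (length(idx)) min(idx) else 1L
    end[c] <- if (length(idx)) max(idx) else 0L
  }
  list(start = start, end = end, lenM = map@chromLengthsCM / 100,
       posM = map@posCM / 100)
}

# drop one gamete per entry of `parents` (indices into animal columns of hap)
.dropGametes <- function(hap, parents, map, mutationRate) {
  r <- .chrRanges(map)
  cpp_drop_gametes(hap, as.integer(parents), r$start, r$end, r$posM, r$lenM,
                   mutationRate)
}

#' Simulate the historical population generating linkage disequilibrium
#'
#' Forward-in-time neutral history: random union of gametes each generation
#' (two distinct parents per offspring, no selection, no structure), with a
#' constant population size during phase 1 and a linear interpolation between
#' the phase-1 size and \code{sizeEnd} during phase 2. Recurrent bidirectional
#' mutation keeps loci polymorphic. Returns the haplotypes of the final
#' historical generation, from which markers and QTL are drawn.
#'
#' @param map a [GenomeMap-class] (the candidate-locus pool).
#' @param nGenPhase1,sizePhase1 length and constant size of phase 1.
#' @param nGenPhase2,sizeEnd length of phase 2 and its final size; the size
#'   path moves linearly from \code{sizePhase1} to \code{sizeEnd}. A shrinking
#'   phase 2 (bottleneck) is expressed with \code{sizeEnd < sizePhase1}.
#' @param mutationRate per-locus recurrent mutation probability per meiosis.
#' @param seed integer seed; the run is fully determined by it.
#' @param initFreq initial allele-1 frequency (scalar or per-locus vector);
#'   founder alleles are drawn independently.
#' @param requireSegregating error (rather than warn) when no locus segregates
#'   in the final generation.
#' @return a [HaplotypePool-class] for the final historical generation.
#' @export
simulateHistorical <- function(map, nGenPhase1, sizePhase1, nGenPhase2,
                               sizeEnd, mutationRate = 2.5e-5, seed = NULL,
                               initFreq = 0.5, requireSegregating = FALSE) {
  stopifnot(sizePhase1 >= 2, sizeEnd >= 2)
  if (!is.null(seed)) set.seed(seed)
  L <- nLoci(map)
  p0 <- rep_len(initFreq, L)
  hap <- matrix(as.raw(rbinom(L * 2L * sizePhase1, 1L, p0)),
                nrow = L, ncol = 2L * sizePhase1)
  sizes <- c(rep(sizePhase1, nGenPhase1),
             if (nGenPhase2 > 0)
               round(sizePhase1 + (sizeEnd - sizePhase1) *
                       seq_len(nGenPhase2) / nGenPhase2))
  for (g in seq_along(sizes)) {
    nPrev <- ncol(hap) / 2L
    nNow <- sizes[g]
    # two distinct parents per offspring, random union of their gametes
    p1 <- sample.int(nPrev, nNow, replace = TRUE)
    p2 <- sample.int(nPrev - 1L, nNow, replace = TRUE)
    p2 <- ifelse(p2 >= p1, p2 + 1L, p2)
    g1 <- .dropGametes(hap, p1, map, mutationRate)
    g2 <- .dropGametes(hap, p2, map, mutationRate)
    hap <- matrix(as.raw(0), nrow = L, ncol = 2L * nNow)
    hap[, seq(1L, 2L * nNow, by = 2L)] <- g1
    hap[, seq(2L, 2L * nNow, by = 2L)] <- g2
  }
  pool <- new("HaplotypePool", map = map, haplotypes = hap)
  f <- alleleFrequencies(pool)
  if (all(f <= 0 | f >= 1)) {
    msg <- "no segregating loci after history; increase the mutation rate or initial polymorphism"
    if (requireSegregating) stop(msg) else warning(msg)
  }
  pool
}

#' Assign marker and QTL roles among segregating loci
#'
#' From the final historical generation, loci with minor allele frequency
#' above \code{mafMin} are eligible. Markers are chosen evenly spaced: the
#' eligible locus nearest to each of \code{nMarkers} equidistant genomic
#' targets (each locus used at most once); QTL are then drawn uniformly at
#' random from the remaining eligible loci, so marker and QTL sets are
#' disjoint. The returned pool is restricted to the selected loci.
#'
#' @param pool a [HaplotypePool-class] from [simulateHistorical()].
#' @param nMarkers,nQtl number of markers and QTL to select.
#' @param mafMin minor-allele-frequency threshold (exclusive).
#' @param seed integer seed for the random QTL draw.
#' @return a [HaplotypePool-class] over the selected loci, whose
#'   [GenomeMap-class] carries \code{"marker"}/\code{"qtl"} roles.
#' @export
selectSegregatingLoci <- function(pool, nMarkers, nQtl, mafMin = 0.1,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  map <- genomeMap(pool)
  f <- alleleFrequencies(pool)
  maf <- pmin(f, 1 - f)
  eligible <- which(maf > mafMin)
  if (length(eligible) < nMarkers + nQtl)
    stop(sprintf(
      "only %d loci segregate with MAF > %g; %d needed (markers + QTL)",
      length(eligible), mafMin, nMarkers + nQtl))
  offs <- cumsum(c(0, map@chromLengthsCM))[map@chrom]
  gpos <- offs + map@posCM
  total <- sum(map@chromLengthsCM)
  targets <- (seq_len(nMarkers) - 0.5) / nMarkers * total
  epos <- gpos[eligible]
  used <- logical(length(eligible))
  markers <- integer(nMarkers)
  for (i in seq_len(nMarkers)) {
    d <- abs(epos - targets[i])
    d[used] <- Inf
    best <- which.min(d) # ties resolve to the lower index
    used[best] <- TRUE
    markers[i] <- eligible[best]
  }
  markers <- sort(markers)
  remaining <- eligible[!used]
  qtl <- sort(remaining[sample.int(length(remaining), nQtl)])
  keep <- sort(c(markers, qtl))
  role <- ifelse(keep %in% markers, "marker", "qtl")
  newMap <- new("GenomeMap", chrom = map@chrom[keep], posCM = map@posCM[keep],
                role = role, chromLengthsCM = map@chromLengthsCM)
  new("HaplotypePool", map = newMap,
      haplotypes = pool@haplotypes[keep, , drop = FALSE])
}

#' Simulate one meiosis
#'
#' Produces a single recombined gamete from a parent's haplotype pair:
#' crossovers per chromosome are Poisson with mean equal to the chromosome
#' length in Morgan, breakpoints uniform (Haldane, no interference), and
#' recurrent mutation flips each transmitted allele with probability
#' \code{mutationRate}.
#'
#' @param parentHaplotypes raw matrix, loci x 2 (the parent's haplotype pair).
#' @param map a [GenomeMap-class] matching the rows.
#' @param mutationRate per-locus mutation probability.
#' @return raw vector of length \code{nLoci(map)}.
#' @export
meiosis <- function(parentHaplotypes, map, mutationRate = 0) {
  stopifnot(is.raw(parentHaplotypes), ncol(parentHaplotypes) == 2,
            nrow(parentHaplotypes) == nLoci(map))
  as.vector(.dropGametes(parentHaplotypes, 1L, map, mutationRate))
}
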