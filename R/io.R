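#' Write and read a genome map as a plain-text map file
#'
#' Tab-separated columns: chromosome, locus id, position in cM, role.
#'
#' @param map a [GenomeMap-class].
#' @param path output file.
#' @export
writeGenomeMap <- function(map, path) {
  df <- data.frame(chrom = map@chrom, locus = seq_along(map@chrom),
                   posCM = map@posCM, role = map@role)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeGenomeMap
#' @param chromLengthsCM chromosome lengths; defaults to the maximum locus
#'   position per chromosome.
#' @export
readGenomeMap <- function(path, chromLengthsCM = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (is.null(chromLengthsCM))
    chromLengthsCM <- tapply(df$posCM, df$chrom, max)
  new("GenomeMap", chrom = as.integer(df$chrom), posCM = df$posCM,
      role = df$role, chromLengthsCM = as.numeric(chromLengthsCM))
}

#' Export a pedigree as CSV
#'
#' Columns id, sire, dam, sex, breed, generation (metafounder parents appear
#' as negative ids); the metafounder table is written as a sidecar CSV next
#' to the main file when metafounders are assigned.
#'
#' @param pop a [Population-class].
#' @param path output CSV path.
#' @export
writePedigree <- function(pop, path) {
  ped <- pedigree(pop)
  write.csv(ped[, c("id", "sire", "dam", "sex", "breed", "generation")],
            path, row.names = FALSE)
  if (nrow(metafounders(pop)) > 0)
    write.csv(metafounders(pop),
              sub("(\\.[^.]+)?$", "_metafounders.csv", path, perl = TRUE)[1],
              row.names = FALSE)
  invisible(path)
}

#' Export marker dosages as a whitespace-separated genotype file
#'
#' One row per animal: id followed by 0/1/2 allele dosages at the markers
#' (PLINK raw-like dialect without header metadata columns).
#'
#' @param pop a [Population-class].
#' @param individuals animal indices to export.
#' @param path output path.
#' @export
writeGenotypes <- function(pop, individuals, path) {
  M <- dosages(pop, loci = markerLoci(genomeMap(pop)),
               individuals = individuals)
  utils::write.table(cbind(id = individuals, M), path, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export phenotypes as CSV
#'
#' @param phenotypes phenotype data.frame (see [simulatePhenotypes()]).
#' @param observed optional ids carrying observed records; sets the
#'   \code{observed} flag column.
#' @param path output CSV path.
#' @export
writePhenotypes <- function(phenotypes, path, observed = NULL) {
  phenotypes$observed <- if (is.null(observed)) TRUE
    else phenotypes$id %in% observed
  write.csv(phenotypes, path, row.names = FALSE)
  invisible(path)
}

#' Export haplotypes as a plain 0/1 text matrix
#'
#' Loci in rows, two columns per individual.
#'
#' @param x a [Population-class] or [HaplotypePool-class].
#' @param path output path.
#' @export
writeHaplotypes <- function(x, path) {
  h <- matrix(as.integer(x@haplotypes), nrow = nrow(x@haplotypes))
  utils::write.table(h, path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
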