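#' Construct a genotyping scenario
#'
#' @param name scenario label.
#' @param strata data.frame with columns \code{type} (\code{"candidate_male"},
#'   \code{"candidate_both"}, \code{"ancestral_sire"},
#'   \code{"ancestral_dam"}), \code{count} and optionally \code{minProgeny}
#'   (minimum progeny number for ancestral-sire strata; 0 = any parent).
#' @return a [GenotypingScenario-class].
#' @export
genotypingScenario <- function(name, strata = NULL) {
  if (is.null(strata) || nrow(strata) == 0) {
    strata <- data.frame(type = character(), count = integer(),
                         minProgeny = integer())
  } else {
    if (is.null(strata$minProgeny)) strata$minProgeny <- 0L
    strata$count <- as.integer(strata$count)
    strata$minProgeny <- as.integer(strata$minProgeny)
  }
  new("GenotypingScenario", name = name,
      budget = as.integer(sum(strata$count)), strata = strata)
}

#' The five standard genotyping scenarios
#'
#' Scenario family for a total genotyping budget: a pedigree-only reference
#' (no genotypes) and four selective designs. With budget B: Sc1 genotypes
#' 100\% random male selection candidates of the latest generation; Sc2 40\%
#' ancestral sires with at least \code{minProgenySires} progeny plus 60\%
#' male candidates; Sc3 100\% candidates of both sexes (unrestricted random
#' draw, so the sexes split roughly evenly); Sc4 30\% ancestral sires, 30\%
#' ancestral dams and 40\% candidates of both sexes. At the full programme
#' scale (B = 5000) these are 5000; 2000 + 3000; 5000; and 1500 + 1500 +
#' 2000 animals respectively.
#'
#' @param budget total number of genotyped animals per genomic scenario.
#' @param minProgenySires progeny threshold applied to the ancestral-sire
#'   stratum of Sc2 only.
#' @return named list of five [GenotypingScenario-class] objects.
#' @export
standardScenarios <- function(budget = 5000, minProgenySires = 10) {
  f <- function(x) as.integer(round(budget * x))
  list(
    RefSc = genotypingScenario("RefSc"),
    Sc1 = genotypingScenario("Sc1", data.frame(
      type = "candidate_male", count = budget, minProgeny = 0L)),
    Sc2 = genotypingScenario("Sc2", data.frame(
      type = c("ancestral_sire", "candidate_male"),
      count = c(f(0.4), budget - f(0.4)),
      minProgeny = c(minProgenySires, 0L))),
    Sc3 = genotypingScenario("Sc3", data.frame(
      type = "candidate_both", count = budget, minProgeny = 0L)),
    Sc4 = genotypingScenario("Sc4", data.frame(
      type = c("ancestral_sire", "ancestral_dam", "candidate_both"),
      count = c(f(0.3), f(0.3), budget - 2L * f(0.3)),
      minProgeny = c(0L, 0L, 0L))))
}

#' Select the genotyped animals of a scenario
#'
#' Samples each stratum uniformly at random without replacement from the
#' pooled multi-breed population (per-breed counts are therefore
#' approximately proportional to breed sizes). Selection candidates are the
#' animals of the latest generation; ancestral animals are parents (progeny
#' count at least 1, or the stratum's \code{minProgeny}) born between
#' \code{minGeneration} and the generation before the candidates. Animals
#' below \code{minGeneration} are never genotyped.
#'
#' @param pop the evaluation [Population-class] (step-4 truncation).
#' @param scenario a [GenotypingScenario-class].
#' @param minGeneration first generation eligible for genotyping.
#' @param seed optional integer seed.
#' @return sorted integer vector of genotyped animal ids (empty for the
#'   reference scenario).
#' @export
selectGenotyped <- function(pop, scenario, minGeneration = 7, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  st <- scenario@strata
  if (nrow(st) == 0) return(integer())
  ped <- pedigree(pop)
  lastGen <- max(ped$generation)
  chosen <- integer()
  for (i in seq_len(nrow(st))) {
    type <- st$type[i]
    minProg <- max(1L, st$minProgeny[i])
    eligible <- switch(type,
      candidate_male = ped$id[ped$generation == lastGen & ped$sex == "M"],
      candidate_both = ped$id[ped$generation == lastGen],
      ancestral_sire = ped$id[ped$generation >= minGeneration &
                                ped$generation < lastGen & ped$sex == "M" &
                                ped$nProgeny >= minProg],
      ancestral_dam = ped$id[ped$generation >= minGeneration &
                               ped$generation < lastGen & ped$sex == "F" &
                               ped$nProgeny >= minProg],
      stop("unknown stratum type: ", type))
    eligible <- setdiff(eligible, chosen)
    if (length(eligible) < st$count[i])
      stop(sprintf(
        "scenario %s stratum '%s': %d eligible animals for a target of %d",
        scenario@name, type, length(eligible), st$count[i]))
    chosen <- c(chosen, sample(eligible, st$count[i]))
  }
  sort(chosen)
}

#' Construct a phenotyping case
#'
#' @param name label like \code{"60 MF"}, \code{"20 M"}, \code{"100 F"}: the
#'   recording percentage followed by the recorded sex(es).
#' @return a [PhenotypingCase-class].
#' @export
phenotypingCase <- function(name) {
  parts <- strsplit(trimws(name), "\\s+")[[1]]
  if (length(parts) != 2) stop("case name must be like '60 MF'")
  new("PhenotypingCase", name = paste(parts, collapse = " "),
      fraction = as.numeric(parts[1]) / 100, sexes = parts[2])
}

#' The nine standard phenotyping cases
#'
#' Recording fractions 100/60/20 percent crossed with both-sex, female-only
#' and male-only recording, in the reporting order 100 MF ... 20 M.
#'
#' @return named list of nine [PhenotypingCase-class] objects.
#' @export
standardCases <- function() {
  nm <- c("100 MF", "60 MF", "20 MF", "100 F", "60 F", "20 F",
          "100 M", "60 M", "20 M")
  setNames(lapply(nm, phenotypingCase), nm)
}

#' Select the phenotyped animals of a case
#'
#' Among animals of the recorded sex(es), an exact-count uniform random
#' subset (without replacement, count = round(fraction * eligible)) carries
#' observed phenotypes; animals of a non-recorded sex never do.
#'
#' @param pop the evaluation [Population-class].
#' @param case a [PhenotypingCase-class].
#' @param seed optional integer seed.
#' @return sorted integer vector of phenotyped animal ids.
#' @export
selectPhenotyped <- function(pop, case, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ped <- pedigree(pop)
  eligible <- if (case@sexes == "MF") ped$id else ped$id[ped$sex == case@sexes]
  if (case@fraction >= 1) return(sort(eligible))
  k <- as.integer(round(case@fraction * length(eligible)))
  sort(sample(eligible, k))
}
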