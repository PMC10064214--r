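#' BreedSpec: per-breed breeding-programme parameters
#'
#' Founding counts and per-generation replacement/growth rates of the
#' breeding males and females of one breed during the selected-breeding step.
#' Replacement is the fraction of breeding animals exiting (oldest first)
#' each generation; growth is the per-generation proportional increase of the
#' breeding-animal count (rounded to the nearest integer).
#'
#' @slot name breed label (e.g. "A").
#' @slot nMales0,nFemales0 founding numbers of breeding males and females.
#' @slot sireRepl,sireGrowth sire replacement and growth rate per generation.
#' @slot damRepl,damGrowth dam replacement and growth rate per generation.
#' @export
setClass("BreedSpec",
  representation(name = "character", nMales0 = "integer", nFemales0 = "integer",
                 sireRepl = "numeric", sireGrowth = "numeric",
                 damRepl = "numeric", damGrowth = "numeric"))

setValidity("BreedSpec", function(object) {
  if (object@nMales0 <= 0 || object@nFemales0 <= 0) return("founding counts must be > 0")
  for (r in c(object@sireRepl, object@damRepl))
    if (r <= 0 || r > 1) return("replacement rates must be in (0, 1]")
  if (object@sireGrowth < 0 || object@damGrowth < 0) return("growth rates must be >= 0")
  TRUE
})

#' @rdname BreedSpec-class
#' @param name,nMales0,nFemales0,sireRepl,sireGrowth,damRepl,damGrowth see slots.
#' @export
breedSpec <- function(name, nMales0, nFemales0, sireRepl, sireGrowth,
                      damRepl, damGrowth) {
  new("BreedSpec", name = name, nMales0 = as.integer(nMales0),
      nFemales0 = as.integer(nFemales0), sireRepl = sireRepl,
      sireGrowth = sireGrowth, damRepl = damRepl, damGrowth = damGrowth)
}

setMethod("show", "BreedSpec", function(object) {
  cat(sprintf("BreedSpec %s: %d sires (repl %.4f, growth %.4f), %d dams (repl %.2f, growth %.4f)\n",
              object@name, object@nMales0, object@sireRepl, object@sireGrowth,
              object@nFemales0, object@damRepl, object@damGrowth))
})

# balanced random sex assignment (exactly half each, randomized order);
# used in the unselected build-up steps where a run of same-sex draws in a
# small cohort would otherwise collapse a line
.assignSexes <- function(k) {
  v <- rep(c("M", "F"), k %/% 2)
  if (k %% 2 == 1) v <- c(v, c("M", "F")[sample.int(2, 1)])
  sample(v)
}

# empty pedigree skeleton
.pedSkeleton <- function(n) {
  data.frame(id = integer(n), sire = integer(n), dam = integer(n),
             sex = character(n), breed = NA_character_,
             generation = integer(n), step = integer(n), nProgeny = integer(n))
}

.appendAnimals <- function(pop, sire, dam, sex, breed, generation, step,
                           mutationRate = 0) {
  ped <- pop@pedigree
  n0 <- nrow(ped)
  k <- length(sire)
  add <- .pedSkeleton(k)
  add$id <- n0 + seq_len(k)
  add$sire <- sire; add$dam <- dam; add$sex <- sex
  add$breed <- breed; add$generation <- generation; add$step <- step
  gS <- .dropGametes(pop@haplotypes, sire, pop@map, mutationRate)
  gD <- .dropGametes(pop@haplotypes, dam, pop@map, mutationRate)
  hap <- matrix(as.raw(0), nrow = nLoci(pop@map), ncol = 2L * (n0 + k))
  hap[, seq_len(2L * n0)] <- pop@haplotypes
  hap[, 2L * n0 + seq(1L, 2L * k, by = 2L)] <- gS
  hap[, 2L * n0 + seq(2L, 2L * k, by = 2L)] <- gD
  tb <- table(factor(c(sire, dam), levels = seq_len(n0)))
  ped$nProgeny <- ped$nProgeny + as.integer(tb)
  pop@pedigree <- rbind(ped, add)
  pop@haplotypes <- hap
  pop
}

#' Expand the base population from historical founders
#'
#' Step 2 of the population build-up: a random sample of historical founders
#' is mated at random for several generations with a fixed number of
#' offspring per dam and random 50:50 sexes. When a generation would exceed
#' \code{maxSize} offspring, a uniform random subset of the planned matings
#' is kept (random culling).
#'
#' @param founders a [HaplotypePool-class] (typically the selected-loci pool
#'   from [selectSegregatingLoci()]).
#' @param nFounderMales,nFounderFemales founder numbers drawn at random from
#'   the pool.
#' @param nGenerations number of expansion generations.
#' @param offspringPerDam litter size per dam per generation.
#' @param maxSize cap on the per-generation number of offspring.
#' @param mutationRate per-locus mutation probability in meiosis.
#' @param seed optional integer seed.
#' @return a [Population-class] containing founders (generation 0) and all
#'   expansion generations (step 2).
#' @export
expandPopulation <- function(founders, nFounderMales, nFounderFemales,
                             nGenerations, offspringPerDam = 5,
                             maxSize = Inf, mutationRate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nPool <- nIndividuals(founders)
  nF0 <- nFounderMales + nFounderFemales
  if (nPool < nF0)
    stop(sprintf("founder pool has %d individuals; %d requested", nPool, nF0))
  pick <- sample.int(nPool, nF0)
  ped <- .pedSkeleton(nF0)
  ped$id <- seq_len(nF0)
  ped$sex <- c(rep("M", nFounderMales), rep("F", nFounderFemales))
  ped$step <- 2L
  hap <- founders@haplotypes[, as.vector(rbind(2L * pick - 1L, 2L * pick)),
                             drop = FALSE]
  pop <- new("Population", pedigree = ped, haplotypes = hap,
             map = genomeMap(founders))
  for (g in seq_len(nGenerations)) {
    prev <- pop@pedigree[pop@pedigree$generation == g - 1L & pop@pedigree$step == 2L, ]
    sires <- prev$id[prev$sex == "M"]
    dams <- prev$id[prev$sex == "F"]
    if (length(sires) == 0 || length(dams) == 0)
      stop(sprintf("expansion generation %d has no breeding %s", g,
                   if (length(sires) == 0) "males" else "females"))
    damVec <- rep(dams, each = offspringPerDam)
    if (length(damVec) > maxSize)
      damVec <- damVec[sort(sample.int(length(damVec), maxSize))]
    k <- length(damVec)
    sireVec <- sires[sample.int(length(sires), k, replace = TRUE)]
    sex <- .assignSexes(k)
    pop <- .appendAnimals(pop, sireVec, damVec, sex, NA_character_, g, 2L,
                          mutationRate)
  }
  pop
}

#' Form reproductively isolated breeds
#'
#' Step 3: disjoint random samples of males and females from the last
#' expansion generation found \code{nBreeds} breeds, each then randomly mated
#' within itself for \code{nGenerations} generations at a fixed litter size.
#' No migration occurs between breeds.
#'
#' @param pop a [Population-class] from [expandPopulation()].
#' @param nBreeds number of breeds (labelled "A", "B", ...).
#' @param malesPerBreed,femalesPerBreed breed founder numbers per sex.
#' @param nGenerations number of within-breed random-mating generations.
#' @param offspringPerDam litter size.
#' @param mutationRate per-locus mutation probability in meiosis.
#' @param seed optional integer seed.
#' @return the input [Population-class] with breed founders labelled and all
#'   breed-formation generations appended (step 3).
#' @export
formBreeds <- function(pop, nBreeds = 5, malesPerBreed = 100,
                       femalesPerBreed = 100, nGenerations = 30,
                       offspringPerDam = 2, mutationRate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ped <- pop@pedigree
  lastGen <- max(ped$generation[ped$step == 2L])
  src <- ped[ped$step == 2L & ped$generation == lastGen, ]
  srcM <- src$id[src$sex == "M"]
  srcF <- src$id[src$sex == "F"]
  if (length(srcM) < nBreeds * malesPerBreed ||
      length(srcF) < nBreeds * femalesPerBreed)
    stop(sprintf(
      "source generation (%d M / %d F) too small for %d disjoint samples of %d M + %d F",
      length(srcM), length(srcF), nBreeds, malesPerBreed, femalesPerBreed))
  breeds <- LETTERS[seq_len(nBreeds)]
  pickM <- matrix(sample(srcM, nBreeds * malesPerBreed), ncol = nBreeds)
  pickF <- matrix(sample(srcF, nBreeds * femalesPerBreed), ncol = nBreeds)
  for (b in seq_len(nBreeds)) {
    pop@pedigree$breed[c(pickM[, b], pickF[, b])] <- breeds[b]
  }
  for (g in seq_len(nGenerations)) {
    sireVec <- integer(); damVec <- integer(); sexVec <- character()
    breedVec <- character()
    ped <- pop@pedigree
    for (b in seq_len(nBreeds)) {
      if (g == 1L) {
        sires <- pickM[, b]; dams <- pickF[, b]
      } else {
        prev <- ped[ped$step == 3L & ped$generation == g - 1L &
                      ped$breed == breeds[b] & !is.na(ped$breed), ]
        sires <- prev$id[prev$sex == "M"]
        dams <- prev$id[prev$sex == "F"]
      }
      if (length(sires) == 0 || length(dams) == 0)
        stop(sprintf("breed %s died out at formation generation %d", breeds[b], g))
      dv <- rep(dams, each = offspringPerDam)
      sireVec <- c(sireVec, sires[sample.int(length(sires), length(dv),
                                             replace = TRUE)])
      damVec <- c(damVec, dv)
      sexVec <- c(sexVec, .assignSexes(length(dv)))
      breedVec <- c(breedVec, rep(breeds[b], length(dv)))
    }
    pop <- .appendAnimals(pop, sireVec, damVec, sexVec, breedVec, g, 3L,
                          mutationRate)
  }
  pop
}

#' Found the selected-breeding base populations
#'
#' Creates the step-4 base animals of each breed as offspring of randomly
#' drawn parent pairs from the breed's final formation generation. Because
#' these base animals are later pedigree-truncated to metafounders, their
#' parent links are recorded as unknown (0) while their haplotypes are real
#' meioses of step-3 parents, preserving breed allele frequencies and
#' linkage disequilibrium.
#'
#' @param pop a [Population-class] from [formBreeds()].
#' @param specs list of [BreedSpec-class], one per breed.
#' @param mutationRate per-locus mutation probability in meiosis.
#' @param seed optional integer seed.
#' @return the population with step-4 generation-0 animals appended.
#' @export
foundBreedBase <- function(pop, specs, mutationRate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ped <- pop@pedigree
  lastGen <- max(ped$generation[ped$step == 3L])
  for (sp in specs) {
    prev <- ped[ped$step == 3L & ped$generation == lastGen &
                  ped$breed == sp@name & !is.na(ped$breed), ]
    sires <- prev$id[prev$sex == "M"]
    dams <- prev$id[prev$sex == "F"]
    if (length(sires) == 0 || length(dams) == 0)
      stop(sprintf("no step-3 parents available for breed %s", sp@name))
    k <- sp@nMales0 + sp@nFemales0
    sireVec <- sires[sample.int(length(sires), k, replace = TRUE)]
    damVec <- dams[sample.int(length(dams), k, replace = TRUE)]
    sex <- c(rep("M", sp@nMales0), rep("F", sp@nFemales0))
    n0 <- nrow(pop@pedigree)
    pop <- .appendAnimals(pop, sireVec, damVec, sex, sp@name, 0L, 4L,
                          mutationRate)
    # sever the pedigree link: base animals carry unknown parents
    idx <- n0 + seq_len(k)
    pop@pedigree$sire[idx] <- 0L
    pop@pedigree$dam[idx] <- 0L
    pop@pedigree$nProgeny[c(sireVec, damVec)] <-
      pop@pedigree$nProgeny[c(sireVec, damVec)] - 1L
  }
  pop
}

#' Replacement plan for one breed and generation
#'
#' Number of breeding animals leaving (replacement fraction, oldest first),
#' the grown target count, and the number of entrants required.
#'
#' @param nCurrent current number of breeding animals of the sex.
#' @param repl replacement fraction per generation.
#' @param growth proportional growth per generation.
#' @return list with \code{nOut}, \code{target} (= \code{round(nCurrent *
#'   (1 + growth))}) and \code{nIn}.
#' @examples
#' replacementPlan(220, 0.5065, 0.072) # target 236 sires
#' @export
replacementPlan <- function(nCurrent, repl, growth) {
  target <- as.integer(round(nCurrent * (1 + growth)))
  nOut <- as.integer(round(repl * nCurrent))
  list(nOut = nOut, target = target, nIn = nOut + (target - nCurrent))
}

# internal: step-4 sub-pedigree with remapped parent indices (base -> 0)
.step4Pedigree <- function(ped) {
  idx <- which(ped$step == 4L)
  id <- ped$id[idx]
  remap <- integer(nrow(ped))
  remap[id] <- seq_along(idx)
  s <- ped$sire[idx]; d <- ped$dam[idx]
  s <- ifelse(s > 0, remap[pmax(s, 1L)], 0L)
  d <- ifelse(d > 0, remap[pmax(d, 1L)], 0L)
  list(idx = idx, sire = as.integer(s), dam = as.integer(d),
       breed = ped$breed[idx], sex = ped$sex[idx],
       generation = ped$generation[idx])
}

#' Run the selected-breeding step
#'
#' Step 4: per generation and breed, active dams are each mated to a random
#' active sire producing one offspring (random 50:50 sex); offspring receive
#' phenotypes immediately. Breeding groups are then updated: the replacement
#' fraction of sires/dams leaves (oldest entry generation first, lowest
#' estimated breeding value first within an entry generation), the group
#' grows by its growth rate, and entrants are the highest-EBV candidates.
#' Candidates are never-bred animals of the right sex and breed from the
#' current cohort, topped up from earlier unused cohorts only when the
#' current cohort cannot meet demand. EBVs are re-estimated each generation
#' by multi-breed pedigree BLUP with unknown-parent groups on all step-4
#' phenotypes recorded so far (true variance components).
#'
#' @param pop a [Population-class] from [foundBreedBase()].
#' @param specs list of [BreedSpec-class].
#' @param arch a [TraitArchitecture-class].
#' @param nGenerations number of selected generations.
#' @param offspringPerDam litter size (1 in the cattle programme).
#' @param selection \code{"ebv"} (pedigree-BLUP selection), \code{"random"},
#'   or \code{"tbv"} (selection directly on true breeding values).
#' @param mutationRate per-locus mutation probability in meiosis.
#' @param strictReplacement error (rather than recruit all candidates with a
#'   message) when a breed's candidate pool cannot meet replacement demand.
#' @param seed optional integer seed.
#' @return list with \code{population} (the extended [Population-class]) and
#'   \code{phenotypes} (data.frame id, sex, breed, generation, tbv, y for all
#'   step-4 animals).
#' @export
runSelectedBreeding <- function(pop, specs, arch, nGenerations = 15,
                                offspringPerDam = 1,
                                selection = c("ebv", "random", "tbv"),
                                mutationRate = 0, strictReplacement = FALSE,
                                seed = NULL) {
  selection <- match.arg(selection)
  if (!is.null(seed)) set.seed(seed)
  breeds <- vapply(specs, function(s) s@name, "")
  ped0 <- pop@pedigree
  baseIdx <- which(ped0$step == 4L & ped0$generation == 0L)
  if (length(baseIdx) == 0) stop("no step-4 base animals; run foundBreedBase() first")
  # upper bound on total offspring (dam counts compound deterministically)
  planned <- 0L
  for (sp in specs) {
    d <- sp@nFemales0
    for (g in seq_len(nGenerations)) {
      planned <- planned + d * offspringPerDam
      d <- as.integer(round(d * (1 + sp@damGrowth)))
    }
  }
  n0 <- nrow(ped0)
  cap <- n0 + planned
  L <- nLoci(pop@map)
  hap <- matrix(as.raw(0), L, 2L * cap)
  hap[, seq_len(2L * n0)] <- pop@haplotypes
  v <- list(sire = c(ped0$sire, integer(planned)),
            dam = c(ped0$dam, integer(planned)),
            sex = c(ped0$sex, character(planned)),
            breed = c(ped0$breed, rep(NA_character_, planned)),
            generation = c(ped0$generation, integer(planned)),
            step = c(ped0$step, integer(planned)),
            nProgeny = c(ped0$nProgeny, integer(planned)))
  nCur <- n0
  asPed <- function() data.frame(
    id = seq_len(nCur), sire = v$sire[seq_len(nCur)],
    dam = v$dam[seq_len(nCur)], sex = v$sex[seq_len(nCur)],
    breed = v$breed[seq_len(nCur)], generation = v$generation[seq_len(nCur)],
    step = v$step[seq_len(nCur)], nProgeny = v$nProgeny[seq_len(nCur)])
  state <- data.frame(id = baseIdx, breed = v$breed[baseIdx],
                      sex = v$sex[baseIdx], entry = 0L)
  phen <- .phenotypesFromBuffers(hap, v, baseIdx, arch)
  for (g in seq_len(nGenerations)) {
    sireVec <- integer(); damVec <- integer(); breedVec <- character()
    for (b in breeds) {
      sires <- state$id[state$breed == b & state$sex == "M"]
      dams <- state$id[state$breed == b & state$sex == "F"]
      dv <- rep(dams, each = offspringPerDam)
      sireVec <- c(sireVec, sires[sample.int(length(sires), length(dv),
                                             replace = TRUE)])
      damVec <- c(damVec, dv)
      breedVec <- c(breedVec, rep(b, length(dv)))
    }
    k <- length(damVec)
    rows <- nCur + seq_len(k)
    gS <- .dropGametes(hap, sireVec, pop@map, mutationRate)
    gD <- .dropGametes(hap, damVec, pop@map, mutationRate)
    hap[, 2L * nCur + seq(1L, 2L * k, by = 2L)] <- gS
    hap[, 2L * nCur + seq(2L, 2L * k, by = 2L)] <- gD
    v$sire[rows] <- sireVec
    v$dam[rows] <- damVec
    v$sex[rows] <- ifelse(runif(k) < 0.5, "M", "F")
    v$breed[rows] <- breedVec
    v$generation[rows] <- g
    v$step[rows] <- 4L
    tb <- tabulate(c(sireVec, damVec), nbins = nCur)
    v$nProgeny[seq_len(nCur)] <- v$nProgeny[seq_len(nCur)] + tb
    nCur <- nCur + k
    phen <- rbind(phen, .phenotypesFromBuffers(hap, v, rows, arch))
    if (g == nGenerations) break
    pedNow <- asPed()
    ebv <- .selectionCriterion(pedNow, phen, arch, selection)
    state <- .updateBreedingGroups(pedNow, state, specs, ebv, g,
                                   strictReplacement)
  }
  outPop <- new("Population", pedigree = asPed(),
                haplotypes = hap[, seq_len(2L * nCur), drop = FALSE],
                map = pop@map, metafounders = pop@metafounders)
  list(population = outPop, phenotypes = phen)
}

# selection criterion for replacement decisions; `ped` is a pedigree frame
.selectionCriterion <- function(ped, phen, arch, selection) {
  ebv <- rep(NA_real_, nrow(ped))
  if (selection == "random") {
    ebv[phen$id] <- runif(nrow(phen))
  } else if (selection == "tbv") {
    ebv[phen$id] <- phen$tbv
  } else {
    s4 <- .step4Pedigree(ped)
    fit <- solveBlupUpg(
      data.frame(id = seq_along(s4$idx), sire = s4$sire, dam = s4$dam),
      groups = s4$breed,
      phenotypes = data.frame(animal = match(phen$id, ped$id[s4$idx]),
                              y = phen$y, sex = phen$sex),
      varA = arch@varA, varE = arch@varE)
    ebv[s4$idx] <- fit$ebv
  }
  ebv
}

.updateBreedingGroups <- function(ped, state, specs, ebv, g,
                                  strictReplacement) {
  for (sp in specs) {
    for (sx in c("M", "F")) {
      repl <- if (sx == "M") sp@sireRepl else sp@damRepl
      growth <- if (sx == "M") sp@sireGrowth else sp@damGrowth
      act <- which(state$breed == sp@name & state$sex == sx)
      plan <- replacementPlan(length(act), repl, growth)
      # candidates: never-bred animals of this breed/sex, current cohort
      # first, earlier unused cohorts as fallback
      cand <- ped[ped$step == 4L & ped$breed == sp@name & ped$sex == sx &
                    ped$nProgeny == 0L & !(ped$id %in% state$id), ]
      cur <- cand[cand$generation == g, ]
      old <- cand[cand$generation < g, ]
      nIn <- plan$nIn
      if (nIn > nrow(cand)) {
        msg <- sprintf(
          "breed %s generation %d: %s candidate pool (%d) below replacement demand (%d)",
          sp@name, g, if (sx == "M") "sire" else "dam", nrow(cand), nIn)
        if (strictReplacement) stop(msg)
        message(msg, "; recruiting all candidates")
        nIn <- nrow(cand)
      }
      nCur <- min(nIn, nrow(cur))
      pickCur <- cur$id[order(ebv[cur$id], decreasing = TRUE)][seq_len(nCur)]
      nOld <- nIn - nCur
      pickOld <- if (nOld > 0)
        old$id[order(ebv[old$id], decreasing = TRUE)][seq_len(nOld)] else integer()
      entrants <- c(pickCur, pickOld)
      # exits keep the group at its grown target size
      nOut <- max(0, (length(act) + length(entrants)) - plan$target)
      nOut <- min(nOut, length(act))
      ord <- act[order(state$entry[act], ebv[state$id[act]])]
      out <- ord[seq_len(nOut)]
      keep <- setdiff(seq_len(nrow(state)), out)
      state <- state[keep, , drop = FALSE]
      if (length(entrants) > 0)
        state <- rbind(state, data.frame(id = entrants, breed = sp@name,
                                         sex = sx, entry = g))
    }
  }
  rownames(state) <- NULL
  state
}

#' Assign breed metafounders to unknown parents
#'
#' Replaces the unknown parents of step-4 base animals by the negative id of
#' their breed's metafounder, creating exactly one metafounder per breed.
#' Animals with known parents are unchanged.
#'
#' @param pop a [Population-class] containing step-4 animals.
#' @return the population with negative metafounder parent ids and a filled
#'   \code{metafounders} table.
#' @export
assignMetafounders <- function(pop) {
  ped <- pop@pedigree
  idx <- which(ped$step == 4L & ped$sire == 0L & ped$dam == 0L)
  breeds <- sort(unique(ped$breed[ped$step == 4L]))
  mf <- data.frame(id = -seq_along(breeds), breed = breeds)
  ped$sire[idx] <- mf$id[match(ped$breed[idx], mf$breed)]
  ped$dam[idx] <- ped$sire[idx]
  pop@pedigree <- ped
  pop@metafounders <- mf
  pop
}

#' Extract the evaluation population (step-4 truncation)
#'
#' Keeps only the selected-breeding animals, renumbers ids densely in
#' topological order, remaps parent links (metafounder ids preserved) and
#' subsets the haplotypes. The original ids are kept in column
#' \code{origId}.
#'
#' @param pop a [Population-class] after [assignMetafounders()].
#' @return a [Population-class] with only step-4 animals.
#' @export
truncateToEvaluation <- function(pop) {
  ped <- pop@pedigree
  idx <- which(ped$step == 4L)
  sub <- ped[idx, ]
  remap <- integer(nrow(ped))
  remap[sub$id] <- seq_along(idx)
  mapPar <- function(p) ifelse(p > 0, remap[pmax(p, 1L)], p)
  dangling <- sub$sire > 0 & remap[pmax(sub$sire, 1L)] == 0L
  if (any(dangling))
    stop("truncation would leave dangling parents; run assignMetafounders() first")
  out <- data.frame(id = seq_along(idx), sire = as.integer(mapPar(sub$sire)),
                    dam = as.integer(mapPar(sub$dam)), sex = sub$sex,
                    breed = sub$breed, generation = sub$generation,
                    step = sub$step, nProgeny = sub$nProgeny,
                    origId = sub$id)
  cols <- as.vector(rbind(2L * idx - 1L, 2L * idx))
  new("Population", pedigree = out,
      haplotypes = pop@haplotypes[, cols, drop = FALSE], map = pop@map,
      metafounders = pop@metafounders)
}
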