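#' Simulate one full breeding-programme replicate
#'
#' Runs the whole build-up for one replicate: historical LD generation,
#' marker/QTL selection, expansion, breed formation, trait calibration on
#' the step-4 base generation, 15 generations of EBV-based selection, and
#' pedigree truncation to the evaluation population with one metafounder
#' per breed. A replicate is fully determined by \code{(preset, seed)}.
#'
#' @param preset preset list or name ("desk"/"production"), see [deskPreset()].
#' @param seed integer master seed; per-stage seeds are spawned from it so
#'   that downstream stages are insensitive to upstream draw counts.
#' @return list with \code{population} (evaluation [Population-class],
#'   metafounders assigned), \code{phenotypes} (data.frame over all
#'   evaluation animals: id, sex, breed, generation, tbv, y) and
#'   \code{arch} (the [TraitArchitecture-class]).
#' @export
simulateProgram <- function(preset, seed) {
  preset <- .resolvePreset(preset)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 7)
  gn <- preset$genome
  map <- uniformGenomeMap(gn$nChrom, gn$chromLengthCM, gn$nPoolLoci)
  hist <- simulateHistorical(map, preset$history$nGenPhase1,
                             preset$history$sizePhase1,
                             preset$history$nGenPhase2,
                             preset$history$sizeEnd,
                             mutationRate = gn$mutationRate, seed = seeds[1])
  pool <- selectSegregatingLoci(hist, gn$nMarkers, gn$nQtl, gn$mafMin,
                                seed = seeds[2])
  ex <- preset$expansion
  pop <- expandPopulation(pool, ex$nFounderMales, ex$nFounderFemales,
                          ex$nGenerations, ex$offspringPerDam, ex$maxSize,
                          mutationRate = gn$mutationRate, seed = seeds[3])
  bf <- preset$breedFormation
  pop <- formBreeds(pop, bf$nBreeds, bf$malesPerBreed, bf$femalesPerBreed,
                    bf$nGenerations, bf$offspringPerDam,
                    mutationRate = gn$mutationRate, seed = seeds[4])
  specs <- .breedSpecs(preset)
  pop <- foundBreedBase(pop, specs, mutationRate = gn$mutationRate,
                        seed = seeds[5])
  ped <- pedigree(pop)
  baseIdx <- which(ped$step == 4L & ped$generation == 0L)
  tr <- preset$trait
  arch <- traitArchitecture(pop, baseIdx, h2 = tr$h2, varP = tr$varP,
                            shape = tr$shape, mu = tr$mu,
                            sexEffects = c(M = tr$sexM, F = tr$sexF),
                            seed = seeds[6])
  res <- runSelectedBreeding(pop, specs, arch,
                             nGenerations = preset$step4$nGenerations,
                             offspringPerDam = preset$step4$offspringPerDam,
                             selection = preset$step4$selection,
                             mutationRate = gn$mutationRate, seed = seeds[7])
  evalPop <- truncateToEvaluation(assignMetafounders(res$population))
  phen <- res$phenotypes
  phen$id <- match(phen$id, pedigree(evalPop)$origId)
  phen <- phen[order(phen$id), ]
  rownames(phen) <- NULL
  list(population = evalPop, phenotypes = phen, arch = arch)
}

#' Evaluate all scenario-by-case cells on one simulated population
#'
#' For each genotyping scenario the genotyped set is drawn once; for each
#' phenotyping case the recorded-animal set is drawn once (shared across
#' scenarios, so cells differ only in the information used). The reference
#' scenario is evaluated by pedigree BLUP with unknown-parent groups, the
#' genomic scenarios by single-step GBLUP with metafounders. Accuracy is the
#' correlation between true and estimated breeding values among the
#' latest-generation selection candidates, overall, by sex, and for
#' candidates without phenotypic records by sex.
#'
#' @param sim result of [simulateProgram()].
#' @param scenarios named list of [GenotypingScenario-class] (default: the
#'   five standard scenarios at the preset budget used for \code{sim}).
#' @param cases named list of [PhenotypingCase-class] (default: the nine
#'   standard cases).
#' @param seed integer seed controlling the genotyped/phenotyped draws.
#' @param minGeneration first genotyping-eligible generation.
#' @param gammaSource \code{"base"} (breed allele frequencies of the step-4
#'   base generation; simulation truth) or \code{"genotyped"} (frequencies
#'   of each scenario's genotyped animals).
#' @return data.frame with columns scenario, case, subset
#'   (\code{all}/\code{M}/\code{F}/\code{noRecM}/\code{noRecF}), accuracy, n.
#' @export
evaluateGrid <- function(sim, scenarios, cases = standardCases(), seed = 1,
                         minGeneration = 7, gammaSource = c("base", "genotyped")) {
  gammaSource <- match.arg(gammaSource)
  pop <- sim$population
  ped <- pedigree(pop)
  phen <- sim$phenotypes
  stopifnot(identical(phen$id, ped$id))
  arch <- sim$arch
  set.seed(seed)
  sseeds <- sample.int(.Machine$integer.max - 1L, length(scenarios))
  cseeds <- sample.int(.Machine$integer.max - 1L, length(cases))
  lastGen <- max(ped$generation)
  cand <- ped$id[ped$generation == lastGen]
  candM <- cand[ped$sex[cand] == "M"]
  candF <- cand[ped$sex[cand] == "F"]
  obsSets <- lapply(seq_along(cases), function(i)
    selectPhenotyped(pop, cases[[i]], seed = cseeds[i]))
  baseIdx <- which(ped$generation == 0L)
  mk <- markerLoci(genomeMap(pop))
  AG <- NULL
  needG <- any(vapply(scenarios, function(s) s@budget > 0, TRUE))
  if (needG && gammaSource == "base") {
    Gamma <- estimateGamma(breedFrequencyMatrix(pop, baseIdx))
    AG <- buildAGammaInverse(ped, Gamma, metafounders(pop))
  }
  out <- list()
  for (j in seq_along(scenarios)) {
    sc <- scenarios[[j]]
    geno <- selectGenotyped(pop, sc, minGeneration, seed = sseeds[j])
    Hinv <- NULL
    if (sc@budget > 0) {
      if (gammaSource == "genotyped") {
        P <- vapply(sort(unique(ped$breed)), function(b)
          alleleFrequencies(pop, loci = mk,
                            individuals = geno[ped$breed[geno] == b]),
          numeric(length(mk)))
        AGj <- buildAGammaInverse(ped, estimateGamma(P), metafounders(pop))
      } else AGj <- AG
      M <- dosages(pop, loci = mk, individuals = geno)
      G <- buildGGamma(M)
      A22 <- relationshipSubset(AGj$Ainv, AGj$m + geno)
      Hinv <- buildHGammaInverse(AGj$Ainv, AGj$m + geno, G, A22)
    }
    for (i in seq_along(cases)) {
      obs <- obsSets[[i]]
      phOb <- data.frame(animal = obs, y = phen$y[obs], sex = phen$sex[obs])
      if (sc@budget == 0) {
        fit <- solveBlupUpg(ped, groups = ped$breed, phenotypes = phOb,
                            varA = arch@varA, varE = arch@varE)
      } else {
        fit <- solveSsgblupMF(Hinv, AGj$m, phenotypes = phOb,
                              varA = arch@varA, varE = arch@varE)
      }
      subsets <- list(all = cand, M = candM, F = candF,
                      noRecM = setdiff(candM, obs),
                      noRecF = setdiff(candF, obs))
      rows <- lapply(names(subsets), function(nm) {
        s <- subsets[[nm]]
        acc <- if (length(s) >= 2) predictionAccuracy(phen$tbv, fit$ebv, s)
               else NA_real_
        data.frame(scenario = names(scenarios)[j], case = names(cases)[i],
                   subset = nm, accuracy = acc, n = length(s))
      })
      out[[length(out) + 1L]] <- do.call(rbind, rows)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run one replicate of the full experimental grid
#'
#' Simulates one population and evaluates every scenario-by-case cell on it
#' (the population is held fixed across scenarios, as in the experimental
#' design).
#'
#' @param preset preset list or name.
#' @param seed integer replicate seed.
#' @param scenarios,cases optional scenario/case name subsets (default all).
#' @return accuracy data.frame as from [evaluateGrid()].
#' @export
runReplicate <- function(preset, seed, scenarios = NULL, cases = NULL) {
  preset <- .resolvePreset(preset)
  set.seed(seed)
  s2 <- sample.int(.Machine$integer.max - 1L, 2)
  sim <- simulateProgram(preset, s2[1])
  scen <- standardScenarios(preset$genotyping$budget,
                            preset$genotyping$minProgenySires)
  if (!is.null(scenarios)) scen <- scen[scenarios]
  cs <- standardCases()
  if (!is.null(cases)) cs <- cs[cases]
  evaluateGrid(sim, scen, cs, seed = s2[2],
               minGeneration = preset$genotyping$minGeneration)
}

#' Construct, write and read a run configuration
#'
#' A run configuration names a preset (optionally with overrides), a master
#' seed, a replicate count and the scenario/case subsets. It serializes to
#' YAML and round-trips losslessly, and a copy is written into every output
#' directory.
#'
#' @param preset preset name ("desk" or "production").
#' @param seed master seed; replicate seeds are spawned from it.
#' @param nReplicates number of replicates.
#' @param scenarios,cases character vectors of scenario/case names (NULL =
#'   all).
#' @param outDir optional output directory for per-replicate CSVs.
#' @param overrides optional named list merged over the preset.
#' @return a validated configuration list.
#' @export
runConfig <- function(preset = "desk", seed = 1, nReplicates = 1,
                      scenarios = NULL, cases = NULL, outDir = NULL,
                      overrides = NULL) {
  cfg <- list(preset = preset, seed = as.integer(seed),
              nReplicates = as.integer(nReplicates), scenarios = scenarios,
              cases = cases, outDir = outDir, overrides = overrides)
  .resolvePreset(cfg$preset, cfg$overrides) # validates
  if (!is.null(scenarios)) {
    known <- names(standardScenarios(1))
    bad <- setdiff(scenarios, known)
    if (length(bad)) stop("unknown scenarios: ", paste(bad, collapse = ", "))
  }
  if (!is.null(cases)) {
    bad <- setdiff(cases, names(standardCases()))
    if (length(bad)) stop("unknown cases: ", paste(bad, collapse = ", "))
  }
  cfg
}

#' @rdname runConfig
#' @param config a configuration list.
#' @param path file path for the YAML copy.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config[!vapply(config, is.null, TRUE)], path)
  invisible(path)
}

#' @rdname runConfig
#' @export
readRunConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  runConfig(preset = raw$preset, seed = raw$seed,
            nReplicates = raw$nReplicates,
            scenarios = unlist(raw$scenarios), cases = unlist(raw$cases),
            outDir = raw$outDir, overrides = raw$overrides)
}

#' Run the full replicated experiment
#'
#' For each replicate: simulate one population and evaluate all requested
#' scenario-by-case cells. With an output directory, per-replicate CSVs are
#' written and completed replicates are skipped on re-runs (resumable); the
#' configuration is serialized alongside.
#'
#' @param config a configuration from [runConfig()].
#' @return data.frame of all replicates' accuracies (column
#'   \code{replicate} added).
#' @export
runExperiment <- function(config) {
  preset <- .resolvePreset(config$preset, config$overrides)
  set.seed(config$seed)
  repSeeds <- sample.int(.Machine$integer.max - 1L, config$nReplicates)
  outDir <- config$outDir
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeRunConfig(config, file.path(outDir, "config.yaml"))
  }
  res <- vector("list", config$nReplicates)
  for (r in seq_len(config$nReplicates)) {
    f <- if (!is.null(outDir))
      file.path(outDir, sprintf("accuracy_rep%03d.csv", r)) else NULL
    if (!is.null(f) && file.exists(f)) {
      message("replicate ", r, " already complete; skipping")
      res[[r]] <- read.csv(f, stringsAsFactors = FALSE)
      next
    }
    df <- tryCatch(
      runReplicate(preset, repSeeds[r], config$scenarios, config$cases),
      error = function(e) {
        message(sprintf("replicate %d failed: %s", r, conditionMessage(e)))
        NULL
      })
    if (is.null(df)) next
    df <- cbind(replicate = r, df)
    if (!is.null(f)) write.csv(df, f, row.names = FALSE)
    res[[r]] <- df
  }
  out <- do.call(rbind, res)
  if (!is.null(outDir) && !is.null(out))
    write.csv(out, file.path(outDir, "accuracy_all.csv"), row.names = FALSE)
  out
}

#' Aggregate replicate accuracies
#'
#' Mean and standard deviation of accuracy per scenario, case and subset
#' across replicates.
#'
#' @param results data.frame from [runExperiment()] or [runReplicate()] (a
#'   \code{replicate} column is added when absent).
#' @return data.frame with columns scenario, case, subset, mean, sd,
#'   nReplicates.
#' @export
summarizeAccuracy <- function(results) {
  if (!"replicate" %in% names(results)) results$replicate <- 1L
  agg <- stats::aggregate(accuracy ~ scenario + case + subset, data = results,
                          FUN = function(x) c(mean = mean(x), sd = sd(x),
                                              n = length(x)),
                          na.action = stats::na.omit)
  out <- data.frame(scenario = agg$scenario, case = agg$case,
                    subset = agg$subset, mean = agg$accuracy[, "mean"],
                    sd = agg$accuracy[, "sd"],
                    nReplicates = agg$accuracy[, "n"])
  out[order(match(out$subset, c("all", "M", "F", "noRecM", "noRecF")),
            match(out$scenario, unique(results$scenario)),
            match(out$case, unique(results$case))), , drop = FALSE]
}

#' Accuracy table in the cases-by-scenarios layout
#'
#' @param summary data.frame from [summarizeAccuracy()].
#' @param subset which candidate subset to tabulate.
#' @return numeric matrix, phenotyping cases in rows, scenarios in columns.
#' @export
accuracyTable <- function(summary, subset = "all") {
  s <- summary[summary$subset == subset, ]
  cases <- unique(s$case)
  scen <- unique(s$scenario)
  m <- matrix(NA_real_, length(cases), length(scen),
              dimnames = list(cases, scen))
  m[cbind(match(s$case, cases), match(s$scenario, scen))] <- s$mean
  m
}

#' Scenario-average accuracies
#'
#' Mean over the phenotyping cases of each scenario's candidate accuracy
#' (the "average prediction accuracy across scenarios" summary).
#'
#' @inheritParams accuracyTable
#' @return named numeric vector, one value per scenario.
#' @export
scenarioAverages <- function(summary, subset = "all") {
  colMeans(accuracyTable(summary, subset), na.rm = TRUE)
}
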