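#' Simulation presets
#'
#' A preset bundles every parameter of the breeding-programme simulation:
#' genome layout, historical phase, expansion, breed formation, per-breed
#' selection parameters, trait model and genotyping budget.
#'
#' \code{productionPreset()} is the full production-scale programme: a 29-
#' chromosome, 2319 cM genome with 50,000 evenly spaced markers and 800
#' random QTL (MAF > 0.1, recurrent mutation 2.5e-5), 1,000 + 200 historical
#' generations (sizes 1,000 then growing to 2,020), 8 expansion generations
#' at 5 offspring per dam, five breeds formed from 100 + 100 founders each
#' and randomly mated for 30 generations at 2 offspring per dam, then 15
#' generations of EBV selection with per-breed replacement/growth rates and
#' a genotyping budget of 5,000 from generation 7 onward.
#'
#' \code{deskPreset()} preserves the full structure at desk scale: a 5 x 80
#' cM genome with 2,000 markers and 200 QTL; a 200-generation history whose
#' size (150 generations at 200, then growth to 400) is chosen so that the
#' cumulative founder drift and the linkage disequilibrium at the marker
#' spacing match the production-scale history; expansion and breed
#' formation at the production sizes (they are cheap and control breed
#' differentiation); step-4 breed sizes at one tenth of the production
#' scale; and a genotyping budget of 500 (the same 3 percent genotyped
#' fraction). A replicate runs in about a minute.
#'
#' @return a named preset list (see \code{vignette("metaGSim-methods")}).
#' @export
productionPreset <- function() {
  list(
    name = "production",
    genome = list(nChrom = 29L, chromLengthCM = 2319 / 29, nPoolLoci = 70000L,
                  nMarkers = 50000L, nQtl = 800L, mafMin = 0.1,
                  mutationRate = 2.5e-5),
    history = list(nGenPhase1 = 1000L, sizePhase1 = 1000L, nGenPhase2 = 200L,
                   sizeEnd = 2020L),
    expansion = list(nFounderMales = 100L, nFounderFemales = 100L,
                     nGenerations = 8L, offspringPerDam = 5L, maxSize = 1500L),
    breedFormation = list(nBreeds = 5L, malesPerBreed = 100L,
                          femalesPerBreed = 100L, nGenerations = 30L,
                          offspringPerDam = 2L),
    breeds = list(
      list(name = "A", nMales0 = 220L, nFemales0 = 1800L,
           sireRepl = 0.5065, sireGrowth = 0.072, damRepl = 0.30, damGrowth = 0.098),
      list(name = "B", nMales0 = 160L, nFemales0 = 1100L,
           sireRepl = 0.5851, sireGrowth = 0.1038, damRepl = 0.30, damGrowth = 0.1629),
      list(name = "C", nMales0 = 140L, nFemales0 = 1200L,
           sireRepl = 0.5252, sireGrowth = 0.073, damRepl = 0.30, damGrowth = 0.103),
      list(name = "D", nMales0 = 120L, nFemales0 = 600L,
           sireRepl = 0.6256, sireGrowth = 0.118, damRepl = 0.30, damGrowth = 0.182),
      list(name = "E", nMales0 = 100L, nFemales0 = 500L,
           sireRepl = 0.5392, sireGrowth = 0.06, damRepl = 0.30, damGrowth = 0.117)),
    step4 = list(nGenerations = 15L, offspringPerDam = 1L, selection = "ebv"),
    trait = list(h2 = 0.3, varP = 1, shape = 0.4, mu = 0,
                 sexM = 0.25, sexF = -0.25),
    genotyping = list(budget = 5000L, minGeneration = 7L,
                      minProgenySires = 10L))
}

#' @rdname productionPreset
#' @export
deskPreset <- function() {
  p <- productionPreset()
  p$name <- "desk"
  p$genome <- list(nChrom = 5L, chromLengthCM = 80, nPoolLoci = 9000L,
                   nMarkers = 2000L, nQtl = 200L, mafMin = 0.1,
                   mutationRate = 2.5e-5)
  p$history <- list(nGenPhase1 = 150L, sizePhase1 = 200L, nGenPhase2 = 50L,
                    sizeEnd = 400L)
  for (i in seq_along(p$breeds)) {
    p$breeds[[i]]$nMales0 <- as.integer(round(p$breeds[[i]]$nMales0 / 10))
    p$breeds[[i]]$nFemales0 <- as.integer(round(p$breeds[[i]]$nFemales0 / 10))
  }
  p$genotyping$budget <- 500L
  p
}

# breedSpec objects from the preset's plain-list breed table
.breedSpecs <- function(preset) {
  lapply(preset$breeds, function(b)
    breedSpec(b$name, b$nMales0, b$nFemales0, b$sireRepl, b$sireGrowth,
              b$damRepl, b$damGrowth))
}

# light structural validation against the preset schema
.validatePreset <- function(p) {
  need <- c("genome", "history", "expansion", "breedFormation", "breeds",
            "step4", "trait", "genotyping")
  miss <- setdiff(need, names(p))
  if (length(miss)) stop("preset is missing fields: ", paste(miss, collapse = ", "))
  gn <- p$genome
  stopifnot(gn$nMarkers > 0, gn$nQtl > 0, gn$nPoolLoci >= gn$nMarkers + gn$nQtl,
            gn$mafMin >= 0, gn$mafMin < 0.5, gn$mutationRate >= 0,
            p$trait$h2 > 0, p$trait$h2 < 1, p$trait$varP > 0,
            p$genotyping$budget >= 0, length(p$breeds) >= 1)
  invisible(.breedSpecs(p)) # breed specs must construct and validate
  invisible(p)
}

# resolve a preset name or list
.resolvePreset <- function(preset, overrides = NULL) {
  if (is.character(preset))
    preset <- switch(preset, desk = deskPreset(),
                     production = productionPreset(),
                     stop("unknown preset name: ", preset))
  if (!is.null(overrides)) preset <- modifyList(preset, overrides)
  .validatePreset(preset)
  preset
}
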