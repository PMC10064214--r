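# Solve the single-trait animal-model mixed-model equations
#   [X'X  X'Z ] [b]   [X'y]
#   [Z'X  Z'Z + lambda * Kinv] [u] = [Z'y]
# Kinv is any inverse relationship structure (grouped A-inverse, gamma
# pedigree inverse, or single-step H-inverse). Sparse Cholesky (CHOLMOD) is
# used when the (possibly constrained) system is positive definite, with a
# sparse LU fallback otherwise.
.solveMME <- function(Kinv, animal, y, X, lambda, dropEq = integer()) {
  nk <- nrow(Kinv)
  X <- as.matrix(X)
  p <- ncol(X)
  nobs <- length(y)
  stopifnot(length(animal) == nobs, nrow(X) == nobs)
  Z <- Matrix::sparseMatrix(i = seq_len(nobs), j = animal, x = 1,
                            dims = c(nobs, nk))
  XtZ <- Matrix::crossprod(Matrix::Matrix(X, sparse = TRUE), Z)
  C <- rbind(
    cbind(Matrix::Matrix(crossprod(X), sparse = TRUE), XtZ),
    cbind(Matrix::t(XtZ), Matrix::crossprod(Z) + lambda * Kinv))
  rhs <- c(as.vector(crossprod(X, y)), as.vector(Matrix::crossprod(Z, y)))
  keep <- setdiff(seq_len(p + nk), p + dropEq)
  Cs <- C[keep, keep, drop = FALSE]
  r <- rhs[keep]
  sol <- tryCatch({
    ch <- Matrix::Cholesky(Matrix::forceSymmetric(Cs), LDL = FALSE, perm = TRUE)
    as.vector(Matrix::solve(ch, r, system = "A"))
  }, error = function(e)
    as.vector(Matrix::solve(Cs, r)))
  full <- numeric(p + nk)
  full[keep] <- sol
  list(b = full[seq_len(p)], u = full[p + seq_len(nk)])
}

# fixed-effect design from a formula and the phenotype frame, reduced to
# full column rank (aliased columns dropped)
.fixedDesign <- function(fixed, data) {
  if (is.null(fixed)) {
    fixed <- if ("sex" %in% names(data) && length(unique(data$sex)) > 1)
      ~sex else ~1
  }
  X <- stats::model.matrix(fixed, data)
  q <- qr(X)
  if (q$rank < ncol(X)) X <- X[, q$pivot[seq_len(q$rank)], drop = FALSE]
  X
}

#' Pedigree BLUP with unknown-parent groups
#'
#' Multi-breed single-trait animal model: phenotypes are modelled with fixed
#' effects (default: intercept and sex) and a random additive genetic effect
#' with grouped pedigree structure. Unknown parents are assigned to groups
#' (one per breed here); in the transformed equations animal solutions are
#' total estimated breeding values, group contribution included. One group
#' equation (the last level) is constrained to zero for identifiability with
#' the intercept.
#'
#' @param ped pedigree data.frame (\code{id} dense 1..n topologically
#'   ordered, \code{sire}, \code{dam}, 0 = unknown; negative metafounder ids
#'   are treated as unknown here).
#' @param groups character/factor of length n: unknown-parent group per
#'   animal (usually breed).
#' @param phenotypes data.frame with \code{animal} (pedigree row index of the
#'   record), \code{y}, and any fixed-effect covariates (e.g. \code{sex}).
#' @param varA,varE additive genetic and residual variances (true simulation
#'   values; the variance ratio \code{lambda = varE / varA} enters the MME).
#' @param fixed fixed-effect formula over the phenotype columns; default
#'   intercept + sex when informative.
#' @return list with \code{ebv} (length n, total EBVs), \code{upg} (named
#'   group solutions, last level constrained to 0), \code{b} (fixed-effect
#'   solutions) and \code{lambda}.
#' @export
solveBlupUpg <- function(ped, groups, phenotypes, varA, varE, fixed = NULL) {
  n <- nrow(ped)
  ped2 <- ped
  ped2$sire <- pmax(ped$sire, 0L)
  ped2$dam <- pmax(ped$dam, 0L)
  A <- buildAInverse(ped2, groups = groups)
  ng <- length(A$groupLevels)
  X <- .fixedDesign(fixed, phenotypes)
  lambda <- varE / varA
  fit <- .solveMME(A$Ainv, phenotypes$animal, phenotypes$y, X, lambda,
                   dropEq = if (ng > 0) n + ng else integer())
  list(ebv = fit$u[seq_len(n)],
       upg = if (ng > 0) setNames(fit$u[n + seq_len(ng)], A$groupLevels) else NULL,
       b = setNames(fit$b, colnames(X)), lambda = lambda)
}

#' Single-step GBLUP with metafounders
#'
#' The same animal model as [solveBlupUpg()] with the grouped pedigree
#' inverse replaced by the combined single-step inverse built on the
#' gamma-augmented pedigree: metafounders take the place of unknown-parent
#' groups (no explicit group term) and every animal, genotyped or not,
#' receives a genomically enhanced breeding value.
#'
#' @param Hinv combined inverse from [buildHGammaInverse()] (or the plain
#'   gamma pedigree inverse when no animal is genotyped), metafounders first.
#' @param m number of metafounders (leading rows of \code{Hinv}).
#' @param phenotypes data.frame with \code{animal} (animal row index, 1..n,
#'   excluding metafounders), \code{y} and fixed-effect covariates.
#' @param varA,varE variance components.
#' @param fixed fixed-effect formula (default intercept + sex).
#' @return list with \code{ebv} (length n), \code{metafounderEffects}
#'   (length m), \code{b}, \code{lambda}.
#' @export
solveSsgblupMF <- function(Hinv, m, phenotypes, varA, varE, fixed = NULL) {
  nk <- nrow(Hinv)
  n <- nk - m
  X <- .fixedDesign(fixed, phenotypes)
  lambda <- varE / varA
  fit <- .solveMME(Hinv, phenotypes$animal + m, phenotypes$y, X, lambda)
  list(ebv = fit$u[m + seq_len(n)],
       metafounderEffects = fit$u[seq_len(m)],
       b = setNames(fit$b, colnames(X)), lambda = lambda)
}

#' Prediction accuracy
#'
#' Pearson correlation between true and estimated breeding values over a
#' subset of animals. Returns \code{NA} (with a warning) when either vector
#' is degenerate.
#'
#' @param tbv,ebv numeric vectors of equal length.
#' @param subset optional index vector naming the animals to correlate.
#' @return numeric scalar in [-1, 1], or NA.
#' @export
predictionAccuracy <- function(tbv, ebv, subset = NULL) {
  if (!is.null(subset)) {
    tbv <- tbv[subset]; ebv <- ebv[subset]
  }
  if (length(tbv) < 2) {
    warning("fewer than 2 animals in subset; accuracy undefined")
    return(NA_real_)
  }
  if (sd(tbv) == 0 || sd(ebv) == 0) {
    warning("degenerate variance; accuracy undefined")
    return(NA_real_)
  }
  cor(tbv, ebv)
}
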