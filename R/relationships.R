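#' Inverse numerator relationship matrix, optionally with unknown-parent groups
#'
#' Assembles the sparse inverse of the pedigree relationship matrix by
#' Henderson's rules, with inbreeding from the Meuwissen-Luo recursion. When
#' \code{groups} is supplied, each animal's unknown parents are replaced by
#' its group's equation (Quaas-Pollak transformed unknown-parent-group
#' model): the returned matrix has one trailing row/column per group, and
#' mixed-model solutions for animals are total breeding values including the
#' group effect.
#'
#' @param ped data.frame with columns \code{id} (dense 1..n, topologically
#'   ordered), \code{sire}, \code{dam} (0 = unknown).
#' @param groups optional character/factor of length n: the unknown-parent
#'   group (e.g. breed) used for any missing parent of that animal.
#' @return list with \code{Ainv} (sparse symmetric, dimension n or
#'   n + nGroups with groups last), \code{groupLevels}, \code{inbreeding}
#'   (diagonal of A minus 1) and \code{mendelian} (per-animal Mendelian
#'   sampling variance ratios).
#' @export
buildAInverse <- function(ped, groups = NULL) {
  n <- nrow(ped)
  sire <- as.integer(ped$sire); dam <- as.integer(ped$dam)
  if (any(sire > ped$id) || any(dam > ped$id))
    stop("pedigree not topologically ordered: parent listed after child")
  ml <- cpp_ml_mendelian(sire, dam, integer(n), matrix(0, 0, 0))
  dg <- ml$diag; mend <- ml$mendelian
  ng <- 0L; gidx <- NULL
  if (!is.null(groups)) {
    gf <- factor(groups)
    ng <- nlevels(gf)
    gidx <- n + as.integer(gf)
  }
  founder <- sire == 0L & dam == 0L
  # founders: classic case contributes a unit diagonal (q = e_i, variance 1);
  # with groups the two phantom group parents give m = 0.5
  mend[founder] <- if (is.null(groups)) 1 else 0.5
  # parent-slot equation index: animal, group (if any), or 0 (absorbed)
  p1 <- ifelse(sire > 0L, sire, if (is.null(groups)) 0L else gidx)
  p2 <- ifelse(dam > 0L, dam, if (is.null(groups)) 0L else gidx)
  dim <- n + ng
  alpha <- 1 / mend
  ii <- c(); jj <- c(); xx <- c()
  add <- function(i, j, x) {
    keep <- i > 0L & j > 0L
    ii <<- c(ii, i[keep]); jj <<- c(jj, j[keep]); xx <<- c(xx, x[keep])
  }
  i <- seq_len(n)
  add(i, i, alpha)
  add(i, p1, -alpha / 2); add(p1, i, -alpha / 2)
  add(i, p2, -alpha / 2); add(p2, i, -alpha / 2)
  add(p1, p1, alpha / 4); add(p2, p2, alpha / 4)
  add(p1, p2, alpha / 4); add(p2, p1, alpha / 4)
  Ainv <- Matrix::forceSymmetric(
    Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(dim, dim)))
  list(Ainv = Ainv, groupLevels = if (ng) levels(factor(groups)) else NULL,
       inbreeding = dg - 1, mendelian = mend)
}

#' Fractional unknown-parent-group contributions
#'
#' Per-animal fractions of ancestry tracing to each unknown-parent group,
#' computed by recursive averaging of parental fractions (an unknown parent
#' contributes its group). Rows sum to 1.
#'
#' @inheritParams buildAInverse
#' @param groups character/factor of length n (required here).
#' @return numeric matrix, animals x groups.
#' @export
upgContributions <- function(ped, groups) {
  gf <- factor(groups)
  n <- nrow(ped)
  Q <- matrix(0, n, nlevels(gf), dimnames = list(NULL, levels(gf)))
  for (i in seq_len(n)) {
    s <- ped$sire[i]; d <- ped$dam[i]
    qs <- if (s > 0) Q[s, ] else { e <- numeric(nlevels(gf)); e[as.integer(gf[i])] <- 1; e }
    qd <- if (d > 0) Q[d, ] else { e <- numeric(nlevels(gf)); e[as.integer(gf[i])] <- 1; e }
    Q[i, ] <- 0.5 * (qs + qd)
  }
  Q
}

#' Metafounder relationship matrix from breed allele frequencies
#'
#' Within/across metafounder relationships are eight times the covariance
#' matrix (across markers) of the per-breed allele-frequency columns. A
#' numerically indefinite result (possible only through rounding) is
#' repaired by clipping negative eigenvalues at zero, with a warning.
#'
#' @param P numeric matrix, markers x breeds, frequency of the counted
#'   (second) allele per breed.
#' @return symmetric positive semidefinite matrix, breeds x breeds.
#' @export
estimateGamma <- function(P) {
  P <- as.matrix(P)
  if (nrow(P) < 2) stop("at least 2 markers are needed to estimate Gamma")
  if (any(P < 0 | P > 1)) stop("allele frequencies must lie in [0, 1]")
  G <- 8 * stats::cov(P)
  ev <- eigen(G, symmetric = TRUE)
  if (any(ev$values < -1e-10)) {
    warning("Gamma was not positive semidefinite; negative eigenvalues clipped at 0")
    G <- ev$vectors %*% diag(pmax(ev$values, 0), nrow(G)) %*% t(ev$vectors)
    G <- (G + t(G)) / 2
  }
  dimnames(G) <- list(colnames(P), colnames(P))
  G
}

#' Per-breed allele-frequency matrix at the markers
#'
#' @param pop a [Population-class] whose map carries marker roles.
#' @param individuals indices of the animals whose genotypes define the
#'   frequencies (typically the step-4 base generation).
#' @return numeric matrix, markers x breeds (columns ordered by breed name).
#' @export
breedFrequencyMatrix <- function(pop, individuals) {
  ped <- pedigree(pop)
  breeds <- sort(unique(ped$breed[individuals]))
  mk <- markerLoci(genomeMap(pop))
  P <- vapply(breeds, function(b)
    alleleFrequencies(pop, loci = mk,
                      individuals = individuals[ped$breed[individuals] == b]),
    numeric(length(mk)))
  colnames(P) <- breeds
  P
}

# combined metafounder-first indexing of a truncated pedigree:
# metafounders occupy rows 1..m (as founders in their own group), animals
# m+1 .. m+n; negative parent ids map onto the metafounder rows.
.mfCombined <- function(ped, mf) {
  m <- nrow(mf)
  mapPar <- function(p) ifelse(p < 0, match(p, mf$id), ifelse(p > 0, m + p, 0L))
  list(m = m, n = nrow(ped),
       sire = as.integer(c(rep(0L, m), mapPar(ped$sire))),
       dam = as.integer(c(rep(0L, m), mapPar(ped$dam))),
       group = as.integer(c(seq_len(m), rep(0L, nrow(ped)))))
}

#' Gamma-augmented pedigree relationship matrix (dense)
#'
#' Tabular recursion for the relationship matrix of a pedigree whose base is
#' a set of metafounders with (co)variances \code{Gamma}: the metafounder
#' block is initialized to \code{Gamma}, descendants follow the standard
#' recursion \code{a(i,j) = (a(sire,j) + a(dam,j)) / 2} with diagonal
#' \code{1 + a(sire,dam) / 2}. Intended for small pedigrees (dense, O(n^2)
#' memory); the evaluation pipeline uses [buildAGammaInverse()] instead.
#'
#' @param ped truncated pedigree data.frame (\code{id} 1..n, \code{sire} /
#'   \code{dam} positive animal ids, negative metafounder ids, or 0).
#' @param Gamma metafounder relationship matrix (see [estimateGamma()]).
#' @param mf metafounder table (data.frame \code{id} negative, \code{breed}),
#'   rows matching \code{Gamma}'s order.
#' @return dense symmetric matrix of dimension nMetafounders + n (metafounders
#'   first).
#' @export
buildAGamma <- function(ped, Gamma, mf) {
  cmb <- .mfCombined(ped, mf)
  N <- cmb$m + cmb$n
  A <- matrix(0, N, N)
  A[seq_len(cmb$m), seq_len(cmb$m)] <- Gamma
  for (k in (cmb$m + 1):N) {
    s <- cmb$sire[k]; d <- cmb$dam[k]
    rs <- if (s > 0) A[s, seq_len(k - 1)] else 0
    rd <- if (d > 0) A[d, seq_len(k - 1)] else 0
    A[k, seq_len(k - 1)] <- (rs + rd) / 2
    A[seq_len(k - 1), k] <- A[k, seq_len(k - 1)]
    A[k, k] <- 1 + (if (s > 0 && d > 0) A[s, d] else 0) / 2
  }
  A
}

#' Sparse inverse of the gamma-augmented pedigree relationship matrix
#'
#' Generalized Henderson rules: each animal contributes its Mendelian
#' sampling precision to itself and its parents (metafounders act as
#' ordinary parents), and the metafounder block receives the inverse of
#' \code{Gamma}. Mendelian variances account for metafounder ancestry via a
#' generalized Meuwissen-Luo recursion with the founder block initialized to
#' \code{Gamma}.
#'
#' @inheritParams buildAGamma
#' @return list with \code{Ainv} (sparse symmetric, metafounders first),
#'   \code{diag} (diagonal of the gamma-augmented relationship matrix),
#'   \code{mendelian}, \code{m} (number of metafounders).
#' @export
buildAGammaInverse <- function(ped, Gamma, mf) {
  cmb <- .mfCombined(ped, mf)
  if (any(cmb$sire[-seq_len(cmb$m)] == 0 | cmb$dam[-seq_len(cmb$m)] == 0))
    stop("all animals must have known or metafounder parents; run assignMetafounders()")
  ml <- cpp_ml_mendelian(cmb$sire, cmb$dam, cmb$group, Gamma)
  N <- cmb$m + cmb$n
  idx <- (cmb$m + 1):N
  alpha <- 1 / ml$mendelian[idx]
  if (any(!is.finite(alpha)))
    stop("non-positive Mendelian variance; Gamma diagonal must be < 4")
  p1 <- cmb$sire[idx]; p2 <- cmb$dam[idx]
  i <- idx
  ii <- c(i, i, p1, i, p2, p1, p2, p1, p2)
  jj <- c(i, p1, i, p2, i, p1, p2, p2, p1)
  xx <- c(alpha, rep(-alpha / 2, 4), rep(alpha / 4, 4))
  Ginv <- tryCatch(solve(Gamma), error = function(e)
    stop("Gamma is singular; repair it (e.g. eigenvalue clipping plus a small ridge) before use"))
  gi <- rep(seq_len(cmb$m), each = cmb$m)
  gj <- rep(seq_len(cmb$m), cmb$m)
  Ainv <- Matrix::sparseMatrix(i = c(ii, gi), j = c(jj, gj),
                               x = c(xx, as.vector(Ginv)), dims = c(N, N))
  list(Ainv = Matrix::forceSymmetric(Ainv), diag = ml$diag,
       mendelian = ml$mendelian, m = cmb$m)
}

#' Relationship submatrix for a set of animals from a sparse inverse
#'
#' Extracts \code{A[idx, idx]} from a sparse symmetric positive-definite
#' \code{Ainv} by solving against unit vectors with one Cholesky
#' factorization.
#'
#' @param Ainv sparse symmetric positive definite inverse relationship matrix.
#' @param idx row/column indices of the required block.
#' @return dense symmetric matrix of dimension \code{length(idx)}.
#' @export
relationshipSubset <- function(Ainv, idx) {
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(Ainv), LDL = FALSE)
  E <- Matrix::sparseMatrix(i = idx, j = seq_along(idx),
                            dims = c(nrow(Ainv), length(idx)), x = 1)
  X <- Matrix::solve(ch, E, system = "A")
  out <- as.matrix(X[idx, , drop = FALSE])
  (out + t(out)) / 2
}

#' Genomic relationship matrix in the metafounder formulation
#'
#' \code{G = w w' / s} where \code{w} codes genotypes AA, Aa, aa as 1, 0, -1
#' (i.e. allele dosage minus 1) and \code{s} is half the number of markers.
#' No allele-frequency centering is applied: in the metafounder formulation
#' the base-population frequency structure is absorbed by Gamma.
#'
#' @param M integer matrix of allele dosages (0/1/2), animals x markers.
#' @return dense symmetric genomic relationship matrix, animals x animals.
#' @export
buildGGamma <- function(M) {
  if (any(is.na(M))) stop("missing genotypes are not supported")
  if (any(M < 0 | M > 2)) stop("dosages must be 0, 1 or 2")
  W <- M - 1
  tcrossprod(W) / (ncol(M) / 2)
}

#' Combined single-step inverse relationship matrix with metafounders
#'
#' Adds the genotyped-block correction \code{solve(GGamma) -
#' solve(A22Gamma)} to the gamma-augmented pedigree inverse. When
#' \code{GGamma} is numerically singular it is blended towards
#' \code{A22Gamma} (weight \code{blend}) before inversion, with a warning;
#' by default the genomic matrix is used as-is.
#'
#' @param AinvGamma sparse inverse from [buildAGammaInverse()] (metafounders
#'   first).
#' @param genotyped combined row indices (into \code{AinvGamma}) of the
#'   genotyped animals, in the row order of \code{GGamma}.
#' @param GGamma genomic relationship matrix from [buildGGamma()].
#' @param A22Gamma pedigree relationship block for the genotyped animals
#'   (e.g. from [relationshipSubset()]), same order.
#' @param blend blending weight towards \code{A22Gamma} applied only on
#'   numerical singularity of \code{GGamma}.
#' @return sparse symmetric combined inverse of the same dimension as
#'   \code{AinvGamma}.
#' @export
buildHGammaInverse <- function(AinvGamma, genotyped, GGamma, A22Gamma,
                               blend = 0.05) {
  k <- length(genotyped)
  if (k == 0) return(Matrix::forceSymmetric(AinvGamma))
  stopifnot(nrow(GGamma) == k, nrow(A22Gamma) == k)
  Gi <- tryCatch(chol2inv(chol(GGamma)), error = function(e) NULL)
  if (is.null(Gi)) {
    warning(sprintf(
      "GGamma numerically singular; blending %.2f towards A22Gamma", blend))
    Gb <- (1 - blend) * GGamma + blend * A22Gamma
    Gi <- tryCatch(chol2inv(chol(Gb)), error = function(e)
      stop("GGamma singular even after blending towards A22Gamma"))
  }
  A22i <- chol2inv(chol(A22Gamma))
  corr <- Gi - A22i
  Hinv <- AinvGamma + Matrix::sparseMatrix(
    i = rep(genotyped, times = k), j = rep(genotyped, each = k),
    x = as.vector(corr), dims = dim(AinvGamma))
  Matrix::forceSymmetric((Hinv + Matrix::t(Hinv)) / 2)
}
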