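# Independent brute-force oracles used to validate the sparse/recursive
# implementations. All are direct dense recursions or plain linear algebra.

# dense numerator relationship matrix by the tabular method (0 = unknown)
oracleTabularA <- function(sire, dam) {
  n <- length(sire)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- sire[i]; d <- dam[i]
    if (i > 1) {
      for (j in seq_len(i - 1)) {
        A[i, j] <- A[j, i] <-
          ((if (s > 0) A[j, s] else 0) + (if (d > 0) A[j, d] else 0)) / 2
      }
    }
    A[i, i] <- 1 + (if (s > 0 && d > 0) A[s, d] else 0) / 2
  }
  A
}

# dense gamma-augmented relationship matrix: metafounder block Gamma first,
# then animals; sire/dam index into the combined order (1..m metafounders)
oracleTabularAGamma <- function(sire, dam, Gamma) {
  m <- nrow(Gamma)
  n <- length(sire)
  N <- m + n
  A <- matrix(0, N, N)
  A[1:m, 1:m] <- Gamma
  for (k in (m + 1):N) {
    i <- k - m
    s <- sire[i]; d <- dam[i]
    for (j in seq_len(k - 1)) {
      A[k, j] <- A[j, k] <-
        ((if (s > 0) A[j, s] else 0) + (if (d > 0) A[j, d] else 0)) / 2
    }
    A[k, k] <- 1 + (if (s > 0 && d > 0) A[s, d] else 0) / 2
  }
  A
}

# dense mixed-model solve: K is the *covariance* structure of the random
# effect (not its inverse); returns list(b, u)
oracleDenseMME <- function(K, X, animal, y, lambda) {
  nk <- nrow(K)
  nobs <- length(y)
  Z <- matrix(0, nobs, nk)
  Z[cbind(seq_len(nobs), animal)] <- 1
  Kinv <- solve(K)
  C <- rbind(cbind(crossprod(X), crossprod(X, Z)),
             cbind(crossprod(Z, X), crossprod(Z) + lambda * Kinv))
  rhs <- c(crossprod(X, y), crossprod(Z, y))
  sol <- solve(C, rhs)
  list(b = sol[seq_len(ncol(X))], u = sol[ncol(X) + seq_len(nk)])
}

# random topologically ordered pedigree: founders then two-parent animals
randomPedigree <- function(n, nFounders = 6, seed = 1) {
  set.seed(seed)
  sire <- integer(n); dam <- integer(n)
  sex <- c(rep(c("M", "F"), length.out = nFounders),
           sample(c("M", "F"), n - nFounders, replace = TRUE))
  for (i in (nFounders + 1):n) {
    males <- which(sex[seq_len(i - 1)] == "M")
    females <- which(sex[seq_len(i - 1)] == "F")
    sire[i] <- if (length(males) == 1) males else sample(males, 1)
    dam[i] <- if (length(females) == 1) females else sample(females, 1)
  }
  data.frame(id = seq_len(n), sire = sire, dam = dam, sex = sex)
}

# random symmetric positive definite metafounder matrix with diagonal < 4
randomGamma <- function(m, seed = 1) {
  set.seed(seed)
  B <- matrix(rnorm(m * m, sd = 0.3), m)
  G <- crossprod(B) + diag(0.3, m)
  sc <- max(diag(G))
  G * (0.6 / sc)
}
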