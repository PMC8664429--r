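## Independent oracles and small fixture builders used across the suite.

## direct restricted log-likelihood from the full V matrix (independent of
## the mixed-model-equations route used by reml_fit)
logreml_direct <- function(y, X, Vparts, theta) {
  n <- length(y)
  V <- matrix(0, n, n)
  for (i in seq_along(Vparts)) V <- V + theta[i] * Vparts[[i]]
  p <- qr(X)$rank
  Vi <- solve(V)
  XVX <- crossprod(X, Vi %*% X)
  P <- Vi - Vi %*% X %*% solve(XVX, crossprod(X, Vi))
  as.numeric(-0.5 * ((n - p) * log(2 * pi) +
                       determinant(V)$modulus +
                       determinant(XVX)$modulus +
                       crossprod(y, P %*% y)))
}

## brute-force linear kernel: explicit double loop over genotype pairs
linear_kernel_bruteforce <- function(X) {
  n <- nrow(X); m <- ncol(X)
  K <- matrix(0, n, n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      K[i, j] <- sum(X[i, ] * X[j, ]) / m
  K
}

## a small single-trial phenotype table with known genotype effects
tiny_trial <- function(n_geno = 6, n_rep = 2, g = NULL, mu = 10,
                       sigma_e = 1, site = "S1", year = 1, seed = 1) {
  set.seed(seed)
  ids <- sprintf("g%02d", seq_len(n_geno))
  if (is.null(g)) g <- stats::rnorm(n_geno)
  names(g) <- ids
  d <- expand.grid(genotype = ids, rep = paste0("R", seq_len(n_rep)),
                   stringsAsFactors = FALSE)
  d$site <- site
  d$year <- year
  d$Y <- mu + g[d$genotype] + stats::rnorm(nrow(d), 0, sigma_e)
  d
}

## random -1/0/1 marker matrix
random_markers <- function(n = 5, m = 8, seed = 1) {
  set.seed(seed)
  M <- matrix(sample(c(-1, 0, 1), n * m, replace = TRUE), n, m)
  rownames(M) <- sprintf("g%02d", seq_len(n))
  colnames(M) <- sprintf("m%02d", seq_len(m))
  M
}
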