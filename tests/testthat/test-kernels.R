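test_that("linear kernel matches closed forms and the brute-force oracle", {
  # all-heterozygote matrix -> zero kernel
  Z <- matrix(0, 3, 4, dimnames = list(paste0("g", 1:3), paste0("m", 1:4)))
  expect_equal(linear_kernel(Z), matrix(0, 3, 3,
    dimnames = list(paste0("g", 1:3), paste0("g", 1:3))), ignore_attr = TRUE)

  # single marker, genotypes 1 and -1 -> [[1,-1],[-1,1]]
  X1 <- matrix(c(1, -1), 2, 1, dimnames = list(c("a", "b"), "m1"))
  expect_equal(linear_kernel(X1),
               matrix(c(1, -1, -1, 1), 2, dimnames = list(c("a", "b"), c("a", "b"))),
               ignore_attr = TRUE)

  # random matrix vs explicit double loop
  M <- random_markers(5, 8, seed = 42)
  K <- linear_kernel(M)
  expect_lt(max(abs(unclass(K) - linear_kernel_bruteforce(M))), 1e-12)

  # 1/N scaling: duplicating every marker leaves the kernel unchanged
  expect_equal(unclass(linear_kernel(cbind(M, M))), unclass(K))

  # symmetry and PSD up to tolerance
  expect_true(isSymmetric(unclass(K)))
  expect_gt(min(eigen(unclass(K), symmetric = TRUE, only.values = TRUE)$values),
            -1e-8 * sum(diag(K)))
})

test_that("gaussian kernel limits, hand value, and monotonicity in h", {
  M <- random_markers(6, 10, seed = 7)
  expect_equal(gaussian_kernel(M, 0), matrix(1, 6, 6,
    dimnames = list(rownames(M), rownames(M))), ignore_attr = TRUE)

  # hand computation: squared distance between (1,1,-1) and (-1,1,-1) is 4
  X <- matrix(c(1, 1, -1, -1, 1, -1), 2, 3, byrow = TRUE,
              dimnames = list(c("a", "b"), paste0("m", 1:3)))
  K <- gaussian_kernel(X, 0.25)
  expect_equal(K["a", "b"], exp(-1), tolerance = 1e-12)
  expect_equal(diag(unclass(K)), c(a = 1, b = 1))

  # identity limit at large h (distinct genotypes)
  Kbig <- gaussian_kernel(M, 1e3)
  expect_lt(max(abs(unclass(Kbig)[upper.tri(Kbig)])), 1e-6)

  # entrywise monotone decreasing in h
  hs <- c(0.01, 0.05, 0.2, 1)
  Ks <- lapply(hs, function(h) unclass(gaussian_kernel(M, h)))
  for (i in seq_along(hs)[-1])
    expect_true(all(Ks[[i]] <= Ks[[i - 1]] + 1e-12))

  expect_error(gaussian_kernel(M, -1), "non-negative")
})

test_that("impute_and_filter applies thresholds and column-mean imputation", {
  M <- random_markers(5, 4, seed = 3)
  # complete matrix with maf_min 0 passes through unchanged
  out <- impute_and_filter(M, maf_min = 0, max_missing = 1)
  expect_equal(unclass(out)[, ], M[, ])

  # a marker that is 80% missing is dropped at max_missing = 0.2
  M2 <- M
  M2[1:4, 2] <- NA
  out2 <- impute_and_filter(M2, maf_min = 0, max_missing = 0.2)
  expect_false("m02" %in% colnames(out2))
  expect_equal(attr(out2, "qc_report")$removed_missing, 1L)

  # hand-computed column means fill the missing cells (columns given
  # explicitly: m01 misses row 4, m02 misses row 3)
  M3 <- cbind(m01 = c(1, -1, 1, NA, 0),
              m02 = c(0, 1, NA, -1, 1),
              m03 = c(1, 1, 1, 1, -1),
              m04 = c(-1, 0, 1, 0, 0))
  rownames(M3) <- paste0("g", 1:5)
  out3 <- impute_and_filter(M3, maf_min = 0, max_missing = 0.5)
  expect_equal(out3[4, "m01"], mean(c(1, -1, 1, 0)))
  expect_equal(out3[3, "m02"], mean(c(0, 1, -1, 1)))

  expect_error(impute_and_filter(M, maf_min = 0.6), "maf_min")
  Mall <- matrix(NA_real_, 3, 2, dimnames = list(letters[1:3], c("x", "y")))
  expect_error(impute_and_filter(Mall), "all markers removed")
})

test_that("bandwidth estimation: degenerate data, scale invariance, recovery", {
  M <- random_markers(100, 80, seed = 9)

  # flat likelihood (constant phenotypes) -> gamma prior mode (3-1)*1.5 = 3
  expect_warning(h0 <- estimate_bandwidth(M, rep(2, 100)), "prior mode")
  expect_equal(as.numeric(h0), 3.0)

  # doubling the phenotypes leaves the selected bandwidth unchanged
  set.seed(1)
  y <- rnorm(100)
  names(y) <- rownames(M)
  h1 <- estimate_bandwidth(M, y)
  h2 <- estimate_bandwidth(M, 2 * y)
  expect_equal(as.numeric(h1), as.numeric(h2))

  # recovery: data simulated from K at h* = 0.5/median distance is recovered
  # within a factor 3 in most replicates
  D2 <- outer(rowSums(M^2), rowSums(M^2), "+") - 2 * tcrossprod(M)
  hstar <- 0.5 / median(D2[upper.tri(D2)])
  Kstar <- exp(-hstar * D2)
  ch <- chol(Kstar + diag(1e-8, 100))
  hit <- 0
  n_rep <- 15
  for (i in seq_len(n_rep)) {
    set.seed(100 + i)
    ys <- as.vector(crossprod(ch, rnorm(100))) + rnorm(100, 0, 0.3)
    names(ys) <- rownames(M)
    hh <- attr(estimate_bandwidth(M, ys), "h_raw")
    if (hh > hstar / 3 && hh < hstar * 3) hit <- hit + 1
  }
  expect_gte(hit, 0.8 * n_rep)
})

test_that("site kernels: shared linear kernel, symmetric gaussian bandwidths", {
  M <- random_markers(30, 40, seed = 5)
  ph <- list(PAL = setNames(rnorm(30), rownames(M)),
             SRO = setNames(rnorm(30), rownames(M)))

  lin <- site_kernels(M, "linear", phenotypes = ph)
  expect_identical(unclass(lin$M0), unclass(lin$PAL))
  expect_identical(unclass(lin$M0), unclass(lin$SRO))

  # identical per-site phenotypes give identical bandwidths
  ph2 <- list(PAL = ph$PAL, SRO = ph$PAL)
  gau <- site_kernels(M, "gaussian", phenotypes = ph2)
  expect_equal(attr(gau$PAL, "bandwidth"), attr(gau$SRO, "bandwidth"))

  # different phenotypes: all three kernels PSD
  gau2 <- site_kernels(M, "gaussian", phenotypes = ph)
  for (K in gau2) {
    ev <- eigen(unclass(K), symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8 * sum(diag(K)))
  }
})
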