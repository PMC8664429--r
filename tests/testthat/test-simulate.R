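test_that("genotype simulation: determinism, fixation limit, frequency law", {
  cfg <- sim_config(n_genotypes = 50, n_markers = 120, seed = 42)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1[, ], g2[, ])
  expect_true(all(g1 %in% c(-1, 0, 1)))

  # zero residual heterozygosity: no heterozygote codes anywhere
  cfg0 <- sim_config(n_genotypes = 40, n_markers = 80,
                     residual_heterozygosity = 0, seed = 7)
  g0 <- simulate_genotypes(cfg0)
  expect_false(any(g0 == 0))

  # the generating allele frequencies follow the configured beta law
  # (Kolmogorov-Smirnov on the drawn per-marker frequencies, alpha = 0.01),
  # and the realised frequencies track them
  cfgb <- sim_config(n_genotypes = 400, n_markers = 10000,
                     residual_heterozygosity = 0, maf_shape = c(1, 3),
                     seed = 13)
  gb <- simulate_genotypes(cfgb)
  p <- attr(gb, "freq")
  ks <- suppressWarnings(ks.test(p, pbeta, 1, 3))
  expect_gt(ks$p.value, 0.01)
  p_hat <- colMeans((gb + 1) / 2)
  expect_lt(mean(abs(p_hat - p)), 0.03)
})

test_that("adjacent markers are correlated through the LD parameter", {
  cfg <- sim_config(n_genotypes = 500, n_markers = 200, n_chromosomes = 1,
                    ld_rho = 0.8, residual_heterozygosity = 0,
                    maf_shape = c(5, 5), seed = 9)
  g <- simulate_genotypes(cfg)
  adj <- sapply(seq_len(ncol(g) - 1), function(j)
    suppressWarnings(cor(g[, j], g[, j + 1])))
  far <- sapply(seq_len(ncol(g) - 50), function(j)
    suppressWarnings(cor(g[, j], g[, j + 50])))
  expect_gt(mean(adj, na.rm = TRUE), 0.3)
  expect_lt(abs(mean(far, na.rm = TRUE)), 0.15)
})

test_that("true values: degenerate correlation, Monte-Carlo recovery of r_g", {
  # r_g = 1: site effects identical up to scale
  cfg1 <- sim_config(n_genotypes = 100, n_markers = 100,
                     genetic_correlation = 1, seed = 5)
  tv1 <- simulate_true_values(simulate_genotypes(cfg1), cfg1)
  e <- tv1$site_effects
  expect_equal(cor(e[, 1], e[, 2]), 1, tolerance = 1e-10)

  # r_g = 0.6: empirical correlation within [0.5, 0.7] across seeds (enough
  # markers that the effective dimension does not inflate the spread)
  rs <- sapply(1:25, function(i) {
    cfg <- sim_config(n_genotypes = 334, n_markers = 600,
                      genetic_correlation = 0.6, seed = 1000 + i)
    tv <- simulate_true_values(simulate_genotypes(cfg), cfg)
    tv$r_g_empirical
  })
  expect_gte(mean(rs > 0.5 & rs < 0.7), 0.9)
})

test_that("trial simulation: noise-free limit and residual variance control", {
  # zero block and residual variance: plot value = site mean + rep shift +
  # true site effect, so within-replicate deviations equal the truth exactly
  sites0 <- list(PAL = site_config("PAL", 50, 0, 0, 0.99),
                 SRO = site_config("SRO", 40, 0, 0, 0.99))
  cfg <- sim_config(n_genotypes = 30, n_markers = 60, n_blocks = 3,
                    sites = sites0, seed = 3)
  ex <- simulate_experiment(cfg)
  d <- ex$phenotypes
  for (s in c("PAL", "SRO")) for (r in unique(d$rep)) {
    sub <- d[d$site == s & d$rep == r, ]
    dev <- sub$Y - mean(sub$Y)
    tru <- ex$truth$site_effects[sub$genotype, s]
    expect_lt(max(abs(dev - (tru - mean(tru)))), 1e-10)
  }

  # empirical residual variance within 10% of sigma2_residual at >= 1e4 plots
  # (block variance switched off so the within-genotype spread is residual)
  sitesv <- list(PAL = site_config("PAL", 88, 0, 9, 0.8),
                 SRO = site_config("SRO", 82, 0, 12, 0.8))
  cfgv <- sim_config(n_genotypes = 1700, n_markers = 50, sites = sitesv,
                     seed = 77)
  exv <- simulate_experiment(cfgv)
  dv <- exv$phenotypes
  for (s in c("PAL", "SRO")) {
    sub <- dv[dv$site == s, ]
    resid_var <- mean(tapply(sub$Y, sub$genotype, var))
    target <- cfgv$sites[[s]]$sigma2_residual
    expect_lt(abs(resid_var - target) / target, 0.10)
  }
})

test_that("trial-level H2 recovery hits the configured target", {
  # target repeatability 0.8 with 3 replicates: Model 1 estimates of the
  # entry-mean H2 land in [0.7, 0.9] for most seeds
  hits <- 0
  n_rep <- 12
  for (i in seq_len(n_rep)) {
    cfg <- sim_config(n_genotypes = 120, n_markers = 80, seed = 4000 + i)
    ex <- simulate_experiment(cfg)
    f <- fit_model1(ex$phenotypes, "Y", site = "SRO")
    h2 <- h2_trial(f$vc[["sigma2_g"]], f$vc[["sigma2_e"]], nr = 3)
    if (h2 >= 0.7 && h2 <= 0.9) hits <- hits + 1
  }
  expect_gte(hits, 0.8 * n_rep)
})

test_that("pipeline-level site correlation tracks the generating r_g", {
  # the adjusted-mean correlation is the genetic correlation attenuated by
  # the entry-mean reliabilities: with per-site H2 = 0.8 the expectation is
  # about 0.6 * 0.8 = 0.48, so seeds should land near that value
  rs <- sapply(1:6, function(i) {
    cfg <- sim_config(n_genotypes = 334, n_markers = 150,
                      genetic_correlation = 0.6, seed = 6000 + i)
    ex <- simulate_experiment(cfg)
    site_correlation(ex$phenotypes, "Y")$estimate
  })
  expect_gt(mean(rs), 0.38)
  expect_lt(mean(rs), 0.60)
  expect_gte(mean(rs >= 0.35 & rs <= 0.65), 0.8)
})

test_that("a second year shares genetics but not noise", {
  cfg <- sim_config(n_genotypes = 40, n_markers = 60, n_years = 2,
                    n_blocks = 4, seed = 12)
  ex <- simulate_experiment(cfg)
  d <- ex$phenotypes
  expect_setequal(unique(d$year), c(1, 2))
  expect_equal(nrow(d), 40 * 3 * 2 * 2)
  # genotype means correlate across years through the shared genetics
  m1 <- tapply(d$Y[d$year == 1 & d$site == "SRO"],
               d$genotype[d$year == 1 & d$site == "SRO"], mean)
  m2 <- tapply(d$Y[d$year == 2 & d$site == "SRO"],
               d$genotype[d$year == 2 & d$site == "SRO"], mean)
  expect_gt(cor(m1, m2[names(m1)]), 0.5)
})

test_that("null genetics emits a warning and zero variance truth", {
  cfg <- sim_config(n_genotypes = 20, n_markers = 10, seed = 2)
  g <- simulate_genotypes(cfg)
  g[] <- 0  # monomorphic, all-heterozygote: no genetic signal possible
  w <- capture_warnings(tv <- simulate_true_values(g, cfg))
  expect_true(any(grepl("null genetics", w)))  # one warning per site
  expect_equal(unname(tv$vc_truth$sigma2_g), 0)
})
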