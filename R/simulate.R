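#' Site configuration for the trial simulator
#'
#' @param name site label.
#' @param trait_mean site-level trait mean (trait units).
#' @param sigma2_block variance of the random incomplete-block effects (also
#'   used for the replicate shifts).
#' @param sigma2_residual plot residual variance for this site.
#' @param target_H2_trial trial-level repeatability the genetics are scaled
#'   to, in (0, 1\]; together with `sigma2_residual` and the number of
#'   replicates it fixes the per-site genotypic variance through the
#'   entry-mean identity `H2 = s2g / (s2g + s2e/NR)`.
#' @param year_shift additive site-wide shift applied to years after the
#'   first (`NULL`: drawn once per later year from `N(0, sigma2_residual)`).
#' @return list of class `site_config`.
#' @export
site_config <- function(name, trait_mean = 0, sigma2_block = 1,
                        sigma2_residual = 9, target_H2_trial = 0.8,
                        year_shift = NULL) {
  if (sigma2_block < 0 || sigma2_residual < 0) stop("variances must be >= 0")
  if (target_H2_trial <= 0 || target_H2_trial > 1)
    stop("target_H2_trial must lie in (0, 1]")
  structure(list(name = name, trait_mean = trait_mean,
                 sigma2_block = sigma2_block,
                 sigma2_residual = sigma2_residual,
                 target_H2_trial = target_H2_trial,
                 year_shift = year_shift), class = "site_config")
}

#' Configuration of the two-site trial simulator
#'
#' The defaults emulate the design of an early-generation two-site rice
#' recurrent-selection trial: 334 candidate genotypes, biallelic SNPs on 12
#' chromosomes, two sites with distinct means and residual variances, a
#' lattice of 16 incomplete blocks in each of 3 replicates per site, per-site
#' trial repeatability set through `target_H2_trial`, and a configurable
#' genetic correlation between the two sites' genotypic values.
#'
#' @param n_genotypes number of genotypes (default 334).
#' @param n_markers number of SNPs (default 992; scalable).
#' @param n_chromosomes chromosomes the markers are spread over (default 12).
#' @param maf_shape two beta-shape parameters for the per-marker alternate
#'   allele frequency (default `c(1, 3)`, skewed towards rare alleles).
#' @param residual_heterozygosity marker-wise i.i.d. probability that a call
#'   is heterozygous (code 0); default 0.05.
#' @param ld_rho first-order (AR1) correlation of allele states between
#'   adjacent markers on a chromosome, a cheap stand-in for LD (default 0.5).
#' @param sites named list of two [site_config()] objects.
#' @param n_replicates replicates per site (default 3).
#' @param n_blocks incomplete blocks per replicate (default 16); plots per
#'   block default to `ceiling(n_genotypes / n_blocks)`.
#' @param genetic_correlation correlation `r_g` in \[-1, 1\] between the two
#'   sites' true genotypic values (default 0.6).
#' @param n_years years to simulate (default 1); later years reuse the same
#'   genetics (zero generation effect) with a site-wide shift and fresh
#'   block/residual draws.
#' @param trait name of the simulated trait column (default `"Y"`).
#' @param seed integer seed; all generator output is bit-reproducible given
#'   the seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_genotypes = 334L, n_markers = 992L,
                       n_chromosomes = 12L, maf_shape = c(1, 3),
                       residual_heterozygosity = 0.05, ld_rho = 0.5,
                       sites = list(
                         PAL = site_config("PAL", trait_mean = 88,
                                           sigma2_residual = 9,
                                           target_H2_trial = 0.8),
                         SRO = site_config("SRO", trait_mean = 82,
                                           sigma2_residual = 12,
                                           target_H2_trial = 0.8)),
                       n_replicates = 3L, n_blocks = 16L,
                       genetic_correlation = 0.6, n_years = 1L,
                       trait = "Y", seed = 1L) {
  if (length(sites) != 2L) stop("exactly two sites are required")
  if (is.null(names(sites)))
    names(sites) <- vapply(sites, `[[`, character(1), "name")
  if (abs(genetic_correlation) > 1) stop("genetic_correlation must lie in [-1, 1]")
  if (residual_heterozygosity < 0 || residual_heterozygosity > 1)
    stop("residual_heterozygosity must lie in [0, 1]")
  if (abs(ld_rho) >= 1) stop("ld_rho must lie in (-1, 1)")
  ppb <- ceiling(n_genotypes / n_blocks)
  if (n_blocks * ppb < n_genotypes) stop("blocks cannot hold all genotypes")
  structure(list(n_genotypes = as.integer(n_genotypes),
                 n_markers = as.integer(n_markers),
                 n_chromosomes = as.integer(n_chromosomes),
                 maf_shape = maf_shape,
                 residual_heterozygosity = residual_heterozygosity,
                 ld_rho = ld_rho, sites = sites,
                 n_replicates = as.integer(n_replicates),
                 n_blocks = as.integer(n_blocks),
                 plots_per_block = as.integer(ppb),
                 genetic_correlation = genetic_correlation,
                 n_years = as.integer(n_years), trait = trait,
                 seed = as.integer(seed)), class = "sim_config")
}

#' Simulate a -1/0/1 genotype matrix
#'
#' Per-marker alternate allele frequencies are drawn from the configured beta
#' distribution; allele states along a chromosome follow a first-order
#' Gaussian-copula dependence (`ld_rho`) to mimic linkage disequilibrium;
#' heterozygous calls are overlaid marker-wise i.i.d. with probability
#' `residual_heterozygosity`.  Monomorphic markers are retained but flagged.
#'
#' @param config a [sim_config()].
#' @return genotype x marker matrix coded -1/0/1 with attributes `map`
#'   (chromosome, position), `freq` (the generating alternate allele
#'   frequencies) and `monomorphic` (ids of observed zero-variance markers).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genotypes
  m <- config$n_markers
  rho <- config$ld_rho
  p <- stats::rbeta(m, config$maf_shape[1], config$maf_shape[2])
  p <- pmin(pmax(p, 1e-4), 1 - 1e-4)
  chrom <- sort(rep_len(seq_len(config$n_chromosomes), m))
  Z <- matrix(NA_real_, n, m)
  for (cc in unique(chrom)) {
    cols <- which(chrom == cc)
    Zc <- matrix(stats::rnorm(n * length(cols)), n, length(cols))
    for (j in seq_along(cols)[-1])
      Zc[, j] <- rho * Zc[, j - 1] + sqrt(1 - rho^2) * Zc[, j]
    Z[, cols] <- Zc
  }
  thr <- stats::qnorm(p)
  G <- ifelse(sweep(Z, 2, thr, "<"), 1, -1)
  if (config$residual_heterozygosity > 0) {
    het <- matrix(stats::runif(n * m) < config$residual_heterozygosity, n, m)
    G[het] <- 0
  }
  dimnames(G) <- list(sprintf("G%03d", seq_len(n)), sprintf("M%05d", seq_len(m)))
  pos <- stats::ave(seq_len(m), chrom, FUN = seq_along)
  mono <- colnames(G)[apply(G, 2, function(x) length(unique(x)) == 1L)]
  structure(G,
            map = data.frame(marker = colnames(G), chrom = chrom,
                             pos = as.integer(pos) * 1000L),
            freq = p, monomorphic = mono)
}

#' Simulate true genotypic values for two sites
#'
#' Marker effects for the two sites are drawn from a bivariate normal with
#' the configured correlation `r_g`, so that the correlation of the resulting
#' genotypic values across sites converges to `r_g`.  Each site's genotypic
#' values are rescaled so that the trial-level repeatability implied by the
#' site's residual variance and the number of replicates hits
#' `target_H2_trial`.  The genotype main effect is the across-site mean; the
#' genotype-by-site effects are the deviations from it.
#'
#' @param markers matrix from [simulate_genotypes()].
#' @param config the matching [sim_config()].
#' @return list of class `true_values` with `main` (named vector g),
#'   `site_effects` (genotype x site matrix of g + gs), `gs` (deviations),
#'   `vc_truth` (the generating variance set per site) and `r_g_empirical`.
#' @export
simulate_true_values <- function(markers, config) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(markers) != config$n_genotypes)
    stop("marker matrix and config disagree on the number of genotypes")
  set.seed(config$seed + 1L)
  rg <- config$genetic_correlation
  m <- ncol(markers)
  sites <- config$sites
  n <- nrow(markers)

  ## per-site genotypic variance implied by the repeatability target
  v_site <- vapply(1:2, function(k) {
    sc <- sites[[k]]
    h2 <- sc$target_H2_trial
    if (h2 >= 1) 1 else h2 / (1 - h2) * sc$sigma2_residual / config$n_replicates
  }, numeric(1))

  ## marker-effect vectors through the genome: one shared component (the
  ## genotype main effect) plus one independent component per site (the
  ## genotype-by-site deviations)
  raw <- markers %*% matrix(stats::rnorm(3 * m), m, 3)
  null_sites <- apply(raw, 2, stats::var) <= 0
  if (any(null_sites))
    for (k in 1:2) warning("all marker effects are zero for site ",
                           sites[[k]]$name,
                           ": null genetics, H2 target unreachable")
  scale_to <- function(x, v) {
    vx <- stats::var(x)
    if (vx <= 0 || v <= 0) return(rep(0, length(x)))
    (x - mean(x)) * sqrt(v / vx)
  }

  if (rg >= 0 && rg < 1) {
    ## orthogonal decomposition: var(g) = r_g * sqrt(v1 v2),
    ## var(gs_s) = v_s - var(g); reproduces cor(site1, site2) = r_g
    vg <- rg * sqrt(v_site[1] * v_site[2])
    vgs <- v_site - vg
    if (any(vgs < 0)) {
      warning("genetic correlation too high for the per-site variance ",
              "targets; interaction variance clamped at zero")
      vgs <- pmax(vgs, 0)
    }
    main <- scale_to(raw[, 1], vg)
    gs <- cbind(scale_to(raw[, 2], vgs[1]), scale_to(raw[, 3], vgs[2]))
    eff <- main + gs
  } else {
    ## degenerate or negative correlation: scale a correlated pair directly
    Z <- raw[, 2:3]
    if (abs(rg) >= 1) Z[, 2] <- sign(rg) * Z[, 1]
    else {
      S <- matrix(c(1, rg, rg, 1), 2)
      Z <- matrix(stats::rnorm(2 * m), m, 2)
      Z <- markers %*% (Z %*% chol(S))
    }
    eff <- cbind(scale_to(Z[, 1], v_site[1]), scale_to(Z[, 2], v_site[2]))
    main <- rowMeans(eff)
    gs <- eff - main
  }
  dimnames(eff) <- list(rownames(markers), names(sites))
  dimnames(gs) <- dimnames(eff)
  names(main) <- rownames(markers)

  vc <- lapply(1:2, function(k)
    list(sigma2_g_site = stats::var(eff[, k]),
         sigma2_residual = sites[[k]]$sigma2_residual,
         sigma2_block = sites[[k]]$sigma2_block,
         target_H2_trial = sites[[k]]$target_H2_trial))
  names(vc) <- names(sites)
  r_emp <- if (all(apply(eff, 2, stats::var) > 0))
    stats::cor(eff[, 1], eff[, 2]) else NA_real_
  structure(list(main = main, site_effects = eff, gs = gs,
                 vc_truth = c(vc, list(
                   sigma2_g = stats::var(main),
                   sigma2_gs = apply(gs, 2, stats::var),
                   genetic_correlation = rg)),
                 r_g_empirical = r_emp), class = "true_values")
}

#' Simulate plot-level phenotypes for the two-site lattice trial
#'
#' Generates one record per genotype x replicate x site x year:
#' `Y = site mean (+ year shift) + replicate shift + block effect + true site
#' effect + residual`, with genotypes assigned at random to the incomplete
#' blocks of each replicate (fresh randomisation per replicate, site and
#' year), block effects drawn from `N(0, sigma2_block)` and residuals from
#' the site-specific `N(0, sigma2_residual)`.  Later years reuse the same
#' genetic values (zero generation effect) with new block and residual draws
#' and a site-wide year shift.
#'
#' @param truth a [simulate_true_values()] result.
#' @param config the matching [sim_config()].
#' @return plot-level phenotype data.frame (`genotype`, `site`, `year`,
#'   `rep`, `block`, trait column).
#' @export
simulate_trial <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "true_values"))
  n <- config$n_genotypes
  if (length(truth$main) != n)
    stop("truth and config disagree on the number of genotypes")
  set.seed(config$seed + 2L)
  if (n %% config$n_blocks != 0L)
    message("note: ", n, " genotypes do not fill ", config$n_blocks,
            " blocks evenly; blocks are left unbalanced")
  ids <- names(truth$main)
  out <- vector("list", 0L)
  for (yy in seq_len(config$n_years)) {
    for (sn in names(config$sites)) {
      sc <- config$sites[[sn]]
      shift <- if (yy == 1L) 0 else {
        if (!is.null(sc$year_shift)) sc$year_shift * (yy - 1L)
        else stats::rnorm(1, 0, sqrt(sc$sigma2_residual))
      }
      for (rr in seq_len(config$n_replicates)) {
        blk <- rep(seq_len(config$n_blocks),
                   each = config$plots_per_block)[seq_len(n)]
        blk <- blk[sample.int(n)]
        beff <- stats::rnorm(config$n_blocks, 0, sqrt(sc$sigma2_block))
        reff <- stats::rnorm(1, 0, sqrt(sc$sigma2_block))
        y <- sc$trait_mean + shift + reff + beff[blk] +
          truth$site_effects[, sn] +
          stats::rnorm(n, 0, sqrt(sc$sigma2_residual))
        out[[length(out) + 1L]] <- data.frame(
          genotype = ids, site = sn, year = yy,
          rep = paste0("R", rr), block = paste0("B", blk),
          stringsAsFactors = FALSE,
          check.names = FALSE,
          Y = as.numeric(y))
      }
    }
  }
  out <- do.call(rbind, out)
  names(out)[names(out) == "Y"] <- config$trait
  rownames(out) <- NULL
  out
}

#' Run the full simulator
#'
#' Convenience wrapper chaining [simulate_genotypes()],
#' [simulate_true_values()] and [simulate_trial()].
#'
#' @param config a [sim_config()].
#' @return list with `genotypes`, `truth`, `phenotypes` and `config`.
#' @export
simulate_experiment <- function(config) {
  g <- simulate_genotypes(config)
  tv <- simulate_true_values(g, config)
  ph <- simulate_trial(tv, config)
  list(genotypes = g, truth = tv, phenotypes = ph, config = config)
}
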