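#' Harmonic mean
#'
#' `n / sum(1/x)` for positive counts; used for the effective number of plots
#' (`NR`) and sites (`NE`) per genotype on an entry-mean basis.
#'
#' @param x vector of positive counts.
#' @return the harmonic mean (numeric scalar).
#' @export
harmonic_mean <- function(x) {
  if (length(x) == 0L) stop("empty input")
  if (any(is.na(x)) || any(x <= 0)) stop("all counts must be positive")
  length(x) / sum(1 / x)
}

#' Effective replication of a design
#'
#' Computes, from a plot-level phenotype table, the harmonic mean number of
#' plots per genotype (`NR`) and of sites per genotype (`NE`) for one trait
#' (records with missing trait values do not count).  The balanced two-site,
#' three-replicate lattice gives `NR = 6` and `NE = 2`.
#'
#' @inheritParams fit_model1
#' @return list with elements `NR` and `NE`.
#' @export
design_harmonic_means <- function(data, trait, year = NULL) {
  data <- .check_pheno(data, trait)
  data <- .subset_pheno(data, trait, year = year)
  plots <- table(data$genotype)
  sites <- tapply(data$site, data$genotype, function(s) length(unique(s)))
  list(NR = harmonic_mean(as.integer(plots)),
       NE = harmonic_mean(as.integer(sites)))
}

#' Trial-level repeatability
#'
#' Broad-sense heritability of a single trial (generation within site), used
#' as a measure of repeatability:
#' \deqn{H^2 = \frac{\sigma^2_g}{\sigma^2_g + \sigma^2_\varepsilon / NR}}
#' with `NR` the harmonic mean number of plots per genotype.
#'
#' @param sigma2_g genotypic variance.
#' @param sigma2_e residual variance.
#' @param nr harmonic mean number of plots per genotype (>= 1).
#' @return repeatability in \[0, 1\].
#' @export
h2_trial <- function(sigma2_g, sigma2_e, nr) {
  .check_vc(c(sigma2_g, sigma2_e))
  if (nr < 1) stop("NR must be >= 1")
  den <- sigma2_g + sigma2_e / nr
  if (den <= 0) stop("all variance components are zero: H2 undefined")
  sigma2_g / den
}

#' Global two-site broad-sense heritability
#'
#' Entry-mean heritability across the two sites of one year, from the Model 2
#' variance components:
#' \deqn{H^2 = \frac{\sigma^2_g}{\sigma^2_g +
#'   (\sigma^2_{gs,s_1} + \sigma^2_{gs,s_2})/NE +
#'   (\sigma^2_{\varepsilon,s_1} + \sigma^2_{\varepsilon,s_2})/NR}}
#' where `NE` and `NR` are the harmonic mean numbers of sites and plots per
#' genotype (2 and 6 for the balanced two-site, three-replicate design).
#'
#' @param sigma2_g genotypic variance.
#' @param sigma2_gs length-2 vector of genotype-by-site interaction variances.
#' @param sigma2_e length-2 vector of site-specific residual variances.
#' @param ne harmonic mean number of sites per genotype, in \[1, 2\].
#' @param nr harmonic mean number of plots per genotype (>= 1).
#' @return heritability in \[0, 1\].
#' @export
h2_global <- function(sigma2_g, sigma2_gs, sigma2_e, ne = 2, nr = 6) {
  if (length(sigma2_gs) != 2L || length(sigma2_e) != 2L)
    stop("sigma2_gs and sigma2_e must each have one value per site (length 2)")
  .check_vc(c(sigma2_g, sigma2_gs, sigma2_e))
  if (ne < 1 || ne > 2) stop("NE must lie in [1, 2]")
  if (nr < 1) stop("NR must be >= 1")
  den <- sigma2_g + sum(sigma2_gs) / ne + sum(sigma2_e) / nr
  if (den <= 0) stop("all variance components are zero: H2 undefined")
  sigma2_g / den
}

.check_vc <- function(v) {
  if (any(is.na(v)) || any(v < 0)) stop("variance components must be non-negative")
  invisible(v)
}

#' Variance decomposition table
#'
#' Expresses each variance component of a fitted two-site model (genotype,
#' genotype-by-site per site, block, residual per site) as a proportion of
#' their sum; proportions add to 1.
#'
#' @param fit a `gp_fit` from [fit_model2()], or a named numeric vector of
#'   variance components.
#' @return data.frame with columns `component`, `variance`, `proportion`.
#' @export
variance_proportions <- function(fit) {
  vc <- if (inherits(fit, "gp_fit")) fit$vc else fit
  if (!is.numeric(vc) || is.null(names(vc))) stop("need a gp_fit or a named numeric vector")
  .check_vc(vc)
  data.frame(component = names(vc), variance = unname(vc),
             proportion = unname(vc) / sum(vc), row.names = NULL)
}

#' Round half away from zero
#'
#' Decimal rounding with halves going up (0.625 -> 0.63), the convention used
#' when comparing computed heritabilities and variance proportions against
#' values printed to two decimals (base R's `round()` rounds half to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded vector.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Reference variance components from a published two-site rice trial
#'
#' Model 2 REML variance components (genotype, genotype-by-site and residual
#' per site, block) for four traits (FL, PH, YLD, ZN) measured over two years
#' in a two-site, three-replicate rice breeding trial of 334 families, as
#' printed in the source study together with the derived variance proportions
#' and global heritabilities.  Components printed as "<0.001" are stored as 0.
#' Shipped as a plain-text table and used to validate the heritability and
#' variance-proportion identities.
#'
#' @return data.frame with columns `trait`, `year`, `component`, `variance`,
#'   `proportion`, `H2` (H2 given on the genotype row only).
#' @export
reference_variance_components <- function() {
  path <- system.file("extdata", "two_site_variance_components.csv",
                      package = "gptrial", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
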