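#' Quality-control, imputation and filtering of a marker matrix
#'
#' Markers are biallelic SNPs coded -1 (homozygous reference), 0
#' (heterozygous) and 1 (homozygous alternate), genotypes in rows.  Markers
#' failing the minor-allele-frequency or missingness thresholds are removed;
#' remaining missing cells are replaced by the marker mean (so imputed values
#' may be fractional in \[-1, 1\]).
#'
#' @param markers genotype x marker matrix coded -1/0/1 with `NA` allowed;
#'   rownames are genotype ids, colnames marker ids.
#' @param maf_min minimum minor allele frequency in \[0, 0.5\] (default 0.01).
#' @param max_missing maximum per-marker missing fraction in \[0, 1\].
#' @return the filtered, imputed matrix with attributes `qc_report` (kept and
#'   removed counts) and `monomorphic` (ids of retained zero-variance
#'   markers, when `maf_min = 0`) and `imputed` (logical, whether any cell
#'   was imputed).
#' @export
impute_and_filter <- function(markers, maf_min = 0.01, max_missing = 0.2) {
  markers <- .check_markers(markers, allow_missing = TRUE)
  if (maf_min < 0 || maf_min > 0.5) stop("maf_min must lie in [0, 0.5]")
  if (max_missing < 0 || max_missing > 1) stop("max_missing must lie in [0, 1]")
  n <- nrow(markers)
  miss <- colMeans(is.na(markers))
  p_alt <- colMeans((markers + 1) / 2, na.rm = TRUE)
  p_alt[is.nan(p_alt)] <- 0
  maf <- pmin(p_alt, 1 - p_alt)
  keep <- miss <= max_missing & maf >= maf_min
  if (!any(keep)) stop("all markers removed by the QC thresholds")
  out <- markers[, keep, drop = FALSE]
  imputed <- FALSE
  if (anyNA(out)) {
    cm <- colMeans(out, na.rm = TRUE)
    idx <- which(is.na(out), arr.ind = TRUE)
    out[idx] <- cm[idx[, 2]]
    imputed <- TRUE
  }
  mono <- colnames(out)[apply(out, 2, function(x) length(unique(x)) == 1L)]
  attr(out, "qc_report") <- list(
    n_in = length(keep), n_kept = sum(keep), n_removed = sum(!keep),
    removed_maf = sum(maf < maf_min & miss <= max_missing),
    removed_missing = sum(miss > max_missing))
  attr(out, "monomorphic") <- mono
  attr(out, "imputed") <- imputed
  out
}

.check_markers <- function(markers, allow_missing = FALSE) {
  markers <- as.matrix(markers)
  if (!is.numeric(markers)) stop("marker matrix must be numeric")
  if (ncol(markers) < 1L) stop("empty marker set")
  if (!allow_missing && anyNA(markers))
    stop("marker matrix contains missing values; run impute_and_filter() first")
  rng <- suppressWarnings(range(markers, na.rm = TRUE))
  if (is.finite(rng[1]) && (rng[1] < -1 || rng[2] > 1))
    stop("marker codes must lie in [-1, 1] (-1/0/1 coding, fractional imputed values allowed)")
  if (is.null(rownames(markers)))
    rownames(markers) <- paste0("G", seq_len(nrow(markers)))
  markers
}

#' Linear (GBLUP) genomic kernel
#'
#' Computes the genomic relationship matrix \eqn{M = XX'/N} from the
#' -1/0/1-coded marker matrix \eqn{X} with \eqn{N} markers, proportional to
#' the classical VanRaden matrix.  The same kernel is used for the genotype
#' main effect and, in the two-site model, for both genotype-by-site
#' interaction terms.
#'
#' @param markers complete genotype x marker matrix (see [impute_and_filter()]).
#' @return a `genomic_kernel`: symmetric PSD genotype x genotype matrix with
#'   attributes `kind = "linear"` and dimnames set to genotype ids.
#' @export
linear_kernel <- function(markers) {
  X <- .check_markers(markers)
  K <- tcrossprod(X) / ncol(X)
  K <- (K + t(K)) / 2
  dimnames(K) <- list(rownames(X), rownames(X))
  structure(K, kind = "linear", class = c("genomic_kernel", class(K)))
}

#' Gaussian (RKHS) genomic kernel
#'
#' Computes \eqn{K_{mn} = \exp(-h \, \lVert x_m - x_n \rVert^2)} between the
#' marker vectors of every pair of genotypes.  The bandwidth `h` controls the
#' decay rate of the covariance with genetic distance: `h = 0` gives an
#' all-ones matrix, large `h` approaches the identity.  The diagonal is
#' exactly 1.
#'
#' @inheritParams linear_kernel
#' @param h non-negative bandwidth.
#' @return a `genomic_kernel` with attributes `kind = "gaussian"` and
#'   `bandwidth = h`.
#' @export
gaussian_kernel <- function(markers, h) {
  X <- .check_markers(markers)
  if (length(h) != 1L || is.na(h) || h < 0) stop("bandwidth h must be a single non-negative number")
  D2 <- .squared_distances(X)
  K <- exp(-h * D2)
  K <- (K + t(K)) / 2
  diag(K) <- 1
  dimnames(K) <- list(rownames(X), rownames(X))
  structure(K, kind = "gaussian", bandwidth = h,
            class = c("genomic_kernel", class(K)))
}

.squared_distances <- function(X) {
  sq <- rowSums(X^2)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(X)
  D2[D2 < 0] <- 0
  D2
}

#' Maximum a posteriori bandwidth for the Gaussian kernel
#'
#' Selects the bandwidth `h` of the Gaussian kernel by maximising, over a
#' log-spaced candidate grid, the restricted (marginal) likelihood of the
#' one-random-effect model \eqn{y = 1\mu + u + e}, \eqn{u \sim N(0, K_h
#' \sigma^2_u)}, profiled over \eqn{(\sigma^2_u, \sigma^2_e)}, plus the log
#' density of a gamma prior on `h`.  The phenotypes are BLUP-adjusted
#' genotype means; in cross-validation the bandwidth is re-estimated at each
#' cycle from the training set only.  The candidate grid spans
#' `[1e-3, 1e2] / median(squared distances)`; ties break to the smaller `h`.
#'
#' @inheritParams linear_kernel
#' @param phenotypes named numeric vector of per-genotype adjusted phenotypes
#'   aligned to `rownames(markers)` (order-matched by name when named).
#' @param prior_shape,prior_scale shape and scale of the gamma prior on the
#'   standardized `h` (defaults 3 and 1.5; prior mode
#'   `(shape - 1) * scale = 3`).
#' @param grid_length number of log-spaced candidate values.
#' @return the selected bandwidth on the standardized-distance scale (the
#'   scale the gamma prior presupposes: squared distances divided by their
#'   median, so that usable bandwidths are of order 1), with attributes
#'   `h_raw` (the equivalent bandwidth for raw squared distances,
#'   `h / median`, the value to pass to [gaussian_kernel()]),
#'   `median_sq_dist`, and `grid` (data.frame of candidates and log-posterior
#'   values).  With a constant phenotype vector the likelihood is flat and
#'   the prior mode is returned with a warning.
#' @export
estimate_bandwidth <- function(markers, phenotypes, prior_shape = 3,
                               prior_scale = 1.5, grid_length = 50L) {
  X <- .check_markers(markers)
  if (prior_shape <= 0 || prior_scale <= 0) stop("prior parameters must be positive")
  y <- phenotypes
  if (!is.null(names(y))) {
    if (!all(rownames(X) %in% names(y)))
      stop("phenotypes missing for some genotypes")
    y <- y[rownames(X)]
  }
  if (length(y) != nrow(X)) stop("phenotypes must align with the genotypes")
  if (length(y) < 3L) stop("need at least 3 genotypes")
  D2 <- .squared_distances(X)
  med <- stats::median(D2[upper.tri(D2)])
  if (!is.finite(med) || med <= 0) med <- 1
  mode_h <- max(prior_shape - 1, 0) * prior_scale
  if (stats::var(y) <= .Machine$double.eps * max(1, mean(y)^2)) {
    warning("constant phenotype vector: likelihood is flat, returning the prior mode")
    return(structure(mode_h, h_raw = mode_h / med, median_sq_dist = med,
                     grid = NULL))
  }
  D2s <- D2 / med
  grid <- exp(seq(log(1e-3), log(1e2), length.out = grid_length))
  obj <- vapply(grid, function(h) {
    K <- exp(-h * D2s)
    diag(K) <- 1
    .profiled_logreml_1rand(y, K) +
      stats::dgamma(h, shape = prior_shape, scale = prior_scale, log = TRUE)
  }, numeric(1))
  best <- which(obj >= max(obj, na.rm = TRUE) - 1e-12)[1L]  # tie -> smaller h
  structure(grid[best], h_raw = grid[best] / med, median_sq_dist = med,
            grid = data.frame(h = grid, log_posterior = obj))
}

## restricted likelihood of y = 1*mu + u + e, u ~ N(0, s2u K), e ~ N(0, s2e I),
## profiled over (s2u, s2e) through the eigendecomposition of K.
.profiled_logreml_1rand <- function(y, K) {
  n <- length(y)
  eg <- eigen(K, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  yt <- as.vector(crossprod(U, y))
  ones <- as.vector(crossprod(U, rep(1, n)))
  ## REML loglik as a function of the ratio lambda = s2u/s2e, s2e profiled out
  f <- function(loglam) {
    lam <- exp(loglam)
    v <- 1 + lam * d
    xvx <- sum(ones^2 / v)
    bh <- sum(ones * yt / v) / xvx
    r <- yt - bh * ones
    ss <- sum(r^2 / v)
    s2e <- ss / (n - 1)
    -0.5 * ((n - 1) * log(2 * pi) + (n - 1) * log(s2e) + sum(log(v)) +
              log(xvx) + ss / s2e)
  }
  opt <- stats::optimize(f, interval = c(-25, 25), maximum = TRUE, tol = 1e-8)
  opt$objective
}

#' Genotype covariance structures for the two-site model
#'
#' Builds the variance-covariance structures used by the two-site mixed
#' model: one kernel for the complete data (`M0`, the genotype main effect)
#' and one per site (for the genotype-by-site interaction terms).  For the
#' linear (GBLUP) kernel the three structures are one and the same matrix
#' (`M = M_site1 = M_site2`).  For the Gaussian (RKHS) kernel each structure
#' gets its own bandwidth, estimated from the corresponding BLUP-adjusted
#' phenotypes: per-site vectors for the site kernels, their across-site
#' genotype mean for `M0`.
#'
#' @inheritParams linear_kernel
#' @param method `"linear"` or `"gaussian"`.
#' @param phenotypes for `method = "gaussian"`: a named list with one
#'   per-genotype adjusted-phenotype vector per site (names are site labels).
#' @param prior_shape,prior_scale gamma prior for bandwidth estimation.
#' @return named list of `genomic_kernel` objects: `M0` plus one entry per
#'   site label (for `"linear"` all entries are the same kernel).
#' @export
site_kernels <- function(markers, method = c("linear", "gaussian"),
                         phenotypes = NULL, prior_shape = 3, prior_scale = 1.5) {
  method <- match.arg(method)
  if (method == "linear") {
    K <- linear_kernel(markers)
    sites <- names(phenotypes)
    if (is.null(sites)) sites <- c("site1", "site2")
    out <- c(list(M0 = K), stats::setNames(rep(list(K), length(sites)), sites))
    return(out)
  }
  if (is.null(phenotypes) || is.null(names(phenotypes)))
    stop("gaussian site kernels need a named list of per-site adjusted phenotypes")
  X <- .check_markers(markers)
  per_site <- lapply(names(phenotypes), function(s) {
    ph <- phenotypes[[s]]
    ids <- intersect(rownames(X), names(ph))
    if (length(ids) < 3L) stop("site label mismatch or too few phenotyped genotypes for site ", s)
    h <- estimate_bandwidth(X[ids, , drop = FALSE], ph[ids],
                            prior_shape = prior_shape, prior_scale = prior_scale)
    gaussian_kernel(X, attr(h, "h_raw"))
  })
  names(per_site) <- names(phenotypes)
  ## main-effect kernel: bandwidth from the across-site mean adjusted phenotype
  all_ids <- rownames(X)
  mat <- sapply(phenotypes, function(ph) ph[match(all_ids, names(ph))])
  y0 <- rowMeans(mat, na.rm = TRUE)
  names(y0) <- all_ids
  ok <- !is.nan(y0)
  h0 <- estimate_bandwidth(X[ok, , drop = FALSE], y0[ok],
                           prior_shape = prior_shape, prior_scale = prior_scale)
  c(list(M0 = gaussian_kernel(X, attr(h0, "h_raw"))), per_site)
}

#' @export
print.genomic_kernel <- function(x, ...) {
  cat(attr(x, "kind"), "genomic kernel over", nrow(x), "genotypes")
  if (!is.null(attr(x, "bandwidth")))
    cat(", bandwidth", signif(attr(x, "bandwidth"), 4))
  cat("\n")
  invisible(x)
}
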