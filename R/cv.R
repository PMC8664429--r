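#' Cross-validation configuration
#'
#' Describes one cell of the sparse-testing cross-validation design used to
#' score predictive ability in the target site: a scheme (`SIN`: single-site
#' calibration, Model 1; `BAL1`/`BAL2`/`IMB`: two-site calibrations, Model
#' 2), a training set size `s`, the number of random samplings, the fixed
#' validation-set size, the genomic prediction method and a master seed.
#'
#' @param scheme one of `"SIN"`, `"BAL1"`, `"BAL2"`, `"IMB"`.
#' @param s training set size per site (typical grid: 25, 50, 100, 200).
#' @param n_iterations number of alternative samplings (default 100).
#' @param validation_size number of predicted genotypes the correlation is
#'   computed on (default 100; automatically reduced when fewer untrained
#'   genotypes remain, e.g. 34 for BAL2 with `s = 200` on 334 genotypes).
#' @param target_site label of the site predictions are scored in.
#' @param gp_method `"gblup"` (linear kernel) or `"rkhs"` (Gaussian kernel
#'   with per-cycle bandwidth re-estimation from the training set's
#'   BLUP-adjusted phenotypes).
#' @param trait,year trait column and year to analyse.
#' @param include_interaction include the target-site interaction BLUP in the
#'   two-site GEBV (default `TRUE`).
#' @param master_seed integer; spawns one reproducible sampling stream per
#'   iteration.
#' @return list of class `cv_config`.
#' @export
cv_config <- function(scheme = c("SIN", "BAL1", "BAL2", "IMB"), s,
                      n_iterations = 100L, validation_size = 100L,
                      target_site = "SRO", gp_method = c("gblup", "rkhs"),
                      trait = "Y", year = 1L, include_interaction = TRUE,
                      master_seed = 1L) {
  scheme <- match.arg(scheme)
  gp_method <- match.arg(gp_method)
  if (s < 3L) stop("training set size s must be at least 3")
  structure(list(scheme = scheme, s = as.integer(s),
                 n_iterations = as.integer(n_iterations),
                 validation_size = as.integer(validation_size),
                 target_site = target_site, gp_method = gp_method,
                 trait = trait, year = year,
                 include_interaction = include_interaction,
                 master_seed = as.integer(master_seed)), class = "cv_config")
}

#' Draw one training/validation partition
#'
#' Implements the four sparse-testing schemes.  `SIN`: `s` genotypes
#' phenotyped in the target site only.  `BAL1`: the same `s` genotypes
#' phenotyped in both sites.  `BAL2`: `s` genotypes phenotyped per site with
#' a 50% overlap, i.e. `floor(s/2)` genotypes shared and `s - floor(s/2)`
#' exclusive to each site, `2s - floor(s/2)` distinct genotypes in total.
#' `IMB`: the whole population phenotyped in the other site and only `s` of
#' them in the target site.  The validation set is sampled from the genotypes
#' with no target-site phenotype in training (for `SIN`/`BAL1`/`BAL2` also
#' excluding other-site training; for `IMB` it is necessarily a subset of the
#' other-site training set) and is capped, with a warning, at the number of
#' eligible genotypes.
#'
#' @param scheme scheme label (see [cv_config()]).
#' @param s training set size per site.
#' @param population character vector of candidate genotype ids.
#' @param validation_size requested validation-set size.
#' @param seed optional integer seed for this draw.
#' @return list of class `cv_partition` with character vectors
#'   `train_target`, `train_other`, `validation`.
#' @export
make_partition <- function(scheme, s, population, validation_size = 100L,
                           seed = NULL) {
  scheme <- match.arg(scheme, c("SIN", "BAL1", "BAL2", "IMB"))
  population <- as.character(population)
  n <- length(population)
  if (!is.null(seed)) set.seed(seed)
  s <- as.integer(s)
  if (scheme %in% c("SIN", "BAL1", "IMB") && s >= n)
    stop("training set size s must leave untrained genotypes")
  if (scheme == "SIN") {
    tt <- sample(population, s)
    to <- character(0)
    pool <- setdiff(population, tt)
  } else if (scheme == "BAL1") {
    tt <- sample(population, s)
    to <- tt
    pool <- setdiff(population, tt)
  } else if (scheme == "BAL2") {
    overlap <- s %/% 2L
    n_distinct <- 2L * s - overlap
    if (n_distinct >= n) stop("BAL2 with s = ", s, " exhausts the population")
    distinct <- sample(population, n_distinct)
    shared <- distinct[seq_len(overlap)]
    target_only <- distinct[overlap + seq_len(s - overlap)]
    other_only <- distinct[(s + seq_len(s - overlap))]
    tt <- c(shared, target_only)
    to <- c(shared, other_only)
    pool <- setdiff(population, distinct)
  } else { # IMB
    to <- population
    tt <- sample(population, s)
    pool <- setdiff(population, tt)
  }
  vs <- validation_size
  if (length(pool) < vs) {
    warning("only ", length(pool), " genotypes eligible for validation (",
            vs, " requested): using all of them")
    vs <- length(pool)
  }
  val <- sample(pool, vs)
  out <- structure(list(train_target = tt, train_other = to, validation = val,
                        scheme = scheme, s = s), class = "cv_partition")
  .check_partition(out)
  out
}

.check_partition <- function(p) {
  stopifnot(length(intersect(p$validation, p$train_target)) == 0L)
  if (p$scheme %in% c("SIN", "BAL1", "BAL2"))
    stopifnot(length(intersect(p$validation, p$train_other)) == 0L)
  if (p$scheme == "IMB")
    stopifnot(all(p$validation %in% p$train_other))
  invisible(p)
}

#' Pearson predictive ability
#'
#' Correlation between the reference BLUP-adjusted phenotypes and the GEBVs
#' over the validation genotypes.  Vectors are aligned by name; a zero
#' variance in either vector yields `NA` with a warning.
#'
#' @param reference named numeric vector (from [blup_adjusted_means()]).
#' @param gebv named numeric vector or a `gebv_table`.
#' @return Pearson correlation in \[-1, 1\], or `NA`.
#' @export
predictive_ability <- function(reference, gebv) {
  if (inherits(gebv, "gebv_table") || is.data.frame(gebv))
    gebv <- stats::setNames(gebv$gebv, gebv$genotype)
  if (!is.null(names(gebv)) && !is.null(names(reference))) {
    shared <- intersect(names(reference), names(gebv))
    reference <- reference[shared]
    gebv <- gebv[shared]
  }
  if (length(reference) < 3L) stop("need at least 3 aligned genotypes")
  if (stats::sd(reference) == 0 || stats::sd(gebv) == 0) {
    warning("zero variance: predictive ability undefined")
    return(NA_real_)
  }
  stats::cor(reference, gebv)
}

#' Run one cross-validation cell
#'
#' Repeated-sampling evaluation of genomic prediction in the target site.
#' The reference adjusted means are computed once from the complete
#' target-site data (Model 1, identity kernel).  Each iteration draws a
#' partition with an iteration-specific seed, masks every target-site
#' phenotype outside the training set (and, for two-site schemes, every
#' other-site phenotype outside the other-site training set), fits Model 1
#' (`SIN`) or Model 2 (`BAL1`/`BAL2`/`IMB`) with the configured kernels — for
#' RKHS the bandwidths are re-estimated from the training set's BLUP-adjusted
#' phenotypes at every cycle — predicts GEBVs for the validation genotypes,
#' and scores the Pearson correlation against the reference.  Non-convergent
#' iterations are excluded from the summary and counted.
#'
#' @param data plot-level phenotype table covering both sites of the year.
#' @param markers complete -1/0/1 marker matrix over all candidate genotypes.
#' @param config a [cv_config()].
#' @return a `cv_result`: data.frame with one row per converged iteration
#'   (`iteration`, `scheme`, `s`, `year`, `gp_method`, `trait`, `pa`),
#'   with attributes `summary` (mean and SD of PA) and `n_failed`.
#' @export
run_cv <- function(data, markers, config) {
  stopifnot(inherits(config, "cv_config"))
  trait <- config$trait
  data <- .check_pheno(data, trait)
  data <- .subset_pheno(data, trait, year = config$year)
  sites <- sort(unique(as.character(data$site)))
  target <- config$target_site
  if (!target %in% sites) stop("target site not present in the data")
  other <- setdiff(sites, target)
  if (config$scheme != "SIN" && length(other) != 1L)
    stop("two-site schemes need exactly two sites")
  markers <- .check_markers(markers)
  population <- intersect(rownames(markers),
                          unique(data$genotype[data$site == target]))
  reference <- blup_adjusted_means(data, trait, site = target)

  gblup <- config$gp_method == "gblup"
  K_lin <- if (gblup) linear_kernel(markers) else NULL

  set.seed(config$master_seed)
  iter_seeds <- sample.int(.Machine$integer.max - 1L, config$n_iterations)

  rows <- vector("list", config$n_iterations)
  n_failed <- 0L
  warm <- NULL
  for (it in seq_len(config$n_iterations)) {
    part <- make_partition(config$scheme, config$s, population,
                           config$validation_size, seed = iter_seeds[it])
    res <- tryCatch(
      .cv_iteration(data, markers, config, part, target, other,
                    K_lin, warm),
      error = function(e) NULL)
    if (is.null(res) || !res$converged) {
      n_failed <- n_failed + 1L
      next
    }
    warm <- res$vc
    pa <- predictive_ability(reference[part$validation], res$gebv)
    rows[[it]] <- data.frame(iteration = it, scheme = config$scheme,
                             s = config$s, year = config$year,
                             gp_method = config$gp_method, trait = trait,
                             pa = pa, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no iteration converged")
  structure(out,
            summary = data.frame(scheme = config$scheme, s = config$s,
                                 year = config$year, gp_method = config$gp_method,
                                 trait = trait, mean_pa = mean(out$pa, na.rm = TRUE),
                                 sd_pa = stats::sd(out$pa, na.rm = TRUE),
                                 n = sum(!is.na(out$pa))),
            n_failed = n_failed,
            class = c("cv_result", "data.frame"))
}

.cv_iteration <- function(data, markers, config, part, target, other,
                          K_lin, warm) {
  trait <- config$trait
  tgt_rows <- data$site == target & data$genotype %in% part$train_target
  if (config$scheme == "SIN") {
    train <- data[tgt_rows, , drop = FALSE]
    K <- if (config$gp_method == "gblup") K_lin else {
      adj <- blup_adjusted_means(train, trait)
      ids <- names(adj)
      h <- estimate_bandwidth(markers[ids, , drop = FALSE], adj)
      gaussian_kernel(markers, attr(h, "h_raw"))
    }
    fit <- fit_model1(train, trait, kernel = K, init = warm)
    gebv <- predict_gebv(fit, genotypes = part$validation)
  } else {
    oth_rows <- data$site == other & data$genotype %in% part$train_other
    train <- data[tgt_rows | oth_rows, , drop = FALSE]
    if (config$gp_method == "gblup") {
      kernels <- K_lin
    } else {
      adj <- stats::setNames(lapply(c(target, other), function(s)
        blup_adjusted_means(train[train$site == s, , drop = FALSE], trait)),
        c(target, other))
      kernels <- site_kernels(markers, "gaussian", phenotypes = adj)
    }
    fit <- fit_model2(train, trait, kernels = kernels, init = warm)
    gebv <- predict_gebv(fit, genotypes = part$validation,
                         target_site = target,
                         include_interaction = config$include_interaction)
  }
  list(gebv = gebv, converged = fit$converged, vc = fit$vc[!is.na(fit$vc)])
}

#' Run a grid of cross-validation cells
#'
#' Convenience wrapper looping [run_cv()] over schemes and training set
#' sizes (and optionally years and GP methods), binding all iteration rows —
#' the input expected by [fit_anova_eta2()].
#'
#' @inheritParams run_cv
#' @param schemes,sizes character/integer vectors of schemes and set sizes.
#' @param years,gp_methods vectors of years and GP methods (defaults: single
#'   values from `...`).
#' @param ... further arguments passed to [cv_config()].
#' @return combined `cv_result` data.frame with a `summary` attribute
#'   (one row per cell).
#' @export
run_cv_grid <- function(data, markers, schemes, sizes, years = 1L,
                        gp_methods = "gblup", ...) {
  cells <- expand.grid(scheme = schemes, s = sizes, year = years,
                       gp_method = gp_methods, stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(cells)), function(i) {
    cfg <- cv_config(scheme = cells$scheme[i], s = cells$s[i],
                     year = cells$year[i], gp_method = cells$gp_method[i], ...)
    run_cv(data, markers, cfg)
  })
  out <- do.call(rbind, lapply(res, as.data.frame))
  structure(out,
            summary = do.call(rbind, lapply(res, attr, "summary")),
            n_failed = sum(vapply(res, attr, integer(1), "n_failed")),
            class = c("cv_result", "data.frame"))
}
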