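## Plot-level phenotype tables: data.frames with columns
## genotype, site, year, rep, block (block nested in rep within site) and one
## numeric column per trait.  Missing trait values are dropped row-wise per
## trait at fit time.

.check_pheno <- function(data, trait, need_block = FALSE) {
  req <- c("genotype", "site", "year", "rep")
  miss <- setdiff(req, names(data))
  if (length(miss)) stop("phenotype table lacks column(s): ", paste(miss, collapse = ", "))
  if (!trait %in% names(data)) stop("trait '", trait, "' not found")
  if (need_block && !"block" %in% names(data))
    stop("phenotype table lacks a 'block' column")
  data
}

.subset_pheno <- function(data, trait, site = NULL, year = NULL) {
  if (!is.null(site)) data <- data[data$site %in% site, , drop = FALSE]
  if (!is.null(year)) data <- data[data$year %in% year, , drop = FALSE]
  data <- data[!is.na(data[[trait]]), , drop = FALSE]
  if (nrow(data) == 0L) stop("no records left after subsetting")
  data
}

.vc_map1 <- c(sigma2_b = "block", sigma2_g = "genotype", sigma2_e = "resid")

.translate_vc <- function(vc, map) {
  if (is.null(vc)) return(NULL)
  bad <- setdiff(names(vc), names(map))
  if (length(bad)) stop("unknown variance component(s): ", paste(bad, collapse = ", "))
  stats::setNames(as.numeric(vc), map[names(vc)])
}

## genotype incidence restricted to the kernel's ordering; errors when data
## contain genotypes absent from the kernel (the reverse is allowed)
.genotype_term <- function(geno, kernel) {
  geno <- as.character(geno)
  if (is.null(kernel)) {
    f <- factor(geno)
    return(list(Z = f, K = NULL, obs = levels(f)))
  }
  ids <- rownames(kernel)
  missing_ids <- setdiff(unique(geno), ids)
  if (length(missing_ids))
    stop("genotype(s) present in the data but absent from the kernel: ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  obs <- ids[ids %in% geno]
  list(Z = factor(geno, levels = obs),
       K = unclass(kernel)[obs, obs, drop = FALSE], obs = obs)
}

#' Fit the single-site genomic mixed model (Model 1)
#'
#' Fits, for one site-by-year trial,
#' \deqn{Y_{ijk} = \mu + r_i + b_{ij} + g_k + \varepsilon_{ijk}}
#' with fixed intercept and replicate effects, random incomplete-block
#' effects nested in replicate (\eqn{b \sim N(0, I\sigma^2_b)}), random
#' genotype effects with a marker-derived or identity covariance
#' (\eqn{g \sim N(0, M\sigma^2_g)}) and i.i.d. residuals.  Estimation is by
#' REML (see [reml_fit()]); the fixed-effect constraint is reference-level
#' (first factor level dropped), so \eqn{\mu} is the expected value of the
#' first replicate.
#'
#' @param data plot-level phenotype table (see [read_phenotypes()]).
#' @param trait name of the trait column to analyse.
#' @param kernel `genomic_kernel` (or plain genotype x genotype matrix with
#'   dimnames), or `NULL` for the identity.
#' @param site,year optional filters; after filtering the data must span a
#'   single site and year.
#' @param fix_vc optional named vector holding components fixed, names among
#'   `sigma2_b`, `sigma2_g`, `sigma2_e`.
#' @param init optional starting values, same names as `fix_vc`.
#' @param ... passed to [reml_fit()].
#' @return a `gp_fit` object with elements `vc` (named `sigma2_b`,
#'   `sigma2_g`, `sigma2_e`), `beta`, `blups` (list with `block` and `g`),
#'   `logREML`, `converged`, `iterations`, `n_records`, plus bookkeeping used
#'   by [predict_gebv()].
#' @export
fit_model1 <- function(data, trait, kernel = NULL, site = NULL, year = NULL,
                       fix_vc = NULL, init = NULL, ...) {
  data <- .check_pheno(data, trait)
  data <- .subset_pheno(data, trait, site, year)
  if (length(unique(data$site)) != 1L || length(unique(data$year)) != 1L)
    stop("Model 1 is a single-trial model: filter to one site and year")
  gt <- .genotype_term(data$genotype, kernel)
  if (length(gt$obs) < 3L) stop("fewer than 3 genotypes with records")
  rep_f <- factor(data$rep)
  X <- stats::model.matrix(~rep_f)
  colnames(X) <- sub("^rep_f", "rep", colnames(X))
  random <- list(genotype = list(Z = gt$Z, K = gt$K))
  has_block <- "block" %in% names(data)
  if (has_block) {
    blk <- factor(paste(data$rep, data$block, sep = ":"))
    random <- c(list(block = list(Z = blk, K = NULL)), random)
  }
  fit <- reml_fit(data[[trait]], X, random,
                  fix_vc = .translate_vc(fix_vc, .vc_map1),
                  init = .translate_vc(init, .vc_map1), ...)
  vc <- c(sigma2_b = if (has_block) unname(fit$vc["block"]) else NA_real_,
          sigma2_g = unname(fit$vc["genotype"]),
          sigma2_e = unname(fit$vc["resid"]))
  structure(list(
    model = 1L, trait = trait,
    site = unique(as.character(data$site)), year = unique(data$year),
    vc = vc, beta = fit$beta,
    blups = list(block = if (has_block) fit$u$block else NULL,
                 g = fit$u$genotype),
    logREML = fit$logREML, converged = fit$converged,
    iterations = fit$iterations, n_records = fit$n,
    kernel = kernel, obs_genotypes = gt$obs,
    constraint = "reference level (first replicate absorbed in the intercept)",
    reml = fit
  ), class = c("gp_model1", "gp_fit"))
}

#' Fit the two-site genomic mixed model with GxE (Model 2)
#'
#' Fits, for the two sites of one year,
#' \deqn{Y_{ijkl} = \mu + s_i + rs_{ij} + b(rs)_{ijk} + g_l + gs_{il} +
#'   \varepsilon_{ijkl}}
#' with fixed intercept, site, and replicate-within-site effects; random
#' blocks within replicate within site; a genotype main effect
#' \eqn{g \sim N(0, M_0\sigma^2_g)}; site-specific genotype-by-site
#' interactions \eqn{gs \sim N(0, \mathrm{blockdiag}(M_{s_1}\sigma^2_{gs,s_1},
#' M_{s_2}\sigma^2_{gs,s_2}))}; and site-specific residual variances (the
#' residual covariance is the Kronecker product of an identity with the
#' per-site variance pair).
#'
#' @inheritParams fit_model1
#' @param kernels `NULL` (identity for all genotype terms), a single kernel
#'   shared by the main and interaction terms (the GBLUP case,
#'   \eqn{M = M_{s_1} = M_{s_2}}), or a named list with entry `M0` (main
#'   effect) plus one kernel per site label (the RKHS case).
#' @param year optional filter; the data must span exactly two sites in one
#'   year.
#' @param fix_vc,init named vectors, names among `sigma2_b`, `sigma2_g`,
#'   `sigma2_gs.<site>`, `sigma2_e.<site>`.
#' @return a `gp_fit` with the six variance components, fixed effects, BLUP
#'   lists (`block`, `g`, and `gs` per site) and REML bookkeeping.
#' @export
fit_model2 <- function(data, trait, kernels = NULL, year = NULL,
                       fix_vc = NULL, init = NULL, ...) {
  data <- .check_pheno(data, trait)
  data <- .subset_pheno(data, trait, year = year)
  sites <- sort(unique(as.character(data$site)))
  if (length(sites) != 2L) stop("Model 2 needs exactly two sites, found: ",
                                paste(sites, collapse = ", "))
  if (length(unique(data$year)) != 1L)
    stop("Model 2 is fitted within a single year")
  for (s in sites) if (!any(data$site == s)) stop("site ", s, " has no records")

  if (inherits(kernels, "genomic_kernel") || (is.matrix(kernels))) {
    kernels <- stats::setNames(c(list(kernels), rep(list(kernels), 2)),
                               c("M0", sites))
  }
  if (!is.null(kernels)) {
    need <- c("M0", sites)
    miss <- setdiff(need, names(kernels))
    if (length(miss)) stop("kernels list lacks entries: ", paste(miss, collapse = ", "))
  }
  K0 <- if (is.null(kernels)) NULL else kernels$M0

  site_f <- factor(data$site, levels = sites)
  rep_f <- factor(data$rep)
  df <- data.frame(site = site_f, rep = rep_f)
  X <- stats::model.matrix(~ site + site:rep, df)
  gt <- .genotype_term(data$genotype, K0)
  if (length(gt$obs) < 3L) stop("fewer than 3 genotypes with records")
  blk <- factor(paste(data$site, data$rep, data$block, sep = ":"))
  n <- nrow(data)
  random <- list(block = list(Z = blk, K = NULL),
                 g = list(Z = gt$Z, K = gt$K))
  gs_obs <- list()
  for (s in sites) {
    rows <- which(data$site == s)
    Ks <- if (is.null(kernels)) NULL else kernels[[s]]
    g_s <- .genotype_term(data$genotype[rows], Ks)
    Z <- Matrix::sparseMatrix(i = rows, j = as.integer(g_s$Z), x = 1,
                              dims = c(n, length(g_s$obs)),
                              dimnames = list(NULL, g_s$obs))
    random[[paste0("gs.", s)]] <- list(Z = Z, K = g_s$K)
    gs_obs[[s]] <- g_s$obs
  }
  map <- stats::setNames(
    c("block", "g", paste0("gs.", sites), "resid", paste0("resid.", sites)),
    c("sigma2_b", "sigma2_g", paste0("sigma2_gs.", sites),
      "sigma2_e", paste0("sigma2_e.", sites)))
  fit <- reml_fit(data[[trait]], X, random, resid_group = site_f,
                  fix_vc = .translate_vc(fix_vc, map),
                  init = .translate_vc(init, map), ...)
  vc <- stats::setNames(
    fit$vc[c("block", "g", paste0("gs.", sites), paste0("resid.", sites))],
    c("sigma2_b", "sigma2_g", paste0("sigma2_gs.", sites),
      paste0("sigma2_e.", sites)))
  gs <- stats::setNames(lapply(sites, function(s) fit$u[[paste0("gs.", s)]]), sites)
  structure(list(
    model = 2L, trait = trait, sites = sites, year = unique(data$year),
    vc = vc, beta = fit$beta,
    blups = list(block = fit$u$block, g = fit$u$g, gs = gs),
    logREML = fit$logREML, converged = fit$converged,
    iterations = fit$iterations, n_records = fit$n,
    kernels = kernels, obs_genotypes = gt$obs, gs_obs = gs_obs,
    constraint = "reference level (first site and replicate absorbed in the intercept)",
    reml = fit
  ), class = c("gp_model2", "gp_fit"))
}

#' @export
print.gp_fit <- function(x, ...) {
  cat("Genomic mixed model (Model ", x$model, "), trait ", x$trait, "\n", sep = "")
  cat(x$n_records, "records;", length(x$obs_genotypes), "genotypes with data\n")
  cat("logREML:", format(x$logREML, digits = 8),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  print(signif(x$vc, 5))
  invisible(x)
}

## conditional-expectation BLUPs for genotypes without records:
## u_new = K[new, obs] K[obs, obs]^{-1} u_obs  (0 under the identity kernel)
.linked_blups <- function(ids, u_obs, kernel) {
  out <- stats::setNames(numeric(length(ids)), ids)
  obs <- names(u_obs)
  inside <- ids %in% obs
  out[inside] <- u_obs[ids[inside]]
  new <- ids[!inside]
  if (length(new)) {
    if (is.null(kernel)) {
      out[new] <- 0
    } else {
      missing_ids <- setdiff(new, rownames(kernel))
      if (length(missing_ids))
        stop("genotype(s) absent from the kernel: ",
             paste(utils::head(missing_ids, 5), collapse = ", "))
      Km <- unclass(kernel)
      out[new] <- as.vector(Km[new, obs, drop = FALSE] %*%
                              solve(Km[obs, obs], u_obs))
    }
  }
  out
}

#' Genomic estimated breeding values
#'
#' Computes GEBVs from a fitted model.  For Model 1,
#' \eqn{\hat Y_k = \hat\mu + \hat g_k}; for Model 2 on the target site,
#' \eqn{\hat Y_{s,l} = \hat\mu + \hat s + \hat g_l} plus, when
#' `include_interaction = TRUE` (the default), the site-specific interaction
#' BLUP \eqn{\hat{gs}_{s,l}}.  Genotypes without phenotypic records receive
#' BLUPs through the kernel covariance with the phenotyped set
#' (zero under the identity kernel).
#'
#' @param fit a `gp_fit` from [fit_model1()] or [fit_model2()].
#' @param genotypes character vector of genotype ids to predict (default: all
#'   genotypes of the fitting kernel, else all phenotyped genotypes).
#' @param target_site for Model 2, the site whose performance is predicted.
#' @param include_interaction add the genotype-by-site interaction BLUP for
#'   the target site (Model 2 only).
#' @return data.frame with columns `genotype` and `gebv` (class
#'   `gebv_table`); the fixed components used are stored in attribute
#'   `components`.
#' @export
predict_gebv <- function(fit, genotypes = NULL, target_site = NULL,
                         include_interaction = TRUE) {
  stopifnot(inherits(fit, "gp_fit"))
  kern0 <- if (fit$model == 1L) fit$kernel else fit$kernels$M0
  if (is.null(genotypes))
    genotypes <- if (!is.null(kern0)) rownames(kern0) else fit$obs_genotypes
  genotypes <- as.character(genotypes)
  mu <- unname(fit$beta["(Intercept)"])
  g <- .linked_blups(genotypes, fit$blups$g, kern0)
  if (fit$model == 1L) {
    gebv <- mu + g
    comp <- list(mu = mu)
  } else {
    if (is.null(target_site)) stop("target_site is required for Model 2 predictions")
    if (!target_site %in% fit$sites)
      stop("target_site must be one of: ", paste(fit$sites, collapse = ", "))
    cf <- paste0("site", target_site)
    s_eff <- if (cf %in% names(fit$beta)) unname(fit$beta[cf]) else 0
    gebv <- mu + s_eff + g
    comp <- list(mu = mu, site_effect = s_eff, site = target_site)
    if (include_interaction) {
      ks <- if (is.null(fit$kernels)) NULL else fit$kernels[[target_site]]
      gs <- .linked_blups(genotypes, fit$blups$gs[[target_site]], ks)
      gebv <- gebv + gs
      comp$interaction <- TRUE
    } else comp$interaction <- FALSE
  }
  structure(data.frame(genotype = genotypes, gebv = unname(gebv),
                       stringsAsFactors = FALSE),
            components = comp, model = fit$model, class = c("gebv_table", "data.frame"))
}

#' BLUP-adjusted genotype means for one trial
#'
#' Fits Model 1 with the identity genotype covariance on the complete data of
#' one site-by-year trial and returns \eqn{\hat\mu + \hat g_k} per genotype.
#' These adjusted means serve as the reference phenotype for predictive
#' ability, as the input to bandwidth estimation, and as the basis of
#' between-site correlations.
#'
#' @inheritParams fit_model1
#' @return named numeric vector (one adjusted mean per genotype with at least
#'   one record), with the underlying fit in attribute `fit`.
#' @export
blup_adjusted_means <- function(data, trait, site = NULL, year = NULL, ...) {
  fit <- fit_model1(data, trait, kernel = NULL, site = site, year = year, ...)
  out <- unname(fit$beta["(Intercept)"]) + fit$blups$g
  attr(out, "fit") <- fit
  out
}

#' Between-site correlation of adjusted genotype means
#'
#' Pearson correlation (with two-sided p-value) between the BLUP-adjusted
#' genotype means of the two sites of one year, over the genotypes shared by
#' both trials.
#'
#' @inheritParams fit_model1
#' @param sites optional pair of site labels (default: the two sites present).
#' @return list with `estimate`, `p_value`, `n` (shared genotypes) and the
#'   underlying `cor.test` in `test`.
#' @export
site_correlation <- function(data, trait, year = NULL, sites = NULL) {
  data <- .check_pheno(data, trait)
  if (is.null(sites)) sites <- sort(unique(as.character(data$site)))
  if (length(sites) != 2L) stop("exactly two sites are required")
  m1 <- blup_adjusted_means(data, trait, site = sites[1], year = year)
  m2 <- blup_adjusted_means(data, trait, site = sites[2], year = year)
  shared <- intersect(names(m1), names(m2))
  if (length(shared) < 3L) stop("fewer than 3 genotypes shared between the sites")
  ct <- stats::cor.test(m1[shared], m2[shared], method = "pearson")
  list(estimate = unname(ct$estimate), p_value = ct$p.value,
       n = length(shared), test = ct)
}

#' Plot-level descriptive statistics
#'
#' Mean, standard error of the mean, minimum, maximum and coefficient of
#' variation (`CV = 100 * SD / mean`, in percent) of a trait, per site-by-year
#' trial.
#'
#' @inheritParams fit_model1
#' @return data.frame with one row per site x year cell.
#' @export
descriptive_stats <- function(data, trait, site = NULL, year = NULL) {
  data <- .check_pheno(data, trait)
  data <- .subset_pheno(data, trait, site, year)
  cells <- split(data[[trait]], list(site = data$site, year = data$year), drop = TRUE)
  out <- do.call(rbind, lapply(names(cells), function(nm) {
    v <- cells[[nm]]
    if (length(v) < 2L) stop("fewer than 2 records in cell ", nm)
    key <- strsplit(nm, ".", fixed = TRUE)[[1]]
    cv <- if (abs(mean(v)) < .Machine$double.eps) {
      warning("zero mean in cell ", nm, ": CV undefined")
      NA_real_
    } else 100 * stats::sd(v) / mean(v)
    data.frame(site = key[1], year = key[2], n = length(v),
               mean = mean(v), se = stats::sd(v) / sqrt(length(v)),
               min = min(v), max = max(v), cv = cv)
  }))
  rownames(out) <- NULL
  out
}
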