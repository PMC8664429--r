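#' Restricted maximum likelihood for kernel mixed models
#'
#' Fits the linear mixed model
#' \deqn{y = X\beta + \sum_r Z_r u_r + e,\qquad u_r \sim N(0, K_r \sigma^2_r),
#'   \quad e \sim N(0, R)}
#' where each random term has its own (possibly kernel-structured) covariance
#' \eqn{K_r} and the residual covariance \eqn{R} is diagonal with one variance
#' per level of `resid_group` (site-grouped residuals when records come from
#' heterogeneous environments).
#'
#' Variance components are estimated by REML using average-information (AI)
#' updates on Henderson's mixed-model equations, with expectation-maximisation
#' (EM) steps at the start and as a fallback whenever an AI step would leave
#' the parameter space or decrease the restricted likelihood.  EM steps keep
#' all components non-negative; estimates are floored at
#' `1e-10 * var(y)`.  The solver is deterministic: no randomness is used.
#'
#' @param y numeric response vector (no missing values).
#' @param X fixed-effect design matrix (a column of ones for the intercept
#'   must be included).  Aliased columns are dropped via a pivoted QR and
#'   recorded in the result.
#' @param random named list of random terms.  Each term is a list with
#'   elements `Z` (an incidence factor of length `n`, or an `n x q` matrix)
#'   and optionally `K`, the `q x q` covariance kernel (`NULL` means identity).
#' @param resid_group optional factor of length `n`; one residual variance is
#'   estimated per level.  `NULL` fits a single residual variance.
#' @param init optional named numeric vector of starting values for the
#'   variance components (names as in the returned `vc`).
#' @param fix_vc optional named numeric vector of components to hold fixed
#'   (not estimated); use it e.g. to compute BLUPs at known variances.
#' @param max_iter,tol_vc,tol_logl convergence controls: iteration cap,
#'   relative-change tolerance on each component, and absolute tolerance on
#'   the change in log restricted likelihood.
#' @param n_em_start number of initial plain EM iterations before AI updates
#'   are attempted.
#'
#' @return an object of class `reml_fit`: a list with elements `vc` (named
#'   variance components), `beta` (named fixed-effect estimates under the
#'   constraint recorded in `dropped_coef`), `u` (named list of BLUP vectors),
#'   `logREML`, `converged`, `iterations`, `fitted`, `residuals`, `n`, `p`,
#'   and `floor`.
#' @export
reml_fit <- function(y, X, random, resid_group = NULL,
                     init = NULL, fix_vc = NULL,
                     max_iter = 500L, tol_vc = 1e-8, tol_logl = 1e-9,
                     n_em_start = 3L) {
  y <- as.numeric(y)
  n <- length(y)
  if (anyNA(y)) stop("missing values in the response; drop them before fitting")
  if (n < 3L) stop("need at least 3 records")
  if (is.null(dim(X))) X <- matrix(X, nrow = n)
  if (nrow(X) != n) stop("X and y dimensions disagree")

  ## drop aliased fixed-effect columns (reference-level / rank constraint)
  qrX <- qr(X)
  keep <- qrX$pivot[seq_len(qrX$rank)]
  dropped <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
  X <- X[, sort(keep), drop = FALSE]
  p <- ncol(X)

  if (is.null(names(random)) || any(!nzchar(names(random))))
    stop("'random' must be a named list")
  terms <- lapply(random, function(tm) {
    Z <- tm$Z
    if (is.factor(Z) || is.character(Z)) {
      f <- factor(Z)
      Z <- Matrix::sparseMatrix(i = seq_len(n), j = as.integer(f),
                                x = 1, dims = c(n, nlevels(f)),
                                dimnames = list(NULL, levels(f)))
    } else {
      Z <- methods::as(methods::as(methods::as(Matrix::Matrix(Z, sparse = TRUE),
                                               "dMatrix"), "generalMatrix"), "CsparseMatrix")
    }
    if (nrow(Z) != n) stop("a Z has the wrong number of rows")
    q <- ncol(Z)
    K <- tm$K
    if (!is.null(K)) {
      K <- as.matrix(K)
      if (!isTRUE(all.equal(dim(K), c(q, q))))
        stop("kernel dimension does not match the number of random levels")
      ## small ridge guards against numerically singular kernels
      ridge <- 1e-8 * mean(diag(K))
      ch <- tryCatch(chol(K), error = function(e) NULL)
      if (is.null(ch)) {
        K <- K + diag(ridge, q)
        ch <- chol(K)
      }
      Kinv <- chol2inv(ch)
      logdetK <- 2 * sum(log(diag(ch)))
    } else {
      Kinv <- NULL
      logdetK <- 0
    }
    list(Z = Z, q = q, Kinv = Kinv, logdetK = logdetK,
         levels = colnames(Z))
  })

  if (is.null(resid_group)) resid_group <- factor(rep("resid", n))
  resid_group <- factor(resid_group)
  g_idx <- split(seq_len(n), resid_group)
  s_names <- paste0("resid", if (nlevels(resid_group) > 1L)
    paste0(".", levels(resid_group)) else "")
  n_s <- lengths(g_idx)

  W <- do.call(cbind, c(list(Matrix::Matrix(X, sparse = TRUE)),
                        lapply(terms, `[[`, "Z")))
  W <- methods::as(methods::as(W, "generalMatrix"), "CsparseMatrix")
  Wt <- Matrix::t(W)
  q_all <- vapply(terms, `[[`, integer(1), "q")
  idx_term <- split(p + seq_len(sum(q_all)), rep(seq_along(terms), q_all))

  vc_names <- c(names(terms), s_names)
  n_t <- length(terms)
  n_vc <- n_t + nlevels(resid_group)
  grp <- as.integer(resid_group)

  vary <- stats::var(y)
  if (vary <= 0) vary <- 1
  flr <- 1e-10 * vary

  ## a warm start (init) is assumed to be near the optimum: go almost
  ## straight to AI updates
  if (!is.null(init)) n_em_start <- min(n_em_start, 1L)

  theta <- rep(vary / n_vc, n_vc)
  names(theta) <- vc_names
  if (!is.null(init)) {
    bad <- setdiff(names(init), vc_names)
    if (length(bad)) stop("unknown component(s) in init: ", paste(bad, collapse = ", "))
    theta[names(init)] <- pmax(init, flr)
  }
  free <- rep(TRUE, n_vc)
  names(free) <- vc_names
  if (!is.null(fix_vc)) {
    bad <- setdiff(names(fix_vc), vc_names)
    if (length(bad)) stop("unknown component(s) in fix_vc: ", paste(bad, collapse = ", "))
    theta[names(fix_vc)] <- pmax(fix_vc, 0)
    free[names(fix_vc)] <- FALSE
  }
  theta[free] <- pmax(theta[free], flr)

  logdetK_sum <- sum(vapply(terms, `[[`, numeric(1), "logdetK"))

  ## precomputed pieces: per residual group, the dense cross-product block of
  ## W and the W'y vector; per random term, flat insertion indices for Kinv
  pq <- p + sum(q_all)
  C0 <- lapply(g_idx, function(ii)
    as.matrix(Matrix::crossprod(W[ii, , drop = FALSE])))
  Wy0 <- lapply(g_idx, function(ii)
    as.vector(Matrix::crossprod(W[ii, , drop = FALSE], y[ii])))
  yy0 <- vapply(g_idx, function(ii) sum(y[ii]^2), numeric(1))
  ins <- lapply(seq_len(n_t), function(r) {
    ii <- idx_term[[r]]
    if (is.null(terms[[r]]$Kinv))
      list(idx = ii + (ii - 1) * pq, val = rep(1, length(ii)))
    else
      list(idx = as.vector(outer(ii, ii, function(a, b) a + (b - 1) * pq)),
           val = as.vector(terms[[r]]$Kinv))
  })

  eval_core <- function(th) {
    w_s <- 1 / th[n_t + seq_along(g_idx)]
    w <- w_s[grp]
    C <- C0[[1]] * w_s[1]
    if (length(C0) > 1L)
      for (s in 2:length(C0)) C <- C + C0[[s]] * w_s[s]
    for (r in seq_len(n_t))
      C[ins[[r]]$idx] <- C[ins[[r]]$idx] + ins[[r]]$val / th[r]
    ch <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(ch)) return(list(logl = -Inf))
    RHS <- Wy0[[1]] * w_s[1]
    if (length(Wy0) > 1L)
      for (s in 2:length(Wy0)) RHS <- RHS + Wy0[[s]] * w_s[s]
    b <- backsolve(ch, backsolve(ch, RHS, transpose = TRUE))
    yPy <- sum(yy0 * w_s) - sum(RHS * b)
    logdetG <- sum(q_all * log(th[seq_len(n_t)])) + logdetK_sum
    logdetR <- sum(n_s * log(th[n_t + seq_len(nlevels(resid_group))]))
    logl <- -0.5 * ((n - p) * log(2 * pi) + logdetR + logdetG +
                      2 * sum(log(diag(ch))) + yPy)
    list(logl = logl, ch = ch, b = b, w = w, th = th)
  }

  extend_core <- function(core) {
    core$Cinv <- chol2inv(core$ch)
    core$e <- y - as.vector(W %*% core$b)
    ## per residual group, sum over its records of w_i' Cinv w_i
    core$grpq <- vapply(C0, function(cs) sum(core$Cinv * cs), numeric(1))
    core$u <- vector("list", n_t)
    core$t1 <- core$tr <- numeric(n_t)
    for (r in seq_len(n_t)) {
      ii <- idx_term[[r]]
      ur <- core$b[ii]
      core$u[[r]] <- ur
      if (is.null(terms[[r]]$Kinv)) {
        core$t1[r] <- sum(ur * ur)
        core$tr[r] <- sum(diag(core$Cinv)[ii])
      } else {
        core$t1[r] <- as.numeric(crossprod(ur, terms[[r]]$Kinv %*% ur))
        core$tr[r] <- sum(terms[[r]]$Kinv * core$Cinv[ii, ii])
      }
    }
    core
  }

  em_step <- function(core) {
    th <- core$th
    new <- th
    for (r in seq_len(n_t))
      new[r] <- (core$t1[r] + core$tr[r]) / q_all[r]
    for (s in seq_len(nlevels(resid_group))) {
      ii <- g_idx[[s]]
      new[n_t + s] <- (sum(core$e[ii]^2) + core$grpq[s]) / n_s[s]
    }
    new[!free] <- th[!free]
    new
  }

  ai_step <- function(core) {
    th <- core$th
    Py <- core$w * core$e
    Fm <- matrix(0, n, n_vc)
    for (r in seq_len(n_t)) {
      Z <- terms[[r]]$Z
      v <- as.vector(Matrix::crossprod(Z, Py))
      if (!is.null(terms[[r]]$Kinv)) {
        ## f = Z K Z' Py ; K applied via solve of Kinv (Kinv u-route avoids
        ## storing K): here we kept only Kinv, so solve
        v <- solve(terms[[r]]$Kinv, v)
      }
      Fm[, r] <- as.vector(Z %*% v)
    }
    for (s in seq_len(nlevels(resid_group)))
      Fm[g_idx[[s]], n_t + s] <- Py[g_idx[[s]]]
    WtF <- as.matrix(Wt %*% (Fm * core$w))
    PF <- Fm * core$w - as.matrix(W %*% (core$Cinv %*% WtF)) * core$w
    AI <- 0.5 * crossprod(Fm, PF)
    AI <- (AI + t(AI)) / 2
    grad <- numeric(n_vc)
    for (r in seq_len(n_t)) {
      trPV <- (q_all[r] - core$tr[r] / th[r]) / th[r]
      grad[r] <- -0.5 * (trPV - core$t1[r] / th[r]^2)
    }
    for (s in seq_len(nlevels(resid_group))) {
      ii <- g_idx[[s]]
      trPD <- (n_s[s] - core$grpq[s] / th[n_t + s]) / th[n_t + s]
      grad[n_t + s] <- -0.5 * (trPD - sum(Py[ii]^2))
    }
    fr <- which(free)
    delta <- tryCatch(solve(AI[fr, fr, drop = FALSE], grad[fr]),
                      error = function(e) NULL)
    if (is.null(delta)) return(NULL)
    new <- th
    new[fr] <- th[fr] + delta
    new
  }

  clamp <- function(th) {
    th[free] <- pmax(th[free], flr)
    th[free][th[free] < 2 * flr] <- flr
    th
  }

  core <- extend_core(eval_core(theta))
  if (!is.finite(core$logl)) stop("non-finite restricted likelihood at starting values")
  iter <- 0L
  steps <- character(0)
  th_prev1 <- th_prev2 <- NULL
  converged <- !any(free)
  while (!converged && iter < max_iter) {
    iter <- iter + 1L
    proposal <- NULL
    if (iter > n_em_start) {
      cand <- ai_step(core)
      if (!is.null(cand)) {
        ## step-halving when the full AI step overshoots
        for (frac in c(1, 0.5, 0.25)) {
          cf <- clamp(core$th + frac * (cand - core$th))
          cc <- eval_core(cf)
          if (is.finite(cc$logl) && cc$logl >= core$logl - 1e-10) {
            proposal <- cc
            steps <- c(steps, "AI")
            break
          }
        }
      }
    }
    if (is.null(proposal)) {
      cand <- clamp(em_step(core))
      ## Aitken delta-squared acceleration after runs of plain EM steps:
      ## geometric EM trails (typically a component heading for the zero
      ## boundary) are extrapolated to their limit in one move
      nst <- length(steps)
      if (nst >= 2L && all(steps[c(nst - 1L, nst)] == "EM") &&
          !is.null(th_prev2)) {
        x0 <- th_prev2; x1 <- th_prev1; x2 <- cand
        den <- x2 - 2 * x1 + x0
        acc <- ifelse(abs(den) > 1e-300, x2 - (x2 - x1)^2 / den, x2)
        acc[!free] <- cand[!free]
        acc <- clamp(ifelse(is.finite(acc), acc, cand))
        ca <- eval_core(acc)
        if (is.finite(ca$logl) && ca$logl >= core$logl - 1e-10) {
          proposal <- ca
          steps <- c(steps, "EM-aitken")
        }
      }
      if (is.null(proposal)) {
        proposal <- eval_core(cand)
        steps <- c(steps, "EM")
        if (!is.finite(proposal$logl)) break
      }
    }
    th_prev2 <- th_prev1
    th_prev1 <- proposal$th
    rel <- max(abs(proposal$th[free] - core$th[free]) /
                 pmax(core$th[free], 1e-6 * vary))
    dlogl <- abs(proposal$logl - core$logl)
    proposal <- extend_core(proposal)
    core <- proposal
    if (rel < tol_vc && dlogl < tol_logl) converged <- TRUE
  }

  u <- lapply(seq_len(n_t), function(r) {
    ur <- core$u[[r]]
    names(ur) <- terms[[r]]$levels
    ur
  })
  names(u) <- names(terms)
  beta <- core$b[seq_len(p)]
  names(beta) <- colnames(X)

  structure(list(
    vc = core$th,
    beta = beta,
    u = u,
    logREML = core$logl,
    converged = converged,
    iterations = iter,
    fitted = as.vector(W %*% core$b),
    residuals = core$e,
    dropped_coef = dropped,
    steps = steps,
    n = n, p = p, floor = flr
  ), class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat("REML fit:", x$n, "records,", x$p, "fixed-effect coefficients\n")
  cat("logREML:", format(x$logREML, digits = 8),
      if (x$converged) "(converged" else "(NOT converged",
      "in", x$iterations, "iterations)\n")
  cat("Variance components:\n")
  print(signif(x$vc, 6))
  invisible(x)
}
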