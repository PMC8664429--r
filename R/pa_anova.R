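#' Eta-squared attribution of predictive-ability variation
#'
#' Fits a fixed-effects ANOVA to per-iteration predictive abilities and
#' expresses each effect's share of variation as
#' \eqn{\eta^2 = SSq_{effect} / SSq_{total}}, where the total is the sum of
#' squares of all effects, interactions and the residual.  Sums of squares
#' are sequential (type I) in the stated factor order; in the balanced
#' designs produced by [run_cv_grid()] (equal iterations per cell) sequential
#' and marginal sums of squares coincide, which the function asserts on
#' balanced inputs.  All factors are treated as categorical, including the
#' training set size.
#'
#' @param results a `cv_result` data.frame (or any data.frame with a `pa`
#'   column and the factor columns).
#' @param factors character vector of factor column names, in the order the
#'   sequential decomposition uses (default: year, GP method, scheme, set
#'   size, keeping those that vary).
#' @param max_order highest interaction order to include (default: all
#'   interactions among the factors).
#' @return an `eta2_table`: data.frame with columns `effect`, `df`, `ssq`,
#'   `eta2` (residual row included; `eta2` sums to 1), with attributes `r2`
#'   (\eqn{1 - SSq_{resid}/SSq_{total}}) and `n`.
#' @export
fit_anova_eta2 <- function(results,
                           factors = c("year", "gp_method", "scheme", "s"),
                           max_order = length(factors)) {
  if (!"pa" %in% names(results)) stop("results must contain a 'pa' column")
  results <- results[!is.na(results$pa), , drop = FALSE]
  factors <- intersect(factors, names(results))
  factors <- factors[vapply(factors, function(f)
    length(unique(results[[f]])) > 1L, logical(1))]
  if (length(factors) == 0L) stop("no factor with more than one level")
  df <- results[, c("pa", factors), drop = FALSE]
  for (f in factors) df[[f]] <- factor(df[[f]])
  cells <- table(df[factors])
  if (any(cells == 0L)) {
    empty <- which(cells == 0L, arr.ind = TRUE)[1, , drop = TRUE]
    lab <- paste(mapply(function(f, i) paste0(f, "=", dimnames(cells)[[f]][i]),
                        factors, empty), collapse = ", ")
    stop("empty design cell: ", lab)
  }
  rhs <- function(fs) {
    if (length(fs) == 1L || max_order <= 1L) paste(fs, collapse = " + ")
    else paste0("(", paste(fs, collapse = " + "), ")^", min(max_order, length(fs)))
  }
  fml <- stats::as.formula(paste("pa ~", rhs(factors)))
  fit <- stats::lm(fml, data = df)
  an <- stats::anova(fit)  # sequential (type I) sums of squares
  ssq <- an[["Sum Sq"]]
  total <- sum(ssq)
  out <- data.frame(effect = rownames(an), df = an$Df, ssq = ssq,
                    eta2 = ssq / total, row.names = NULL)
  out$effect[out$effect == "Residuals"] <- "residual"
  balanced <- length(unique(as.vector(cells))) == 1L
  if (balanced && length(factors) > 1L) {
    ## sequential and marginal SS must agree in a balanced design: refit with
    ## the factor order reversed and compare the main-effect SS
    fml2 <- stats::as.formula(paste("pa ~", rhs(rev(factors))))
    an2 <- stats::anova(stats::lm(fml2, data = df))
    for (f in factors) {
      d <- abs(an[f, "Sum Sq"] - an2[f, "Sum Sq"])
      if (d > 1e-8 * max(total, 1))
        warning("sequential SS depend on factor order for ", f,
                " despite balance (difference ", signif(d, 3), ")")
    }
  }
  r2 <- 1 - ssq[length(ssq)] / total
  structure(out, r2 = r2, n = nrow(df), factor_order = factors,
            class = c("eta2_table", "data.frame"))
}

#' @export
print.eta2_table <- function(x, ...) {
  cat("Eta-squared decomposition (sequential SS; n =", attr(x, "n"),
      "; R2 =", signif(attr(x, "r2"), 4), ")\n")
  print.data.frame(cbind(x[, c("effect", "df")],
                         ssq = signif(x$ssq, 5), eta2 = signif(x$eta2, 4)))
  invisible(x)
}
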