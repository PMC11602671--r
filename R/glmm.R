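# Mixed models for diversity indices: index ~ zone + (1|year) + (1|season)
# + (1|site).

#' GLMM of a diversity index on depth stratum
#'
#' Fits `index ~ zone + (1|year) + (1|season) + (1|site)` by maximum
#' likelihood with the Laplace approximation (`lme4::glmer`), with a Poisson
#' log-link family for integer richness and a Gamma log-link family for
#' positive continuous indices. The log link is used for the Gamma family
#' (rather than the canonical inverse link) for stability with
#' strictly positive indices. The zone contrast is assessed with a Wald
#' test; "significant" means p < 0.05.
#'
#' @param values response vector (richness counts or positive index values).
#' @param zone factor/character of depth strata aligned with `values`.
#' @param year,season,site random-intercept grouping factors; any factor
#'   with fewer than 2 levels is dropped with a warning.
#' @param family `"poisson-log"` or `"gamma-log"`.
#' @return a `glmm_result` list: `family`, `fixed` (data.frame with
#'   `estimate`, `std_error`, `test_value`, `p_value` per coefficient),
#'   `random_variances`, `converged`, `n` and the underlying `fit`.
#' @export
fit_glmm <- function(values, zone, year = NULL, season = NULL, site = NULL,
                     family = c("gamma-log", "poisson-log")) {
  family <- match.arg(family)
  keep <- is.finite(values)
  if (family == "gamma-log") keep <- keep & values > 0
  if (any(!keep)) {
    warning(sum(!keep), " missing/non-positive value(s) dropped")
  }
  dat <- data.frame(y = values, zone = factor(zone))[keep, , drop = FALSE]
  rterms <- character(0)
  for (g in c("year", "season", "site")) {
    v <- get(g)
    if (is.null(v)) next
    v <- factor(v)[keep]
    if (nlevels(droplevels(v)) < 2) {
      warning("random factor '", g, "' has < 2 levels and is dropped")
      next
    }
    dat[[g]] <- v
    rterms <- c(rterms, sprintf("(1|%s)", g))
  }
  if (!length(rterms)) stop("no usable random factors")
  form <- stats::as.formula(paste("y ~ zone +", paste(rterms, collapse = " + ")))
  fam <- if (family == "poisson-log") stats::poisson("log") else stats::Gamma("log")

  fit <- suppressMessages(suppressWarnings(
    lme4::glmer(form, data = dat, family = fam)
  ))
  sm <- summary(fit)$coefficients
  msgs <- fit@optinfo$conv$lme4$messages
  vc <- as.data.frame(lme4::VarCorr(fit))
  rv <- stats::setNames(vc$vcov[is.na(vc$var2)], vc$grp[is.na(vc$var2)])
  structure(
    list(family = family,
         fixed = data.frame(term = rownames(sm), estimate = sm[, 1],
                            std_error = sm[, 2], test_value = sm[, 3],
                            p_value = sm[, 4], row.names = NULL),
         random_variances = rv[names(rv) != "Residual"],
         boundary = any(rv[names(rv) != "Residual"] < 1e-8),
         converged = is.null(msgs),
         n = nrow(dat),
         fit = fit),
    class = "glmm_result"
  )
}

#' @exportS3Method base::print
print.glmm_result <- function(x, ...) {
  cat("GLMM (", x$family, ", Laplace ML), n = ", x$n, "\n", sep = "")
  print(x$fixed, digits = 3)
  cat("random-intercept variances:\n")
  print(round(x$random_variances, 4))
  if (!x$converged) cat("NOTE: convergence warnings reported by the optimizer\n")
  invisible(x)
}

#' Zone p-value helper
#' @param res a `glmm_result`.
#' @return Wald p-value of the (first) zone contrast.
#' @export
zone_p_value <- function(res) {
  ix <- grep("^zone", res$fixed$term)[1]
  res$fixed$p_value[ix]
}
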