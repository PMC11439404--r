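# Gamma GLM of community AGS on soil pH. Genome sizes are strictly positive
# and right-skewed, so the Gamma family is the natural response model; the
# explained variation is summarized by the deviance pseudo R-squared
# 1 - D_residual / D_null.

#' Fit a Gamma GLM of average genome size on soil pH
#'
#' Fits `ags ~ ph` with a Gamma-distributed response by iteratively
#' reweighted least squares (convergence at relative deviance change below
#' 1e-8, at most 100 iterations). The default inverse link is the canonical
#' Gamma link; a log link is available. The fit is summarized by its
#' coefficients on the link scale, the Pearson dispersion estimate, the null
#' and residual deviances, and the deviance-explained pseudo R-squared
#' `1 - residual_deviance / null_deviance` (the squared Pearson correlation
#' between observed and fitted values is also reported for transparency).
#'
#' @param ph numeric vector of soil pH values (finite).
#' @param ags numeric vector of average genome sizes in bp (> 0), same
#'   length as `ph`.
#' @param link `"inverse"` (default) or `"log"`.
#' @return an object of class `ags_glm` with `print`, `summary`, `coef`,
#'   `predict`, `fitted`, `residuals` and `plot` methods.
#' @examples
#' set.seed(1)
#' ph <- runif(50, 4, 9)
#' ags <- rgamma(50, shape = 30, rate = 30 / exp(15.5 - 0.15 * ph))
#' fit <- fit_gamma_glm(ph, ags, link = "log")
#' coef(fit)
#' summary(fit)
#' @export
fit_gamma_glm <- function(ph, ags, link = c("inverse", "log")) {
  link <- match.arg(link)
  ph <- as.numeric(ph)
  ags <- as.numeric(ags)
  if (length(ph) != length(ags)) {
    stop("ph and ags must have the same length", call. = FALSE)
  }
  keep <- is.finite(ph) & !is.na(ags)
  ph <- ph[keep]
  ags <- ags[keep]
  n <- length(ags)
  if (n < 3L) stop("need at least 3 complete observations", call. = FALSE)
  if (any(!is.finite(ags)) || any(ags <= 0)) {
    stop("ags must be finite and > 0 (Gamma response)", call. = FALSE)
  }
  dat <- data.frame(ph = ph, ags = ags)
  fit <- stats::glm(ags ~ ph,
    family = stats::Gamma(link = link), data = dat,
    control = stats::glm.control(epsilon = 1e-8, maxit = 100)
  )
  if (!fit$converged) {
    warning("Gamma GLM did not converge in 100 IRLS iterations", call. = FALSE)
  }
  pearson <- sum(stats::residuals(fit, type = "pearson")^2)
  dispersion <- pearson / fit$df.residual
  # a constant response has zero null deviance: nothing to explain
  pseudo_r2 <- if (fit$null.deviance <= .Machine$double.eps) {
    0
  } else {
    1 - fit$deviance / fit$null.deviance
  }
  structure(
    list(
      glm = fit,
      link = link,
      coefficients = stats::coef(fit),
      dispersion = dispersion,
      null_deviance = fit$null.deviance,
      residual_deviance = fit$deviance,
      pseudo_r2 = pseudo_r2,
      cor_fitted_sq = if (stats::sd(ags) == 0 || stats::sd(stats::fitted(fit)) == 0) {
        NA_real_ # undefined for a constant observed or fitted series
      } else {
        stats::cor(ags, stats::fitted(fit))^2
      },
      n = n,
      converged = fit$converged
    ),
    class = "ags_glm"
  )
}

#' @export
coef.ags_glm <- function(object, ...) object$coefficients

#' @export
fitted.ags_glm <- function(object, ...) stats::fitted(object$glm)

#' @export
residuals.ags_glm <- function(object, type = "deviance", ...) {
  stats::residuals(object$glm, type = type, ...)
}

#' Predict mean AGS at new pH values
#'
#' @param object an `ags_glm` fit.
#' @param newdata numeric vector of pH values, or a data.frame with a `ph`
#'   column; omitted = fitted values.
#' @param type `"response"` (mean AGS, default) or `"link"`.
#' @param ... unused.
#' @export
predict.ags_glm <- function(object, newdata = NULL, type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    return(stats::predict(object$glm, type = type))
  }
  if (is.numeric(newdata)) newdata <- data.frame(ph = newdata)
  stats::predict(object$glm, newdata = newdata, type = type)
}

#' @export
print.ags_glm <- function(x, ...) {
  cat(sprintf(
    "Gamma GLM (%s link), AGS ~ pH, n = %d\n", x$link, x$n
  ))
  cat(sprintf(
    "  intercept %.6g, slope %.6g (link scale)\n",
    x$coefficients[1L], x$coefficients[2L]
  ))
  cat(sprintf("  pseudo R-squared %.2f\n", x$pseudo_r2))
  if (!x$converged) cat("  WARNING: IRLS did not converge\n")
  invisible(x)
}

#' @export
summary.ags_glm <- function(object, ...) {
  structure(
    list(
      fit = object,
      glm_summary = summary(object$glm, dispersion = object$dispersion)
    ),
    class = "summary.ags_glm"
  )
}

#' @export
print.summary.ags_glm <- function(x, ...) {
  f <- x$fit
  print(f)
  cat(sprintf(
    "  dispersion (Pearson) %.4g\n  null deviance %.6g on %d df\n  residual deviance %.6g on %d df\n  squared obs-fitted correlation %.3f\n",
    f$dispersion, f$null_deviance, f$glm$df.null,
    f$residual_deviance, f$glm$df.residual, f$cor_fitted_sq
  ))
  cat("\nCoefficients:\n")
  stats::printCoefmat(x$glm_summary$coefficients)
  invisible(x)
}

#' Plot observed AGS against pH with the best-fit curve
#'
#' @param x an `ags_glm` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ags_glm <- function(x, ...) {
  ph <- x$glm$model$ph
  ags <- x$glm$model$ags
  graphics::plot(ph, ags / 1e6,
    xlab = "soil pH", ylab = "AGS (Mbp)",
    main = sprintf(
      "Gamma GLM (%s link), pseudo R² = %.2f",
      x$link, x$pseudo_r2
    ), ...
  )
  grid_ph <- seq(min(ph), max(ph), length.out = 200)
  graphics::lines(grid_ph, predict(x, grid_ph) / 1e6, lwd = 2)
  invisible(x)
}

#' Per-group Gamma GLM fits of AGS on pH
#'
#' Fits one Gamma GLM per group (e.g. soil environment type) plus the pooled
#' fit over all observations, and tabulates slope, pseudo R-squared and the
#' slope sign for each. Groups with fewer than 3 observations are skipped
#' with a warning.
#'
#' @inheritParams fit_gamma_glm
#' @param groups group labels, same length as `ph`.
#' @return an object of class `ags_glm_groups`: a list with `fits` (named
#'   list of `ags_glm`, including `"(pooled)"`) and `table` (data.frame with
#'   columns group, n, link, intercept, slope, pseudo_r2, slope_sign).
#' @export
grouped_fits <- function(ph, ags, groups, link = c("inverse", "log")) {
  link <- match.arg(link)
  stopifnot(length(groups) == length(ph), length(ph) == length(ags))
  groups <- as.character(groups)
  fits <- list(`(pooled)` = fit_gamma_glm(ph, ags, link))
  for (g in sort(unique(groups))) {
    sel <- groups == g
    if (sum(sel) < 3L) {
      warning("group ", sQuote(g), " has fewer than 3 samples; skipped",
        call. = FALSE
      )
      next
    }
    fits[[g]] <- fit_gamma_glm(ph[sel], ags[sel], link)
  }
  tab <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(
      group = nm, n = f$n, link = f$link,
      intercept = unname(f$coefficients[1L]),
      slope = unname(f$coefficients[2L]),
      pseudo_r2 = f$pseudo_r2,
      slope_sign = ifelse(f$coefficients[2L] < 0, "negative",
        ifelse(f$coefficients[2L] > 0, "positive", "zero")
      ),
      stringsAsFactors = FALSE
    )
  }))
  rownames(tab) <- NULL
  structure(list(fits = fits, table = tab), class = "ags_glm_groups")
}

#' @export
print.ags_glm_groups <- function(x, ...) {
  cat("Per-group Gamma GLM fits of AGS on pH:\n")
  tab <- x$table
  tab$pseudo_r2 <- round(tab$pseudo_r2, 2)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Fold-underestimation of an observed percentage against an assumed range
#'
#' Given an observed percentage and an assumed (low, high) percentage range,
#' the observed value represents an `observed/low`- to `observed/high`-fold
#' underestimation by the assumed range. Values are rounded to 1 decimal for
#' reporting.
#'
#' @param observed_median observed percentage, > 0.
#' @param assumed_range numeric length-2 `(low, high)` percentages,
#'   0 < low <= high.
#' @return named numeric `c(high_fold, low_fold)` — the fold factors against
#'   the low and high ends of the range respectively.
#' @examples
#' fold_underestimate(38.8, c(4, 9)) # 9.7-fold to 4.3-fold
#' @export
fold_underestimate <- function(observed_median, assumed_range) {
  if (length(assumed_range) != 2L) {
    stop("assumed_range must be (low, high)", call. = FALSE)
  }
  low <- assumed_range[1L]
  high <- assumed_range[2L]
  if (!all(is.finite(c(observed_median, low, high))) ||
    observed_median <= 0 || low <= 0 || high <= 0) {
    stop("all inputs must be finite and > 0", call. = FALSE)
  }
  if (low > high) stop("assumed_range must satisfy low <= high", call. = FALSE)
  c(
    high_fold = round(observed_median / low, 1),
    low_fold = round(observed_median / high, 1)
  )
}

#' Percent difference relative to an explicit reference
#'
#' `100 * |reference - other| / reference`, rounded to the nearest integer
#' for reporting. The caller states which value is the reference
#' (denominator); "x% lower" and "x% higher" comparisons in the literature
#' differ only in which quantity they divide by.
#'
#' @param reference the denominator value, > 0.
#' @param other the value compared against it.
#' @return integer percent difference.
#' @examples
#' percent_difference(6.8, 4.7) # 31
#' percent_difference(4.7, 3.0) # 36
#' @export
percent_difference <- function(reference, other) {
  if (!is.finite(reference) || reference <= 0) {
    stop("reference must be finite and > 0", call. = FALSE)
  }
  round(100 * abs(reference - other) / reference)
}

#' Write a fit-summary table to CSV
#'
#' @param fits an `ags_glm_groups` object (or a single `ags_glm`).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_fit_summary <- function(fits, path) {
  tab <- if (inherits(fits, "ags_glm_groups")) {
    fits$table
  } else if (inherits(fits, "ags_glm")) {
    grouped_single <- grouped_fits(
      fits$glm$model$ph, fits$glm$model$ags,
      rep("all", fits$n), fits$link
    )
    grouped_single$table[grouped_single$table$group == "(pooled)", ]
  } else {
    stop("fits must be an ags_glm or ags_glm_groups object", call. = FALSE)
  }
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
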