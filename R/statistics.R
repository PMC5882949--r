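# Group comparisons, reproducibility metrics, and dose-response fitting.

#' Kruskal-Wallis test with Scheffe-type post-hoc contrasts
#'
#' Nonparametric comparison of k groups: the overall tie-corrected
#' Kruskal-Wallis rank test, followed by simultaneous Scheffe-type contrasts
#' on the rank means. For groups i, j the contrast statistic is
#' \eqn{(\bar R_i - \bar R_j)^2 / (S^2 (1/n_i + 1/n_j))} with the
#' tie-corrected rank variance \eqn{S^2 = (\sum R^2 - N(N+1)^2/4)/(N-1)},
#' referred to a chi-square distribution with k - 1 degrees of freedom — the
#' classical nonparametric analogue of Scheffe's simultaneous contrasts.
#'
#' @param x either a list of numeric vectors (one per group), a formula
#'   \code{response ~ group}, or a numeric vector (then \code{g} gives the
#'   grouping factor).
#' @param g grouping factor when \code{x} is a numeric vector.
#' @param data data.frame for the formula interface.
#' @param alpha significance threshold applied to all reported p-values.
#' @param ... unused.
#' @return object of class \code{kw_scheffe}: overall \code{statistic} (H),
#'   \code{df}, \code{p.value}, per-group \code{n} and \code{rank_means},
#'   symmetric matrices \code{pairwise.p} and \code{significant}, plus
#'   \code{degenerate} (TRUE when all observations are tied, in which case
#'   the p-values are NA).
#' @export
kw_scheffe <- function(x, ...) UseMethod("kw_scheffe")

#' @rdname kw_scheffe
#' @export
kw_scheffe.formula <- function(x, data, alpha = 1e-4, ...) {
  mf <- stats::model.frame(x, data)
  kw_scheffe.default(mf[[1]], g = factor(mf[[2]]), alpha = alpha)
}

#' @rdname kw_scheffe
#' @export
kw_scheffe.list <- function(x, alpha = 1e-4, ...) {
  if (is.null(names(x))) names(x) <- paste0("group", seq_along(x))
  v <- unlist(x, use.names = FALSE)
  g <- factor(rep(names(x), lengths(x)), levels = names(x))
  kw_scheffe.default(v, g = g, alpha = alpha)
}

#' @rdname kw_scheffe
#' @export
kw_scheffe.default <- function(x, g, alpha = 1e-4, ...) {
  g <- factor(g)
  k <- nlevels(g)
  if (k < 2L) stop("need at least 2 groups")
  if (any(tabulate(g) < 2L)) stop("each group needs at least 2 observations")
  n <- tabulate(g)
  names(n) <- levels(g)
  N <- length(x)
  r <- rank(x)
  rm <- tapply(r, g, mean)
  s2 <- (sum(r^2) - N * (N + 1)^2 / 4) / (N - 1)
  degenerate <- s2 <= 0
  pw <- matrix(NA_real_, k, k, dimnames = list(levels(g), levels(g)))
  if (degenerate) {
    H <- NA_real_
    p <- NA_real_
  } else {
    kt <- stats::kruskal.test(x, g)
    H <- unname(kt$statistic)
    p <- kt$p.value
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        stat <- (rm[i] - rm[j])^2 / (s2 * (1 / n[i] + 1 / n[j]))
        pw[i, j] <- pw[j, i] <- stats::pchisq(stat, df = k - 1,
                                              lower.tail = FALSE)
      }
    }
    diag(pw) <- 1
  }
  structure(
    list(statistic = H, df = k - 1L, p.value = p, n = n,
         rank_means = rm, pairwise.p = pw,
         significant = !is.na(pw) & pw < alpha, alpha = alpha,
         degenerate = degenerate),
    class = "kw_scheffe"
  )
}

#' @export
print.kw_scheffe <- function(x, ...) {
  cat("Kruskal-Wallis rank test with Scheffe-type post-hoc contrasts\n")
  if (x$degenerate) {
    cat("  degenerate: all observations tied; p-values undefined\n")
    return(invisible(x))
  }
  cat(sprintf("  H = %.4g, df = %d, p = %.3g\n", x$statistic, x$df, x$p.value))
  cat(sprintf("  groups: %s\n",
              paste(sprintf("%s (n=%d)", names(x$n), x$n), collapse = ", ")))
  cat(sprintf("  pairwise p (Scheffe, threshold %g):\n", x$alpha))
  print(signif(x$pairwise.p, 3))
  invisible(x)
}

#' Reproducibility report across samples
#'
#' Summarises agreement of per-cell morphometrics between independently
#' processed samples: for each metric the mean absolute pairwise difference
#' of the per-sample means and the coefficient of variation
#' (sd of the sample means / their mean); optionally the mean pairwise
#' normalized cross-correlation between the samples' morphology maps.
#'
#' @param tables list (length >= 2) of per-cell data.frames, one per sample.
#' @param metrics character vector of metric columns; defaults to the
#'   numeric columns common to all samples.
#' @param maps optional list of \code{\link{population_map}}s, one per
#'   sample.
#' @return object of class \code{reproducibility_report}: data.frame
#'   \code{metrics} with columns \code{metric}, \code{mean_abs_diff},
#'   \code{cv}, plus \code{cc_morph} (mean pairwise map correlation or NA)
#'   and the per-sample means.
#' @export
reproducibility <- function(tables, metrics = NULL, maps = NULL) {
  if (length(tables) < 2L) stop("need at least 2 samples")
  if (is.null(metrics)) {
    metrics <- Reduce(intersect, lapply(tables, function(d) {
      names(d)[vapply(d, is.numeric, logical(1))]
    }))
    metrics <- setdiff(metrics, c("cell_id", "n_px", "centroid_x",
                                  "centroid_y"))
  }
  means <- sapply(metrics, function(m) {
    vapply(tables, function(d) mean(d[[m]], na.rm = TRUE), numeric(1))
  })
  means <- matrix(means, nrow = length(tables),
                  dimnames = list(NULL, metrics))
  res <- data.frame(
    metric = metrics,
    mean_abs_diff = vapply(metrics, function(m) {
      mu <- means[, m]
      d <- abs(outer(mu, mu, "-"))
      mean(d[upper.tri(d)])
    }, numeric(1)),
    cv = vapply(metrics, function(m) {
      mu <- means[, m]
      stats::sd(mu) / mean(mu)
    }, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  cc <- NA_real_
  if (!is.null(maps)) {
    if (length(maps) != length(tables)) stop("one map per sample required")
    pairs <- utils::combn(length(maps), 2)
    cc <- mean(apply(pairs, 2, function(ij) {
      morphology_cc(maps[[ij[1]]], maps[[ij[2]]])
    }))
  }
  structure(
    list(metrics = res, cc_morph = cc, sample_means = means,
         n_samples = length(tables)),
    class = "reproducibility_report"
  )
}

#' @export
print.reproducibility_report <- function(x, ...) {
  cat("reproducibility across", x$n_samples, "samples\n")
  df <- x$metrics
  df$mean_abs_diff <- signif(df$mean_abs_diff, 3)
  df$cv <- signif(df$cv, 3)
  print(df, row.names = FALSE)
  if (!is.na(x$cc_morph)) cat(sprintf("CC^morph = %.3f\n", x$cc_morph))
  invisible(x)
}

#' Fit a logistic Hill dose-response model
#'
#' Nonlinear least squares of
#' \eqn{y = bottom + (top - bottom) / (1 + (x / ic50)^{hill})}, parameterised
#' in log-dose (so ic50 stays positive), with nonparametric case-resampling
#' bootstrap confidence intervals. Initialisation: top/bottom from the mean
#' responses at the extreme doses, ic50 from the dose whose mean response is
#' nearest the half-range, hill = 1.
#'
#' @param dose positive dose vector.
#' @param response response vector (same length).
#' @param n_boot bootstrap resamples for the confidence intervals (0 to skip).
#' @param level confidence level.
#' @param seed optional RNG seed making the bootstrap reproducible.
#' @return object of class \code{hill_fit} with elements \code{coefficients}
#'   (top, bottom, ic50, hill), \code{ci} (percentile bootstrap intervals),
#'   \code{fitted}, \code{residuals}, \code{data}, \code{boot}
#'   (resampled coefficients) and \code{convInfo}.
#' @export
hill_fit <- function(dose, response, n_boot = 1000, level = 0.95,
                     seed = NULL) {
  stopifnot(length(dose) == length(response), all(dose > 0),
            all(is.finite(dose)), all(is.finite(response)))
  if (length(unique(dose)) < 5L) {
    stop("need at least 5 dose levels spanning the transition")
  }
  dat <- data.frame(lx = log(dose), y = response)
  mu <- tapply(response, dose, mean)
  ds <- sort(unique(dose))
  top0 <- mu[[as.character(ds[1])]]
  bottom0 <- mu[[as.character(ds[length(ds)])]]
  half <- (top0 + bottom0) / 2
  ic0 <- ds[which.min(abs(mu[as.character(ds)] - half))]
  fit1 <- function(d, start) {
    minpack.lm::nlsLM(
      y ~ bottom + (top - bottom) / (1 + exp(hill * (lx - lic))),
      data = d, start = start,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )
  }
  start0 <- list(top = top0, bottom = bottom0, lic = log(ic0), hill = 1)
  fit <- tryCatch(fit1(dat, start0), error = function(e) e)
  if (inherits(fit, "error")) {
    stop("Hill fit did not converge (flat or unidentifiable response): ",
         conditionMessage(fit))
  }
  cf <- stats::coef(fit)
  est <- c(top = unname(cf["top"]), bottom = unname(cf["bottom"]),
           ic50 = exp(unname(cf["lic"])), hill = unname(cf["hill"]))
  boot <- NULL
  ci <- NULL
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    n <- nrow(dat)
    start_hat <- as.list(cf)
    boot <- matrix(NA_real_, n_boot, 4,
                   dimnames = list(NULL, names(est)))
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      fb <- tryCatch(fit1(dat[idx, , drop = FALSE], start_hat),
                     error = function(e) NULL)
      if (!is.null(fb)) {
        cb <- stats::coef(fb)
        boot[b, ] <- c(cb["top"], cb["bottom"], exp(cb["lic"]), cb["hill"])
      }
    }
    qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
    ci <- t(apply(boot, 2, stats::quantile, probs = qs, na.rm = TRUE))
  }
  structure(
    list(coefficients = est, ci = ci, level = level,
         fitted = stats::fitted(fit), residuals = stats::resid(fit),
         data = data.frame(dose = dose, response = response),
         boot = boot, nls = fit),
    class = "hill_fit"
  )
}

#' @export
coef.hill_fit <- function(object, ...) object$coefficients

#' @export
fitted.hill_fit <- function(object, ...) object$fitted

#' @export
residuals.hill_fit <- function(object, ...) object$residuals

#' Predict responses from a Hill fit
#'
#' @param object a \code{\link{hill_fit}}.
#' @param newdata optional data.frame with a \code{dose} column (or a numeric
#'   dose vector); defaults to the fitted doses.
#' @param ... unused.
#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) {
    object$data$dose
  } else if (is.data.frame(newdata)) {
    newdata$dose
  } else {
    as.numeric(newdata)
  }
  cf <- object$coefficients
  cf["bottom"] + (cf["top"] - cf["bottom"]) /
    (1 + (d / cf["ic50"])^cf["hill"])
}

#' Simulate responses from a fitted Hill model
#'
#' Draws \code{nsim} response vectors at the fitted doses using Gaussian
#' noise with the residual standard deviation.
#'
#' @param object a \code{\link{hill_fit}}.
#' @param nsim number of simulated response vectors.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return data.frame with one column per simulation.
#' @export
simulate.hill_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- predict(object)
  s <- stats::sd(object$residuals)
  out <- as.data.frame(replicate(nsim, mu + stats::rnorm(length(mu), sd = s)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
print.hill_fit <- function(x, ...) {
  cat("logistic Hill dose-response fit\n")
  cf <- x$coefficients
  for (p in names(cf)) {
    if (!is.null(x$ci)) {
      cat(sprintf("  %-7s %.4g  [%.4g, %.4g]\n", p, cf[p],
                  x$ci[p, 1], x$ci[p, 2]))
    } else {
      cat(sprintf("  %-7s %.4g\n", p, cf[p]))
    }
  }
  cat(sprintf("  residual sd %.3g on %d observations\n",
              stats::sd(x$residuals), nrow(x$data)))
  invisible(x)
}

#' @export
summary.hill_fit <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Plot a Hill dose-response fit
#'
#' Data points, the fitted curve on a log-dose axis, and (when a bootstrap
#' was run) the pointwise bootstrap confidence band.
#'
#' @param x a \code{\link{hill_fit}}.
#' @param n_curve points on the fitted curve.
#' @param ... passed to \code{\link[graphics]{plot}}.
#' @export
plot.hill_fit <- function(x, n_curve = 200, ...) {
  d <- x$data
  xs <- exp(seq(log(min(d$dose)), log(max(d$dose)), length.out = n_curve))
  graphics::plot(d$dose, d$response, log = "x",
                 xlab = "dose", ylab = "response", ...)
  if (!is.null(x$boot)) {
    bs <- x$boot[stats::complete.cases(x$boot), , drop = FALSE]
    curves <- apply(bs, 1, function(cf) {
      cf["bottom"] + (cf["top"] - cf["bottom"]) /
        (1 + (xs / cf["ic50"])^cf["hill"])
    })
    band <- apply(curves, 1, stats::quantile,
                  probs = c((1 - x$level) / 2, 1 - (1 - x$level) / 2))
    graphics::polygon(c(xs, rev(xs)), c(band[1, ], rev(band[2, ])),
                      col = grDevices::grey(0.85), border = NA)
    graphics::points(d$dose, d$response)
  }
  graphics::lines(xs, predict(x, xs), lwd = 2)
  invisible(x)
}
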