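# Fitting dose-response-parameter plots versus cofactor amount with
# nested shapes (constant, linear through origin, linear, Michaelis-
# Menten, general linear-fractional) and reading off the qualitative plot
# signature used by the rule table.

#' Fit a parameter plot as a linear-fractional function of cofactor amount
#'
#' Weighted least squares (`1/sem^2`; unweighted when `sem` is `NULL`) of
#' the general linear-fractional shape `y = (a + bx)/(1 + dx)` with
#' positivity constraints on `a`, `b`, `d`, together with the nested null
#' shapes constant, linear-through-origin `b*x`, linear `a + b*x` and
#' Michaelis-Menten `V*x/(m + x)`.  Each shape is scored by
#' `BIC = chi2 + k log n`, mirroring how competing plot shapes are
#' compared on real traces.
#'
#' @param x Cofactor amounts (already including any endogenous offset).
#' @param y Parameter values.
#' @param sem Per-point standard errors (`> 0`), or `NULL`.
#' @return A `param_fit` object: `shape` (BIC-best), `lf` (the best shape
#'   as a [linear_fractional()]), `coef`, `bic` (named vector over
#'   shapes), `chi2`, `k`, `n`, `x_intercept`, `x_intercept_se`.
#' @export
fit_param_vs_cofactor <- function(x, y, sem = NULL) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y) & (if (is.null(sem)) TRUE else is.finite(sem))
  if (!all(keep)) {
    x <- x[keep]; y <- y[keep]
    if (!is.null(sem)) sem <- sem[keep]
  }
  if (length(x) < 2L) stop("need at least 2 finite points")
  n <- length(x)
  w <- if (is.null(sem)) rep(1, n) else {
    stopifnot(all(sem > 0)); 1 / sem^2
  }
  chi2_of <- function(pred) sum(w * (y - pred)^2)
  shapes <- list()

  # constant
  a <- sum(w * y) / sum(w)
  shapes$const <- list(k = 1, chi2 = chi2_of(rep(a, n)),
                       lf = linear_fractional(a, 0, 1, 0), coef = c(a = a))
  # linear through the origin
  b <- sum(w * x * y) / sum(w * x^2)
  shapes$linear_origin <- list(k = 1, chi2 = chi2_of(b * x),
                               lf = linear_fractional(0, b, 1, 0),
                               coef = c(b = b))
  # linear
  X <- cbind(1, x)
  cf <- tryCatch(solve(crossprod(X * sqrt(w)), crossprod(X * sqrt(w), y * sqrt(w))),
                 error = function(e) NULL)
  if (!is.null(cf)) {
    pred <- X %*% cf
    cov_lin <- tryCatch({
      s2 <- chi2_of(pred) / max(1, n - 2)
      if (is.null(sem)) s2 * solve(crossprod(X * sqrt(w))) else solve(crossprod(X * sqrt(w)))
    }, error = function(e) NULL)
    shapes$linear <- list(k = 2, chi2 = chi2_of(pred),
                          lf = linear_fractional(cf[1], cf[2], 1, 0),
                          coef = c(a = cf[1], b = cf[2]), cov = cov_lin)
  }
  # Michaelis-Menten V x / (m + x), profiled over m
  if (n >= 3 && any(x > 0)) {
    rss_m <- function(logm) {
      m <- exp(logm); xs <- x / (m + x)
      V <- sum(w * xs * y) / sum(w * xs^2)
      chi2_of(V * xs)
    }
    lo <- log(max(min(x[x > 0]) / 100, 1e-9)); hi <- log(max(x) * 100)
    grid <- seq(lo, hi, length.out = 50)
    g0 <- grid[which.min(vapply(grid, rss_m, numeric(1)))]
    op <- stats::optimize(rss_m, c(max(lo, g0 - 1), min(hi, g0 + 1)), tol = 1e-10)
    m <- exp(op$minimum); xs <- x / (m + x)
    V <- sum(w * xs * y) / sum(w * xs^2)
    shapes$mm <- list(k = 2, chi2 = chi2_of(V * xs),
                      lf = linear_fractional(0, V, m, 1),
                      coef = c(V = V, m = m))
  }
  # general linear-fractional (a + b x)/(1 + d x), profiled over d >= 0
  if (n >= 4) {
    fit_ab <- function(d) {
      den <- 1 + d * x
      Z <- cbind(1 / den, x / den)
      cf <- tryCatch(solve(crossprod(Z * sqrt(w)), crossprod(Z * sqrt(w), y * sqrt(w))),
                     error = function(e) c(0, 0))
      cf <- pmax(as.numeric(cf), 0)
      list(cf = cf, chi2 = chi2_of(Z %*% cf))
    }
    rss_d <- function(logd) fit_ab(exp(logd))$chi2
    lo <- log(1e-6 / max(x[x > 0], 1)); hi <- log(1e4 / max(min(x[x > 0]), 1e-9))
    grid <- seq(lo, hi, length.out = 50)
    g0 <- grid[which.min(vapply(grid, rss_d, numeric(1)))]
    op <- stats::optimize(rss_d, c(max(lo, g0 - 1), min(hi, g0 + 1)), tol = 1e-10)
    cand <- list(exp(op$minimum), 0)
    best <- NULL
    for (d in cand) {
      f <- fit_ab(d)
      if (is.null(best) || f$chi2 < best$chi2) best <- c(f, d = d)
    }
    shapes$lf <- list(k = 3, chi2 = best$chi2,
                      lf = linear_fractional(best$cf[1], best$cf[2], 1, best$d),
                      coef = c(a = best$cf[1], b = best$cf[2], d = best$d))
  }

  bic <- vapply(shapes, function(s) s$chi2 + s$k * log(n), numeric(1))
  best_name <- names(which.min(bic))
  best <- shapes[[best_name]]

  # x-axis intersection of the numerator a + b x
  xi <- NA_real_; xi_se <- NA_real_
  cf <- best$coef
  if (best_name %in% c("linear", "lf") && cf["b"] != 0) {
    xi <- -cf["a"] / cf["b"]
    if (best_name == "linear" && !is.null(best$cov)) {
      # delta method on -a/b
      gr <- c(-1 / cf["b"], cf["a"] / cf["b"]^2)
      xi_se <- sqrt(drop(t(gr) %*% best$cov %*% gr))
    }
  }
  if (best_name %in% c("linear_origin", "mm")) { xi <- 0; xi_se <- 0 }

  structure(list(shape = best_name, lf = best$lf, coef = best$coef,
                 chi2 = vapply(shapes, `[[`, numeric(1), "chi2"),
                 bic = bic, k = best$k, n = n,
                 x_intercept = unname(xi), x_intercept_se = unname(xi_se),
                 x = x, y = y, sem = sem),
            class = "param_fit")
}

#' @export
print.param_fit <- function(x, ...) {
  cat(sprintf("<param_fit> best shape: %s (BIC %.2f); coef: %s\n", x$shape,
              min(x$bic), paste(sprintf("%s=%.4g", names(x$coef), x$coef),
                                collapse = ", ")))
  invisible(x)
}

# point estimates of half-max concentrations are noisy; only decisive
# inequalities are reported ("unknown" otherwise).  Exact equality is a
# posterior-level statement, tested via posterior_halfmax_ordering().
ordering_of <- function(h1, h2, rel_tol = 0.2) {
  if (!is.finite(h1) || !is.finite(h2)) return("unknown")
  if (abs(h1 - h2) <= rel_tol * max(abs(h1), abs(h2))) return("unknown")
  if (h1 < h2) "<" else ">"
}

#' Extract the qualitative plot signature from the four parameter fits
#'
#' Produces the feature set matched against the prediction rule table:
#' monotonic direction of each parameter, linearity and origin behaviour
#' of `Amax` and `Amin` at the true zero of total factor (exogenous +
#' endogenous), whether decreasing plots approach zero, and the half-max
#' orderings of `Amin` vs `Amax` and of their reciprocals.
#'
#' @param fits Named list with `amax`, `amin`, `ic50`, `ratio`
#'   entries, each a `param_fit`.
#' @param endogenous_level Endogenous factor amount in the units of the x
#'   axis (0 for small molecules); the true zero sits at
#'   `x = -endogenous_level`.
#' @param amax_gt_amin Whether raw (un-normalised) `Amax` exceeded `Amin`
#'   in the underlying dose-response fits.
#' @param const_tol Tolerance of the constant classification (passed to
#'   [lf_shape()]).
#' @param ord_tol Relative tolerance below which half-max orderings are
#'   reported as unknown.
#' @param const_margin A direction is only called when the flat (constant)
#'   shape loses by at least this much BIC; weak or noise-dominated
#'   trends are reported as "const" (non-informative) rather than as an
#'   unreliable direction.
#' @param range_tol Minimum relative variation of the fitted curve over
#'   the data range for a direction call, per parameter; near-horizontal
#'   traces below it are read as constant, the way slowly-varying
#'   experimental parameter plots are.  `IC50` and the ratio
#'   `Amax*IC50/Amin` compound two and three fitted quantities and carry
#'   the heaviest small-sample estimator bias at four-dose designs, so
#'   their direction calls require stronger trends.
#' @return A `plot_signature` list.
#' @export
extract_signature <- function(fits, endogenous_level = 0, amax_gt_amin = TRUE,
                              const_tol = 0.05, ord_tol = 0.2,
                              const_margin = 2,
                              range_tol = c(amax = 0.25, amin = 0.25,
                                            ic50 = 0.4, ratio = 0.8)) {
  stopifnot(all(c("amax", "amin", "ic50", "ratio") %in% names(fits)))
  dirs <- character(0); lin <- logical(0); orig <- logical(0)
  pos0 <- logical(0); zero_inf <- logical(0)
  hmax <- c(); hrec <- c()
  for (p in c("amax", "amin", "ic50", "ratio")) {
    f <- fits[[p]]
    sh <- lf_shape(f$lf, const_tol = const_tol)
    fitted_rng <- range(lf_eval(f$lf, seq(min(f$x), max(f$x), length.out = 25)))
    rel_rng <- diff(fitted_rng) / max(mean(abs(fitted_rng)), .Machine$double.xmin)
    rtol <- if (length(range_tol) > 1L) range_tol[[p]] else range_tol
    d <- if (f$shape == "const" ||
             f$bic["const"] - min(f$bic) <= const_margin ||
             rel_rng <= rtol) "const" else sh$direction
    dirs[p] <- d
    lin[p] <- f$shape %in% c("linear", "linear_origin")
    # extrapolation to the true zero is only meaningful when the fitted
    # curve has no pole between the true zero and the data; otherwise the
    # value at the smallest measured x stands in
    pole <- if (f$lf$d != 0) -f$lf$c / f$lf$d else -Inf
    v0 <- if (pole > -endogenous_level - 1e-12 && pole <= min(f$x)) {
      lf_eval(f$lf, min(f$x))
    } else {
      lf_eval(f$lf, -endogenous_level)
    }
    # "through the origin" is judged against the curve's own scale at the
    # first measured point, not the (group-inflated) series maximum
    ref <- abs(lf_eval(f$lf, min(f$x)))
    near0 <- abs(v0) <= 0.05 * max(ref, .Machine$double.xmin)
    through <- if (!is.na(f$x_intercept) && !is.na(f$x_intercept_se)) {
      abs(f$x_intercept + endogenous_level) <= 2 * max(f$x_intercept_se, 1e-12)
    } else near0
    orig[p] <- d == "inc" && (near0 || through)
    pos0[p] <- is.finite(v0) && v0 > 0 && !orig[p]
    asym <- if (f$lf$d != 0) f$lf$b / f$lf$d else NA_real_
    zero_inf[p] <- d == "dec" && is.finite(asym) &&
      abs(asym) <= 0.05 * max(abs(v0), max(abs(f$y)))
    hmax[p] <- if (f$lf$d != 0) f$lf$c / f$lf$d else Inf
    hrec[p] <- if (f$lf$b != 0) f$lf$a / f$lf$b else Inf
  }
  structure(list(
    direction = dirs,
    linear = lin,
    through_origin = orig,
    positive_at_true_zero = pos0,
    approaches_zero = zero_inf,
    ord_amin_amax = ordering_of(hmax["amin"], hmax["amax"], ord_tol),
    ord_inv_amin_amax = ordering_of(hrec["amin"], hrec["amax"], ord_tol),
    half_max = hmax, reciprocal_half_max = hrec,
    amax_gt_amin = isTRUE(amax_gt_amin),
    endogenous_level = endogenous_level
  ), class = "plot_signature")
}

#' @export
print.plot_signature <- function(x, ...) {
  cat("<plot_signature>\n")
  for (p in names(x$direction)) {
    cat(sprintf("  %-5s: %-5s%s%s%s\n", p, x$direction[p],
                if (x$linear[p]) " linear" else "",
                if (x$through_origin[p]) " through-origin" else "",
                if (x$positive_at_true_zero[p]) " positive-at-true-zero" else ""))
  }
  cat(sprintf("  H(Amin) %s H(Amax); H(1/Amin) %s H(1/Amax); Amax>Amin: %s\n",
              x$ord_amin_amax, x$ord_inv_amin_amax, x$amax_gt_amin))
  invisible(x)
}
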