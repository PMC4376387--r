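# Fitting the repression dose-response per assay cell, building normalised
# dose-response-parameter plots, and reading off their qualitative shape.

#' Fit the first-order repression (or induction) dose-response
#'
#' Two-stage procedure: the zero-dose plateau is estimated directly as the
#' mean activity of the vehicle (EtOH) wells, subtracted from the data,
#' and the remainder is fitted to a Michaelis-Menten function by least
#' squares, giving `Amin` and `IC50` (for repression:
#' `A = (Amax + Amin * S/IC50) / (1 + S/IC50)`).  A joint three-parameter
#' fit is available for comparison.
#'
#' @param doses Steroid doses, `>= 0`, with at least one zero (vehicle)
#'   and three positive doses.
#' @param activities Activities (replicates allowed: repeated doses).
#' @param mode `"repression"` (activity falls with dose; fits `Amax`,
#'   `Amin`, `IC50`) or `"induction"` (rises; fits `EC50`).
#' @param method `"two-stage"` (default) or `"joint"`.
#' @return A `dr_param_estimate` list: `amax`, `amin`, `ic50` (or `ec50`),
#'   `ratio = amax*ic50/amin`, `r_squared`, `se` (approximate standard
#'   errors), and `flags` (`flat`, `wrong_mode`, `clipped`).
#' @export
fit_dose_response <- function(doses, activities,
                              mode = c("repression", "induction"),
                              method = c("two-stage", "joint")) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  stopifnot(length(doses) == length(activities), all(doses >= 0))
  if (!any(doses == 0)) stop("no zero-dose (vehicle) rows in the group")
  if (length(unique(doses[doses > 0])) < 3L) {
    stop("need at least 3 positive doses")
  }
  a0 <- mean(activities[doses == 0])
  s <- doses[doses > 0]; a <- activities[doses > 0]
  flags <- list(flat = FALSE, wrong_mode = FALSE, clipped = FALSE)

  # direction sanity: activity should fall (repression) / rise (induction)
  slope_sign <- sign(suppressWarnings(stats::cor(s, a)))
  if (!is.na(slope_sign)) {
    if (mode == "repression" && slope_sign > 0) flags$wrong_mode <- TRUE
    if (mode == "induction" && slope_sign < 0) flags$wrong_mode <- TRUE
  }

  rng <- max(abs(c(activities, 1))) * 1e-10
  if (stats::sd(activities) <= rng) {
    est <- list(amax = a0, amin = a0, ic50 = NA_real_, ec50 = NA_real_,
                ratio = NA_real_, r_squared = NA_real_,
                se = c(amin = NA_real_, ic50 = NA_real_),
                flags = modifyList(flags, list(flat = TRUE)), mode = mode)
    class(est) <- "dr_param_estimate"
    return(est)
  }

  # y = a0 - A (repression) or A - a0 (induction) is Michaelis-Menten in S:
  # y = amp * S / (k + S); profile the half-saturation, amplitude is linear
  y <- if (mode == "repression") a0 - a else a - a0
  amp_for <- function(k) {
    xs <- s / (k + s)
    sum(xs * y) / sum(xs * xs)
  }
  rss_for <- function(logk) {
    k <- exp(logk)
    amp <- amp_for(k)
    sum((y - amp * s / (k + s))^2)
  }
  lo <- log(min(s) / 100); hi <- log(max(s) * 100)
  # coarse grid then golden-section polish: the profiled RSS can be
  # multimodal for noisy 4-point designs
  grid <- seq(lo, hi, length.out = 60)
  r <- vapply(grid, rss_for, numeric(1))
  g0 <- grid[which.min(r)]
  opt <- stats::optimize(rss_for, c(max(lo, g0 - 0.5), min(hi, g0 + 0.5)),
                         tol = 1e-12)
  k <- exp(opt$minimum)
  amp <- amp_for(k)

  if (method == "joint") {
    obj <- function(p) {
      a0j <- p[1]; ampj <- p[2]; kj <- exp(p[3])
      yy <- if (mode == "repression") a0j - activities else activities - a0j
      sum((yy - ampj * doses / (kj + doses))^2)
    }
    fitj <- stats::optim(c(a0, amp, log(k)), obj, method = "Nelder-Mead",
                         control = list(maxit = 5000, reltol = 1e-14))
    a0 <- fitj$par[1]; amp <- fitj$par[2]; k <- exp(fitj$par[3])
  }

  # a half-suppression point far outside the measured dose range is not
  # identifiable from a three-positive-dose design; report NA rather than
  # a bracket artefact (and when it runs high the amplitude -- hence Amin
  # -- is equally undetermined)
  flags$ic50_unidentifiable <- k > max(s) * 10 || k < min(s) / 20
  if (mode == "repression") {
    amax <- a0
    amin <- amax - amp
    if (amin < 0) { amin <- 0; flags$clipped <- TRUE
      warning("fitted Amin < 0; clipped to 0") }
    ic50 <- k; ec50 <- NA_real_
  } else {
    amin <- a0
    amax <- amin + amp
    ic50 <- NA_real_; ec50 <- k
  }

  pred <- if (mode == "repression") {
    (amax + (amin / k) * doses) / (1 + doses / k)
  } else {
    (amin + (amax / k) * doses) / (1 + doses / k)
  }
  ss_res <- sum((activities - pred)^2)
  ss_tot <- sum((activities - mean(activities))^2)

  if (flags$ic50_unidentifiable) {
    if (mode == "repression") {
      ic50 <- NA_real_
      if (k > max(s)) amin <- NA_real_
    } else {
      ec50 <- NA_real_
      if (k > max(s)) amax <- NA_real_
    }
  }
  # without appreciable repression the half-suppression point (and hence
  # the combination Amax*IC50/Amin) is not a meaningful quantity
  flags$weak_repression <- mode == "repression" && is.finite(amin) &&
    amin > 0 && amax / amin < 1.3
  if (flags$weak_repression) ic50 <- NA_real_
  ratio <- if (mode == "repression" && is.finite(amin) && amin > 0 &&
               is.finite(ic50)) amax * ic50 / amin else NA_real_

  # asymptotic SEs of (amp, k) from the stage-two Jacobian
  xs <- s / (k + s)
  Jm <- cbind(xs, -amp * s / (k + s)^2)
  se <- tryCatch({
    sigma2 <- sum((y - amp * xs)^2) / max(1, length(y) - 2)
    cv <- sigma2 * solve(crossprod(Jm))
    c(amin = sqrt(cv[1, 1]), ic50 = sqrt(cv[2, 2]))
  }, error = function(e) c(amin = NA_real_, ic50 = NA_real_))

  est <- list(amax = amax, amin = amin, ic50 = ic50, ec50 = ec50,
              ratio = ratio, r_squared = 1 - ss_res / ss_tot,
              se = se, flags = flags, mode = mode)
  class(est) <- "dr_param_estimate"
  est
}

#' @export
print.dr_param_estimate <- function(x, ...) {
  cat(sprintf("<dr_param_estimate> Amax=%.4g Amin=%.4g %s=%.4g ratio=%.4g R2=%.4f\n",
              x$amax, x$amin,
              if (x$mode == "repression") "IC50" else "EC50",
              if (x$mode == "repression") x$ic50 else x$ec50,
              x$ratio, x$r_squared))
  invisible(x)
}

#' Build normalised dose-response-parameter plots from an assay table
#'
#' Every (reporter dose x cofactor dose) cell of every experiment is fitted
#' with [fit_dose_response()]; within each experiment all four parameters
#' are divided by their value in the anchor cell (lowest reporter and
#' lowest cofactor dose), then averaged across experiments with the SEM
#' propagated.
#'
#' @param table An assay table as produced by [generate_assay()] (columns
#'   `reporter_dose`, `cofactor_id`, `cofactor_dose`, `steroid_dose`,
#'   `replicate`, `experiment`, `activity`).
#' @param x_var Which titration forms the x axis: `"cofactor"` or
#'   `"reporter"` (the other variable labels the trace).
#' @param mode Passed to [fit_dose_response()].
#' @return A `param_plot_dataset`: long data frame with columns `param`
#'   (`amax`/`amin`/`ic50`/`ratio`), `x`, `group` (the other dose), `value`,
#'   `sem`, `n`; attributes `x_var` and `frac_amax_gt_amin` (fraction of
#'   cell fits with raw `Amax > Amin`).
#' @export
normalize_grid <- function(table, x_var = c("cofactor", "reporter"),
                           mode = "repression") {
  x_var <- match.arg(x_var)
  req <- c("reporter_dose", "cofactor_dose", "steroid_dose", "activity")
  if (!all(req %in% names(table))) {
    stop("assay table must have columns: ", paste(req, collapse = ", "))
  }
  if (is.null(table$experiment)) table$experiment <- 1L

  cells <- unique(table[c("experiment", "reporter_dose", "cofactor_dose")])
  fits <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    sub <- table[table$experiment == cells$experiment[i] &
                 table$reporter_dose == cells$reporter_dose[i] &
                 table$cofactor_dose == cells$cofactor_dose[i], ]
    fits[[i]] <- fit_dose_response(sub$steroid_dose, sub$activity, mode = mode)
  }
  cells$amax <- vapply(fits, `[[`, numeric(1), "amax")
  cells$amin <- vapply(fits, `[[`, numeric(1), "amin")
  cells$ic50 <- vapply(fits, function(f) {
    if (f$mode == "repression") f$ic50 else f$ec50
  }, numeric(1))
  cells$ratio <- vapply(fits, `[[`, numeric(1), "ratio")
  frac_gt <- mean(cells$amax > cells$amin, na.rm = TRUE)

  # per-experiment normalisation to the anchor cell
  r0 <- min(cells$reporter_dose); c0 <- min(cells$cofactor_dose)
  params <- c("amax", "amin", "ic50", "ratio")
  for (e in unique(cells$experiment)) {
    idx <- cells$experiment == e
    anchor <- cells[idx & cells$reporter_dose == r0 & cells$cofactor_dose == c0, ]
    if (nrow(anchor) != 1L) stop("missing anchor cell (lowest reporter and cofactor) in experiment ", e)
    for (p in params) cells[idx, p] <- cells[idx, p] / anchor[[p]]
  }

  xcol <- if (x_var == "cofactor") "cofactor_dose" else "reporter_dose"
  gcol <- if (x_var == "cofactor") "reporter_dose" else "cofactor_dose"
  out <- list()
  for (p in params) {
    v <- cells[[p]]
    v[!is.finite(v)] <- NA
    agg_mean <- stats::aggregate(v, by = list(x = cells[[xcol]], group = cells[[gcol]]),
                                 FUN = mean, na.rm = TRUE)
    agg_sd <- stats::aggregate(v, by = list(x = cells[[xcol]], group = cells[[gcol]]),
                               FUN = stats::sd, na.rm = TRUE)
    agg_n <- stats::aggregate(v, by = list(x = cells[[xcol]], group = cells[[gcol]]),
                              FUN = function(z) sum(is.finite(z)))
    out[[p]] <- data.frame(param = p, x = agg_mean$x, group = agg_mean$group,
                           value = agg_mean[[3]],
                           sem = agg_sd[[3]] / sqrt(agg_n[[3]]),
                           n = agg_n[[3]])
  }
  ds <- do.call(rbind, out)
  rownames(ds) <- NULL
  ds <- ds[order(ds$param, ds$group, ds$x), ]
  class(ds) <- c("param_plot_dataset", "data.frame")
  attr(ds, "x_var") <- x_var
  attr(ds, "frac_amax_gt_amin") <- frac_gt
  ds
}

#' Linearise plasmid amounts against a saturating Western-blot calibration
#'
#' Expressed protein saturates with transfected plasmid:
#' `OD = m1 * p / (m2 + p)`.  The fitted `m2` converts plasmid amounts to
#' their functional linear equivalents `m2 * p / (m2 + p)`.
#'
#' @param od Optical densities of the protein band.
#' @param plasmid Transfected plasmid amounts (ng), same length.
#' @return A list with `calibration` (list `m1`, `m2`),
#'   `corrected_plasmid`, and `identity` (`TRUE` when no saturation could
#'   be detected and the correction is the identity, with a warning).
#' @export
western_linearize <- function(od, plasmid) {
  stopifnot(length(od) == length(plasmid), all(plasmid >= 0))
  if (length(unique(plasmid)) < 3L) stop("need >= 3 plasmid levels")
  pos <- plasmid > 0
  rss_for <- function(logm2) {
    m2 <- exp(logm2)
    xs <- plasmid / (m2 + plasmid)
    m1 <- sum(xs * od) / sum(xs * xs)
    sum((od - m1 * xs)^2)
  }
  lo <- log(min(plasmid[pos]) / 100); hi <- log(max(plasmid) * 100)
  grid <- seq(lo, hi, length.out = 60)
  opt_g <- grid[which.min(vapply(grid, rss_for, numeric(1)))]
  opt <- stats::optimize(rss_for, c(max(lo, opt_g - 0.5), min(hi, opt_g + 0.5)),
                         tol = 1e-12)
  m2 <- exp(opt$minimum)
  xs <- plasmid / (m2 + plasmid)
  m1 <- sum(xs * od) / sum(xs * xs)
  # saturation undetectable when m2 ran into the upper profiling bound
  if (m2 > max(plasmid) * 50) {
    warning("no curvature detected in Western calibration; returning identity correction")
    return(list(calibration = list(m1 = m1, m2 = Inf),
                corrected_plasmid = plasmid, identity = TRUE))
  }
  list(calibration = list(m1 = m1, m2 = m2),
       corrected_plasmid = m2 * plasmid / (m2 + plasmid),
       identity = FALSE)
}
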