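# Brute-force equilibrium solver (no CLS approximation) and the CLS
# regime diagnostics.  The solver is the package's independent oracle for
# the closed-form reduction.

# Given free accelerator concentrations X (length n) compute all species.
# Yin is the productive combination [Y*] + beta [Y'] that feeds the next
# reaction; every complex from step j onwards contains accelerator i <= j.
equilibrium_species <- function(chain, decels, y0, X) {
  n <- length(chain$steps)
  ystar <- yprime <- yin <- numeric(n)
  prev <- y0
  for (i in seq_len(n)) {
    alpha_beta <- 0; alpha_tot <- 0
    for (d in decels) {
      if (d$step != i) next
      alpha_tot <- alpha_tot + d$alpha * d$q_prime * d$conc
      alpha_beta <- alpha_beta + d$alpha * d$beta * d$q_prime * d$conc
    }
    ystar[i] <- chain$steps[[i]]$q * X[i] * prev
    yprime[i] <- alpha_tot * ystar[i]
    yin[i] <- ystar[i] * (1 + alpha_beta)
    prev <- yin[i]
  }
  list(ystar = ystar, yprime = yprime, yin = yin)
}

# conservation residuals F_i = [X_i] g_i + sum_{j >= i} ([Y*_j] + [Y'_j]) - X_i^T
equilibrium_residual <- function(chain, decels, y0, X) {
  n <- length(chain$steps)
  sp <- equilibrium_species(chain, decels, y0, X)
  tot <- rev(cumsum(rev(sp$ystar + sp$yprime)))
  vapply(seq_len(n), function(i) {
    g <- decel_factors(decels, i)$g
    X[i] * g + tot[i] - chain$steps[[i]]$X_total
  }, numeric(1))
}

#' Exact equilibrium of a reaction chain (brute force, no CLS approximation)
#'
#' Solves the steady-state equilibrium relations together with the exact
#' mass-conservation sums (every downstream complex counted against every
#' accelerator it contains) by damped Newton iteration on log free-accelerator
#' concentrations, with multistart to guarantee the positive root.  This is
#' the independent oracle against which the closed-form reduction is checked.
#'
#' @param chain A [reaction_chain()].
#' @param decels List of [decelerator_spec()] objects.
#' @param y0 Inducer concentration `[Y0]` (defaults to the chain's).
#' @param tol Relative residual tolerance.
#' @return A list with `X` (free accelerators), `Y` (productive products),
#'   `Ystar`, `Yprime`, `activity`, and `residual` (max relative residual).
#' @export
solve_equilibrium_numeric <- function(chain, decels = list(),
                                      y0 = chain$inducer_conc, tol = 1e-10) {
  n <- length(chain$steps)
  XT <- vapply(chain$steps, `[[`, numeric(1), "X_total")
  if (y0 < 0) stop("y0 must be >= 0")
  if (y0 == 0 || all(XT == 0)) {
    g <- vapply(seq_len(n), function(i) decel_factors(decels, i)$g, numeric(1))
    return(list(X = XT / g, Y = numeric(n), Ystar = numeric(n),
                Yprime = numeric(n), activity = 0, residual = 0))
  }
  scale <- pmax(XT, max(XT) * 1e-12)
  fn <- function(logX) equilibrium_residual(chain, decels, y0, exp(logX)) / scale

  starts <- list(log(pmax(XT, 1e-12)),
                 log(pmax(XT, 1e-12)) - 2,
                 log(pmax(XT, 1e-12)) - 8)
  best <- NULL
  for (s in starts) {
    x <- s
    ok <- TRUE
    for (iter in 1:200) {
      Fv <- fn(x)
      if (max(abs(Fv)) < tol) break
      J <- numeric_jacobian(fn, x, Fv)
      step <- tryCatch(solve(J, -Fv), error = function(e) NULL)
      if (is.null(step)) { ok <- FALSE; break }
      # damped line search on the residual norm
      t <- 1
      repeat {
        xn <- x + t * step
        Fn <- fn(xn)
        if (all(is.finite(Fn)) && max(abs(Fn)) < max(abs(Fv))) break
        t <- t / 2
        if (t < 1e-10) { ok <- FALSE; break }
      }
      if (!ok) break
      x <- xn
    }
    Fv <- fn(x)
    res <- max(abs(Fv))
    if (ok && (is.null(best) || res < best$res)) best <- list(x = x, res = res)
    if (!is.null(best) && best$res < tol) break
  }
  if (is.null(best)) stop("equilibrium solver failed from every start")
  if (best$res >= tol) {
    stop(sprintf("equilibrium solver did not converge: max relative residual %.3e",
                 best$res))
  }
  X <- exp(best$x)
  sp <- equilibrium_species(chain, decels, y0, X)
  w_idx <- which(seq_len(n) >= chain$first_weighted)
  activity <- sum(chain$activity_weights * sp$yin[w_idx])
  list(X = X, Y = sp$yin, Ystar = sp$ystar, Yprime = sp$yprime,
       activity = activity, residual = best$res)
}

numeric_jacobian <- function(fn, x, Fx = fn(x)) {
  n <- length(x)
  J <- matrix(0, length(Fx), n)
  h <- 1e-7 * pmax(abs(x), 1)
  for (j in seq_len(n)) {
    xp <- x; xp[j] <- xp[j] + h[j]
    J[, j] <- (fn(xp) - Fx) / h[j]
  }
  J
}

#' Check the concentration-limited-step regime of a chain
#'
#' Classifies every step as pre-CLS, CLS or post-CLS and reports whether
#' the asymptotic conditions behind the closed form hold numerically:
#' accelerators at pre-CLS steps (other than the first of each run) and at
#' the CLS must be limited with respect to their affinities
#' (`q * X_total <= threshold`), while post-CLS accelerators must remain
#' in excess (bound fraction small at the chain's operating point).
#'
#' @param chain A [reaction_chain()].
#' @param decels List of [decelerator_spec()] objects.
#' @param threshold Limitedness threshold for `q * X_total` ("<<1"; the
#'   default 0.01 puts it two orders below 1).
#' @param excess_tol Maximum tolerated bound fraction of a post-CLS
#'   accelerator.
#' @return A data frame with one row per step: `role`, `q_X_total` margin,
#'   `bound_fraction`, and a logical `valid`; attribute `"valid"` gives the
#'   chain-level verdict.  Advisory only: never throws.
#' @export
check_cls_conditions <- function(chain, decels = list(), threshold = 0.01,
                                 excess_tol = 0.1) {
  n <- length(chain$steps)
  rb <- step_roles(chain)
  qx <- vapply(chain$steps, function(s) s$q * s$X_total, numeric(1))

  # first step of each pre-run is exempt (only accelerators *after* the
  # head of a run must be limited for downstream products to shrink)
  exempt <- rep(FALSE, n)
  r <- rb$roles
  for (i in seq_len(n)) {
    if (r[i] == "pre" && (i == 1L || r[i - 1L] %in% c("post"))) exempt[i] <- TRUE
  }
  if (r[1L] %in% c("pre", "cls")) exempt[1L] <- TRUE

  # bound fraction of post-CLS accelerators at the operating point,
  # estimated from the closed-form product concentrations
  bound <- rep(NA_real_, n)
  if (is.finite(chain$inducer_conc) && chain$inducer_conc > 0) {
    red <- tryCatch(chain_reduce(chain, decels), error = function(e) NULL)
    if (!is.null(red)) {
      y0 <- chain$inducer_conc
      for (i in seq_len(n)) {
        if (r[i] != "post") next
        tri <- red$triples[[i]]
        Yi <- tri$N * y0 / (tri$C + tri$D * y0)
        bound[i] <- Yi / chain$steps[[i]]$X_total
      }
    }
  }

  # effective CLS margin: the pre-CLS conservations neglect the sum of
  # all products at and after the CLS, which per unit of feed product is
  # q_c * X_c^T * (1 + L) with L the downstream pseudo-first-order load;
  # conservation also caps that sum at X_c^T, so relative to the feed
  # concentration the neglected term is at most X_c^T / [Y_feed]
  margin <- qx
  for (i in seq_len(n)) {
    if (r[i] != "cls") next
    L <- 0; run <- 1
    for (j in which(r == "post" & rb$block == rb$block[i])) {
      dfj <- decel_factors(decels, j)
      qxj <- chain$steps[[j]]$q * chain$steps[[j]]$X_total
      L <- L + run * qxj * dfj$u / dfj$g
      run <- run * qxj * dfj$b / dfj$g
    }
    m1 <- qx[i] * (1 + L)
    # conservation also caps the neglected product sum at X_c^T, so its
    # relative weight in the preceding conservation equation is at most
    # X_c^T over the preceding accelerator pool (or the inducer dose)
    prev_pool <- if (i == 1L) chain$inducer_conc else
      chain$steps[[i - 1L]]$X_total
    m2 <- if (is.finite(prev_pool) && prev_pool > 0)
      chain$steps[[i]]$X_total / prev_pool else Inf
    margin[i] <- min(m1, m2)
  }

  valid <- logical(n)
  for (i in seq_len(n)) {
    valid[i] <- switch(r[i],
      pre = exempt[i] || qx[i] <= threshold,
      cls = margin[i] <= threshold,
      post = is.na(bound[i]) || bound[i] <= excess_tol
    )
  }
  out <- data.frame(step = seq_len(n), role = r, q_X_total = qx,
                    margin = margin, exempt = exempt,
                    bound_fraction = bound, valid = valid)
  attr(out, "valid") <- all(valid)
  out
}

#' Steady state of the equivalent irreversible ("hit-and-run") schemes
#'
#' Integrates the irreversible mass-action ODEs to steady state and returns
#' the product concentration.  Two schemes are supported: `"post-CLS-like"`
#' (`P + X -> P' + X`, `P' -> P`; steady state `[P'] = q X_T [P]` with
#' `q = kf/kr`, mimicking a pseudo-first-order post-CLS reaction) and
#' `"CLS-like"` (`P + X -> X' + P`, `X' -> X`, optionally followed by
#' `X' + U -> X'' + U`, `X'' -> X'`; steady state
#' `[X'] = q X_T [P] / (1 + q [P] + q q' U_T [P])`, mimicking a CLS).
#'
#' @param scheme_kind `"post-CLS-like"` or `"CLS-like"`.
#' @param kf,kr Forward/backward rates of the primary reaction (`> 0`).
#' @param totals Named list: `X_total` (and `P_total` for the post-CLS
#'   scheme; optional `U_total`, `kf2`, `kr2` for the diverting reaction of
#'   the CLS scheme).
#' @param upstream_conc Free upstream concentration (`[P]` held fixed for
#'   the CLS-like scheme; ignored for post-CLS-like where `P` is conserved).
#' @param tol Steady-state tolerance on the scaled time derivative.
#' @return The steady-state product concentration (`[P']` or `[X']`).
#' @export
hit_and_run_steady_state <- function(scheme_kind = c("post-CLS-like", "CLS-like"),
                                     kf, kr, totals, upstream_conc = 1,
                                     tol = 1e-10) {
  scheme_kind <- match.arg(scheme_kind)
  if (kf <= 0 || kr <= 0) stop("rates must be positive")
  if (scheme_kind == "post-CLS-like") {
    PT <- totals$P_total; XT <- totals$X_total
    deriv <- function(s) kf * (PT - s) * XT - kr * s
    rate <- kf * XT + kr
    state <- 0
  } else {
    XT <- totals$X_total
    UT <- if (is.null(totals$U_total)) 0 else totals$U_total
    kf2 <- if (is.null(totals$kf2)) kf else totals$kf2
    kr2 <- if (is.null(totals$kr2)) kr else totals$kr2
    P <- upstream_conc
    deriv <- function(s) {
      X <- XT - s[1] - s[2]
      c(kf * X * P - kr * s[1] - kf2 * s[1] * UT + kr2 * s[2],
        kf2 * s[1] * UT - kr2 * s[2])
    }
    rate <- kf * P + kr + kf2 * UT + kr2
    state <- c(0, 0)
  }
  dt <- 0.1 / rate
  scale <- max(unlist(totals[c("P_total", "X_total")]), 1e-12, na.rm = TRUE)
  for (it in 1:2e6) {
    k1 <- deriv(state)
    k2 <- deriv(state + dt / 2 * k1)
    k3 <- deriv(state + dt / 2 * k2)
    k4 <- deriv(state + dt * k3)
    state <- state + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (max(abs(deriv(state))) < tol * scale * rate) break
  }
  state[1]
}
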