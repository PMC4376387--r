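# Symbolic derivation of T(S), U(S) and the four dose-response parameters
# for a GR + cofactor configuration.  The scaffold chain is built with
# krat symbols and reduced by exactly the same chain_reduce() code as the
# numeric forward model, then the steroid dependence [GR] = G [S]/(K + [S])
# is substituted and the fractions cleared, leaving T and U as polynomials
# linear in [S] and linear in the cofactor amount X.

psym <- function(name) kp_var(name)

# decelerator alpha/beta/gamma structure for a mechanism, as krat scalars;
# `tag` distinguishes the cofactor (F) from the receptor (G)
decel_params <- function(mech, tag) {
  tp <- mech$decel_type
  a_sym <- psym(paste0("alpha", tag))
  g_sym <- psym(paste0("gamma", tag))
  b_sym <- psym(paste0("beta", tag))
  if (is.null(tp)) return(list(alpha = a_sym, beta = b_sym, gamma = g_sym))
  ag <- psym(paste0("ag", tag))  # shared strength for the noncompetitive type
  list(
    alpha = switch(substr(tp, 2, 2), C = 0, U = a_sym, N = ag),
    gamma = switch(substr(tp, 2, 2), C = g_sym, U = 0, N = ag),
    beta = if (substr(tp, 1, 1) == "P") b_sym else 0
  )
}

# Build the canonical symbolic scaffold chain for a configuration.
# Regions: head step / pre-CLS slots / CLS (reporter) / post-CLS slots.
# Accelerator factors occupy a slot with their amount as X_total;
# decelerator factors attach to a carrier step (or to the partner's step
# for same-step arrangements) with their amount as free concentration.
build_scaffold <- function(cfg) {
  gr_is_accel <- cfg$gr_mech$kind == "A"
  gr_var <- if (gr_is_accel) "GRX" else "DGR"

  # placement list in chain order within each region
  place <- list(before = list(), at = list(), after = list())
  add <- function(place, region, who, mech, var) {
    place[[region]] <- c(place[[region]], list(list(who = who, mech = mech, var = var)))
    place
  }
  entries <- list(
    list(who = "F", mech = cfg$factor_mech, pos = cfg$factor_pos, var = "X"),
    list(who = "G", mech = cfg$gr_mech, pos = cfg$gr_pos, var = gr_var)
  )
  if (cfg$order == "GR-before-F") entries <- entries[c(2, 1)]
  for (e in entries) place <- add(place, e$pos, e$who, e$mech, e$var)

  steps <- list()
  decel_queue <- list()      # list of (step_index, who, mech, var)
  gr_step <- NA_integer_

  push_step <- function(q_name, X) {
    steps[[length(steps) + 1L]] <<- list(q = psym(q_name), X_total = X)
    length(steps)
  }

  # head (inducer-proximal) step: hidden background accelerator
  push_step("qh", psym("Xh"))

  handle_region <- function(region) {
    ents <- place[[region]]
    at_cls <- region == "at"
    if (cfg$order == "same-step" && length(ents) == 2L) {
      acc <- ents[[which(vapply(ents, function(e) e$mech$kind, "") == "A")]]
      dec <- ents[[which(vapply(ents, function(e) e$mech$kind, "") == "D")]]
      i <- if (at_cls) push_step("qc", psym(acc$var)) else
        push_step(paste0("q", acc$who), psym(acc$var))
      decel_queue[[length(decel_queue) + 1L]] <<-
        list(step = i, who = dec$who, mech = dec$mech, var = dec$var)
      if (acc$who == "G") gr_step <<- i
      return(i)
    }
    cls_i <- NA_integer_
    cls_taken <- FALSE
    for (e in ents) {
      if (e$mech$kind == "A") {
        i <- if (at_cls) push_step("qc", psym(e$var)) else
          push_step(paste0("q", e$who), psym(e$var))
        if (at_cls) { cls_i <- i; cls_taken <- TRUE }
        if (e$who == "G") gr_step <<- i
      } else {
        # decelerator: carrier step with hidden accelerator, unless at the
        # CLS where it inhibits the reporter step itself
        i <- if (at_cls) {
          if (!cls_taken) { cls_i <- push_step("qc", psym("R")); cls_taken <- TRUE }
          cls_i
        } else {
          push_step(paste0("qc", e$who), psym(paste0("Xc", e$who)))
        }
        decel_queue[[length(decel_queue) + 1L]] <<-
          list(step = i, who = e$who, mech = e$mech, var = e$var)
      }
    }
    if (at_cls && !cls_taken) cls_i <- push_step("qc", psym("R"))
    cls_i
  }

  handle_region("before")
  cls_index <- handle_region("at")
  if (is.na(cls_index)) cls_index <- push_step("qc", psym("R"))
  handle_region("after")

  n <- length(steps)
  decels <- lapply(decel_queue, function(d) {
    pp <- decel_params(d$mech, d$who)
    list(step = d$step, conc = psym(d$var), q_prime = psym(paste0("qp", d$who)),
         alpha = pp$alpha, beta = pp$beta, gamma = pp$gamma)
  })

  # activity weights: CLS product normalised to 1, every later product gets
  # a free positive weight symbol (the general non-cooperative activity)
  w <- vector("list", n - cls_index + 1L)
  w[[1]] <- 1
  if (n > cls_index) {
    for (i in seq(cls_index + 1L, n)) w[[i - cls_index + 1L]] <- psym(paste0("w", i))
  }
  chain <- structure(list(steps = steps, cls_index = cls_index,
                          inducer_conc = NA, activity_weights = w,
                          first_weighted = cls_index),
                     class = "reaction_chain")
  list(chain = chain, decels = decels, gr_var = gr_var, gr_step = gr_step,
       gr_is_accel = gr_is_accel, cls_index = cls_index, n_steps = n)
}

# chain_reduce needs generic weighted sums: activity_weights may be a list
# of krat scalars in the symbolic scaffold.  (numeric chains keep vectors)
# -> handled transparently because `w[k] * N` dispatches on krat.

#' Derive T(S) and U(S) for a configuration
#'
#' Builds the symbolic scaffold chain for the configuration, reduces it to
#' the activity `A = V [Y0] / (1 + W [Y0])`, substitutes the steroid
#' occupancy `[GR] = G [S] / (K + [S])` for the receptor variable and
#' clears the fractions, giving `A = T([S]) / U([S])` with `T` and `U`
#' polynomials of degree one in `[S]` whose coefficients are degree-one
#' polynomials in the cofactor amount `X` with positive composite
#' coefficients by construction.
#'
#' @param config A [configuration()].
#' @return An object of class `tu_form`: list with `T`, `U` (kpoly in the
#'   package's internal symbolic representation), `cofactor = "X"`,
#'   `steroid = "S"`, `config`, `scaffold`, and `symbols` (all free
#'   parameter symbols other than `S` and `X`).
#' @export
derive_TU <- function(config) {
  stopifnot(inherits(config, "configuration"))
  sc <- build_scaffold(config)
  red <- chain_reduce_sym(sc$chain, sc$decels)
  Y0 <- psym("Y0")
  A <- kr_new(red$N * Y0, red$C + red$D * Y0)
  GS <- kp_var("G") * kp_var("S")
  KS <- kp_var("K") + kp_var("S")
  A2 <- kr_subst_lf(A, sc$gr_var, GS, KS)
  Tp <- A2$num; Up <- A2$den
  if (kp_degree(Tp, "S") > 1L || kp_degree(Up, "S") > 1L ||
      kp_degree(Tp, "X") > 1L || kp_degree(Up, "X") > 1L) {
    stop("internal error: T/U not linear in S and X for ", config_id(config))
  }
  syms <- setdiff(union(Tp$vars, Up$vars), c("S", "X"))
  structure(list(T = Tp, U = Up, cofactor = "X", steroid = "S",
                 config = config, scaffold = sc, symbols = syms),
            class = "tu_form")
}

# symbolic chain_reduce wrapper: polynomial unit scalar
chain_reduce_sym <- function(chain, decels) {
  chain_reduce(chain, decels, one = kp_const(1))
}

#' @export
print.tu_form <- function(x, ...) {
  cat("<tu_form>", config_id(x$config), "\n")
  cat(sprintf("  T: %d monomials; U: %d monomials; symbols: %s\n",
              length(x$T$coef), length(x$U$coef),
              paste(x$symbols, collapse = ", ")))
  invisible(x)
}

# symbolic linear-fractional in one variable with kpoly coefficients
lf_sym <- function(a, b, c, d, var = "X") {
  structure(list(a = kp_canonical(as_kpoly(a)), b = kp_canonical(as_kpoly(b)),
                 c = kp_canonical(as_kpoly(c)), d = kp_canonical(as_kpoly(d)),
                 var = var), class = "lf_sym")
}

#' Dose-response parameter plots implied by a T/U form
#'
#' From `A = (T(0) + T' S) / (U(0) + U' S)` the four dose-response
#' parameters follow as `Amax = T(0)/U(0)`, `Amin = T'/U'`,
#' `IC50 = U(0)/U'` and `Amax*IC50/Amin = T(0)/T'`; each is a
#' linear-fractional function of the cofactor amount `X`.
#'
#' @param tu A `tu_form` from [derive_TU()].
#' @return An object of class `dr_param_forms`: symbolic linear-fractional
#'   forms `amax`, `amin`, `ic50`, `ratio` (each with kpoly coefficients
#'   `a`,`b`,`c`,`d` in `X`), plus `ic50_defined`.
#' @export
dr_param_forms <- function(tu) {
  stopifnot(inherits(tu, "tu_form"))
  Ts <- kp_split(tu$T, tu$steroid)
  Us <- kp_split(tu$U, tu$steroid)
  T0 <- Ts[[1]]; T1 <- if (length(Ts) > 1L) Ts[[2]] else kp_const(0)
  U0 <- Us[[1]]; U1 <- if (length(Us) > 1L) Us[[2]] else kp_const(0)
  sx <- function(p) {
    parts <- kp_split(p, tu$cofactor)
    list(c0 = parts[[1]], c1 = if (length(parts) > 1L) parts[[2]] else kp_const(0))
  }
  t0 <- sx(T0); t1 <- sx(T1); u0 <- sx(U0); u1 <- sx(U1)
  ic50_defined <- !(kp_is_zero(U1))
  structure(list(
    amax = lf_sym(t0$c0, t0$c1, u0$c0, u0$c1, tu$cofactor),
    amin = lf_sym(t1$c0, t1$c1, u1$c0, u1$c1, tu$cofactor),
    ic50 = lf_sym(u0$c0, u0$c1, u1$c0, u1$c1, tu$cofactor),
    ratio = lf_sym(t0$c0, t0$c1, t1$c0, t1$c1, tu$cofactor),
    ic50_defined = ic50_defined,
    symbols = tu$symbols, config = tu$config
  ), class = "dr_param_forms")
}

#' Evaluate symbolic parameter forms at numeric parameter values
#'
#' @param forms A `dr_param_forms` object.
#' @param env Named list of numeric values for every free symbol.
#' @return A list of numeric [linear_fractional()] objects
#'   (`amax`, `amin`, `ic50`, `ratio`).
#' @export
eval_param_forms <- function(forms, env) {
  ev <- function(lfs) {
    linear_fractional(kp_eval(lfs$a, env), kp_eval(lfs$b, env),
                      kp_eval(lfs$c, env), kp_eval(lfs$d, env),
                      canonical = TRUE)
  }
  list(amax = ev(forms$amax), amin = ev(forms$amin),
       ic50 = ev(forms$ic50), ratio = ev(forms$ratio))
}

lf_cross <- function(x1, x2, y1, y2) x1 * y2 - x2 * y1

#' Check the four compatibility conditions
#'
#' The theory ties the numerators and denominators of the four parameter
#' plots together: (a) the numerator of `Amax` equals (up to a positive
#' scale) the numerator of `Amax*IC50/Amin`; (b) the numerator of `Amin`
#' equals the denominator of `Amax*IC50/Amin`; (c) the denominator of
#' `Amax` equals the numerator of `IC50`; (d) the denominator of `Amin`
#' equals the denominator of `IC50`.  Arbitrary linear-fractional
#' quadruples do not satisfy these, so they are a falsifiable validity
#' check.  Works on symbolic forms (`dr_param_forms`; equality is exact
#' polynomial cancellation of the cross products) and on numeric
#' quadruples of [linear_fractional()] objects (proportionality to a
#' relative tolerance on normalised coefficients).
#'
#' @param forms A `dr_param_forms` or a list with numeric
#'   `amax`, `amin`, `ic50`, `ratio` [linear_fractional()] entries.
#' @param tol Relative tolerance for the numeric check.
#' @return Named logical vector `c(a=, b=, c=, d=)`.
#' @export
check_compatibility <- function(forms, tol = 1e-9) {
  sym <- inherits(forms, "dr_param_forms")
  pairs <- list(
    a = list(num1 = forms$amax, part1 = c("a", "b"), num2 = forms$ratio, part2 = c("a", "b")),
    b = list(num1 = forms$amin, part1 = c("a", "b"), num2 = forms$ratio, part2 = c("c", "d")),
    c = list(num1 = forms$amax, part1 = c("c", "d"), num2 = forms$ic50, part2 = c("a", "b")),
    d = list(num1 = forms$amin, part1 = c("c", "d"), num2 = forms$ic50, part2 = c("c", "d"))
  )
  out <- logical(4)
  names(out) <- names(pairs)
  for (k in names(pairs)) {
    p <- pairs[[k]]
    x1 <- p$num1[[p$part1[1]]]; x2 <- p$num1[[p$part1[2]]]
    y1 <- p$num2[[p$part2[1]]]; y2 <- p$num2[[p$part2[2]]]
    if (sym) {
      cross <- kp_add(kp_mul(x1, y2), kp_neg(kp_mul(x2, y1)))
      out[k] <- kp_is_zero(cross, tol = prop_tol_sym(x1, x2, y1, y2, tol))
    } else {
      cross <- lf_cross(x1, x2, y1, y2)
      scale <- max(abs(x1 * y2), abs(x2 * y1))
      out[k] <- abs(cross) <= tol * max(scale, .Machine$double.xmin)
    }
  }
  out
}

prop_tol_sym <- function(x1, x2, y1, y2, tol) {
  mx <- function(p) if (length(p$coef)) max(abs(p$coef)) else 0
  tol * max(mx(kp_mul(x1, y2)), mx(kp_mul(x2, y1)), .Machine$double.xmin)
}
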