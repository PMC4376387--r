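#' Linear-fractional function y = (a + b x) / (c + d x)
#'
#' The universal functional family of the theory: every dose-response and
#' every dose-response-parameter plot is linear-fractional (first-order
#' Hill).  The family is closed under composition, which is what makes the
#' closed-form chain reduction possible.
#'
#' @param a,b,c,d Real coefficients.  `c` and `d` must not both be zero.
#' @param canonical If `TRUE` (default) and `c != 0`, coefficients are
#'   rescaled so that `c = 1`.
#' @return An object of class `linear_fractional`.
#' @examples
#' f <- linear_fractional(1, 2, 1, 1)   # (1 + 2x) / (1 + x)
#' lf_eval(f, c(0, 1, Inf))
#' @export
linear_fractional <- function(a, b, c, d, canonical = TRUE) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c), is.numeric(d))
  if (c == 0 && d == 0) stop("degenerate linear-fractional: c and d both zero")
  if (canonical && c != 0) {
    b <- b / c; a <- a / c; d <- d / c; c <- 1
  }
  structure(list(a = a, b = b, c = c, d = d), class = "linear_fractional")
}

#' @export
print.linear_fractional <- function(x, ...) {
  cat(sprintf("<linear_fractional> y = (%g + %g x) / (%g + %g x)\n",
              x$a, x$b, x$c, x$d))
  invisible(x)
}

#' Evaluate a linear-fractional function
#'
#' @param lf A [linear_fractional()] object.
#' @param x Numeric vector (may include `Inf`, mapped to the asymptote `b/d`).
#' @return Numeric vector of the same length as `x`.
#' @export
lf_eval <- function(lf, x) {
  out <- (lf$a + lf$b * x) / (lf$c + lf$d * x)
  inf <- is.infinite(x)
  if (any(inf)) out[inf] <- if (lf$d != 0) lf$b / lf$d else sign(x[inf]) * Inf * sign(lf$b / lf$c)
  out
}

#' Compose two linear-fractional functions
#'
#' Returns the coefficients of `f(g(x))`, again linear-fractional: the family
#' forms a group under composition (for non-degenerate members).
#'
#' @param f,g [linear_fractional()] objects.
#' @return A [linear_fractional()] object equal to `f` after `g`.
#' @export
lf_compose <- function(f, g) {
  # f((a_g + b_g x)/(c_g + d_g x))
  linear_fractional(
    a = f$a * g$c + f$b * g$a,
    b = f$a * g$d + f$b * g$b,
    c = f$c * g$c + f$d * g$a,
    d = f$c * g$d + f$d * g$b,
    canonical = FALSE
  )
}

#' Qualitative shape of a linear-fractional plot
#'
#' Classifies the plot of `y = (a + bx)/(c + dx)` over a positive range the
#' way a parameter-vs-cofactor trace is read: `y` increases iff `ad < bc`,
#' decreases iff `ad > bc` and is constant iff `ad = bc`.  The half-maximal
#' abscissa is `c/d`, and `a/b` for `1/y`.  A tolerance band turns
#' near-degenerate traces into "const", mirroring how near-horizontal
#' experimental traces are read.
#'
#' @param lf A [linear_fractional()] object.
#' @param x_range Positive range of the abscissa used only to report values
#'   at the range ends.
#' @param const_tol Relative tolerance for calling the trace constant:
#'   `|ad - bc| <= const_tol * max(|ad|, |bc|, tiny)`.
#' @return A list with elements `direction` (`"inc"`, `"dec"` or `"const"`),
#'   `half_max` (`c/d`), `reciprocal_half_max` (`a/b`),
#'   `linear_through_origin`, `positive_intercept`, `approaches_zero`
#'   (whether `y -> 0` as `x -> Inf`), and `value_at_zero`.
#' @export
lf_shape <- function(lf, x_range = c(0, 100), const_tol = 0.05) {
  if (lf$c == 0 && lf$d == 0) stop("degenerate linear-fractional: c = d = 0")
  det <- lf$a * lf$d - lf$b * lf$c
  scale <- max(abs(lf$a * lf$d), abs(lf$b * lf$c))
  direction <- if (scale == 0 || abs(det) <= const_tol * scale) {
    "const"
  } else if (det < 0) "inc" else "dec"
  at_zero <- if (lf$c != 0) lf$a / lf$c else Inf
  at_inf <- if (lf$d != 0) lf$b / lf$d else Inf
  rel0 <- function(x, y) abs(x) <= 1e-9 * max(abs(y), 1e-300)
  list(
    direction = direction,
    half_max = if (lf$d != 0) lf$c / lf$d else Inf,
    reciprocal_half_max = if (lf$b != 0) lf$a / lf$b else Inf,
    # y = (b/c) x exactly: no constant term and no denominator saturation
    linear_through_origin = rel0(lf$a, lf$b) && rel0(lf$d, lf$c),
    positive_intercept = is.finite(at_zero) && at_zero > 0 && !rel0(lf$a, lf$b),
    approaches_zero = is.finite(at_inf) && rel0(lf$b, lf$a),
    value_at_zero = at_zero,
    value_at_range = lf_eval(lf, x_range)
  )
}
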