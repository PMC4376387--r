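# Sparse multivariate polynomials (kpoly) and rational functions (krat).
#
# This is the small symbolic layer used to derive T(S)/U(S) forms exactly.
# Coefficients stay numeric (integers when the inputs are symbolic), so
# identities such as the compatibility conditions can be verified as
# exact polynomial cancellations rather than by floating-point fitting.
#
# Representation: list(vars = character(), expo = integer matrix
# (n_monomials x n_vars), coef = numeric(n_monomials)).  The zero
# polynomial has 0 rows.

kp_new <- function(vars, expo, coef) {
  structure(list(vars = vars, expo = expo, coef = coef), class = "kpoly")
}

#' @noRd
kp_const <- function(x) {
  if (x == 0) {
    kp_new(character(0), matrix(integer(0), 0, 0), numeric(0))
  } else {
    kp_new(character(0), matrix(integer(0), 1, 0), as.numeric(x))
  }
}

#' @noRd
kp_var <- function(name) {
  kp_new(name, matrix(1L, 1, 1), 1)
}

is_kpoly <- function(x) inherits(x, "kpoly")

as_kpoly <- function(x) {
  if (is_kpoly(x)) x else kp_const(x)
}

# canonicalise: union duplicate monomials, drop zero coefficients and
# unused variables
kp_canonical <- function(p) {
  if (length(p$coef) == 0L) return(kp_const(0))
  keys <- apply(p$expo, 1L, paste, collapse = ",")
  s <- tapply(p$coef, keys, sum)
  ukeys <- names(s)
  coef <- as.numeric(s)
  expo <- do.call(rbind, lapply(strsplit(ukeys, ","), as.integer))
  if (is.null(expo)) expo <- matrix(integer(0), 0, length(p$vars))
  keep <- coef != 0
  coef <- coef[keep]
  expo <- expo[keep, , drop = FALSE]
  if (length(coef) == 0L) return(kp_const(0))
  used <- colSums(expo) > 0L
  kp_new(p$vars[used], expo[, used, drop = FALSE], coef)
}

# align two polynomials onto a shared variable set
kp_align <- function(p, q) {
  vars <- union(p$vars, q$vars)
  pad <- function(x) {
    expo <- matrix(0L, nrow(x$expo), length(vars))
    if (length(x$vars)) expo[, match(x$vars, vars)] <- x$expo
    kp_new(vars, expo, x$coef)
  }
  list(pad(p), pad(q))
}

kp_add <- function(p, q) {
  pq <- kp_align(as_kpoly(p), as_kpoly(q))
  kp_canonical(kp_new(pq[[1]]$vars,
                      rbind(pq[[1]]$expo, pq[[2]]$expo),
                      c(pq[[1]]$coef, pq[[2]]$coef)))
}

kp_neg <- function(p) {
  p <- as_kpoly(p)
  p$coef <- -p$coef
  p
}

kp_mul <- function(p, q) {
  p <- as_kpoly(p); q <- as_kpoly(q)
  if (length(p$coef) == 0L || length(q$coef) == 0L) return(kp_const(0))
  pq <- kp_align(p, q)
  p <- pq[[1]]; q <- pq[[2]]
  np <- nrow(p$expo); nq <- nrow(q$expo)
  ip <- rep(seq_len(np), each = nq)
  iq <- rep(seq_len(nq), times = np)
  kp_canonical(kp_new(p$vars,
                      p$expo[ip, , drop = FALSE] + q$expo[iq, , drop = FALSE],
                      p$coef[ip] * q$coef[iq]))
}

kp_pow <- function(p, n) {
  n <- as.integer(n)
  stopifnot(n >= 0L)
  out <- kp_const(1)
  base <- as_kpoly(p)
  while (n > 0L) {
    if (n %% 2L == 1L) out <- kp_mul(out, base)
    base_needed <- n %/% 2L > 0L
    if (base_needed) base <- kp_mul(base, base)
    n <- n %/% 2L
  }
  out
}

#' @export
Ops.kpoly <- function(e1, e2) {
  if (.Generic == "-" && missing(e2)) return(kp_neg(e1))
  if (.Generic == "+" && missing(e2)) return(e1)
  switch(.Generic,
    "+" = kp_add(e1, e2),
    "-" = kp_add(e1, kp_neg(e2)),
    "*" = kp_mul(e1, e2),
    "^" = kp_pow(e1, e2),
    "==" = kp_is_zero(kp_add(as_kpoly(e1), kp_neg(e2))),
    stop("operation '", .Generic, "' not defined for kpoly objects")
  )
}

kp_is_zero <- function(p, tol = 0) {
  p <- kp_canonical(as_kpoly(p))
  if (length(p$coef) == 0L) return(TRUE)
  if (tol <= 0) return(FALSE)
  max(abs(p$coef)) <= tol
}

kp_degree <- function(p, var) {
  p <- as_kpoly(p)
  j <- match(var, p$vars)
  if (is.na(j) || nrow(p$expo) == 0L) return(0L)
  max(p$expo[, j])
}

# coefficients of p viewed as a polynomial in `var`:
# list of kpoly, element k+1 = coefficient of var^k
kp_split <- function(p, var) {
  p <- kp_canonical(as_kpoly(p))
  d <- kp_degree(p, var)
  j <- match(var, p$vars)
  out <- vector("list", d + 1L)
  for (k in 0:d) {
    if (is.na(j)) {
      out[[k + 1L]] <- if (k == 0L) p else kp_const(0)
    } else {
      rows <- p$expo[, j] == k
      expo <- p$expo[rows, , drop = FALSE]
      expo[, j] <- 0L
      out[[k + 1L]] <- kp_canonical(kp_new(p$vars, expo, p$coef[rows]))
    }
  }
  out
}

# vectorised evaluation; env is a named list (or one-row data.frame) whose
# elements are numeric vectors of common length
kp_eval <- function(p, env) {
  p <- as_kpoly(p)
  n <- if (length(env)) max(lengths(env)) else 1L
  if (length(p$coef) == 0L) return(rep(0, n))
  missing_vars <- setdiff(p$vars, names(env))
  if (length(missing_vars)) {
    stop("no value supplied for symbol(s): ", paste(missing_vars, collapse = ", "))
  }
  acc <- rep(0, n)
  for (i in seq_along(p$coef)) {
    term <- rep(p$coef[i], n)
    for (j in seq_along(p$vars)) {
      e <- p$expo[i, j]
      if (e > 0L) term <- term * env[[p$vars[j]]]^e
    }
    acc <- acc + term
  }
  acc
}

#' @export
print.kpoly <- function(x, ...) {
  x <- kp_canonical(x)
  if (length(x$coef) == 0L) {
    cat("<kpoly> 0\n")
    return(invisible(x))
  }
  terms <- vapply(seq_along(x$coef), function(i) {
    mono <- x$vars[x$expo[i, ] > 0L]
    pows <- x$expo[i, x$expo[i, ] > 0L]
    sym <- paste(ifelse(pows > 1L, paste0(mono, "^", pows), mono), collapse = "*")
    if (nzchar(sym)) paste0(format(x$coef[i]), "*", sym) else format(x$coef[i])
  }, character(1))
  cat("<kpoly>", paste(terms, collapse = " + "), "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Rational functions num/den over kpoly.  No gcd cancellation is attempted:
# the chain algebra below never needs it because step maps have numerators
# without constant terms, so composition preserves the linear-fractional
# degree structure exactly.

kr_new <- function(num, den) {
  structure(list(num = kp_canonical(as_kpoly(num)),
                 den = kp_canonical(as_kpoly(den))), class = "krat")
}

is_krat <- function(x) inherits(x, "krat")

as_krat <- function(x) {
  if (is_krat(x)) x else kr_new(as_kpoly(x), kp_const(1))
}

#' @export
Ops.krat <- function(e1, e2) {
  if (.Generic == "-" && missing(e2)) {
    e1 <- as_krat(e1); return(kr_new(kp_neg(e1$num), e1$den))
  }
  a <- as_krat(e1); b <- as_krat(e2)
  switch(.Generic,
    "+" = kr_new(kp_add(kp_mul(a$num, b$den), kp_mul(b$num, a$den)),
                 kp_mul(a$den, b$den)),
    "-" = kr_new(kp_add(kp_mul(a$num, b$den), kp_neg(kp_mul(b$num, a$den))),
                 kp_mul(a$den, b$den)),
    "*" = kr_new(kp_mul(a$num, b$num), kp_mul(a$den, b$den)),
    "/" = kr_new(kp_mul(a$num, b$den), kp_mul(a$den, b$num)),
    stop("operation '", .Generic, "' not defined for krat objects")
  )
}

kr_eval <- function(r, env) {
  r <- as_krat(r)
  kp_eval(r$num, env) / kp_eval(r$den, env)
}

#' @export
print.krat <- function(x, ...) {
  cat("<krat> numerator:\n  ")
  print(x$num)
  cat("denominator:\n  ")
  print(x$den)
  invisible(x)
}

# substitute var := num_lf/den_lf into a rational function and clear the
# denominators consistently (both sides multiplied by den_lf^D)
kr_subst_lf <- function(r, var, num_lf, den_lf) {
  r <- as_krat(r)
  D <- max(kp_degree(r$num, var), kp_degree(r$den, var))
  sub_one <- function(p) {
    parts <- kp_split(p, var)
    acc <- kp_const(0)
    for (k in seq_along(parts)) {
      deg <- k - 1L
      term <- kp_mul(parts[[k]],
                     kp_mul(kp_pow(num_lf, deg), kp_pow(den_lf, D - deg)))
      acc <- kp_add(acc, term)
    }
    acc
  }
  kr_new(sub_one(r$num), sub_one(r$den))
}
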