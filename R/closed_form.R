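# Closed-form reduction of a reaction chain to its linear-fractional
# dose-response, valid in the CLS regime.  The same code runs on plain
# numerics and on krat symbolic scalars (used by derive_TU), so the
# symbolic forms and the numeric forward model cannot drift apart.

# role of every step: "pre", "cls" or "post", plus the CLS block each step
# belongs to.  Between two CLS steps the in-excess (post) run comes first,
# then the limited (pre) run of the next block; the split is decided by
# q * X_total against `excess_threshold` (post-CLS accelerators are in
# excess, pre-CLS ones are limited).
step_roles <- function(chain, excess_threshold = 0.1) {
  n <- length(chain$steps)
  cls <- chain$cls_index
  roles <- character(n)
  block <- integer(n)
  roles[cls] <- "cls"
  for (m in seq_along(cls)) {
    c_m <- cls[m]
    nxt <- if (m < length(cls)) cls[m + 1L] else n + 1L
    seg <- setdiff(seq(c_m + 1L, length.out = max(0L, nxt - c_m - 1L)), cls)
    in_post <- TRUE
    for (i in seg) {
      qx <- qx_numeric(chain$steps[[i]])
      if (m < length(cls) && (!is.na(qx) && qx < excess_threshold)) in_post <- FALSE
      roles[i] <- if (in_post) "post" else "pre"
      block[i] <- if (in_post) m else m + 1L
    }
    block[c_m] <- m
  }
  pre_head <- seq_len(cls[1L] - 1L)
  roles[pre_head] <- "pre"
  block[pre_head] <- 1L
  list(roles = roles, block = block)
}

qx_numeric <- function(step) {
  if (is.numeric(step$q) && is.numeric(step$X_total)) step$q * step$X_total else NA_real_
}

# binding factors contributed by the decelerators attached to step i
# (mutually exclusive binding, so multiple decelerators add):
#   g = accelerator binding       1 + sum gamma q' D
#   u = product binding           1 + sum alpha q' D   (mass conservation)
#   b = productive combination    1 + sum alpha beta q' D
decel_factors <- function(decels, i, one = 1) {
  g <- one; u <- one; b <- one
  for (d in decels) {
    if (d$step != i) next
    qd <- d$q_prime * d$conc
    g <- g + d$gamma * qd * one
    u <- u + d$alpha * qd * one
    b <- b + d$alpha * d$beta * qd * one
  }
  list(g = g, u = u, b = b)
}

# Reduce the chain to activity A = N y0 / (C + D y0) plus per-step product
# representations.  All arithmetic is generic: supply numeric parameters
# for the forward model or kpoly symbols for derivations.  The reduction
# is division-free (post-step binding denominators are cleared against the
# downstream load structurally), so on symbolic inputs N, C and D come out
# as genuine polynomials with positive composite coefficients.
chain_reduce <- function(chain, decels = list(), one = 1) {
  n <- length(chain$steps)
  rb <- step_roles(chain)
  roles <- rb$roles; block <- rb$block

  bad <- vapply(decels, function(d) d$step < 1L || d$step > n, TRUE)
  if (any(bad)) stop("decelerator attached to undefined step")

  # post-step pass-through numerators/denominators: f_j = fn_j / fd_j
  fn <- vector("list", n); fd <- vector("list", n); mn <- vector("list", n)
  for (i in seq_len(n)) {
    if (roles[i] != "post") next
    dfi <- decel_factors(decels, i, one)
    qi <- chain$steps[[i]]$q; Xi <- chain$steps[[i]]$X_total
    fn[[i]] <- qi * Xi * dfi$b   # productive pass-through
    mn[[i]] <- qi * Xi * dfi$u   # mass counted against the CLS accelerator
    fd[[i]] <- dfi$g
  }

  # for the CLS of block `blk`: F_all = prod fd_j, and the cleared load
  # L * F_all = sum_j mn_j * prod_{k<j} fn_k * prod_{k>j} fd_k
  block_load <- function(blk) {
    post <- which(roles == "post" & block == blk)
    F_all <- one
    for (j in post) F_all <- F_all * fd[[j]]
    LF <- 0 * one
    lead <- one                       # prod_{k<j} fn_k
    trail <- vector("list", length(post))  # prod_{k>j} fd_k
    if (length(post)) {
      trail[[length(post)]] <- one
      for (idx in rev(seq_along(post))[-1]) {
        trail[[idx]] <- trail[[idx + 1L]] * fd[[post[idx + 1L]]]
      }
      for (idx in seq_along(post)) {
        LF <- LF + lead * mn[[post[idx]]] * trail[[idx]]
        lead <- lead * fn[[post[idx]]]
      }
    }
    list(F_all = F_all, LF = LF, post = post, trail = trail)
  }

  # weights: which steps carry activity, and in which block
  w <- chain$activity_weights
  w_idx <- which(seq_len(n) >= chain$first_weighted)
  wk <- function(i) {
    v <- if (is.list(w)) w[[i - chain$first_weighted + 1L]] else w[i - chain$first_weighted + 1L]
    v
  }
  w_zero <- function(i) {
    v <- wk(i); is.numeric(v) && length(v) == 1L && v == 0
  }
  active <- w_idx[!vapply(w_idx, w_zero, logical(1))]
  blocks_used <- unique(block[active])
  if (length(blocks_used) > 1L) {
    stop("activity weights span more than one CLS block; ",
         "the activity is then not a single linear-fractional function")
  }
  a_blk <- blocks_used

  # compose the per-step maps; current product [Y_i] = N y0 / (C + D y0)
  N <- one; C <- one; D <- 0 * one
  A_N <- NULL; A_C <- NULL; A_D <- NULL
  triples <- vector("list", n)
  for (i in seq_len(n)) {
    qi <- chain$steps[[i]]$q; Xi <- chain$steps[[i]]$X_total
    dfi <- decel_factors(decels, i, one)
    if (roles[i] == "pre") {
      N2 <- (qi * Xi * dfi$b) * N
      D2 <- dfi$g * D + (qi * dfi$u) * N
      C2 <- dfi$g * C
      N <- N2; C <- C2; D <- D2
    } else if (roles[i] == "cls") {
      bl <- block_load(block[i])
      B <- qi * Xi * dfi$b
      N2 <- B * bl$F_all * N
      C2 <- dfi$g * bl$F_all * C
      D2 <- dfi$g * bl$F_all * D +
        qi * (dfi$u * bl$F_all + dfi$b * bl$LF) * N
      if (block[i] == a_blk) {
        # activity A = [Y_cls] * (w_c + sum w_i prod f); cleared by F_all:
        # WsumF = sum_{i active} w_i prod_{k<=i} fn_k prod_{k>i} fd_k
        WsumF <- 0 * one
        lead <- one
        if (i %in% active) WsumF <- WsumF + wk(i) * bl$F_all
        for (idx in seq_along(bl$post)) {
          j <- bl$post[idx]
          lead <- lead * fn[[j]]
          if (j %in% active) WsumF <- WsumF + wk(j) * lead * bl$trail[[idx]]
        }
        A_N <- B * N * WsumF
        A_C <- C2
        A_D <- D2
      }
      N <- N2; C <- C2; D <- D2
    } else { # post: proportional map, cleared against fd
      N <- fn[[i]] * N
      C <- fd[[i]] * C
      D <- fd[[i]] * D
    }
    triples[[i]] <- list(N = N, C = C, D = D)
  }
  if (is.null(A_N)) stop("internal error: no activity accumulated")
  list(N = A_N, C = A_C, D = A_D, triples = triples, roles = roles,
       block = block)
}

#' Closed-form dose-response of a reaction chain
#'
#' Builds the activity `A = V [Y0] / (1 + W [Y0])` by recursive composition
#' of the per-step linear-fractional maps: saturating pre-CLS steps, the
#' CLS step carrying the pseudo-first-order downstream load, and
#' proportional post-CLS steps.  Decelerators modify the `V` and `W`
#' denominators through their binding factors.  `Amax = V/W` and
#' `EC50 = 1/W` are attached as attributes.
#'
#' @param chain A [reaction_chain()].  The chain should be in the CLS
#'   regime (see [check_cls_conditions()]); outside it the closed form and
#'   the exact equilibrium diverge.
#' @param decels List of [decelerator_spec()] objects.
#' @return A [linear_fractional()] object in `[Y0]` with attributes
#'   `V`, `W`, `Amax`, `EC50`.
#' @examples
#' ch <- reaction_chain(
#'   list(reaction_step(1, 1), reaction_step(0.01, 1), reaction_step(1, 1)),
#'   cls_index = 2, activity_weights = c(0, 1))
#' attr(closed_form_dose_response(ch), "Amax")  # 0.01/1.02
#' @export
closed_form_dose_response <- function(chain, decels = list()) {
  red <- chain_reduce(chain, decels)
  V <- red$N / red$C
  W <- red$D / red$C
  out <- linear_fractional(0, V, 1, W, canonical = FALSE)
  attr(out, "V") <- V
  attr(out, "W") <- W
  attr(out, "Amax") <- V / W
  attr(out, "EC50") <- 1 / W
  out
}

#' Effective accelerator step acting through a hetero-oligomer
#'
#' An accelerator `X` that first binds a superabundant partner `Z`
#' (`X + Z <-> XZ`, affinity `r`) and then drives `Y[i-1] -> Y[i]` with
#' affinity `q` behaves like a plain accelerator with effective strength
#' `r q [Z] / (1 + r [Z])`, saturating in `[Z]`:
#' `[Yi] = (r q XT [Z] / (1 + r[Z])) y / (1 + (r q [Z] / (1 + r[Z])) y)`.
#'
#' @param olig An [oligomer_spec()].
#' @param q Affinity of the product-forming reaction.
#' @param X_total Total concentration of the limited factor `X`.
#' @param y_prev Concentration of the previous product `[Y[i-1]]`.
#' @return The product concentration `[Y[i]]`.
#' @export
oligomer_effective_step <- function(olig, q, X_total, y_prev) {
  stopifnot(q >= 0, X_total >= 0, all(y_prev >= 0))
  eff <- olig$r * q * olig$Z_total / (1 + olig$r * olig$Z_total)
  eff * X_total * y_prev / (1 + eff * y_prev)
}
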