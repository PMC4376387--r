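#' Mechanism of a transcription cofactor
#'
#' A factor acts kinetically either as an accelerator (enzymatic-activator
#' like: combines with the previous product to form the next) or as one of
#' six decelerator types (enzymatic-inhibitor like), independent of whether
#' the observed output rises or falls.
#'
#' @param kind `"A"` (accelerator) or `"D"` (decelerator).
#' @param decel_type For decelerators: one of `"LC"`, `"LU"`, `"LN"`,
#'   `"PC"`, `"PU"`, `"PN"` (linear/partial x competitive/uncompetitive/
#'   noncompetitive), or `NULL` for a generic decelerator with free
#'   alpha/beta/gamma.
#' @export
mechanism <- function(kind = c("A", "D"), decel_type = NULL) {
  kind <- match.arg(kind)
  if (kind == "A" && !is.null(decel_type)) {
    stop("decel_type only applies to decelerators")
  }
  if (!is.null(decel_type)) {
    decel_type <- toupper(decel_type)
    stopifnot(decel_type %in% c("LC", "LU", "LN", "PC", "PU", "PN"))
  }
  structure(list(kind = kind, decel_type = decel_type), class = "mechanism")
}

mech_label <- function(m) {
  if (m$kind == "A") "A" else if (is.null(m$decel_type)) "D" else m$decel_type
}

#' Configuration of the steroid receptor and one cofactor
#'
#' Positions are coarse-grained relative to the concentration-limited step
#' (CLS): `"before"`, `"at"` or `"after"`, plus the relative order of the
#' two factors.  Admissibility follows the counting of the theory: GR as an
#' accelerator can only repress after the CLS; two factors can share a step
#' only if one is an accelerator and the other a decelerator; two distinct
#' factors cannot both be the accelerator at the (single) CLS.
#'
#' @param factor_mech,gr_mech [mechanism()] objects for the cofactor and GR.
#' @param factor_pos,gr_pos `"before"`, `"at"` or `"after"` (the CLS).
#' @param order `"GR-before-F"`, `"GR-after-F"` or `"same-step"`.  When the
#'   two positions differ the order is implied and checked.
#' @export
configuration <- function(factor_mech, factor_pos, gr_mech, gr_pos, order) {
  poss <- c("before", "at", "after")
  stopifnot(inherits(factor_mech, "mechanism"), inherits(gr_mech, "mechanism"),
            factor_pos %in% poss, gr_pos %in% poss,
            order %in% c("GR-before-F", "GR-after-F", "same-step"))
  rank <- c(before = 1L, at = 2L, after = 3L)
  if (order == "same-step") {
    if (factor_pos != gr_pos) stop("same-step configuration with different positions")
    if (sum(c(factor_mech$kind, gr_mech$kind) == "A") != 1L) {
      stop("same-step requires exactly one accelerator and one decelerator")
    }
  } else {
    if (rank[factor_pos] != rank[gr_pos]) {
      implied <- if (rank[gr_pos] < rank[factor_pos]) "GR-before-F" else "GR-after-F"
      if (order != implied) stop("order inconsistent with positions")
    }
    if (factor_pos == "at" && gr_pos == "at") {
      stop("two distinct factors cannot both act at the single CLS")
    }
  }
  if (gr_mech$kind == "A" && gr_pos != "after") {
    stop("GR cannot repress as an accelerator before or at the CLS")
  }
  structure(list(factor_mech = factor_mech, factor_pos = factor_pos,
                 gr_mech = gr_mech, gr_pos = gr_pos, order = order),
            class = "configuration")
}

#' @export
print.configuration <- function(x, ...) {
  cat(sprintf("<configuration> F: %s %s CLS; GR: %s %s CLS; %s\n",
              mech_label(x$factor_mech), x$factor_pos,
              mech_label(x$gr_mech), x$gr_pos, x$order))
  invisible(x)
}

config_id <- function(cfg) {
  sprintf("F:%s@%s|GR:%s@%s|%s", mech_label(cfg$factor_mech), cfg$factor_pos,
          mech_label(cfg$gr_mech), cfg$gr_pos, cfg$order)
}

#' Enumerate the admissible GR + cofactor configurations
#'
#' Follows the counting convention of the theory: 5 unordered distinct-step
#' positional arrangements of two factors relative to the CLS become 10
#' ordered arrangements; 3 more place the two factors at the same step (one
#' accelerator, one decelerator).  GR can act as a decelerator in all 13
#' arrangements, or as an accelerator after the CLS in 5 of them, giving 18
#' configurations in total.  The cofactor's own mechanism is not part of
#' this count; each returned configuration carries a default concrete
#' instantiation (cofactor = accelerator wherever the arrangement permits)
#' used by [derive_TU()], and decelerator-subtype-expanded counts are
#' reported separately in the `"counts"` attribute without folding them
#' into the headline 18.
#'
#' @param gr_decel_type Concrete decelerator subtype given to GR in the
#'   GR-as-decelerator configurations (default `"LC"`, linear competitive);
#'   `NULL` keeps GR as a generic decelerator.
#' @return A list of [configuration()] objects with attribute `"counts"`:
#'   `total`, `gr_decelerator`, `gr_accelerator_after_cls`,
#'   `ordered_positional`, `same_step`, `subtype_expanded`.
#' @export
enumerate_configurations <- function(gr_decel_type = "LC") {
  poss <- c("before", "at", "after")
  # ordered distinct-step arrangements (F position, GR position, order)
  arr <- list()
  unordered <- list(c("before", "before"), c("before", "at"), c("before", "after"),
                    c("at", "after"), c("after", "after"))
  for (u in unordered) {
    if (u[1] == u[2]) {
      arr[[length(arr) + 1L]] <- list(f = u[1], g = u[2], order = "GR-before-F")
      arr[[length(arr) + 1L]] <- list(f = u[1], g = u[2], order = "GR-after-F")
    } else {
      # the two assignments of {F, GR} to the two positions
      o1 <- if (match(u[1], poss) < match(u[2], poss)) "GR-after-F" else "GR-before-F"
      arr[[length(arr) + 1L]] <- list(f = u[1], g = u[2], order = o1)
      o2 <- if (match(u[2], poss) < match(u[1], poss)) "GR-after-F" else "GR-before-F"
      arr[[length(arr) + 1L]] <- list(f = u[2], g = u[1], order = o2)
    }
  }
  n_ordered <- length(arr)  # 10
  same <- lapply(poss, function(p) list(f = p, g = p, order = "same-step"))
  n_same <- length(same)    # 3

  configs <- list()
  # GR as decelerator in all 13 arrangements
  for (a in c(arr, same)) {
    fmech <- mechanism("A")
    if (a$order == "same-step") fmech <- mechanism("A")  # F is the accelerator
    configs[[length(configs) + 1L]] <-
      configuration(fmech, a$f, mechanism("D", gr_decel_type), a$g, a$order)
  }
  n_decel <- length(configs)
  # GR as accelerator after the CLS
  for (a in c(arr, same)) {
    if (a$g != "after") next
    fmech <- if (a$order == "same-step") mechanism("D", "LC") else mechanism("A")
    configs[[length(configs) + 1L]] <-
      configuration(fmech, a$f, mechanism("A"), a$g, a$order)
  }
  n_accel <- length(configs) - n_decel

  counts <- list(total = length(configs),
                 gr_decelerator = n_decel,
                 gr_accelerator_after_cls = n_accel,
                 ordered_positional = n_ordered,
                 same_step = n_same,
                 # 6 decelerator subtypes for each GR-as-D configuration
                 subtype_expanded = n_decel * 6L + n_accel)
  names(configs) <- vapply(configs, config_id, character(1))
  attr(configs, "counts") <- counts
  configs
}
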