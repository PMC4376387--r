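# Rule engine: match a plot signature against the prediction rule table
# and intersect the fired predictions over the configuration universe.

#' Load the prediction rule table
#'
#' The 22 rules live as data in `inst/extdata/table1_rules.json` so that
#' side constraints can be audited and applied as a post-filter rather
#' than being buried in code.
#'
#' @param path Optional path to an alternative rules file.
#' @return The parsed rule list.
#' @export
load_rules <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "table1_rules.json", package = "clskinetics")
    if (path == "") path <- file.path("inst", "extdata", "table1_rules.json")
  }
  jsonlite::fromJSON(path, simplifyVector = FALSE)$entries
}

# expanded configuration universe: concrete decelerator subtypes for both
# factors over the 13 positional arrangements (one accelerator per step:
# two factors can share a step only as accelerator + decelerator, and GR
# accelerates only after the CLS)
config_universe <- function() {
  mechs <- c("A", "LC", "LU", "LN", "PC", "PU", "PN")
  poss <- c("before", "at", "after")
  rows <- list()
  arr <- list()
  for (fp in poss) for (gp in poss) {
    if (fp == "at" && gp == "at") { arr[[length(arr) + 1L]] <- c(fp, gp, "same-step"); next }
    rank <- match(c(fp, gp), poss)
    if (rank[1] == rank[2]) {
      arr[[length(arr) + 1L]] <- c(fp, gp, "GR-before-F")
      arr[[length(arr) + 1L]] <- c(fp, gp, "GR-after-F")
      arr[[length(arr) + 1L]] <- c(fp, gp, "same-step")
    } else {
      arr[[length(arr) + 1L]] <- c(fp, gp, if (rank[2] < rank[1]) "GR-before-F" else "GR-after-F")
    }
  }
  for (a in arr) for (fm in mechs) for (gm in mechs) {
    if (gm == "A" && a[2] != "after") next
    same <- a[3] == "same-step"
    n_acc <- (fm == "A") + (gm == "A")
    if (same && n_acc != 1L) next
    rows[[length(rows) + 1L]] <- data.frame(f_mech = fm, f_pos = a[1],
                                            g_mech = gm, g_pos = a[2],
                                            order = a[3])
  }
  do.call(rbind, rows)
}

mech_matches <- function(label, classes) {
  if (is.null(classes)) return(rep(TRUE, length(label)))
  hit <- rep(FALSE, length(label))
  for (cl in classes) {
    hit <- hit | switch(cl,
      A = label == "A",
      D = label != "A",
      C = label %in% c("LC", "PC"),
      U = label %in% c("LU", "PU"),
      N = label %in% c("LN", "PN"),
      L = label %in% c("LC", "LU", "LN"),
      P = label %in% c("PC", "PU", "PN"),
      label == cl)
  }
  hit
}

rel_matches <- function(order, rel) {
  if (is.null(rel)) return(rep(TRUE, length(order)))
  switch(rel,
    "after-F" = order == "GR-after-F",
    "before-F" = order == "GR-before-F",
    "at-F" = order == "same-step",
    "after-GR" = order == "GR-before-F",
    "after-or-at-GR" = order %in% c("GR-before-F", "same-step"),
    stop("unknown rel constraint: ", rel))
}

alt_matches <- function(universe, alt) {
  ok <- rep(TRUE, nrow(universe))
  f <- alt$factor; g <- alt$gr
  if (!is.null(f)) {
    ok <- ok & mech_matches(universe$f_mech, unlist(f$mech))
    if (!is.null(f$pos)) ok <- ok & universe$f_pos %in% unlist(f$pos)
    ok <- ok & rel_matches(universe$order, f$rel)
  }
  if (!is.null(g)) {
    ok <- ok & mech_matches(universe$g_mech, unlist(g$mech))
    if (!is.null(g$pos)) ok <- ok & universe$g_pos %in% unlist(g$pos)
    ok <- ok & rel_matches(universe$order, g$rel)
  }
  ok
}

signature_fields <- function(sig) {
  list(
    amax_dir = unname(sig$direction["amax"]),
    amin_dir = unname(sig$direction["amin"]),
    ic50_dir = unname(sig$direction["ic50"]),
    ratio_dir = unname(sig$direction["ratio"]),
    amax_linear = unname(sig$linear["amax"]),
    amin_linear = unname(sig$linear["amin"]),
    amax_origin = unname(sig$through_origin["amax"]),
    amin_origin = unname(sig$through_origin["amin"]),
    amax_pos0 = unname(sig$positive_at_true_zero["amax"]),
    amin_pos0 = unname(sig$positive_at_true_zero["amin"]),
    amax_zero_inf = unname(sig$approaches_zero["amax"]),
    amin_zero_inf = unname(sig$approaches_zero["amin"]),
    ord_amin_amax = sig$ord_amin_amax,
    ord_inv = sig$ord_inv_amin_amax
  )
}

#' Classify a plot signature with the prediction rule table
#'
#' Fires every rule entry whose condition matches the signature, collects
#' the predictions with their entry provenance, and reports the
#' intersection: the concrete (mechanism, position, order) combinations of
#' the cofactor and GR consistent with at least one alternative of every
#' fired entry.  A contradictory signature yields an empty intersection
#' (reported, not an error).
#'
#' @param sig A `plot_signature` from [extract_signature()].
#' @param rules Rule list from [load_rules()].
#' @return A list: `fired` (data frame of entry id, property, prediction
#'   texts), `survivors` (subset of the configuration universe), `empty`.
#' @export
classify <- function(sig, rules = load_rules()) {
  stopifnot(inherits(sig, "plot_signature"))
  fields <- signature_fields(sig)
  uni <- config_universe()
  fired <- list()
  alive <- rep(TRUE, nrow(uni))
  for (e in rules) {
    cond_ok <- all(vapply(names(e$when), function(f) {
      want <- e$when[[f]]
      have <- fields[[f]]
      !is.null(have) && !is.na(have) && identical(unname(have), want)
    }, logical(1)))
    if (!cond_ok) next
    hit <- rep(FALSE, nrow(uni))
    for (alt in e$predictions) hit <- hit | alt_matches(uni, alt)
    alive <- alive & hit
    fired[[length(fired) + 1L]] <- data.frame(
      id = e$id, property = e$property,
      predictions = paste(vapply(e$predictions, `[[`, character(1), "text"),
                          collapse = " | "))
  }
  fired_df <- if (length(fired)) do.call(rbind, fired) else
    data.frame(id = integer(0), property = character(0), predictions = character(0))
  list(fired = fired_df, survivors = uni[alive, , drop = FALSE],
       empty = !any(alive))
}
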