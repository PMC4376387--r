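# End-to-end pipeline: simulate (or load) -> fit dose-responses ->
# normalised parameter plots -> signature -> rule-table classification +
# GR feasibility -> MCMC/BIC model comparison -> report bundle.

#' Collapse a parameter-plot dataset across trace groups
#'
#' Averages the normalised series over the grouping variable (e.g. the
#' reporter dose for cofactor-axis plots), propagating the SEM.
#'
#' @param ds A `param_plot_dataset`.
#' @return A `param_plot_dataset` with a single group.
#' @export
collapse_groups <- function(ds) {
  out <- list()
  for (p in unique(ds$param)) {
    sub <- ds[ds$param == p, ]
    agg <- stats::aggregate(sub$value, by = list(x = sub$x), FUN = mean)
    sem2 <- stats::aggregate(sub$sem^2, by = list(x = sub$x),
                             FUN = function(v) sqrt(sum(v)) / length(v))
    ngrp <- stats::aggregate(sub$n, by = list(x = sub$x), FUN = sum)
    out[[p]] <- data.frame(param = p, x = agg$x, group = 1,
                           value = agg[[2]], sem = sem2[[2]], n = ngrp[[2]])
  }
  ds2 <- do.call(rbind, out)
  rownames(ds2) <- NULL
  class(ds2) <- c("param_plot_dataset", "data.frame")
  attr(ds2, "x_var") <- attr(ds, "x_var")
  attr(ds2, "frac_amax_gt_amin") <- attr(ds, "frac_amax_gt_amin")
  ds2
}

#' Fit the four parameter plots of a (collapsed) dataset
#'
#' @param ds A `param_plot_dataset` (collapsed to one group, or it will
#'   be collapsed).
#' @param endogenous Endogenous cofactor level added to the x axis.
#' @return Named list of `param_fit` objects (`amax`, `amin`, `ic50`,
#'   `ratio`).
#' @export
fit_param_plots <- function(ds, endogenous = 0) {
  if (length(unique(ds$group)) > 1L) ds <- collapse_groups(ds)
  fits <- list()
  for (p in c("amax", "amin", "ic50", "ratio")) {
    sub <- ds[ds$param == p, ]
    sem <- sub$sem
    # floor the SEM at 2% of the series scale: chi2-based BIC shape
    # selection needs errors in measurement units, and noiseless or
    # single-experiment series otherwise degenerate
    floor_p <- 0.02 * stats::median(abs(sub$value), na.rm = TRUE)
    sem[!is.finite(sem) | sem < floor_p] <- floor_p
    fits[[p]] <- tryCatch(
      fit_param_vs_cofactor(sub$x + endogenous, sub$value, sem),
      error = function(e) {
        # series with (almost) no identifiable points: report a flat,
        # non-informative trace rather than failing the stage
        warning("parameter series '", p, "' has too few identifiable points; ",
                "treated as constant")
        v <- mean(sub$value[is.finite(sub$value)])
        if (!is.finite(v)) v <- 1
        structure(list(shape = "const",
                       lf = linear_fractional(v, 0, 1, 0),
                       coef = c(a = v),
                       chi2 = c(const = 0), bic = c(const = 0), k = 1,
                       n = sum(is.finite(sub$value)),
                       x_intercept = NA_real_, x_intercept_se = NA_real_,
                       x = sub$x + endogenous, y = sub$value, sem = sem),
                  class = "param_fit")
      })
  }
  fits
}

#' Run the full analysis pipeline
#'
#' Stages: simulate (or load) the assay table; fit every grid cell's
#' dose-response; build normalised parameter plots; fit their shapes and
#' extract the qualitative signature; classify with the rule table and
#' run the GR feasibility scan; compare the predicted/permuted/
#' unconstrained model structures by MCMC + BIC; write the report bundle.
#' Fully deterministic given the seed.
#'
#' @param config A `pipeline_config` list (or path to its JSON):
#'   fields `simulate` (with `configuration` = list(factor_mech,
#'   factor_pos, gr_mech, gr_pos, order), optional `overrides`,
#'   `endogenous`, `design`, `noise`) or `input_csv`; optional `mcmc`
#'   (`iterations`), `feasibility` (`n_samples`), `mode`, `seed`,
#'   `outdir`.
#' @param seed Overrides `config$seed`.
#' @param outdir Overrides `config$outdir`; `NULL` writes nothing.
#' @return A `pipeline_result` list with all stage outputs.
#' @export
run_pipeline <- function(config, seed = NULL, outdir = NULL) {
  if (is.character(config)) config <- jsonlite::fromJSON(config, simplifyVector = FALSE)
  seed <- if (!is.null(seed)) seed else if (!is.null(config$seed)) config$seed else 1
  outdir <- if (!is.null(outdir)) outdir else config$outdir
  mode <- if (!is.null(config$mode)) config$mode else "repression"

  # --- stage: data -------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    cc <- sim$configuration
    cfg <- configuration(as_mech(cc$factor_mech), cc$factor_pos,
                         as_mech(cc$gr_mech), cc$gr_pos, cc$order)
    endo <- sim$endogenous %||% 0
    truth <- ground_truth(cfg, overrides = sim$overrides %||% list(),
                          endogenous = endo)
    design <- do.call(assay_design, sim$design %||% list())
    noise <- do.call(noise_model, sim$noise %||% list())
    table <- generate_assay(truth, design, noise, seed = seed)
  } else if (!is.null(config$input_csv)) {
    table <- utils::read.csv(config$input_csv)
    truth <- NULL
    endo <- config$endogenous %||% 0
  } else {
    stop("pipeline config needs either `simulate` or `input_csv`")
  }

  # --- stage: fit --------------------------------------------------------
  ds <- normalize_grid(table, x_var = "cofactor", mode = mode)
  fits <- fit_param_plots(ds, endogenous = endo)
  sig <- extract_signature(fits, endogenous_level = endo,
                           amax_gt_amin = attr(ds, "frac_amax_gt_amin") > 0.5)

  # --- stage: classify ---------------------------------------------------
  cls <- classify(sig)
  n_feas <- config$feasibility$n_samples %||% 2000
  inference <- infer_gr_action(list(F = sig), n_samples = n_feas,
                               seed = seed)

  # --- stage: compare ----------------------------------------------------
  iters <- config$mcmc$iterations %||% 2e4
  comparison <- model_compare(ds, iterations = iters, seed = seed)

  result <- structure(list(
    table = table, dataset = ds, fits = fits, signature = sig,
    classification = cls, inference = inference, comparison = comparison,
    truth = if (exists("truth")) truth else NULL,
    seed = seed, mode = mode, config = config), class = "pipeline_result")

  if (!is.null(outdir)) write_report_bundle(result, outdir)
  result
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# accept a mechanism object, a label string ("A", "D", "LC", ...) or a
# list(kind=, decel_type=) from a JSON config
as_mech <- function(m) {
  if (inherits(m, "mechanism")) return(m)
  if (is.character(m) && length(m) == 1L) {
    if (m %in% c("A", "D")) return(mechanism(m))
    return(mechanism("D", m))
  }
  mechanism(m$kind, m$decel_type)
}

#' Write the report bundle of a pipeline run
#'
#' CSV/JSON artefacts plus a human-readable summary; content is a pure
#' function of (inputs, config, seed) — no timestamps.
#'
#' @param result A `pipeline_result`.
#' @param outdir Output directory (created if needed).
#' @export
write_report_bundle <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$table, file.path(outdir, "assay_table.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(result$dataset),
                   file.path(outdir, "parameter_plots.csv"), row.names = FALSE)
  fits_json <- lapply(result$fits, function(f) {
    list(shape = f$shape, coef = as.list(f$coef), bic = as.list(f$bic),
         x_intercept = f$x_intercept)
  })
  jsonlite::write_json(fits_json, file.path(outdir, "param_fits.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  sig <- result$signature
  jsonlite::write_json(
    list(direction = as.list(sig$direction), linear = as.list(sig$linear),
         through_origin = as.list(sig$through_origin),
         positive_at_true_zero = as.list(sig$positive_at_true_zero),
         ord_amin_amax = sig$ord_amin_amax,
         ord_inv_amin_amax = sig$ord_inv_amin_amax,
         amax_gt_amin = sig$amax_gt_amin),
    file.path(outdir, "signature.json"), auto_unbox = TRUE, pretty = TRUE)
  utils::write.csv(result$classification$fired,
                   file.path(outdir, "classification_entries.csv"),
                   row.names = FALSE)
  utils::write.csv(result$classification$survivors,
                   file.path(outdir, "classification_survivors.csv"),
                   row.names = FALSE)
  feas <- result$inference$feasibility
  utils::write.csv(data.frame(configuration = rownames(feas), feas,
                              check.names = FALSE),
                   file.path(outdir, "gr_feasibility.csv"), row.names = FALSE)
  utils::write.csv(result$comparison$table,
                   file.path(outdir, "model_comparison.csv"), row.names = FALSE)
  jsonlite::write_json(list(seed = result$seed, mode = result$mode),
                       file.path(outdir, "run_meta.json"), auto_unbox = TRUE)
  writeLines(pipeline_summary(result), file.path(outdir, "summary.txt"))
  invisible(outdir)
}

#' One-paragraph human-readable conclusion of a pipeline run
#'
#' @param result A `pipeline_result`.
#' @return Character vector of summary lines.
#' @export
pipeline_summary <- function(result) {
  sig <- result$signature
  surv <- result$inference$survivors
  lines <- c(
    "== kinetic repression pipeline summary ==",
    sprintf("seed: %d  mode: %s", result$seed, result$mode),
    sprintf("signature: Amax %s, Amin %s, IC50 %s, ratio %s; Amax>Amin: %s",
            sig$direction["amax"], sig$direction["amin"],
            sig$direction["ic50"], sig$direction["ratio"], sig$amax_gt_amin),
    sprintf("rule-table entries fired: %s",
            paste(result$classification$fired$id, collapse = ", ")),
    sprintf("surviving configurations (%d):", length(surv)))
  for (nm in names(surv)) {
    cfg <- surv[[nm]]
    lines <- c(lines, sprintf(
      "  factor: %s %s CLS; GR: %s %s CLS (%s)",
      if (cfg$factor_mech$kind == "A") "accelerator" else "decelerator",
      cfg$factor_pos,
      if (cfg$gr_mech$kind == "A") "accelerator" else "decelerator",
      cfg$gr_pos, cfg$order))
  }
  lines <- c(lines,
             sprintf("model comparison (BIC): best = %s", result$comparison$best),
             paste(utils::capture.output(print(result$comparison$table,
                                               row.names = FALSE)),
                   collapse = "\n"))
  lines
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(paste(pipeline_summary(x), collapse = "\n"), "\n")
  invisible(x)
}

#' Command-line entry point
#'
#' `Rscript -e 'clskinetics::run_pipeline_cli()' --args --config cfg.json
#' --seed 1 --outdir out` (or via the wrapper script shipped in
#' `inst/scripts/run_pipeline.R`).  Flags: `--config PATH`, `--seed INT`,
#' `--outdir PATH`, `--mode repression|induction`, `--full-scale-mcmc`.
#'
#' @param args Command-line arguments (default `commandArgs(TRUE)`).
#' @return The `pipeline_result`, invisibly.
#' @export
run_pipeline_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  get_opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) == 1L && i < length(args)) args[i + 1L] else default
  }
  cfg_path <- get_opt("--config")
  if (is.null(cfg_path)) stop("--config PATH is required")
  config <- jsonlite::fromJSON(cfg_path, simplifyVector = FALSE)
  seed <- as.integer(get_opt("--seed", config$seed %||% 1))
  outdir <- get_opt("--outdir", config$outdir %||% "pipeline_out")
  config$mode <- get_opt("--mode", config$mode %||% "repression")
  if ("--full-scale-mcmc" %in% args) {
    config$mcmc$iterations <- 2e7
  }
  result <- run_pipeline(config, seed = seed, outdir = outdir)
  message("pipeline complete; outputs in ", outdir)
  invisible(result)
}
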