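# Synthetic competition-assay generator: forward-simulates the kinetic
# model for a known (mechanism, position) ground truth so that the entire
# inference pipeline can be tested end to end without any external data.

#' Ground truth for a synthetic competition assay
#'
#' Fills the symbolic scaffold of a configuration with concrete positive
#' parameter values.  Defaults emulate the assay the model describes: a
#' saturating induction head step, a reporter-occupied CLS whose
#' accelerator stays concentration-limited over the titrated range
#' (`q * X_total <= 0.01`), post-CLS accelerators of order-one effect,
#' receptor scale `G = 10` with steroid binding constant `K = 30` nM and
#' receptor-step strength giving several-fold repression, and a diverted
#' post-receptor branch with 3% of the productive branch's activity
#' weight.
#'
#' @param config A [configuration()].
#' @param overrides Named list of parameter values overriding defaults
#'   (symbol names as in `derive_TU(config)$symbols`).
#' @param endogenous Endogenous cofactor level in dose units (added to
#'   every nominal cofactor dose; 0 for small molecules, about 2.7
#'   ng-equivalents for a TIF2-like protein cofactor).
#' @param cls_scale Concentration per dose unit of whichever species
#'   occupies the CLS (reporter plasmid, or the cofactor when it acts at
#'   the CLS).  The default 1e-3 keeps the CLS accelerator limited
#'   (`q_c * conc <= 0.01`) while the post-CLS pools stay in excess --
#'   the molar-scale separation that defines the CLS regime.
#' @return A `ground_truth` list: `config`, `tu` (symbolic form), `params`
#'   (named numeric), `endogenous`, `cls_scale`, `cls_var`.
#' @export
ground_truth <- function(config, overrides = list(), endogenous = 2.7,
                         cls_scale = 2.5e-4) {
  tu <- derive_TU(config)
  sc <- tu$scaffold
  roles <- step_roles(sc$chain)$roles
  decel_steps <- vapply(sc$decels, `[[`, integer(1), "step")
  params <- list()
  for (s in tu$symbols) {
    params[[s]] <-
      if (s == "Y0") 10 else
      if (s == "G") 10 else
      if (s == "K") 30 else
      if (s == "qh") 1 else
      if (s == "Xh") 10 else
      # q_c applies to the scaled CLS occupant (dose * cls_scale), so the
      # load term q_c*[Y1]*(1+L) can reach order one -- needed for
      # post-CLS diversion to repress -- while q_c * conc stays << 1
      if (s == "qc") 0.05 else
      if (s == "qF" || s == "qG") {
        who <- substr(s, 2, 2)
        step <- which(vapply(sc$chain$steps, function(st) {
          identical(st$X_total$vars, if (who == "G") "GRX" else "X")
        }, logical(1)))[1]
        if (length(step) && !is.na(step) && roles[step] == "pre") 5e-5
        else if (who == "G") 3 else 0.3
      } else
      if (grepl("^qc[FG]$", s)) {   # carrier step affinity
        step <- decel_steps[match(substr(s, 3, 3), vapply(sc$decels, function(d) {
          if (identical(d$conc$vars, "DGR")) "G" else "F"
        }, character(1)))]
        if (!is.na(step) && roles[step] == "pre") 1e-3 else 0.3
      } else
      if (grepl("^Xc", s)) {              # carrier accelerator amount
        step <- decel_steps[match(substr(s, 3, 3), vapply(sc$decels, function(d) {
          if (identical(d$conc$vars, "DGR")) "G" else "F"
        }, character(1)))]
        if (!is.na(step) && roles[step] == "pre") 5 else 10
      } else
      if (grepl("^qp", s)) {              # decelerator affinity q'
        if (grepl("G$", s)) 0.3 else 0.03
      } else
      if (grepl("^(alpha|gamma|ag)", s)) 1 else
      if (grepl("^beta", s)) 0.5 else
      if (grepl("^w[0-9]+$", s)) {
        i <- as.integer(sub("w", "", s))
        if (sc$gr_is_accel && !is.na(sc$gr_step) && i >= sc$gr_step) 0.03 else 1
      } else 1
  }
  # the head pool compensates the attenuation of intermediate pre-CLS
  # steps so the product concentration feeding the CLS keeps its scale
  # (the CLS load term carries all post-CLS repression).  Compensation is
  # capped so no intermediate step saturates in its input (q_i * [Y_in]
  # <= 0.3): a decelerator acting on a saturated step would be shielded.
  if (!("Xh" %in% names(overrides)) && sc$cls_index > 2L) {
    y0 <- params$Y0
    y1_base <- 10 * y0 / (1 + y0)
    atten <- 1; y1_cap <- Inf; run <- 1
    for (i in seq(2L, sc$cls_index - 1L)) {
      st <- sc$chain$steps[[i]]
      q_i <- params[[st$q$vars]]
      x_i <- if (identical(st$X_total$vars, "X")) 30 + endogenous else
        params[[st$X_total$vars]]
      y1_cap <- min(y1_cap, 0.3 / (q_i * run))
      run <- run * q_i * x_i
      atten <- atten * q_i * x_i
    }
    y1 <- max(y1_base, min(y1_base / atten, y1_cap))
    params$Xh <- y1 * (1 + y0) / y0
  }
  params[names(overrides)] <- overrides
  cls_var <- sc$chain$steps[[sc$cls_index]]$X_total$vars
  structure(list(config = config, tu = tu, params = params,
                 endogenous = endogenous, cls_scale = cls_scale,
                 cls_var = cls_var), class = "ground_truth")
}

#' Mean activity surface of a ground truth
#'
#' Evaluates `A = T(S)/U(S)` at given reporter dose, total cofactor amount
#' and steroid dose (vectorised over `steroid`).
#'
#' @param truth A [ground_truth()].
#' @param reporter Reporter dose (enters the CLS accelerator symbol `R`
#'   when the cofactor does not occupy the CLS).
#' @param cofactor Total cofactor amount (exogenous + endogenous).
#' @param steroid Steroid dose(s).
#' @export
truth_activity <- function(truth, reporter, cofactor, steroid) {
  env <- truth$params
  env$R <- reporter * truth$cls_scale
  env$X <- if (identical(truth$cls_var, "X")) cofactor * truth$cls_scale else cofactor
  env$S <- steroid
  kp_eval(truth$tu$T, env) / kp_eval(truth$tu$U, env)
}

#' Assay design of a synthetic competition experiment
#'
#' Defaults follow the factorial used in the assays the model describes:
#' a 4 x 4 grid of reporter and cofactor doses, four steroid doses
#' including vehicle (0), triplicates, and independently jittered
#' experiments.  Dose grids bracket the expected IC50.
#'
#' @param reporter_doses,cofactor_doses,steroid_doses Dose grids (ng for
#'   plasmids, nM for steroid; arbitrary-but-consistent units).
#' @param replicates Wells per condition.
#' @param n_experiments Independent repeat experiments.
#' @export
assay_design <- function(reporter_doses = c(10, 35, 70, 140),
                         cofactor_doses = c(0, 10, 30, 100),
                         steroid_doses = c(0, 3, 30, 300),
                         replicates = 3, n_experiments = 4) {
  stopifnot(any(steroid_doses == 0), length(steroid_doses[steroid_doses > 0]) >= 3,
            replicates >= 1, n_experiments >= 1)
  structure(list(reporter_doses = reporter_doses,
                 cofactor_doses = cofactor_doses,
                 steroid_doses = steroid_doses,
                 replicates = replicates, n_experiments = n_experiments),
            class = "assay_design")
}

#' Replicate noise model
#'
#' Multiplicative log-normal noise (luciferase counts are positive with
#' roughly constant CV): per-well CV plus an experiment-level scale
#' jitter.  An additive-Gaussian option exists for sensitivity analysis.
#'
#' @param replicate_cv Coefficient of variation of replicate wells.
#' @param experiment_jitter SD of the log-normal per-experiment scale.
#' @param distribution `"lognormal"` or `"additive"`.
#' @export
noise_model <- function(replicate_cv = 0.05, experiment_jitter = 0.10,
                        distribution = c("lognormal", "additive")) {
  stopifnot(replicate_cv >= 0, experiment_jitter >= 0)
  structure(list(replicate_cv = replicate_cv,
                 experiment_jitter = experiment_jitter,
                 distribution = match.arg(distribution)), class = "noise_model")
}

#' Generate a synthetic competition-assay table
#'
#' Mean activity per grid cell comes from the forward model
#' (`A = T(S)/U(S)` at the cell's reporter, total cofactor and steroid
#' amounts); replicates are drawn from the noise model.  Reproducible by
#' seed; the ground truth rides along as an attribute (sidecar).
#'
#' @param truth A [ground_truth()].
#' @param design An [assay_design()].
#' @param noise A [noise_model()].
#' @param seed RNG seed.
#' @return A data frame (`assay_table`) with columns `reporter_dose`,
#'   `cofactor_id`, `cofactor_dose`, `steroid_dose`, `replicate`,
#'   `experiment`, `activity`; attributes `truth` and `design`.
#' @export
generate_assay <- function(truth, design = assay_design(),
                           noise = noise_model(), seed = 1) {
  stopifnot(inherits(truth, "ground_truth"), inherits(design, "assay_design"))
  set.seed(seed)
  grid <- expand.grid(reporter_dose = design$reporter_doses,
                      cofactor_dose = design$cofactor_doses,
                      steroid_dose = design$steroid_doses,
                      KEEP.OUT.ATTRS = FALSE)
  mean_act <- vapply(seq_len(nrow(grid)), function(i) {
    truth_activity(truth, grid$reporter_dose[i],
                   grid$cofactor_dose[i] + truth$endogenous,
                   grid$steroid_dose[i])
  }, numeric(1))
  sdlog_rep <- sqrt(log(1 + noise$replicate_cv^2))
  rows <- list()
  for (e in seq_len(design$n_experiments)) {
    scale_e <- if (noise$experiment_jitter > 0) {
      exp(stats::rnorm(1, -noise$experiment_jitter^2 / 2, noise$experiment_jitter))
    } else 1
    for (rep_i in seq_len(design$replicates)) {
      act <- if (noise$distribution == "lognormal") {
        if (sdlog_rep > 0) {
          mean_act * scale_e * exp(stats::rnorm(nrow(grid), -sdlog_rep^2 / 2, sdlog_rep))
        } else mean_act * scale_e
      } else {
        mean_act * scale_e + stats::rnorm(nrow(grid), 0,
                                          noise$replicate_cv * mean(mean_act))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        reporter_dose = grid$reporter_dose,
        cofactor_id = "F",
        cofactor_dose = grid$cofactor_dose,
        steroid_dose = grid$steroid_dose,
        replicate = rep_i, experiment = e, activity = act)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("assay_table", "data.frame")
  attr(out, "truth") <- truth
  attr(out, "design") <- design
  attr(out, "seed") <- seed
  out
}

#' Generate parameter-plot data directly from a model structure
#'
#' Draws the four parameter series from the predicted, permuted or
#' unconstrained model equations with known parameters, simulating
#' `n_experiments` noisy repeats and returning means with SEMs — the
#' direct input for [model_compare()] recovery studies.
#'
#' @param model A [model_spec()] (or its id string).
#' @param params Generating parameter vector (length `model$k`).
#' @param x Cofactor amounts.
#' @param reporter Reporter scale values (recycled; default 1).
#' @param cv Relative noise per simulated experiment.
#' @param n_experiments Number of simulated repeats.
#' @param seed RNG seed.
#' @return A `param_plot_dataset` with attribute `truth_params`.
#' @export
generate_param_plots <- function(model, params, x = c(0, 10, 30, 100),
                                 reporter = 1, cv = 0.05, n_experiments = 4,
                                 seed = 1) {
  if (is.character(model)) model <- model_spec(model)
  stopifnot(length(params) == model$k)
  set.seed(seed)
  r <- rep_len(reporter, length(x))
  dat0 <- list(x = x, r = r,
               y = matrix(1, length(x), 4), s = matrix(1, length(x), 4))
  # reuse the chi_squared prediction code path to get the mean curves
  p <- as.numeric(params)
  pred <- switch(model$id,
    predicted = cbind(p[5] * r * (p[1] + x) / (p[2] + x),
                      p[6] * r * (p[3] + x) / (p[4] + x),
                      p[7] * (p[2] + x) / (p[4] + x),
                      p[8] * (p[1] + x) / (p[3] + x)),
    permuted = cbind(p[5] * r * (p[1] + x) / (p[4] + x),
                     p[6] * r * (p[2] + x) / (p[3] + x),
                     p[7] * (p[3] + x) / (p[2] + x),
                     p[8] * (p[4] + x) / (p[1] + x)),
    unconstrained = cbind(p[9] * r * (p[1] + x) / (p[5] + x),
                          p[10] * r * (p[2] + x) / (p[6] + x),
                          p[11] * (p[3] + x) / (p[7] + x),
                          p[12] * (p[4] + x) / (p[8] + x)))
  params_names <- c("amax", "amin", "ic50", "ratio")
  out <- list()
  for (j in 1:4) {
    draws <- matrix(stats::rnorm(length(x) * n_experiments, 1, cv),
                    length(x), n_experiments) * pred[, j]
    mu <- rowMeans(draws)
    sem <- apply(draws, 1, stats::sd) / sqrt(n_experiments)
    out[[j]] <- data.frame(param = params_names[j], x = x, group = r,
                           value = mu, sem = sem, n = n_experiments)
  }
  ds <- do.call(rbind, out)
  class(ds) <- c("param_plot_dataset", "data.frame")
  attr(ds, "x_var") <- "cofactor"
  attr(ds, "truth_params") <- params
  attr(ds, "truth_model") <- model$id
  ds
}

#' Generate a synthetic Western-blot calibration table
#'
#' Optical density saturates with transfected plasmid:
#' `OD = m1 * p / (m2 + p)`, times log-normal noise.
#'
#' @param calibration List with `m1`, `m2` (`> 0`).
#' @param plasmid Plasmid amounts (ng).
#' @param cv Noise CV (0 for noiseless).
#' @param seed RNG seed.
#' @return Data frame with `plasmid_ng` and `od`.
#' @export
generate_western <- function(calibration = list(m1 = 10, m2 = 50),
                             plasmid = c(10, 25, 50, 100, 200),
                             cv = 0.05, seed = 1) {
  stopifnot(calibration$m1 > 0, calibration$m2 > 0)
  set.seed(seed)
  od <- calibration$m1 * plasmid / (calibration$m2 + plasmid)
  if (cv > 0) {
    sdlog <- sqrt(log(1 + cv^2))
    od <- od * exp(stats::rnorm(length(od), -sdlog^2 / 2, sdlog))
  }
  data.frame(plasmid_ng = plasmid, od = od)
}

#' Instantiate the numeric reaction chain of a ground truth
#'
#' Builds the concrete [reaction_chain()] and decelerator list of the
#' configuration's scaffold at given reporter, cofactor and steroid
#' amounts — the bridge between the symbolic forms and the brute-force
#' equilibrium oracle.
#'
#' @param truth A [ground_truth()].
#' @param reporter,cofactor,steroid Scalar amounts (cofactor is the total).
#' @return List with `chain` and `decels`.
#' @export
truth_chain <- function(truth, reporter, cofactor, steroid) {
  sc <- truth$tu$scaffold
  env <- truth$params
  env$R <- reporter * truth$cls_scale
  env$X <- if (identical(truth$cls_var, "X")) cofactor * truth$cls_scale else cofactor
  gr_conc <- env$G * steroid / (env$K + steroid)
  env[[sc$gr_var]] <- gr_conc
  ev <- function(p) if (is.numeric(p)) p else kp_eval(p, env)[1]
  steps <- lapply(sc$chain$steps, function(s) reaction_step(ev(s$q), ev(s$X_total)))
  w <- vapply(sc$chain$activity_weights, ev, numeric(1))
  chain <- reaction_chain(steps, sc$chain$cls_index, inducer_conc = env$Y0,
                          activity_weights = w)
  decels <- list()
  for (d in sc$decels) {
    conc <- ev(d$conc)
    alpha <- ev(d$alpha); beta <- ev(d$beta); gamma <- ev(d$gamma)
    if (alpha == 0 && gamma == 0) next
    decels[[length(decels) + 1L]] <-
      decelerator_spec(d$step, conc, ev(d$q_prime), alpha, min(beta, 1), gamma)
  }
  list(chain = chain, decels = decels)
}
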