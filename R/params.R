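#' Exposure condition
#'
#' Describes how extracellular H2O2 is delivered. A `bolus` is a single acute
#' addition that the cell population clears within a couple of hours; dose is
#' in uM-equivalents and the initial intracellular concentration equals the
#' dose label. `continuous` models enzymatic production (glucose oxidase);
#' dose is in mU/mL and is converted to a constant intracellular production
#' rate by `k_gox` (see [kinetic_params()]). `none` is the untreated control.
#'
#' @param mode One of `"bolus"`, `"continuous"`, `"none"`.
#' @param dose Non-negative scalar. uM-equivalent for bolus, mU/mL for
#'   continuous. Must be 0 when `mode = "none"`.
#' @param treatment_start Hours after movie start at which treatment is added.
#' @return An object of class `exposure_condition`.
#' @export
#' @examples
#' exposure_condition("bolus", 100)
#' exposure_condition("none")
exposure_condition <- function(mode = c("bolus", "continuous", "none"),
                               dose = 0, treatment_start = 0) {
  mode <- match.arg(mode)
  if (!is.numeric(dose) || length(dose) != 1L || is.na(dose) || dose < 0) {
    stop("invalid condition: `dose` must be a single non-negative number",
         call. = FALSE)
  }
  if (mode == "none" && dose != 0) {
    stop("invalid condition: mode 'none' requires dose = 0", call. = FALSE)
  }
  if (!is.numeric(treatment_start) || treatment_start < 0) {
    stop("invalid condition: `treatment_start` must be >= 0", call. = FALSE)
  }
  structure(list(mode = mode, dose = dose,
                 treatment_start = treatment_start),
            class = "exposure_condition")
}

#' @export
print.exposure_condition <- function(x, ...) {
  unit <- switch(x$mode, bolus = "uM-equivalent", continuous = "mU/mL", "")
  cat(sprintf("<exposure_condition> mode=%s dose=%g %s (t0=%g h)\n",
              x$mode, x$dose, unit, x$treatment_start))
  invisible(x)
}

#' Perturbation mode
#'
#' Genetic/chemical perturbations of the peroxiredoxin--sulfiredoxin system.
#' `srxn1_multiplier` scales the SRXN1 repair rate (`k_srx`): overexpression
#' uses a value > 1, the J14 inhibitor sets it to 0. `prdx_capacity_multiplier`
#' in (0, 1] models loss of peroxiredoxin protein (knockout/knockdown); it
#' scales both H2O2 scavenging (`k_clear`) and the hyperoxidized-fraction
#' threshold `theta_F` downward, since less PRDX means less scavenging and a
#' smaller buffer that must be hyperoxidized before the relay collapses.
#'
#' @param label One of `"control"`, `"srxn1_oe"`, `"srxn1_inhibited"`,
#'   `"prdx1_ko"`, `"prdx2_kd"`, `"prdx_inhibited"`.
#' @param srxn1_multiplier Non-negative scalar; default depends on label.
#' @param prdx_capacity_multiplier Scalar in (0, 1]; default depends on label.
#' @return An object of class `perturbation_mode`.
#' @export
perturbation_mode <- function(label = c("control", "srxn1_oe",
                                        "srxn1_inhibited", "prdx1_ko",
                                        "prdx2_kd", "prdx_inhibited"),
                              srxn1_multiplier = NULL,
                              prdx_capacity_multiplier = NULL) {
  label <- match.arg(label)
  defaults <- list(
    control         = c(srx = 1, cap = 1),
    srxn1_oe        = c(srx = 4, cap = 1),
    srxn1_inhibited = c(srx = 0, cap = 1),
    prdx1_ko        = c(srx = 1, cap = 0.6),
    prdx2_kd        = c(srx = 1, cap = 0.8),
    prdx_inhibited  = c(srx = 1, cap = 0.5)
  )[[label]]
  if (is.null(srxn1_multiplier)) srxn1_multiplier <- defaults[["srx"]]
  if (is.null(prdx_capacity_multiplier)) {
    prdx_capacity_multiplier <- defaults[["cap"]]
  }
  if (!is.numeric(srxn1_multiplier) || srxn1_multiplier < 0) {
    stop("`srxn1_multiplier` must be >= 0", call. = FALSE)
  }
  if (!is.numeric(prdx_capacity_multiplier) ||
      prdx_capacity_multiplier <= 0 || prdx_capacity_multiplier > 1) {
    stop("`prdx_capacity_multiplier` must be in (0, 1]", call. = FALSE)
  }
  if (label == "control" &&
      (srxn1_multiplier != 1 || prdx_capacity_multiplier != 1)) {
    stop("control perturbation requires both multipliers = 1", call. = FALSE)
  }
  if (label == "srxn1_inhibited" && srxn1_multiplier != 0) {
    stop("srxn1_inhibited requires srxn1_multiplier = 0", call. = FALSE)
  }
  structure(list(label = label,
                 srxn1_multiplier = srxn1_multiplier,
                 prdx_capacity_multiplier = prdx_capacity_multiplier),
            class = "perturbation_mode")
}

#' @export
print.perturbation_mode <- function(x, ...) {
  cat(sprintf("<perturbation_mode> %s (srxn1 x%g, prdx capacity x%g)\n",
              x$label, x$srxn1_multiplier, x$prdx_capacity_multiplier))
  invisible(x)
}

#' Kinetic parameters of the redox/TF/death model
#'
#' Full parameterization of the mechanistic model. Intracellular H2O2 (`H`,
#' uM-equivalents) is cleared at first order (`k_clear`). The hyperoxidized
#' peroxiredoxin fraction `P` follows mass-action hyperoxidation
#' (`k_hyp * H * (1 - P)`) against first-order SRXN1 repair (`k_srx * P`).
#' While `P > theta_F` the redox relay is collapsed: FOXO1 relaxes toward its
#' nuclear plateau `f_max` with time constant `tau_f`, p53 accumulation is
#' frozen, and damage repair is suspended; otherwise FOXO1 relaxes back
#' toward `f_min`. Oxidative damage integrates as
#' `dD/dt = k_dmg * H - k_rep * D * 1(P < theta_F)` and drives both p53
#' (drive `u = D * 1(P < theta_F) + k_srx * P`, active above `theta_p`, with
#' induction dead time `tau_act`) and death through the hazard
#' `lambda_0 + lambda_d * max(0, D - D_c)`. p53 follows a delayed-negative-feedback
#' p53/MDM2 oscillator (`beta_p`, `alpha_p`, `gamma_m`, `delta_m`,
#' `tau_delay`) whose default period is about 5.5 h.
#'
#' Defaults are the shipped calibrated set: the death submodel
#' (`lambda_d`, `D_c`, `k_dmg`, `cv_cell`) was fitted against the six printed
#' death fractions (bolus 50/80/100/300 uM and continuous 0.5/2 mU/mL) and
#' the entry/exit-to-onset timing constraints; see the methods vignette.
#'
#' @param k_clear /h, intracellular H2O2 clearance.
#' @param k_hyp /(uM h), hyperoxidation rate constant.
#' @param k_srx /h, SRXN1 repair rate of hyperoxidized PRDX.
#' @param theta_F fraction in (0,1): hyperoxidized-PRDX threshold above which
#'   the FOXO1 group activates and p53 accumulation is blocked.
#' @param theta_p damage-drive threshold for p53-group activation.
#' @param k_dmg damage accrual per uM H2O2 per hour.
#' @param k_dmg_P damage accrual per hour while the PRDX buffer is
#'   hyperoxidized (`P > theta_F`): loss of the scavenging relay lets
#'   endogenous oxidative damage accrue even after exogenous H2O2 is gone.
#' @param k_rep /h, damage repair rate (active only while `P < theta_F`).
#' @param tau_f h, FOXO1 nucleocytoplasmic relaxation time.
#' @param tau_act h, dead time between relay reactivation/damage signaling and
#'   p53 stabilization (sets the exit-to-onset lag).
#' @param beta_p p53 production at full drive (scaled units/h).
#' @param alpha_p /(MDM2 h), MDM2-dependent p53 degradation.
#' @param gamma_m /h, p53-dependent MDM2 production (acts with delay
#'   `tau_delay` through a Hill function of order `hill_m` with midpoint
#'   `K_m`; the nonlinearity is what sustains the limit cycle).
#' @param delta_m /h, MDM2 turnover.
#' @param tau_delay h, transcriptional delay in MDM2 induction.
#' @param K_m Hill midpoint of delayed MDM2 induction (model p53 units).
#' @param hill_m Hill coefficient of MDM2 induction.
#' @param m_basal basal fractional MDM2 production.
#' @param p_basal basal fractional p53 drive (sets the unstressed baseline).
#' @param f_min,f_max bounds of the FOXO1 nuclear fraction.
#' @param lambda_d /h per unit excess damage: death hazard coefficient.
#' @param lambda_0 /h baseline hazard (treatment-independent background
#'   death, about 1% per 24 h at the default).
#' @param D_c damage threshold of the death hazard.
#' @param cv_cell lognormal coefficient of variation of per-cell multipliers
#'   applied to `k_hyp`, `k_clear`, `theta_F` and `D_c`.
#' @param sigma_meas SD of multiplicative (lognormal) measurement noise
#'   applied to both channels.
#' @param k_gox uM-equivalent/h of intracellular production per mU/mL of
#'   glucose oxidase (continuous-mode dose conversion).
#' @param gox_dip fractional dip of continuous production after the first
#'   hour (0 disables; production is `k_gox * dose * (1 - gox_dip)` for
#'   t > 1 h after treatment).
#' @param p53_scale output scale: reported p53 is `p53_scale` times the model
#'   state (arbitrary units).
#' @param density_coupling per-cell-plated dose attenuation constant `c` in
#'   `dose_eff = dose / (1 + c * n_plated)`; 0 disables.
#' @param n_plated number of cells plated (only used when
#'   `density_coupling > 0`).
#' @return An object of class `kinetic_params` (a validated named list).
#' @export
kinetic_params <- function(k_clear = 2.3,
                           k_hyp = 0.0262,
                           k_srx = 0.036,
                           theta_F = 0.555,
                           theta_p = 0.06,
                           k_dmg = 0.01,
                           k_dmg_P = 0.775,
                           k_rep = 0.1,
                           tau_f = 0.2,
                           tau_act = 1.2,
                           beta_p = 4,
                           alpha_p = 2,
                           gamma_m = 3,
                           delta_m = 1,
                           tau_delay = 1.8,
                           K_m = 1.2,
                           hill_m = 4,
                           m_basal = 0.1,
                           p_basal = 0.05,
                           f_min = 0.1,
                           f_max = 0.9,
                           lambda_d = 0.44,
                           lambda_0 = 4.2e-4,
                           D_c = 5.45,
                           cv_cell = 0.17,
                           sigma_meas = 0.05,
                           k_gox = 11.2,
                           gox_dip = 0,
                           p53_scale = 100,
                           density_coupling = 0,
                           n_plated = 0) {
  p <- as.list(environment())
  rates <- c("k_clear", "k_hyp", "k_srx", "theta_p", "k_dmg", "k_dmg_P",
             "k_rep", "tau_f", "tau_act", "beta_p", "alpha_p", "gamma_m",
             "delta_m", "tau_delay", "K_m", "hill_m", "m_basal", "p_basal",
             "lambda_d", "lambda_0", "D_c", "cv_cell", "sigma_meas",
             "k_gox", "p53_scale", "density_coupling", "n_plated")
  for (nm in rates) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      stop(sprintf("parameter `%s` must be a single non-negative number", nm),
           call. = FALSE)
    }
  }
  if (p$theta_F <= 0 || p$theta_F >= 1) {
    stop("`theta_F` must be in (0, 1)", call. = FALSE)
  }
  if (!(p$f_min >= 0 && p$f_min < p$f_max && p$f_max <= 1)) {
    stop("need 0 <= f_min < f_max <= 1", call. = FALSE)
  }
  if (p$gox_dip < 0 || p$gox_dip >= 1) {
    stop("`gox_dip` must be in [0, 1)", call. = FALSE)
  }
  if (p$tau_f <= 0) stop("`tau_f` must be > 0", call. = FALSE)
  structure(p, class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("<kinetic_params>\n")
  nm <- names(x)
  for (i in seq_along(x)) cat(sprintf("  %-16s %g\n", nm[i], x[[i]]))
  invisible(x)
}

#' Simulation configuration
#'
#' Bundles an exposure condition, perturbation, kinetic parameters, population
#' size, time grid and seed into a fully reproducible simulation description.
#' Identical configurations (including the seed) produce bitwise-identical
#' outputs.
#'
#' @param condition An [exposure_condition()].
#' @param perturbation A [perturbation_mode()].
#' @param params A [kinetic_params()] set.
#' @param n_cells Positive integer, population size.
#' @param t_end Hours of observation (default 24).
#' @param dt_sample Sampling interval in hours (default 1/3, i.e. 20 min);
#'   `t_end / dt_sample` must be an integer number of frames.
#' @param seed Integer RNG root seed; per-cell streams are derived from
#'   `(seed, cell_index)` so populations are order-independent.
#' @return An object of class `simulation_config`.
#' @export
#' @examples
#' cfg <- simulation_config(exposure_condition("bolus", 100), n_cells = 10)
simulation_config <- function(condition = exposure_condition("none"),
                              perturbation = perturbation_mode("control"),
                              params = kinetic_params(),
                              n_cells = 100,
                              t_end = 24,
                              dt_sample = 1 / 3,
                              seed = 1L) {
  stopifnot(inherits(condition, "exposure_condition"),
            inherits(perturbation, "perturbation_mode"),
            inherits(params, "kinetic_params"))
  if (!is.numeric(n_cells) || n_cells < 1 || n_cells != round(n_cells)) {
    stop("`n_cells` must be a positive integer", call. = FALSE)
  }
  if (t_end <= 0 || dt_sample <= 0) {
    stop("`t_end` and `dt_sample` must be positive", call. = FALSE)
  }
  n_frames <- t_end / dt_sample
  if (abs(n_frames - round(n_frames)) > 1e-9) {
    stop("`t_end / dt_sample` must be an integer frame count", call. = FALSE)
  }
  if (!is.numeric(seed) || seed != round(seed)) {
    stop("`seed` must be an integer", call. = FALSE)
  }
  structure(list(condition = condition, perturbation = perturbation,
                 params = params, n_cells = as.integer(n_cells),
                 t_end = t_end, dt_sample = dt_sample,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf("<simulation_config> %d cells, %g h @ %g h sampling, seed %d\n",
              x$n_cells, x$t_end, x$dt_sample, x$seed))
  print(x$condition)
  print(x$perturbation)
  invisible(x)
}
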