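# Two-compartment PK simulator with an intermittent extracorporeal clearance
# acting on the unbound central concentration; synthetic stand-in for the
# animal dialysis experiments.

#' Two-compartment simulator parameters
#'
#' Linear two-compartment disposition with a constant-rate infusion and an
#' extracorporeal (dialyzer) clearance switched on only inside dialysis
#' windows. Both the dialyzer and any nonrenal clearance act on the unbound
#' central concentration `fu * C1`; renal clearance is fixed at zero, the
#' anephric condition the animal model creates by bilateral nephrectomy.
#' `v_peripheral = 0` degenerates to a one-compartment model.
#'
#' @param v_central central volume, L; > 0.
#' @param v_peripheral peripheral volume, L; >= 0 (0 = one-compartment).
#' @param q_intercompartmental distribution clearance between the
#'   compartments, L/h; >= 0.
#' @param fu unbound fraction in plasma, in (0, 1].
#' @param cl_dialyzer dialyzer clearance, L/h, applied only inside
#'   `dialysis_windows`.
#' @param cl_nonrenal nonrenal (e.g. hepatic) clearance, L/h; default 0 so
#'   that mass balance closes on the dialysate alone.
#' @param infusion_rate drug input rate, mg/h.
#' @param infusion_start start of the infusion, h.
#' @param infusion_duration length of the infusion, h.
#' @param dialysis_windows two-column matrix (or list of length-2 vectors)
#'   of `(start, end)` hours; windows must be increasing and non-overlapping.
#' @return an object of class `two_compartment_params`.
#' @export
#' @examples
#' two_compartment_params(v_central = 0.2, v_peripheral = 0.4,
#'                        q_intercompartmental = 0.05, fu = 0.65,
#'                        cl_dialyzer = 0.06, infusion_rate = 6.6,
#'                        infusion_duration = 1,
#'                        dialysis_windows = rbind(c(1, 3)))
two_compartment_params <- function(v_central, v_peripheral = 0,
                                   q_intercompartmental = 0, fu = 1,
                                   cl_dialyzer = 0, cl_nonrenal = 0,
                                   infusion_rate = 0, infusion_start = 0,
                                   infusion_duration = 0,
                                   dialysis_windows = NULL) {
  if (is.list(dialysis_windows)) {
    dialysis_windows <- do.call(rbind, dialysis_windows)
  }
  if (is.null(dialysis_windows)) {
    dialysis_windows <- matrix(numeric(0), ncol = 2)
  }
  dialysis_windows <- matrix(as.numeric(dialysis_windows), ncol = 2)
  stopifnot(
    is.numeric(v_central), length(v_central) == 1L, v_central > 0,
    is.numeric(v_peripheral), length(v_peripheral) == 1L, v_peripheral >= 0,
    is.numeric(q_intercompartmental), q_intercompartmental >= 0,
    is.numeric(fu), fu > 0, fu <= 1,
    is.numeric(cl_dialyzer), cl_dialyzer >= 0,
    is.numeric(cl_nonrenal), cl_nonrenal >= 0,
    is.numeric(infusion_rate), infusion_rate >= 0,
    is.numeric(infusion_start), infusion_start >= 0,
    is.numeric(infusion_duration), infusion_duration >= 0
  )
  if (v_peripheral > 0 && q_intercompartmental <= 0) {
    stop("a peripheral compartment needs `q_intercompartmental` > 0", call. = FALSE)
  }
  if (nrow(dialysis_windows)) {
    if (any(dialysis_windows[, 2] <= dialysis_windows[, 1])) {
      stop("each dialysis window must have end > start", call. = FALSE)
    }
    if (nrow(dialysis_windows) > 1L) {
      o <- order(dialysis_windows[, 1])
      dialysis_windows <- dialysis_windows[o, , drop = FALSE]
      if (any(dialysis_windows[-1L, 1] < dialysis_windows[-nrow(dialysis_windows), 2])) {
        stop("dialysis windows must be non-overlapping", call. = FALSE)
      }
    }
  }
  structure(
    list(v_central = v_central, v_peripheral = v_peripheral,
         q_intercompartmental = q_intercompartmental, fu = fu,
         cl_dialyzer = cl_dialyzer, cl_nonrenal = cl_nonrenal,
         infusion_rate = infusion_rate, infusion_start = infusion_start,
         infusion_duration = infusion_duration,
         dialysis_windows = dialysis_windows),
    class = "two_compartment_params"
  )
}

# piecewise-constant right-hand side; within a segment rate and cl_hd are fixed
.pk_rhs <- function(t, state, parms) {
  c1 <- state[1L] / parms$vc
  c2 <- if (parms$vp > 0) state[2L] / parms$vp else 0
  flux <- parms$q * (c1 - c2)
  elim_hd <- parms$cl_hd * parms$fu * c1
  elim_nr <- parms$cl_nr * parms$fu * c1
  dA1 <- parms$rate - (if (parms$vp > 0) flux else 0) - elim_hd - elim_nr
  dA2 <- if (parms$vp > 0) flux else 0
  list(c(dA1, dA2, elim_hd, elim_nr))
}

#' Simulate a dialysis study on the two-compartment model
#'
#' Integrates the amounts in the central and peripheral compartments plus the
#' cumulative drug mass eliminated into dialysate and by nonrenal routes:
#' \deqn{dC_1/dt = [rate(t) - Q(C_1 - C_2) - (CL_{HD}(t) + CL_{nr}) f_u C_1]/V_c}
#' \deqn{dC_2/dt = Q(C_1 - C_2)/V_p}
#' with \eqn{CL_{HD}(t)} equal to `cl_dialyzer` inside dialysis windows and 0
#' outside. Integration is piecewise over segments bounded by the infusion
#' start/stop and window edges, so the clearance discontinuity is never
#' smeared across a step; each segment uses an adaptive stiff-capable solver
#' (`deSolve::lsoda`) at tight tolerances.
#'
#' @param params a [two_compartment_params].
#' @param grid strictly increasing output times, h; must span the infusion
#'   and every dialysis window.
#' @param rtol,atol solver tolerances.
#' @return an object of class `simulated_study`: a list with `times`
#'   (the supplied grid augmented with segment boundaries), `c_central`,
#'   `c_peripheral` (mg/L), `amount_central`, `amount_peripheral`,
#'   `cumulative_dialysate_mass`, `cumulative_nonrenal_mass`,
#'   `dose_administered` (mg infused by each time), `dose` (total),
#'   `removal_percent_true`, and the `params`.
#' @export
simulate_hd_study <- function(params, grid, rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(params, "two_compartment_params"))
  grid <- as.numeric(grid)
  if (length(grid) < 2L || any(diff(grid) <= 0)) {
    stop("`grid` must be strictly increasing with >= 2 points", call. = FALSE)
  }
  inf_end <- params$infusion_start + params$infusion_duration
  needed_end <- max(inf_end, if (nrow(params$dialysis_windows))
    max(params$dialysis_windows) else -Inf)
  if (params$infusion_rate > 0 || nrow(params$dialysis_windows)) {
    if (min(grid) > params$infusion_start || max(grid) < needed_end) {
      stop("`grid` must cover the infusion and all dialysis windows", call. = FALSE)
    }
  }
  out <- .integrate_piecewise(params, grid, init = c(A1 = 0, A2 = 0, Ad = 0, Ae = 0),
                              rtol = rtol, atol = atol)
  dose_admin <- params$infusion_rate *
    pmin(pmax(out$t - params$infusion_start, 0), params$infusion_duration)
  dose <- params$infusion_rate * params$infusion_duration
  .as_study(params, out, dose_admin, dose)
}

# shared piecewise integrator: splits [min(grid), max(grid)] at the infusion
# edges and every window edge, holding rate and cl_hd constant per segment
.integrate_piecewise <- function(params, grid, init, rtol, atol, bolus = FALSE) {
  inf_end <- params$infusion_start + params$infusion_duration
  bounds <- c(if (!bolus) c(params$infusion_start, inf_end),
              as.numeric(params$dialysis_windows))
  bounds <- bounds[bounds > min(grid) & bounds < max(grid)]
  times <- sort(unique(c(grid, bounds)))
  in_window <- function(t) {
    w <- params$dialysis_windows
    nrow(w) && any(t >= w[, 1] & t < w[, 2])
  }
  seg_edges <- sort(unique(c(min(times), max(times), bounds)))
  state <- init
  out_t <- times[1L]
  out_s <- matrix(state, nrow = 1L)
  for (i in seq_len(length(seg_edges) - 1L)) {
    t0 <- seg_edges[i]; t1 <- seg_edges[i + 1L]
    mid <- (t0 + t1) / 2
    parms <- list(
      vc = params$v_central, vp = params$v_peripheral,
      q = params$q_intercompartmental, fu = params$fu,
      cl_nr = params$cl_nonrenal,
      cl_hd = if (in_window(mid)) params$cl_dialyzer else 0,
      rate = if (!bolus && mid >= params$infusion_start && mid < inf_end)
        params$infusion_rate else 0
    )
    seg_times <- sort(unique(c(t0, times[times > t0 & times <= t1], t1)))
    sol <- deSolve::lsoda(y = state, times = seg_times, func = .pk_rhs,
                          parms = parms, rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1L] < 0) {
      stop("ODE integration failed on segment [", t0, ", ", t1, "]", call. = FALSE)
    }
    state <- sol[nrow(sol), -1L]
    keep <- sol[-1L, , drop = FALSE]
    out_t <- c(out_t, keep[, 1L])
    out_s <- rbind(out_s, keep[, -1L, drop = FALSE])
  }
  list(t = out_t, s = out_s)
}

.as_study <- function(params, out, dose_admin, dose) {
  n <- length(out$t)
  removal <- if (dose > 0) unname(100 * out$s[n, 3L] / dose) else NA_real_
  structure(
    list(times = out$t,
         c_central = out$s[, 1L] / params$v_central,
         c_peripheral = if (params$v_peripheral > 0)
           out$s[, 2L] / params$v_peripheral else rep(0, n),
         amount_central = out$s[, 1L],
         amount_peripheral = out$s[, 2L],
         cumulative_dialysate_mass = out$s[, 3L],
         cumulative_nonrenal_mass = out$s[, 4L],
         dose_administered = dose_admin, dose = dose,
         removal_percent_true = removal,
         params = params),
    class = "simulated_study"
  )
}

#' Bolus variant of the simulator
#'
#' Places `dose` mg in the central compartment at the first grid time
#' instead of infusing it, then integrates the same piecewise system as
#' [simulate_hd_study]. Used for closed-form checks where the bolus solution
#' is analytic.
#'
#' @param params a [two_compartment_params] (its infusion fields are ignored).
#' @param dose bolus dose, mg.
#' @inheritParams simulate_hd_study
#' @return a `simulated_study`; `removal_percent_true` is relative to `dose`.
#' @export
simulate_hd_bolus <- function(params, dose, grid, rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(params, "two_compartment_params"), dose > 0)
  grid <- as.numeric(grid)
  if (length(grid) < 2L || any(diff(grid) <= 0)) {
    stop("`grid` must be strictly increasing with >= 2 points", call. = FALSE)
  }
  p <- params
  p$infusion_rate <- 0; p$infusion_duration <- 0
  out <- .integrate_piecewise(p, grid, init = c(A1 = dose, A2 = 0, Ad = 0, Ae = 0),
                              rtol = rtol, atol = atol, bolus = TRUE)
  .as_study(p, out, dose_admin = rep(dose, length(out$t)), dose = dose)
}

#' Mass-balance error of a simulated study
#'
#' Relative deviation of (body amount + cumulative dialysate + cumulative
#' nonrenal elimination) from the dose administered so far, at every output
#' time. Near-zero early denominators (before any drug is given) are skipped.
#'
#' @param study a `simulated_study`.
#' @return vector of relative errors, one per reported time with nonzero
#'   administered dose.
#' @export
mass_balance_error <- function(study) {
  stopifnot(inherits(study, "simulated_study"))
  total <- study$amount_central + study$amount_peripheral +
    study$cumulative_dialysate_mass + study$cumulative_nonrenal_mass
  keep <- study$dose_administered > 0
  abs(total[keep] - study$dose_administered[keep]) / study$dose_administered[keep]
}

#' Convert a simulated study into a dialysate recovery measurement
#'
#' The dialysate volume is `flow * duration` and the pooled dialysate
#' concentration is the cumulative simulated drug mass divided by that
#' volume, so the resulting [drug_removal_rate] equals the simulator's
#' `removal_percent_true` by construction.
#'
#' @param study a `simulated_study` with a positive dose.
#' @param dialysate_flow dialysate flow, mL/min; > 0.
#' @param duration recovered-session length, h; must not exceed the total
#'   simulated window time.
#' @return a [removal_measurement].
#' @export
sample_dialysate <- function(study, dialysate_flow = 5, duration = 2) {
  stopifnot(inherits(study, "simulated_study"))
  if (dialysate_flow <= 0) stop("`dialysate_flow` must be positive", call. = FALSE)
  w <- study$params$dialysis_windows
  total_window <- if (nrow(w)) sum(w[, 2] - w[, 1]) else 0
  if (duration > total_window + 1e-9) {
    stop("`duration` (", duration, " h) exceeds the simulated dialysis time (",
         total_window, " h)", call. = FALSE)
  }
  volume_ml <- dialysate_flow * duration * 60
  mass <- study$cumulative_dialysate_mass[length(study$cumulative_dialysate_mass)]
  removal_measurement(
    dialysate_concentration = mass / volume_ml,
    dialysate_volume = volume_ml,
    dose = study$dose,
    session_duration = duration
  )
}

#' Generate a noisy multi-subject cohort
#'
#' Simulates `n_subjects` animals from one parameter set with lognormal
#' inter-subject variability on the disposition parameters (`v_central`,
#' `v_peripheral`, `q_intercompartmental`, `cl_dialyzer`) and lognormal
#' multiplicative measurement noise on the sampled concentrations. All
#' randomness flows from the single `seed`; subject-level draws are taken
#' sequentially from that one generator, so the cohort is reproducible
#' byte-for-byte.
#'
#' @param params a [two_compartment_params] describing the typical subject.
#' @param grid sampling times, h.
#' @param n_subjects number of animals; >= 1.
#' @param noise_cv coefficient of variation of the measurement noise
#'   (0 = noiseless).
#' @param param_cv coefficient of variation of inter-subject parameter
#'   variability (default 0.15, a typical small-animal PK spread).
#' @param seed integer seed.
#' @param dialysate_flow dialysate flow for the recovery measurement, mL/min.
#' @return a list of class `hd_cohort`; per subject a list with `series`
#'   (a [conc_time_series]), `removal` (a [removal_measurement]), the true
#'   `removal_percent_true` and the perturbed `params`.
#' @export
generate_cohort <- function(params, grid, n_subjects = 6, noise_cv = 0.1,
                            param_cv = 0.15, seed = 1, dialysate_flow = 5) {
  stopifnot(inherits(params, "two_compartment_params"),
            n_subjects >= 1, noise_cv >= 0, param_cv >= 0)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  # lognormal with unit median: exp(N(0, sdlog)), sdlog = sqrt(log(1 + cv^2))
  sdlog_p <- sqrt(log(1 + param_cv^2))
  sdlog_e <- sqrt(log(1 + noise_cv^2))
  w <- params$dialysis_windows
  total_window <- if (nrow(w)) sum(w[, 2] - w[, 1]) else 0

  subjects <- lapply(seq_len(n_subjects), function(i) {
    p <- params
    if (param_cv > 0) {
      p$v_central <- p$v_central * exp(rnorm(1, 0, sdlog_p))
      if (p$v_peripheral > 0)
        p$v_peripheral <- p$v_peripheral * exp(rnorm(1, 0, sdlog_p))
      if (p$q_intercompartmental > 0)
        p$q_intercompartmental <- p$q_intercompartmental * exp(rnorm(1, 0, sdlog_p))
      if (p$cl_dialyzer > 0)
        p$cl_dialyzer <- p$cl_dialyzer * exp(rnorm(1, 0, sdlog_p))
    }
    study <- simulate_hd_study(p, grid)
    idx <- match(grid, study$times)
    conc <- study$c_central[idx]
    if (noise_cv > 0) {
      conc <- conc * exp(rnorm(length(conc), 0, sdlog_e))
    }
    series <- conc_time_series(
      times = grid, concentrations = conc, dose = study$dose,
      infusion_duration = p$infusion_duration
    )
    removal <- if (total_window > 0 && study$dose > 0)
      sample_dialysate(study, dialysate_flow, total_window) else NULL
    list(series = series, removal = removal,
         removal_percent_true = study$removal_percent_true, params = p)
  })
  structure(list(subjects = subjects, seed = as.integer(seed),
                 noise_cv = noise_cv, param_cv = param_cv),
            class = "hd_cohort")
}

#' Typical rat study parameterization
#'
#' A realistic anephric-rat dialysis scenario usable as the simulator
#' default: a 0.66 kg rat, vancomycin-like disposition (central volume
#' 0.3 L/kg, peripheral 0.55 L/kg, unbound fraction 0.65), a 1-h constant
#' infusion of 10 mg/kg, and a single 2-h dialysis window starting at the
#' end of the infusion with a dialyzer clearance of about 0.83 mL/min scaled
#' by the unbound fraction at the membrane.
#'
#' @param body_weight_kg rat body weight, kg.
#' @return a [two_compartment_params].
#' @export
default_rat_params <- function(body_weight_kg = 0.66) {
  two_compartment_params(
    v_central = 0.30 * body_weight_kg,
    v_peripheral = 0.55 * body_weight_kg,
    q_intercompartmental = 0.06,
    fu = 0.65,
    cl_dialyzer = 0.83 / 1000 * 60,   # 0.83 mL/min in L/h
    cl_nonrenal = 0,
    infusion_rate = 10 * body_weight_kg,  # 10 mg/kg over 1 h
    infusion_start = 0,
    infusion_duration = 1,
    dialysis_windows = rbind(c(1, 3))
  )
}
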