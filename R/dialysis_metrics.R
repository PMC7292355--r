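# Closed-form dialysis quantities: dialyzer clearance, Daugirdas Kt/V,
# dialysate-recovery removal rate, first-order extrapolation, protein binding.

#' Dialyzer inlet/outlet sample
#'
#' Bundles one paired measurement across the dialyzer: the solute (or drug)
#' concentration entering the dialyzer, the concentration leaving it, the
#' blood flow, and the hematocrit. The outlet concentration is expected to be
#' already corrected for hemoconcentration/dilution across the dialyzer;
#' this constructor takes it at face value.
#'
#' @param c_inlet concentration at the dialyzer inlet (e.g. mg/dL); >= 0.
#' @param c_outlet concentration at the dialyzer outlet, same units; >= 0.
#' @param blood_flow blood flow Q_B through the circuit, mL/min; > 0.
#' @param hematocrit red-cell volume fraction of blood, in \[0, 1).
#'
#' @return an object of class `dialyzer_sample`.
#' @seealso [hd_clearance]
#' @export
#' @examples
#' dialyzer_sample(c_inlet = 111, c_outlet = 18, blood_flow = 1, hematocrit = 0.3)
dialyzer_sample <- function(c_inlet, c_outlet, blood_flow, hematocrit) {
  stopifnot(
    is.numeric(c_inlet), length(c_inlet) == 1L, is.finite(c_inlet), c_inlet >= 0,
    is.numeric(c_outlet), length(c_outlet) == 1L, is.finite(c_outlet), c_outlet >= 0,
    is.numeric(blood_flow), length(blood_flow) == 1L, is.finite(blood_flow), blood_flow > 0,
    is.numeric(hematocrit), length(hematocrit) == 1L, is.finite(hematocrit)
  )
  if (hematocrit < 0 || hematocrit >= 1) {
    stop("`hematocrit` must be a fraction in [0, 1), not a percent; got ",
         hematocrit, call. = FALSE)
  }
  structure(
    list(c_inlet = c_inlet, c_outlet = c_outlet,
         blood_flow = blood_flow, hematocrit = hematocrit),
    class = "dialyzer_sample"
  )
}

#' Dialyzer clearance from an arteriovenous concentration pair
#'
#' Clearance of a solute by the dialyzer, computed from the extraction across
#' it: `((Ca - Cv) / Ca) * Q_B * (1 - Hct)`, where `Ca` and `Cv` are inlet
#' and outlet concentrations, `Q_B` is blood flow and `Hct` hematocrit. The
#' `(1 - Hct)` factor converts blood flow to the plasma flow actually exposed
#' to the membrane. A negative result (outlet above inlet, possible with
#' sampling noise) is returned with a warning rather than an error.
#'
#' @param sample a [dialyzer_sample].
#' @return clearance in mL/min; never exceeds `blood_flow * (1 - hematocrit)`.
#' @export
#' @examples
#' # urea across a miniature dialyzer at unit blood flow
#' hd_clearance(dialyzer_sample(111, 18, blood_flow = 1, hematocrit = 0))
hd_clearance <- function(sample) {
  stopifnot(inherits(sample, "dialyzer_sample"))
  if (sample$c_inlet <= 0) {
    stop("extraction ratio undefined: inlet concentration is zero", call. = FALSE)
  }
  cl <- (sample$c_inlet - sample$c_outlet) / sample$c_inlet *
    sample$blood_flow * (1 - sample$hematocrit)
  if (cl < 0) {
    warning("outlet concentration exceeds inlet: negative measured clearance (",
            format(cl), " mL/min); likely sampling noise", call. = FALSE)
  }
  cl
}

#' Dialysis session record
#'
#' One dialysis run: pre/post blood urea nitrogen, session duration,
#' ultrafiltration volume and post-dialysis body weight. `ufv` and `bw` must
#' share a unit system (volume of 1 unit weighing 1 unit: L with kg, or mL
#' with g); the `unit_system` argument declares which, purely as a
#' consistency check on magnitudes the formula itself cannot see.
#'
#' A post-dialysis BUN above the pre-dialysis value is physiologically odd
#' but can occur (urea generation, access recirculation); it is flagged via
#' the returned `$flag`, not rejected.
#'
#' @param bun_pre pre-dialysis BUN, mg/dL; > 0.
#' @param bun_post post-dialysis BUN, mg/dL; > 0.
#' @param duration dialysis time Td, hours; >= 0.
#' @param ufv ultrafiltration volume, same unit system as `bw`; >= 0.
#' @param bw post-dialysis body weight; > 0.
#' @param unit_system `"L_kg"` or `"mL_g"`.
#' @return an object of class `dialysis_session`; `$flag` is `NA_character_`
#'   or a short description of an anomaly.
#' @seealso [ktv_daugirdas]
#' @export
dialysis_session <- function(bun_pre, bun_post, duration, ufv, bw,
                             unit_system = c("L_kg", "mL_g")) {
  unit_system <- match.arg(unit_system)
  stopifnot(
    is.numeric(bun_pre), length(bun_pre) == 1L, is.finite(bun_pre), bun_pre > 0,
    is.numeric(bun_post), length(bun_post) == 1L, is.finite(bun_post), bun_post > 0,
    is.numeric(duration), length(duration) == 1L, is.finite(duration), duration >= 0,
    is.numeric(ufv), length(ufv) == 1L, is.finite(ufv), ufv >= 0,
    is.numeric(bw), length(bw) == 1L, is.finite(bw), bw > 0
  )
  flag <- NA_character_
  if (bun_post > bun_pre) flag <- "bun_post > bun_pre"
  structure(
    list(bun_pre = bun_pre, bun_post = bun_post, duration = duration,
         ufv = ufv, bw = bw, unit_system = unit_system, flag = flag),
    class = "dialysis_session"
  )
}

#' Daugirdas second-generation Kt/V
#'
#' Single-pool dialysis dose from the pre/post BUN ratio `R`:
#' `Kt/V = -ln(R - 0.008 * Td) + (4 - 3.5 * R) * UFV / BW`.
#' The 0.008 coefficient is per hour, so `Td` must be in hours; `UFV` and
#' `BW` must share a unit system (enforced by [dialysis_session]).
#'
#' @param session a [dialysis_session].
#' @return dimensionless Kt/V; nonnegative whenever `R <= 1` and `UFV >= 0`.
#' @export
#' @examples
#' # clinical-scale session
#' ktv_daugirdas(dialysis_session(60, 18, duration = 4, ufv = 2, bw = 60))
#' # rat-scale session (mL with g)
#' ktv_daugirdas(dialysis_session(117, 106, duration = 2, ufv = 2.4, bw = 658.4,
#'                                unit_system = "mL_g"))
ktv_daugirdas <- function(session) {
  stopifnot(inherits(session, "dialysis_session"))
  r <- session$bun_post / session$bun_pre
  arg <- r - 0.008 * session$duration
  if (arg <= 0) {
    stop("Daugirdas log argument non-positive: R = ", format(r),
         ", Td = ", format(session$duration),
         " h gives R - 0.008*Td = ", format(arg), call. = FALSE)
  }
  -log(arg) + (4 - 3.5 * r) * session$ufv / session$bw
}

#' Dialysate recovery measurement
#'
#' The drug mass recovered in the total dialysate effluent of a session,
#' expressed through its concentration and recovered volume, together with
#' the administered dose.
#'
#' @param dialysate_concentration drug concentration in recovered dialysate, mg/mL; >= 0.
#' @param dialysate_volume recovered dialysate volume, mL; >= 0.
#' @param dose total administered dose, mg; > 0.
#' @param session_duration dialysis time, hours; >= 0.
#' @return an object of class `removal_measurement`.
#' @seealso [drug_removal_rate]
#' @export
removal_measurement <- function(dialysate_concentration, dialysate_volume,
                                dose, session_duration = 2) {
  stopifnot(
    is.numeric(dialysate_concentration), length(dialysate_concentration) == 1L,
    is.finite(dialysate_concentration), dialysate_concentration >= 0,
    is.numeric(dialysate_volume), length(dialysate_volume) == 1L,
    is.finite(dialysate_volume), dialysate_volume >= 0,
    is.numeric(dose), length(dose) == 1L, is.finite(dose),
    is.numeric(session_duration), length(session_duration) == 1L,
    is.finite(session_duration), session_duration >= 0
  )
  if (dose <= 0) stop("`dose` must be positive", call. = FALSE)
  structure(
    list(dialysate_concentration = dialysate_concentration,
         dialysate_volume = dialysate_volume,
         dose = dose, session_duration = session_duration),
    class = "removal_measurement"
  )
}

#' Drug removal rate from dialysate recovery
#'
#' Percent of the administered dose recovered in the dialysate:
#' `100 * concentration * volume / dose`. A value above 100 means more drug
#' was recovered than given and is rejected as a mass-balance violation.
#'
#' @param m a [removal_measurement].
#' @return removal rate in percent, in \[0, 100\].
#' @export
#' @examples
#' drug_removal_rate(removal_measurement(0.01, 600, dose = 30))  # 20 %
drug_removal_rate <- function(m) {
  stopifnot(inherits(m, "removal_measurement"))
  rate <- 100 * m$dialysate_concentration * m$dialysate_volume / m$dose
  if (rate > 100) {
    stop("mass-balance violation: recovered ",
         format(m$dialysate_concentration * m$dialysate_volume),
         " mg exceeds the administered dose of ", format(m$dose), " mg",
         call. = FALSE)
  }
  rate
}

#' First-order extrapolation of a removal rate to another session length
#'
#' Under first-order kinetics the fraction remaining after time `t` is
#' `(1 - R)^(t / t_measured)` where `R` is the measured removed fraction, so
#' the removal at `t_target` is
#' `100 * (1 - (1 - rate/100)^(t_target / t_measured))`.
#' The function is monotone nondecreasing and concave in `t_target` and
#' reproduces the measured rate at `t_target = t_measured`. The canonical use
#' is converting a 2-hour rat session to the 4-hour clinical session length.
#'
#' It can be applied either to a group mean removal rate or per subject with
#' the results averaged; the two differ slightly because the transform is
#' nonlinear.
#'
#' @param rate_measured removal rate in percent over `t_measured`; in \[0, 100).
#' @param t_measured duration of the measured session, hours; > 0.
#' @param t_target duration to extrapolate to, hours; >= 0.
#' @return extrapolated removal rate in percent.
#' @export
#' @examples
#' extrapolate_removal(17.8, 2, 4)   # 2-h vancomycin removal carried to 4 h
extrapolate_removal <- function(rate_measured, t_measured = 2, t_target = 4) {
  stopifnot(
    is.numeric(rate_measured), length(rate_measured) == 1L, is.finite(rate_measured),
    is.numeric(t_measured), length(t_measured) == 1L, is.finite(t_measured),
    t_measured > 0,
    is.numeric(t_target), length(t_target) == 1L, is.finite(t_target),
    t_target >= 0
  )
  if (rate_measured < 0 || rate_measured >= 100) {
    stop("`rate_measured` must lie in [0, 100) percent; got ",
         format(rate_measured),
         if (rate_measured == 100) " (complete removal cannot be carried backwards)",
         call. = FALSE)
  }
  # -expm1(k*log1p(-f)) form of 1-(1-f)^k, accurate for small fractions
  -100 * expm1(t_target / t_measured * log1p(-rate_measured / 100))
}

#' Ultrafiltration pair for protein binding
#'
#' Serum drug concentration before ultrafiltration and the concentration in
#' the ultrafiltrate (the free, unbound drug), in the same units.
#'
#' @param c_total serum concentration before ultrafiltration; > 0.
#' @param c_filtrate ultrafiltrate concentration; in \[0, c_total\].
#' @return an object of class `ultrafiltration_pair`.
#' @seealso [protein_binding_rate]
#' @export
ultrafiltration_pair <- function(c_total, c_filtrate) {
  stopifnot(
    is.numeric(c_total), length(c_total) == 1L, is.finite(c_total),
    is.numeric(c_filtrate), length(c_filtrate) == 1L, is.finite(c_filtrate),
    c_filtrate >= 0
  )
  if (c_total <= 0) stop("`c_total` must be positive", call. = FALSE)
  structure(list(c_total = c_total, c_filtrate = c_filtrate),
            class = "ultrafiltration_pair")
}

#' Plasma protein binding rate from ultrafiltration
#'
#' Percent of drug bound to plasma protein, from total and ultrafiltrate
#' concentrations: `100 * (C_T - C_F) / C_T`. An ultrafiltrate concentration
#' above the total signals an assay or filtration artifact (e.g. membrane
#' adsorption calibration error) and is an error, not a clamp.
#'
#' @param u an [ultrafiltration_pair].
#' @return binding rate in percent, in \[0, 100\].
#' @export
#' @examples
#' protein_binding_rate(ultrafiltration_pair(100, 65))  # 35 %
protein_binding_rate <- function(u) {
  stopifnot(inherits(u, "ultrafiltration_pair"))
  if (u$c_filtrate > u$c_total) {
    stop("negative binding: ultrafiltrate concentration (",
         format(u$c_filtrate), ") exceeds total (", format(u$c_total),
         "); assay or filtration artifact", call. = FALSE)
  }
  100 * (u$c_total - u$c_filtrate) / u$c_total
}
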