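# Noncompartmental moment analysis: AUC, AUMC, MRT, CL, steady-state Vd.

#' Plasma concentration-time series
#'
#' A single subject's sampled plasma curve with its dosing context. At least
#' three points are required; times must be strictly increasing.
#'
#' @param times sampling times, hours; strictly increasing.
#' @param concentrations plasma concentrations, mg/L; same length, >= 0.
#' @param dose total administered dose, mg; > 0.
#' @param infusion_duration length of the constant-rate infusion, hours
#'   (0 for a bolus).
#' @param body_weight subject body weight, kg; used to express Vd per kg.
#' @return an object of class `conc_time_series`.
#' @export
conc_time_series <- function(times, concentrations, dose,
                             infusion_duration = 0, body_weight = 1) {
  stopifnot(
    is.numeric(times), is.numeric(concentrations),
    length(times) == length(concentrations),
    all(is.finite(times)), all(is.finite(concentrations)),
    is.numeric(dose), length(dose) == 1L, is.finite(dose), dose > 0,
    is.numeric(infusion_duration), length(infusion_duration) == 1L,
    infusion_duration >= 0,
    is.numeric(body_weight), length(body_weight) == 1L, body_weight > 0
  )
  if (length(times) < 3L) stop("need at least 3 sampling points", call. = FALSE)
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing", call. = FALSE)
  if (any(concentrations < 0)) stop("negative concentration", call. = FALSE)
  structure(
    list(times = as.numeric(times), concentrations = as.numeric(concentrations),
         dose = dose, infusion_duration = infusion_duration,
         body_weight = body_weight),
    class = "conc_time_series"
  )
}

# trapezoid moments over the observed grid; method "linear" or "log" for the
# down-slope segments (log only where both endpoints are positive and falling)
.trapezoid_moments <- function(t, c, method = "linear") {
  dt <- diff(t)
  c1 <- c[-length(c)]; c2 <- c[-1L]
  auc_seg <- (c1 + c2) / 2 * dt
  aumc_seg <- (t[-length(t)] * c1 + t[-1L] * c2) / 2 * dt
  if (method == "log") {
    use <- c1 > 0 & c2 > 0 & c2 < c1
    if (any(use)) {
      k <- log(c1[use] / c2[use]) / dt[use]
      auc_seg[use] <- (c1[use] - c2[use]) / k
      # exact first moment of an exponential segment
      t1 <- t[-length(t)][use]; t2 <- t[-1L][use]
      aumc_seg[use] <- (t1 * c1[use] - t2 * c2[use]) / k +
        (c1[use] - c2[use]) / k^2
    }
  }
  list(auc = sum(auc_seg), aumc = sum(aumc_seg))
}

#' Noncompartmental analysis of a plasma curve
#'
#' Computes AUC and AUMC by the trapezoid rule over the observed range plus
#' a log-linear tail extrapolation to infinity, the terminal slope by
#' ordinary least squares on the log of the last `n_terminal` positive
#' concentrations, and the derived parameters MRT, total clearance and
#' steady-state volume of distribution. For an infusion of duration
#' `T_inf`, `MRT = AUMC/AUC - T_inf/2` and
#' `V_ss = Dose * AUMC / AUC^2 - Dose * T_inf / (2 * AUC)`; both reduce to
#' the bolus forms at `T_inf = 0`.
#'
#' If the curve ends in zeros after a finite pulse, no tail is added and the
#' extrapolated fraction is 0.
#'
#' @param series a [conc_time_series].
#' @param n_terminal number of terminal points for the log-linear fit
#'   (default 3).
#' @param method trapezoid variant for the observed range: `"linear"`
#'   (default) or `"log"` (log-trapezoid on falling positive segments).
#' @return an object of class `nca_result`: a list with `auc_0_inf`
#'   (mg·h/L), `aumc_0_inf` (mg·h²/L), `mrt` (h), `cl_total` (L/h), `vd_ss`
#'   (L/kg), `terminal_slope` (1/h, positive = declining),
#'   `n_terminal_points`, and `extrapolated_fraction` of the AUC.
#' @export
#' @examples
#' tt <- seq(0, 40, by = 0.01)
#' s <- conc_time_series(tt, 10 * exp(-0.5 * tt), dose = 20)
#' nca(s)$auc_0_inf  # ~ C0/k = 20
nca <- function(series, n_terminal = 3, method = c("linear", "log")) {
  stopifnot(inherits(series, "conc_time_series"))
  method <- match.arg(method)
  if (n_terminal < 2) stop("`n_terminal` must be at least 2", call. = FALSE)
  t <- series$times; cc <- series$concentrations

  mom <- .trapezoid_moments(t, cc, method)
  c_last <- cc[length(cc)]

  if (c_last == 0) {
    # finite pulse fully observed: no tail
    lambda_z <- NA_real_
    n_used <- 0L
    auc_tail <- 0; aumc_tail <- 0
  } else {
    pos <- which(cc > 0)
    if (length(pos) < 2L) stop("need at least 2 positive concentrations for the terminal fit",
                               call. = FALSE)
    idx <- utils::tail(pos, n_terminal)
    if (length(idx) < 2L) stop("terminal fit needs >= 2 positive points", call. = FALSE)
    fit <- stats::lm(log(cc[idx]) ~ t[idx])
    lambda_z <- -unname(coef(fit)[2L])
    n_used <- length(idx)
    if (!is.finite(lambda_z) || lambda_z <= 0) {
      stop("non-positive terminal slope: the curve is not declining over the last ",
           n_used, " points; cannot extrapolate the tail", call. = FALSE)
    }
    t_last <- t[length(t)]
    auc_tail <- c_last / lambda_z
    aumc_tail <- c_last * t_last / lambda_z + c_last / lambda_z^2
  }

  auc <- mom$auc + auc_tail
  aumc <- mom$aumc + aumc_tail
  if (auc <= 0) stop("non-positive AUC", call. = FALSE)
  t_inf <- series$infusion_duration
  mrt <- aumc / auc - t_inf / 2
  cl <- series$dose / auc
  vss <- (series$dose * aumc / auc^2 - series$dose * t_inf / (2 * auc)) /
    series$body_weight

  structure(
    list(auc_0_inf = auc, aumc_0_inf = aumc, mrt = mrt,
         cl_total = cl, vd_ss = vss,
         terminal_slope = lambda_z, n_terminal_points = n_used,
         extrapolated_fraction = auc_tail / auc),
    class = "nca_result"
  )
}

#' Steady-state volume of distribution per kilogram
#'
#' Convenience wrapper around [nca] returning only `V_ss / BW` in L/kg:
#' `V_ss = Dose * AUMC / AUC^2 - Dose * T_inf / (2 * AUC)`, the bolus form
#' `Dose * AUMC / AUC^2` when `T_inf = 0`.
#'
#' @inheritParams nca
#' @return steady-state volume of distribution, L/kg.
#' @export
vd_ss <- function(series, n_terminal = 3, method = c("linear", "log")) {
  nca(series, n_terminal = n_terminal, method = method)$vd_ss
}

#' @export
print.nca_result <- function(x, ...) {
  cat("Noncompartmental analysis\n")
  cat(sprintf("  AUC(0-inf):  %.4g mg.h/L  (%.1f%% extrapolated)\n",
              x$auc_0_inf, 100 * x$extrapolated_fraction))
  cat(sprintf("  AUMC(0-inf): %.4g mg.h^2/L\n", x$aumc_0_inf))
  cat(sprintf("  MRT:         %.4g h\n", x$mrt))
  cat(sprintf("  CL:          %.4g L/h\n", x$cl_total))
  cat(sprintf("  Vss:         %.4g L/kg\n", x$vd_ss))
  if (is.finite(x$terminal_slope))
    cat(sprintf("  lambda_z:    %.4g /h (over %d points)\n",
                x$terminal_slope, x$n_terminal_points))
  invisible(x)
}
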