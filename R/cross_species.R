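# Cross-species prediction of human dialyzability from rat removal rates,
# protein binding and volume of distribution.

.resolve_range <- function(lo, hi, convention) {
  switch(convention,
         upper = hi,
         lower = lo,
         mid   = (lo + hi) / 2,
         stop("unknown range convention: ", convention, call. = FALSE))
}

#' Load the packaged six-drug parameter table
#'
#' Returns the per-drug cross-species parameters for the six studied drugs
#' (amikacin AMK, aprindine AP, vancomycin VCM, doripenem DRPM, valproate
#' VPA, acetaminophen APAP): measured 2-h rat removal rate, its 4-h
#' first-order estimate, the reported human 4-h dialyzability, and protein
#' binding rate (PBR, percent) and volume of distribution (Vd, L/kg) for
#' both species. Aprindine was not detected in dialysate and is encoded as
#' exactly 0 % removal in both species.
#'
#' Human dialyzability and human Vd are reported in the literature as
#' ranges; a single point must be chosen for regression. The resolution
#' convention is configurable per quantity (`"upper"`, `"mid"`, `"lower"`).
#' The defaults — upper bound for dialyzability, lower bound for Vd — are
#' the pair under which the fitted prediction equations reproduce the
#' reference adjusted-R² values; see the methods vignette for the numerical
#' justification and the caveat that the literature does not state which
#' point was used.
#'
#' @param path CSV file of drug parameters; defaults to the packaged table.
#'   Columns: `drug, removal_2h, removal_4h, dd_human_lo, dd_human_hi,
#'   pbr_rat, pbr_human, vd_rat, vd_human_lo, vd_human_hi`.
#' @param dd_convention how to resolve the printed human dialyzability range.
#' @param vd_convention how to resolve the printed human Vd range.
#' @return a data.frame of class `drug_table` with one row per drug and
#'   resolved point columns `dd_human` and `vd_human` alongside the raw
#'   range columns.
#' @export
#' @examples
#' load_drug_table()
load_drug_table <- function(path = system.file("extdata", "drug_parameters.csv",
                                               package = "dialyzr"),
                            dd_convention = c("upper", "mid", "lower"),
                            vd_convention = c("lower", "mid", "upper")) {
  dd_convention <- match.arg(dd_convention)
  vd_convention <- match.arg(vd_convention)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("drug", "removal_2h", "removal_4h", "dd_human_lo", "dd_human_hi",
              "pbr_rat", "pbr_human", "vd_rat", "vd_human_lo", "vd_human_hi")
  missing <- setdiff(needed, names(d))
  if (length(missing)) {
    stop("drug table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(d$drug)) stop("duplicate drug names in table", call. = FALSE)
  for (col in setdiff(needed, "drug")) {
    bad <- which(!is.finite(d[[col]]))
    if (length(bad)) {
      stop("drug ", d$drug[bad[1L]], ": field `", col, "` is missing or non-numeric",
           call. = FALSE)
    }
  }
  pct <- c("removal_2h", "removal_4h", "dd_human_lo", "dd_human_hi",
           "pbr_rat", "pbr_human")
  for (col in pct) {
    if (any(d[[col]] < 0 | d[[col]] > 100)) {
      stop("percent column `", col, "` outside [0, 100]", call. = FALSE)
    }
  }
  if (any(d$vd_rat <= 0 | d$vd_human_lo <= 0 | d$vd_human_hi <= 0)) {
    stop("volumes of distribution must be positive", call. = FALSE)
  }
  d$dd_human <- .resolve_range(d$dd_human_lo, d$dd_human_hi, dd_convention)
  d$vd_human <- .resolve_range(d$vd_human_lo, d$vd_human_hi, vd_convention)
  attr(d, "dd_convention") <- dd_convention
  attr(d, "vd_convention") <- vd_convention
  class(d) <- c("drug_table", "data.frame")
  d
}

#' Human/rat unbound-fraction ratio
#'
#' Ratio of plasma protein *unbinding* rates, `(100 - PBR_human) /
#' (100 - PBR_rat)`, the factor by which the dialyzable (free) fraction
#' differs between the species.
#'
#' @param pbr_rat rat protein binding rate, percent; < 100.
#' @param pbr_human human protein binding rate, percent.
#' @return dimensionless ratio.
#' @export
#' @examples
#' unbound_ratio(26.1, 2.5)  # doripenem: rat binds more, ratio > 1
unbound_ratio <- function(pbr_rat, pbr_human) {
  stopifnot(is.numeric(pbr_rat), is.numeric(pbr_human))
  if (any(pbr_rat >= 100)) {
    stop("rat PBR of 100 % leaves no unbound drug: ratio undefined", call. = FALSE)
  }
  (100 - pbr_human) / (100 - pbr_rat)
}

#' Human/rat volume-of-distribution ratio
#'
#' @param vd_rat rat Vd, L/kg; > 0.
#' @param vd_human human Vd (resolved point value), L/kg; > 0.
#' @return dimensionless ratio `vd_human / vd_rat`.
#' @export
vd_ratio <- function(vd_rat, vd_human) {
  stopifnot(is.numeric(vd_rat), is.numeric(vd_human))
  if (any(vd_rat <= 0) || any(vd_human <= 0)) {
    stop("volumes of distribution must be positive", call. = FALSE)
  }
  vd_human / vd_rat
}

#' Build the design for one candidate prediction equation
#'
#' The response is always the human dialyzability `dd_human`. The four
#' candidate predictor sets are:
#' \describe{
#'   \item{Eq 1}{`x1 = removal_4h_rat` — raw rat removal.}
#'   \item{Eq 2}{`x1 = removal_4h_rat * unbound_ratio` — rat removal scaled
#'     by the human/rat free-fraction ratio.}
#'   \item{Eq 3}{`x1 = removal_4h_rat`, `x2 = vd_human / vd_rat`.}
#'   \item{Eq 4}{`x1 = removal_4h_rat`,
#'     `x2 = [(100 - PBR)/Vd]_human / [(100 - PBR)/Vd]_rat`.}
#' }
#'
#' @param records a `drug_table` (see [load_drug_table]).
#' @param equation_id integer in 1..4.
#' @param check_n enforce the minimum row count needed for fitting (set to
#'   `FALSE` when building predictors for prediction only).
#' @return a data.frame with columns `drug`, `y`, `x1` and (for equations 3
#'   and 4) `x2`, with attribute `equation_id`.
#' @export
build_design <- function(records, equation_id, check_n = TRUE) {
  stopifnot(inherits(records, "data.frame"))
  if (!equation_id %in% 1:4) stop("`equation_id` must be 1, 2, 3 or 4", call. = FALSE)
  needed <- c("drug", "removal_4h", "dd_human", "pbr_rat", "pbr_human",
              "vd_rat", "vd_human")
  for (col in needed) {
    if (is.null(records[[col]])) stop("missing column `", col, "`", call. = FALSE)
    if (col != "drug" && any(!is.finite(records[[col]]))) {
      bad <- records$drug[which(!is.finite(records[[col]]))[1L]]
      stop("drug ", bad, ": field `", col, "` is missing", call. = FALSE)
    }
  }
  n_pred <- if (equation_id %in% c(1L, 2L)) 1L else 2L
  n_min <- if (n_pred == 1L) 4L else 5L
  if (check_n && nrow(records) < n_min) {
    stop("need at least ", n_min, " drugs for a ", n_pred, "-predictor model",
         call. = FALSE)
  }
  ub <- unbound_ratio(records$pbr_rat, records$pbr_human)
  vr <- vd_ratio(records$vd_rat, records$vd_human)
  des <- data.frame(drug = records$drug, y = records$dd_human)
  if (equation_id == 1L) {
    des$x1 <- records$removal_4h
  } else if (equation_id == 2L) {
    des$x1 <- records$removal_4h * ub
  } else if (equation_id == 3L) {
    des$x1 <- records$removal_4h
    des$x2 <- vr
  } else {
    des$x1 <- records$removal_4h
    des$x2 <- ub / vr
  }
  attr(des, "equation_id") <- as.integer(equation_id)
  des
}

#' Fit one prediction equation by ordinary least squares
#'
#' Fits `y ~ x1` or `y ~ x1 + x2` on a design from [build_design] and
#' summarizes it as a `regression_fit`: intercept `a0`, slopes `a1` (and
#' `a2`), R², adjusted R² `1 - (1 - R²)(n - 1)/(n - p - 1)`, and the overall
#' F-test p-value. Per-coefficient t-test p-values are carried along but are
#' not used for model selection.
#'
#' @param design output of [build_design].
#' @return an object of class `regression_fit`.
#' @export
fit_ols <- function(design) {
  stopifnot(is.data.frame(design), all(c("y", "x1") %in% names(design)))
  has_x2 <- "x2" %in% names(design)
  p <- if (has_x2) 2L else 1L
  n <- nrow(design)
  if (n <= p + 1L) stop("too few observations for ", p, " predictor(s)", call. = FALSE)
  fml <- if (has_x2) y ~ x1 + x2 else y ~ x1
  fit <- stats::lm(fml, data = design)
  qrr <- fit$qr$rank
  if (qrr < p + 1L) {
    stop("singular design: predictor columns are linearly dependent", call. = FALSE)
  }
  s <- summary(fit)
  fstat <- s$fstatistic
  p_overall <- unname(stats::pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE))
  cf <- coef(fit)
  structure(
    list(a0 = unname(cf[1L]), a1 = unname(cf[2L]),
         a2 = if (has_x2) unname(cf[3L]) else NA_real_,
         r_squared = s$r.squared, adj_r_squared = s$adj.r.squared,
         p_value = p_overall,
         coef_p_values = unname(s$coefficients[, 4L]),
         n = n, n_predictors = p,
         equation_id = attr(design, "equation_id"),
         lm = fit),
    class = "regression_fit"
  )
}

#' @export
print.regression_fit <- function(x, ...) {
  eq <- if (is.null(x$equation_id)) "?" else x$equation_id
  cat(sprintf("Prediction equation %s (n = %d):\n", eq, x$n))
  cat(sprintf("  a0 = %.4g, a1 = %.4g%s\n", x$a0, x$a1,
              if (is.finite(x$a2)) sprintf(", a2 = %.4g", x$a2) else ""))
  cat(sprintf("  R^2 = %.4f, adj R^2 = %.4f, overall p = %.4g\n",
              x$r_squared, x$adj_r_squared, x$p_value))
  invisible(x)
}

#' Fit all four candidate equations
#'
#' @param records a `drug_table`.
#' @return a named list of four `regression_fit` objects (`eq1`..`eq4`).
#' @export
#' @examples
#' fits <- fit_all_equations(load_drug_table())
#' sapply(fits, function(f) f$adj_r_squared)
fit_all_equations <- function(records) {
  setNames(lapply(1:4, function(i) fit_ols(build_design(records, i))),
           paste0("eq", 1:4))
}

#' Select the best prediction equation by adjusted R-squared
#'
#' @param fits a list of `regression_fit` objects (at least 2).
#' @return the `equation_id` of the fit with the largest adjusted R²; exact
#'   ties resolve to the lowest id.
#' @export
select_best_model <- function(fits) {
  if (length(fits) == 0L) stop("no fits supplied", call. = FALSE)
  if (length(fits) == 1L) return(fits[[1L]]$equation_id)
  ids <- vapply(fits, function(f) as.integer(f$equation_id), integer(1))
  adj <- vapply(fits, function(f) f$adj_r_squared, numeric(1))
  best <- which(adj == max(adj))
  unname(ids[best[which.min(ids[best])]])
}

#' Predict human dialyzability for one drug
#'
#' Evaluates a fitted prediction equation on a drug's predictors. The raw
#' value is always reported; a copy clipped to \[0, 100\] is provided
#' separately since a percent outside that range is not physically
#' realizable but the raw value is what the linear model says.
#'
#' @param fit a `regression_fit`.
#' @param record a one-row `drug_table` slice (or list) with the fields the
#'   equation needs.
#' @return a list with `raw` and `clipped` predicted dialyzability, percent.
#' @export
predict_dd_human <- function(fit, record) {
  stopifnot(inherits(fit, "regression_fit"))
  eq <- fit$equation_id
  if (is.null(eq)) stop("fit carries no equation id", call. = FALSE)
  one <- as.data.frame(record, stringsAsFactors = FALSE)
  if (is.null(one$dd_human)) one$dd_human <- 0  # response unused for prediction
  des <- build_design(one, eq, check_n = FALSE)
  has_x2 <- "x2" %in% names(des)
  if (has_x2 != (fit$n_predictors == 2L)) {
    stop("equation arity mismatch between fit and record", call. = FALSE)
  }
  raw <- fit$a0 + fit$a1 * des$x1 + if (has_x2) fit$a2 * des$x2 else 0
  list(raw = raw, clipped = pmin(100, pmax(0, raw)))
}
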