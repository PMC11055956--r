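# Observer scores, the Vascular Effect Index (VEI) and compartmental
# effect indices.
#
# The VEI condenses the treated/control ratios of three pseudovessel
# descriptors - total PV volume (rV), supply index (rSI) and mean
# segments per network (rSN) - into one score calibrated against human
# observer ratings:
#
#   VEI = x1 * rV^y1 + x2 * rSI^y2 + x3 * rSN^y3
#
# with weight factors x1..x3 and nonlinear correction exponents y1..y3.
# The published calibration is x = (0.6, -0.11, 0.44), y = (0.65, 1.5,
# 1.5); identity ratios then give VEI = 0.93.

#' VEI model
#'
#' @param x1,x2,x3 weight factors (finite).
#' @param y1,y2,y3 nonlinear correction exponents (> 0).
#' @return object of class `vei_model`. Defaults are the published
#'   calibration.
#' @export
vei_model <- function(x1 = 0.6, x2 = -0.11, x3 = 0.44,
                      y1 = 0.65, y2 = 1.5, y3 = 1.5) {
  v <- c(x1 = x1, x2 = x2, x3 = x3, y1 = y1, y2 = y2, y3 = y3)
  if (any(!is.finite(v))) stop("all VEI parameters must be finite")
  if (any(v[c("y1", "y2", "y3")] <= 0)) stop("exponents must be positive")
  structure(as.list(v), class = "vei_model")
}

#' @export
print.vei_model <- function(x, ...) {
  cat(sprintf("VEI = %.3g*rV^%.3g + %.3g*rSI^%.3g + %.3g*rSN^%.3g\n",
              x$x1, x$y1, x$x2, x$y2, x$x3, x$y3))
  invisible(x)
}

#' Compute the VEI for treated/control ratio(s)
#'
#' @param ratios data.frame with columns `rV`, `rSI`, `rSN` (one row per
#'   treatment group), or a numeric length-3 vector in that order.
#' @param model a [vei_model()].
#' @return numeric vector of VEI values.
#' @export
compute_vei <- function(ratios, model = vei_model()) {
  stopifnot(inherits(model, "vei_model"))
  if (is.numeric(ratios) && length(ratios) == 3)
    ratios <- data.frame(rV = ratios[1], rSI = ratios[2], rSN = ratios[3])
  if (!all(c("rV", "rSI", "rSN") %in% names(ratios)))
    stop("ratios must provide rV, rSI and rSN")
  r <- ratios[c("rV", "rSI", "rSN")]
  if (any(!is.finite(as.matrix(r))) || any(as.matrix(r) <= 0))
    stop("all ratios must be finite and positive")
  model$x1 * r$rV^model$y1 + model$x2 * r$rSI^model$y2 + model$x3 * r$rSN^model$y3
}

#' Aggregate observer ratings into an observer score
#'
#' The observer score of a treatment group is the arithmetic mean of all
#' side-by-side gradings of treated versus control VTSs. The canonical
#' grade set is \{-1, -0.5, 0, +0.5, +1\}; files graded on a +-2 integer
#' scale are imported with `scale = "two"` (divided by 2).
#'
#' @param ratings data.frame with columns `observer`, `treated_id`,
#'   `control_id`, `grade`.
#' @param scale `"unit"` (half-point grades) or `"two"` (+-2 integers,
#'   rescaled on import).
#' @return list with `os`, `n_ratings`, `per_observer` (data.frame).
#' @export
aggregate_observer_score <- function(ratings, scale = c("unit", "two")) {
  scale <- match.arg(scale)
  need <- c("observer", "treated_id", "control_id", "grade")
  if (!all(need %in% names(ratings)))
    stop("ratings need columns observer, treated_id, control_id, grade")
  if (nrow(ratings) == 0) stop("no ratings to aggregate")
  g <- ratings$grade
  if (scale == "two") g <- g / 2
  allowed <- c(-1, -0.5, 0, 0.5, 1)
  if (any(!g %in% allowed))
    stop("grades must be in {-1, -0.5, 0, +0.5, +1} (after rescaling)")
  if (any(ratings$treated_id == ratings$control_id))
    stop("a VTS cannot be rated against itself")
  per_obs <- aggregate(list(mean_grade = g),
                       by = list(observer = ratings$observer), FUN = mean)
  list(os = mean(g), n_ratings = length(g), per_observer = per_obs)
}

#' Correlate the observer score with descriptor parameters
#'
#' Per parameter: Pearson r with the exact two-tailed t-distribution p
#' value and a Fisher-z 95 percent confidence interval. Zero-variance
#' parameters are flagged with an undefined r.
#'
#' @param os numeric observer scores, one per group.
#' @param params data.frame/matrix of parameter values (rows = groups).
#' @param conf_level confidence level for the Fisher-z interval.
#' @return data.frame: parameter, r, p, ci_lo, ci_hi, n, flag.
#' @export
correlate_os_parameters <- function(os, params, conf_level = 0.95) {
  params <- as.data.frame(params)
  if (length(os) != nrow(params)) stop("os and params disagree in length")
  if (length(os) < 3) stop("need at least 3 groups for a correlation")
  out <- lapply(names(params), function(nm) {
    x <- params[[nm]]
    ok <- is.finite(x) & is.finite(os)
    n <- sum(ok)
    if (n < 3 || sd(x[ok]) == 0 || sd(os[ok]) == 0)
      return(data.frame(parameter = nm, r = NA_real_, p = NA_real_,
                        ci_lo = NA_real_, ci_hi = NA_real_, n = n,
                        flag = "undefined"))
    ct <- cor.test(x[ok], os[ok], method = "pearson",
                   conf.level = conf_level, alternative = "two.sided")
    data.frame(parameter = nm, r = unname(ct$estimate), p = ct$p.value,
               ci_lo = ct$conf.int[1], ci_hi = ct$conf.int[2], n = n,
               flag = "")
  })
  do.call(rbind, out)
}

#' Fit the VEI model to ratio/observer-score data
#'
#' Stepwise calibration: stage 1 estimates the weight factors by ordinary
#' least squares with all exponents fixed at 1 (no intercept; the model
#' has none); stage 2 jointly refines all six parameters by bounded
#' Levenberg-Marquardt nonlinear least squares, initialized from stage 1
#' with exponents at 1 and exponent bounds (0.1, 5).
#'
#' Observer scores live on a bounded grading scale while the power-law
#' VEI is unbounded, so groups whose score sits at the scale limit carry
#' no quantitative information about how far beyond the limit the effect
#' went. Such censored rows (|os| >= `censor_bound`) are excluded from
#' the fit (with a message); disable with `censor_bound = Inf`.
#'
#' @param tab data.frame with columns `rV`, `rSI`, `rSN`, `os`.
#' @param exponent_bounds length-2 bounds for all three exponents.
#' @param censor_bound magnitude at which a score is treated as censored.
#' @return list: `model` ([vei_model()]), `stage1` (named weights),
#'   `residual_rms`, `fitted`, `n`, `n_censored`.
#' @export
fit_vei_model <- function(tab, exponent_bounds = c(0.1, 5),
                          censor_bound = 1) {
  need <- c("rV", "rSI", "rSN", "os")
  if (!all(need %in% names(tab))) stop("tab needs columns rV, rSI, rSN, os")
  tab <- tab[complete.cases(tab[need]), ]
  n_censored <- sum(abs(tab$os) >= censor_bound)
  if (n_censored > 0) {
    message(sprintf("excluding %d group(s) with scores censored at +-%g",
                    n_censored, censor_bound))
    tab <- tab[abs(tab$os) < censor_bound, ]
  }
  n <- nrow(tab)
  if (n < 6) stop("need at least 6 groups: the model has six free parameters")
  X <- as.matrix(tab[c("rV", "rSI", "rSN")])
  if (any(X <= 0)) stop("all ratios must be positive")
  sds <- apply(X, 2, sd)
  if (any(sds < 1e-12) || qr(X)$rank < 3)
    stop("degenerate design: ratios carry no usable variation")

  s1 <- lm(os ~ 0 + rV + rSI + rSN, data = tab)
  w <- coef(s1)

  fit <- minpack.lm::nlsLM(
    os ~ x1 * rV^y1 + x2 * rSI^y2 + x3 * rSN^y3,
    data = tab,
    start = list(x1 = unname(w["rV"]), x2 = unname(w["rSI"]),
                 x3 = unname(w["rSN"]), y1 = 1, y2 = 1, y3 = 1),
    lower = c(-10, -10, -10, exponent_bounds[1], exponent_bounds[1],
              exponent_bounds[1]),
    upper = c(10, 10, 10, exponent_bounds[2], exponent_bounds[2],
              exponent_bounds[2]),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- coef(fit)
  model <- vei_model(x1 = cf[["x1"]], x2 = cf[["x2"]], x3 = cf[["x3"]],
                     y1 = cf[["y1"]], y2 = cf[["y2"]], y3 = cf[["y3"]])
  fitted_vei <- compute_vei(tab, model)
  list(model = model,
       stage1 = c(x1 = unname(w["rV"]), x2 = unname(w["rSI"]),
                  x3 = unname(w["rSN"])),
       residual_rms = sqrt(mean((tab$os - fitted_vei)^2)),
       fitted = fitted_vei, n = n, n_censored = n_censored)
}

#' Bounded ratio-change map
#'
#' `b(r) = (r - 1) / (r + 1)`: antisymmetric under r -> 1/r, 0 at no
#' change, and bounded in (-1, +1) for finite positive ratios.
#'
#' @param r positive ratio(s).
#' @return values in (-1, 1).
#' @export
bounded_ratio_index <- function(r) {
  if (any(!is.finite(r)) || any(r <= 0)) stop("ratios must be finite and positive")
  (r - 1) / (r + 1)
}

#' Compartmental effect indices for one treatment group
#'
#' Bounded [-1, +1] summaries of a treatment's effect per compartment,
#' from treated/control descriptor-mean ratios via
#' [bounded_ratio_index()]. Signs are set so the named effect is
#' positive when it occurs: the anti-angiogenic index is positive when
#' the relative CD31 volume shrinks, the vascular-disruptive index when
#' the total PV network length shrinks, and the tumor-cell / fibroblast
#' indices when the compartment's cell density and relative volume grow.
#'
#' @param treated,control named numeric vectors of group means with
#'   entries `cd31_volume_rel`, `pv_total_length_um`,
#'   `tumor_cell_density_mm3`, `tumor_volume_rel`,
#'   `fibroblast_cell_density_mm3`, `fibroblast_volume_rel`. Control
#'   means must be positive.
#' @return list: `anti_angiogenic`, `vascular_disruptive`, `tumor_cell`,
#'   `fibroblast`, each in [-1, 1].
#' @export
effect_indices <- function(treated, control) {
  need <- c("cd31_volume_rel", "pv_total_length_um", "tumor_cell_density_mm3",
            "tumor_volume_rel", "fibroblast_cell_density_mm3",
            "fibroblast_volume_rel")
  if (!all(need %in% names(treated)) || !all(need %in% names(control)))
    stop(sprintf("treated and control need entries: %s",
                 paste(need, collapse = ", ")))
  if (any(control[need] <= 0)) stop("control means must be positive")
  r <- unlist(treated[need]) / unlist(control[need])
  b <- bounded_ratio_index(r)
  list(anti_angiogenic = unname(-b["cd31_volume_rel"]),
       vascular_disruptive = unname(-b["pv_total_length_um"]),
       tumor_cell = unname(mean(b[c("tumor_cell_density_mm3", "tumor_volume_rel")])),
       fibroblast = unname(mean(b[c("fibroblast_cell_density_mm3",
                                    "fibroblast_volume_rel")])))
}
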