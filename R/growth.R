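#' Construct a growth-curve set
#'
#' Bundles a plate-reader optical-density time series with per-well metadata.
#' Times are stored in hours; readers that parse `time_min` columns convert
#' before calling this constructor.
#'
#' @param times Numeric vector of time points in hours, strictly increasing.
#' @param od Numeric matrix of optical densities, one row per well, one column
#'   per time point. Row names identify wells.
#' @param wells Data frame with one row per well and columns `well`, `strain`,
#'   `dose_uM`, `replicate`, `role`. `role` is one of `"sample"`, `"blank"`,
#'   `"vehicle-control"`.
#' @return An object of class `growth_curve_set`.
#' @export
growth_curve_set <- function(times, od, wells) {
  times <- as.numeric(times)
  od <- as.matrix(od)
  if (length(times) < 1L) stop("at least one time point required")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (ncol(od) != length(times)) {
    stop("od must have one column per time point (", length(times),
         " expected, got ", ncol(od), ")")
  }
  wells <- as.data.frame(wells, stringsAsFactors = FALSE)
  req <- c("well", "strain", "dose_uM", "replicate", "role")
  miss <- setdiff(req, names(wells))
  if (length(miss)) stop("well map missing columns: ", paste(miss, collapse = ", "))
  if (nrow(wells) != nrow(od)) stop("well map rows must match od rows")
  bad <- setdiff(unique(wells$role), c("sample", "blank", "vehicle-control"))
  if (length(bad)) stop("unknown well role(s): ", paste(bad, collapse = ", "))
  rownames(od) <- wells$well
  structure(list(times = times, od = od, wells = wells),
            class = "growth_curve_set")
}

#' @export
print.growth_curve_set <- function(x, ...) {
  cat("growth_curve_set:", nrow(x$od), "wells x", length(x$times),
      "time points (", round(min(x$times), 2), "-", round(max(x$times), 2),
      "h )\n")
  print(table(x$wells$role))
  invisible(x)
}

#' Background-correct and replicate-average growth curves
#'
#' Subtracts the per-time-point mean of the blank wells from every non-blank
#' well, floors negative corrected values at zero (recording which wells were
#' floored), and averages replicate wells into one curve per
#' (strain, dose, role) group.
#'
#' @param raw A [growth_curve_set()] containing at least one blank well.
#' @return A `growth_curve_set` with one averaged, corrected curve per
#'   (strain, dose, role) group. The well map gains `n_rep` (replicates
#'   averaged) and `floored` (any value floored at 0 in the group) columns.
#' @export
correct_and_average <- function(raw) {
  stopifnot(inherits(raw, "growth_curve_set"))
  blank <- raw$wells$role == "blank"
  if (!any(blank)) stop("no blank wells present; background correction requires at least one")
  blank_mean <- colMeans(raw$od[blank, , drop = FALSE])
  samp <- !blank
  corr <- sweep(raw$od[samp, , drop = FALSE], 2, blank_mean)
  floored_well <- rowSums(corr < 0) > 0
  corr[corr < 0] <- 0
  w <- raw$wells[samp, , drop = FALSE]
  key <- interaction(w$strain, w$dose_uM, w$role, drop = TRUE)
  groups <- split(seq_len(nrow(w)), key)
  od_avg <- t(vapply(groups, function(i) colMeans(corr[i, , drop = FALSE]),
                     numeric(length(raw$times))))
  meta <- do.call(rbind, lapply(groups, function(i) {
    data.frame(well = paste0("avg_", w$strain[i[1]], "_", w$dose_uM[i[1]]),
               strain = w$strain[i[1]], dose_uM = w$dose_uM[i[1]],
               replicate = "avg", role = w$role[i[1]],
               n_rep = length(i), floored = any(floored_well[i]),
               stringsAsFactors = FALSE)
  }))
  rownames(meta) <- NULL
  out <- growth_curve_set(raw$times, od_avg, meta[, c("well", "strain", "dose_uM", "replicate", "role")])
  out$wells$n_rep <- meta$n_rep
  out$wells$floored <- meta$floored
  out
}

#' Area under a growth curve
#'
#' Trapezoidal integral of optical density over time, the total-growth
#' measure used for dose-response and group comparisons.
#'
#' @param times Time points in hours, strictly increasing, length >= 2.
#' @param od Optical densities at `times`.
#' @return The integral in OD*h.
#' @export
auc <- function(times, od) {
  if (length(times) < 2L) stop("AUC requires at least 2 time points")
  if (length(od) != length(times)) stop("od and times lengths differ")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  sum(diff(times) * (od[-1] + od[-length(od)]) / 2)
}

#' Dose-response inhibition profile from replicate AUC values
#'
#' Summarises per-replicate AUC values into mean, standard error and the
#' fractional growth inhibition relative to the zero-dose (vehicle) mean:
#' `inhibition(d) = 1 - mean_auc(d) / mean_auc(0)`.
#'
#' @param aucs Data frame with columns `dose_uM` and `auc`, one row per
#'   replicate. Dose 0 must be present.
#' @return A data frame of class `dose_response` with columns `dose_uM`
#'   (ascending), `n`, `mean_auc`, `se_auc`, `inhibition`. Inhibition at
#'   dose 0 is exactly 0.
#' @export
inhibition_profile <- function(aucs) {
  aucs <- as.data.frame(aucs)
  stopifnot(all(c("dose_uM", "auc") %in% names(aucs)))
  if (!any(aucs$dose_uM == 0)) stop("dose 0 (vehicle) replicates are required")
  sp <- split(aucs$auc, aucs$dose_uM)
  doses <- as.numeric(names(sp))
  o <- order(doses)
  doses <- doses[o]; sp <- sp[o]
  n <- lengths(sp)
  mean_auc <- vapply(sp, mean, 0)
  se_auc <- vapply(sp, function(v) if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0, 0)
  m0 <- mean_auc[doses == 0]
  if (m0 <= 0) stop("mean AUC at dose 0 must be positive")
  inhibition <- 1 - mean_auc / m0
  inhibition[doses == 0] <- 0
  structure(data.frame(dose_uM = doses, n = as.integer(n), mean_auc = mean_auc,
                       se_auc = se_auc, inhibition = inhibition, row.names = NULL),
            class = c("dose_response", "data.frame"))
}

#' Estimate the ICx concentration from an inhibition profile
#'
#' Piecewise-linear interpolation of inhibition against log10(dose) between
#' the two positive doses bracketing the target inhibition x/100. The zero
#' dose only anchors the baseline (inhibition 0) and is excluded from the log
#' axis. If the target is not bracketed the nearest measured dose is returned
#' with `extrapolated = TRUE` (or an error when `extrapolate = FALSE`).
#'
#' @param profile A [inhibition_profile()] result (or data frame with
#'   `dose_uM` and `inhibition`).
#' @param x Target percent inhibition in (0, 100), e.g. 20 for the IC20.
#' @param extrapolate Return the nearest bound when the target is outside the
#'   measured inhibition range? Default `TRUE`.
#' @return List of class `icx_estimate` with `x`, `concentration` (same dose
#'   units as the profile), `bracketing_doses`, `extrapolated`.
#' @export
estimate_icx <- function(profile, x, extrapolate = TRUE) {
  stopifnot(is.numeric(x), length(x) == 1L, x > 0, x < 100)
  d <- profile$dose_uM; inh <- profile$inhibition
  pos <- d > 0
  if (sum(pos) < 1L) stop("at least one positive dose is required")
  d <- d[pos]; inh <- inh[pos]
  o <- order(d); d <- d[o]; inh <- inh[o]
  target <- x / 100
  res <- function(conc, lo, hi, extra) {
    structure(list(x = x, concentration = conc, bracketing_doses = c(lo, hi),
                   extrapolated = extra), class = "icx_estimate")
  }
  for (i in seq_along(d)) {
    if (abs(inh[i] - target) < .Machine$double.eps^0.5) {
      return(res(d[i], d[i], d[i], FALSE))
    }
  }
  if (length(d) >= 2L) {
    for (i in seq_len(length(d) - 1L)) {
      lo <- inh[i]; hi <- inh[i + 1L]
      if ((lo < target && hi > target) || (lo > target && hi < target)) {
        lg <- log10(d[i]) + (target - lo) / (hi - lo) * (log10(d[i + 1L]) - log10(d[i]))
        return(res(10^lg, d[i], d[i + 1L], FALSE))
      }
    }
  }
  if (!extrapolate) stop("target inhibition ", target, " not bracketed by the profile")
  nearest <- which.min(abs(inh - target))
  res(d[nearest], d[nearest], d[nearest], TRUE)
}

#' Pooled-variance two-sample t-test on AUC replicates
#'
#' Two-sided Student t-test assuming equal variance between groups. With zero
#' pooled variance the degenerate conventions are: equal means give t = 0,
#' p = 1; unequal means give infinite t and p = 0.
#'
#' @param auc_a,auc_b Numeric replicate values, each of length >= 2.
#' @return List with `t`, `df`, `p`.
#' @export
compare_groups <- function(auc_a, auc_b) {
  na <- length(auc_a); nb <- length(auc_b)
  if (na < 2L || nb < 2L) stop("each group needs at least 2 replicates")
  df <- na + nb - 2L
  sp2 <- ((na - 1) * stats::var(auc_a) + (nb - 1) * stats::var(auc_b)) / df
  delta <- mean(auc_a) - mean(auc_b)
  if (sp2 <= 0) {
    if (abs(delta) < .Machine$double.eps^0.5) return(list(t = 0, df = df, p = 1))
    return(list(t = sign(delta) * Inf, df = df, p = 0))
  }
  t <- delta / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Convert a molar concentration to mass concentration
#'
#' @param c_uM Concentration in micromolar (uM), >= 0.
#' @param molar_mass Molar mass in g/mol, > 0.
#' @return Concentration in mg/L (`c_uM * molar_mass / 1000`).
#' @examples
#' convert_concentration(330, 252.31)  # benzo[a]pyrene IC20 dose, 83.26 mg/L
#' @export
convert_concentration <- function(c_uM, molar_mass) {
  if (any(c_uM < 0)) stop("concentration must be non-negative")
  if (any(molar_mass <= 0)) stop("molar mass must be positive")
  c_uM * molar_mass / 1000
}
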