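#' Construct a reporter plate
#'
#' Paired OD and GFP time courses for a GFP-fusion stress-reporter assay,
#' read on the same grid (default every 5 min over 2 h).
#'
#' @param times Time points in minutes, strictly increasing.
#' @param od,gfp Numeric matrices, wells x time points, sharing shape.
#' @param wells Data frame with columns `well`, `orf`, `stress_category`,
#'   `dose_mgL`, `role` (one of `"experiment"`, `"vehicle-control"`,
#'   `"medium-control"`, `"internal-control"`), `replicate`.
#' @return Object of class `reporter_plate`.
#' @export
reporter_plate <- function(times, od, gfp, wells) {
  times <- as.numeric(times)
  od <- as.matrix(od); gfp <- as.matrix(gfp)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (!identical(dim(od), dim(gfp))) stop("od and gfp must share shape")
  if (ncol(od) != length(times)) stop("matrices must have one column per time point")
  wells <- as.data.frame(wells, stringsAsFactors = FALSE)
  req <- c("well", "orf", "stress_category", "dose_mgL", "role", "replicate")
  miss <- setdiff(req, names(wells))
  if (length(miss)) stop("well map missing columns: ", paste(miss, collapse = ", "))
  if (nrow(wells) != nrow(od)) stop("well map rows must match matrix rows")
  bad <- setdiff(unique(wells$role),
                 c("experiment", "vehicle-control", "medium-control", "internal-control"))
  if (length(bad)) stop("unknown well role(s): ", paste(bad, collapse = ", "))
  rownames(od) <- wells$well; rownames(gfp) <- wells$well
  structure(list(times = times, od = od, gfp = gfp, wells = wells),
            class = "reporter_plate")
}

#' @export
print.reporter_plate <- function(x, ...) {
  cat("reporter_plate:", nrow(x$od), "wells x", length(x$times),
      "time points (", max(x$times), "min )\n")
  print(table(x$wells$role))
  invisible(x)
}

#' Background-correct reporter signals against medium controls
#'
#' Subtracts, per time point, the mean OD and GFP of the medium-control
#' wells matched to each well's chemical condition (same dose; falling back
#' to dose-0 medium controls when no dose-matched ones exist). Corrected
#' values are floored at a small positive epsilon (a fraction of each
#' channel's dynamic range) and flooring is flagged per well.
#'
#' @param plate A [reporter_plate()].
#' @param epsilon_frac Floor, as a fraction of the channel's dynamic range;
#'   default 1e-4.
#' @return A `reporter_plate` without the medium-control wells; the well map
#'   gains a logical `floored` column.
#' @export
correct_signals <- function(plate, epsilon_frac = 1e-4) {
  stopifnot(inherits(plate, "reporter_plate"))
  w <- plate$wells
  med <- w$role == "medium-control"
  if (!any(med)) stop("no medium-control wells present")
  eps_od <- epsilon_frac * max(diff(range(plate$od)), .Machine$double.eps)
  eps_gfp <- epsilon_frac * max(diff(range(plate$gfp)), .Machine$double.eps)
  keep <- which(!med)
  od_c <- plate$od[keep, , drop = FALSE]
  gfp_c <- plate$gfp[keep, , drop = FALSE]
  floored <- logical(length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    match_med <- med & w$dose_mgL == w$dose_mgL[i]
    if (!any(match_med)) match_med <- med & w$dose_mgL == 0
    if (!any(match_med)) {
      stop("no medium control for condition dose ", w$dose_mgL[i], " mg/L")
    }
    od_bg <- colMeans(plate$od[match_med, , drop = FALSE])
    gfp_bg <- colMeans(plate$gfp[match_med, , drop = FALSE])
    od_j <- plate$od[i, ] - od_bg
    gfp_j <- plate$gfp[i, ] - gfp_bg
    floored[j] <- any(od_j < eps_od) || any(gfp_j < eps_gfp)
    od_c[j, ] <- pmax(od_j, eps_od)
    gfp_c[j, ] <- pmax(gfp_j, eps_gfp)
  }
  out <- reporter_plate(plate$times, od_c, gfp_c, w[keep, , drop = FALSE])
  out$wells$floored <- floored
  out
}

#' Per-cell expression level
#'
#' P = corrected GFP / corrected OD, pointwise over the time course:
#' fluorescence normalized by cell density.
#'
#' @param gfp_c,od_c Corrected signal vectors or wells x time matrices
#'   (post-flooring, strictly positive OD).
#' @return Same shape as the inputs.
#' @export
expression_level <- function(gfp_c, od_c) {
  if (!identical(dim(gfp_c), dim(od_c)) || length(gfp_c) != length(od_c)) {
    stop("gfp and od must share shape")
  }
  gfp_c / od_c
}

#' Plate normalization against internal-control wells
#'
#' Divides every well's expression level P by the plate-wise median P of the
#' designated internal-control wells at each time point, removing plate-wide
#' multiplicative factors. Skipped with a warning when no internal-control
#' wells are designated.
#'
#' @param P Wells x time matrix of expression levels.
#' @param internal_rows Row indices (or names) of the internal-control wells.
#' @return Normalized matrix.
#' @export
plate_normalize <- function(P, internal_rows) {
  if (length(internal_rows) == 0L) {
    warning("no internal-control wells designated; plate normalization skipped")
    return(P)
  }
  ref <- apply(P[internal_rows, , drop = FALSE], 2, stats::median)
  if (any(ref <= 0)) stop("internal-control expression level is non-positive at some time point")
  sweep(P, 2, ref, "/")
}

#' Induction factor time series
#'
#' I(t) = P_experiment(t) / P_vehicle(t): fold-change in per-cell expression
#' relative to the matched vehicle control.
#'
#' @param P_experiment,P_vehicle Expression-level series on the same grid.
#' @return Induction series.
#' @export
induction_series <- function(P_experiment, P_vehicle) {
  if (length(P_experiment) != length(P_vehicle)) {
    stop("experiment and vehicle series are on different time grids")
  }
  P_experiment / P_vehicle
}

#' Protein Expression Level Index
#'
#' Time-average of the induction factor over the exposure window: the
#' trapezoidal integral of I over [t_first, t_last] divided by the window
#' length. Dimensionless; identically 1 for a vehicle-vs-vehicle series.
#'
#' @param I Induction series, length >= 2.
#' @param times Time points (any consistent unit), strictly increasing.
#' @return The PELI value.
#' @export
peli <- function(I, times) {
  if (length(I) < 2L) stop("PELI requires at least 2 time points")
  if (length(I) != length(times)) stop("I and times lengths differ")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  sum(diff(times) * (I[-1] + I[-length(I)]) / 2) / (times[length(times)] - times[1])
}

#' Aggregate replicate PELIs and call activation
#'
#' Mean and sample SD over replicates; an ORF is activated when the mean
#' PELI exceeds the signal-to-noise cutoff (default 1.5).
#'
#' @param pelis Numeric replicate PELI values, length >= 1.
#' @param cutoff Activation cutoff; default 1.5.
#' @return List with `mean`, `sd` (0 and flagged via `single_replicate` when
#'   n = 1), `n`, `activated`.
#' @export
aggregate_and_call <- function(pelis, cutoff = 1.5) {
  stopifnot(length(pelis) >= 1L)
  m <- mean(pelis)
  list(mean = m,
       sd = if (length(pelis) > 1L) stats::sd(pelis) else 0,
       n = length(pelis),
       single_replicate = length(pelis) == 1L,
       activated = m > cutoff)
}

#' Full reporter-plate PELI analysis
#'
#' Runs signal correction, per-cell expression, optional internal-control
#' plate normalization, induction against matched vehicle controls (matched
#' by ORF and replicate; by ORF with replicate-averaged vehicle P when
#' replicate ids differ), PELI integration and activation calling.
#'
#' @param plate A [reporter_plate()].
#' @param cutoff Activation cutoff on the mean PELI; default 1.5.
#' @param epsilon_frac Passed to [correct_signals()].
#' @return List of class `peli_result`: `records` data frame (`orf`,
#'   `dose_mgL`, `peli_mean`, `peli_sd`, `n_rep`, `activated`, `category`),
#'   `replicates` (per-replicate PELIs), `induction` (per experiment well
#'   I(t) matrix), `times`.
#' @export
peli_analysis <- function(plate, cutoff = 1.5, epsilon_frac = 1e-4) {
  corr <- correct_signals(plate, epsilon_frac = epsilon_frac)
  P <- expression_level(corr$gfp, corr$od)
  w <- corr$wells
  internal <- which(w$role == "internal-control")
  if (length(internal)) P <- plate_normalize(P, internal)
  exps <- which(w$role == "experiment")
  veh <- which(w$role == "vehicle-control")
  if (!length(veh)) stop("no vehicle-control wells present")
  I_mat <- matrix(NA_real_, length(exps), ncol(P),
                  dimnames = list(w$well[exps], NULL))
  rep_rows <- vector("list", length(exps))
  for (j in seq_along(exps)) {
    i <- exps[j]
    vi <- veh[w$orf[veh] == w$orf[i] & w$replicate[veh] == w$replicate[i]]
    if (!length(vi)) vi <- veh[w$orf[veh] == w$orf[i]]
    if (!length(vi)) stop("no vehicle control for ORF ", w$orf[i])
    Pv <- if (length(vi) > 1L) colMeans(P[vi, , drop = FALSE]) else P[vi, ]
    I_mat[j, ] <- induction_series(P[i, ], Pv)
    rep_rows[[j]] <- data.frame(orf = w$orf[i], dose_mgL = w$dose_mgL[i],
                                replicate = w$replicate[i],
                                category = w$stress_category[i],
                                peli = peli(I_mat[j, ], corr$times),
                                stringsAsFactors = FALSE)
  }
  reps <- do.call(rbind, rep_rows)
  key <- interaction(reps$orf, reps$dose_mgL, drop = TRUE)
  records <- do.call(rbind, lapply(split(reps, key), function(s) {
    ag <- aggregate_and_call(s$peli, cutoff = cutoff)
    data.frame(orf = s$orf[1], dose_mgL = s$dose_mgL[1], peli_mean = ag$mean,
               peli_sd = ag$sd, n_rep = ag$n, activated = ag$activated,
               category = s$category[1], stringsAsFactors = FALSE)
  }))
  rownames(records) <- NULL
  structure(list(records = records, replicates = reps, induction = I_mat,
                 times = corr$times, cutoff = cutoff),
            class = "peli_result")
}

#' Export the log-induction heat-map matrix
#'
#' ln(I) per ORF and time point, rows grouped by stress category (a supplied
#' category order, then ORF id), one column block per dose. Rendering is
#' left to the plotting layer; the export is a plain matrix/TSV.
#'
#' @param I_by_dose Named list (dose -> ORF x time matrix of replicate-mean
#'   induction factors).
#' @param orf_categories Named character vector ORF -> stress category.
#' @param category_order Display order of the categories; default the sorted
#'   unique categories.
#' @param path Optional TSV output path.
#' @return Matrix of ln(I), rows = ORFs (category-grouped), columns =
#'   `dose:time` labels; attribute `row_category` carries the grouping.
#' @export
heatmap_export <- function(I_by_dose, orf_categories,
                           category_order = sort(unique(orf_categories)),
                           path = NULL) {
  stopifnot(length(I_by_dose) >= 1L, !is.null(names(I_by_dose)))
  orfs <- rownames(I_by_dose[[1]])
  cats <- orf_categories[orfs]
  ord <- order(match(cats, category_order), orfs)
  blocks <- lapply(names(I_by_dose), function(d) {
    m <- log(I_by_dose[[d]][ord, , drop = FALSE])
    colnames(m) <- paste0(d, ":", seq_len(ncol(m)))
    m
  })
  out <- do.call(cbind, blocks)
  attr(out, "row_category") <- unname(cats[ord])
  if (!is.null(path)) {
    df <- data.frame(orf = rownames(out), category = attr(out, "row_category"),
                     out, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' Rank ORFs by PELI score per dose
#'
#' Within each dose, ORFs are sorted by mean PELI in decreasing order, ties
#' broken lexicographically by ORF id; the stress category rides along.
#'
#' @param records The `records` data frame of a [peli_analysis()] result.
#' @return Data frame with `dose_mgL`, `rank`, `orf`, `peli_mean`,
#'   `category`.
#' @export
rank_profile <- function(records) {
  stopifnot(nrow(records) >= 1L)
  out <- do.call(rbind, lapply(split(records, records$dose_mgL), function(s) {
    o <- order(-s$peli_mean, s$orf)
    data.frame(dose_mgL = s$dose_mgL[o], rank = seq_along(o), orf = s$orf[o],
               peli_mean = s$peli_mean[o], category = s$category[o],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
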