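#' Construct a barcode-array experiment
#'
#' Container for pooled deletion-screen barcode hybridization data: per-probe
#' intensities across arrays, the probe-to-gene map with null-feature flags,
#' and per-array condition metadata.
#'
#' @param intensities Non-negative numeric matrix, probes x arrays.
#' @param probes Data frame with columns `probe_id`, `gene_id` (NA for null
#'   features), `is_null_feature` (logical).
#' @param arrays Data frame with columns `array_id`, `dose_uM`, `generations`,
#'   `arm` (`"treatment"` or `"control"`), `replicate`.
#' @param saturation_ceiling Signal level above which probe intensities are
#'   treated as saturated and winsorized during preprocessing.
#' @return An object of class `array_experiment`.
#' @export
array_experiment <- function(intensities, probes, arrays, saturation_ceiling) {
  intensities <- as.matrix(intensities)
  probes <- as.data.frame(probes, stringsAsFactors = FALSE)
  arrays <- as.data.frame(arrays, stringsAsFactors = FALSE)
  stopifnot(all(c("probe_id", "gene_id", "is_null_feature") %in% names(probes)),
            all(c("array_id", "dose_uM", "generations", "arm", "replicate") %in% names(arrays)))
  if (nrow(probes) != nrow(intensities)) stop("probe table rows must match intensity rows")
  if (nrow(arrays) != ncol(intensities)) stop("array metadata rows must match intensity columns")
  if (any(intensities < 0)) stop("intensities must be non-negative")
  if (any(!is.na(probes$gene_id[probes$is_null_feature]))) {
    stop("null-feature probes must not carry a gene id")
  }
  bad <- setdiff(unique(arrays$arm), c("treatment", "control"))
  if (length(bad)) stop("unknown array arm(s): ", paste(bad, collapse = ", "))
  if (!is.numeric(saturation_ceiling) || saturation_ceiling <= 0) {
    stop("saturation_ceiling must be a positive number")
  }
  rownames(intensities) <- probes$probe_id
  colnames(intensities) <- arrays$array_id
  structure(list(intensities = intensities, probes = probes, arrays = arrays,
                 saturation_ceiling = saturation_ceiling),
            class = "array_experiment")
}

#' @export
print.array_experiment <- function(x, ...) {
  cat("array_experiment:", sum(!x$probes$is_null_feature), "gene probes,",
      sum(x$probes$is_null_feature), "null features,",
      nrow(x$arrays), "arrays\n")
  print(table(arm = x$arrays$arm, generations = x$arrays$generations))
  invisible(x)
}

#' Saturation-adjust, log-transform and background-correct arrays
#'
#' Per array: intensities above the saturation ceiling are winsorized to the
#' ceiling (and counted); signals are log2-transformed after adding a
#' pseudocount; the robust location (median) of the log2 null features is
#' subtracted so the chip background sits at zero; the robust scale
#' (MAD x 1.4826) of the null features is retained as the per-array
#' background scale.
#'
#' @param exp An [array_experiment()].
#' @param pseudocount Added before log2 to avoid -Inf on zero probes; default 1.
#' @return List of class `dssa_preprocessed` with `signal` (gene x array
#'   adjusted log2 matrix, rows named by gene id), `null_scale` (per-array
#'   background MAD scale), `n_winsorized` (per-array count), `arrays`
#'   (metadata carried through).
#' @export
preprocess_arrays <- function(exp, pseudocount = 1) {
  stopifnot(inherits(exp, "array_experiment"))
  is_null <- exp$probes$is_null_feature
  if (!any(is_null)) stop("arrays carry no null features; background cannot be estimated")
  x <- exp$intensities
  if (any(colSums(x) == 0)) {
    stop("all-zero array(s): ",
         paste(colnames(x)[colSums(x) == 0], collapse = ", "))
  }
  winz <- x > exp$saturation_ceiling
  x[winz] <- exp$saturation_ceiling
  lx <- log2(x + pseudocount)
  null_loc <- apply(lx[is_null, , drop = FALSE], 2, stats::median)
  null_scale <- apply(lx[is_null, , drop = FALSE], 2, stats::mad)
  adj <- sweep(lx, 2, null_loc)
  gene <- adj[!is_null, , drop = FALSE]
  rownames(gene) <- exp$probes$gene_id[!is_null]
  structure(list(signal = gene, null_scale = null_scale,
                 n_winsorized = colSums(winz), arrays = exp$arrays),
            class = "dssa_preprocessed")
}

#' Enumerate treatment-control array pairs
#'
#' Matches every treatment array to every control array of the same
#' generation arm (Cartesian pairing), so 3 treatment replicates against 12
#' controls yield 36 pairs per (dose, generations) group.
#'
#' @param arrays Array metadata data frame (or an [array_experiment()]).
#' @param match_generations Require treatment and control generations to
#'   agree (default TRUE; override only for deliberate cross-arm checks).
#' @return Data frame with `pair_id`, `treatment`, `control`, `dose_uM`,
#'   `generations`.
#' @export
build_pairs <- function(arrays, match_generations = TRUE) {
  if (inherits(arrays, "array_experiment")) arrays <- arrays$arrays
  trt <- arrays[arrays$arm == "treatment", , drop = FALSE]
  ctl <- arrays[arrays$arm == "control", , drop = FALSE]
  if (nrow(trt) == 0L) stop("no treatment arrays")
  if (nrow(ctl) == 0L) stop("no control arrays")
  out <- do.call(rbind, lapply(seq_len(nrow(trt)), function(i) {
    c_i <- if (match_generations) ctl[ctl$generations == trt$generations[i], , drop = FALSE] else ctl
    if (nrow(c_i) == 0L) {
      stop("no control arrays for generation arm ", trt$generations[i])
    }
    data.frame(treatment = trt$array_id[i], control = c_i$array_id,
               dose_uM = trt$dose_uM[i], generations = trt$generations[i],
               stringsAsFactors = FALSE)
  }))
  out <- cbind(pair_id = paste(out$treatment, out$control, sep = ":"), out)
  rownames(out) <- NULL
  out
}

#' Lowess-normalize one treatment-control pair
#'
#' Computes per-gene M = log2(treatment) - log2(control) and
#' A = (log2 t + log2 c)/2 and removes the intensity-dependent trend by
#' subtracting a robust lowess fit of M on A (span `span`, 3 robustifying
#' iterations). With fewer than `min_genes` genes the global median of M is
#' subtracted instead and the result flagged.
#'
#' @param t_signal,c_signal Adjusted log2 signals for the same genes on the
#'   treatment and control array.
#' @param span Lowess span, default 0.4.
#' @param min_genes Minimum gene count for lowess; default 30.
#' @return List with `m` (normalized log-ratios, named by gene), `a`,
#'   `lowess_skipped` flag.
#' @export
normalize_pair <- function(t_signal, c_signal, span = 0.4, min_genes = 30) {
  if (length(t_signal) != length(c_signal)) stop("gene sets of the pair differ in length")
  m <- t_signal - c_signal
  a <- (t_signal + c_signal) / 2
  if (length(m) < min_genes) {
    return(list(m = m - stats::median(m), a = a, lowess_skipped = TRUE))
  }
  fit <- stats::lowess(a, m, f = span, iter = 3)
  trend <- stats::approx(fit$x, fit$y, xout = a, rule = 2, ties = mean)$y
  list(m = m - trend, a = a, lowess_skipped = FALSE)
}

#' Alpha-outlier detection on normalized log-ratios
#'
#' Robust-Gaussian outlier calling: the center (median) and scale
#' (MAD x 1.4826) of the m-values define a reference null
#' Normal(center, scale^2); each gene gets a two-sided p-value, q-values are
#' Benjamini-Hochberg, and genes with q <= alpha are called with the sign of
#' their deviation. If the scale is zero no outliers exist and all q = 1.
#'
#' @param m Named vector of normalized log2 ratios for one pair.
#' @param alpha Per-pair call level on the q-value, default 0.05.
#' @return List of class `pair_outlier_result`: data frame `genes`
#'   (`m`, `q_value`, `sign`, `call`), `residual_variance` (robust scale^2),
#'   `alpha`.
#' @export
detect_outliers <- function(m, alpha = 0.05) {
  center <- stats::median(m)
  scale <- stats::mad(m)
  dev <- m - center
  if (scale == 0) {
    q <- rep(1, length(m))
    sgn <- rep(0L, length(m))
  } else {
    p <- 2 * stats::pnorm(-abs(dev) / scale)
    q <- stats::p.adjust(p, method = "BH")
    sgn <- as.integer(sign(dev))
  }
  genes <- data.frame(gene = names(m), m = unname(m), q_value = q, sign = sgn,
                      call = q <= alpha & sgn != 0L, stringsAsFactors = FALSE)
  structure(list(genes = genes, residual_variance = scale^2, alpha = alpha),
            class = "pair_outlier_result")
}

#' Flag effective treatment-control pairs
#'
#' Pairs whose residual variance exceeds the Tukey upper fence
#' (Q3 + 1.5 x IQR over the group's pairs) are marked non-effective, the
#' programmatic analogue of excluding box-plot outliers. Serial correlation
#' in pair-to-pair variability is reported (lag-1 autocorrelation of the
#' residual scale across pair order) but never auto-excludes.
#'
#' @param residual_variances Numeric vector, one per pair, in pair order.
#' @return List with `effective` (logical), `fence` (upper fence used),
#'   `lag1_autocorrelation` of the residual scales (NA with < 3 pairs).
#' @export
select_effective_pairs <- function(residual_variances) {
  v <- residual_variances
  if (length(v) < 4L) stop("at least 4 pairs are required to set an exclusion fence")
  qs <- stats::quantile(v, c(0.25, 0.75), names = FALSE)
  fence <- qs[2] + 1.5 * (qs[2] - qs[1])
  effective <- v <= fence
  if (!any(effective)) stop("all pairs excluded by the variance fence; inspect the group manually")
  s <- sqrt(v)
  lag1 <- if (length(s) >= 3L && stats::sd(s[-length(s)]) > 0 &&
              stats::sd(s[-1]) > 0) {
    stats::cor(s[-length(s)], s[-1])
  } else NA_real_
  list(effective = effective, fence = fence, lag1_autocorrelation = lag1)
}

#' Upper-tail exact binomial probability
#'
#' P(X >= k) for X ~ Binomial(m, pi0); k = 0 gives exactly 1.
#'
#' @param k Successes observed (0..m).
#' @param m Number of trials (effective pairs).
#' @param pi0 Null per-trial success probability.
#' @return Upper-tail probability.
#' @export
binomial_tail <- function(k, m, pi0) {
  stopifnot(k >= 0, k <= m, pi0 > 0, pi0 < 1)
  stats::pbinom(k - 1, m, pi0, lower.tail = FALSE)
}

#' Aggregate per-pair outlier calls into per-gene binomial calls
#'
#' For each gene the dominant sign is the strict majority sign of its
#' m-values over the effective pairs (an exact tie yields no call). A pair is
#' a "success" when the gene is an outlier there (q <= alpha) with the
#' dominant sign. The raw p-value is the upper binomial tail
#' P(X >= k | m, pi0), corrected across genes by Benjamini-Hochberg
#' q-values. In strict mode a call additionally requires success in every
#' effective pair (k = m).
#'
#' @param pair_results List of [detect_outliers()] results for the group's
#'   effective pairs (same gene order in each).
#' @param pi0 Null success probability per pair; default 0.05, the per-pair
#'   call level.
#' @param alpha_q Q-value threshold for a gene call; default 0.05.
#' @param strict Require k = m (default TRUE, the simultaneous-success rule);
#'   FALSE calls on the binomial tail alone.
#' @return Data frame with `gene`, `k`, `m`, `p`, `q`, `sign`, `called`.
#' @export
gene_binomial_calls <- function(pair_results, pi0 = 0.05, alpha_q = 0.05,
                                strict = TRUE) {
  stopifnot(length(pair_results) >= 1L, pi0 > 0, pi0 < 1)
  genes <- pair_results[[1]]$genes$gene
  sig <- vapply(pair_results, function(r) r$genes$call, logical(length(genes)))
  sgn <- vapply(pair_results, function(r) r$genes$sign, integer(length(genes)))
  m_pairs <- length(pair_results)
  sig <- matrix(sig, nrow = length(genes))
  sgn <- matrix(sgn, nrow = length(genes))
  n_pos <- rowSums(sgn > 0)
  n_neg <- rowSums(sgn < 0)
  dominant <- ifelse(n_pos > n_neg, 1L, ifelse(n_neg > n_pos, -1L, 0L))
  k <- rowSums(sig & sgn == dominant & dominant != 0L)
  p <- vapply(k, binomial_tail, 0, m = m_pairs, pi0 = pi0)
  p[dominant == 0L] <- 1
  q <- stats::p.adjust(p, method = "BH")
  called <- q <= alpha_q & dominant != 0L
  if (strict) called <- called & k == m_pairs
  data.frame(gene = genes, k = as.integer(k), m = m_pairs, p = p, q = q,
             sign = dominant, called = called, stringsAsFactors = FALSE)
}

#' Per-gene fitness scores
#'
#' Mean adjusted log2 signal over exposed arrays minus the mean over control
#' arrays. Negative scores mark strains that grow worse under exposure
#' (sensitive, gene required for tolerance); positive scores mark resistant
#' strains.
#'
#' @param signal Adjusted log2 gene x array matrix from
#'   [preprocess_arrays()].
#' @param exposed_ids,control_ids Column (array) ids of the exposed and
#'   control arrays.
#' @return Named numeric vector of per-gene scores (log2 units).
#' @export
fitness_scores <- function(signal, exposed_ids, control_ids) {
  if (length(exposed_ids) < 1L || length(control_ids) < 1L) {
    stop("at least one exposed and one control array are required")
  }
  miss <- setdiff(c(exposed_ids, control_ids), colnames(signal))
  if (length(miss)) stop("arrays missing from signal matrix: ", paste(miss, collapse = ", "))
  rowMeans(signal[, exposed_ids, drop = FALSE]) -
    rowMeans(signal[, control_ids, drop = FALSE])
}

#' Run the full differential strain sensitivity analysis
#'
#' Orchestrates preprocessing, treatment-control pairing, lowess pair
#' normalization, alpha-outlier detection, effective-pair selection, exact
#' binomial aggregation with q-value correction, and fitness scoring, per
#' (dose, generations) condition.
#'
#' @param exp An [array_experiment()].
#' @param span,alpha,pi0,alpha_q,strict,pseudocount Stage parameters; see
#'   [normalize_pair()], [detect_outliers()], [gene_binomial_calls()],
#'   [preprocess_arrays()].
#' @param pi0_empirical Use the observed mean per-pair call rate as the
#'   binomial null probability instead of `pi0`? Default FALSE.
#' @return List of class `dssa_result`: `calls` data frame (`gene`,
#'   `condition`, `dose_uM`, `generations`, `k`, `m`, `p`, `q`,
#'   `fitness_score`, `label`), `pair_info` (per-pair residual variance and
#'   effectiveness), `preprocessed`.
#' @export
dssa <- function(exp, span = 0.4, alpha = 0.05, pi0 = 0.05, alpha_q = 0.05,
                 strict = TRUE, pseudocount = 1, pi0_empirical = FALSE) {
  pre <- preprocess_arrays(exp, pseudocount = pseudocount)
  pairs <- build_pairs(exp)
  conds <- unique(pairs[, c("dose_uM", "generations")])
  all_calls <- list()
  pair_info <- list()
  for (ci in seq_len(nrow(conds))) {
    d <- conds$dose_uM[ci]; g <- conds$generations[ci]
    cp <- pairs[pairs$dose_uM == d & pairs$generations == g, , drop = FALSE]
    outl <- lapply(seq_len(nrow(cp)), function(i) {
      nm <- normalize_pair(pre$signal[, cp$treatment[i]],
                           pre$signal[, cp$control[i]], span = span)
      detect_outliers(nm$m, alpha = alpha)
    })
    rv <- vapply(outl, `[[`, 0, "residual_variance")
    eff <- select_effective_pairs(rv)
    eff_outl <- outl[eff$effective]
    pi0_use <- if (pi0_empirical) {
      max(1e-6, mean(vapply(eff_outl, function(r) mean(r$genes$call), 0)))
    } else pi0
    calls <- gene_binomial_calls(eff_outl, pi0 = pi0_use, alpha_q = alpha_q,
                                 strict = strict)
    trt_ids <- unique(cp$treatment)
    ctl_ids <- unique(cp$control)
    fs <- fitness_scores(pre$signal, trt_ids, ctl_ids)
    calls$fitness_score <- unname(fs[calls$gene])
    calls$label <- ifelse(calls$called & calls$fitness_score < 0, "sensitive",
                          ifelse(calls$called & calls$fitness_score > 0,
                                 "resistant", "none"))
    calls$condition <- paste0(d, "uM_", g, "G")
    calls$dose_uM <- d
    calls$generations <- g
    all_calls[[ci]] <- calls
    pair_info[[ci]] <- data.frame(cp, residual_variance = rv,
                                  effective = eff$effective,
                                  stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, all_calls)
  calls <- calls[, c("gene", "condition", "dose_uM", "generations", "k", "m",
                     "p", "q", "sign", "fitness_score", "label", "called")]
  structure(list(calls = calls, pair_info = do.call(rbind, pair_info),
                 preprocessed = pre),
            class = "dssa_result")
}

#' Summarize gene calls across conditions
#'
#' Per-condition sensitive/resistant counts, union counts over all
#' conditions, genes called in at least `min_conditions` conditions, and the
#' overlap between generation arms.
#'
#' @param calls The `calls` data frame of a [dssa()] result (or any data
#'   frame with `gene`, `condition`, `generations`, `label`).
#' @param min_conditions Threshold for the recurrence table; default 3.
#' @return List with `per_condition`, `union_counts`, `recurrent`,
#'   `generation_overlap`.
#' @export
summarize_conditions <- function(calls, min_conditions = 3) {
  called <- calls[calls$label %in% c("sensitive", "resistant"), , drop = FALSE]
  conds <- unique(calls$condition)
  per_condition <- do.call(rbind, lapply(conds, function(cc) {
    sub <- called[called$condition == cc, , drop = FALSE]
    data.frame(condition = cc,
               sensitive = sum(sub$label == "sensitive"),
               resistant = sum(sub$label == "resistant"),
               stringsAsFactors = FALSE)
  }))
  union_counts <- c(
    sensitive = length(unique(called$gene[called$label == "sensitive"])),
    resistant = length(unique(called$gene[called$label == "resistant"])))
  recurrent <- if (nrow(called)) {
    counts <- tapply(called$condition, list(called$gene, called$label),
                     function(x) length(unique(x)))
    counts[is.na(counts)] <- 0
    data.frame(
      label = colnames(counts)[col(counts)][counts >= min_conditions],
      gene = rownames(counts)[row(counts)][counts >= min_conditions],
      n_conditions = counts[counts >= min_conditions],
      stringsAsFactors = FALSE)
  } else data.frame(label = character(), gene = character(), n_conditions = integer())
  gens <- split(called$gene, called$generations)
  gens <- lapply(gens, unique)
  generation_overlap <- if (length(gens) == 2L) {
    list(only_first = setdiff(gens[[1]], gens[[2]]),
         only_second = setdiff(gens[[2]], gens[[1]]),
         both = intersect(gens[[1]], gens[[2]]))
  } else gens
  list(per_condition = per_condition, union_counts = union_counts,
       recurrent = recurrent, generation_overlap = generation_overlap)
}
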