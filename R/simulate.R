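#' Configuration for a synthetic pooled deletion screen
#'
#' Defines the conditions of a simulated competitive-growth barcode screen:
#' strain count, null features, growth generations, doses, planted selection
#' coefficients, replicate/control structure and the saturating
#' hybridization model.
#'
#' Strain abundances start from a lognormal pool composition and grow
#' competitively: a strain with selection coefficient s multiplies by
#' 2^(g (1 - s)) over g generations (s > 0: fitness deficit under exposure,
#' expected sensitive call; s < 0: gain, resistant). Abundances are
#' renormalized to relative abundance, mapped through a saturating
#' (Michaelis-type) hybridization response with the given asymptote and
#' half-saturation constant, and multiplied by lognormal measurement noise.
#' Null features are drawn from the lognormal chip background.
#'
#' @param n_strains Number of deletion strains; default 4000.
#' @param n_null_features Number of background-only probes; default 2000.
#' @param generations Growth generations, 5 or 15; default 5.
#' @param doses Exposure doses (uM); default `c(82.5, 165, 330)`.
#' @param selection Named numeric vector (gene -> s, |s| < 1); genes not
#'   named are neutral. Default none planted.
#' @param replicates Treatment arrays per dose; default 3.
#' @param controls Control arrays per generation arm; default 12.
#' @param dose_scaling `"proportional"` scales s by dose/max(doses);
#'   `"threshold"` applies full s at any positive dose (the sharp threshold
#'   response regime); default `"proportional"`.
#' @param abundance_sdlog Lognormal spread of the starting pool composition;
#'   default 0.5.
#' @param hybridization List: `asymptote` (signal units, default 16384),
#'   `half_saturation` (abundance units; default 4 x mean relative
#'   abundance), `noise_sdlog` (default 0.1), `background_meanlog`
#'   (default log(64)), `background_sdlog` (default 0.4),
#'   `saturation_ceiling` (default 0.41 x asymptote, near the upper
#'   percentiles of the simulated signals so the winsorization path is
#'   exercised).
#' @param seed Mandatory integer seed.
#' @return Object of class `pool_sim_config`.
#' @export
pool_sim_config <- function(n_strains = 4000, n_null_features = 2000,
                            generations = 5, doses = c(82.5, 165, 330),
                            selection = numeric(), replicates = 3,
                            controls = 12,
                            dose_scaling = c("proportional", "threshold"),
                            abundance_sdlog = 0.5,
                            hybridization = list(), seed) {
  if (missing(seed)) stop("seed is mandatory in the simulation config")
  stopifnot(n_strains >= 1, n_null_features >= 1,
            generations %in% c(5, 15), all(doses > 0),
            replicates >= 1, controls >= 1)
  if (length(selection) && (is.null(names(selection)) || any(abs(selection) >= 1))) {
    stop("selection must be a named vector with |s| < 1")
  }
  dose_scaling <- match.arg(dose_scaling)
  h <- utils::modifyList(list(asymptote = 16384,
                              half_saturation = 4 / n_strains,
                              noise_sdlog = 0.1,
                              background_meanlog = log(64),
                              background_sdlog = 0.4,
                              saturation_ceiling = NULL), hybridization)
  if (is.null(h$saturation_ceiling)) h$saturation_ceiling <- 0.41 * h$asymptote
  structure(list(n_strains = n_strains, n_null_features = n_null_features,
                 generations = generations, doses = doses,
                 selection = selection, replicates = replicates,
                 controls = controls, dose_scaling = dose_scaling,
                 abundance_sdlog = abundance_sdlog, hybridization = h,
                 seed = as.integer(seed)),
            class = "pool_sim_config")
}

#' Simulate a pooled deletion-screen barcode experiment
#'
#' Generates treatment and control arrays under the competitive-growth and
#' hybridization model of [pool_sim_config()], together with a ground-truth
#' table of planted selection coefficients and expected call labels.
#'
#' @param cfg A [pool_sim_config()].
#' @return List with `experiment` (an [array_experiment()]) and `truth`
#'   (data frame `gene`, `s`, `expected_label`).
#' @export
simulate_pool_screen <- function(cfg) {
  stopifnot(inherits(cfg, "pool_sim_config"))
  set.seed(cfg$seed)
  genes <- sprintf("GENE%04d", seq_len(cfg$n_strains))
  s <- stats::setNames(numeric(cfg$n_strains), genes)
  if (length(cfg$selection)) {
    unknown <- setdiff(names(cfg$selection), genes)
    if (length(unknown)) stop("selection names not among simulated genes: ",
                              paste(utils::head(unknown, 5), collapse = ", "))
    s[names(cfg$selection)] <- cfg$selection
  }
  a0 <- stats::rlnorm(cfg$n_strains, sdlog = cfg$abundance_sdlog)
  a0 <- a0 / sum(a0)
  h <- cfg$hybridization
  g <- cfg$generations

  hybridize <- function(rel_abundance, n_arrays) {
    sig <- h$asymptote * rel_abundance / (rel_abundance + h$half_saturation)
    vapply(seq_len(n_arrays), function(i) {
      gene_sig <- sig * stats::rlnorm(length(sig), sdlog = h$noise_sdlog)
      null_sig <- stats::rlnorm(cfg$n_null_features,
                                meanlog = h$background_meanlog,
                                sdlog = h$background_sdlog)
      c(gene_sig, null_sig)
    }, numeric(length(sig) + cfg$n_null_features))
  }

  cols <- list(); meta <- list()
  for (d in cfg$doses) {
    s_eff <- if (cfg$dose_scaling == "proportional") s * d / max(cfg$doses) else s
    a <- a0 * 2^(g * (1 - s_eff))
    a <- a / sum(a)
    sig <- hybridize(a, cfg$replicates)
    colnames(sig) <- sprintf("T_%g_%dG_r%d", d, g, seq_len(cfg$replicates))
    cols[[length(cols) + 1L]] <- sig
    meta[[length(meta) + 1L]] <- data.frame(
      array_id = colnames(sig), dose_uM = d, generations = g,
      arm = "treatment", replicate = seq_len(cfg$replicates),
      stringsAsFactors = FALSE)
  }
  a_ctl <- a0 * 2^g
  a_ctl <- a_ctl / sum(a_ctl)
  sig <- hybridize(a_ctl, cfg$controls)
  colnames(sig) <- sprintf("C_%dG_r%d", g, seq_len(cfg$controls))
  cols[[length(cols) + 1L]] <- sig
  meta[[length(meta) + 1L]] <- data.frame(
    array_id = colnames(sig), dose_uM = 0, generations = g, arm = "control",
    replicate = seq_len(cfg$controls), stringsAsFactors = FALSE)

  intensities <- do.call(cbind, cols)
  probes <- data.frame(
    probe_id = c(genes, sprintf("NULL%05d", seq_len(cfg$n_null_features))),
    gene_id = c(genes, rep(NA_character_, cfg$n_null_features)),
    is_null_feature = rep(c(FALSE, TRUE), c(cfg$n_strains, cfg$n_null_features)),
    stringsAsFactors = FALSE)
  exp <- array_experiment(intensities, probes, do.call(rbind, meta),
                          saturation_ceiling = h$saturation_ceiling)
  truth <- data.frame(gene = genes, s = unname(s),
                      expected_label = ifelse(s > 0, "sensitive",
                                              ifelse(s < 0, "resistant", "none")),
                      stringsAsFactors = FALSE)
  list(experiment = exp, truth = truth)
}

#' Configuration for a synthetic GFP reporter plate
#'
#' @param orfs Data frame with columns `orf`, `category`.
#' @param I_star True induction factors: matrix (ORFs x doses) or a vector
#'   recycled across doses. All values > 0.
#' @param doses Exposure doses (mg/L); default 10.
#' @param replicates Triplicate by default.
#' @param times Time grid in minutes; default every 5 min over 2 h.
#' @param growth List `r` (per-minute logistic rate, default 0.008), `K`
#'   (carrying capacity OD, default 1.2), `od0` (inoculum OD, default 0.3).
#' @param p_base GFP fluorescence per OD unit at baseline expression;
#'   default 1000.
#' @param od_bg,gfp_bg Medium background levels; defaults 0.04 and 50.
#' @param sigma_od,sigma_gfp Multiplicative Gaussian noise SDs; default 0.02.
#' @param profile Optional function `(t_minutes, i_star)` returning the
#'   induction profile I*(t); default constant `i_star`.
#' @param n_medium Medium-control wells per dose; default 3.
#' @param seed Mandatory integer seed.
#' @return Object of class `reporter_sim_config`.
#' @export
reporter_sim_config <- function(orfs, I_star, doses = 10, replicates = 3,
                                times = seq(0, 120, by = 5),
                                growth = list(r = 0.008, K = 1.2, od0 = 0.3),
                                p_base = 1000, od_bg = 0.04, gfp_bg = 50,
                                sigma_od = 0.02, sigma_gfp = 0.02,
                                profile = NULL, n_medium = 3, seed) {
  if (missing(seed)) stop("seed is mandatory in the simulation config")
  orfs <- as.data.frame(orfs, stringsAsFactors = FALSE)
  stopifnot(all(c("orf", "category") %in% names(orfs)), all(doses > 0),
            replicates >= 1)
  I_star <- matrix(I_star, nrow = nrow(orfs), ncol = length(doses))
  if (any(I_star <= 0)) stop("true induction factors must be positive")
  growth <- utils::modifyList(list(r = 0.008, K = 1.2, od0 = 0.3), growth)
  structure(list(orfs = orfs, I_star = I_star, doses = doses,
                 replicates = replicates, times = times, growth = growth,
                 p_base = p_base, od_bg = od_bg, gfp_bg = gfp_bg,
                 sigma_od = sigma_od, sigma_gfp = sigma_gfp,
                 profile = profile, n_medium = n_medium,
                 seed = as.integer(seed)),
            class = "reporter_sim_config")
}

#' Simulate a GFP stress-reporter plate
#'
#' OD follows logistic growth; vehicle-well GFP tracks baseline expression
#' (`p_base` per OD unit); experiment-well GFP is scaled by the ORF's true
#' induction profile I*(t). Both channels sit on the medium background and
#' carry multiplicative Gaussian noise. The ground truth is the time-average
#' of I*(t), i.e. the PELI an ideal pipeline recovers.
#'
#' @param cfg A [reporter_sim_config()].
#' @return List with `plate` (a [reporter_plate()]) and `truth` (data frame
#'   `orf`, `dose_mgL`, `true_peli`).
#' @export
simulate_reporter_plate <- function(cfg) {
  stopifnot(inherits(cfg, "reporter_sim_config"))
  set.seed(cfg$seed)
  t <- cfg$times
  gr <- cfg$growth
  od_true <- gr$K / (1 + ((gr$K - gr$od0) / gr$od0) * exp(-gr$r * t))
  prof <- if (is.null(cfg$profile)) function(tt, i) rep(i, length(tt)) else cfg$profile
  n_t <- length(t)
  wells <- list(); od <- list(); gfp <- list()
  add_well <- function(id, orf, cat, dose, role, rep_id, i_star) {
    I_t <- prof(t, i_star)
    od_m <- cfg$od_bg + od_true * (1 + stats::rnorm(n_t, 0, cfg$sigma_od))
    gfp_m <- cfg$gfp_bg + I_t * cfg$p_base * od_true *
      (1 + stats::rnorm(n_t, 0, cfg$sigma_gfp))
    wells[[length(wells) + 1L]] <<- data.frame(
      well = id, orf = orf, stress_category = cat, dose_mgL = dose,
      role = role, replicate = rep_id, stringsAsFactors = FALSE)
    od[[length(od) + 1L]] <<- od_m
    gfp[[length(gfp) + 1L]] <<- gfp_m
  }
  truth <- list()
  for (di in seq_along(cfg$doses)) {
    d <- cfg$doses[di]
    for (oi in seq_len(nrow(cfg$orfs))) {
      orf <- cfg$orfs$orf[oi]; cat <- cfg$orfs$category[oi]
      i_star <- cfg$I_star[oi, di]
      for (r in seq_len(cfg$replicates)) {
        add_well(sprintf("E_%s_%g_r%d", orf, d, r), orf, cat, d,
                 "experiment", r, i_star)
      }
      I_t <- prof(t, i_star)
      truth[[length(truth) + 1L]] <- data.frame(
        orf = orf, dose_mgL = d,
        true_peli = sum(diff(t) * (I_t[-1] + I_t[-n_t]) / 2) / (t[n_t] - t[1]),
        stringsAsFactors = FALSE)
    }
    for (m in seq_len(cfg$n_medium)) {
      wells[[length(wells) + 1L]] <- data.frame(
        well = sprintf("M_%g_%d", d, m), orf = NA_character_,
        stress_category = NA_character_, dose_mgL = d, role = "medium-control",
        replicate = m, stringsAsFactors = FALSE)
      od[[length(od) + 1L]] <- cfg$od_bg * (1 + stats::rnorm(n_t, 0, cfg$sigma_od))
      gfp[[length(gfp) + 1L]] <- cfg$gfp_bg * (1 + stats::rnorm(n_t, 0, cfg$sigma_gfp))
    }
  }
  for (oi in seq_len(nrow(cfg$orfs))) {
    orf <- cfg$orfs$orf[oi]; cat <- cfg$orfs$category[oi]
    for (r in seq_len(cfg$replicates)) {
      add_well(sprintf("V_%s_r%d", orf, r), orf, cat, 0,
               "vehicle-control", r, 1)
    }
  }
  for (m in seq_len(cfg$n_medium)) {
    wells[[length(wells) + 1L]] <- data.frame(
      well = sprintf("M_0_%d", m), orf = NA_character_,
      stress_category = NA_character_, dose_mgL = 0, role = "medium-control",
      replicate = m, stringsAsFactors = FALSE)
    od[[length(od) + 1L]] <- cfg$od_bg * (1 + stats::rnorm(n_t, 0, cfg$sigma_od))
    gfp[[length(gfp) + 1L]] <- cfg$gfp_bg * (1 + stats::rnorm(n_t, 0, cfg$sigma_gfp))
  }
  plate <- reporter_plate(t, do.call(rbind, od), do.call(rbind, gfp),
                          do.call(rbind, wells))
  list(plate = plate, truth = do.call(rbind, truth))
}

#' Simulate Hill-type dose-dependent growth inhibition
#'
#' Growth curves share a logistic time shape; the plateau is scaled by the
#' Hill inhibition fraction f(d) = d^h / (d^h + IC50^h), so the true ICx is
#' available in closed form (IC20 = IC50 (0.2/0.8)^(1/h)). Plates carry
#' blank wells at the medium background and additive Gaussian read noise.
#'
#' @param hill List `ic50` (uM), `slope` (Hill coefficient h), `od_max`
#'   (uninhibited plateau OD), `rate` (logistic rate per hour, default 0.6),
#'   `t_mid` (inflection time in hours, default 8).
#' @param doses Doses in uM, including 0; default
#'   `c(0, 75, 150, 300, 600, 1200, 2400)`.
#' @param replicates Wells per dose; default 3.
#' @param times Time grid in hours; default every 15 min over 24 h.
#' @param od0 Inoculum OD; default 0.0165.
#' @param blank_od Medium background OD; default 0.04.
#' @param noise_sd Additive read noise SD; default 0.01.
#' @param n_blanks Blank wells; default 3.
#' @param seed Mandatory integer seed.
#' @return List with `curves` (a [growth_curve_set()] including blanks) and
#'   `true_ic20` (uM, Hill closed form).
#' @export
simulate_growth_doseresponse <- function(hill = list(ic50 = 600, slope = 2,
                                                     od_max = 1, rate = 0.6,
                                                     t_mid = 8),
                                         doses = c(0, 75, 150, 300, 600, 1200, 2400),
                                         replicates = 3,
                                         times = seq(0, 24, by = 0.25),
                                         od0 = 0.0165, blank_od = 0.04,
                                         noise_sd = 0.01, n_blanks = 3, seed) {
  if (missing(seed)) stop("seed is mandatory")
  hill <- utils::modifyList(list(ic50 = 600, slope = 2, od_max = 1,
                                 rate = 0.6, t_mid = 8), hill)
  stopifnot(hill$ic50 > 0, hill$slope > 0, hill$od_max > od0)
  set.seed(as.integer(seed))
  shape <- 1 / (1 + exp(-hill$rate * (times - hill$t_mid)))
  f <- function(d) d^hill$slope / (d^hill$slope + hill$ic50^hill$slope)
  wells <- list(); od <- list()
  for (d in doses) {
    plateau <- od0 + (hill$od_max - od0) * (1 - f(d))
    curve <- od0 + (plateau - od0) * shape
    for (r in seq_len(replicates)) {
      wells[[length(wells) + 1L]] <- data.frame(
        well = sprintf("S_%g_r%d", d, r), strain = "WT", dose_uM = d,
        replicate = r, role = "sample", stringsAsFactors = FALSE)
      od[[length(od) + 1L]] <- blank_od + curve +
        stats::rnorm(length(times), 0, noise_sd)
    }
  }
  for (b in seq_len(n_blanks)) {
    wells[[length(wells) + 1L]] <- data.frame(
      well = sprintf("B_%d", b), strain = NA_character_, dose_uM = 0,
      replicate = b, role = "blank", stringsAsFactors = FALSE)
    od[[length(od) + 1L]] <- blank_od + stats::rnorm(length(times), 0, noise_sd)
  }
  curves <- growth_curve_set(times, do.call(rbind, od), do.call(rbind, wells))
  list(curves = curves,
       true_ic20 = hill$ic50 * (0.2 / 0.8)^(1 / hill$slope))
}
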