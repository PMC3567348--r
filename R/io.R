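read_tsv_checked <- function(path) {
  df <- tryCatch(
    utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop("cannot read ", path, ": ", conditionMessage(e)))
  if (nrow(df) == 0L) stop("empty table: ", path)
  df
}

require_numeric <- function(df, cols, path) {
  for (cc in cols) {
    v <- df[[cc]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad)) {
        stop("non-numeric value in column '", cc, "' of ", path,
             " at data line ", bad[1], " ('", v[bad[1]], "')")
      }
      df[[cc]] <- num
    }
  }
  df
}

#' Read a plate-reader table and well map
#'
#' Growth plates are wide tab-delimited tables (first column `time_min`, one
#' column per well) with a well map `well, strain, dose_uM, replicate, role`.
#' Reporter plates are long tables `well, time_min, od, gfp` with a well map
#' `well, orf, stress_category, dose_mgL, role, replicate`. Times are
#' converted from minutes to hours for growth plates and kept in minutes for
#' reporter plates.
#'
#' @param path Plate table path.
#' @param well_map_path Well-map path.
#' @param type `"growth"` or `"reporter"`.
#' @return A [growth_curve_set()] or [reporter_plate()].
#' @export
read_plate_table <- function(path, well_map_path, type = c("growth", "reporter")) {
  type <- match.arg(type)
  tab <- read_tsv_checked(path)
  map <- read_tsv_checked(well_map_path)
  if (type == "growth") {
    if (names(tab)[1] != "time_min") stop("first column of ", path, " must be time_min")
    tab <- require_numeric(tab, names(tab), path)
    dup <- which(duplicated(tab$time_min))
    if (length(dup)) stop("duplicated time row in ", path, " at data line ", dup[1])
    wells <- setdiff(names(tab), "time_min")
    missing_wells <- setdiff(wells, map$well)
    if (length(missing_wells)) {
      stop("wells missing from well map: ", paste(missing_wells, collapse = ", "))
    }
    map <- map[match(wells, map$well), , drop = FALSE]
    od <- t(as.matrix(tab[, wells, drop = FALSE]))
    growth_curve_set(tab$time_min / 60, od, map)
  } else {
    req <- c("well", "time_min", "od", "gfp")
    miss <- setdiff(req, names(tab))
    if (length(miss)) stop(path, " missing columns: ", paste(miss, collapse = ", "))
    tab <- require_numeric(tab, c("time_min", "od", "gfp"), path)
    dup <- which(duplicated(tab[, c("well", "time_min")]))
    if (length(dup)) {
      stop("duplicated (well, time) row in ", path, " at data line ", dup[1])
    }
    times <- sort(unique(tab$time_min))
    wells <- unique(tab$well)
    missing_wells <- setdiff(wells, map$well)
    if (length(missing_wells)) {
      stop("wells missing from well map: ", paste(missing_wells, collapse = ", "))
    }
    map <- map[match(wells, map$well), , drop = FALSE]
    shape <- function(col) {
      m <- matrix(NA_real_, length(wells), length(times),
                  dimnames = list(wells, NULL))
      m[cbind(match(tab$well, wells), match(tab$time_min, times))] <- tab[[col]]
      if (anyNA(m)) stop("incomplete time grid for well(s): ",
                         paste(utils::head(wells[rowSums(is.na(m)) > 0], 5), collapse = ", "))
      m
    }
    reporter_plate(times, shape("od"), shape("gfp"), map)
  }
}

#' Write a growth-curve set as a plate table and well map
#'
#' @param gcs A [growth_curve_set()].
#' @param path,well_map_path Output paths.
#' @export
write_plate_table <- function(gcs, path, well_map_path) {
  tab <- data.frame(time_min = gcs$times * 60, t(gcs$od), check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(gcs$wells[, c("well", "strain", "dose_uM", "replicate", "role")],
                     well_map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a reporter plate in long format with its well map
#'
#' @param plate A [reporter_plate()].
#' @param path,well_map_path Output paths.
#' @export
write_reporter_table <- function(plate, path, well_map_path) {
  n_t <- length(plate$times)
  long <- data.frame(
    well = rep(plate$wells$well, each = n_t),
    time_min = rep(plate$times, nrow(plate$od)),
    od = as.vector(t(plate$od)),
    gfp = as.vector(t(plate$gfp)))
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    plate$wells[, c("well", "orf", "stress_category", "dose_mgL", "role", "replicate")],
    well_map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a barcode-array intensity table and metadata
#'
#' The array table is tab-delimited with columns `probe_id`, `gene_id`
#' (empty or `NULL` for null features), `is_null_feature`, then one column
#' per array. Metadata: `array_id, dose_uM, generations, arm, replicate`.
#'
#' @param path Array table path.
#' @param metadata_path Metadata path.
#' @param saturation_ceiling Passed to [array_experiment()].
#' @return An [array_experiment()].
#' @export
read_array_table <- function(path, metadata_path, saturation_ceiling) {
  tab <- read_tsv_checked(path)
  meta <- read_tsv_checked(metadata_path)
  req <- c("probe_id", "gene_id", "is_null_feature")
  miss <- setdiff(req, names(tab))
  if (length(miss)) stop(path, " missing columns: ", paste(miss, collapse = ", "))
  array_cols <- setdiff(names(tab), req)
  not_in_meta <- setdiff(array_cols, meta$array_id)
  if (length(not_in_meta)) {
    stop("array(s) in table missing from metadata: ",
         paste(not_in_meta, collapse = ", "))
  }
  meta <- meta[match(array_cols, meta$array_id), , drop = FALSE]
  tab <- require_numeric(tab, array_cols, path)
  intens <- as.matrix(tab[, array_cols, drop = FALSE])
  if (any(intens < 0)) stop("negative intensity in ", path)
  gene_id <- tab$gene_id
  gene_id[gene_id %in% c("", "NULL", "NA")] <- NA_character_
  probes <- data.frame(probe_id = tab$probe_id, gene_id = gene_id,
                       is_null_feature = as.logical(tab$is_null_feature),
                       stringsAsFactors = FALSE)
  array_experiment(intens, probes, meta, saturation_ceiling)
}

#' Write an array experiment as a table and metadata file
#'
#' @param exp An [array_experiment()].
#' @param path,metadata_path Output paths.
#' @export
write_array_table <- function(exp, path, metadata_path) {
  gene_id <- exp$probes$gene_id
  gene_id[is.na(gene_id)] <- "NULL"
  tab <- data.frame(probe_id = exp$probes$probe_id, gene_id = gene_id,
                    is_null_feature = exp$probes$is_null_feature,
                    exp$intensities, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(exp$arrays, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

write_tsv_atomic <- function(df, path) {
  tmp <- tempfile(tmpdir = dirname(path))
  utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

#' Run one analysis pipeline end to end
#'
#' Thin orchestration over the module functions: reads the inputs named in
#' the config, runs the requested stage, and writes tab-delimited results
#' plus a JSON run manifest (package version, seed, config echo) next to
#' them. Configs are plain lists or YAML files.
#'
#' Modes: `"growth"` (plate -> AUC/inhibition profile and ICx per strain),
#' `"dssa"` (array table -> gene-call and condition-summary tables),
#' `"enrich"` (GMT + gene lists -> enrichment table), `"peli"` (reporter
#' plate -> PELI, heat-map and rank tables), `"simulate"` (write synthetic
#' screen inputs).
#'
#' @param config List or YAML path. Common fields: `out_dir`, `seed`.
#'   Mode-specific fields: see the vignette.
#' @param mode One of `"growth"`, `"dssa"`, `"enrich"`, `"peli"`,
#'   `"simulate"`.
#' @return Invisibly, a character vector of files written.
#' @export
run_pipeline <- function(config, mode = c("growth", "dssa", "enrich", "peli",
                                          "simulate")) {
  mode <- match.arg(mode)
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config), !is.null(config$out_dir))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- character()
  emit <- function(df, name) {
    p <- file.path(config$out_dir, name)
    write_tsv_atomic(df, p)
    out <<- c(out, p)
  }
  cfg_val <- function(name, default) {
    if (!is.null(config[[name]])) config[[name]] else default
  }

  if (mode == "growth") {
    gcs <- read_plate_table(config$plate, config$well_map, type = "growth")
    avg <- correct_and_average(gcs)
    samp <- gcs$wells$role == "sample"
    aucs <- data.frame(
      strain = gcs$wells$strain[samp], dose_uM = gcs$wells$dose_uM[samp],
      auc = apply(gcs$od[samp, , drop = FALSE] -
                    rep(colMeans(gcs$od[gcs$wells$role == "blank", , drop = FALSE]),
                        each = sum(samp)), 1,
                  function(v) auc(gcs$times, pmax(v, 0))))
    rows <- lapply(split(aucs, aucs$strain), function(s) {
      prof <- inhibition_profile(s[, c("dose_uM", "auc")])
      data.frame(strain = s$strain[1], prof, stringsAsFactors = FALSE)
    })
    profile_tab <- do.call(rbind, rows)
    emit(profile_tab, "dose_response.tsv")
    icx_target <- cfg_val("icx_target", 20)
    icx_rows <- lapply(split(profile_tab, profile_tab$strain), function(s) {
      est <- estimate_icx(s, icx_target)
      data.frame(strain = s$strain[1], x = est$x,
                 concentration = est$concentration,
                 extrapolated = est$extrapolated, stringsAsFactors = FALSE)
    })
    emit(do.call(rbind, icx_rows), "icx.tsv")
  } else if (mode == "dssa") {
    exp <- read_array_table(config$array_table, config$array_metadata,
                            saturation_ceiling = cfg_val("saturation_ceiling", 16384))
    res <- dssa(exp,
                span = cfg_val("lowess_span", 0.4),
                alpha = cfg_val("alpha", 0.05),
                pi0 = cfg_val("pi0", 0.05),
                alpha_q = cfg_val("alpha_q", 0.05),
                strict = cfg_val("strict", TRUE))
    emit(res$calls[, c("gene", "condition", "k", "m", "p", "q",
                       "fitness_score", "label")], "gene_calls.tsv")
    summ <- summarize_conditions(res$calls,
                                 min_conditions = cfg_val("min_conditions", 3))
    emit(summ$per_condition, "condition_counts.tsv")
    emit(res$pair_info, "pair_info.tsv")
  } else if (mode == "enrich") {
    test_set <- readLines(config$test_set, warn = FALSE)
    test_set <- test_set[nzchar(trimws(test_set))]
    reference <- cfg_val("reference", "universe")
    if (!identical(reference, "universe")) {
      reference <- readLines(reference, warn = FALSE)
      reference <- reference[nzchar(trimws(reference))]
      # a custom reference defines the assay universe together with the GMT
      db <- read_gmt(config$gmt)
      db <- annotation_db(db$categories,
                          universe = union(db$universe, reference),
                          names = db$names)
    } else {
      db <- read_gmt(config$gmt)
    }
    res <- enrich(test_set, db, reference = reference,
                  threshold = cfg_val("threshold", 0.01))
    res$display_p <- display_p(res$p)
    emit(res, "enrichment.tsv")
  } else if (mode == "peli") {
    plate <- read_plate_table(config$plate, config$well_map, type = "reporter")
    res <- peli_analysis(plate, cutoff = cfg_val("peli_cutoff", 1.5))
    emit(res$records, "peli.tsv")
    emit(rank_profile(res$records), "rank_profile.tsv")
    w <- res$records
    I_mean <- do.call(rbind, lapply(split(seq_len(nrow(res$induction)),
                                          sub("^E_([^_]+)_.*$", "\\1", rownames(res$induction))),
                                    function(i) colMeans(res$induction[i, , drop = FALSE])))
    hm <- data.frame(orf = rownames(I_mean), log(I_mean), check.names = FALSE)
    emit(hm, "heatmap_lnI.tsv")
  } else if (mode == "simulate") {
    if (is.null(config$seed)) stop("seed is mandatory for simulation")
    cfg <- pool_sim_config(
      n_strains = cfg_val("n_strains", 4000),
      n_null_features = cfg_val("n_null_features", 2000),
      generations = cfg_val("generations", 5),
      doses = cfg_val("doses", c(82.5, 165, 330)),
      replicates = cfg_val("replicates", 3),
      controls = cfg_val("controls", 12),
      seed = config$seed)
    sim <- simulate_pool_screen(cfg)
    write_array_table(sim$experiment,
                      file.path(config$out_dir, "array_table.tsv"),
                      file.path(config$out_dir, "array_metadata.tsv"))
    out <- c(out, file.path(config$out_dir, c("array_table.tsv", "array_metadata.tsv")))
    emit(sim$truth, "truth.tsv")
  }

  manifest <- list(package = "fitscreen",
                   version = as.character(utils::packageVersion("fitscreen")),
                   mode = mode, seed = config$seed, config = config,
                   files = basename(out))
  mpath <- file.path(config$out_dir, paste0("manifest_", mode, ".json"))
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, null = "null",
                       pretty = TRUE)
  invisible(c(out, mpath))
}
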