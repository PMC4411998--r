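# Experiment orchestration: simulate -> isolate -> fractal -> measure ->
# ANOVAR over a multi-plant multi-week design, mirroring a two-group
# (control vs. salt stress), three-plants-per-group, three-week study at
# desk-scale grid resolution.

#' Default experiment configuration
#'
#' Two groups of three plants scanned over three weeks: controls with upper
#' axes from week 1, salt-stressed plants with delayed upper-axis onset and
#' reduced elongation/branching. Per-plant RNG seeds are derived from
#' \code{seed} and are distinct.
#'
#' @param seed base integer seed.
#' @param n_weeks number of weekly snapshots.
#' @param replicates plants per group.
#' @param phantom a \code{\link{phantomSpec}}.
#' @param grid_scale multiplier on the desk-scale grid (2 doubles nx, ny;
#'   use 4 with 512 x 512 x 300 ambitions).
#' @return list of class \code{ExperimentConfig}.
#' @export
experimentConfig <- function(seed = 1L, n_weeks = 3L, replicates = 3L,
                             phantom = phantomSpec(), grid_scale = 1) {
  if (replicates < 1L) stop("replicates must be >= 1")
  if (grid_scale != 1) {
    d <- pmax(8L, as.integer(round(phantom$dims * grid_scale)))
    phantom <- phantomSpec(dims = d, spacing = phantom$spacing,
                           hu_root = phantom$hu_root, hu_sand = phantom$hu_sand,
                           noise_sd = phantom$noise_sd,
                           partial_volume = phantom$partial_volume)
  }
  groups <- list(control = list(preset = "control", n = replicates),
                 salt = list(preset = "salt", n = replicates))
  plant_seeds <- list()
  i <- 0L
  for (gname in names(groups)) for (r in seq_len(groups[[gname]]$n)) {
    i <- i + 1L
    plant_seeds[[paste0(gname, "_", r)]] <- as.integer(seed * 101L + i * 7919L) %% 2147483629L
  }
  cfg <- list(seed = as.integer(seed), n_weeks = as.integer(n_weeks),
              groups = groups, phantom = phantom,
              rules = list(primary = list(max_layers = 4, hu_max = 850),
                           secondary = list(max_layers = 2, hu_max = 950)),
              fractal_mode = "fixed-middle",
              seed_depth = 10, stem_radius = 2, seed_radius = 3,
              min_component = 50,
              plant_seeds = plant_seeds)
  class(cfg) <- "ExperimentConfig"
  cfg
}

#' Load an experiment configuration from YAML
#'
#' The file may override \code{seed}, \code{n_weeks}, \code{replicates},
#' \code{grid_scale} and any \code{phantom} field; unknown keys are an
#' error. Omitted keys keep their defaults.
#'
#' @param path YAML file.
#' @return list of class \code{ExperimentConfig}.
#' @export
readExperimentConfig <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("seed", "n_weeks", "replicates", "grid_scale", "phantom")
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  ph <- do.call(phantomSpec, if (is.null(y$phantom)) list() else y$phantom)
  experimentConfig(seed = if (is.null(y$seed)) 1L else y$seed,
                   n_weeks = if (is.null(y$n_weeks)) 3L else y$n_weeks,
                   replicates = if (is.null(y$replicates)) 3L else y$replicates,
                   phantom = ph,
                   grid_scale = if (is.null(y$grid_scale)) 1 else y$grid_scale)
}

.presetFor <- function(name, rng_seed) {
  switch(name,
         control = controlPreset(rng_seed),
         salt = saltPreset(rng_seed),
         stop("unknown preset: ", name))
}

# measure one plant across all weeks; returns rows for growth_records plus
# per-week cube-count tables
.measurePlant <- function(plant, gname, params, cfg, outdir, keep_volumes) {
  spec <- cfg$phantom
  ext <- spec$dims * spec$spacing
  tree <- growArchitecture(params, n_weeks = cfg$n_weeks, extent = ext,
                           seed_depth = cfg$seed_depth)
  stem_center <- ext[1:2] / 2
  region <- stemSeedRegion(spec$dims, spec$spacing, stem_center,
                           cfg$seed_depth, cfg$stem_radius, cfg$seed_radius)
  rows <- NULL
  for (week in seq_len(cfg$n_weeks)) {
    stage <- function(what) sprintf("%s [plant %s, week %d]", what, plant, week)
    noise_seed <- (cfg$plant_seeds[[plant]] + 7129L * week) %% 2147483629L
    ph <- tryCatch(voxelizePhantom(tree, week, spec, rng_seed = noise_seed),
                   error = function(e) stop(stage("simulate failed: "),
                                            conditionMessage(e), call. = FALSE))
    mask <- segmentRootMaterial(ph$grid, hu_max = cfg$rules$primary$hu_max,
                                min_component = cfg$min_component)
    if (!any(mask)) stop(stage("isolate found no root material"), call. = FALSE)
    skel <- skeletonizeMask(mask, spacing = spec$spacing)
    labeled <- classifyCompartments(skel, stem_center, cfg$seed_depth,
                                    cfg$stem_radius, cfg$seed_radius)
    rmask <- expandSkeleton(labeled, ph$grid, rules = cfg$rules,
                            exclude = region)
    vols <- compartmentVolume(rmask)
    lens <- skeletonLength(labeled)
    has_upper <- sum(labeled@compartment %in% "upper") > 0L

    lower_sel <- which(labeled@compartment %in% "lower")
    fd <- NA_real_
    cc <- NULL
    if (length(lower_sel) >= 2L) {
      lower_coords <- labeled@coords[lower_sel, , drop = FALSE]
      ladder <- dyadicLadder(max(spec$dims))
      cc <- cubeCounts(lower_coords, ladder)
      keep <- selectSidelengths(cc, mode = cfg$fractal_mode)
      fd <- fractalDim(fitFractalDimension(cc, keep))
    }

    if (!is.null(outdir)) {
      pw <- file.path(outdir, "plants", sprintf("%s_week%d", plant, week))
      dir.create(pw, recursive = TRUE, showWarnings = FALSE)
      writeSkeletonCSV(labeled, file.path(pw, "skeleton.csv"))
      writeSWC(tree, file.path(pw, "truth.swc"), week = week)
      if (!is.null(cc))
        utils::write.csv(cc, file.path(pw, "cube_counts.csv"),
                         row.names = FALSE)
      if (keep_volumes)
        writeMetaImage(ph$grid, file.path(pw, "phantom.mhd"))
    }

    rows <- rbind(rows, data.frame(
      plant = plant, group = gname, week = week,
      volume_lower_mm3 = vols["lower"],
      volume_upper_mm3 = if (has_upper) vols["upper"] else NA_real_,
      volume_combined_mm3 = vols["lower"] +
        (if (has_upper) vols["upper"] else 0),
      length_lower_mm = lens["lower"],
      length_upper_mm = if (has_upper) lens["upper"] else NA_real_,
      length_combined_mm = lens["lower"] +
        (if (has_upper) lens["upper"] else 0),
      fd_lower = fd, row.names = NULL))
  }
  rows
}

#' Run the full phenotyping pipeline over an experiment
#'
#' For every plant and week: generate the phantom, isolate the root system
#' (segmentation, thinning, labeling, layer growing), estimate the
#' lower-root fractal dimension, and measure volumes and lengths. Then
#' derive growth rates, length increments and FD ratios, run the
#' repeated-measures ANOVARs, and write all result tables to
#' \code{outdir}. Deterministic under a fixed config.
#'
#' @param config an \code{\link{experimentConfig}}.
#' @param outdir output directory (created). NULL computes in memory only.
#' @param keep_volumes also write each phantom volume as MetaImage.
#' @return invisibly, a list with \code{records} (the per-plant-per-week
#'   tidy table), \code{derived}, \code{summary}, and \code{anovar} (one
#'   entry per trait family).
#' @export
runPipeline <- function(config = experimentConfig(), outdir = "rootct_run",
                        keep_volumes = FALSE) {
  stopifnot(inherits(config, "ExperimentConfig"))
  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  records <- NULL
  for (gname in names(config$groups)) {
    gspec <- config$groups[[gname]]
    for (r in seq_len(gspec$n)) {
      plant <- paste0(gname, "_", r)
      params <- .presetFor(gspec$preset, config$plant_seeds[[plant]])
      records <- rbind(records,
                       .measurePlant(plant, gname, params, config, outdir,
                                     keep_volumes))
    }
  }
  derived <- deriveWeeklyStats(records)
  summary_tab <- summarizeGroups(records, derived)

  an <- list(
    fd = .anovarWide(records, "fd_lower"),
    fdr = .anovarWide(derived$fdr, "fdr", timecol = "ratio"),
    volume_lower = .anovarWide(records, "volume_lower_mm3"),
    volume_upper = .anovarWide(records, "volume_upper_mm3"),
    volume_combined = .anovarWide(records, "volume_combined_mm3"),
    rate_lower = .anovarWide(derived$rates, "rate_lower", timecol = "interval"),
    rate_upper = .anovarWide(derived$rates, "rate_upper", timecol = "interval"),
    rate_combined = .anovarWide(derived$rates, "rate_combined", timecol = "interval"),
    length_lower = .anovarWide(records, "length_lower_mm"),
    length_upper = .anovarWide(records, "length_upper_mm"),
    length_combined = .anovarWide(records, "length_combined_mm"),
    increment_lower = .anovarWide(derived$increments, "inc_lower", timecol = "interval"),
    increment_upper = .anovarWide(derived$increments, "inc_upper", timecol = "interval"),
    increment_combined = .anovarWide(derived$increments, "inc_combined", timecol = "interval")
  )

  if (!is.null(outdir)) {
    utils::write.csv(records, file.path(outdir, "growth_records.csv"),
                     row.names = FALSE)
    utils::write.csv(records[, c("plant", "group", "week", "fd_lower")],
                     file.path(outdir, "fd_table.csv"), row.names = FALSE)
    utils::write.csv(derived$fdr, file.path(outdir, "fdr_table.csv"),
                     row.names = FALSE, na = "N/A")
    utils::write.csv(summary_tab, file.path(outdir, "group_summary.csv"),
                     row.names = FALSE, na = "N/A")
    .writeAnovarCSV(an["fd"], file.path(outdir, "anovar_fd.csv"))
    .writeAnovarCSV(an["fdr"], file.path(outdir, "anovar_fdr.csv"))
    .writeAnovarCSV(an[c("volume_lower", "volume_upper", "volume_combined")],
                    file.path(outdir, "anovar_volumes.csv"))
    .writeAnovarCSV(an[c("rate_lower", "rate_upper", "rate_combined")],
                    file.path(outdir, "anovar_rates.csv"))
    .writeAnovarCSV(an[c("length_lower", "length_upper", "length_combined")],
                    file.path(outdir, "anovar_lengths.csv"))
    .writeAnovarCSV(an[c("increment_lower", "increment_upper",
                         "increment_combined")],
                    file.path(outdir, "anovar_increments.csv"))
    cfg_path <- file.path(outdir, "config.yaml")
    yaml::write_yaml(.configAsList(config), cfg_path)
    log <- c(sprintf("rootCT run %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
             sprintf("config md5: %s", unname(tools::md5sum(cfg_path))),
             sprintf("base seed: %d", config$seed),
             sprintf("plant seeds: %s",
                     paste(names(config$plant_seeds),
                           unlist(config$plant_seeds), sep = "=",
                           collapse = ", ")))
    writeLines(log, file.path(outdir, "run_log.txt"))
  }
  invisible(list(records = records, derived = derived, summary = summary_tab,
                 anovar = an))
}

.configAsList <- function(cfg) {
  list(seed = cfg$seed, n_weeks = cfg$n_weeks,
       groups = lapply(cfg$groups, function(g) list(preset = g$preset, n = g$n)),
       phantom = list(dims = cfg$phantom$dims, spacing = cfg$phantom$spacing,
                      hu_root = cfg$phantom$hu_root,
                      hu_sand = cfg$phantom$hu_sand,
                      noise_sd = cfg$phantom$noise_sd),
       rules = cfg$rules, fractal_mode = cfg$fractal_mode,
       plant_seeds = cfg$plant_seeds)
}

#' Derive weekly growth statistics from the record table
#'
#' Relative growth rates of volume and length increments between
#' consecutive weeks, and FD ratios against week 1. A compartment absent
#' at week t yields a missing (not zero) rate, mirroring N/A entries.
#'
#' @param records the per-plant-per-week data.frame from
#'   \code{\link{runPipeline}}.
#' @return list with data.frames \code{rates}, \code{increments},
#'   \code{fdr}.
#' @export
deriveWeeklyStats <- function(records) {
  rate_or_na <- function(v0, v1) {
    if (is.na(v0) || is.na(v1) || v0 <= 0) NA_real_ else (v1 - v0) / v0
  }
  inc_or_na <- function(l0, l1) {
    if (is.na(l0) || is.na(l1)) NA_real_ else l1 - l0
  }
  rates <- NULL; incs <- NULL; fdr <- NULL
  for (plant in unique(records$plant)) {
    pr <- records[records$plant == plant, ]
    pr <- pr[order(pr$week), ]
    grp <- pr$group[1]
    for (w in seq_len(nrow(pr) - 1)) {
      a <- pr[w, ]; b <- pr[w + 1, ]
      iv <- sprintf("%d-%d", a$week, b$week)
      rates <- rbind(rates, data.frame(
        plant = plant, group = grp, interval = iv,
        rate_lower = rate_or_na(a$volume_lower_mm3, b$volume_lower_mm3),
        rate_upper = rate_or_na(a$volume_upper_mm3, b$volume_upper_mm3),
        rate_combined = rate_or_na(a$volume_combined_mm3, b$volume_combined_mm3)))
      incs <- rbind(incs, data.frame(
        plant = plant, group = grp, interval = iv,
        inc_lower = inc_or_na(a$length_lower_mm, b$length_lower_mm),
        inc_upper = inc_or_na(a$length_upper_mm, b$length_upper_mm),
        inc_combined = inc_or_na(a$length_combined_mm, b$length_combined_mm)))
    }
    if (nrow(pr) >= 2 && !is.na(pr$fd_lower[1]) && pr$fd_lower[1] > 0) {
      rr <- fdRatios(pr$fd_lower)
      fdr <- rbind(fdr, data.frame(
        plant = plant, group = grp,
        ratio = sprintf("%d/1", pr$week[-1]), fdr = rr))
    }
  }
  list(rates = rates, increments = incs, fdr = fdr)
}

#' Group-by-week means and standard errors of every trait
#'
#' SE = sample standard deviation / sqrt(n), with n counting non-missing
#' values only; a single value gives SE NA and an empty cell gives N/A.
#'
#' @param records per-plant-per-week record table.
#' @param derived optional output of \code{\link{deriveWeeklyStats}}; when
#'   supplied, rates, increments and FD ratios are summarized too.
#' @return long data.frame: group, week (or interval/ratio), trait, n,
#'   mean, se.
#' @export
summarizeGroups <- function(records, derived = NULL) {
  melt <- function(df, idcols, timecol) {
    traits <- setdiff(names(df), c("plant", "group", timecol))
    out <- NULL
    for (tr in traits) {
      agg <- split(df[[tr]], list(df$group, df[[timecol]]), drop = TRUE)
      for (cell in names(agg)) {
        v <- agg[[cell]]
        n <- sum(!is.na(v))
        parts <- strsplit(cell, "\\.")[[1]]
        out <- rbind(out, data.frame(
          group = parts[1], time = parts[2], trait = tr, n = n,
          mean = if (n) mean(v, na.rm = TRUE) else NA_real_,
          se = if (n >= 2) stats::sd(v[!is.na(v)]) / sqrt(n) else NA_real_))
      }
    }
    out
  }
  out <- melt(records, c("plant", "group"), "week")
  if (!is.null(derived)) {
    out <- rbind(out,
                 melt(derived$rates, c("plant", "group"), "interval"),
                 melt(derived$increments, c("plant", "group"), "interval"),
                 if (!is.null(derived$fdr))
                   melt(derived$fdr, c("plant", "group"), "ratio"))
  }
  out[order(out$trait, out$time, out$group), ]
}

# run one repeated-measures ANOVAR on a trait, restricting to the time
# levels at which every subject has a value (listwise restriction)
.anovarWide <- function(df, trait, timecol = "week") {
  if (is.null(df) || !trait %in% names(df)) return(NULL)
  tl <- sort(unique(df[[timecol]]))
  all_levels <- tl
  ok <- vapply(tl, function(t) !anyNA(df[[trait]][df[[timecol]] == t]),
               logical(1))
  used <- tl[ok]
  per_time_na <- setdiff(all_levels, used)
  if (length(used) < 2L)
    return(list(table = NULL, used_levels = used, dropped_levels = per_time_na))
  sub <- df[df[[timecol]] %in% used, ]
  rm <- repeatedMeasuresData(sub[[trait]], sub$plant, sub$group,
                             sub[[timecol]])
  res <- anovarUnivariate(rm)
  res$dropped_levels <- per_time_na
  res
}

# serialize a family of AnovarTable results to one CSV with N/A cells
.writeAnovarCSV <- function(results, path) {
  rows <- NULL
  for (nm in names(results)) {
    res <- results[[nm]]
    if (is.null(res) || is.null(res$table)) {
      rows <- rbind(rows, data.frame(trait = nm, source = "insufficient data",
                                     df1 = NA, df2 = NA, F = NA, P = NA,
                                     P_adjusted = NA, epsilon = NA))
      next
    }
    for (dl in res$dropped_levels)
      rows <- rbind(rows, data.frame(trait = nm,
                                     source = paste0("Group (time ", dl, ")"),
                                     df1 = NA, df2 = NA, F = NA, P = NA,
                                     P_adjusted = NA, epsilon = NA))
    pt <- res$per_time
    for (i in seq_len(nrow(pt)))
      rows <- rbind(rows, data.frame(trait = nm,
                                     source = paste0("Group (time ", pt$time[i], ")"),
                                     df1 = pt$df1[i], df2 = pt$df2[i],
                                     F = pt$F[i], P = pt$P[i],
                                     P_adjusted = NA, epsilon = NA))
    tb <- res$table
    for (i in seq_len(nrow(tb)))
      rows <- rbind(rows, data.frame(trait = nm, source = tb$effect[i],
                                     df1 = tb$df1[i], df2 = tb$df2[i],
                                     F = tb$F[i], P = tb$P[i],
                                     P_adjusted = tb$P_adjusted[i],
                                     epsilon = res$epsilon))
  }
  utils::write.csv(rows, path, row.names = FALSE, na = "N/A")
  invisible(path)
}
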