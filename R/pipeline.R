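#' Read a plain key=value pipeline configuration file
#'
#' Lines of `key = value`; `#` starts a comment; comma-separated values
#' become vectors. Relative paths are resolved against the config file's
#' directory.
#'
#' @param path Config file path.
#' @return Named list of character vectors with attribute `dir`.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    cfg[[key]] <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
  }
  attr(cfg, "dir") <- dirname(normalizePath(path))
  cfg
}

cfg_num <- function(cfg, key, default = NULL) {
  if (is.null(cfg[[key]])) return(default)
  as.numeric(cfg[[key]])
}

cfg_chr <- function(cfg, key, default = NULL) {
  if (is.null(cfg[[key]])) return(default)
  cfg[[key]]
}

cfg_path <- function(cfg, key) {
  p <- cfg[[key]]
  if (is.null(p)) return(NULL)
  if (!grepl("^(/|[A-Za-z]:)", p)) p <- file.path(attr(cfg, "dir"), p)
  p
}

#' Read protected-area polygons from GeoJSON and rasterize them
#'
#' Cells whose centers fall inside any polygon are masked. Polygon `name`
#' properties are preserved for per-patch overlap reporting.
#'
#' @param path GeoJSON FeatureCollection of polygons.
#' @param grid A `grid_spec`.
#' @return A `protected_areas` object.
#' @export
read_protected_areas_geojson <- function(path, grid) {
  gj <- jsonlite::read_json(path)
  ctr <- cell_centers(grid)
  px <- rep(ctr$lon, each = grid$n_rows)
  py <- rep(ctr$lat, times = grid$n_cols)
  polys <- list(); pmasks <- list(); areas <- numeric(0)
  mask <- matrix(FALSE, grid$n_rows, grid$n_cols)
  for (i in seq_along(gj$features)) {
    ft <- gj$features[[i]]
    nm <- if (!is.null(ft$properties$name)) ft$properties$name
          else sprintf("PA%02d", i)
    ring <- ft$geometry$coordinates[[1]]
    v <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    v <- v[-nrow(v), , drop = FALSE]  # drop closing vertex
    polys[[nm]] <- v
    areas[nm] <- polygon_area_km2(v[, 1], v[, 2])
    inside <- matrix(points_in_polygon(px, py, v[, 1], v[, 2]),
                     grid$n_rows, grid$n_cols)
    pmasks[[nm]] <- inside
    mask <- mask | inside
  }
  structure(list(polygons = polys, areas_km2 = areas, mask = mask,
                 polygon_masks = pmasks, grid = grid),
            class = "protected_areas")
}

#' Generate the packaged synthetic demo fixture set
#'
#' Builds a complete miniature study region: a 60 x 60 grid of six
#' environmental layers with two deliberately collinear pairs, three prey
#' species with known truth suitability models (one with a quadratic
#' response), occurrence samples from those surfaces, future stacks for two
#' horizons under four SSP scenarios (warming shifts growing with forcing),
#' a two-city distance-decay human footprint field and six random protected
#' areas. Truth parameters are echoed into the manifest so recovery can be
#' verified downstream.
#'
#' @param dir Output directory (created).
#' @param seed Integer master seed.
#' @return Invisibly, the path to the generated `config.cfg`.
#' @export
make_demo <- function(dir, seed = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  grid <- grid_spec(60, 60, 0.05, origin_lon = 103, origin_lat = 31)
  layer_names <- paste0("env", 1:6)
  C <- diag(6)
  C[1, 2] <- C[2, 1] <- 0.9   # collinear pair: env1/env2
  C[3, 4] <- C[4, 3] <- 0.85  # collinear pair: env3/env4
  current <- gen_env_stack(grid, layer_names, C, smoothness = 4, seed = seed)

  truths <- list(
    prey_a = truth_model(c(env1 = 3.0, "env1^2" = -1.5, env3 = -2.0),
                         intercept = -2.0),
    prey_b = truth_model(c(env3 = 2.5, env5 = 1.5, "env5^2" = -2.0),
                         intercept = -1.5),
    prey_c = truth_model(c(env5 = -2.0, env6 = 2.5, "env6^2" = -1.0),
                         intercept = -1.8)
  )
  n_occ <- c(prey_a = 220, prey_b = 260, prey_c = 240)
  occ <- list()
  for (i in seq_along(truths)) {
    sp <- names(truths)[i]
    suit <- make_truth_suitability(current, truths[[sp]])
    occ[[sp]] <- sample_occurrences(suit, grid, n_occ[[sp]], species_id = sp,
                                    seed = seed + i)
  }
  write_occurrences(occ, file.path(dir, "occurrences.csv"))

  stacks_dir <- file.path(dir, "stacks")
  write_stack_ascii(current, file.path(stacks_dir, "current"))
  ssp_shift <- c(ssp126 = 0.3, ssp245 = 0.6, ssp370 = 1.0, ssp585 = 1.4)
  horizon_mult <- c(h2050 = 1, h2070 = 1.8)
  for (hz in names(horizon_mult)) {
    for (sc in names(ssp_shift)) {
      delta <- ssp_shift[[sc]] * horizon_mult[[hz]]
      fut <- gen_future_stack(
        current,
        shift = c(env1 = delta, env3 = -0.5 * delta, env5 = 0.4 * delta),
        scale = c(env6 = 1 + 0.05 * delta),
        scenario_tag = sc, period_tag = hz
      )
      write_stack_ascii(fut, file.path(stacks_dir, paste0(hz, "_", sc)))
    }
  }

  hfi_centers <- data.frame(lon = c(103.6, 105.2), lat = c(30.5, 28.8),
                            intensity = c(30, 22))
  hfi <- gen_hfi(grid, hfi_centers, decay_scale = 40, noise_sd = 0.3,
                 seed = seed + 10)
  write_ascii_grid(hfi, grid, file.path(dir, "hfi.asc"))

  pa <- gen_protected_areas(grid, 6, size_range_km2 = c(300, 3000),
                            seed = seed + 20)
  write_protected_areas_geojson(pa, file.path(dir, "protected_areas.geojson"))

  cfg_lines <- c(
    "# synthetic demo pipeline configuration",
    "occurrences = occurrences.csv",
    "stacks_dir = stacks",
    "hfi = hfi.asc",
    "pa_geojson = protected_areas.geojson",
    "min_dist_km = 10",
    "cor_threshold = 0.8",
    "rm_grid = 1, 2",
    "combos = L, LQ",
    "n_reps = 10",
    "split = 0.75",
    "class_thresholds = 0.1, 0.3, 0.5",
    "min_patch_km2 = 100",
    "hfi_threshold = 8.0",
    "hfi_area_fraction = 0.5",
    "connectivity = 8",
    "male_density = 0.46",
    "female_density = 1.32",
    "sex_partition = 0.5",
    "max_background = 10000",
    "n_hinge_knots = 5",
    sprintf("seed = %d", seed)
  )
  writeLines(cfg_lines, file.path(dir, "config.cfg"))

  man <- c(
    sprintf("seed = %d", seed),
    sprintf("grid = %d x %d @ %g deg, origin (%g, %g)", grid$n_rows,
            grid$n_cols, grid$cell_size_deg, grid$origin_lon,
            grid$origin_lat),
    sprintf("species = %s", paste(names(truths), collapse = ", ")),
    sprintf("stacks = current + %s",
            paste(outer(names(horizon_mult), names(ssp_shift), paste,
                        sep = "_"), collapse = ", ")),
    unlist(lapply(names(truths), function(sp) {
      tm <- truths[[sp]]
      sprintf("truth.%s = intercept %g; %s; link %s", sp, tm$intercept,
              paste(sprintf("%s:%g", names(tm$coefficients),
                            tm$coefficients), collapse = " "),
              tm$link)
    })),
    sprintf("occurrences.%s = %d", names(n_occ), n_occ)
  )
  writeLines(man, file.path(dir, "manifest.txt"))
  invisible(file.path(dir, "config.cfg"))
}

pipeline_stage <- function(name, log, expr) {
  log(sprintf("stage %s: start", name))
  res <- tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  log(sprintf("stage %s: done", name))
  res
}

#' Run the full habitat-screening pipeline
#'
#' Executes, for every species in the occurrence file: spatial thinning,
#' correlation screening with contribution-based removal, Kuenm-style
#' calibration, replicate-averaged current prediction and projection onto
#' every future stack; then SSP-scenario averaging, the equal-weight prey
#' overlay per period, four-level classification, three-period stability
#' superposition, patch extraction and screening (minimum area and
#' human-footprint rules), protected-area overlap and carrying capacity.
#' All randomness derives from the config seed; a rerun with the same
#' config and seed produces byte-identical tables and maps.
#'
#' @param config Path to a key=value config file (see [make_demo()]) or a
#'   pre-parsed config list.
#' @param out_dir Output run directory (created).
#' @return Invisibly, a list with the main results (area table, core
#'   patches, capacity table, summary) and the manifest path.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (is.character(config)) read_config(config) else config
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_lines <- character(0)
  log <- function(msg) {
    log_lines <<- c(log_lines, msg)
    writeLines(log_lines, log_path)
  }
  seed <- as.integer(cfg_num(cfg, "seed", 1))

  inputs <- pipeline_stage("inputs", log, {
    occ_path <- cfg_path(cfg, "occurrences")
    stacks_dir <- cfg_path(cfg, "stacks_dir")
    hfi_path <- cfg_path(cfg, "hfi")
    pa_path <- cfg_path(cfg, "pa_geojson")
    for (p in c(occ_path, stacks_dir, hfi_path, pa_path))
      if (is.null(p) || !file.exists(p)) stop("missing input: ", p)
    dirs <- list.dirs(stacks_dir, recursive = FALSE)
    tags <- basename(dirs)
    if (!"current" %in% tags) stop("no 'current' stack directory")
    stacks <- list()
    for (d in dirs) {
      tg <- basename(d)
      if (tg == "current") {
        stacks[[tg]] <- read_stack_ascii(d, "current", "none")
      } else {
        parts <- strsplit(tg, "_", fixed = TRUE)[[1]]
        stacks[[tg]] <- read_stack_ascii(d, parts[1], parts[2])
      }
    }
    hfi <- read_ascii_grid(hfi_path)
    grid <- stacks$current$grid
    if (!same_grid(hfi$grid, grid)) stop("footprint grid mismatch")
    list(occ = read_occurrences(occ_path), stacks = stacks,
         hfi = hfi$values, grid = grid,
         pa = read_protected_areas_geojson(pa_path, grid),
         checksums = tools::md5sum(c(occ_path, hfi_path, pa_path)))
  })
  grid <- inputs$grid
  current <- inputs$stacks$current
  future_tags <- setdiff(names(inputs$stacks), "current")
  horizons <- unique(vapply(strsplit(future_tags, "_"), `[[`, character(1), 1))

  thinned <- pipeline_stage("thinning", log, {
    lapply(inputs$occ, thin_occurrences,
           min_distance_km = cfg_num(cfg, "min_dist_km", 10))
  })
  occ_cells <- pipeline_stage("presence-cells", log, {
    lapply(thinned, occurrences_to_cells, grid = grid)
  })

  bg <- sample_background(current, cfg_num(cfg, "max_background", 10000),
                          seed)
  screened <- pipeline_stage("variable-screening", log, {
    rep_corr <- pairwise_correlation(current, seed = seed)
    lapply(occ_cells, function(cells) {
      sc <- variable_contributions(cells, bg, current)
      select_variables(rep_corr, sc,
                       threshold = cfg_num(cfg, "cor_threshold", 0.8))
    })
  })

  per_species <- pipeline_stage("sdm", log, {
    out <- list()
    for (sp in names(occ_cells)) {
      retained <- as.character(screened[[sp]])
      cal <- calibrate(
        occ_cells[[sp]], current,
        rm_grid = cfg_num(cfg, "rm_grid", c(0.5, 1, 2, 4)),
        combos = as.list(cfg_chr(cfg, "combos",
                                 c("L", "LQ", "LQP", "LQH", "LQPH"))),
        split = cfg_num(cfg, "split", 0.75), seed = seed,
        n_hinge_knots = cfg_num(cfg, "n_hinge_knots", 5),
        max_background = cfg_num(cfg, "max_background", 10000),
        retained_layers = retained
      )
      sel <- which(cal$selected)
      if (length(sel) == 0) stop("no calibration candidate selected for ", sp)
      best <- sel[order(cal$aicc[sel], cal$reg_multiplier[sel])][1]
      reps <- replicate_run(
        occ_cells[[sp]], current, cal$feature_combo[best],
        cal$reg_multiplier[best],
        n_reps = cfg_num(cfg, "n_reps", 10),
        split = cfg_num(cfg, "split", 0.75), seed = seed,
        n_hinge_knots = cfg_num(cfg, "n_hinge_knots", 5),
        max_background = cfg_num(cfg, "max_background", 10000),
        retained_layers = retained
      )
      proj <- list(current = reps$mean_map)
      for (tg in future_tags) {
        maps <- lapply(reps$models, predict, stack = inputs$stacks[[tg]],
                       output = "cloglog")
        proj[[tg]] <- Reduce(`+`, maps) / length(maps)
      }
      out[[sp]] <- list(calibration = cal, chosen = cal[best, ],
                        mean_auc = reps$mean_auc, projections = proj)
    }
    out
  })

  period_maps <- pipeline_stage("scenario-mean", log, {
    lapply(per_species, function(sp) {
      maps <- list(current = sp$projections$current)
      for (hz in horizons) {
        tags <- grep(paste0("^", hz, "_"), names(sp$projections),
                     value = TRUE)
        maps[[hz]] <- scenario_mean(sp$projections[tags])
      }
      maps
    })
  })

  periods <- c("current", horizons)
  tiger_maps <- pipeline_stage("prey-overlay", log, {
    out <- list()
    for (pd in periods)
      out[[pd]] <- prey_overlay(lapply(period_maps, `[[`, pd))
    out
  })

  th <- cfg_num(cfg, "class_thresholds", c(0.1, 0.3, 0.5))
  classified <- pipeline_stage("classification", log, {
    all_maps <- c(period_maps, list(tiger = tiger_maps))
    lapply(all_maps, function(maps)
      lapply(maps, classify_suitability, grid = grid, thresholds = th))
  })

  area_tab <- pipeline_stage("area-accounting", log, {
    tabs <- lapply(names(classified), function(sp) {
      ar <- lapply(classified[[sp]], class_areas)
      change_table(ar$current, ar[setdiff(names(ar), "current")],
                   species = sp)
    })
    do.call(rbind, tabs)
  })

  stable <- pipeline_stage("stability", log, {
    stability_superposition(classified$tiger[periods])
  })

  site_cfg <- screening_config(
    min_patch_km2 = cfg_num(cfg, "min_patch_km2", 100),
    hfi_threshold = cfg_num(cfg, "hfi_threshold", 8),
    hfi_area_fraction = cfg_num(cfg, "hfi_area_fraction", 0.5),
    connectivity = cfg_num(cfg, "connectivity", 8)
  )
  screening <- pipeline_stage("site-screening", log, {
    high_mask <- !is.na(stable$levels) & stable$levels == 3L
    patches <- extract_patches(high_mask, grid, site_cfg$connectivity)
    scr <- screen_patches(patches, inputs$hfi, grid, site_cfg)
    ov <- pa_overlap(scr$core, inputs$pa, grid)
    list(patches = patches, core = ov$patches, summary = ov$summary,
         rejections = scr$rejections)
  })

  dens <- density_params(
    male_density = cfg_num(cfg, "male_density", 0.46),
    female_density = cfg_num(cfg, "female_density", 1.32),
    sex_partition_fraction = cfg_num(cfg, "sex_partition", 0.5)
  )
  cap_tab <- pipeline_stage("carrying-capacity", log, {
    capacity_table(screening$core, dens)
  })
  report <- rank_report(screening$core, top_n = 20, density = dens)

  pipeline_stage("outputs", log, {
    num <- function(df) {
      df[] <- lapply(df, function(col)
        if (is.numeric(col)) round(col, 6) else col)
      df
    }
    utils::write.csv(num(area_tab), file.path(out_dir, "area_table.csv"),
                     row.names = FALSE)
    utils::write.csv(num(cap_tab), file.path(out_dir, "capacity_table.csv"),
                     row.names = FALSE)
    utils::write.csv(num(report), file.path(out_dir, "core_sites.csv"),
                     row.names = FALSE)
    utils::write.csv(num(screening$rejections),
                     file.path(out_dir, "rejection_log.csv"),
                     row.names = FALSE)
    for (pd in periods)
      write_ascii_grid(round(tiger_maps[[pd]], 8), grid,
                       file.path(out_dir, paste0("tiger_", pd, ".asc")))
    write_ascii_grid(stable$levels, grid,
                     file.path(out_dir, "tiger_stable_levels.asc"))
    sm <- screening$summary
    cal_rows <- do.call(rbind, lapply(names(per_species), function(sp)
      data.frame(species = sp, per_species[[sp]]$calibration)))
    utils::write.csv(num(cal_rows),
                     file.path(out_dir, "calibration_table.csv"),
                     row.names = FALSE)
    out_files <- list.files(out_dir, pattern = "\\.(csv|asc)$",
                            full.names = TRUE)
    man <- c(
      sprintf("seed = %d", seed),
      sprintf("config_md5 = %s",
              if (is.character(config)) unname(tools::md5sum(config))
              else "inline"),
      sprintf("input_md5.%s = %s", basename(names(inputs$checksums)),
              unname(inputs$checksums)),
      sprintf("species = %s", paste(names(per_species), collapse = ", ")),
      sprintf("selected.%s = rm %g combo %s (test AUC %.4f)",
              names(per_species),
              vapply(per_species, function(s) s$chosen$reg_multiplier,
                     numeric(1)),
              vapply(per_species, function(s) s$chosen$feature_combo,
                     character(1)),
              vapply(per_species, function(s) s$mean_auc, numeric(1))),
      sprintf("core_patches = %d", length(screening$core)),
      sprintf("core_total_km2 = %.2f", sm$total_core_km2),
      sprintf("pa_overlap_km2 = %.2f", sm$overlap_km2),
      sprintf("pa_overlap_pct = %.1f", sm$overlap_pct),
      sprintf("output_md5.%s = %s", basename(out_files),
              unname(tools::md5sum(out_files)))
    )
    writeLines(man, file.path(out_dir, "run_manifest.txt"))
  })

  invisible(list(area_table = area_tab, core_patches = screening$core,
                 capacity_table = cap_tab, core_sites = report,
                 summary = screening$summary,
                 per_species = per_species,
                 manifest = file.path(out_dir, "run_manifest.txt")))
}
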