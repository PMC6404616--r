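#' Pipeline configuration
#'
#' Assembles the full configuration of a screen run: simulation parameters,
#' scoring thresholds and consensus rule, enrichment settings and the
#' dose-response stage. Values not supplied fall back to the defaults below;
#' unknown keys are rejected with the offending key path so a typo in a
#' YAML file cannot silently change a run.
#'
#' @param ... Named overrides of the default configuration (nested lists
#'   follow the same structure as the defaults).
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    n_strains = 1000L,
    compounds = c("BHA", "BHT", "BPA"),
    concentrations = list(BHA = 0.3, BHT = 0.6, BPA = 0.6),
    frac_sensitive = 0.1,
    frac_resistant = 0.02,
    effect_ranges = list(sensitive = c(0.1, 0.4), resistant = c(2.5, 6)),
    noise_cv = 0.15,
    n_replicates = 3L,
    base_density = 1000,
    scoring = list(t_sens = 0.5, t_res = 2.0,
                   consensus_m = 2L, consensus_t = 2L,
                   wt_strain = "wt", log_floor = 0.05, alpha = 0.05),
    use_images = FALSE,
    plate = list(n_rows = 8L, n_cols = 12L),
    render = list(spot_radius_px = 8, grid_pitch_px = 40, margin_px = 30,
                  bg_level = 500, bg_gradient_amplitude = 200,
                  pixel_noise_sd = 20, saturation_ceiling = 60000,
                  amp_per_density = 5),
    cluster = list(metric = "euclidean", linkage = "average",
                   max_rows = 200L),
    enrichment = list(n_terms = 50L, term_size_range = c(20L, 100L),
                      planted_folds = list(T0001 = 4),
                      method = "bonferroni"),
    dose_response = list(ic50 = list(BHA = 0.4, BHT = 0.8, BPA = 0.9),
                         hill_slope = 2,
                         concentrations = c(0, 0.05, 0.1, 0.2, 0.4, 0.8,
                                            1.6, 3.2),
                         noise_sd = 0)
  )
  merge_config(defaults, list(...), path = "")
}

merge_config <- function(defaults, overrides, path) {
  if (!length(overrides)) {
    return(structure(defaults, class = "pipeline_config"))
  }
  keys <- names(overrides)
  if (is.null(keys) || any(keys == "")) {
    ps_abort(sprintf("configuration overrides at '%s' must be named",
                     if (nzchar(path)) path else "<root>"), "config_error")
  }
  for (key in keys) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults)) {
      ps_abort(sprintf("unknown configuration key: %s", full),
               "config_error")
    }
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]])) &&
        is.list(overrides[[key]])) {
      defaults[[key]] <- unclass(merge_config(defaults[[key]],
                                              overrides[[key]], full))
    } else {
      defaults[[key]] <- overrides[[key]]
    }
  }
  structure(defaults, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file of overrides; keys mirror [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    ps_abort(sprintf("config file not found: %s", path), "io_error")
  }
  overrides <- tryCatch(yaml::read_yaml(path), error = function(e) {
    ps_abort(sprintf("malformed YAML in %s: %s", path,
                     conditionMessage(e)), "config_error")
  })
  do.call(pipeline_config, overrides %||% list())
}

config_to_screen_config <- function(config) {
  s <- config$scoring
  screen_config(t_sens = s$t_sens, t_res = s$t_res,
                consensus_m = s$consensus_m, consensus_t = s$consensus_t,
                wt_strain = s$wt_strain, log_floor = s$log_floor,
                alpha = s$alpha)
}

# Chunk the strain list (wild type first on every plate) into plate layouts.
strains_to_layouts <- function(strains, wt_strain, n_rows, n_cols,
                               plate_prefix = "P") {
  per_plate <- n_rows * n_cols - 1L  # one wt position per plate
  others <- setdiff(strains, wt_strain)
  n_plates <- ceiling(length(others) / per_plate)
  lapply(seq_len(n_plates), function(p) {
    chunk <- others[((p - 1L) * per_plate + 1L):min(p * per_plate,
                                                    length(others))]
    ids <- c(wt_strain, chunk,
             rep("EMPTY", n_rows * n_cols - 1L - length(chunk)))
    grid <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows))
    plate_layout(
      plate_id = sprintf("%s%02d", plate_prefix, p),
      n_rows = n_rows, n_cols = n_cols,
      positions = data.frame(row = grid$row, col = grid$col,
                             strain_id = ids, is_wt = ids == wt_strain),
      wt_strain = wt_strain
    )
  })
}

density_grid_for_layout <- function(layout, density_by_strain) {
  m <- matrix(0, layout$n_rows, layout$n_cols)
  p <- layout$positions
  filled <- p$strain_id != "EMPTY"
  m[cbind(p$row[filled], p$col[filled])] <-
    density_by_strain[p$strain_id[filled]]
  m
}

# Render -> detect -> quantify -> collapse one plate, returning per-strain
# densities measured from the image.
image_path_densities <- function(layout, density_by_strain, render,
                                 seed) {
  params <- do.call(render_params, c(render, list(seed = seed)))
  img <- render_plate_image(density_grid_for_layout(layout,
                                                    density_by_strain),
                            layout, params)
  grid <- detect_grid(img, layout$n_rows, layout$n_cols)
  quant <- quantify_spots(img, grid, layout,
                          saturation_level = params$saturation_ceiling)
  quant_to_strain_densities(quant)
}

#' Generate a synthetic screen bundle on disk
#'
#' Runs the synthetic-data generator and writes a self-contained bundle:
#' plate layouts, per-condition density tables, the planted truth, one
#' rendered example image per compound, and a manifest JSON with MD5
#' checksums (identical config + seed gives identical checksums).
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly (list with `files`, `checksums`, `seed`).
#' @export
run_simulate <- function(config = pipeline_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (config$n_strains < 1) ps_abort("empty strain list", "empty_input_error")
  sim <- simulate_screen(
    n_strains = config$n_strains, compounds = config$compounds,
    frac_sensitive = config$frac_sensitive,
    frac_resistant = config$frac_resistant,
    effect_ranges = config$effect_ranges, noise_cv = config$noise_cv,
    n_replicates = config$n_replicates, base_density = config$base_density,
    seed = config$seed, wt_strain = config$scoring$wt_strain)

  files <- character(0)
  densities_path <- file.path(out_dir, "densities.tsv")
  write_results_table(sim$densities, densities_path)
  files <- c(files, densities_path)

  truth_long <- data.frame(
    strain = rep(rownames(sim$truth$effect), ncol(sim$truth$effect)),
    compound = rep(colnames(sim$truth$effect),
                   each = nrow(sim$truth$effect)),
    rho = as.vector(sim$truth$effect))
  truth_path <- file.path(out_dir, "truth.tsv")
  write_results_table(truth_long, truth_path)
  files <- c(files, truth_path)

  layouts <- strains_to_layouts(sim$truth$strains,
                                config$scoring$wt_strain,
                                config$plate$n_rows, config$plate$n_cols)
  for (ly in layouts) {
    p <- file.path(out_dir, sprintf("layout_%s.tsv", ly$plate_id))
    write_plate_layout(ly, p)
    files <- c(files, p)
  }

  # one example rendered image per compound (first plate, first replicate)
  first <- layouts[[1]]
  d1 <- sim$densities[sim$densities$replicate == 1, ]
  for (cp in config$compounds) {
    dmap <- stats::setNames(d1$density_treated[d1$compound == cp],
                            d1$strain[d1$compound == cp])
    params <- do.call(render_params,
                      c(config$render, list(seed = config$seed)))
    img <- render_plate_image(density_grid_for_layout(first, dmap),
                              first, params)
    p <- file.path(out_dir, sprintf("plate_%s_%s_rep1.tiff",
                                    first$plate_id, cp))
    write_plate_image(img, p)
    files <- c(files, p)
  }
  write_manifest(files, config, out_dir)
}

write_manifest <- function(files, config, out_dir) {
  manifest <- list(
    seed = config$seed,
    config = unclass(config),
    files = stats::setNames(as.list(unname(tools::md5sum(files))),
                            basename(files))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Run the full screening pipeline on simulated data
#'
#' Executes the whole chain the way a real screen is analyzed: simulate a
#' screen (optionally rendering and re-digitizing plate images), score GSVs
#' and call sensitivity, summarize cross-compound overlaps, cluster the
#' log2 GSV profiles of responsive strains, test gene-set enrichment of the
#' sensitive set against a synthetic annotation universe, and estimate
#' IC50/IC80 from dose-response curves. Each stage writes a TSV (plus
#' figures) into `out_dir`; a summary report and a manifest JSON with MD5
#' checksums close the run. Any stage failure aborts with the stage name.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return A list with the main in-memory results (`scores`, `overlap`,
#'   `cluster`, `enrichment`, `ic_table`, `truth`) and the manifest,
#'   invisibly.
#' @export
run_full <- function(config = pipeline_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (config$n_strains < 1) ps_abort("empty strain list", "empty_input_error")
  log_path <- file.path(out_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  logf <- function(level, fmt, ...) {
    writeLines(sprintf("%s [%s] %s", format(Sys.time(), "%H:%M:%S"),
                       level, sprintf(fmt, ...)), log_con)
  }
  stage <- function(name, expr) {
    logf("INFO", "stage %s: start", name)
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        ps_abort(sprintf("stage '%s' failed: %s", name,
                         conditionMessage(e)), "stage_error")
      }),
      phenolscreen_warning = function(w) {
        logf("WARN", "stage %s: %s", name, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  }
  files <- character(0)
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    write_results_table(df, p)
    files <<- c(files, p)
    p
  }
  scfg <- config_to_screen_config(config)

  sim <- stage("simulate", simulate_screen(
    n_strains = config$n_strains, compounds = config$compounds,
    frac_sensitive = config$frac_sensitive,
    frac_resistant = config$frac_resistant,
    effect_ranges = config$effect_ranges, noise_cv = config$noise_cv,
    n_replicates = config$n_replicates, base_density = config$base_density,
    seed = config$seed, wt_strain = scfg$wt_strain))
  densities <- sim$densities

  if (isTRUE(config$use_images)) {
    densities <- stage("quantify", {
      layouts <- strains_to_layouts(sim$truth$strains, scfg$wt_strain,
                                    config$plate$n_rows,
                                    config$plate$n_cols)
      out <- list()
      idx <- 0L
      for (cp in config$compounds) for (r in seq_len(config$n_replicates)) {
        sel <- sim$densities$compound == cp & sim$densities$replicate == r
        tmap <- stats::setNames(sim$densities$density_treated[sel],
                                sim$densities$strain[sel])
        cmap <- stats::setNames(sim$densities$density_control[sel],
                                sim$densities$strain[sel])
        for (ly in layouts) {
          idx <- idx + 1L
          dt <- image_path_densities(ly, tmap, config$render,
                                     seed = (config$seed + 7L * idx) %%
                                       .Machine$integer.max)
          du <- image_path_densities(ly, cmap, config$render,
                                     seed = (config$seed + 7L * idx + 3L) %%
                                       .Machine$integer.max)
          out[[idx]] <- data.frame(
            strain = dt$strain, compound = cp, replicate = r,
            density_treated = dt$density,
            density_control = du$density[match(dt$strain, du$strain)])
        }
      }
      do.call(rbind, out)
    })
  }

  scores <- stage("score", score_screen(densities, scfg))
  emit(scores, "scores.tsv")

  sens_sets <- lapply(config$compounds, function(cp) {
    scores$strain[scores$compound == cp & scores$call == "SENSITIVE"]
  })
  names(sens_sets) <- config$compounds
  overlap <- stage("overlap", overlap_analysis(sens_sets))
  emit(as.data.frame(overlap), "overlap.tsv")

  cluster <- stage("cluster", {
    responsive <- unique(
      scores$strain[scores$call %in% c("SENSITIVE", "RESISTANT")])
    if (length(responsive) > config$cluster$max_rows) {
      responsive <- responsive[seq_len(config$cluster$max_rows)]
    }
    if (length(responsive) >= 2) {
      pm <- build_profile_matrix(
        scores[scores$strain %in% responsive, ], floor = scfg$log_floor)
      cl <- hierarchical_cluster(pm, metric = config$cluster$metric,
                                 linkage = config$cluster$linkage)
      nw <- file.path(out_dir, "cluster.nwk")
      write_cluster_newick(cl, nw)
      files <- c(files, nw)
      plot_profile_heatmap(pm, cl, file.path(out_dir, "heatmap.png"))
      cl
    } else {
      logf("WARN", "cluster: fewer than 2 responsive strains; skipped")
      NULL
    }
  })

  enrichment <- stage("enrich", {
    query <- sens_sets[[which.max(lengths(sens_sets))]]
    ann <- simulate_annotation_universe(
      n_terms = config$enrichment$n_terms,
      term_size_range = config$enrichment$term_size_range,
      planted = unlist(config$enrichment$planted_folds),
      gene_ids = setdiff(sim$truth$strains, scfg$wt_strain),
      query = query, seed = config$seed + 101L)
    res <- enrich_gene_sets(query, ann$annotation, alpha = scfg$alpha,
                            method = config$enrichment$method)
    emit(res, "enrichment.tsv")
    sig <- res[res$significant & res$family == "term", ]
    lay <- bubble_layout(sig)
    if (nrow(lay)) {
      plot_bubble(lay, center_label = sprintf("%d query genes", res$n[1]),
                  path = file.path(out_dir, "bubble.png"))
    }
    res
  })

  ic_table <- stage("ic", {
    rows <- lapply(config$compounds, function(cp) {
      ic50 <- config$dose_response$ic50[[cp]] %||% 0.5
      curve <- simulate_dose_response(
        ic50 = ic50, hill_slope = config$dose_response$hill_slope,
        concentrations = config$dose_response$concentrations,
        noise_sd = config$dose_response$noise_sd,
        seed = config$seed + 211L, compound = cp)
      data.frame(compound = cp, true_ic50 = ic50,
                 ic50_interp = estimate_ic(curve, 50, "interp"),
                 ic80_interp = estimate_ic(curve, 80, "interp"),
                 ic50_logistic = estimate_ic(curve, 50, "logistic"),
                 ic80_logistic = estimate_ic(curve, 80, "logistic"))
    })
    do.call(rbind, rows)
  })
  emit(ic_table, "ic_estimates.tsv")

  report <- stage("report", {
    counts <- as.data.frame(table(compound = scores$compound,
                                  call = scores$call))
    lines <- c(
      sprintf("screen of %d strains x %d compounds, %d replicates, seed %d",
              config$n_strains, length(config$compounds),
              config$n_replicates, config$seed),
      "", "calls per category:",
      sprintf("  %s %s: %d", counts$compound, counts$call, counts$Freq),
      "", "overlap of sensitive sets:",
      utils::capture.output(print(overlap)))
    p <- file.path(out_dir, "report.txt")
    writeLines(lines, p)
    files <- c(files, p)
    lines
  })

  manifest <- write_manifest(files, config, out_dir)
  logf("INFO", "run complete: %d files", length(files))
  invisible(list(scores = scores, overlap = overlap, cluster = cluster,
                 enrichment = enrichment, ic_table = ic_table,
                 truth = sim$truth, manifest = manifest,
                 out_dir = out_dir, report = report))
}
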