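# End-to-end orchestration: phantom -> mesh -> CCI at both severities ->
# strain fields -> callosal segments -> synthetic outcomes -> mixed-effects
# report, driven by one YAML config with per-stage seeds, stage caching and
# a checksummed run manifest.

#' Default pipeline configuration
#'
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return Nested list understood by [run_all()].
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    phantom = list(voxel_size = 0.5),
    mesh = list(smooth_iterations = 5, smooth_relaxation = 0.2),
    impact = list(depths = c(1, 2), velocity = 3.5, diameter = 5,
                  center = c(3, 0)),
    solver = list(dt_safety = 0.45, mass_scaling = TRUE),
    fields = list(strain_thresholds = c(0.3, 0.35, 0.4),
                  rate_thresholds = c(1.5, 2.0, 2.5),
                  observed_contusion_fraction = 0.04),
    segments = list(coronal_y = 0),
    outcomes = list(n_mild = 10, n_moderate = 11),
    associate = list(predictors = c("strain", "strain_rate"))
  )
}

#' Read a pipeline configuration from YAML
#' @param path YAML file.
#' @return Config list merged over [default_config()].
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  base <- default_config(seed = user$seed %||% 1)
  modifyList(base, user)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# order-independent config hash (sorted-key JSON, md5)
config_hash <- function(config) {
  canon <- function(x) {
    if (is.list(x)) lapply(x[order(names(x))], canon) else x
  }
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(canon(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

.stage_cached <- function(out_dir, stage, hash, files) {
  hf <- file.path(out_dir, paste0(".", stage, ".hash"))
  file.exists(hf) && readLines(hf, warn = FALSE)[1] == hash &&
    all(file.exists(file.path(out_dir, files)))
}

.stage_done <- function(out_dir, stage, hash) {
  writeLines(hash, file.path(out_dir, paste0(".", stage, ".hash")))
}

#' Run the full pipeline
#'
#' Executes the stages in dependency order, skipping stages whose inputs
#' (stage-relevant config) and outputs are unchanged since the previous run
#' in the same directory.
#'
#' @param config Path to a YAML config, or a config list.
#' @param out_dir Output directory (created if needed).
#' @param stages Stages to run (dependencies are loaded from cache).
#' @return A `run_manifest`: config hash, seeds, per-stage timing, file
#'   inventory with md5 checksums, and headline summaries.
#' @export
run_all <- function(config = default_config(), out_dir = "ccistrain_run",
                    stages = c("phantom", "mesh", "simulate", "fields",
                               "segments", "outcomes", "associate")) {
  if (is.character(config)) config <- read_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- list(outcomes = config$seed + 1000L)
  timing <- list(); summaries <- list()
  t_stage <- function(expr) {
    t0 <- Sys.time()
    force(expr)
    as.numeric(Sys.time() - t0, units = "secs")
  }

  # -- phantom ---------------------------------------------------------
  h_ph <- config_hash(config$phantom)
  ph_file <- "phantom.nii.gz"
  if (!.stage_cached(out_dir, "phantom", h_ph, ph_file)) {
    timing$phantom <- t_stage({
      spec <- do.call(phantom_spec, config$phantom)
      vol <- make_phantom(spec)
      write_label_volume(vol, file.path(out_dir, ph_file))
    })
    .stage_done(out_dir, "phantom", h_ph)
  }
  vol <- read_label_volume(file.path(out_dir, ph_file))

  # -- mesh ------------------------------------------------------------
  h_me <- config_hash(config[c("phantom", "mesh")])
  me_file <- "mesh.vtk"
  if (!.stage_cached(out_dir, "mesh", h_me, me_file)) {
    timing$mesh <- t_stage({
      mesh <- voxel_to_hex(vol)
      mesh <- smooth_surface(mesh, config$mesh$smooth_iterations,
                             config$mesh$smooth_relaxation)
      write_mesh_vtk(mesh, file.path(out_dir, me_file))
    })
    .stage_done(out_dir, "mesh", h_me)
  }
  mesh <- read_mesh_vtk(file.path(out_dir, me_file))

  # -- simulate --------------------------------------------------------
  h_si <- config_hash(config[c("phantom", "mesh", "impact", "solver")])
  depths <- config$impact$depths
  sim_files <- c(sprintf("force_%gmm.csv", depths),
                 sprintf("sim_%gmm.rds", depths))
  if ("simulate" %in% stages &&
      !.stage_cached(out_dir, "simulate", h_si, sim_files)) {
    timing$simulate <- t_stage({
      for (d in depths) {
        imp <- impactor_spec(diameter = config$impact$diameter,
                             velocity = config$impact$velocity, depth = d,
                             center = config$impact$center)
        cfg <- do.call(sim_config, config$solver)
        res <- run_cci(mesh, default_materials(), imp, cfg)
        utils::write.csv(res$force,
                         file.path(out_dir, sprintf("force_%gmm.csv", d)),
                         row.names = FALSE)
        utils::write.csv(res$energy,
                         file.path(out_dir, sprintf("energy_%gmm.csv", d)),
                         row.names = FALSE)
        saveRDS(res, file.path(out_dir, sprintf("sim_%gmm.rds", d)))
      }
    })
    .stage_done(out_dir, "simulate", h_si)
  }
  runs <- lapply(depths, function(d) {
    readRDS(file.path(out_dir, sprintf("sim_%gmm.rds", d)))
  })
  names(runs) <- as.character(depths)
  summaries$peak_force <- vapply(runs, peak_force, 0)

  # -- fields ----------------------------------------------------------
  h_fi <- config_hash(config[c("phantom", "mesh", "impact", "solver",
                               "fields")])
  fld_files <- sprintf("strain_%gmm.csv", depths)
  fields <- lapply(runs, reduce_history)
  if (!.stage_cached(out_dir, "fields", h_fi, fld_files)) {
    timing$fields <- t_stage({
      fracs <- list()
      for (d in as.character(depths)) {
        write_strain_field(fields[[d]],
                           file.path(out_dir, sprintf("strain_%smm.csv", d)))
        fracs[[d]] <- c(
          vapply(config$fields$strain_thresholds, function(s) {
            volume_fraction_above(fields[[d]], "strain", s)
          }, 0),
          vapply(config$fields$rate_thresholds, function(s) {
            volume_fraction_above(fields[[d]], "strain_rate", s)
          }, 0))
      }
      fr <- do.call(rbind, fracs)
      colnames(fr) <- c(paste0("strain_", config$fields$strain_thresholds),
                        paste0("rate_", config$fields$rate_thresholds))
      rmse <- rmse_prediction(fr, config$fields$observed_contusion_fraction)
      utils::write.csv(
        data.frame(threshold = colnames(fr), t(fr), rmse = rmse),
        file.path(out_dir, "volume_fractions.csv"), row.names = FALSE)
    })
    .stage_done(out_dir, "fields", h_fi)
  }

  # -- segments --------------------------------------------------------
  mask <- make_cc_mask(vol, coronal_index(vol, config$segments$coronal_y))
  segs <- split_cc(mask)
  seg_summ <- list()
  for (d in as.character(depths)) {
    sm <- cc_segment_summary(fields[[d]], segs)
    sm$depth_mm <- as.numeric(d)
    seg_summ[[d]] <- sm
  }
  seg_all <- do.call(rbind, seg_summ)
  timing$segments <- t_stage({
    utils::write.csv(seg_all, file.path(out_dir, "segment_summary.csv"),
                     row.names = FALSE)
    write_segment_nifti(segs, vol, file.path(out_dir, "segments.nii.gz"))
  })
  summaries$strain_rate_pearson_r <- {
    ip <- seg_all[seg_all$hemisphere == "ipsi", ]
    pearson_r(ip$mean[ip$quantity == "strain"],
              ip$mean[ip$quantity == "strain_rate"])
  }

  # -- outcomes --------------------------------------------------------
  sev_of_depth <- stats::setNames(c("mild", "moderate"),
                                  as.character(range(depths)))
  strain_cov <- do.call(rbind, lapply(as.character(depths), function(d) {
    ip <- seg_summ[[d]][seg_summ[[d]]$hemisphere == "ipsi", ]
    data.frame(severity = sev_of_depth[[d]], segment = ip$segment[1:5],
               strain = ip$mean[ip$quantity == "strain"],
               strain_rate = ip$mean[ip$quantity == "strain_rate"])
  }))
  # standardise covariates over the ten ipsilateral segment means
  strain_cov$strain <- as.numeric(scale(strain_cov$strain))
  strain_cov$strain_rate <- as.numeric(scale(strain_cov$strain_rate))
  tab <- gen_outcomes(strain_cov, default_effect_specs(),
                      n_mild = config$outcomes$n_mild,
                      n_moderate = config$outcomes$n_moderate,
                      seed = seeds$outcomes)
  timing$outcomes <- t_stage({
    utils::write.csv(tab, file.path(out_dir, "outcomes.csv"),
                     row.names = FALSE)
  })

  # -- associate -------------------------------------------------------
  assoc <- list()
  for (meas in unique(tab$measure)) {
    ch <- ipsi_minus_reference(tab[tab$measure == meas, ], "paired_contra")
    for (pred in config$associate$predictors) {
      f <- fit_lme(ch, fixed = pred)
      pr <- tryCatch(predictive_r2(ch, fixed = pred)$value,
                     error = function(e) NA)
      assoc[[paste(meas, pred, sep = "_")]] <-
        list(measure = meas, predictor = pred,
             slope = unname(f$coefficients[pred]),
             marginal_r2 = marginal_r2(f), predictive_r2 = pr)
    }
  }
  timing$associate <- t_stage({
    jsonlite::write_json(assoc, file.path(out_dir, "association.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })
  summaries$marginal_r2 <- vapply(assoc, `[[`, 0, "marginal_r2")

  # -- manifest --------------------------------------------------------
  files <- setdiff(list.files(out_dir), grep("^\\.", list.files(out_dir),
                                             value = TRUE))
  inv <- tools::md5sum(file.path(out_dir, files))
  names(inv) <- files
  manifest <- structure(list(config_hash = config_hash(config),
                             seed = config$seed, stage_seeds = seeds,
                             files = as.list(inv), timing = timing,
                             summaries = summaries,
                             energy = lapply(runs, function(r) {
                               utils::tail(r$energy, 1)
                             })),
                        class = "run_manifest")
  jsonlite::write_json(lapply(unclass(manifest), unclass),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  # the manifest lists itself in the returned object (its md5 cannot be
  # embedded in its own file)
  manifest$files[["manifest.json"]] <-
    unname(tools::md5sum(file.path(out_dir, "manifest.json")))
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("run_manifest (config", substr(x$config_hash, 1, 8), "seed", x$seed,
      ")\n")
  cat("  peak forces [N]:",
      paste(names(x$summaries$peak_force),
            signif(x$summaries$peak_force, 4), collapse = ", "), "\n")
  cat("  strain vs strain-rate r:",
      round(x$summaries$strain_rate_pearson_r, 3), "\n")
  cat("  marginal R2:",
      paste(names(x$summaries$marginal_r2),
            round(x$summaries$marginal_r2, 3), collapse = ", "), "\n")
  cat("  files:", length(x$files), "\n")
  invisible(x)
}
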