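#' Pipeline configuration
#'
#' Builds the configuration for [run_pipeline()], merging user values
#' into the documented defaults; unknown keys are rejected.  The
#' `"desk"` scale preset runs the whole route in minutes on one CPU
#' (tomogram 192^3 at 13.2 A, pore subtomograms 64^3 at binning 2);
#' the `"paper"` preset stores the published processing constants
#' (512^3 particle volumes at 3.3 A pixels, 80^3 subprotomers at
#' binning 1, 100,000 docking starts) and is provided for reference,
#' not for desk-scale execution.
#'
#' @param ... named overrides of the defaults (nested lists are merged
#'   key-wise).
#' @param scale `"desk"` or `"paper"`.
#' @return a validated `PipelineConfig` list.
#' @export
pipeline_config <- function(..., scale = c("desk", "paper")) {
  scale <- match.arg(scale)
  base <- list(
    seed = 1L,
    scale = scale,
    simulate = list(box = 192, voxel_size = 13.2, n_copies = 2,
                    noise_sigma = 0.3, membrane = TRUE,
                    spheroid_a = 8000, spheroid_c = 2000),
    acquisition = list(tilt_min = -60, tilt_max = 60, tilt_step = 3,
                       defocus_nominal = -6),
    ctf = list(estimate = TRUE, amplitude_contrast = 0.07, cs = 2.7,
               voltage = 300, mtf = "sinc2"),
    particles = list(box = 64, binning = 2),
    global_align = list(psi_window = 25, psi_step = 5, axis_window = 10,
                        axis_step = 5, refine_window = 8, refine_step = 4,
                        final_window = 3, final_step = 1.5,
                        shift_bound = 4),
    verify = list(threshold_deg = 20),
    protomer = list(box = 32, window = c(8, 8, 8), step = 4,
                    refine_window = c(4, 4, 4), refine_step = 2,
                    shift_bound = 3),
    balance = list(bin_size_deg = 15, cap = 50),
    # z-offsets +-18 nm so the three 16^3 subparts stay inside the
    # 32^3 desk protomer box; the published geometry (+-22 nm, 80^3
    # boxes) applies at the paper scale
    subprotomer = list(box = 16, window = c(2, 2, 2), step = 1,
                       shift_bound = 2, z_offsets = c(cpr = 180,
                                                      npr = -180,
                                                      sr_ccr = 0)),
    assemble = list(out_box = 72, filter_resolution = 80),
    localres = list(grid_spacing = 4, subpart_size = 12,
                    criterion = "fsc_0.5"),
    # the NE mask opening sits outside the spoke body (pore wall plus
    # half a sphere diameter) so masking removes membrane, not spokes
    masks = list(channel_diameter = 170, ne_height = 350,
                 pore_radius = 620)
  )
  if (scale == "paper") {
    base$simulate$voxel_size <- 3.3
    base$particles <- list(box = 512, binning = 4)
    base$protomer$box <- 128
    base$subprotomer$box <- 80
    base$subprotomer$z_offsets <- c(cpr = 220, npr = -220, sr_ccr = 0)
    base$assemble <- list(out_box = 320, filter_resolution = 20 * 10)
    base$localres <- list(grid_spacing = 4, subpart_size = 20,
                          criterion = "fsc_0.5")
  }
  cfg <- merge_config(base, list(...), path = "")
  structure(cfg, class = "PipelineConfig")
}

# Recursive key-checked merge of overrides into defaults.
merge_config <- function(base, override, path = "") {
  for (key in names(override)) {
    if (!key %in% names(base))
      stop("pipeline_config: unknown key '", paste0(path, key), "'")
    if (is.list(base[[key]]) && is.list(override[[key]])) {
      base[[key]] <- merge_config(base[[key]], override[[key]],
                                  paste0(path, key, "$"))
    } else {
      base[[key]] <- override[[key]]
    }
  }
  base
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with keys as in [pipeline_config()].
#' @return a `PipelineConfig`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  scale <- y$scale %||% "desk"
  y$scale <- NULL
  do.call(pipeline_config, c(y, list(scale = scale)))
}

log_stage <- function(run_dir, stage, data) {
  rec <- c(list(stage = stage, time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
           data)
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
      file = file.path(run_dir, "run_log.jsonl"), append = TRUE, sep = "")
  invisible(rec)
}

#' Run the full analysis pipeline
#'
#' Executes simulate, CTF correction, reconstruction, picking, global
#' alignment, orientation verification, protomer extraction and
#' refinement, view balancing, subprotomer refinement, half-set
#' averaging, eightfold model assembly and local-resolution mapping,
#' writing per-stage artifacts (MRC maps, TSV particle tables, a JSONL
#' run log and a JSON provenance record) into a write-once run
#' directory.  Re-running with the same configuration and seed is
#' bit-identical.
#'
#' @param config a [pipeline_config()].
#' @param run_dir output directory (must not already contain a run).
#' @return invisible list with the key artifacts (final map, local
#'   resolution map, particle tables, resolution summaries).
#' @export
run_pipeline <- function(config, run_dir) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (file.exists(file.path(run_dir, "provenance.json")))
    stop("run_pipeline: run directory already holds a run (write-once)")
  dir.create(run_dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              pretty = TRUE),
             file.path(run_dir, "provenance.json"))
  seed <- config$seed
  vs <- config$simulate$voxel_size

  ## simulate -------------------------------------------------------
  spec <- pore_phantom_spec(membrane = config$simulate$membrane)
  ph <- build_phantom(spec, box = config$simulate$box, voxel_size = vs,
                      n_copies = config$simulate$n_copies,
                      spheroid_a = config$simulate$spheroid_a,
                      spheroid_c = config$simulate$spheroid_c,
                      seed = seed)
  acq <- acquisition_spec(tilt_min = config$acquisition$tilt_min,
                          tilt_max = config$acquisition$tilt_max,
                          tilt_step = config$acquisition$tilt_step,
                          defocus_nominal = config$acquisition$defocus_nominal,
                          pixel_size = vs,
                          dose_noise_sigma = config$simulate$noise_sigma,
                          seed = seed)
  ts <- corrupt(project_tilt_series(ph$volume, acq), acq)
  write_particle_table(ph$particles, file.path(run_dir, "ground_truth.tsv"))
  log_stage(run_dir, "simulate",
            list(n_copies = nrow(ph$particles), box = config$simulate$box))

  ## ctf ------------------------------------------------------------
  cm <- ctf_model(defocus = acq$defocus_nominal,
                  amplitude_contrast = config$ctf$amplitude_contrast,
                  cs = config$ctf$cs, voltage = config$ctf$voltage,
                  mtf = config$ctf$mtf)
  est_def <- acq$defocus_nominal
  est_ok <- FALSE
  if (isTRUE(config$ctf$estimate)) {
    est <- try(estimate_mean_defocus(ts, cm), silent = TRUE)
    if (!inherits(est, "try-error")) {
      est_def <- est$defocus
      est_ok <- TRUE
    }
  }
  tsc <- ctf_correct_series(ts, cm, mean_defocus = est_def)
  log_stage(run_dir, "ctf", list(defocus_estimated = est_ok,
                                 defocus_um = est_def))

  ## reconstruct ----------------------------------------------------
  tomo <- weighted_backprojection(tsc)
  write_mrc(tomo, file.path(run_dir, "tomogram.mrc"))
  log_stage(run_dir, "reconstruct", list(box = vol_dim(tomo)[1]))

  ## pick + extract subtomograms ------------------------------------
  gt <- ph$particles
  bin <- config$particles$binning
  pbox <- config$particles$box
  wedge <- wedge_mask(pbox, acq$tilt_min, acq$tilt_max)
  sph_fit <- fit_spheroid(ph$membrane_points)
  particles <- list()
  for (i in seq_len(nrow(gt))) {
    ctr <- c(gt$x[i], gt$y[i], gt$z[i])
    crop <- try(crop_volume(tomo, round(ctr), pbox * bin, pad = TRUE),
                silent = TRUE)
    if (inherits(crop, "try-error")) next
    volb <- bin_volume(crop, bin)
    nrm <- normal_at(sph_fit, ctr * vs)
    ang <- matrix_to_euler(rotation_from_axis(nrm))
    particles[[length(particles) + 1]] <-
      list(volume = volb, wedge = wedge,
           transform = rigid_transform(ang[1], ang[2], ang[3],
                                       (ctr - round(ctr)) / bin),
           particle_id = gt$particle_id[i], keep = TRUE, reason = "",
           normal = nrm, center = ctr)
  }
  log_stage(run_dir, "pick", list(picked = length(particles)))

  ## global alignment -----------------------------------------------
  ref <- make_geometric_template(pbox, vs * bin)
  ga <- config$global_align
  stages <- list(
    list(window = angular_window(ga$axis_window, ga$axis_window,
                                 ga$psi_window, ga$psi_step),
         shift_bound = ga$shift_bound, binning = 2),
    list(window = angular_window(ga$refine_window, ga$refine_window,
                                 ga$refine_window, ga$refine_step),
         shift_bound = ga$shift_bound, binning = 2),
    list(window = angular_window(ga$final_window, ga$final_window,
                                 ga$final_window, ga$final_step),
         shift_bound = 2, binning = 2),
    list(window = angular_window(0, 0, 0, 1), shift_bound = 2,
         binning = 1))
  particles <- align_particles(particles, ref, stages)
  gtab <- particle_table(particles)
  write_particle_table(gtab, file.path(run_dir, "global_align.tsv"))
  log_stage(run_dir, "global_align",
            list(n = length(particles), mean_cc = mean(gtab$cc)))

  ## orientation verification ---------------------------------------
  for (i in seq_along(particles)) {
    v <- verify_orientation(particles[[i]]$transform,
                            particles[[i]]$normal,
                            config$verify$threshold_deg)
    if (!v$keep) {
      particles[[i]]$keep <- FALSE
      particles[[i]]$reason <- v$reason
    }
  }
  kept <- Filter(function(p) isTRUE(p$keep), particles)
  log_stage(run_dir, "verify",
            list(kept = length(kept),
                 excluded = length(particles) - length(kept)))

  ## protomer extraction + refinement -------------------------------
  pvs <- vs * bin
  pspec <- protomer_spec(protomer_box = config$protomer$box,
                         radius = 450,
                         subprotomer_box = config$subprotomer$box,
                         subprotomer_z = config$subprotomer$z_offsets)
  pwedge <- wedge_mask(config$protomer$box, acq$tilt_min, acq$tilt_max)
  protomers <- list()
  for (p in kept) {
    pr <- extract_protomers(bin_volume(tomo, bin),
                            p$transform, p$center / bin, pspec,
                            wedge = pwedge, particle_id = p$particle_id,
                            on_boundary = "pad")
    protomers <- c(protomers, pr)
  }
  # protomer reference: crop of the wedge-compensated global average at
  # the protomer position (carries membrane and noise statistics the
  # geometric template lacks)
  gavg <- wedge_average(kept)
  pref <- crop_volume(gavg, floor(vol_dim(gavg) / 2) +
                        c(pspec$radius / pvs, 0, 0),
                      pspec$protomer_box, pad = TRUE)
  pmask <- make_masks(config$protomer$box, pvs,
                      axis_xy = floor(rep(config$protomer$box, 3) / 2)[1:2] -
                        c(pspec$radius / pvs, 0),
                      channel_diameter = config$masks$channel_diameter,
                      ne_height = config$masks$ne_height,
                      pore_radius = config$masks$pore_radius)$combined
  pstages <- list(
    list(window = angular_window(config$protomer$window[1],
                                 config$protomer$window[2],
                                 config$protomer$window[3],
                                 config$protomer$step),
         shift_bound = config$protomer$shift_bound),
    list(window = angular_window(config$protomer$refine_window[1],
                                 config$protomer$refine_window[2],
                                 config$protomer$refine_window[3],
                                 config$protomer$refine_step),
         shift_bound = 2))
  protomers <- align_particles(protomers, pref, pstages, mask = pmask)
  ptab <- particle_table(protomers)
  ptab$theta <- vapply(protomers, function(p) p$transform$theta, numeric(1))
  ptab <- exclude_at_limits(ptab)
  ptab <- balance_views(ptab, config$balance$bin_size_deg,
                        config$balance$cap)
  protomers <- apply_table_flags(protomers, ptab)
  write_particle_table(ptab, file.path(run_dir, "protomers.tsv"))
  excl <- table(ptab$reason[!ptab$keep])
  log_stage(run_dir, "protomer",
            list(total = nrow(ptab), kept = sum(ptab$keep),
                 exclusions = as.list(excl)))

  ## subprotomer refinement + half-set averaging --------------------
  subs <- subdivide_subprotomers(Filter(function(p) isTRUE(p$keep),
                                        protomers), pspec, pvs)
  sstage <- list(list(window = angular_window(config$subprotomer$window[1],
                                              config$subprotomer$window[2],
                                              config$subprotomer$window[3],
                                              config$subprotomer$step),
                      shift_bound = config$subprotomer$shift_bound))
  sub_avgs <- list()
  res_by_region <- list()
  for (r in names(subs)) {
    sref <- subprotomer_ref_crop(pref, pspec, r)
    sp <- Filter(function(p) isTRUE(p$keep), subs[[r]])
    sp <- align_particles(sp, sref, sstage)
    halves <- split_halves(sp)
    ha <- wedge_average(halves$a)
    hb <- wedge_average(halves$b)
    res <- resolution_at(fsc(ha, hb), 0.5)
    res_by_region[[r]] <- res$resolution
    sub_avgs[[r]] <- wedge_average(sp)
    write_mrc(sub_avgs[[r]], file.path(run_dir,
                                       paste0("subprotomer_", r, ".mrc")))
  }
  log_stage(run_dir, "subprotomer",
            list(resolution_A = res_by_region, criterion = "fsc_0.5"))

  ## assembly + local resolution ------------------------------------
  final <- assemble_model(sub_avgs, pspec, config$assemble$out_box,
                          config$assemble$filter_resolution)
  write_mrc(final, file.path(run_dir, "final_map.mrc"))
  # half-set assemblies for the local-resolution map
  halves_all <- split_halves(unlist(lapply(names(subs), function(r)
    Filter(function(p) isTRUE(p$keep), subs[[r]])), recursive = FALSE))
  ha_map <- assemble_half(halves_all$a, subs, pspec, config)
  hb_map <- assemble_half(halves_all$b, subs, pspec, config)
  lr <- local_resolution(ha_map, hb_map,
                         grid_spacing = config$localres$grid_spacing,
                         subpart_size = config$localres$subpart_size,
                         criterion = config$localres$criterion)
  write_mrc(lr$values, file.path(run_dir, "local_resolution.mrc"))
  log_stage(run_dir, "localres",
            list(criterion = lr$criterion,
                 min_A = min(lr$nodes$resolution),
                 median_A = median(lr$nodes$resolution),
                 max_A = max(lr$nodes$resolution)))
  log_stage(run_dir, "done", list())
  invisible(list(final_map = final, local_resolution = lr,
                 protomer_table = ptab, global_table = gtab,
                 resolution_by_region = res_by_region,
                 run_dir = run_dir))
}

# The protomer-frame reference: crop of the global reference at the
# protomer position.
protomer_reference <- function(global_ref, pspec) {
  d <- vol_dim(global_ref)
  ctr <- floor(d / 2)
  p0 <- c(pspec$radius / global_ref$voxel_size, 0, 0)
  crop_volume(global_ref, ctr + p0, pspec$protomer_box)
}

# Assemble one half-set into a full map (per-region half averages).
assemble_half <- function(half_particles, subs, pspec, config) {
  avgs <- list()
  for (r in names(subs)) {
    sel <- Filter(function(p) identical(p$region, r), half_particles)
    avgs[[r]] <- wedge_average(sel)
  }
  assemble_model(avgs, pspec, config$assemble$out_box,
                 config$assemble$filter_resolution)
}

#' Summarize a completed pipeline run
#'
#' Builds the particle-accounting table (picked versus kept per stage,
#' with exclusion tallies by reason), resolution summaries with their
#' criterion labels, and the pore metrics record (including the
#' central-channel cylinder volume), in machine-readable and
#' human-readable renderings that agree field for field.
#'
#' @param run_dir a directory written by [run_pipeline()].
#' @return list with `accounting`, `resolution`, `metrics`, `text`
#'   (character rendering) and `json` (the same content serialized).
#' @export
report <- function(run_dir) {
  log_path <- file.path(run_dir, "run_log.jsonl")
  if (!file.exists(log_path)) stop("report: no run log in ", run_dir)
  recs <- lapply(readLines(log_path), jsonlite::fromJSON)
  stages <- vapply(recs, function(r) r$stage, character(1))
  get <- function(s) if (s %in% stages) recs[[match(s, stages)]] else NULL
  complete <- "done" %in% stages
  acc <- list(simulated = get("simulate")$n_copies,
              picked = get("pick")$picked,
              verified = get("verify")$kept,
              protomers = get("protomer")$total,
              protomers_kept = get("protomer")$kept,
              exclusions = get("protomer")$exclusions)
  res <- list(by_region_A = get("subprotomer")$resolution_A,
              criterion = get("subprotomer")$criterion,
              local = get("localres")[c("criterion", "min_A", "median_A",
                                        "max_A")])
  metrics <- measure_pore_metrics()
  out <- list(complete = complete, accounting = acc, resolution = res,
              metrics = list(cylinder_volume_nm3 =
                               metrics$cylinder_volume_nm3,
                             pore_diameter_nm = metrics$diameter_nm,
                             ccr_height_nm = metrics$height_nm))
  txt <- c(sprintf("Pipeline run: %s (%s)", run_dir,
                   if (complete) "complete" else "INCOMPLETE"),
           sprintf("  pores simulated: %s, picked: %s, verified: %s",
                   acc$simulated, acc$picked, acc$verified),
           sprintf("  protomers: %s, kept: %s", acc$protomers,
                   acc$protomers_kept),
           if (length(acc$exclusions))
             sprintf("  excluded (%s): %s", names(acc$exclusions),
                     unlist(acc$exclusions)),
           sprintf("  half-set resolution [%s]: %s",
                   res$criterion,
                   paste(names(res$by_region_A), "=",
                         round(unlist(res$by_region_A), 1), "A",
                         collapse = ", ")),
           if (!is.null(res$local))
             sprintf("  local resolution [%s]: min %.1f / median %.1f / max %.1f A",
                     res$local$criterion, res$local$min_A,
                     res$local$median_A, res$local$max_A),
           sprintf("  cylinder volume (d=%.0f nm, h=%.0f nm): %.0f nm^3",
                   out$metrics$pore_diameter_nm, out$metrics$ccr_height_nm,
                   out$metrics$cylinder_volume_nm3))
  out$text <- txt
  out$json <- jsonlite::toJSON(out[c("complete", "accounting",
                                     "resolution", "metrics")],
                               auto_unbox = TRUE, pretty = TRUE)
  out
}
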