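# End-to-end pipeline driver: phantom -> simulated scan -> flat-field and
# ring correction -> TIE-Hom retrieval -> FBP -> de-trend / unsharp ->
# quality report -> optional section registration, with every artifact
# written under an output directory and every stage parameterised by one
# config (YAML file or named list). Reruns with an identical config are
# bit-identical.

.required_blocks <- c("phantom", "scan", "detector", "phase_retrieval")

#' Load and validate a pipeline config
#'
#' @param config path to a YAML file or a named list. Required blocks:
#'   `phantom`, `scan`, `detector`, `phase_retrieval`; optional:
#'   `preprocess`, `enhance`, `register`, `seed`.
#' @return the validated config list.
#' @export
load_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop_vh("config must be a YAML file path or a named list")
  missing <- setdiff(.required_blocks, names(config))
  if (length(missing) > 0) {
    stop_vh("config is missing required block(s): %s",
            paste(missing, collapse = ", "))
  }
  config
}

.cfg_call <- function(fun, block, extra = list()) {
  args <- block[intersect(names(block), names(formals(fun)))]
  do.call(fun, c(args, extra))
}

#' Run the virtual-histology pipeline
#'
#' Executes the configured stages in order and writes artifacts under
#' `out_dir`: `raw/` (projection stack), `recon/` (reconstructed slices),
#' `report.json` (quality metrics) and, when a `register` block is present,
#' `section.tif` plus `overlay.tif`. All randomness derives from the config
#' seeds, so rerunning with the same config reproduces every file exactly.
#'
#' @param config YAML path or list, see [load_config()].
#' @param out_dir output directory.
#' @param stages subset of `c("simulate", "reconstruct", "report",
#'   "register")`; later stages read earlier artifacts from `out_dir` when
#'   not run in the same call.
#' @return (invisibly) a list with the objects produced by the stages run.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("simulate", "reconstruct", "report")) {
  cfg <- load_config(config)
  stages <- match.arg(stages, c("simulate", "reconstruct", "report", "register"),
                      several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  master_seed <- cfg$seed %||% 1L

  ph_block <- cfg$phantom
  ph_block$seed <- ph_block$seed %||% master_seed
  ph_block$shape <- unlist(ph_block$shape)
  spec <- .cfg_call(phantom_spec, ph_block)
  geom <- .cfg_call(scan_geometry, cfg$scan)
  det_block <- cfg$detector
  det_block$seed <- det_block$seed %||% (master_seed + 1L)
  det <- .cfg_call(detector_model, det_block)
  out <- list(config = cfg)

  if ("simulate" %in% stages) {
    vol <- generate_phantom(spec)
    table <- build_material_table(geom$energy_keV)
    rmap <- labels_to_refractive(vol, table,
                                 edge_sigma_px = ph_block$edge_sigma_px %||% 0)
    stack <- simulate_scan(rmap, geom, det)
    write_projection_stack(stack, file.path(out_dir, "raw"))
    out$phantom <- vol
    out$stack <- stack
  }

  if ("reconstruct" %in% stages) {
    stack <- out$stack %||% read_projection_stack(file.path(out_dir, "raw"))
    pp <- cfg$preprocess %||% list()
    trans <- flat_field_correct(stack, floor = pp$floor %||% 1e-6)
    pr <- cfg$phase_retrieval
    params <- tie_hom_params(
      delta_beta = pr$delta_beta %||% 350,
      energy_keV = pr$energy_keV %||% geom$energy_keV,
      distance_mm = pr$distance_mm %||% geom$distance_mm,
      pixel_um = pr$pixel_um %||% geom$pixel_um)
    provenance <- c("flat_field_correct",
                    sprintf("remove_rings(window=%d)", pp$ring_window %||% 9L),
                    sprintf("tie_hom(delta_beta=%g, z=%gmm)",
                            params$delta_beta, params$distance_mm))
    n_rows <- dim(trans)[2]
    retrieved <- array(0, dim(trans))
    for (z in seq_len(n_rows)) {
      s <- as_sinogram(trans, stack$geom, z)
      s <- remove_rings(s, window = pp$ring_window %||% 9L)
      s$values <- pmax(s$values, pp$floor %||% 1e-6)  # rings can undershoot
      s <- retrieve(s, params)
      retrieved[, z, ] <- s$values
    }
    recon <- reconstruct_volume(retrieved, stack$geom, provenance)
    en <- cfg$enhance %||% list()
    vol <- out$phantom %||% generate_phantom(spec)
    out$phantom <- vol
    bg_mask <- detrend_reference_mask(vol, 1)
    if (isTRUE(en$detrend %||% TRUE)) {
      for (k in seq_len(dim(recon$volume)[3])) {
        recon$volume[, , k] <- detrend(recon$volume[, , k], bg_mask)
      }
      recon$provenance <- c(recon$provenance, "detrend(order=2)")
    }
    ua <- en$unsharp_amount %||% 1
    us <- en$unsharp_sigma %||% 2
    if (ua > 0) {
      for (k in seq_len(dim(recon$volume)[3])) {
        recon$volume[, , k] <- unsharp_mask(recon$volume[, , k], ua, us)
      }
      recon$provenance <- c(recon$provenance,
                            sprintf("unsharp_mask(amount=%g, sigma=%g)", ua, us))
    }
    write_volume_tiff(recon, file.path(out_dir, "recon"))
    out$recon <- recon
  }

  if ("report" %in% stages) {
    recon <- out$recon %||% read_volume_tiff(file.path(out_dir, "recon"))
    vol <- out$phantom %||% generate_phantom(spec)  # deterministic ground truth
    out$report <- .pipeline_report(recon, vol, spec)
    write_quality_report(out$report, file.path(out_dir, "report.json"))
  }

  if ("register" %in% stages) {
    recon <- out$recon %||% read_volume_tiff(file.path(out_dir, "recon"))
    rg <- cfg$register %||% list()
    k <- rg$depth %||% max(1L, dim(recon$volume)[3] %/% 2)
    section <- simulate_section(
      recon, k, thickness_um = rg$thickness_um %||% 5,
      transform = rigid_transform_2d(rg$theta_deg %||% 0,
                                     c(rg$t_row %||% 0, rg$t_col %||% 0)),
      intensity = c(rg$gain %||% 1, rg$offset %||% 0),
      dropout_frac = rg$dropout_frac %||% 0,
      seed = rg$seed %||% (master_seed + 2L))
    fit <- find_best_plane(recon, section,
                           search = list(theta_range = rg$theta_range %||% c(-10, 10),
                                         theta_step = rg$theta_step %||% 1))
    .write_scaled_tiff(section, file.path(out_dir, "section.tif"), range(section))
    write_overlay(recon$volume[, , fit$depth], section, fit$transform,
                  file.path(out_dir, "overlay.tif"))
    jsonlite::write_json(
      list(best_depth = fit$depth, theta_deg = fit$transform$theta_deg,
           t = fit$transform$t, score = fit$transform$score,
           scores = as.list(fit$scores)),
      file.path(out_dir, "registration.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    out$registration <- fit
  }

  invisible(out)
}

#' Paraffin background mask of a phantom slice
#'
#' The paraffin voxels of slice `k`, eroded away from interfaces — the
#' background region used for de-trending and cupping scoring.
#' @param vol a `labeled_volume`.
#' @param k slice index.
#' @param erode_px erosion half-width in pixels.
#' @export
paraffin_background <- function(vol, k = 1, erode_px = 3) {
  material_mask(vol, "paraffin", k, erode_px = erode_px)
}

#' De-trending reference mask of a phantom slice
#'
#' Paraffin background plus the eroded glandular compartment. The paraffin
#' of a full-field block scan is a thin annulus, over which a 2D quadratic
#' is unconstrained in the interior; adding the spatially distributed,
#' nominally homogeneous glandular tissue keeps the fitted trend anchored
#' across the whole field of view.
#' @param vol a `labeled_volume`.
#' @param k slice index.
#' @export
detrend_reference_mask <- function(vol, k = 1) {
  paraffin_background(vol, k) | material_mask(vol, "glandular", k, erode_px = 8)
}

# quality metrics for a reconstructed phantom scan, using the ground-truth
# label map for ROI definitions
.pipeline_report <- function(recon, vol, spec) {
  d3 <- dim(recon$volume)[3]
  k <- max(1L, d3 %/% 2 + d3 %% 2)
  slice <- recon$volume[, , k]
  crop <- function(m) { # detector window may be narrower than the phantom
    d <- dim(vol$labels)
    if (all(d[1:2] == dim(m))) return(vol$labels[, , min(k, d[3])])
    stop_vh("phantom/reconstruction size mismatch in report stage")
  }
  labels_k <- crop(slice)
  lv <- list(labels = array(labels_k, c(dim(labels_k), 1)), legend = vol$legend)
  roi_g <- material_mask(lv, "glandular", 1, erode_px = 4)
  roi_a <- material_mask(lv, "adipose", 1, erode_px = 4)
  cnr_ga <- if (sum(roi_g) >= 25 && sum(roi_a) >= 25) {
    cnr(slice, roi_g, roi_a)
  } else NA_real_
  # edge segment across the tissue/paraffin boundary, located from the
  # ground-truth tissue mask; several candidate rows and both crossings
  # are tried, since a single row may hit an object near the boundary
  tm <- vol$tissue_mask
  cy0 <- round(mean(row(tm)[tm]))
  fw <- NA_real_
  for (dy in c(0, -7, 7, -14, 14, -21, 21)) {
    cy <- cy0 + dy
    if (cy < 2 || cy > nrow(slice) - 1 || !any(tm[cy, ])) next
    for (x_edge in c(max(which(tm[cy, ])), min(which(tm[cy, ])))) {
      half_seg <- min(15, ncol(slice) - x_edge - 1, x_edge - 1)
      fw <- tryCatch(
        edge_fwhm(slice, c(cy, x_edge - half_seg), c(cy, x_edge + half_seg),
                  pixel_um = recon$voxel_um),
        error = function(e) NA_real_)
      if (is.finite(fw)) break
    }
    if (is.finite(fw)) break
  }
  if (!is.finite(fw)) stop_vh("no measurable tissue/paraffin edge found for the report")
  bg <- detrend_reference_mask(vol, min(k, dim(vol$labels)[3]))
  quality_report(
    cnr = list(glandular_vs_adipose = cnr_ga),
    edge_fwhm_um = fw,
    ring_score = ring_score(slice),
    cupping_score = cupping_score(slice, bg),
    provenance = recon$provenance)
}
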