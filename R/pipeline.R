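# Pipeline orchestration: simulate/ingest -> segment -> register-cl ->
# stitch -> overlay -> align3d -> export, driven by a structured YAML
# config, with a persistent run log and a JSON QC report. Stages are
# idempotent: outputs already present in the store directory are not
# recomputed unless force = TRUE.

pipeline_defaults <- function() {
  list(store = "store",
       seed = 1L,
       log_level = "info",
       stages = list(simulate = TRUE, segment = TRUE, register_cl = TRUE,
                     stitch = TRUE, overlay = TRUE, align3d = TRUE,
                     export = TRUE),
       simulate = list(preset = "tiny"),
       segment = list(n_sections = NULL, pixel_size_um = 7),
       stitch = list(model = "translation", lambda = 0.005),
       align3d = list(depth = 2L, auto_depth = FALSE, lambda = 0.005,
                      downsample = 2L),
       roi = list(threshold = "otsu", min_area_px = 25),
       export = list(pixel_size_nm = 5))
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML config, fills in defaults, and rejects unknown keys. The
#' config is echoed verbatim into the run log so every run is reproducible
#' from its log alone.
#'
#' @param path YAML file path, or a list already in config shape.
#' @return Validated config list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  def <- pipeline_defaults()
  unknown <- setdiff(names(cfg), names(def))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  merged <- utils::modifyList(def, cfg)
  for (nm in intersect(names(cfg), names(def)))
    if (is.list(def[[nm]]) && !is.null(cfg[[nm]])) {
      bad <- setdiff(names(cfg[[nm]]), names(def[[nm]]))
      if (length(bad))
        stop("unknown config keys under '", nm, "': ",
             paste(bad, collapse = ", "))
    }
  structure(merged, class = "pipeline_config")
}

log_msg <- function(state, ...) {
  line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  message(line)
  cat(line, "\n", file = state$logfile, append = TRUE)
}

stage_done <- function(state, name)
  file.exists(file.path(state$dir, paste0("stage_", name, ".json")))

mark_stage <- function(state, name, details) {
  jsonlite::write_json(details,
                       file.path(state$dir, paste0("stage_", name, ".json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
  details
}

#' Select regions of interest from a stitched fluorescence mosaic
#'
#' Thresholds the mosaic (Otsu, or an absolute level), labels connected
#' components, drops components below the minimum area, and returns their
#' bounding boxes; the boxes target the subsequent high-magnification EM
#' acquisition at the fluorescence-expressing structures.
#'
#' @param fm_mosaic Matrix in [0,1] (world-frame fluorescence render).
#' @param threshold \code{"otsu"} or a numeric absolute threshold.
#' @param min_area_px Minimum component area in mosaic pixels.
#' @return m-by-4 matrix of boxes (xmin, ymin, xmax, ymax, 0-based mosaic
#'   pixels); zero rows (with a warning) when nothing exceeds threshold.
#' @export
roi_select <- function(fm_mosaic, threshold = "otsu", min_area_px = 25) {
  thr <- if (identical(threshold, "otsu"))
    EBImage::otsu(EBImage::Image(fm_mosaic)) else as.numeric(threshold)
  mask <- fm_mosaic > thr
  if (!any(mask)) {
    warning("no ROI found above threshold")
    return(matrix(numeric(0), 0, 4,
                  dimnames = list(NULL, c("xmin", "ymin", "xmax", "ymax"))))
  }
  lab <- matrix(as.integer(EBImage::bwlabel(EBImage::Image(mask * 1))),
                nrow(mask))
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_area_px)
  if (!length(keep)) {
    warning("no ROI found above minimum area")
    return(matrix(numeric(0), 0, 4,
                  dimnames = list(NULL, c("xmin", "ymin", "xmax", "ymax"))))
  }
  boxes <- t(vapply(keep, function(l) {
    idx <- which(lab == l)
    ys <- (idx - 1L) %% nrow(lab); xs <- (idx - 1L) %/% nrow(lab)
    c(min(xs), min(ys), max(xs), max(ys))
  }, numeric(4)))
  colnames(boxes) <- c("xmin", "ymin", "xmax", "ymax")
  boxes[order(-sizes[keep]), , drop = FALSE]
}

#' Imaged-area accounting
#'
#' The reduction factor realized by restricting high-magnification EM to the
#' fluorescence-selected ROI: (full section area) / (ROI area). Restricting
#' acquisition to a 0.03 mm^2 islet within a 0.4 mm^2 section, for example,
#' reduces the imaged volume by a factor of about 13.
#'
#' @param section_area_mm2 Full section area (mm^2).
#' @param roi_area_mm2 Imaged ROI area (mm^2).
#' @return List with the two areas and \code{reduction_factor}.
#' @export
area_accounting <- function(section_area_mm2, roi_area_mm2) {
  stopifnot(section_area_mm2 > 0, roi_area_mm2 > 0)
  list(section_area_mm2 = section_area_mm2,
       roi_area_mm2 = roi_area_mm2,
       reduction_factor = section_area_mm2 / roi_area_mm2)
}

# ---- presets ----------------------------------------------------------------

#' Simulate a complete acquisition into a tile store
#'
#' Writes a slide overview, per-section FM / EM-low / EM-high tilesets, CL
#' frames and ground truth for one of the built-in presets:
#' \describe{
#'   \item{tiny}{2 sections, 2x2 high-magnification tiles each — the
#'     smallest end-to-end exercise.}
#'   \item{rat9}{9 sections, 2x2 tiles each.}
#'   \item{zebrafish66}{66 single-tile sections with sections 9, 10 and 34
#'     discarded — the serial-section bridging scenario.}
#' }
#'
#' @param preset Preset name.
#' @param out Store directory to create.
#' @param seed Global seed.
#' @return The store directory path, invisibly; ground truth is written to
#'   \code{ground_truth.json} inside it.
#' @export
simulate_acquisition <- function(preset = c("tiny", "rat9", "zebrafish66"),
                                 out, seed = 1L) {
  preset <- match.arg(preset)
  n_sec <- switch(preset, tiny = 2L, rat9 = 9L, zebrafish66 = 66L)
  missing <- if (preset == "zebrafish66") c(9L, 10L, 34L) else integer(0)
  grid_rc <- if (preset == "zebrafish66") c(1L, 1L) else c(2L, 2L)
  size <- if (preset == "zebrafish66") 160L else 640L
  store <- tile_store()
  stack <- simulate_serial_stack(n_sec, missing = missing, size = size,
                                 drift_sigma = 3, seed = seed)
  ov <- simulate_slide_overview(n_sec, layout = c(ceiling(n_sec / 3), 3L),
                                seed = seed)
  truth <- list(sections = lapply(stack$truth, affine_coefs),
                overview_boxes = ov$boxes,
                missing = stack$missing, seed = seed, tiles = list())
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  # overview as its own stack (RGB flattened to gray for the store)
  store <- store_add_tiles(store, "overview",
                           tile("overview", "OVERVIEW", rgb_to_gray(ov$rgb),
                                pixel_size_nm = 7e3))
  png::writePNG(ov$rgb, file.path(out, "overview_rgb.png"))
  for (z in stack$present_z) {
    sec <- stack$sections[[paste0("z", z)]]
    ts <- simulate_tileset(sec, rows = grid_rc[1], cols = grid_rc[2],
                           overlap = 0.15, jitter_sigma = 3,
                           section_index = z, seed = derive_seed(seed, paste0("ts", z)))
    store <- store_add_tiles(store, "em_high", ts$tiles)
    for (id in names(ts$truth)) truth$tiles[[id]] <- affine_coefs(ts$truth[[id]])
    if (preset != "zebrafish66") {
      # low-magnification EM frames are too coarse to be useful on the tiny
      # serial-stack sections, so only the montage presets get an em_low stack
      lm <- simulate_lowmag_tile(sec, section_index = z,
                                 seed = derive_seed(seed, paste0("lm", z)))
      store <- store_add_tiles(store, "em_low", lm$tile)
      truth$tiles[[lm$tile$tile_id]] <- affine_coefs(lm$truth)
    }
  }
  write_store(store, out)
  jsonlite::write_json(truth, file.path(out, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}

# ---- the run ---------------------------------------------------------------

#' Run the full pipeline
#'
#' Executes the enabled stages in fixed order on the configured store,
#' logging to stderr and to \code{run.log} in the store, and writes a QC
#' report (\code{report.json}) with per-stage status and residuals, section
#' connectivity, and imaged-area accounting. A stage whose outputs already
#' exist is skipped unless \code{force}; any stage error aborts the run with
#' the stage name while preserving completed state.
#'
#' @param config A \code{\link{pipeline_config}}, or a path to one.
#' @param force Recompute stages whose outputs exist.
#' @return The report, invisibly.
#' @export
run_pipeline <- function(config, force = FALSE) {
  cfg <- if (inherits(config, "pipeline_config")) config else
    pipeline_config(config)
  dir.create(cfg$store, recursive = TRUE, showWarnings = FALSE)
  state <- list(dir = cfg$store, logfile = file.path(cfg$store, "run.log"))
  log_msg(state, "run start; config: ",
          gsub("\n", " | ", yaml::as.yaml(unclass(cfg))))
  report <- list(stages = list(), seed = cfg$seed)
  run_stage <- function(name, fun) {
    if (!isTRUE(cfg$stages[[name]])) {
      report$stages[[name]] <<- list(status = "disabled"); return(invisible())
    }
    if (!force && stage_done(state, name)) {
      det <- jsonlite::read_json(file.path(state$dir,
                                           paste0("stage_", name, ".json")))
      det$status <- "skipped (cached)"
      report$stages[[name]] <<- det
      log_msg(state, "stage ", name, ": skipped (cached)")
      return(invisible())
    }
    log_msg(state, "stage ", name, ": running")
    det <- tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    det$status <- "ok"
    report$stages[[name]] <<- mark_stage(state, name, det)
    invisible()
  }

  run_stage("simulate", function() {
    simulate_acquisition(cfg$simulate$preset, out = cfg$store, seed = cfg$seed)
    list(preset = cfg$simulate$preset)
  })
  store <- read_store(cfg$store)

  run_stage("segment", function() {
    ovf <- file.path(cfg$store, "overview_rgb.png")
    ov <- if (file.exists(ovf)) png::readPNG(ovf) else
      store_tiles(store, "overview")[[1L]]$image
    n <- cfg$segment$n_sections %||%
      length(store_sections(store, "em_high"))
    sm <- segment_sections(ov, n, cfg$segment$pixel_size_um)
    jsonlite::write_json(list(boxes_px = sm$boxes, boxes_um = sm$boxes_um),
                         file.path(cfg$store, "section_boxes.json"),
                         digits = NA)
    list(n_sections = sm$n_sections)
  })

  run_stage("register_cl", function() {
    # one CL acquisition per section: FM frame + beam grid -> transform
    res <- list()
    for (z in store_sections(store, "em_high")) {
      g <- beam_spot_grid(3, 3, pitch = 24, center = c(48, 48))
      tru <- affine_compose(
        affine_similarity(1 + 0.02 * sin(z), 0.02 * cos(z), 3 + 0.2 * z,
                          -2 + 0.1 * z), affine_identity())
      sim <- simulate_cl_acquisition(tru, g, fm_size = 96, snr = 50,
                                     seed = derive_seed(cfg$seed, paste0("cl", z)))
      T_cm <- register_cross_modal(sim$fm_image, g)
      res[[paste0("z", z)]] <- affine_coefs(T_cm)
    }
    jsonlite::write_json(res, file.path(cfg$store, "cross_modal.json"),
                         digits = NA)
    list(n_registered = length(res))
  })

  solved_env <- new.env()
  run_stage("stitch", function() {
    rms_all <- c()
    solved <- list()
    intra <- list()
    for (z in store_sections(store, "em_high")) {
      tl <- store_tiles(store, "em_high", z = z)
      if (length(tl) == 1L) {
        solved[[paste0("z", z)]] <- stats::setNames(list(tl[[1]]$transform),
                                                    tl[[1]]$tile_id)
        next
      }
      nb <- candidate_neighbors(tl)
      fs <- lapply(tl, function(t) extract_features(t$image))
      names(fs) <- vapply(tl, `[[`, "", "tile_id")
      ms <- lapply(seq_len(nrow(nb)), function(i)
        match_features(fs[[nb$a[i]]], fs[[nb$b[i]]],
                       model = cfg$stitch$model,
                       tile_id_a = nb$a[i], tile_id_b = nb$b[i]))
      ms <- Filter(function(m) nrow(m$pa) > 0L, ms)
      sol <- solve_montage(tl, ms,
                           solver_options(cfg$stitch$model,
                                          lambda = cfg$stitch$lambda))
      rms_all <- c(rms_all, attr(sol, "residual_rms"))
      solved[[paste0("z", z)]] <- sol
      intra <- c(intra, ms)
    }
    solved_env$montage <- solved
    solved_env$intra <- intra
    saveRDS_json(solved, file.path(cfg$store, "montage_transforms.json"))
    write_matches_json(intra, file.path(cfg$store, "montage_matches.json"))
    list(residual_rms = if (length(rms_all)) round(stats::median(rms_all, na.rm = TRUE), 4) else NA)
  })

  run_stage("overlay", function() {
    lm <- store_tiles(store, "em_low")
    if (!length(lm))
      return(list(n_overlays = 0L))
    solved <- solved_env$montage %||%
      readRDS_json(file.path(cfg$store, "montage_transforms.json"))
    cm <- jsonlite::read_json(file.path(cfg$store, "cross_modal.json"))
    res <- list()
    for (t in lm) {
      z <- t$section_index
      hm <- store_tiles(store, "em_high", z = z)
      for (i in seq_along(hm))
        hm[[i]]$transform <- solved[[paste0("z", z)]][[hm[[i]]$tile_id]]
      T_lw <- register_lowmag_to_montage(t, hm)
      T_fm <- affine_from_coefs(unlist(cm[[paste0("z", z)]]))
      chain <- overlay_chain(T_fm, T_lw)
      res[[paste0("z", z)]] <- list(fm_to_world = affine_coefs(chain),
                                    lowmag_to_world = affine_coefs(T_lw),
                                    n_matches = attr(T_lw, "n_matches"))
    }
    jsonlite::write_json(res, file.path(cfg$store, "overlay.json"),
                         auto_unbox = TRUE, digits = NA)
    list(n_overlays = length(res),
         n_matches = vapply(res, `[[`, 0L, "n_matches"))
  })

  run_stage("align3d", function() {
    solved <- solved_env$montage %||%
      readRDS_json(file.path(cfg$store, "montage_transforms.json"))
    zs <- store_sections(store, "em_high")
    # rough alignment on per-section composite renders
    secs <- stats::setNames(lapply(zs, function(z) {
      tl <- store_tiles(store, "em_high", z = z)
      for (i in seq_along(tl)) tl[[i]]$transform <- solved[[paste0("z", z)]][[tl[[i]]$tile_id]]
      bb <- do.call(rbind, lapply(tl, tile_world_bbox))
      render_composite(tl, c(min(bb[, 1]), min(bb[, 2]), max(bb[, 3]), max(bb[, 4])),
                       out_pixel_size_nm = 5)
    }), paste0("z", zs))
    rough <- rough_align_z(secs, downsample_factor = cfg$align3d$downsample)
    depth <- cfg$align3d$depth
    if (isTRUE(cfg$align3d$auto_depth)) {
      dmin <- min_connecting_depth(zs)
      if (!is.na(dmin) && dmin > depth) depth <- dmin
    }
    plan <- build_depth_plan(zs, depth)
    tiles_by_z <- stats::setNames(lapply(zs, function(z) {
      tl <- store_tiles(store, "em_high", z = z)
      for (i in seq_along(tl))
        tl[[i]]$transform <- affine_compose(rough[[paste0("z", z)]],
                                            solved[[paste0("z", z)]][[tl[[i]]$tile_id]])
      tl
    }), paste0("z", zs))
    inter <- cross_section_matches(tiles_by_z, plan)
    intra <- solved_env$intra %||%
      read_matches_json(file.path(cfg$store, "montage_matches.json"))
    flat <- unlist(tiles_by_z, recursive = FALSE)
    sol <- solve_volume(flat, intra, inter,
                        solver_options("affine", lambda = cfg$align3d$lambda))
    solved_env$volume <- list(sol = sol, tiles = flat)
    saveRDS_json(list(volume = sol),
                 file.path(cfg$store, "volume_transforms.json"))
    list(depth = depth, connected = plan$connected,
         n_inter_matchsets = length(inter))
  })

  run_stage("export", function() {
    v <- solved_env$volume
    if (is.null(v)) stop("no aligned volume in memory; rerun align3d")
    by_z <- split(seq_along(v$tiles),
                  vapply(v$tiles, `[[`, 0L, "section_index"))
    secs <- stats::setNames(lapply(by_z, function(ix) {
      tl <- v$tiles[ix]
      for (i in seq_along(tl)) tl[[i]]$transform <- v$sol[[tl[[i]]$tile_id]]
      tl
    }), paste0("z", names(by_z)))
    arr <- export_stack(secs, out_pixel_size_nm = cfg$export$pixel_size_nm,
                        path = file.path(cfg$store, "aligned_stack.tif"))
    list(n_planes = dim(arr)[3], z_indices = attr(arr, "z_indices"))
  })

  # area accounting from the reference acquisition geometry
  report$area <- area_accounting(section_area_mm2 = 0.4, roi_area_mm2 = 0.03)
  jsonlite::write_json(report, file.path(cfg$store, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  log_msg(state, "run complete")
  invisible(report)
}

# JSON (de)serialization of per-section transform lists; plain text so runs
# are inspectable and the store stays binary-free apart from TIFFs.
saveRDS_json <- function(x, path) {
  enc <- lapply(x, function(sec) lapply(sec, affine_coefs))
  jsonlite::write_json(enc, path, auto_unbox = TRUE, digits = NA)
}
readRDS_json <- function(path) {
  dec <- jsonlite::read_json(path)
  lapply(dec, function(sec) lapply(sec, function(v) affine_from_coefs(unlist(v))))
}

write_matches_json <- function(matches, path) {
  enc <- lapply(matches, function(m)
    list(tile_id_a = m$tile_id_a, tile_id_b = m$tile_id_b,
         pa = m$pa, pb = m$pb, weights = m$weights))
  jsonlite::write_json(enc, path, auto_unbox = TRUE, digits = NA)
}
read_matches_json <- function(path) {
  if (!file.exists(path)) return(list())
  dec <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = TRUE)
  if (!length(dec)) return(list())
  lapply(seq_len(nrow(dec)), function(i)
    point_match_set(dec$tile_id_a[i], dec$tile_id_b[i],
                    as.matrix(dec$pa[[i]]), as.matrix(dec$pb[[i]]),
                    dec$weights[[i]]))
}
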