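# End-to-end orchestration: segmentation -> registration -> optical-flow
# direction -> perfusion, with a JSON-serialisable run report.

#' Pipeline configuration
#'
#' Bundles the inputs and stage parameters of a full preoperative vs
#' postoperative run. Videos and masks may be given as in-memory objects or
#' as file paths understood by [read_video()] / [read_mask()]. When a
#' trained segmentation model is supplied the vessel masks are predicted
#' from the stable frames; alternatively precomputed masks can be passed
#' directly.
#'
#' @param pre_video,post_video `icg_video` objects or paths.
#' @param model Optional trained [build_multitask_unet()] handle.
#' @param pre_masks,post_masks Optional lists with `all` and `recipient`
#'   logical masks (used when `model` is `NULL`).
#' @param pre_centerline,post_centerline Optional ordered (row, col)
#'   centreline matrices for the recipient vessel; traced from the masks
#'   when absent.
#' @param rois Optional list of [roi()] objects (defined in the
#'   postoperative frame) for time-luminance curves.
#' @param hs [hs_params()].
#' @param direction [direction_config()].
#' @param ratio Ratio-test threshold for registration.
#' @param overlap_min,min_matches Registration success thresholds.
#' @param out_dir Optional directory for artifacts (frames, maps, report).
#' @param seed Seed controlling the RANSAC sampler.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(pre_video, post_video, model = NULL,
                            pre_masks = NULL, post_masks = NULL,
                            pre_centerline = NULL, post_centerline = NULL,
                            rois = NULL, hs = hs_params(),
                            direction = direction_config(), ratio = 0.8,
                            overlap_min = 0.35, min_matches = 10,
                            out_dir = NULL, seed = 1) {
  if (is.null(model) && (is.null(pre_masks) || is.null(post_masks))) {
    stop("supply either a trained segmentation model or precomputed masks")
  }
  structure(list(pre_video = pre_video, post_video = post_video,
                 model = model, pre_masks = pre_masks,
                 post_masks = post_masks,
                 pre_centerline = pre_centerline,
                 post_centerline = post_centerline, rois = rois, hs = hs,
                 direction = direction, ratio = ratio,
                 overlap_min = overlap_min, min_matches = min_matches,
                 out_dir = out_dir, seed = seed),
            class = "pipeline_config")
}

#' Run the full blood-flow analysis pipeline
#'
#' Executes, in order: stable-frame selection and vessel segmentation on
#' both videos (or mask pass-through), registration of the preoperative
#' vessel map onto the postoperative one, flow-direction classification of
#' the recipient vessel in both videos, change detection, and perfusion
#' mapping (the preoperative map is computed on the registered, warped
#' video). A stage failure is recorded in the report and downstream stages
#' that depend on it are skipped.
#'
#' @param config A [pipeline_config()].
#' @return A `run_report` list with per-stage results; written as
#'   `report.json` to `out_dir` when configured.
#' @export
run_pipeline <- function(config) {
  report <- list(version = as.character(utils::packageVersion("icgflow")),
                 seed = config$seed, stages = list())

  pre <- if (inherits(config$pre_video, "icg_video")) config$pre_video else
    read_video(config$pre_video)
  post <- if (inherits(config$post_video, "icg_video")) config$post_video else
    read_video(config$post_video)

  # --- segmentation ---------------------------------------------------
  seg <- tryCatch({
    get_masks <- function(video, masks) {
      if (!is.null(masks)) {
        list(all = masks$all, recipient = masks$recipient,
             stable_frame = select_stable_frame(video), predicted = FALSE)
      } else {
        sf <- select_stable_frame(video)
        p <- predict_with_tta(config$model, video$frames[, , sf])
        list(all = p$mask_all, recipient = p$mask_receip, stable_frame = sf,
             predicted = TRUE)
      }
    }
    list(pre = get_masks(pre, config$pre_masks),
         post = get_masks(post, config$post_masks))
  }, error = function(e) structure(list(error = conditionMessage(e)),
                                   class = "stage_error"))
  report$stages$segmentation <- if (inherits(seg, "stage_error")) seg else {
    list(pre_stable_frame = seg$pre$stable_frame,
         post_stable_frame = seg$post$stable_frame,
         pre_vessel_px = sum(seg$pre$all), post_vessel_px = sum(seg$post$all),
         predicted = seg$pre$predicted)
  }
  if (inherits(seg, "stage_error")) return(finish_report(report, config))

  # --- registration ---------------------------------------------------
  reg <- tryCatch(
    register_pair(seg$pre$all, seg$post$all, ratio = config$ratio,
                  overlap_min = config$overlap_min,
                  min_matches = config$min_matches, seed = config$seed),
    error = function(e) structure(list(error = conditionMessage(e)),
                                  class = "stage_error"))
  report$stages$registration <- if (inherits(reg, "stage_error")) reg else {
    c(reg$metrics,
      list(homography = if (!is.null(reg$homography))
        unclass(reg$homography) else NULL))
  }

  # --- flow direction -------------------------------------------------
  dir_stage <- tryCatch({
    lab_pre <- vessel_flow_direction(pre, seg$pre$recipient,
                                     config$pre_centerline, config$hs,
                                     config$direction)
    lab_post <- vessel_flow_direction(post, seg$post$recipient,
                                      config$post_centerline, config$hs,
                                      config$direction)
    list(pre = lab_pre, post = lab_post,
         change = direction_change(lab_pre, lab_post))
  }, error = function(e) structure(list(error = conditionMessage(e)),
                                   class = "stage_error"))
  report$stages$direction <- if (inherits(dir_stage, "stage_error")) dir_stage else {
    list(pre = dir_stage$pre$category,
         pre_confidence = dir_stage$pre$confidence,
         post = dir_stage$post$category,
         post_confidence = dir_stage$post$confidence,
         change = dir_stage$change)
  }

  # --- perfusion ------------------------------------------------------
  perf <- tryCatch({
    reg_ok <- !inherits(reg, "stage_error") && isTRUE(reg$metrics$success)
    post_map <- perfusion_color_map(post, seg$post$all)
    out <- list(post_map = post_map)
    if (reg_ok) {
      warped_frames <- array(0, dim = dim(pre$frames))
      for (f in seq_len(n_frames(pre))) {
        warped_frames[, , f] <- warp_image(pre$frames[, , f], reg$homography,
                                           dim(pre$frames)[1:2], "bilinear")
      }
      warped_pre <- icg_video(round(warped_frames), pre$fps)
      out$pre_map_registered <- perfusion_color_map(warped_pre, reg$warped_mask)
      out$comparable <- TRUE
    } else {
      out$comparable <- FALSE
    }
    if (!is.null(config$rois)) {
      out$curves <- lapply(config$rois, function(r) luminance_curve(post, r))
      out$delay_times <- vapply(out$curves, delay_time, numeric(1))
    }
    out
  }, error = function(e) structure(list(error = conditionMessage(e)),
                                   class = "stage_error"))
  report$stages$perfusion <- if (inherits(perf, "stage_error")) perf else {
    res <- list(comparable = perf$comparable)
    if (!is.null(perf$delay_times)) res$delay_times <- perf$delay_times
    res
  }

  if (!inherits(perf, "stage_error") && !is.null(config$out_dir)) {
    write_perfusion_map(perf$post_map,
                        png_file = file.path(config$out_dir, "perfusion_post.png"),
                        tiff_file = file.path(config$out_dir, "ttp_post.tif"))
    if (isTRUE(perf$comparable)) {
      write_perfusion_map(perf$pre_map_registered,
                          png_file = file.path(config$out_dir,
                                               "perfusion_pre_registered.png"))
    }
  }
  finish_report(report, config)
}

finish_report <- function(report, config) {
  report$ok <- !any(vapply(report$stages, inherits, logical(1), "stage_error"))
  class(report) <- "run_report"
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(unclass_deep(report),
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         matrix = "rowmajor")
  }
  report
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(x, unclass_deep) else
    if (is.object(x)) unclass(x) else x
}

#' @export
print.run_report <- function(x, ...) {
  cat("ICG blood-flow pipeline report\n")
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    if (inherits(st, "stage_error")) {
      cat(sprintf("  %-13s FAILED: %s\n", nm, st$error))
    } else if (nm == "direction") {
      cat(sprintf("  %-13s pre %s, post %s -> %s\n", nm, st$pre, st$post,
                  st$change))
    } else if (nm == "registration") {
      cat(sprintf("  %-13s success %s (overlap %.2f, %d matches)\n", nm,
                  st$success, st$overlap, st$n_matches))
    } else {
      cat(sprintf("  %-13s ok\n", nm))
    }
  }
  invisible(x)
}
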