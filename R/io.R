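# Readers and writers for videos (PNG frame sequences), masks, ROIs, flow
# fields and ground truth.

#' Read an ICG video
#'
#' Accepts a directory of numbered grayscale PNG frames (sorted by file
#' name), a character vector of PNG paths, or a numeric H x W x T array.
#' Colour frames are converted to grayscale by the Rec. 601 luma transform.
#' Values are returned on the 8-bit 0-255 scale.
#'
#' @param path Directory, vector of PNG files, or array.
#' @param fps Frames per second; used when the source carries no rate
#'   metadata (PNG sequences never do). Default 25.
#' @return An [icg_video()].
#' @export
read_video <- function(path, fps = 25) {
  if (is.array(path) || is.matrix(path)) return(icg_video(path, fps))
  files <- if (length(path) == 1 && dir.exists(path)) {
    sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
  } else as.character(path)
  if (length(files) == 0 || !all(file.exists(files))) {
    stop("no frames found at ", paste(path, collapse = ", "))
  }
  frames <- lapply(files, read_gray_png)
  d <- dim(frames[[1]])
  if (!all(vapply(frames, function(f) all(dim(f) == d), logical(1)))) {
    stop("frames differ in shape")
  }
  arr <- array(unlist(frames), dim = c(d, length(frames)))
  icg_video(round(arr), fps = fps)
}

read_gray_png <- function(file) {
  img <- png::readPNG(file)
  if (length(dim(img)) == 3) {
    img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  }
  img * 255
}

#' Write an ICG video as a numbered PNG sequence
#'
#' @param video An `icg_video`.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @return Invisibly, the written file paths.
#' @export
write_video <- function(video, dir, prefix = "frame") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nt <- n_frames(video)
  paths <- file.path(dir, sprintf("%s_%05d.png", prefix, seq_len(nt)))
  for (i in seq_len(nt)) {
    png::writePNG(pmin(pmax(video$frames[, , i] / 255, 0), 1), paths[i])
  }
  invisible(paths)
}

#' Read or write a binary mask PNG
#'
#' @param file PNG path.
#' @return `read_mask`: logical matrix.
#' @export
read_mask <- function(file) {
  read_gray_png(file) > 127
}

#' @rdname read_mask
#' @param mask Logical matrix.
#' @export
write_mask <- function(mask, file) {
  dir.create(dirname(file), showWarnings = FALSE, recursive = TRUE)
  png::writePNG(matrix(as.numeric(mask), nrow(mask)), file)
  invisible(file)
}

#' Read or write regions of interest as JSON
#'
#' The JSON format is a list of objects with `id`, `polygon` (n x 2 array of
#' (x, y) vertices) and optional `label`.
#'
#' @param file JSON path.
#' @param shape Frame shape `c(H, W)` for rasterisation.
#' @return `read_rois`: list of [roi()] objects.
#' @export
read_rois <- function(file, shape) {
  spec <- jsonlite::read_json(file, simplifyVector = TRUE)
  if (is.data.frame(spec)) spec <- split(spec, seq_len(nrow(spec)))
  lapply(spec, function(s) {
    poly <- matrix(unlist(s$polygon), ncol = 2, byrow = !is.matrix(s$polygon))
    roi(id = s$id, polygon = poly, shape = shape,
        label = if (!is.null(s$label)) s$label else "")
  })
}

#' @rdname read_rois
#' @param rois List of [roi()] objects (stored as bounding polygons of their
#'   masks is not attempted; pass polygon-based ROIs to round-trip exactly).
#' @param polygons List of n x 2 polygon matrices, one per ROI id.
#' @param ids Character vector of ids.
#' @export
write_rois <- function(file, polygons, ids, rois = NULL) {
  spec <- mapply(function(p, id) list(id = id, polygon = p),
                 polygons, ids, SIMPLIFY = FALSE)
  jsonlite::write_json(spec, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Write a flow field as a two-band 32-bit float TIFF
#'
#' Band 1 is u (x velocity), band 2 is v (y velocity), px/frame.
#'
#' @param flow A `flow_field`.
#' @param file TIFF path.
#' @export
write_flow_field <- function(flow, file) {
  dir.create(dirname(file), showWarnings = FALSE, recursive = TRUE)
  arr <- array(c(flow$u, flow$v), dim = c(dim(flow$u), 2))
  tiff::writeTIFF(arr, file, bits.per.sample = 32, reduce = FALSE)
  invisible(file)
}

#' Write generator ground truth
#'
#' Homography and direction labels as JSON, the arrival-time map as a
#' 32-bit float TIFF (background encoded as -1).
#'
#' @param truth A `ground_truth` or `ground_truth_pair`.
#' @param dir Output directory.
#' @export
write_ground_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(direction = truth$direction)
  if (!is.null(truth$true_homography)) {
    meta$true_homography <- unclass(truth$true_homography)
  }
  jsonlite::write_json(meta, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  ams <- truth$arrival_map
  if (is.matrix(ams)) ams <- list(arrival = ams)
  for (nm in names(ams)) {
    am <- ams[[nm]]
    am[is.na(am)] <- -1
    # float TIFF values must lie in [0,1] for the writer: store scaled,
    # with the scale recorded alongside
    sc <- max(am, 1)
    tiff::writeTIFF((am + 1) / (sc + 1), file.path(dir, paste0("arrival_", nm, ".tif")),
                    bits.per.sample = 32)
    meta[[paste0("arrival_scale_", nm)]] <- sc
  }
  jsonlite::write_json(meta, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(dir)
}

#' Write a perfusion map to PNG (colour) and TIFF (time-to-peak)
#'
#' @param map A `perfusion_map`.
#' @param png_file,tiff_file Output paths (either may be `NULL`).
#' @export
write_perfusion_map <- function(map, png_file = NULL, tiff_file = NULL) {
  if (!is.null(png_file)) {
    dir.create(dirname(png_file), showWarnings = FALSE, recursive = TRUE)
    png::writePNG(map$rgb, png_file)
  }
  if (!is.null(tiff_file)) {
    dir.create(dirname(tiff_file), showWarnings = FALSE, recursive = TRUE)
    ttp <- map$ttp
    ttp[is.na(ttp)] <- -1
    sc <- max(ttp, 1)
    tiff::writeTIFF((ttp + 1) / (sc + 1), tiff_file, bits.per.sample = 32)
  }
  invisible(NULL)
}
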