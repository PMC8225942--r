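# Segmentation module: samples, joint loss, flip augmentation, training,
# test-time averaging, and overlap metrics.

#' Construct a segmentation training sample
#'
#' @param image Numeric H x W matrix (any intensity range; normalised to
#'   \[0, 1\] at training time).
#' @param label_all Logical H x W mask of all vessels.
#' @param label_receip Logical H x W mask of the recipient vessel; must be a
#'   subset of `label_all`.
#' @return A `seg_sample` list.
#' @export
seg_sample <- function(image, label_all, label_receip) {
  image <- as.matrix(image)
  if (!all(dim(image) == dim(label_all)) ||
      !all(dim(image) == dim(label_receip))) {
    stop("image and labels must share one shape")
  }
  if (any(label_receip & !label_all)) {
    stop("recipient label must be a subset of the all-vessel label")
  }
  structure(list(image = image, label_all = label_all == 1,
                 label_receip = label_receip == 1), class = "seg_sample")
}

flip_sample <- function(s, how) {
  f <- switch(how,
              identity = function(m) m,
              horizontal = function(m) m[, rev(seq_len(ncol(m))), drop = FALSE],
              vertical = function(m) m[rev(seq_len(nrow(m))), , drop = FALSE],
              diagonal = function(m) t(m),
              rot180 = function(m) m[rev(seq_len(nrow(m))),
                                     rev(seq_len(ncol(m))), drop = FALSE])
  seg_sample(f(s$image), f(s$label_all), f(s$label_receip))
}

#' Four-fold flip augmentation
#'
#' Expands each sample into four: the original plus its horizontal, vertical
#' and diagonal (transpose) flips, labels flipped identically.
#'
#' @param samples List of [seg_sample()] objects.
#' @return List of length `4 * length(samples)`.
#' @export
augment_fourfold <- function(samples) {
  out <- vector("list", 4L * length(samples))
  k <- 1L
  for (s in samples) {
    for (how in c("identity", "horizontal", "vertical", "diagonal")) {
      out[[k]] <- flip_sample(s, how)
      k <- k + 1L
    }
  }
  out
}

#' Joint segmentation loss
#'
#' Weighted two-task negative log-likelihood: `alpha` times the mean per-pixel
#' NLL of the all-vessel head plus `beta` times that of the recipient head,
#' each head's probability being the softmax probability assigned to the true
#' label at each pixel. Probabilities are clamped away from zero by a small
#' epsilon before the log.
#'
#' @param pred A prediction with `prob_all` and `prob_receip` H x W matrices
#'   (probability of the vessel class), e.g. from [predict_segmenter()].
#' @param sample A [seg_sample()] with matching shape.
#' @param alpha,beta Task weights.
#' @return Nonnegative scalar loss.
#' @export
multitask_loss <- function(pred, sample, alpha = 1, beta = 1) {
  if (!all(dim(pred$prob_all) == dim(sample$label_all))) {
    stop("prediction and sample shapes differ")
  }
  eps <- 1e-12
  nll <- function(p_vessel, label) {
    p_true <- ifelse(label, p_vessel, 1 - p_vessel)
    -mean(log(pmax(p_true, eps)))
  }
  alpha * nll(pred$prob_all, sample$label_all) +
    beta * nll(pred$prob_receip, sample$label_receip)
}

stack_batch <- function(samples) {
  imgs <- lapply(samples, function(s) {
    m <- s$image
    top <- max(m, 1)
    if (top > 1) m <- m / 255
    as.vector(m)
  })
  list(x = matrix(unlist(imgs), ncol = 1),
       y_all = unlist(lapply(samples, function(s) as.integer(s$label_all))),
       y_receip = unlist(lapply(samples, function(s) as.integer(s$label_receip))))
}

#' Train the multi-task segmenter
#'
#' Adam optimisation of the joint NLL loss over randomly drawn batches, with
#' the stepped learning-rate schedule from the configuration. All samples
#' must share one shape with sides divisible by `2^encoder_depth`. Training
#' aborts with a diagnostic if the loss turns non-finite.
#'
#' @param model A [build_multitask_unet()] handle.
#' @param samples List of [seg_sample()] objects (at least 2, or 1 for
#'   deliberate overfitting checks).
#' @param config A [seg_config()]; defaults to the model's own.
#' @param seed Seed for batch sampling (reproducible trace).
#' @param verbose Print loss every 25 iterations.
#' @return The model with trained parameters plus `loss_trace` and
#'   `lr_trace` (one value per iteration).
#' @export
train_segmenter <- function(model, samples, config = model$config, seed = 1,
                            verbose = FALSE) {
  if (length(samples) < 1) stop("need training samples")
  H <- nrow(samples[[1]]$image); W <- ncol(samples[[1]]$image)
  div <- 2^config$encoder_depth
  if (H %% div != 0 || W %% div != 0) {
    stop(sprintf("sample sides must be divisible by %d", div))
  }
  state <- adam_init(model$params)
  loss_trace <- numeric(config$total_iterations)
  lr_trace <- numeric(config$total_iterations)
  npx <- H * W

  with_seed(seed, {
    for (it in seq_len(config$total_iterations)) {
      ids <- sample.int(length(samples), config$batch_size, replace = TRUE)
      batch <- stack_batch(samples[ids])
      N <- length(ids)
      fwd <- unet_forward(model, batch$x, H, W, N, train = TRUE)

      n_tot <- npx * N
      p_all <- fwd$prob_all; p_rec <- fwd$prob_receip
      ia <- cbind(seq_len(n_tot), batch$y_all + 1L)
      ir <- cbind(seq_len(n_tot), batch$y_receip + 1L)
      eps <- 1e-12
      loss <- config$alpha * (-mean(log(pmax(p_all[ia], eps)))) +
        config$beta * (-mean(log(pmax(p_rec[ir], eps))))
      if (!is.finite(loss)) {
        stop(sprintf("training diverged (non-finite loss at iteration %d)", it))
      }
      loss_trace[it] <- loss
      lr <- lr_at(it - 1L, config$lr_schedule)  # schedule indexed from 0
      lr_trace[it] <- lr

      one_all <- cbind(1 - batch$y_all, batch$y_all)
      one_rec <- cbind(1 - batch$y_receip, batch$y_receip)
      dl_all <- config$alpha * (p_all - one_all) / n_tot
      dl_rec <- config$beta * (p_rec - one_rec) / n_tot
      grads <- unet_backward(model, fwd, dl_all, dl_rec, H, W, N)
      st <- adam_step(model$params, grads, state, lr)
      model$params <- st$params
      state <- st$state
      if (verbose && it %% 25 == 0) {
        message(sprintf("iter %3d  lr %.4g  loss %.4f", it, lr, loss))
      }
    }
  })
  model$loss_trace <- loss_trace
  model$lr_trace <- lr_trace
  model
}

# Reflection-pad a matrix so both sides are divisible by `div`.
pad_reflect <- function(m, div) {
  H <- nrow(m); W <- ncol(m)
  ph <- (div - H %% div) %% div
  pw <- (div - W %% div) %% div
  if (ph > 0) m <- rbind(m, m[rev(seq_len(nrow(m)))[seq_len(ph)], , drop = FALSE])
  if (pw > 0) m <- cbind(m, m[, rev(seq_len(ncol(m)))[seq_len(pw)], drop = FALSE])
  list(m = m, H = H, W = W)
}

#' Predict vessel probabilities for one image
#'
#' Single forward pass of the trained network. Inputs whose sides are not
#' divisible by `2^encoder_depth` are reflection-padded and the output
#' cropped back.
#'
#' @param model Trained [build_multitask_unet()] handle.
#' @param image Numeric H x W matrix.
#' @return A `seg_prediction` list: `prob_all`, `prob_receip` (H x W vessel
#'   probabilities), `mask_all`, `mask_receip` (thresholded), `threshold`.
#' @export
predict_segmenter <- function(model, image) {
  img <- as.matrix(image)
  if (max(img) > 1) img <- img / 255
  div <- 2^model$config$encoder_depth
  pd <- pad_reflect(img, div)
  H <- nrow(pd$m); W <- ncol(pd$m)
  fwd <- unet_forward(model, matrix(as.vector(pd$m), ncol = 1), H, W, 1L)
  pa <- matrix(fwd$prob_all[, 2], H, W)[seq_len(pd$H), seq_len(pd$W)]
  pr <- matrix(fwd$prob_receip[, 2], H, W)[seq_len(pd$H), seq_len(pd$W)]
  thr <- model$config$threshold
  structure(list(prob_all = pa, prob_receip = pr,
                 mask_all = pa >= thr, mask_receip = pr >= thr,
                 threshold = thr), class = "seg_prediction")
}

#' Predict with five-view test-time averaging
#'
#' Runs the network on the original image and on its horizontal, vertical
#' and diagonal flips plus the 180-degree rotation, maps each probability
#' map back to the original orientation, and averages the five.
#'
#' @inheritParams predict_segmenter
#' @return A `seg_prediction` (as in [predict_segmenter()]).
#' @export
predict_with_tta <- function(model, image) {
  views <- c("identity", "horizontal", "vertical", "diagonal", "rot180")
  unflip <- list(identity = function(m) m,
                 horizontal = function(m) m[, rev(seq_len(ncol(m))), drop = FALSE],
                 vertical = function(m) m[rev(seq_len(nrow(m))), , drop = FALSE],
                 diagonal = function(m) t(m),
                 rot180 = function(m) m[rev(seq_len(nrow(m))),
                                        rev(seq_len(ncol(m))), drop = FALSE])
  flip_img <- unflip  # every view transform is an involution
  acc_all <- 0; acc_rec <- 0
  for (v in views) {
    p <- predict_segmenter(model, flip_img[[v]](as.matrix(image)))
    acc_all <- acc_all + unflip[[v]](p$prob_all)
    acc_rec <- acc_rec + unflip[[v]](p$prob_receip)
  }
  pa <- acc_all / length(views); pr <- acc_rec / length(views)
  thr <- model$config$threshold
  structure(list(prob_all = pa, prob_receip = pr,
                 mask_all = pa >= thr, mask_receip = pr >= thr,
                 threshold = thr), class = "seg_prediction")
}

#' Save or load a trained segmenter
#'
#' The weights go to a single serialised file, the configuration to a JSON
#' sidecar (`<path>.json`) for human inspection.
#'
#' @param model Trained [build_multitask_unet()] handle.
#' @param path Checkpoint file path.
#' @return `load_segmenter`: the restored model handle.
#' @export
save_segmenter <- function(model, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  saveRDS(model, path)
  jsonlite::write_json(unclass(model$config), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(path)
}

#' @rdname save_segmenter
#' @export
load_segmenter <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "multitask_unet")) stop("not a segmenter checkpoint")
  model
}

check_binary_pair <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("masks must share one shape")
  va <- unique(as.vector(a)); vb <- unique(as.vector(b))
  ok <- function(v) all(v %in% c(0, 1, TRUE, FALSE))
  if (!ok(va) || !ok(vb)) stop("masks must be binary")
}

#' Dice coefficient of two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param maskA,maskB Binary matrices of one shape.
#' @return Value in \[0, 1\].
#' @export
dice <- function(maskA, maskB) {
  check_binary_pair(maskA, maskB)
  a <- maskA == 1; b <- maskB == 1
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Jaccard index of two binary masks
#'
#' `|A n B| / |A u B|`; defined as 1 when both masks are empty.
#'
#' @inheritParams dice
#' @return Value in \[0, 1\].
#' @export
jaccard <- function(maskA, maskB) {
  check_binary_pair(maskA, maskB)
  a <- maskA == 1; b <- maskB == 1
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

#' Select the earliest brightness-stable frame
#'
#' Finds the first frame from which the (vessel-region) frame-mean
#' brightness no longer changes — i.e. the start of the wash-in plateau, the
#' frames on which vessels are fully filled and segmentation is performed.
#' Operationally: the frame after the last per-frame change of at least
#' `eps` intensity units, provided at least `window` stable frames follow
#' it. If the video never stabilises the last frame is returned with a
#' warning.
#'
#' @param video An `icg_video` with at least 2 frames.
#' @param mask Optional logical mask restricting the brightness average.
#' @param eps Per-frame change threshold (intensity units, default 0.5).
#' @param window Minimum number of stable frames required after the plateau
#'   starts (default 5).
#' @return Frame index (1-based).
#' @export
select_stable_frame <- function(video, mask = NULL, eps = 0.5, window = 5) {
  d <- dim(video$frames)
  if (d[3] < 2) stop("need at least 2 frames")
  fr <- matrix(video$frames, d[1] * d[2], d[3])
  m <- if (is.null(mask)) colMeans(fr) else colMeans(fr[which(mask), , drop = FALSE])
  ch <- abs(diff(m))
  if (all(ch < eps)) return(1L)
  last_change <- max(which(ch >= eps))
  stable <- last_change + 1L
  if (d[3] - stable < min(window, d[3] - 1L) - 1L) {
    warning("brightness never stabilises; returning the last frame")
    return(d[3])
  }
  stable
}
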