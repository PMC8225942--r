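# Multi-task U-Net: one contracting encoder, two structurally identical
# expanding decoders (all-vessel head and recipient-vessel head), trained
# jointly with a weighted negative log-likelihood loss.

#' Segmentation configuration
#'
#' Training and architecture settings for the multi-task vessel segmenter.
#' The learning-rate schedule is the plateau-style step schedule 0.01 /
#' 0.001 / 0.0001 switching at iterations 0, 20 and 100, with 150 iterations
#' of batch 32 in total, under Adam.
#'
#' @param alpha,beta Loss weights for the all-vessel and recipient-vessel
#'   heads (both 1 by default; `alpha + beta` must be positive).
#' @param batch_size Images per iteration (default 32).
#' @param lr_schedule Data frame / list of `iteration` and `rate` pairs;
#'   the rate applies from that iteration on. Rates must be positive and
#'   nonincreasing.
#' @param total_iterations Optimisation steps (default 150).
#' @param encoder_depth Number of encoder blocks, each ending in a 2x2 max
#'   pool (default 4), so inputs must have sides divisible by
#'   `2^encoder_depth` (others are reflection-padded).
#' @param widths Channel widths of the encoder blocks, finest first.
#' @param threshold Binarisation threshold on predicted probabilities.
#' @return A `seg_config` list.
#' @export
seg_config <- function(alpha = 1, beta = 1, batch_size = 32,
                       lr_schedule = data.frame(
                         iteration = c(0, 20, 100),
                         rate = c(0.01, 0.001, 0.0001)),
                       total_iterations = 150, encoder_depth = 4,
                       widths = c(8, 16, 32, 64), threshold = 0.5) {
  if (alpha < 0 || beta < 0 || alpha + beta <= 0) {
    stop("alpha and beta must be nonnegative with a positive sum")
  }
  lr_schedule <- as.data.frame(lr_schedule)
  if (any(lr_schedule$rate <= 0) || is.unsorted(-lr_schedule$rate)) {
    stop("learning rates must be positive and nonincreasing")
  }
  if (length(widths) != encoder_depth) {
    stop("need one channel width per encoder level")
  }
  structure(list(alpha = alpha, beta = beta, batch_size = batch_size,
                 lr_schedule = lr_schedule,
                 total_iterations = total_iterations,
                 encoder_depth = encoder_depth, widths = widths,
                 threshold = threshold), class = "seg_config")
}

lr_at <- function(iteration, schedule) {
  i <- max(which(schedule$iteration <= iteration))
  schedule$rate[i]
}

#' Build the multi-task U-Net
#'
#' One shared contracting path (per level: two 3x3 convolutions with ReLU
#' followed by 2x2 max pooling) feeding two structurally identical decoder
#' paths (per level: 2x2 up-convolution, concatenation of the corresponding
#' encoder feature map, two 3x3 convolutions with ReLU), each closed by a
#' 1x1 convolution to two-class logits. Softmax turns the logits of each
#' head into per-pixel probabilities for the all-vessel and recipient-vessel
#' tasks.
#'
#' @param config A [seg_config()].
#' @param seed Seed for the (He) weight initialisation.
#' @return A `multitask_unet` model handle.
#' @export
build_multitask_unet <- function(config = seg_config(), seed = 1) {
  d <- config$encoder_depth
  w <- config$widths
  wb <- w[d]  # bottleneck width
  with_seed(seed, {
    enc <- lapply(seq_len(d), function(l) {
      cin <- if (l == 1) 1L else w[l - 1]
      list(c1 = conv3_init(cin, w[l]), c2 = conv3_init(w[l], w[l]))
    })
    bott <- list(c1 = conv3_init(w[d], wb), c2 = conv3_init(wb, wb))
    head_params <- function() {
      dec <- lapply(rev(seq_len(d)), function(l) {
        cin <- if (l == d) wb else w[l + 1]
        list(up = up_init(cin, w[l]),
             c1 = conv3_init(2L * w[l], w[l]),
             c2 = conv3_init(w[l], w[l]))
      })
      list(dec = dec, final = conv1_init(w[1], 2L))
    }
    structure(list(params = list(enc = enc, bott = bott,
                                 head_all = head_params(),
                                 head_receip = head_params()),
                   config = config), class = "multitask_unet")
  })
}

# Forward pass on a stacked batch. Returns head probabilities and, when
# train = TRUE, every intermediate activation needed by the backward pass.
unet_forward <- function(model, x, H, W, N, train = FALSE) {
  cfg <- model$config; d <- cfg$encoder_depth
  p <- model$params
  cache <- list(enc = vector("list", d), heads = list())
  skips <- vector("list", d)
  cur <- x; ch <- H; cw <- W
  for (l in seq_len(d)) {
    idx <- conv3_idx(ch, cw, N)
    a1 <- conv3_fw(cur, p$enc[[l]]$c1, idx); r1 <- relu_fw(a1)
    a2 <- conv3_fw(r1, p$enc[[l]]$c2, idx); r2 <- relu_fw(a2)
    pi <- pool_idx(ch, cw, N)
    pl <- pool_fw(r2, pi)
    if (train) cache$enc[[l]] <- list(x_in = cur, r1 = r1, r2 = r2,
                                      arg = pl$arg, H = ch, W = cw)
    skips[[l]] <- r2
    cur <- pl$out
    ch <- ch %/% 2L; cw <- cw %/% 2L
  }
  idx <- conv3_idx(ch, cw, N)
  b1 <- conv3_fw(cur, p$bott$c1, idx); rb1 <- relu_fw(b1)
  b2 <- conv3_fw(rb1, p$bott$c2, idx); rb2 <- relu_fw(b2)
  if (train) cache$bott <- list(x_in = cur, r1 = rb1, r2 = rb2, H = ch, W = cw)

  run_head <- function(hp, hname) {
    z <- rb2; zh <- ch; zw <- cw
    hc <- vector("list", d)
    for (i in seq_len(d)) {
      l <- d - i + 1L
      ui <- up_idx(zh, zw, N)
      up <- up_fw(z, hp$dec[[i]]$up, ui)
      zh <- zh * 2L; zw <- zw * 2L
      cat_in <- cbind(up, skips[[l]])
      idx <- conv3_idx(zh, zw, N)
      a1 <- conv3_fw(cat_in, hp$dec[[i]]$c1, idx); r1 <- relu_fw(a1)
      a2 <- conv3_fw(r1, hp$dec[[i]]$c2, idx); r2 <- relu_fw(a2)
      if (train) hc[[i]] <- list(x_in = z, cat_in = cat_in, r1 = r1, r2 = r2,
                                 Hin = zh %/% 2L, Win = zw %/% 2L)
      z <- r2
    }
    logits <- conv1_fw(z, hp$final)
    if (train) cache$heads[[hname]] <<- list(dec = hc, feat = z)
    list(logits = logits, prob = softmax2(logits))
  }
  out_all <- run_head(p$head_all, "all")
  out_receip <- run_head(p$head_receip, "receip")
  res <- list(prob_all = out_all$prob, prob_receip = out_receip$prob,
              logits_all = out_all$logits, logits_receip = out_receip$logits)
  if (train) res$cache <- cache
  res
}

# Backward pass: gradients of the weighted NLL loss w.r.t. every parameter.
# dl_all / dl_receip are gradients w.r.t. the two heads' logits.
unet_backward <- function(model, fwd, dl_all, dl_receip, H, W, N) {
  cfg <- model$config; d <- cfg$encoder_depth
  p <- model$params; cache <- fwd$cache

  back_head <- function(hp, hcache, dlogits) {
    g_final <- conv1_bw(dlogits, hcache$feat, hp$final)
    dz <- g_final$dx
    gdec <- vector("list", d)
    dskips <- vector("list", d)
    for (i in rev(seq_len(d))) {
      l <- d - i + 1L
      hc <- hcache$dec[[i]]
      zh <- hc$Hin * 2L; zw <- hc$Win * 2L
      idx <- conv3_idx(zh, zw, N)
      dz <- relu_bw(dz, hc$r2)
      g2 <- conv3_bw(dz, hc$r1, hp$dec[[i]]$c2, idx)
      dz <- relu_bw(g2$dx, hc$r1)
      g1 <- conv3_bw(dz, hc$cat_in, hp$dec[[i]]$c1, idx)
      w_up <- length(hp$dec[[i]]$up$b)
      dup <- g1$dx[, seq_len(w_up), drop = FALSE]
      dskips[[l]] <- g1$dx[, -seq_len(w_up), drop = FALSE]
      ui <- up_idx(hc$Hin, hc$Win, N)
      gu <- up_bw(dup, hc$x_in, hp$dec[[i]]$up, ui)
      gdec[[i]] <- list(up = gu$grad, c1 = g1$grad, c2 = g2$grad)
      dz <- gu$dx
    }
    list(grads = list(dec = gdec, final = g_final$grad),
         dbott = dz, dskips = dskips)
  }

  ba <- back_head(p$head_all, cache$heads$all, dl_all)
  br <- back_head(p$head_receip, cache$heads$receip, dl_receip)

  # bottleneck
  bc <- cache$bott
  idx <- conv3_idx(bc$H, bc$W, N)
  dz <- relu_bw(ba$dbott + br$dbott, bc$r2)
  g2 <- conv3_bw(dz, bc$r1, p$bott$c2, idx)
  dz <- relu_bw(g2$dx, bc$r1)
  g1 <- conv3_bw(dz, bc$x_in, p$bott$c1, idx)
  gbott <- list(c1 = g1$grad, c2 = g2$grad)
  dz <- g1$dx

  genc <- vector("list", d)
  for (l in rev(seq_len(d))) {
    ec <- cache$enc[[l]]
    dpool <- pool_bw(dz, ec$arg, nrow(ec$r2))
    dr2 <- dpool + ba$dskips[[l]] + br$dskips[[l]]
    idx <- conv3_idx(ec$H, ec$W, N)
    dr2 <- relu_bw(dr2, ec$r2)
    g2 <- conv3_bw(dr2, ec$r1, p$enc[[l]]$c2, idx)
    dr1 <- relu_bw(g2$dx, ec$r1)
    g1 <- conv3_bw(dr1, ec$x_in, p$enc[[l]]$c1, idx)
    genc[[l]] <- list(c1 = g1$grad, c2 = g2$grad)
    dz <- g1$dx
  }
  list(enc = genc, bott = gbott, head_all = ba$grads,
       head_receip = br$grads)
}
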