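# Shared fixture builders. Everything is generated in code at test time;
# seeds are fixed so every run sees identical data.

# A stable-frame segmentation sample: vessels at plateau brightness over a
# dark background, labels from the generating tree.
make_seg_sample <- function(seed, shape = c(64, 64), n_branches = 3) {
  tree <- generate_vessel_tree(seed, pmax(shape, 64), n_branches)
  sp <- wash_in_spec(duration = 0.2, arrival_start = 0, arrival_span = 0.01,
                     rise_time = 0.02)
  g <- generate_icg_video(tree, sp, seed = seed)
  s <- seg_sample(g$video$frames[, , n_frames(g$video)], tree$mask,
                  tree$recipient_mask)
  if (any(shape < 64)) {
    # central crop for fast small-scale training checks
    r0 <- (nrow(s$image) - shape[1]) %/% 2
    c0 <- (ncol(s$image) - shape[2]) %/% 2
    ri <- r0 + seq_len(shape[1]); ci <- c0 + seq_len(shape[2])
    s <- seg_sample(s$image[ri, ci], s$label_all[ri, ci],
                    s$label_receip[ri, ci])
  }
  s
}

# An analytically translated smooth blob pair: the second frame is the first
# shifted by exactly `shift` pixels in x (no resampling error).
blob_pair <- function(shift = 2, size = 128, sigma = 15) {
  f <- function(cx) outer(seq_len(size), seq_len(size), function(r, c) {
    255 * exp(-((r - size / 2)^2 + (c - cx)^2) / (2 * sigma^2))
  })
  list(a = f(size / 2 - shift / 2), b = f(size / 2 + shift / 2),
       mask = f(size / 2) > 0.2 * 255)
}

# One case of the registration transform grid: a vessel tree observed under
# a known similarity; 256 px / 7 branches give keypoint counts comparable to
# clinical vessel maps.
registration_case <- function(i, size = 256) {
  tree <- generate_vessel_tree(i, c(size, size), 7)
  rot <- c(0, 5, 10, 20)[(i %% 4) + 1]
  sc <- c(0.9, 1.0, 1.2)[(i %% 3) + 1]
  tr <- c((i %% 7) - 3, ((i * 3) %% 7) - 3)
  Ht <- similarity_homography(rot, sc, tr, c(size, size))
  post <- warp_image(tree$mask, Ht, c(size, size), "nearest")
  list(tree = tree, truth = Ht, post = post, size = size)
}

corner_error <- function(H_est, H_true, size) {
  corners <- cbind(c(1, size, 1, size), c(1, 1, size, size))
  max(sqrt(rowSums((apply_homography(H_est, corners) -
                      apply_homography(H_true, corners))^2)))
}
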