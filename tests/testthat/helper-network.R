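# Plain-R reference forward pass (independent of the compiled engine).
# Deliberately written as naive loops over the documented semantics:
# zero-padded 3x3 convolutions, BN in evaluation mode (running
# statistics), SE gating, global max/average pooling head.

ref_forward <- function(model, img) {
  cfg <- model$config
  p <- model$params
  H <- cfg$rows; W <- cfg$cols
  x <- array(as.numeric(img) / 255, dim = c(H, W, cfg$channels))
  bn_i <- 0L
  for (l in seq_len(cfg$conv_layers)) {
    cin <- dim(x)[3]
    out <- array(0, dim = c(H, W, cfg$filters))
    Wl <- p$conv_W[[l]]
    for (f in seq_len(cfg$filters)) {
      acc <- matrix(p$conv_b[[l]][f], H, W)
      for (dx in -1:1) for (dy in -1:1) {
        k <- (dx + 1L) * 3L + (dy + 1L)          # tap index, 0-based
        for (cc in seq_len(cin)) {
          w <- Wl[f, k * cin + cc]
          shifted <- matrix(0, H, W)
          ys <- max(1, 1 + dy):min(H, H + dy)    # source rows y + dy
          xs <- max(1, 1 + dx):min(W, W + dx)
          shifted[ys - dy, xs - dx] <- x[ys, xs, cc]
          acc <- acc + w * shifted
        }
      }
      out[, , f] <- pmax(acc, 0)
    }
    x <- out
    if (l %% cfg$se_every == 0) {
      bn_i <- bn_i + 1L
      sd <- sqrt(p$bn_rvar[[bn_i]] + 1e-5)
      for (f in seq_len(cfg$filters)) {
        x[, , f] <- (x[, , f] - p$bn_rmean[[bn_i]][f]) / sd[f] *
          p$bn_gamma[[bn_i]][f] + p$bn_beta[[bn_i]][f]
      }
      x <- se_block(x, p$se_W1[[bn_i]], p$se_b1[[bn_i]],
                    p$se_W2[[bn_i]], p$se_b2[[bn_i]])$output
    }
  }
  mx <- apply(x, 3, max)
  av <- apply(x, 3, mean)
  stats::plogis(sum(p$head_w * c(mx, av)) + p$head_b)
}
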