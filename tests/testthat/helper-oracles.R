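# Independent oracles used across tests.

# naive BFS flood fill for 3D connected components, pure R
flood_fill_components <- function(mask, connectivity = 26) {
  d <- dim(mask)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  m <- abs(offs$dx) + abs(offs$dy) + abs(offs$dz)
  offs <- offs[m > 0 & m <= switch(as.character(connectivity),
                                   "6" = 1, "18" = 2, "26" = 3), ]
  lab <- array(0L, d)
  nxt <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      p <- arrayInd(v, d)
      for (o in seq_len(nrow(offs))) {
        q <- p + c(offs$dx[o], offs$dy[o], offs$dz[o])
        if (any(q < 1) || any(q > d)) next
        w <- q[1] + (q[2] - 1) * d[1] + (q[3] - 1) * d[1] * d[2]
        if (mask[w] && lab[w] == 0L) {
          lab[w] <- nxt
          queue <- c(queue, w)
        }
      }
    }
  }
  lab
}

# noiseless phantom acquired directly at the 5 mm analysis thickness
# (no resampling step), used by several files
small_phantom_spec <- function(noise_sigma = 0, ...) {
  phantom_spec(shape = c(192L, 192L, 20L), spacing_mm = c(1, 1, 5),
               noise_sigma = noise_sigma, ...)
}
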