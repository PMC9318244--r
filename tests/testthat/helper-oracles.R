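# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately re-derive each quantity with the most
# literal possible code, separate from the package implementation.

# Literal per-box double loop over the eps-grid: max-min+1 per box.
bruteBoxSum <- function(px, eps) {
  total <- 0
  for (r0 in seq(1, nrow(px), by = eps)) {
    for (c0 in seq(1, ncol(px), by = eps)) {
      box <- px[r0:min(r0 + eps - 1, nrow(px)),
                c0:min(c0 + eps - 1, ncol(px)), drop = FALSE]
      total <- total + (max(box) - min(box) + 1)
    }
  }
  total
}

# Literal per-pixel divide-blend: multiply, add one, divide, truncate, clamp.
bruteDivideBlend <- function(lo, up) {
  out <- lo
  for (i in seq_len(nrow(lo))) for (j in seq_len(ncol(lo))) {
    e <- trunc(lo[i, j] * 256 / (up[i, j] + 1))
    out[i, j] <- min(255, e)
  }
  out
}

# Literal greedy raster ROI placement: per-pixel inside check, no
# summed-area table.
bruteGreedyROIs <- function(mask, s) {
  acc <- matrix(integer(), 0, 2)
  for (r in seq_len(nrow(mask) - s + 1)) {
    for (c in seq_len(ncol(mask) - s + 1)) {
      if (!all(mask[r:(r + s - 1), c:(c + s - 1)])) next
      ok <- TRUE
      if (nrow(acc) > 0)
        ok <- !any(abs(acc[, 1] - r) < s & abs(acc[, 2] - c) < s)
      if (ok) acc <- rbind(acc, c(r, c))
    }
  }
  acc
}

# Binary disc mask centred in an n x n frame.
discMask <- function(radius, n = 2 * radius + 21) {
  ctr <- (n + 1) / 2
  outer(seq_len(n), seq_len(n),
        function(r, c) (r - ctr)^2 + (c - ctr)^2 < radius^2)
}

randomImage <- function(nr, nc) GrayImage(matrix(sample(0:255, nr * nc, TRUE), nr, nc))

# Segmentation chain without the cleanup warnings cluttering test output.
quietSegment <- function(img, ...) suppressWarnings(segmentLesion(img, ...))

# Shape FD of one rendered synthetic lesion (the pipeline's shape stage).
lesionShapeFD <- function(params) {
  seg <- quietSegment(renderLesion(params))
  fd(estimateFD(seg$blended, powerSeriesScales(dim(seg$blended))))
}
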