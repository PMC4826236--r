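# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so generators never perturb user-level randomness.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Zero-mean, unit-sd Gaussian random field with correlation length `sigma`
# (pixels), built by smoothing white noise.
smooth_field <- function(h, w, sigma) {
  # pad so the Gaussian kernel never exceeds the field, then crop back
  k <- 2L * as.integer(2 * ceiling(3 * sigma) + 1) + 1L
  H <- max(h, k); W <- max(w, k)
  z <- matrix(stats::rnorm(H * W), H, W)
  if (sigma > 0) {
    z <- as_plain(EBImage::gblur(z, sigma = sigma))
  }
  z <- z[seq_len(h), seq_len(w), drop = FALSE]
  s <- stats::sd(as.vector(z))
  if (s == 0) return(matrix(0, h, w))
  (z - mean(z)) / s
}

# EBImage returns Image objects; collapse back to a plain matrix.
as_plain <- function(x) {
  x <- EBImage::imageData(x)
  dim2 <- dim(x)
  if (length(dim2) > 2L) dim(x) <- dim2[1:2]
  x
}

# Round half away from zero (half-up for non-negative input), matching the
# fixed-point convention used for intensity rescaling.
round_half_up <- function(x) floor(x + 0.5)

# Clip, round and coerce a float canvas to an image_grid of the given depth.
as_image <- function(canvas, bit_depth = 8L) {
  top <- 2^bit_depth - 1
  v <- round_half_up(pmin(pmax(canvas, 0), top))
  image_grid(matrix(v, nrow(canvas), ncol(canvas)), bit_depth = bit_depth)
}

# Logical disc mask utilities ------------------------------------------------

# Pixel (row, col) offsets covered by a disc of radius r centred at 0.
disc_offsets <- function(r) {
  rr <- ceiling(r)
  d <- expand.grid(dr = -rr:rr, dc = -rr:rr)
  d[d$dr^2 + d$dc^2 <= r^2, , drop = FALSE]
}

# Paint a disc into a logical matrix, clipped at the borders.
paint_disc <- function(mask, row, col, r) {
  off <- disc_offsets(r)
  rows <- row + off$dr
  cols <- col + off$dc
  keep <- rows >= 1 & rows <= nrow(mask) & cols >= 1 & cols <= ncol(mask)
  mask[cbind(rows[keep], cols[keep])] <- TRUE
  mask
}
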