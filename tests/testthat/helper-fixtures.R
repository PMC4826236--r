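# Shared in-code fixtures; everything is generated at test time.

tiny_texture_spec <- function(seed = 1L, regime = "control", ...) {
  scene_spec(height = 160L, width = 160L, n_nuclei = 5L,
             texture_regime = regime, seed = seed, ...)
}

tiny_foci_spec <- function(seed = 1L, ...) {
  foci_scene_spec(height = 220L, width = 220L, n_nuclei = 3L,
                  seed = seed, ...)
}

# Two ellipses whose interiors overlap, on a dark background: the classic
# touching-nuclei case for watershed splitting.
touching_ellipses_image <- function() {
  h <- 90L; w <- 120L
  canvas <- matrix(0L, h, w)
  for (centre in list(c(45, 45), c(45, 75))) {
    dy <- outer(seq_len(h) - centre[1], rep(1, w))
    dx <- outer(rep(1, h), seq_len(w) - centre[2])
    inside <- (dx / 20)^2 + (dy / 16)^2 <= 1
    canvas[inside] <- 200L
  }
  image_grid(canvas, bit_depth = 8L)
}

# A disc mask of radius r centred in an h x w label matrix, labelled `lab`.
disc_label <- function(h, w, cy, cx, r, lab = 1L, base = NULL) {
  m <- if (is.null(base)) matrix(0L, h, w) else base
  d2 <- outer((seq_len(h) - cy)^2, (seq_len(w) - cx)^2, "+")
  m[d2 <= r^2] <- lab
  m
}
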