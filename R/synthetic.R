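#' Synthetic-scene specification
#'
#' Parameters for the three classes of generated fluorescence scenes:
#' chromatin-texture nuclei (control vs treated), punctate foci channels,
#' and tissue-microarray-like multichannel cores. Intensities are on the
#' scale of the requested bit depth (default 8-bit); all geometry is in
#' pixels. `clumpiness` is the target area fraction of heterochromatin
#' clumps inside each nucleus and is forced to 0 under the control
#' regime. Clumps are rendered at `base_level * clump_gain` with the
#' inter-clump background dimmed so the nuclear mean intensity is
#' conserved — texture, not brightness, separates the regimes — which
#' requires `clumpiness * clump_gain < 1`.
#'
#' @param height,width canvas size in pixels.
#' @param n_nuclei number of nuclei to place.
#' @param nucleus_radius_range min and max mean radius in pixels (>= 2).
#' @param texture_regime `"control"` or `"treated"`.
#' @param clumpiness heterochromatin area fraction in `[0, 1)`.
#' @param clump_gain clump intensity factor (>= 1).
#' @param base_level mean nuclear intensity.
#' @param texture_sd sd of the smooth intranuclear intensity field.
#' @param noise_sd sd of the additive Poisson-like acquisition noise at
#'   `base_level` (scaled by `sqrt(intensity / base_level)` elsewhere).
#' @param foci_per_nucleus planted foci per nucleus: a single count, a
#'   `c(min, max)` range sampled uniformly per nucleus, or one count per
#'   nucleus.
#' @param focus_sigma Gaussian spot sd in pixels.
#' @param focus_amplitude spot peak height above background.
#' @param foci_background mean background level of the foci channel.
#' @param epithelium_fraction fraction of the TMA core covered by
#'   epithelium, in `[0, 0.95]`.
#' @param target_level_nuclear,target_level_cytoplasmic target-channel
#'   intensity in the two epithelial compartments.
#' @param cytokeratin_level cytokeratin intensity on epithelium.
#' @param allow_border allow nuclei to touch the canvas border.
#' @param bit_depth image bit depth, 8 or 16.
#' @param seed integer seed; equal (spec, seed) pairs generate
#'   bit-identical scenes.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(height = 256L, width = 256L, n_nuclei = 12L,
                       nucleus_radius_range = c(12, 18),
                       texture_regime = c("control", "treated"),
                       clumpiness = 0.4, clump_gain = 1.2,
                       base_level = 120, texture_sd = 10, noise_sd = 5,
                       foci_per_nucleus = 7L, focus_sigma = 1.5,
                       focus_amplitude = 150, foci_background = 10,
                       epithelium_fraction = 0.5,
                       target_level_nuclear = 200,
                       target_level_cytoplasmic = 50,
                       cytokeratin_level = 180,
                       allow_border = FALSE, bit_depth = 8L, seed = 1L) {
  texture_regime <- match.arg(texture_regime)
  if (texture_regime == "control") clumpiness <- 0
  if (clumpiness < 0 || clumpiness >= 1) stop("`clumpiness` must be in [0, 1)")
  if (clump_gain < 1) stop("`clump_gain` must be >= 1")
  if (clumpiness * clump_gain >= 1) {
    stop("clumpiness * clump_gain must be < 1 to conserve the nuclear mean")
  }
  if (min(nucleus_radius_range) < 2) stop("nucleus radii must be >= 2 px")
  if (length(nucleus_radius_range) != 2L ||
      nucleus_radius_range[1] > nucleus_radius_range[2]) {
    stop("`nucleus_radius_range` must be c(min, max)")
  }
  if (any(c(base_level, texture_sd, noise_sd, focus_amplitude, foci_background,
            target_level_nuclear, target_level_cytoplasmic,
            cytokeratin_level) < 0)) {
    stop("intensity parameters must be >= 0")
  }
  if (epithelium_fraction < 0 || epithelium_fraction > 0.95) {
    stop("`epithelium_fraction` must be in [0, 0.95]")
  }
  if (any(foci_per_nucleus < 0) || any(foci_per_nucleus != round(foci_per_nucleus))) {
    stop("`foci_per_nucleus` must be non-negative integer(s)")
  }
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_nuclei = as.integer(n_nuclei),
                 nucleus_radius_range = nucleus_radius_range,
                 texture_regime = texture_regime, clumpiness = clumpiness,
                 clump_gain = clump_gain, base_level = base_level,
                 texture_sd = texture_sd, noise_sd = noise_sd,
                 foci_per_nucleus = as.integer(foci_per_nucleus),
                 focus_sigma = focus_sigma, focus_amplitude = focus_amplitude,
                 foci_background = foci_background,
                 epithelium_fraction = epithelium_fraction,
                 target_level_nuclear = target_level_nuclear,
                 target_level_cytoplasmic = target_level_cytoplasmic,
                 cytokeratin_level = cytokeratin_level,
                 allow_border = isTRUE(allow_border),
                 bit_depth = as.integer(bit_depth), seed = as.integer(seed)),
            class = "scene_spec")
}

#' Scene presets for the three study conditions
#'
#' Thin wrappers around [scene_spec()] with geometry suited to each image
#' class: texture scenes use the base defaults; foci scenes use fewer,
#' larger nuclei on a larger canvas so that up to a dozen spots fit at
#' the 4-sigma pairwise separation the planter enforces; TMA scenes use
#' many small nuclei inside an epithelium blob.
#'
#' @param ... overrides passed on to [scene_spec()].
#' @return A `scene_spec`.
#' @export
foci_scene_spec <- function(...) {
  override <- list(...)
  base <- list(height = 360L, width = 360L, n_nuclei = 8L,
               nucleus_radius_range = c(22, 28))
  do.call(scene_spec, utils::modifyList(base, override))
}

#' @rdname foci_scene_spec
#' @export
tma_scene_spec <- function(...) {
  override <- list(...)
  base <- list(height = 300L, width = 300L, n_nuclei = 40L,
               nucleus_radius_range = c(6, 10))
  do.call(scene_spec, utils::modifyList(base, override))
}

# --- geometry ---------------------------------------------------------------

# Place n non-overlapping ellipses; returns a data.frame of centres, axes
# and orientations. Overlap is tested on bounding circles with a 2 px gap.
place_nuclei <- function(spec) {
  h <- spec$height; w <- spec$width
  rr <- spec$nucleus_radius_range
  placed <- data.frame(cy = numeric(), cx = numeric(), a = numeric(),
                       b = numeric(), theta = numeric())
  tries <- 0L
  max_tries <- 400L * max(1L, spec$n_nuclei)
  while (nrow(placed) < spec$n_nuclei) {
    if (tries >= max_tries) {
      stop(sprintf(paste0("could not place %d non-overlapping nuclei on a ",
                          "%dx%d canvas; use a larger canvas or fewer nuclei"),
                   spec$n_nuclei, h, w))
    }
    tries <- tries + 1L
    r <- stats::runif(1, rr[1], rr[2])
    ecc <- stats::runif(1, 1.0, 1.6)
    a <- r * sqrt(ecc); b <- r / sqrt(ecc)
    margin <- if (spec$allow_border) 0 else a + 1
    if (h - margin <= margin || w - margin <= margin) { next }
    cy <- stats::runif(1, 1 + margin, h - margin)
    cx <- stats::runif(1, 1 + margin, w - margin)
    if (nrow(placed) > 0) {
      d <- sqrt((placed$cy - cy)^2 + (placed$cx - cx)^2)
      if (any(d < placed$a + a + 2)) next
    }
    placed <- rbind(placed, data.frame(cy = cy, cx = cx, a = a, b = b,
                                       theta = stats::runif(1, 0, pi)))
  }
  placed
}

# Rasterize placed ellipses into an integer label matrix.
rasterize_nuclei <- function(placed, h, w) {
  lab <- matrix(0L, h, w)
  for (k in seq_len(nrow(placed))) {
    e <- placed[k, ]
    r0 <- max(1L, floor(e$cy - e$a)); r1 <- min(h, ceiling(e$cy + e$a))
    c0 <- max(1L, floor(e$cx - e$a)); c1 <- min(w, ceiling(e$cx + e$a))
    rows <- r0:r1; cols <- c0:c1
    dy <- outer(rows - e$cy, rep(1, length(cols)))
    dx <- outer(rep(1, length(rows)), cols - e$cx)
    u <- (dx * cos(e$theta) + dy * sin(e$theta)) / e$a
    v <- (-dx * sin(e$theta) + dy * cos(e$theta)) / e$b
    inside <- u^2 + v^2 <= 1
    block <- lab[rows, cols]
    block[inside] <- k
    lab[rows, cols] <- block
  }
  lab
}

# Poisson-like additive noise: Gaussian with sd growing as sqrt(signal).
add_noise <- function(canvas, noise_sd, base_level) {
  if (noise_sd <= 0) return(canvas)
  scale <- sqrt(pmax(canvas, 1) / max(base_level, 1))
  canvas + matrix(stats::rnorm(length(canvas)), nrow(canvas)) * noise_sd * scale
}

# --- texture scenes ---------------------------------------------------------

#' Generate a chromatin-texture scene
#'
#' Places non-overlapping elliptical nuclei on a dark background. Control
#' nuclei have a homogeneous interior: `base_level` plus a smooth
#' correlated field (correlation length about a quarter of the nucleus
#' radius). Treated nuclei additionally carry disk-shaped heterochromatin
#' clumps covering about `clumpiness` of the nuclear area at
#' `base_level * clump_gain`, with the inter-clump background dimmed so
#' the nuclear mean is conserved. Poisson-like noise is added last.
#' Deterministic given `spec$seed`.
#'
#' @param spec a [scene_spec()].
#' @return A `synthetic_scene` list: `channels` (named [image_grid]s,
#'   here `dapi`), `truth_nuclei` ([label_mask]), `spec`.
#' @export
generate_texture_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, {
    placed <- place_nuclei(spec)
    lab <- rasterize_nuclei(placed, spec$height, spec$width)
    canvas <- matrix(0, spec$height, spec$width)
    for (k in seq_len(nrow(placed))) {
      sel <- which(lab == k, arr.ind = TRUE)
      rr <- range(sel[, 1]); cc <- range(sel[, 2])
      rows <- rr[1]:rr[2]; cols <- cc[1]:cc[2]
      inmask <- lab[rows, cols, drop = FALSE] == k
      r_mean <- sqrt(placed$a[k] * placed$b[k])
      field <- smooth_field(length(rows), length(cols), r_mean / 4)
      levels <- matrix(spec$base_level, length(rows), length(cols))
      if (spec$texture_regime == "treated" && spec$clumpiness > 0) {
        gain <- plant_clumps(inmask, spec$clumpiness, max(2, round(r_mean / 5)),
                             spec$clump_gain)
        clump <- gain > 1
        n_bg <- sum(inmask & !clump)
        if (any(clump) && n_bg > 0) {
          # dim the inter-clump background so the nuclear mean intensity
          # is exactly conserved (pattern, not brightness, changes)
          bg_gain <- max(0, (sum(inmask) - sum(gain[clump])) / n_bg)
          levels[clump] <- spec$base_level * gain[clump]
          levels[inmask & !clump] <- spec$base_level * bg_gain
        }
      }
      block <- canvas[rows, cols]
      block[inmask] <- levels[inmask] + spec$texture_sd * field[inmask]
      canvas[rows, cols] <- block
    }
    canvas <- add_noise(canvas, spec$noise_sd, spec$base_level)
    list_scene(channels = list(dapi = as_image(canvas, spec$bit_depth)),
               truth_nuclei = label_mask(lab), spec = spec)
  })
}

# Plant discs of radius r at random in-mask centres until the clump union
# covers >= `fraction` of the mask area (inside a nucleus bounding box).
# Condensed chromatin is not one flat plateau, so each clump carries its
# own intensity gain, jittered uniformly around `clump_gain` (later clumps
# overwrite earlier ones where they overlap). Returns a gain matrix that
# is 1 outside clumps.
plant_clumps <- function(inmask, fraction, r, clump_gain) {
  gain <- matrix(1, nrow(inmask), ncol(inmask))
  target <- fraction * sum(inmask)
  px <- which(inmask, arr.ind = TRUE)
  guard <- 0L
  while (sum(gain > 1 & inmask) < target && guard < 10000L) {
    guard <- guard + 1L
    c0 <- px[sample.int(nrow(px), 1L), ]
    g_k <- stats::runif(1, 1 + 0.25 * (clump_gain - 1),
                        1 + 1.75 * (clump_gain - 1))
    disc <- paint_disc(matrix(FALSE, nrow(inmask), ncol(inmask)),
                       c0[1], c0[2], r)
    gain[disc] <- g_k
  }
  gain[!inmask] <- 1
  gain
}

# --- foci scenes ------------------------------------------------------------

#' Generate a foci scene
#'
#' Builds a control-regime DAPI channel (for segmentation) and a foci
#' channel of Gaussian spots planted at uniformly sampled in-nucleus
#' positions with pairwise separation >= 4 * `focus_sigma`, over a low
#' noisy background. Every planted spot is recorded in `truth_foci`.
#'
#' @param spec a [scene_spec()] (see [foci_scene_spec()] for suitable
#'   geometry); `foci_per_nucleus` may be one count, a `c(min, max)`
#'   range, or one count per nucleus.
#' @return A `synthetic_scene` with channels `dapi` and `foci`,
#'   `truth_nuclei`, and `truth_foci` (data.frame `nucleus`, `row`,
#'   `col`, 0-based pixel coordinates).
#' @export
generate_foci_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, {
    placed <- place_nuclei(spec)
    lab <- rasterize_nuclei(placed, spec$height, spec$width)
    n <- nrow(placed)
    counts <- spec$foci_per_nucleus
    counts <- if (length(counts) == 1L) rep(counts, n)
      else if (length(counts) == 2L) sample(counts[1]:counts[2], n, replace = TRUE)
      else if (length(counts) == n) counts
      else stop("`foci_per_nucleus` must have length 1, 2, or n_nuclei")
    dapi <- matrix(0, spec$height, spec$width)
    dapi[lab > 0L] <- spec$base_level
    dapi <- dapi + spec$texture_sd * smooth_field(spec$height, spec$width, 4) *
      (lab > 0L)
    dapi <- add_noise(dapi, spec$noise_sd, spec$base_level)

    foci <- matrix(spec$foci_background, spec$height, spec$width)
    sep <- 4 * spec$focus_sigma
    dm <- as_plain(EBImage::distmap(EBImage::Image(lab > 0L)))
    truth <- data.frame(nucleus = integer(), row = integer(), col = integer())
    for (k in seq_len(n)) {
      if (counts[k] == 0L) next
      cand <- which(lab == k & dm >= 2 * spec$focus_sigma, arr.ind = TRUE)
      pts <- matrix(numeric(), 0, 2)
      tries <- 0L
      while (nrow(pts) < counts[k]) {
        if (tries > 400L * counts[k] || nrow(cand) == 0L) {
          stop(sprintf(paste0("cannot place %d foci at separation %.1f px in ",
                              "nucleus %d; reduce the count or enlarge nuclei"),
                       counts[k], sep, k))
        }
        tries <- tries + 1L
        p <- cand[sample.int(nrow(cand), 1L), ]
        if (nrow(pts) > 0 &&
            any((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2 < sep^2)) next
        pts <- rbind(pts, p)
      }
      for (i in seq_len(nrow(pts))) {
        foci <- add_spot(foci, pts[i, 1], pts[i, 2],
                         spec$focus_amplitude, spec$focus_sigma)
      }
      truth <- rbind(truth, data.frame(nucleus = k, row = pts[, 1] - 1L,
                                       col = pts[, 2] - 1L))
    }
    foci <- add_noise(foci, spec$noise_sd, spec$foci_background)
    list_scene(channels = list(dapi = as_image(dapi, spec$bit_depth),
                               foci = as_image(foci, spec$bit_depth)),
               truth_nuclei = label_mask(lab), truth_foci = truth, spec = spec)
  })
}

# Add a Gaussian spot (peak `amp`, sd `sigma`) at integer centre (r, c).
add_spot <- function(canvas, r, c, amp, sigma) {
  rad <- ceiling(4 * sigma)
  rows <- max(1, r - rad):min(nrow(canvas), r + rad)
  cols <- max(1, c - rad):min(ncol(canvas), c + rad)
  d2 <- outer((rows - r)^2, (cols - c)^2, "+")
  canvas[rows, cols] <- canvas[rows, cols] + amp * exp(-d2 / (2 * sigma^2))
  canvas
}

# --- TMA scenes -------------------------------------------------------------

#' Generate a tissue-microarray core scene
#'
#' A circular core (radius 45% of the smaller canvas side) carries an
#' epithelium blob occupying `epithelium_fraction` of the core area
#' (carved as the upper quantile of a smooth random field, so the
#' realized fraction matches the request to within pixel rounding).
#' Nuclei are placed inside the epithelium. Channels: `dapi` (nuclei),
#' `cytokeratin` (epithelium), `target` (`target_level_nuclear` on
#' nuclear pixels, `target_level_cytoplasmic` on epithelial non-nuclear
#' pixels), each plus noise.
#'
#' @param spec a [scene_spec()] (see [tma_scene_spec()]).
#' @return A `synthetic_scene` with channels `dapi`, `cytokeratin`,
#'   `target`; `truth_nuclei`; `truth_compartments` ([label_mask], 0 =
#'   background, 1 = cytoplasmic, 2 = nuclear); and `truth_core`
#'   (logical core mask).
#' @export
generate_tma_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, {
    h <- spec$height; w <- spec$width
    core_r <- 0.45 * min(h, w)
    cy <- (h + 1) / 2; cx <- (w + 1) / 2
    d2 <- outer((seq_len(h) - cy)^2, (seq_len(w) - cx)^2, "+")
    core <- d2 <= core_r^2
    f <- spec$epithelium_fraction
    epi <- matrix(FALSE, h, w)
    if (f > 0) {
      field <- smooth_field(h, w, core_r / 4)
      thr <- stats::quantile(field[core], 1 - f, names = FALSE)
      epi <- core & field >= thr
    }
    lab <- place_tma_nuclei(epi, spec)
    nuclear <- lab > 0L & epi
    cyto <- epi & !nuclear
    dapi <- matrix(0, h, w); dapi[nuclear] <- spec$base_level
    ck <- matrix(0, h, w); ck[epi] <- spec$cytokeratin_level
    target <- matrix(0, h, w)
    target[nuclear] <- spec$target_level_nuclear
    target[cyto] <- spec$target_level_cytoplasmic
    dapi <- add_noise(dapi, spec$noise_sd, spec$base_level)
    ck <- add_noise(ck, spec$noise_sd, spec$cytokeratin_level)
    target <- add_noise(target, spec$noise_sd,
                        max(spec$target_level_nuclear, 1))
    comp <- matrix(0L, h, w)
    comp[cyto] <- 1L
    comp[nuclear] <- 2L
    list_scene(channels = list(dapi = as_image(dapi, spec$bit_depth),
                               cytokeratin = as_image(ck, spec$bit_depth),
                               target = as_image(target, spec$bit_depth)),
               truth_nuclei = label_mask(lab),
               truth_compartments = label_mask(comp, compact = FALSE),
               truth_core = core, spec = spec)
  })
}

# Circular nuclei with centres inside the epithelium; places as many of
# the requested nuclei as fit without overlap.
place_tma_nuclei <- function(epi, spec) {
  h <- nrow(epi); w <- ncol(epi)
  lab <- matrix(0L, h, w)
  if (!any(epi) || spec$n_nuclei == 0L) return(lab)
  rr <- spec$nucleus_radius_range
  dm <- as_plain(EBImage::distmap(EBImage::Image(epi)))
  centres <- data.frame(cy = numeric(), cx = numeric(), r = numeric())
  k <- 0L; tries <- 0L
  while (k < spec$n_nuclei && tries < 400L * spec$n_nuclei) {
    tries <- tries + 1L
    r <- stats::runif(1, rr[1], rr[2])
    cand <- which(dm >= r * 0.5, arr.ind = TRUE)
    if (nrow(cand) == 0L) break
    p <- cand[sample.int(nrow(cand), 1L), ]
    if (nrow(centres) > 0) {
      d <- sqrt((centres$cy - p[1])^2 + (centres$cx - p[2])^2)
      if (any(d < centres$r + r + 1)) next
    }
    k <- k + 1L
    centres <- rbind(centres, data.frame(cy = p[1], cx = p[2], r = r))
    off <- disc_offsets(r)
    rows <- p[1] + off$dr; cols <- p[2] + off$dc
    keep <- rows >= 1 & rows <= h & cols >= 1 & cols <= w
    idx <- cbind(rows[keep], cols[keep])
    idx <- idx[epi[idx], , drop = FALSE]
    lab[idx] <- k
  }
  lab
}

# --- scene container and sidecar I/O ---------------------------------------

list_scene <- function(channels, truth_nuclei, spec, truth_foci = NULL,
                       truth_compartments = NULL, truth_core = NULL) {
  structure(list(channels = channels, truth_nuclei = truth_nuclei,
                 truth_foci = truth_foci,
                 truth_compartments = truth_compartments,
                 truth_core = truth_core, spec = spec),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %dx%d, channels: %s, %d nuclei (seed %d)\n",
              x$spec$height, x$spec$width,
              paste(names(x$channels), collapse = ", "),
              n_labels(x$truth_nuclei), x$spec$seed))
  invisible(x)
}

#' Write a scene as multichannel TIFF plus a JSON ground-truth sidecar
#'
#' @param scene a `synthetic_scene`.
#' @param path output TIFF path; the sidecar is written next to it with a
#'   `.json` extension.
#' @return Named character vector of the two paths, invisibly.
#' @export
write_scene <- function(scene, path) {
  write_image(scene$channels, path)
  lab <- scene$truth_nuclei
  ids <- seq_len(max(0L, max(lab)))
  areas <- if (length(ids)) tabulate(lab[lab > 0L], nbins = max(lab)) else integer()
  sidecar <- list(
    spec = scene$spec[setdiff(names(scene$spec), character())],
    channels = names(scene$channels),
    nuclei = data.frame(label = ids, area_px = areas),
    foci = scene$truth_foci
  )
  json_path <- sub("\\.tiff?$", ".json", path)
  if (identical(json_path, path)) json_path <- paste0(path, ".json")
  jsonlite::write_json(sidecar, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(tiff = path, json = json_path))
}
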