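#' GLCM computation parameters
#'
#' Settings for grey-level co-occurrence matrix construction. The default
#' — 32 grey levels, distance 1, all four 2-D directions, symmetric
#' counting, features averaged over directions — trades fidelity against
#' the sparsity of matrices built from small nuclear regions: 256-level
#' matrices from a few hundred pixels are mostly empty and make the
#' correlation feature unstable.
#'
#' @param levels number of grey levels G after quantization (2..256).
#' @param distance pixel offset between the two pixels of a pair.
#' @param angles subset of `c(0, 45, 90, 135)` degrees. 0 degrees pairs a
#'   pixel with its right neighbour, 90 degrees with the one above.
#' @param symmetric count each ordered pair in both directions.
#' @param average_over_angles average features (not matrices) over angles.
#' @return A `glcm_params` list.
#' @export
glcm_params <- function(levels = 32L, distance = 1L,
                        angles = c(0, 45, 90, 135),
                        symmetric = TRUE, average_over_angles = TRUE) {
  levels <- as.integer(levels)
  distance <- as.integer(distance)
  if (levels < 2L || levels > 256L) stop("`levels` must be in 2..256")
  if (distance < 1L) stop("`distance` must be >= 1")
  if (length(angles) == 0L || !all(angles %in% c(0, 45, 90, 135))) {
    stop("`angles` must be a non-empty subset of {0, 45, 90, 135}")
  }
  structure(list(levels = levels, distance = distance,
                 angles = sort(unique(angles)),
                 symmetric = isTRUE(symmetric),
                 average_over_angles = isTRUE(average_over_angles)),
            class = "glcm_params")
}

#' Quantize an 8-bit image into G grey levels
#'
#' Uniform binning of the `[0, 255]` intensity axis into `levels` bins of
#' width `256 / levels`; the quantized level of value `v` is
#' `floor(v * levels / 256)`. Pixels outside `mask` are set to `NA`, the
#' sentinel excluded from pair counting.
#'
#' @param image an 8-bit [image_grid].
#' @param mask optional logical matrix selecting the region of interest;
#'   an all-`FALSE` mask is an error (unusable ROI).
#' @param levels number of grey levels (<= 256).
#' @return An integer matrix of levels in `0..levels-1`, `NA` outside the
#'   mask.
#' @export
quantize_image <- function(image, mask = NULL, levels = 32L) {
  if (bit_depth(image) != 8L) stop("quantization expects an 8-bit image; see to_8bit()")
  levels <- as.integer(levels)
  if (levels < 2L || levels > 256L) stop("`levels` must be in 2..256")
  q <- matrix(as.integer(floor(as.numeric(as_matrix(image)) * levels / 256)),
              nrow(image), ncol(image))
  if (!is.null(mask)) {
    stopifnot_same_dim(image, mask, "image and mask")
    if (!any(mask)) stop("empty mask: no pixels in the region of interest")
    q[!mask] <- NA_integer_
  }
  q
}

# (row, col) offset of a pair partner for an angle, in the convention where
# row grows downward: 0 deg -> (0, d); 45 deg -> (-d, d); 90 deg -> (-d, 0);
# 135 deg -> (-d, -d).
angle_offset <- function(angle, distance) {
  switch(as.character(angle),
         "0"   = c(0L, distance),
         "45"  = c(-distance, distance),
         "90"  = c(-distance, 0L),
         "135" = c(-distance, -distance),
         stop("unsupported angle"))
}

#' Grey-level co-occurrence matrices of a quantized region
#'
#' Counts ordered pixel pairs `(i, j)` at the requested offset(s) whose
#' two endpoints both lie inside the region (`NA` marks outside pixels;
#' pairs crossing the region boundary are discarded, so bounding-box
#' background never leaks into the matrix). With `symmetric = TRUE` every
#' pair is also counted reversed. Each matrix is normalized by its total
#' pair count. One matrix per angle is returned; feature averaging over
#' angles happens downstream in [haralick_features()].
#'
#' @param levelled integer matrix of grey levels (from [quantize_image()]),
#'   `NA` outside the region of interest.
#' @param params a [glcm_params()] object.
#' @return A list of `glcm` objects (one per angle), each with elements
#'   `p` (G x G probability matrix), `angle`, `n_pairs` and `params`.
#' @export
compute_glcm <- function(levelled, params = glcm_params()) {
  stopifnot(inherits(params, "glcm_params"))
  G <- params$levels
  vals <- levelled[!is.na(levelled)]
  if (length(vals) && (min(vals) < 0L || max(vals) >= G)) {
    stop("levelled grid holds values outside 0..levels-1")
  }
  out <- lapply(params$angles, function(ang) {
    off <- angle_offset(ang, params$distance)
    counts <- pair_counts(levelled, off[1], off[2], G)
    if (params$symmetric) counts <- counts + t(counts)
    n <- sum(counts)
    if (n == 0L) {
      stop(sprintf("no valid pixel pairs at angle %d: region too small for distance %d",
                   ang, params$distance))
    }
    structure(list(p = counts / n, angle = ang, n_pairs = n, params = params),
              class = "glcm")
  })
  names(out) <- paste0("angle_", params$angles)
  out
}

# Count ordered co-occurring pairs at offset (dr, dc); result[i+1, j+1] is
# the number of pairs with level i at the first pixel and j at the second.
pair_counts <- function(g, dr, dc, G) {
  h <- nrow(g); w <- ncol(g)
  r_lo <- max(1L, 1L - dr); r_hi <- min(h, h - dr)
  c_lo <- max(1L, 1L - dc); c_hi <- min(w, w - dc)
  if (r_lo > r_hi || c_lo > c_hi) return(matrix(0L, G, G))
  r1 <- r_lo:r_hi
  c1 <- c_lo:c_hi
  a <- g[r1, c1, drop = FALSE]
  b <- g[r1 + dr, c1 + dc, drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(matrix(0L, G, G))
  idx <- a[ok] * G + b[ok] + 1L
  matrix(tabulate(idx, nbins = G * G), G, G, byrow = TRUE)
}

#' Haralick texture features of a GLCM
#'
#' Computes the five second-order texture statistics from a co-occurrence
#' probability matrix `p` over levels `i, j = 0..G-1`:
#' \itemize{
#'   \item ASM (angular second moment) `sum p(i,j)^2` — uniformity;
#'   \item contrast `sum (i-j)^2 p(i,j)` — local grey-level variation;
#'   \item correlation `sum (i-mu_x)(j-mu_y) p(i,j) / (sd_x sd_y)` with
#'     marginal moments; undefined when either marginal sd is zero;
#'   \item IDM (inverse difference moment) `sum p(i,j)/(1+(i-j)^2)` —
#'     local homogeneity;
#'   \item entropy `-sum p log2 p` (bits), with `0 log 0 := 0`.
#' }
#' Given a list of per-angle matrices, each feature is the unweighted mean
#' over angles; correlation is averaged only over the angles where it is
#' defined, and is flagged undefined when no angle defines it.
#'
#' @param glcm a `glcm` object from [compute_glcm()], or a list of them.
#' @return A one-row data.frame: `asm`, `contrast`, `correlation`, `idm`,
#'   `entropy`, `correlation_defined`.
#' @export
haralick_features <- function(glcm) {
  if (inherits(glcm, "glcm")) glcm <- list(glcm)
  per <- lapply(glcm, haralick_one)
  feats <- do.call(rbind, per)
  corr_ok <- feats$correlation_defined
  data.frame(
    asm = mean(feats$asm),
    contrast = mean(feats$contrast),
    correlation = if (any(corr_ok)) mean(feats$correlation[corr_ok]) else NA_real_,
    idm = mean(feats$idm),
    entropy = mean(feats$entropy),
    correlation_defined = any(corr_ok)
  )
}

haralick_one <- function(g) {
  p <- g$p
  G <- nrow(p)
  lv <- 0:(G - 1)
  px <- rowSums(p)
  py <- colSums(p)
  mux <- sum(lv * px); muy <- sum(lv * py)
  sdx <- sqrt(sum((lv - mux)^2 * px))
  sdy <- sqrt(sum((lv - muy)^2 * py))
  D2 <- outer(lv, lv, function(i, j) (i - j)^2)
  pos <- p > 0
  corr_def <- sdx > 0 && sdy > 0
  data.frame(
    asm = sum(p^2),
    contrast = sum(D2 * p),
    correlation = if (corr_def) {
      (sum(outer(lv, lv) * p) - mux * muy) / (sdx * sdy)
    } else NA_real_,
    idm = sum(p / (1 + D2)),
    entropy = -sum(p[pos] * log2(p[pos])),
    correlation_defined = corr_def
  )
}

#' Per-nucleus texture profile of a sample
#'
#' Quantizes the image once on the global 8-bit axis, then builds one GLCM
#' set per labelled nucleus (pairs restricted to that nucleus's pixels)
#' and computes its Haralick features. Per-sample means over nuclei are
#' attached, with undefined correlations excluded from the correlation
#' mean and their count reported; this per-nucleus-then-average order
#' mirrors per-sample reporting of nuclear texture.
#'
#' @param image an [image_grid]; a 16-bit image is converted with
#'   [to_8bit()] first.
#' @param nuclei a [label_mask] of the same size.
#' @param params a [glcm_params()] object.
#' @param erode_px radius (pixels) by which each nuclear mask is eroded
#'   before pair extraction. Segmentation boundaries sit on the
#'   intensity fall-off at the nuclear rim, and those partial-volume
#'   pixels inject spurious dark-bright pairs into the matrix; a small
#'   erosion (default 2 px) confines the features to interior chromatin.
#'   Set 0 to use the masks as given.
#' @return A list of class `texture_profile`: `per_nucleus` (data.frame
#'   with `nucleus_id`, `area_px`, the five features and
#'   `correlation_defined`), `sample_means` (named numeric; `NA` where
#'   undefined), `n_nuclei`, `n_correlation_undefined`, `params`.
#' @export
nucleus_texture_profile <- function(image, nuclei, params = glcm_params(),
                                    erode_px = 2L) {
  stopifnot_same_dim(image, nuclei, "image and nuclei mask")
  image <- to_8bit(image)
  ids <- sort(unique(as.vector(nuclei[nuclei > 0L])))
  q <- quantize_image(image, mask = NULL, levels = params$levels)
  brush <- if (erode_px > 0) EBImage::makeBrush(2L * as.integer(erode_px) + 1L,
                                                shape = "disc") else NULL
  feature_names <- c("asm", "contrast", "correlation", "idm", "entropy")
  rows <- lapply(ids, function(k) {
    sel <- which(nuclei == k, arr.ind = TRUE)
    rr <- range(sel[, 1]); cc <- range(sel[, 2])
    sub <- q[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
    inmask <- as_matrix(nuclei)[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE] == k
    if (!is.null(brush)) {
      shrunk <- as_plain(EBImage::erode(EBImage::Image(inmask), brush)) > 0
      if (any(shrunk)) inmask <- shrunk
    }
    sub[!inmask] <- NA_integer_
    feats <- tryCatch(haralick_features(compute_glcm(sub, params)),
                      error = function(e) {
                        data.frame(asm = NA_real_, contrast = NA_real_,
                                   correlation = NA_real_, idm = NA_real_,
                                   entropy = NA_real_, correlation_defined = FALSE)
                      })
    cbind(data.frame(nucleus_id = k, area_px = nrow(sel)), feats)
  })
  per <- if (length(rows)) do.call(rbind, rows) else
    data.frame(nucleus_id = integer(), area_px = integer(),
               asm = numeric(), contrast = numeric(), correlation = numeric(),
               idm = numeric(), entropy = numeric(),
               correlation_defined = logical())
  means <- vapply(feature_names, function(f) {
    v <- per[[f]]
    if (f == "correlation") v <- v[per$correlation_defined]
    v <- v[!is.na(v)]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  structure(list(per_nucleus = per,
                 sample_means = means,
                 n_nuclei = length(ids),
                 n_correlation_undefined = sum(!per$correlation_defined),
                 params = params),
            class = "texture_profile")
}

#' @export
print.texture_profile <- function(x, ...) {
  cat(sprintf("<texture_profile> %d nuclei (%d with undefined correlation)\n",
              x$n_nuclei, x$n_correlation_undefined))
  print(round(x$sample_means, 4))
  invisible(x)
}

#' Percent change of treated relative to control feature means
#'
#' `100 * (treated - control) / control` per feature. A feature undefined
#' in either group, or with a zero control mean, propagates as `NA`
#' rather than raising an error.
#'
#' @param treated,control named numeric vectors of per-sample feature
#'   means (e.g. `sample_means` from [nucleus_texture_profile()]).
#' @return Named numeric vector of percent changes.
#' @export
percent_change <- function(treated, control) {
  feats <- intersect(names(control), names(treated))
  if (length(feats) == 0L) stop("no shared features between groups")
  out <- vapply(feats, function(f) {
    mc <- control[[f]]; mt <- treated[[f]]
    if (is.na(mc) || is.na(mt) || mc == 0) NA_real_ else 100 * (mt - mc) / mc
  }, numeric(1))
  names(out) <- feats
  out
}

# Direction in which each texture feature moves when a chromatin pattern
# strengthens: +1 = feature rises with the pattern, -1 = feature falls.
# ASM tracks overall homogeneity, entropy disorder (anti-homogeneity and
# pro-heterogeneity), correlation falls with heterogeneity, contrast and
# low IDM mark high local grey-level contrast.
pattern_associations <- function() {
  list(
    homogeneity   = c(asm = 1, entropy = -1, idm = 1),
    heterogeneity = c(correlation = -1, entropy = 1),
    contrast      = c(contrast = 1, idm = -1)
  )
}

#' Interpret per-feature percent changes as chromatin-pattern calls
#'
#' Each feature whose absolute percent change reaches `threshold` casts a
#' vote on the chromatin patterns it is associated with (see
#' `pattern_associations()`): the vote is the sign of the change times the
#' feature's association sign. Per pattern, unanimous non-zero votes give
#' `increased`/`decreased`, all votes below threshold give `unchanged`,
#' and conflicting votes give `indeterminate`. Undefined feature changes
#' abstain.
#'
#' @param changes named numeric vector of percent changes (names among
#'   `asm`, `contrast`, `correlation`, `idm`, `entropy`).
#' @param threshold minimum absolute percent change for a feature to vote
#'   (default 5).
#' @return A list of class `pattern_call`: `homogeneity`,
#'   `heterogeneity`, `contrast_pattern` (each one of `"increased"`,
#'   `"decreased"`, `"unchanged"`, `"indeterminate"`) and `votes`, the
#'   per-feature contributions per pattern.
#' @export
interpret_chromatin_pattern <- function(changes, threshold = 5) {
  if (all(is.na(changes))) stop("all feature changes are undefined")
  assoc <- pattern_associations()
  votes <- list()
  call_one <- function(pattern) {
    a <- assoc[[pattern]]
    feats <- intersect(names(a), names(changes))
    v <- vapply(feats, function(f) {
      ch <- changes[[f]]
      if (is.na(ch)) return(NA_real_)
      if (abs(ch) < threshold) 0 else sign(ch) * a[[f]]
    }, numeric(1))
    votes[[pattern]] <<- v
    v <- v[!is.na(v)]
    if (length(v) == 0L) return("indeterminate")
    nz <- v[v != 0]
    if (length(nz) == 0L) return("unchanged")
    if (all(nz > 0)) return("increased")
    if (all(nz < 0)) return("decreased")
    "indeterminate"
  }
  res <- list(homogeneity = call_one("homogeneity"),
              heterogeneity = call_one("heterogeneity"),
              contrast_pattern = call_one("contrast"))
  res$votes <- votes
  class(res) <- "pattern_call"
  res
}

#' @export
print.pattern_call <- function(x, ...) {
  cat(sprintf("<pattern_call> homogeneity: %s, heterogeneity: %s, contrast: %s\n",
              x$homogeneity, x$heterogeneity, x$contrast_pattern))
  invisible(x)
}
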