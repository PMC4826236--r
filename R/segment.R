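#' Nucleus segmentation parameters
#'
#' Defaults are tuned to the synthetic generator's default nucleus radii
#' (12-18 px): objects below `min_area` are treated as debris and above
#' `max_area` as clusters or artefacts.
#'
#' @param smoothing_sigma Gaussian pre-smoothing sd in pixels (0 = none).
#' @param min_area,max_area retained object area bounds in pixels^2.
#' @param split_touching split touching objects with a distance-transform
#'   watershed.
#' @param watershed_tolerance minimum height of an object peak in the
#'   distance map (pixels) for it to seed its own label; raising it merges
#'   spurious splits of a single convex nucleus.
#' @param exclude_border drop objects touching the image border.
#' @return A `segmentation_params` list.
#' @export
segmentation_params <- function(smoothing_sigma = 2, min_area = 100,
                                max_area = 10000, split_touching = TRUE,
                                watershed_tolerance = 3,
                                exclude_border = FALSE) {
  if (smoothing_sigma < 0) stop("`smoothing_sigma` must be >= 0")
  if (min_area >= max_area) stop("`min_area` must be < `max_area`")
  structure(list(smoothing_sigma = smoothing_sigma, min_area = min_area,
                 max_area = max_area, split_touching = isTRUE(split_touching),
                 watershed_tolerance = watershed_tolerance,
                 exclude_border = isTRUE(exclude_border)),
            class = "segmentation_params")
}

#' Segment nuclei from a DAPI channel
#'
#' Deterministic pipeline: Gaussian smoothing, Otsu global threshold,
#' hole filling, optional distance-transform watershed separation of
#' touching nuclei, area filtering and optional border-object removal.
#' A constant image returns an empty mask (0 nuclei), not an error.
#'
#' @param dapi an 8- or 16-bit [image_grid].
#' @param params a [segmentation_params()] object.
#' @return A [label_mask] with compacted labels 1..K.
#' @export
segment_nuclei <- function(dapi, params = segmentation_params()) {
  stopifnot(inherits(params, "segmentation_params"))
  x <- as.numeric(as_matrix(dapi)) / (2^bit_depth(dapi) - 1)
  x <- matrix(x, nrow(dapi), ncol(dapi))
  if (diff(range(x)) == 0) {
    return(label_mask(matrix(0L, nrow(dapi), ncol(dapi))))
  }
  if (params$smoothing_sigma > 0) {
    x <- as_plain(EBImage::gblur(x, sigma = params$smoothing_sigma))
  }
  thr <- EBImage::otsu(EBImage::Image(x), range = range(x))
  bw <- x > thr
  bw <- as_plain(EBImage::fillHull(EBImage::Image(bw))) > 0
  lab <- if (params$split_touching) {
    dm <- as_plain(EBImage::distmap(EBImage::Image(bw)))
    as_plain(EBImage::watershed(EBImage::Image(dm),
                                tolerance = params$watershed_tolerance, ext = 1))
  } else {
    as_plain(EBImage::bwlabel(EBImage::Image(bw)))
  }
  lab <- filter_labels(lab, params)
  label_mask(lab)
}

# Area filter + optional border removal; keeps integer labels, zeroing
# rejected objects.
filter_labels <- function(lab, params) {
  storage.mode(lab) <- "integer"
  if (max(lab) == 0L) return(lab)
  areas <- tabulate(lab[lab > 0L], nbins = max(lab))
  drop <- which(areas < params$min_area | areas > params$max_area)
  if (params$exclude_border) {
    border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    drop <- union(drop, border[border > 0L])
  }
  if (length(drop)) lab[lab %in% drop] <- 0L
  lab
}

#' Epithelial compartment masks from cytokeratin and DAPI channels
#'
#' The epithelium is the Otsu-thresholded, hole-filled cytokeratin mask;
#' the nuclear compartment is segmented nuclei intersected with the
#' epithelium, and the cytoplasmic compartment is the epithelial
#' remainder. A constant (e.g. all-zero) cytokeratin channel yields an
#' all-background mask.
#'
#' @param dapi,cytokeratin [image_grid]s of equal size.
#' @param params a [segmentation_params()] object (used for the nuclear
#'   segmentation).
#' @return A [label_mask] with labels 0 = background, 1 = cytoplasmic,
#'   2 = nuclear (so nuclear and cytoplasmic are disjoint by
#'   construction and their union is the epithelium).
#' @export
compartment_masks <- function(dapi, cytokeratin,
                              params = segmentation_params()) {
  stopifnot_same_dim(dapi, cytokeratin, "dapi and cytokeratin")
  ck <- as.numeric(as_matrix(cytokeratin)) / (2^bit_depth(cytokeratin) - 1)
  ck <- matrix(ck, nrow(cytokeratin), ncol(cytokeratin))
  if (diff(range(ck)) == 0) {
    return(label_mask(matrix(0L, nrow(ck), ncol(ck)), compact = FALSE))
  }
  if (params$smoothing_sigma > 0) {
    ck <- as_plain(EBImage::gblur(ck, sigma = params$smoothing_sigma))
  }
  thr <- EBImage::otsu(EBImage::Image(ck), range = range(ck))
  epi <- as_plain(EBImage::fillHull(EBImage::Image(ck > thr))) > 0
  nuclei <- segment_nuclei(dapi, params)
  out <- matrix(0L, nrow(ck), ncol(ck))
  out[epi] <- 1L
  out[epi & nuclei > 0L] <- 2L
  label_mask(out, compact = FALSE)
}

#' Match predicted objects to ground-truth objects by overlap
#'
#' Greedy one-to-one matching by decreasing pixel overlap; each match
#' reports its intersection-over-union. Used to score segmentation
#' against generator ground truth.
#'
#' @param predicted,truth [label_mask]s of equal size.
#' @param iou_threshold minimum IoU for a pairing to count as a match.
#' @return A list: `matches` (data.frame `truth`, `predicted`, `iou`),
#'   `precision`, `recall`, `n_predicted`, `n_truth`.
#' @export
match_labels <- function(predicted, truth, iou_threshold = 0.5) {
  stopifnot_same_dim(predicted, truth, "masks")
  np <- max(predicted); nt <- max(truth)
  empty <- data.frame(truth = integer(), predicted = integer(), iou = numeric())
  if (np == 0L || nt == 0L) {
    return(list(matches = empty,
                precision = if (np == 0L) NA_real_ else 0,
                recall = if (nt == 0L) NA_real_ else 0,
                n_predicted = np, n_truth = nt))
  }
  both <- predicted > 0L & truth > 0L
  inter <- table(factor(predicted[both], levels = 1:np),
                 factor(truth[both], levels = 1:nt))
  area_p <- tabulate(predicted[predicted > 0L], nbins = np)
  area_t <- tabulate(truth[truth > 0L], nbins = nt)
  iou <- as.matrix(inter) /
    (outer(area_p, area_t, "+") - as.matrix(inter))
  matches <- empty
  used_p <- logical(np); used_t <- logical(nt)
  ord <- order(-as.vector(iou))
  for (k in ord) {
    if (iou[k] < iou_threshold || iou[k] <= 0) break
    p <- (k - 1) %% np + 1
    t <- (k - 1) %/% np + 1
    if (used_p[p] || used_t[t]) next
    used_p[p] <- TRUE; used_t[t] <- TRUE
    matches <- rbind(matches,
                     data.frame(truth = t, predicted = p, iou = iou[k]))
  }
  list(matches = matches,
       precision = nrow(matches) / np,
       recall = nrow(matches) / nt,
       n_predicted = np, n_truth = nt)
}
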