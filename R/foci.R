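#' Foci detection parameters
#'
#' Multi-scale Laplacian-of-Gaussian blob detection settings and the
#' positivity cut-point. The detection threshold is relative to the
#' channel's dynamic range, so counts are invariant to a linear gain
#' rescale of the image.
#'
#' @param log_sigma_min,log_sigma_max blob scale range (Gaussian sd, px).
#' @param n_scales number of scales spanning the range.
#' @param detection_threshold minimum blob response as a fraction of the
#'   channel dynamic range, in `(0, 1)`.
#' @param min_separation minimum distance between two detected foci (px);
#'   closer maxima are merged into the stronger one.
#' @param positivity_cutpoint foci count above which a cell is called
#'   positive; the default 5 treats up to five foci per cell as negative
#'   background.
#' @return A `foci_params` list.
#' @export
foci_params <- function(log_sigma_min = 1, log_sigma_max = 2.5,
                        n_scales = 4L, detection_threshold = 0.15,
                        min_separation = 5, positivity_cutpoint = 5L) {
  if (log_sigma_min > log_sigma_max) stop("`log_sigma_min` must be <= `log_sigma_max`")
  if (detection_threshold <= 0 || detection_threshold >= 1) {
    stop("`detection_threshold` must be in (0, 1)")
  }
  if (positivity_cutpoint < 0) stop("`positivity_cutpoint` must be >= 0")
  structure(list(log_sigma_min = log_sigma_min, log_sigma_max = log_sigma_max,
                 n_scales = as.integer(n_scales),
                 detection_threshold = detection_threshold,
                 min_separation = min_separation,
                 positivity_cutpoint = as.integer(positivity_cutpoint)),
            class = "foci_params")
}

# Scale-normalized LoG kernel; responds positively to bright blobs of
# radius ~ sqrt(2) * sigma, with zero response to flat regions.
log_kernel <- function(sigma) {
  half <- ceiling(3.5 * sigma)
  ax <- -half:half
  g <- outer(ax, ax, function(x, y) exp(-(x^2 + y^2) / (2 * sigma^2)))
  g <- g / sum(g)
  lap <- outer(ax, ax, function(x, y) (x^2 + y^2 - 2 * sigma^2) / sigma^4)
  ker <- lap * g
  -(sigma^2) * (ker - mean(ker))
}

#' Detect and count foci per nucleus
#'
#' Multi-scale Laplacian-of-Gaussian blob detection restricted to
#' in-nucleus pixels: the response is maximized over scales, local maxima
#' above `detection_threshold` times the channel dynamic range are kept,
#' maxima closer than `min_separation` are merged (strongest wins), and
#' each focus is assigned to the nucleus containing its peak.
#'
#' @param foci_channel an [image_grid].
#' @param nuclei a [label_mask] with at least one nucleus.
#' @param params a [foci_params()] object.
#' @return A list of class `foci_result`: `per_nucleus` (data.frame
#'   `nucleus_id`, `foci_count`, `positive`), `foci` (data.frame
#'   `nucleus`, `row`, `col`, `response`; coordinates 0-based),
#'   `fraction_positive`, `histogram` (table of counts), `params`.
#' @export
detect_foci <- function(foci_channel, nuclei, params = foci_params()) {
  stopifnot_same_dim(foci_channel, nuclei, "channel and nuclei mask")
  stopifnot(inherits(params, "foci_params"))
  n_nuc <- max(nuclei)
  if (n_nuc == 0L) stop("no nuclei in mask: nothing to count foci in")
  img <- matrix(as.numeric(as_matrix(foci_channel)),
                nrow(foci_channel), ncol(foci_channel))
  rng <- diff(range(img))
  ids <- seq_len(n_nuc)
  if (rng == 0) {
    return(foci_result(ids, data.frame(nucleus = integer(), row = integer(),
                                       col = integer(), response = numeric()),
                       params))
  }
  sigmas <- if (params$n_scales == 1L) params$log_sigma_min else
    seq(params$log_sigma_min, params$log_sigma_max,
        length.out = params$n_scales)
  resp <- matrix(-Inf, nrow(img), ncol(img))
  for (s in sigmas) {
    r <- as_plain(EBImage::filter2(img, log_kernel(s)))
    resp <- pmax(resp, r)
  }
  thr <- params$detection_threshold * rng
  localmax <- as_plain(EBImage::dilate(
    resp, EBImage::makeBrush(3L, shape = "box")))
  cand <- which(resp >= thr & resp >= localmax & nuclei > 0L, arr.ind = TRUE)
  peaks <- data.frame(nucleus = integer(), row = integer(), col = integer(),
                      response = numeric())
  if (nrow(cand) > 0L) {
    rv <- resp[cand]
    ord <- order(-rv)
    keep_r <- numeric(); keep_c <- numeric()
    sep2 <- params$min_separation^2
    for (k in ord) {
      r0 <- cand[k, 1]; c0 <- cand[k, 2]
      if (length(keep_r) &&
          any((keep_r - r0)^2 + (keep_c - c0)^2 < sep2)) next
      keep_r <- c(keep_r, r0); keep_c <- c(keep_c, c0)
      peaks <- rbind(peaks, data.frame(nucleus = nuclei[r0, c0],
                                       row = r0 - 1L, col = c0 - 1L,
                                       response = resp[r0, c0]))
    }
  }
  res <- foci_result(ids, peaks, params)
  if (n_nuc < 100L) {
    # field practice counts >= 100 nuclei per slide for stable fractions
    warning(sprintf("only %d nuclei analysed; fractions from < 100 nuclei are unstable",
                    n_nuc), call. = FALSE)
  }
  res
}

foci_result <- function(ids, peaks, params) {
  counts <- vapply(ids, function(k) sum(peaks$nucleus == k), integer(1))
  per <- data.frame(nucleus_id = ids, foci_count = counts,
                    positive = vapply(counts, classify_positive, logical(1),
                                      cutpoint = params$positivity_cutpoint))
  structure(list(per_nucleus = per, foci = peaks,
                 fraction_positive = mean(per$positive),
                 histogram = table(factor(counts, levels = 0:max(c(counts, 1)))),
                 params = params),
            class = "foci_result")
}

#' @export
print.foci_result <- function(x, ...) {
  cat(sprintf("<foci_result> %d nuclei, %d foci, %.1f%% positive (> %d foci)\n",
              nrow(x$per_nucleus), nrow(x$foci), 100 * x$fraction_positive,
              x$params$positivity_cutpoint))
  invisible(x)
}

#' Classify a cell as foci-positive
#'
#' A cell is positive when its foci count strictly exceeds the cut-point;
#' counts up to and including the cut-point are treated as negative
#' background. The boundary convention (a count equal to the cut-point is
#' negative) is a package convention recorded with every result.
#'
#' @param count non-negative foci count.
#' @param cutpoint background cut-point (default 5).
#' @return Logical.
#' @export
classify_positive <- function(count, cutpoint = 5L) {
  if (count < 0) stop("`count` must be >= 0")
  count > cutpoint
}
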