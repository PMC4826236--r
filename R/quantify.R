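#' Score a target channel within tissue compartments
#'
#' Compartment-based immunofluorescence scoring of a tissue-microarray
#' core: the score of a compartment is the total target intensity over
#' its pixels divided by its pixel count (mean intensity, in arbitrary
#' units). The epithelium fraction is the share of core pixels that are
#' epithelial (nuclear or cytoplasmic); cores below 5% epithelium are
#' flagged for exclusion (see [exclude_low_epithelium()]). Background
#' (label 0) pixels never enter any score.
#'
#' @param target an [image_grid] of the target channel.
#' @param compartments a [label_mask] with 0 = background, 1 =
#'   cytoplasmic, 2 = nuclear (as from [compartment_masks()]).
#' @param core optional logical matrix marking the core region over which
#'   the epithelium fraction is computed; defaults to the whole image.
#' @param core_id identifier echoed into the result.
#' @param epithelium_threshold minimum epithelium fraction for inclusion.
#' @return A one-row data.frame of class `compartment_score`: `core_id`,
#'   `nuclear_score`, `cytoplasmic_score` (`NA` when the compartment is
#'   empty), `epithelium_fraction`, `included`.
#' @export
score_core <- function(target, compartments, core = NULL, core_id = NA,
                       epithelium_threshold = 0.05) {
  stopifnot_same_dim(target, compartments, "target and compartments")
  v <- as.numeric(as_matrix(target))
  lab <- as.vector(as_matrix(compartments))
  mean_of <- function(sel) if (any(sel)) sum(v[sel]) / sum(sel) else NA_real_
  core_px <- if (is.null(core)) length(lab) else sum(core)
  epi_frac <- if (core_px > 0) sum(lab > 0L) / core_px else 0
  out <- data.frame(core_id = core_id,
                    nuclear_score = mean_of(lab == 2L),
                    cytoplasmic_score = mean_of(lab == 1L),
                    epithelium_fraction = epi_frac,
                    included = epi_frac >= epithelium_threshold)
  class(out) <- c("compartment_score", class(out))
  out
}

#' Drop cores with too little epithelium
#'
#' Cores whose epithelium fraction is strictly below `threshold` are
#' excluded so that retained cores are representative tissue; a fraction
#' exactly at the threshold is kept. The filter is idempotent and the
#' kept and dropped sets partition the input.
#'
#' @param scores a data.frame of per-core scores (rows from
#'   [score_core()], with `core_id` and `epithelium_fraction` columns).
#' @param threshold exclusion boundary (default 0.05, i.e. 5%).
#' @return A list: `included` (filtered data.frame), `excluded`
#'   (dropped rows), `excluded_ids` (their `core_id`s), `threshold`.
#' @export
exclude_low_epithelium <- function(scores, threshold = 0.05) {
  stopifnot(is.data.frame(scores), "epithelium_fraction" %in% names(scores))
  drop <- scores$epithelium_fraction < threshold
  kept <- scores[!drop, , drop = FALSE]
  kept$included <- TRUE
  list(included = kept,
       excluded = scores[drop, , drop = FALSE],
       excluded_ids = scores$core_id[drop],
       threshold = threshold)
}
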