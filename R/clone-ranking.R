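#' Background-eliminating threshold from a reference image
#'
#' Deterministic stand-in for thresholding "until the background
#' disappears": the smallest grey level `t` such that no reference pixel
#' exceeds `t`, i.e. `t = max(reference)`. The reference is a matched
#' negative-control image (e.g. a wild-type section) or a designated
#' background region. A robust percentile rule is available for references
#' with hot pixels.
#'
#' @param reference A [micrograph()] (or integer matrix).
#' @param method `"max"` (default) or `"quantile"`.
#' @param probs Upper tail probability kept above threshold when
#'   `method = "quantile"` (default 0.999: smallest integer `t` with at
#'   most 0.1% of reference pixels above it).
#' @return Integer grey-level threshold.
#' @export
background_threshold <- function(reference, method = c("max", "quantile"),
                                 probs = 0.999) {
  method <- match.arg(method)
  v <- as.integer(reference)
  if (length(v) == 0L) abort("empty reference image.")
  if (method == "max") return(max(v))
  tol <- (1 - probs) * length(v)
  # smallest integer t with #(v > t) <= tol
  t <- as.integer(quantile(v, probs, type = 1))
  while (sum(v > t) > tol) t <- t + 1L
  t
}

#' Count pixels above a threshold
#'
#' The positive-pixel statistic used to score staining intensity.
#'
#' @param img A [micrograph()] (or integer matrix).
#' @param threshold Grey level; pixels with intensity strictly above it
#'   are counted.
#' @return Integer count.
#' @export
positive_pixel_count <- function(img, threshold) {
  sum(unclass(img) > threshold)
}

#' Rank nanobody clones by background-corrected positive pixels
#'
#' For each replicate image the matched reference fixes a
#' background-eliminating threshold ([background_threshold()]); the
#' clone's score is its positive-pixel count at that threshold, aggregated
#' as mean and sample SD across replicates. Clones are ranked by
#' descending mean; exactly equal means share a tie group (competition
#' ranking: 1, 2, 3, 3, 5), with alphabetical clone id as the
#' deterministic secondary order.
#'
#' @param stains A tibble with columns `clone_id`, `replicate`, `image`
#'   (list of micrographs) and `reference` (list of matched reference
#'   micrographs).
#' @param method,probs Passed to [background_threshold()].
#' @return A `clone_ranking` tibble: `clone_id`, `n_replicates`,
#'   `mean_count`, `sd_count`, `rank`, ordered best first.
#' @export
rank_clones <- function(stains, method = "max", probs = 0.999) {
  required <- c("clone_id", "replicate", "image", "reference")
  if (nrow(stains) == 0L) abort("`stains` must contain at least one image.")
  if (!all(required %in% names(stains))) {
    abort(paste("`stains` needs columns:", paste(required, collapse = ", ")))
  }
  per_rep <- dplyr::mutate(
    stains,
    threshold = purrr::map_dbl(.data$reference, background_threshold,
                               method = method, probs = probs),
    count = purrr::map2_dbl(.data$image, .data$threshold,
                            positive_pixel_count))
  reps <- table(per_rep$clone_id)
  if (length(unique(reps)) > 1L) {
    warn("clones have unequal replicate counts.")
  }
  out <- per_rep |>
    dplyr::group_by(.data$clone_id) |>
    dplyr::summarise(n_replicates = dplyr::n(),
                     mean_count = mean(.data$count),
                     sd_count = if (dplyr::n() > 1) sd(.data$count) else 0,
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean_count), .data$clone_id)
  out$rank <- rank(-out$mean_count, ties.method = "min")
  class(out) <- c("clone_ranking", class(out))
  out
}

#' @export
tidy.clone_ranking <- function(x, ...) as_tibble(x)

#' Format a ranking as the field's "A > B = C" string
#' @param x A `clone_ranking`.
#' @return A single string, best clone first, ties joined with `=`.
#' @export
ranking_string <- function(x) {
  groups <- split(x$clone_id, x$rank)
  paste(vapply(groups, paste, character(1), collapse = " = "),
        collapse = " > ")
}
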