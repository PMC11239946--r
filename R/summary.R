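otsu_log_split <- function(logd) {
  # exhaustive maximisation of between-class variance over all splits of the
  # sorted sample; returns the split index (objects 1..k vs k+1..n) and the
  # effectiveness eta = between-class / total variance in [0, 1]
  v <- sort(logd)
  n <- length(v)
  tot_mean <- mean(v)
  tot_var <- mean((v - tot_mean)^2)
  if (tot_var == 0) return(list(k = NA_integer_, eta = 0))
  k <- seq_len(n - 1L)
  csum <- cumsum(v)
  m1 <- csum[k] / k
  m2 <- (csum[n] - csum[k]) / (n - k)
  w1 <- k / n
  between <- w1 * (1 - w1) * (m1 - m2)^2
  best <- which.max(between)
  list(k = best, eta = between[best] / tot_var,
       threshold_log = (v[best] + v[best + 1L]) / 2)
}

#' Split deposit diameters into oligomer and plaque populations
#'
#' Two-class variance minimisation (the Otsu criterion) on log-diameter:
#' small soluble oligomers (~2 um footprint) and large plaques (~14 um) are
#' both plausibly multiplicative in spread, so the split is made on the log
#' scale. The data-driven threshold is only trusted when the optimal
#' split's between-class/total variance ratio exceeds `bimodality_floor`;
#' otherwise the sample is treated as unimodal and the fixed
#' `fallback_cutoff_um` is applied (6 um, the rounded-up geometric midpoint
#' of 2 and 14 um: `sqrt(2*14) ~ 5.3`). Objects strictly below the
#' threshold are oligomers, at or above it plaques.
#'
#' @param diameters_um Positive equivalent diameters in micrometres.
#' @param bimodality_floor Minimum Otsu effectiveness (between/total
#'   variance, in `[0,1]`) required to accept the data-driven threshold.
#'   A unimodal Gaussian sample cannot exceed ~0.68 (the `2/pi` bound),
#'   while well-separated 2 vs 14 um mixtures score above 0.9; default 0.75.
#' @param fallback_cutoff_um Fixed cutoff used when bimodality is not
#'   established.
#' @return A `population_split`: list with `threshold_um`, `class`
#'   (character vector, `"oligomer"`/`"plaque"`), `method`
#'   (`"otsu"`/`"fallback"`), and `separation` (the effectiveness score).
#' @export
split_populations <- function(diameters_um, bimodality_floor = 0.75,
                              fallback_cutoff_um = 6) {
  d <- diameters_um
  if (length(d) == 0L) abort("`diameters_um` must be non-empty.")
  if (any(!is.finite(d)) || any(d <= 0)) {
    abort("`diameters_um` must be positive and finite.")
  }
  ot <- otsu_log_split(log(d))
  if (!is.na(ot$k) && ot$eta >= bimodality_floor) {
    threshold <- exp(ot$threshold_log)
    method <- "otsu"
  } else {
    threshold <- fallback_cutoff_um
    method <- "fallback"
  }
  structure(list(threshold_um = threshold,
                 class = ifelse(d < threshold, "oligomer", "plaque"),
                 method = method,
                 separation = ot$eta,
                 n = length(d)),
            class = "population_split")
}

#' @export
print.population_split <- function(x, ...) {
  cat(sprintf(
    "<population_split> threshold %.3g um (%s, separation %.3f): %d oligomer, %d plaque\n",
    x$threshold_um, x$method, x$separation,
    sum(x$class == "oligomer"), sum(x$class == "plaque")))
  invisible(x)
}

#' @export
tidy.population_split <- function(x, ...) {
  tibble(class = c("oligomer", "plaque"),
         n = c(sum(x$class == "oligomer"), sum(x$class == "plaque")))
}

#' @export
glance.population_split <- function(x, ...) {
  tibble(threshold_um = x$threshold_um, method = x$method,
         separation = x$separation, n = x$n)
}

#' Classify measured deposits by size
#'
#' Convenience wrapper: runs [split_populations()] on the
#' `equivalent_diameter_um` column and fills the `class` column.
#'
#' @param objects Tibble from [measure_objects()].
#' @param ... Passed to [split_populations()].
#' @return `objects` with `class` filled; the `population_split` object is
#'   attached as attribute `"split"`.
#' @export
classify_deposits <- function(objects, ...) {
  if (nrow(objects) == 0L) return(objects)
  sp <- split_populations(objects$equivalent_diameter_um, ...)
  objects$class <- sp$class
  attr(objects, "split") <- sp
  objects
}

#' Per-region summary of deposit burden
#'
#' Aggregates measured, classified deposits into one row per ROI: density
#' statistics are computed across slides (mean and sample SD of per-slide
#' object count / ROI area), while area and eccentricity statistics pool
#' objects. Class-wise mean diameters report the oligomer and plaque
#' populations separately. A single-slide SD is reported as 0 with the
#' `single_slide` flag set (keeps the table numeric). Slides contributing
#' zero objects to an ROI enter its density mean as 0, so pass `slides`
#' when some slides are empty.
#'
#' @param objects Tibble with at least `slide_id`, `roi_name`,
#'   `area_um2`, `equivalent_diameter_um`, `eccentricity`, `class`.
#'   Objects with `roi_name` `NA` are dropped.
#' @param roi_areas_mm2 Named numeric vector of ROI areas in mm^2.
#' @param slides Character vector of all slide ids (default: those present
#'   in `objects`).
#' @return A tibble, one row per ROI, ordered by `roi_name`.
#' @export
region_summary <- function(objects, roi_areas_mm2, slides = NULL) {
  stopifnot(is.numeric(roi_areas_mm2), !is.null(names(roi_areas_mm2)))
  if (!"slide_id" %in% names(objects)) {
    abort("`objects` needs a `slide_id` column.")
  }
  obj <- dplyr::filter(objects, !is.na(.data$roi_name))
  if (is.null(slides)) slides <- sort(unique(as.character(obj$slide_id)))
  if (length(slides) == 0L) {
    warn("no slides to summarise.")
    return(tibble())
  }
  rois <- sort(names(roi_areas_mm2))
  out <- purrr::map_dfr(rois, function(rn) {
    o <- dplyr::filter(obj, .data$roi_name == rn)
    counts <- vapply(slides,
                     function(s) sum(o$slide_id == s), numeric(1))
    dens <- density_per_mm2(counts, roi_areas_mm2[[rn]])
    single <- length(slides) == 1L
    tibble(
      roi_name = rn,
      n_slides = length(slides),
      n_objects = nrow(o),
      density_mean = mean(dens),
      density_sd = if (single) 0 else sd(dens),
      single_slide = single,
      area_mean_um2 = if (nrow(o)) mean(o$area_um2) else NA_real_,
      area_sd_um2 = if (nrow(o) > 1) sd(o$area_um2) else 0,
      diameter_mean_oligomer_um =
        mean(o$equivalent_diameter_um[o$class == "oligomer"]),
      diameter_mean_plaque_um =
        mean(o$equivalent_diameter_um[o$class == "plaque"]),
      eccentricity_mean = if (nrow(o)) mean(o$eccentricity) else NA_real_,
      eccentricity_sd = if (nrow(o) > 1) sd(o$eccentricity) else 0)
  })
  class(out) <- c("region_summary", class(out))
  out
}

#' Unpaired two-sample t-test on positive-pixel counts
#'
#' Student's pooled-variance two-sample t (the conventional "unpaired
#' t-test"): `t = (mean1 - mean2) / sqrt(sp2 * (1/n1 + 1/n2))` with
#' `df = n1 + n2 - 2` and a two-sided p-value from the t distribution.
#' The sign convention is group1 minus group2. Welch's unequal-variance
#' form is available with `var_equal = FALSE`.
#'
#' @param group1,group2 Numeric vectors, each of length >= 2.
#' @param var_equal Pool the variances (default TRUE).
#' @return A `group_comparison`: list with `t`, `df`, `p_value`, per-group
#'   means, sds and ns.
#' @export
unpaired_t_test <- function(group1, group2, var_equal = TRUE) {
  n1 <- length(group1); n2 <- length(group2)
  if (n1 < 2 || n2 < 2) abort("each group needs at least 2 observations.")
  m1 <- mean(group1); m2 <- mean(group2)
  v1 <- var(group1); v2 <- var(group2)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    df <- n1 + n2 - 2
    se2 <- sp2 * (1 / n1 + 1 / n2)
  } else {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  if (se2 == 0) {
    if (m1 == m2) {
      t <- 0; p <- 1
    } else {
      abort("degenerate input: zero variance but unequal means.")
    }
  } else {
    t <- (m1 - m2) / sqrt(se2)
    p <- 2 * pt(-abs(t), df)
  }
  structure(list(t = t, df = df, p_value = p,
                 mean1 = m1, mean2 = m2, sd1 = sqrt(v1), sd2 = sqrt(v2),
                 n1 = n1, n2 = n2, var_equal = var_equal),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> t = %.4g, df = %.4g, p = %.4g\n",
              x$t, x$df, x$p_value))
  cat(sprintf("  group1: mean %.4g (n = %d); group2: mean %.4g (n = %d)\n",
              x$mean1, x$n1, x$mean2, x$n2))
  invisible(x)
}

#' @export
tidy.group_comparison <- function(x, ...) {
  tibble(estimate = x$mean1 - x$mean2, estimate1 = x$mean1,
         estimate2 = x$mean2, statistic = x$t, df = x$df,
         p.value = x$p_value,
         method = if (x$var_equal) "student" else "welch")
}

#' @export
glance.group_comparison <- function(x, ...) tidy(x, ...)

#' @importFrom stats pt
NULL
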