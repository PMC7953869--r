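# Intensity normalisation: outlier clipping, median alignment, min-max scale.
# Applied per series over the whole volume, before VOI use, to compensate for
# scanner- and patient-dependent intensity scales.

#' Normalisation configuration
#'
#' @param outlier_low,outlier_high percentile fractions used for outlier
#'   clipping; `0 <= low < high <= 1`
#' @param target_median where the volume median lands after the full
#'   normalisation chain, strictly inside (0, 1)
#' @return object of class `normalization_config`
#' @export
normalization_config <- function(outlier_low = 0.01, outlier_high = 0.99,
                                 target_median = 0.5) {
  stopifnot(outlier_low >= 0, outlier_high <= 1, outlier_low < outlier_high,
            target_median > 0, target_median < 1)
  structure(list(outlier_low = outlier_low, outlier_high = outlier_high,
                 target_median = target_median),
            class = "normalization_config")
}

#' Clip intensity outliers
#'
#' Clips intensities below/above the configured percentiles to the percentile
#' values; a constant volume is returned unchanged.
#'
#' @param volume numeric array of intensities
#' @param config a [normalization_config()]
#' @return array of the same shape
#' @export
clip_outliers <- function(volume, config = normalization_config()) {
  stopifnot(length(volume) > 0)
  if (max(volume) == min(volume)) return(volume)
  q <- stats::quantile(volume, c(config$outlier_low, config$outlier_high),
                       names = FALSE)
  volume[volume < q[1]] <- q[1]
  volume[volume > q[2]] <- q[2]
  volume
}

#' Median normalisation
#'
#' Two-segment piecewise-linear monotone map aligning the histogram landmarks
#' (min, median, max) to (0, `target_median`, 1): intensities below the
#' median are mapped linearly onto \[0, target_median\], those above onto
#' \[target_median, 1\].  A subsequent [minmax_scale()] is then the identity,
#' so the volume median after the full chain equals `target_median`.  If the
#' median coincides with the minimum or maximum the lower/upper segment is
#' degenerate and the map falls back to plain min-max scaling.
#'
#' @inheritParams clip_outliers
#' @return array of the same shape with values in \[0, 1\]
#' @export
median_normalize <- function(volume, config = normalization_config()) {
  lo <- min(volume); hi <- max(volume)
  if (hi <= lo)
    stop("median normalisation needs positive intensity spread (constant volume)")
  med <- stats::median(volume)
  if (med <= lo || med >= hi) return((volume - lo) / (hi - lo))
  tm <- config$target_median
  out <- volume
  low <- volume <= med
  out[low] <- tm * (volume[low] - lo) / (med - lo)
  out[!low] <- tm + (1 - tm) * (volume[!low] - med) / (hi - med)
  out
}

#' Min-max scaling to \[0, 1\]
#'
#' @param volume numeric array with `max > min`
#' @return array affinely rescaled so min = 0 and max = 1
#' @export
minmax_scale <- function(volume) {
  lo <- min(volume); hi <- max(volume)
  if (hi <= lo) stop("min-max scaling undefined for a constant volume")
  (volume - lo) / (hi - lo)
}

#' Full normalisation chain
#'
#' Outlier clipping, median normalisation, then min-max scaling.  The chain
#' is monotone (rank-preserving), maps any finite volume with positive spread
#' into \[0, 1\], and is invariant to positive affine transforms of the raw
#' intensities, which is its purpose: inter-patient and inter-scanner
#' intensity scales cancel out.
#'
#' @inheritParams clip_outliers
#' @return normalised array in \[0, 1\]
#' @export
normalize_volume <- function(volume, config = normalization_config()) {
  minmax_scale(median_normalize(clip_outliers(volume, config), config))
}

#' @rdname normalize_volume
#' @param series a [volume_series()]
#' @return `normalize_series`: the series with normalised intensities
#' @export
normalize_series <- function(series, config = normalization_config()) {
  series$intensities <- tryCatch(
    normalize_volume(series$intensities, config),
    error = function(e) stop("normalisation failed for ", series$modality,
                             " series: ", conditionMessage(e)))
  series
}
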