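# Per-finding multiparametric sample bundles.

#' Construct a multiparametric sample
#'
#' The per-finding bundle the networks consume: six VOIs (three T2W
#' acquisition planes, DWI, ADC, K-Trans), the zone one-hot code and the
#' class label.
#'
#' @param finding a [finding_record()]
#' @param vois named list of six 3D arrays (or [extract_voi()] objects),
#'   names `r paste(MODALITIES, collapse = ", ")`
#' @return object of class `mp_sample`
#' @export
mp_sample <- function(finding, vois) {
  stopifnot(setequal(names(vois), MODALITIES))
  vois <- lapply(vois[MODALITIES], function(v) if (inherits(v, "voi")) v$grid else v)
  stopifnot(all(vapply(vois, function(v) length(dim(v)) == 3L, logical(1))))
  structure(list(finding = finding,
                 vois = vois,
                 zone_code = zone_onehot(finding$zone),
                 label = as.integer(isTRUE(finding$significant))),
            class = "mp_sample")
}

#' @export
print.mp_sample <- function(x, ...) {
  cat(sprintf("<mp_sample %s/%s  zone %s  label %s>\n",
              x$finding$patient_id, x$finding$finding_id, x$finding$zone,
              if (x$label == 1L) "significant" else "insignificant"))
  invisible(x)
}

#' Build multiparametric samples from series and findings
#'
#' Normalises each series over its whole volume, then extracts the
#' fixed-physical-size VOI around each finding.
#'
#' @param findings list of [finding_record()]
#' @param series_for function(finding) returning the named list of six
#'   [volume_series()] for that finding's patient
#' @param edge_mm VOI physical edge length in mm
#' @param norm_config a [normalization_config()]
#' @return list of [mp_sample()]
#' @export
prepare_samples <- function(findings, series_for, edge_mm = 30,
                            norm_config = normalization_config()) {
  lapply(findings, function(f) {
    series <- series_for(f)
    stopifnot(setequal(names(series), MODALITIES))
    vois <- lapply(series[MODALITIES], function(s)
      extract_voi(normalize_series(s, norm_config), f$position_mm, edge_mm))
    mp_sample(f, vois)
  })
}

# Stack a list of mp_samples into per-modality (X,Y,Z,B,1) tensors plus the
# zone matrix and label vector consumed by the network forward pass.
batch_tensors <- function(samples) {
  B <- length(samples)
  vols <- lapply(MODALITIES, function(m) {
    d <- dim(samples[[1]]$vois[[m]])
    arr <- array(0, dim = c(d, B, 1L))
    for (i in seq_len(B)) arr[, , , i, 1L] <- samples[[i]]$vois[[m]]
    arr
  })
  names(vols) <- MODALITIES
  list(vols = vols,
       zone = t(vapply(samples, `[[`, numeric(5), "zone_code")),
       zones = vapply(samples, function(s) s$finding$zone, character(1)),
       labels = vapply(samples, `[[`, integer(1), "label"))
}
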