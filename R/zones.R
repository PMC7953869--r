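#' Prostate zones and PI-RADS stream routing
#'
#' The five anatomic zones used throughout the package, in the fixed order
#' that also defines the zone one-hot encoding: peripheral zone (PZ),
#' transition zone (TZ), central zone (CZ), anterior fibromuscular stroma
#' (AFS) and seminal vesicles (SV).
#'
#' @format Character vector of length 5.
#' @export
ZONES <- c("PZ", "TZ", "CZ", "AFS", "SV")

# PROSTATEx findings-file vocabulary -> canonical zone labels.
# The public findings file abbreviates the anterior fibromuscular stroma "AS".
.zone_aliases <- c(PZ = "PZ", TZ = "TZ", CZ = "CZ", AFS = "AFS", AS = "AFS",
                   SV = "SV")

#' Parse a zone label
#'
#' Maps findings-table zone strings (including the PROSTATEx abbreviation
#' "AS" for the anterior fibromuscular stroma) onto the canonical enumeration.
#'
#' @param x character vector of zone strings
#' @return character vector of canonical zone labels
#' @export
parse_zone <- function(x) {
  x <- toupper(trimws(x))
  out <- .zone_aliases[x]
  bad <- is.na(out)
  if (any(bad))
    stop("unknown prostate zone label(s): ",
         paste(unique(x[bad]), collapse = ", "),
         " (expected one of ", paste(names(.zone_aliases), collapse = ", "), ")")
  unname(out)
}

#' Zone one-hot encoding
#'
#' Encodes a prostate zone as the five-element binary vector fed to the
#' modality-specific dense layers, element order (PZ, TZ, CZ, AFS, SV).
#'
#' @param zone a zone label (see [ZONES])
#' @return numeric vector of length 5 with exactly one element equal to 1
#' @export
#' @examples
#' zone_onehot("PZ")
#' zone_onehot("SV")
zone_onehot <- function(zone) {
  zone <- parse_zone(zone)
  stopifnot(length(zone) == 1L)
  as.numeric(ZONES == zone)
}

#' PI-RADS dominant-sequence stream for a zone
#'
#' Under PI-RADS the peripheral zone is assessed primarily on DWI (with DCE
#' in a supporting role) while the transition zone is assessed primarily on
#' T2W (with DWI supporting).  Lesions in the AFS and SV follow the TZ rules;
#' the central zone, absent from the cohort but present in PI-RADS, is routed
#' to its nearest neighbouring zone's rules (TZ).
#'
#' @inheritParams zone_onehot
#' @return `"PZ_stream"` or `"TZ_stream"`
#' @export
#' @examples
#' stream_for_zone("PZ")   # PZ_stream
#' stream_for_zone("AFS")  # TZ_stream
stream_for_zone <- function(zone) {
  zone <- parse_zone(zone)
  stopifnot(length(zone) == 1L)
  if (zone == "PZ") "PZ_stream" else "TZ_stream"
}

#' Route sub-network logits according to the lesion zone
#'
#' The knowledge-encoded model (M2) forms its final logits as the arithmetic
#' mean of the two zone-relevant auxiliary-classifier logit vectors:
#' DWI/ADC and DCE for peripheral-zone lesions, T2W and DWI/ADC for
#' transition-zone (and AFS/SV/CZ) lesions.
#'
#' @inheritParams zone_onehot
#' @param t2_logits,da_logits,dce_logits 2-element logit vectors from the
#'   T2W, DWI/ADC and DCE auxiliary classifiers
#' @return 2-element routed logit vector
#' @export
#' @examples
#' route_logits("PZ", t2_logits = c(9, 9), da_logits = c(1, 0),
#'               dce_logits = c(0, 1))  # c(0.5, 0.5); T2 ignored
route_logits <- function(zone, t2_logits, da_logits, dce_logits) {
  stopifnot(length(t2_logits) == 2L, length(da_logits) == 2L,
            length(dce_logits) == 2L)
  if (stream_for_zone(zone) == "PZ_stream") (da_logits + dce_logits) / 2
  else (t2_logits + da_logits) / 2
}
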