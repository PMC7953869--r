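# Findings-table input and clinical-significance labelling.

#' Construct a finding record
#'
#' One suspicious lesion: its patient, world-frame position in millimetres,
#' prostate zone and clinical-significance label.  PI-RADS and Gleason
#' fields are optional; a lesion scored PI-RADS 1-2 was not biopsied and so
#' carries no Gleason score.
#'
#' @param patient_id,finding_id identifiers (coerced to character)
#' @param position_mm numeric 3-vector, scanner world frame (x, y, z) in mm
#' @param zone zone label, see [ZONES] (PROSTATEx "AS" accepted for AFS)
#' @param significant logical or NA if unknown
#' @param pirads optional integer 1-5
#' @param gleason optional integer Gleason score
#' @return an object of class `finding_record`
#' @export
finding_record <- function(patient_id, finding_id, position_mm, zone,
                           significant = NA, pirads = NULL, gleason = NULL) {
  stopifnot(length(position_mm) == 3L, all(is.finite(position_mm)))
  zone <- parse_zone(zone)
  if (!is.null(pirads)) {
    stopifnot(pirads %in% 1:5)
    if (pirads <= 2 && !is.null(gleason))
      stop("finding ", finding_id, ": PI-RADS <= 2 lesions are not biopsied; ",
           "a Gleason score must be absent")
  }
  structure(list(patient_id = as.character(patient_id),
                 finding_id = as.character(finding_id),
                 position_mm = as.numeric(position_mm),
                 zone = zone,
                 significant = as.logical(significant),
                 pirads = pirads, gleason = gleason),
            class = "finding_record")
}

#' @export
print.finding_record <- function(x, ...) {
  cat(sprintf("<finding %s/%s  zone %s  pos (%.1f, %.1f, %.1f) mm  %s>\n",
              x$patient_id, x$finding_id, x$zone,
              x$position_mm[1], x$position_mm[2], x$position_mm[3],
              if (isTRUE(x$significant)) "significant"
              else if (identical(x$significant, FALSE)) "insignificant"
              else "label unknown"))
  invisible(x)
}

.parse_pos <- function(s) {
  v <- suppressWarnings(as.numeric(strsplit(trimws(gsub("[(),]", " ", s)),
                                            "\\s+")[[1]]))
  if (length(v) != 3L || anyNA(v)) NULL else v
}

#' Read a findings table
#'
#' Reads a lesion findings table in the PROSTATEx CSV dialect: columns for
#' patient id (`ProxID`), finding id (`fid`), world position in mm (`pos`,
#' whitespace- or comma-separated triplet), `zone`, and either a clinical
#' significance flag (`ClinSig`) or `pirads`/`gleason` columns from which
#' the label is derived via [label_significance()].
#'
#' @param path path to the CSV file
#' @return list of [finding_record()] objects
#' @export
read_findings <- function(path) {
  if (!file.exists(path)) stop("findings file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- tolower(names(df))
  col <- function(...) {
    for (nm in c(...)) if (nm %in% names(df)) return(nm)
    NULL
  }
  c_pat <- col("proxid", "patient_id")
  c_fid <- col("fid", "finding_id")
  c_pos <- col("pos", "position", "position_mm")
  c_zone <- col("zone")
  c_sig <- col("clinsig", "significant")
  c_pirads <- col("pirads", "pi_rads")
  c_gleason <- col("gleason", "ggg", "gs")
  missing_cols <- c(patient = is.null(c_pat), finding = is.null(c_fid),
                    position = is.null(c_pos), zone = is.null(c_zone))
  if (any(missing_cols))
    stop("findings file ", path, " lacks required column(s): ",
         paste(names(missing_cols)[missing_cols], collapse = ", "))
  if (is.null(c_sig) && is.null(c_pirads))
    stop("findings file ", path,
         " needs either a ClinSig column or pirads/gleason columns")

  records <- vector("list", nrow(df))
  errors <- character()
  for (i in seq_len(nrow(df))) {
    rec <- tryCatch({
      pos <- .parse_pos(df[[c_pos]][i])
      if (is.null(pos)) stop("unparseable position '", df[[c_pos]][i], "'")
      pirads <- if (!is.null(c_pirads)) as.integer(df[[c_pirads]][i]) else NULL
      gleason <- if (!is.null(c_gleason) && !is.na(df[[c_gleason]][i]))
        as.integer(df[[c_gleason]][i]) else NULL
      sig <- if (!is.null(c_sig)) {
        v <- toupper(as.character(df[[c_sig]][i]))
        v %in% c("TRUE", "1", "YES")
      } else label_significance(pirads, gleason) == "significant"
      finding_record(df[[c_pat]][i], df[[c_fid]][i], pos, df[[c_zone]][i],
                     significant = sig, pirads = pirads, gleason = gleason)
    }, error = function(e) conditionMessage(e))
    if (is.character(rec)) errors <- c(errors, sprintf("row %d: %s", i, rec))
    else records[[i]] <- rec
  }
  if (length(errors))
    stop("malformed findings rows in ", path, ":\n  ",
         paste(errors, collapse = "\n  "))
  records
}

#' Clinical-significance label from PI-RADS and Gleason scores
#'
#' Lesions scored PI-RADS 2 or lower were not biopsied and are labelled
#' insignificant.  Biopsied lesions (PI-RADS > 2) are clinically significant
#' when their Gleason score is 7 or above.
#'
#' @param pirads integer 1-5
#' @param gleason integer Gleason score; must be present iff `pirads > 2`
#' @return `"significant"` or `"insignificant"`
#' @export
#' @examples
#' label_significance(2)              # insignificant (not biopsied)
#' label_significance(4, gleason = 7) # significant
#' label_significance(3, gleason = 6) # insignificant
label_significance <- function(pirads, gleason = NULL) {
  stopifnot(length(pirads) == 1L, pirads %in% 1:5)
  if (pirads <= 2) {
    if (!is.null(gleason))
      stop("PI-RADS <= 2 lesions are not biopsied; Gleason score must be absent")
    return("insignificant")
  }
  if (is.null(gleason) || is.na(gleason))
    stop("inconsistent record: PI-RADS ", pirads,
         " implies biopsy, but no Gleason score is present")
  if (gleason >= 7) "significant" else "insignificant"
}
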