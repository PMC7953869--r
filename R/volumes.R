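# Volume input, world-to-voxel geometry and VOI extraction.

MODALITIES <- c("T2W_tra", "T2W_sag", "T2W_cor", "DWI", "ADC", "KTRANS")

#' Construct a volume series
#'
#' One 3D intensity grid with its acquisition geometry: voxel spacing,
#' world-frame origin and direction-cosine orientation matrix.  World
#' coordinates are `origin + orientation %*% (spacing * index)` with
#' 0-based voxel indices.
#'
#' @param modality one of `r paste(MODALITIES, collapse = ", ")`
#' @param intensities 3D numeric array
#' @param spacing_mm numeric 3-vector of voxel spacings (mm), all positive
#' @param origin_mm numeric 3-vector, world position of voxel (0,0,0)
#' @param orientation 3x3 direction-cosine matrix (default identity)
#' @return object of class `volume_series`
#' @export
volume_series <- function(modality, intensities, spacing_mm,
                          origin_mm = c(0, 0, 0), orientation = diag(3)) {
  modality <- match.arg(modality, MODALITIES)
  stopifnot(is.array(intensities), length(dim(intensities)) == 3L,
            all(dim(intensities) >= 1L),
            length(spacing_mm) == 3L, all(spacing_mm > 0),
            length(origin_mm) == 3L,
            is.matrix(orientation), all(dim(orientation) == c(3L, 3L)))
  structure(list(modality = modality, intensities = intensities,
                 spacing_mm = as.numeric(spacing_mm),
                 origin_mm = as.numeric(origin_mm),
                 orientation = orientation),
            class = "volume_series")
}

#' @export
print.volume_series <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<volume %s  %d x %d x %d  spacing %.2f x %.2f x %.2f mm>\n",
              x$modality, d[1], d[2], d[3],
              x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3]))
  invisible(x)
}

# round half away from zero (round() rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Map a world-frame position to voxel indices
#'
#' Applies the inverse affine of (origin, spacing, orientation) and rounds
#' to the nearest integer (half away from zero).  The result is a 0-based
#' index triplet and may lie outside the grid; callers decide how to handle
#' out-of-grid positions.
#'
#' @param position_mm numeric 3-vector, world frame (mm)
#' @param series a [volume_series()]
#' @return integer 3-vector of 0-based voxel indices
#' @export
world_to_voxel <- function(position_mm, series) {
  stopifnot(length(position_mm) == 3L, all(is.finite(position_mm)))
  if (abs(det(series$orientation)) < 1e-12)
    stop("singular orientation matrix for ", series$modality, " series")
  v <- solve(series$orientation, position_mm - series$origin_mm) /
    series$spacing_mm
  as.integer(round_half_away(v))
}

#' Extract a fixed-physical-size VOI around a lesion
#'
#' Extracts a cube of physical edge length `edge_mm` (default 3 cm, matching
#' the PI-RADS size criterion for high-suspicion lesions) centred on the
#' lesion, without any resampling: the per-axis extent in voxels is
#' `round(edge_mm / spacing)` (half away from zero), so extents differ
#' between modalities with different voxel spacings.  For even extents the
#' centre voxel sits left of centre at 0-based offset `extent/2`.  Voxels
#' outside the source grid are filled by replicating the nearest edge voxel.
#'
#' @param series a [volume_series()]
#' @param centre_mm lesion centre in world coordinates (mm)
#' @param edge_mm physical edge length of the cube (mm)
#' @return object of class `voi`: list with the subvolume grid, modality,
#'   source spacing, centre voxel index and edge length
#' @export
extract_voi <- function(series, centre_mm, edge_mm = 30) {
  stopifnot(edge_mm > 0)
  ext <- as.integer(round_half_away(edge_mm / series$spacing_mm))
  stopifnot(all(ext >= 1L))
  ctr <- world_to_voxel(centre_mm, series)
  d <- dim(series$intensities)
  start <- ctr - ext %/% 2L            # 0-based window start
  if (any(start >= d) || any(start + ext <= 0L))
    stop("VOI for ", series$modality,
         " lies entirely outside the source grid (centre voxel ",
         paste(ctr, collapse = ","), ")")
  # replicate-edge padding via clamped index lookup
  ix <- pmin(pmax(start[1] + seq_len(ext[1]) - 1L, 0L), d[1] - 1L) + 1L
  iy <- pmin(pmax(start[2] + seq_len(ext[2]) - 1L, 0L), d[2] - 1L) + 1L
  iz <- pmin(pmax(start[3] + seq_len(ext[3]) - 1L, 0L), d[3] - 1L) + 1L
  grid <- series$intensities[ix, iy, iz, drop = FALSE]
  structure(list(modality = series$modality, grid = grid,
                 spacing_mm = series$spacing_mm, centre_voxel = ctr,
                 edge_mm = edge_mm),
            class = "voi")
}

#' @export
print.voi <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<voi %s  %d x %d x %d voxels  %.0f mm edge>\n",
              x$modality, d[1], d[2], d[3], x$edge_mm))
  invisible(x)
}

## ---- file input ------------------------------------------------------------

#' Read an image volume
#'
#' Reads NIfTI (`.nii`/`.nii.gz`, via RNifti) or MetaImage (`.mhd` + raw)
#' volumes, the formats in which mpMRI series and K-Trans maps are
#' distributed, into a [volume_series()].
#'
#' @param path path to the volume file
#' @param modality modality tag for the series
#' @return a [volume_series()]
#' @export
read_volume <- function(path, modality) {
  if (!file.exists(path)) stop("volume file not found: ", path)
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    xf <- RNifti::xform(img)
    A <- xf[1:3, 1:3]
    spacing <- sqrt(colSums(A^2))
    orient <- sweep(A, 2, spacing, `/`)
    volume_series(modality, array(as.numeric(img), dim = dim(img)[1:3]),
                  spacing_mm = spacing, origin_mm = xf[1:3, 4],
                  orientation = orient)
  } else if (grepl("\\.mhd$", path)) {
    read_mhd(path, modality)
  } else stop("unsupported volume format: ", path,
              " (expected .nii, .nii.gz or .mhd)")
}

# Minimal MetaImage (MHD header + raw voxel file) reader; raw data are
# stored x-fastest, matching R's column-major array layout.
read_mhd <- function(path, modality) {
  lines <- readLines(path, warn = FALSE)
  kv <- list()
  for (ln in lines) {
    p <- regmatches(ln, regexpr("=", ln), invert = TRUE)[[1]]
    if (length(p) == 2L) kv[[trimws(p[1])]] <- trimws(p[2])
  }
  dims <- as.integer(strsplit(kv$DimSize, "\\s+")[[1]])
  spacing <- if (!is.null(kv$ElementSpacing))
    as.numeric(strsplit(kv$ElementSpacing, "\\s+")[[1]]) else c(1, 1, 1)
  origin <- if (!is.null(kv$Offset))
    as.numeric(strsplit(kv$Offset, "\\s+")[[1]]) else c(0, 0, 0)
  orient <- if (!is.null(kv$TransformMatrix))
    matrix(as.numeric(strsplit(kv$TransformMatrix, "\\s+")[[1]]), 3, 3)
  else diag(3)
  type <- kv$ElementType %||% "MET_FLOAT"
  datafile <- kv$ElementDataFile
  if (is.null(datafile) || identical(datafile, "LOCAL"))
    stop("MHD reader supports only external raw data files: ", path)
  raw_path <- file.path(dirname(path), datafile)
  n <- prod(dims)
  con <- file(raw_path, "rb")
  on.exit(close(con))
  vals <- switch(type,
    MET_FLOAT  = readBin(con, "double", n, size = 4),
    MET_DOUBLE = readBin(con, "double", n, size = 8),
    MET_SHORT  = readBin(con, "integer", n, size = 2, signed = TRUE),
    MET_USHORT = readBin(con, "integer", n, size = 2, signed = FALSE),
    MET_UCHAR  = as.integer(readBin(con, "raw", n)),
    stop("unsupported MHD element type: ", type))
  volume_series(modality, array(as.numeric(vals), dim = dims),
                spacing_mm = spacing, origin_mm = origin, orientation = orient)
}

#' Write a volume series to NIfTI
#'
#' @param series a [volume_series()]
#' @param path output path (`.nii` or `.nii.gz`)
#' @return `path`, invisibly
#' @export
write_volume <- function(series, path) {
  img <- RNifti::asNifti(series$intensities)
  A <- sweep(series$orientation, 2, series$spacing_mm, `*`)
  xf <- rbind(cbind(A, series$origin_mm), c(0, 0, 0, 1))
  img <- RNifti::`sform<-`(img, structure(xf, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
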