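#' Image volume container
#'
#' A thin container for a 3-D scalar array on a regular grid: the voxel data,
#' the voxel spacing in millimetres, and the physical offset of the grid
#' corner. Voxel centers sit at `origin + (index - 0.5) * spacing` (1-based
#' indices), i.e. the half-voxel center convention.
#'
#' @param data 3-D numeric array.
#' @param spacing_mm positive length-3 numeric, voxel edge lengths in mm.
#' @param origin length-3 numeric offset of the grid corner (mm).
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing_mm = c(1, 1, 1), origin = c(0, 0, 0)) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (any(dim(data) < 2L)) stop("image_volume: each axis needs at least 2 voxels")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("image_volume: spacing must be a strictly positive length-3 numeric")
  structure(list(data = data, spacing_mm = spacing_mm, origin = as.numeric(origin)),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels @ ", paste(signif(x$spacing_mm, 4), collapse = " x "), " mm\n", sep = "")
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

as_image_volume <- function(x, spacing_mm = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (inherits(x, "image_volume")) x else image_volume(x, spacing_mm, origin)
}

#' Resample a volume and its mask onto an isotropic grid
#'
#' Resamples both images onto a grid of `target_mm` voxels covering the same
#' physical extent. Intensities are trilinearly interpolated; the mask is
#' resampled by nearest neighbour so it stays binary. Grids are aligned by
#' physical coordinates under the half-voxel center convention.
#'
#' @param volume,mask `image_volume` objects on the same grid (mask binary).
#' @param target_mm target voxel size, scalar or length-3 (mm).
#' @param patient_id optional label used in error messages.
#' @return list with elements `volume` and `mask`, both `image_volume`.
#' @export
resample_isotropic <- function(volume, mask, target_mm = c(2, 2, 2), patient_id = NULL) {
  stopifnot(inherits(volume, "image_volume"), inherits(mask, "image_volume"))
  if (!identical(dim(volume$data), dim(mask$data)))
    stop("resample_isotropic: mask is not aligned to the volume grid")
  if (length(target_mm) == 1L) target_mm <- rep(target_mm, 3)
  target_mm <- as.numeric(target_mm)
  stopifnot(all(target_mm > 0))

  din <- dim(volume$data)
  extent <- din * volume$spacing_mm
  dout <- pmax(as.integer(ceiling(extent / target_mm - 1e-9)), 2L)

  v <- cpp_resample3d(as.numeric(volume$data), as.integer(din), volume$spacing_mm,
                      volume$origin, dout, target_mm, volume$origin, nearest = FALSE)
  m <- cpp_resample3d(as.numeric(mask$data != 0), as.integer(din), mask$spacing_mm,
                      mask$origin, dout, target_mm, mask$origin, nearest = TRUE)
  dim(v) <- dout; dim(m) <- dout
  if (sum(m) == 0)
    stop("resample_isotropic: resampled mask is empty",
         if (!is.null(patient_id)) paste0(" for patient ", patient_id) else "")
  list(volume = image_volume(v, target_mm, volume$origin),
       mask = image_volume(m, target_mm, mask$origin))
}

#' Discretize masked intensities with a fixed bin width
#'
#' Gray levels are assigned as
#' `level(x) = floor((I(x) - min(I[mask])) / bin_width) + 1`,
#' referenced to the masked minimum (fixed-bin-size convention), so levels are
#' invariant to intensity shifts of the whole image. Voxels outside the mask
#' are coded 0.
#'
#' @param volume `image_volume` or 3-D array of intensities.
#' @param mask `image_volume` or 3-D binary array.
#' @param bin_width positive bin width in intensity units.
#' @return An object of class `discretized_roi`: list with `levels` (integer
#'   array, 0 outside the mask), `n_levels`, `bin_width`, `min_intensity`.
#' @export
discretize <- function(volume, mask, bin_width = 25) {
  if (bin_width <= 0) stop("discretize: bin_width must be positive")
  vol <- if (inherits(volume, "image_volume")) volume$data else volume
  msk <- if (inherits(mask, "image_volume")) mask$data else mask
  stopifnot(identical(dim(vol), dim(msk)))
  inside <- msk != 0
  if (!any(inside)) stop("discretize: mask is empty")
  mn <- min(vol[inside])
  lev <- array(0L, dim(vol))
  lev[inside] <- as.integer(floor((vol[inside] - mn) / bin_width)) + 1L
  structure(list(levels = lev, n_levels = max(lev), bin_width = bin_width,
                 min_intensity = mn),
            class = "discretized_roi")
}

#' @export
print.discretized_roi <- function(x, ...) {
  cat("<discretized_roi> ", sum(x$levels > 0), " voxels, ", x$n_levels,
      " gray levels (bin width ", x$bin_width, ")\n", sep = "")
  invisible(x)
}

# ---- I/O: NIfTI via RNifti, NRRD via a minimal built-in reader/writer ----

#' Read / write image volumes
#'
#' `read_volume()` and `write_volume()` dispatch on the file extension:
#' `.nii` / `.nii.gz` through the RNifti package, `.nrrd` through a minimal
#' built-in NRRD codec (raw or ascii encoding, little-endian).
#'
#' @param file path to a `.nii`, `.nii.gz` or `.nrrd` file.
#' @return `read_volume()` returns an `image_volume`.
#' @export
read_volume <- function(file) {
  if (grepl("\\.nrrd$", file, ignore.case = TRUE)) return(read_nrrd(file))
  img <- RNifti::readNifti(file)
  image_volume(array(as.numeric(img), dim(img)[1:3]),
               spacing_mm = RNifti::pixdim(img)[1:3])
}

#' @rdname read_volume
#' @param volume an `image_volume` (or 3-D array) to write.
#' @param encoding for NRRD output, `"raw"` or `"ascii"`.
#' @export
write_volume <- function(volume, file, encoding = "raw") {
  volume <- as_image_volume(volume)
  if (grepl("\\.nrrd$", file, ignore.case = TRUE))
    return(write_nrrd(volume, file, encoding))
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- volume$spacing_mm
  RNifti::writeNifti(img, file)
  invisible(file)
}

write_nrrd <- function(volume, file, encoding = c("raw", "ascii")) {
  encoding <- match.arg(encoding)
  d <- dim(volume$data)
  con <- file(file, "wb")
  on.exit(close(con))
  hdr <- c("NRRD0004",
           "# radprog volume",
           "type: double",
           "dimension: 3",
           paste("sizes:", paste(d, collapse = " ")),
           paste("spacings:", paste(volume$spacing_mm, collapse = " ")),
           "endian: little",
           paste("encoding:", encoding),
           "")
  writeLines(hdr, con, sep = "\n")
  if (encoding == "raw") {
    writeBin(as.numeric(volume$data), con, size = 8, endian = "little")
  } else {
    writeLines(paste(format(as.numeric(volume$data), digits = 17), collapse = " "), con)
  }
  invisible(file)
}

read_nrrd <- function(file) {
  con <- file(file, "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L || line == "") break
    hdr <- c(hdr, line)
  }
  field <- function(key) {
    hit <- grep(paste0("^", key, ": "), hdr, value = TRUE)
    if (length(hit) == 0L) return(NULL)
    sub(paste0("^", key, ": "), "", hit[[1]])
  }
  sizes <- as.integer(strsplit(field("sizes"), " ")[[1]])
  spac <- field("spacings")
  spacing <- if (is.null(spac)) rep(1, 3) else as.numeric(strsplit(spac, " ")[[1]])
  enc <- field("encoding")
  type <- field("type")
  n <- prod(sizes)
  if (identical(enc, "raw")) {
    size <- switch(type, double = 8L, float = 4L,
                   stop("read_nrrd: unsupported raw type ", type))
    what <- "numeric"
    dat <- readBin(con, what, n = n, size = size, endian = "little")
  } else if (identical(enc, "ascii") || identical(enc, "text")) {
    dat <- scan(con, what = numeric(), n = n, quiet = TRUE)
  } else stop("read_nrrd: unsupported encoding ", enc)
  image_volume(array(dat, sizes), spacing_mm = spacing)
}
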