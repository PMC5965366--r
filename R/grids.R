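#' @useDynLib dose4d, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft rnorm runif sd quantile approx
#' @importFrom utils write.csv read.csv modifyList
NULL

# ---- core raster types -----------------------------------------------------
#
# Coordinate convention (used everywhere): 0-based voxel indices, voxel
# centers at world = origin + index * spacing, world units mm, fixed patient
# axes LR = x, AP = y, SI = z. Grids are axis-aligned.

#' Create a voxel grid
#'
#' The universal raster container: a 3D scalar field (density in g/cm3, dose
#' in Gy, energy in J-surrogate units, or mass in g) on an axis-aligned grid.
#' Voxel centers sit at `origin + index * spacing` with 0-based indices and
#' world coordinates in mm (LR = x, AP = y, SI = z).
#'
#' @param data 3D numeric array.
#' @param spacing numeric length-3, voxel spacing in mm (all > 0).
#' @param origin numeric length-3, world position (mm) of the center of
#'   voxel (0,0,0).
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(data, spacing, origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L) stop("data must be a 3D array")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0)) stop("spacing must be 3 positive values")
  if (length(origin) != 3L) stop("origin must have length 3")
  if (!all(is.finite(data))) stop("all grid values must be finite")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %s voxels, spacing %s mm, origin %s mm\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              paste(format(x$origin), collapse = ", ")))
  cat(sprintf("  range [%.4g, %.4g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' Grid geometry descriptor
#'
#' Geometry without payload: dimensions, spacing and origin.
#' @param dim integer length-3 voxel counts.
#' @param spacing numeric length-3 spacing mm.
#' @param origin numeric length-3 origin mm.
#' @return An object of class `grid_geometry`.
#' @export
grid_geometry <- function(dim, spacing, origin = c(0, 0, 0)) {
  dim <- as.integer(dim)
  if (length(dim) != 3L || any(dim < 1L)) stop("dim must be 3 positive integers")
  if (any(spacing <= 0)) stop("degenerate spacing")
  structure(list(dim = dim, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)), class = "grid_geometry")
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("<grid_geometry> %s @ %s mm\n", paste(x$dim, collapse = "x"),
              paste(format(x$spacing), collapse = "x")))
  invisible(x)
}

geom_of <- function(g) {
  if (inherits(g, "grid_geometry")) return(g)
  grid_geometry(dim(if (!is.null(g$data)) g$data else g$mask), g$spacing, g$origin)
}

same_geometry <- function(a, b, tol = 1e-9) {
  ga <- geom_of(a); gb <- geom_of(b)
  all(ga$dim == gb$dim) && all(abs(ga$spacing - gb$spacing) < tol) &&
    all(abs(ga$origin - gb$origin) < tol)
}

#' World coordinates of voxel centers
#'
#' @param geom a `grid_geometry`, `voxel_grid` or `roi_mask`.
#' @param index integer matrix (n x 3) of 0-based voxel indices; if `NULL`,
#'   all voxel centers in array order.
#' @return numeric matrix (n x 3) of world mm coordinates.
#' @export
grid_points <- function(geom, index = NULL) {
  g <- geom_of(geom)
  if (is.null(index)) {
    index <- as.matrix(expand.grid(i = 0:(g$dim[1] - 1), j = 0:(g$dim[2] - 1),
                                   k = 0:(g$dim[3] - 1)))
  }
  sweep(sweep(index, 2, g$spacing, "*"), 2, g$origin, "+")
}

#' Map world coordinates to (fractional) voxel indices
#' @param geom grid geometry or grid.
#' @param pts numeric matrix (n x 3) world mm.
#' @return numeric matrix of 0-based fractional indices.
#' @export
world_to_index <- function(geom, pts) {
  g <- geom_of(geom)
  sweep(sweep(pts, 2, g$origin, "-"), 2, g$spacing, "/")
}

#' Create an ROI mask
#'
#' A named boolean mask on a grid geometry.
#' @param mask 3D logical array.
#' @param name label, e.g. "GTV", "lung", "cord", "airways", "ITV", "MTV", "PTV".
#' @param spacing,origin grid geometry of the mask.
#' @return Object of class `roi_mask`.
#' @export
roi_mask <- function(mask, name, spacing, origin = c(0, 0, 0)) {
  if (length(dim(mask)) != 3L) stop("mask must be a 3D array")
  structure(list(mask = mask != 0, name = as.character(name),
                 spacing = as.numeric(spacing), origin = as.numeric(origin)),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> '%s': %d voxels, %.2f cm3\n", x$name, sum(x$mask),
              mask_volume_cm3(x)))
  invisible(x)
}

#' Volume of a mask in cm3
#' @param mask an `roi_mask`.
#' @export
mask_volume_cm3 <- function(mask) {
  sum(mask$mask) * prod(mask$spacing) / 1000
}

#' Create a deformation field
#'
#' Per-voxel 3-vector mm displacements sampled on a (sub-)grid; zero outside
#' the sampled box. `direction` is "push" (phase -> reference) or "pull"
#' (reference -> phase).
#'
#' @param vectors 4D numeric array (nx, ny, nz, 3) of mm displacements.
#' @param spacing numeric length-3, sampling spacing mm.
#' @param origin world mm of the first sampled node.
#' @param direction "push" or "pull".
#' @param max_motion displacement magnitude bound used for validation (mm).
#' @return Object of class `deformation_field`.
#' @export
deformation_field <- function(vectors, spacing, origin = c(0, 0, 0),
                              direction = c("push", "pull"),
                              max_motion = 50) {
  direction <- match.arg(direction)
  d <- dim(vectors)
  if (length(d) != 4L || d[4] != 3L) stop("vectors must be (nx,ny,nz,3)")
  if (!all(is.finite(vectors))) stop("non-finite displacement")
  mag2 <- vectors[, , , 1]^2 + vectors[, , , 2]^2 + vectors[, , , 3]^2
  if (max(mag2) > max_motion^2)
    stop(sprintf("displacement exceeds max_motion = %g mm", max_motion))
  structure(list(vectors = vectors, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), direction = direction),
            class = "deformation_field")
}

#' Evaluate a deformation field at world points
#' @param field a `deformation_field`.
#' @param pts numeric matrix (n x 3) world mm.
#' @return matrix (n x 3) of displacements (zero outside the sampled box).
#' @export
dvf_eval <- function(field, pts) {
  d <- dim(field$vectors)
  cpp_trilinear_vec(field$vectors, d[1:3], field$spacing, field$origin,
                    as.matrix(pts))
}

# ---- file IO ---------------------------------------------------------------

nifti_like <- function(path) grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)
meta_like  <- function(path) grepl("\\.mh[ad]$", path, ignore.case = TRUE)

#' Read a scalar grid from NIfTI or MetaImage
#'
#' Supports axis-aligned `.nii`/`.nii.gz` (via RNifti) and uncompressed
#' local-raw `.mha`. The payload must be a 3D scalar field; vector-valued
#' files are rejected.
#'
#' @param path file path.
#' @return a `voxel_grid`.
#' @export
read_grid <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (nifti_like(path)) {
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) == 4L && d[4] == 1L) { img <- array(img, d[1:3]); d <- d[1:3] }
    if (length(d) != 3L) stop("not a 3D scalar payload: ", path)
    hdr <- RNifti::niftiHeader(path)
    spacing <- hdr$pixdim[2:4]
    if (any(spacing <= 0)) stop("grid spacing absent or non-positive")
    origin <- c(hdr$srow_x[4], hdr$srow_y[4], hdr$srow_z[4])
    voxel_grid(array(as.numeric(img), d), spacing, origin)
  } else if (meta_like(path)) {
    read_mha(path, vector_ok = FALSE)
  } else stop("unsupported grid format: ", path)
}

#' Write a scalar grid to NIfTI or MetaImage
#' @param grid a `voxel_grid` or `roi_mask` (masks are written as uint8).
#' @param path destination `.nii`, `.nii.gz`, or `.mha`.
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path) {
  is_mask <- inherits(grid, "roi_mask")
  data <- if (is_mask) array(as.integer(grid$mask), dim(grid$mask)) else grid$data
  if (nifti_like(path)) {
    img <- RNifti::asNifti(data)
    RNifti::pixdim(img) <- grid$spacing
    aff <- diag(c(grid$spacing, 1))
    aff[1:3, 4] <- grid$origin
    RNifti::sform(img) <- structure(aff, code = 2L)
    RNifti::qform(img) <- structure(aff, code = 2L)
    RNifti::writeNifti(img, path, datatype = if (is_mask) "uint8" else "double")
  } else if (meta_like(path)) {
    write_mha(data, grid$spacing, grid$origin, path,
              type = if (is_mask) "MET_UCHAR" else "MET_DOUBLE")
  } else stop("unsupported grid format: ", path)
  invisible(path)
}

#' Write a deformation field (3-vector payload) to NIfTI
#' @param field a `deformation_field`.
#' @param path destination `.nii`/`.nii.gz`.
#' @export
write_dvf <- function(field, path) {
  if (!nifti_like(path)) stop("DVFs are written as NIfTI")
  img <- RNifti::asNifti(field$vectors)
  RNifti::pixdim(img) <- c(field$spacing, 1)
  aff <- diag(c(field$spacing, 1)); aff[1:3, 4] <- field$origin
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a deformation field written by [write_dvf()]
#' @param path NIfTI path with (nx,ny,nz,3) payload.
#' @param direction "push" or "pull" tag to attach.
#' @export
read_dvf <- function(path, direction = "push") {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L || d[4] != 3L) stop("not a 3-vector payload: ", path)
  hdr <- RNifti::niftiHeader(path)
  deformation_field(array(as.numeric(img), d), hdr$pixdim[2:4],
                    c(hdr$srow_x[4], hdr$srow_y[4], hdr$srow_z[4]),
                    direction = direction, max_motion = Inf)
}

# Minimal MetaImage (.mha, local raw, uncompressed) support.
read_mha <- function(path, vector_ok = FALSE) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed MetaImage header")
    key <- trimws(kv[1]); val <- trimws(kv[2])
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  if (!identical(hdr[["ElementDataFile"]], "LOCAL"))
    stop("only LOCAL-raw MetaImage supported")
  if (identical(hdr[["CompressedData"]], "True"))
    stop("compressed MetaImage not supported")
  dims <- as.integer(strsplit(hdr[["DimSize"]], "\\s+")[[1]])
  if (length(dims) != 3L) stop("not a 3D payload")
  nch <- as.integer(hdr[["ElementNumberOfChannels"]] %||% "1")
  if (nch != 1L && !vector_ok) stop("vector-valued file passed as scalar")
  spacing <- as.numeric(strsplit(hdr[["ElementSpacing"]] %||%
                                   hdr[["ElementSize"]], "\\s+")[[1]])
  origin <- as.numeric(strsplit(hdr[["Offset"]] %||% "0 0 0", "\\s+")[[1]])
  type <- hdr[["ElementType"]]
  n <- prod(dims) * nch
  data <- switch(type,
    MET_DOUBLE = readBin(con, "double", n, size = 8),
    MET_FLOAT  = readBin(con, "double", n, size = 4),
    MET_UCHAR  = as.numeric(readBin(con, "integer", n, size = 1, signed = FALSE)),
    MET_SHORT  = as.numeric(readBin(con, "integer", n, size = 2, signed = TRUE)),
    stop("unsupported ElementType: ", type))
  voxel_grid(array(data, dims), spacing, origin)
}

write_mha <- function(data, spacing, origin, path, type = "MET_DOUBLE") {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False", "CompressedData = False",
           "TransformMatrix = 1 0 0 0 1 0 0 0 1",
           paste("Offset =", paste(format(origin, scientific = FALSE), collapse = " ")),
           paste("ElementSpacing =", paste(format(spacing, scientific = FALSE), collapse = " ")),
           paste("DimSize =", paste(dim(data), collapse = " ")),
           paste("ElementType =", type),
           "ElementDataFile = LOCAL")
  writeLines(hdr, con)
  if (type == "MET_UCHAR") writeBin(as.integer(data), con, size = 1)
  else writeBin(as.numeric(data), con, size = 8)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- resampling ------------------------------------------------------------

#' Resample a grid onto a target geometry
#'
#' Nearest-neighbour or trilinear interpolation with edge clamping (trilinear
#' output therefore never overshoots the source value range). When source and
#' target geometry coincide the input is returned unchanged.
#'
#' @param grid a `voxel_grid`.
#' @param target a `grid_geometry` (or grid whose geometry is used).
#' @param mode "trilinear" or "nearest".
#' @return a `voxel_grid` on the target geometry.
#' @export
resample <- function(grid, target, mode = c("trilinear", "nearest")) {
  mode <- match.arg(mode)
  tg <- geom_of(target)
  if (any(tg$spacing <= 0)) stop("degenerate target spacing")
  if (same_geometry(grid, tg)) return(grid)
  out <- cpp_resample(grid$data, dim(grid$data), grid$spacing, grid$origin,
                      tg$dim, tg$spacing, tg$origin,
                      if (mode == "nearest") 0L else 1L)
  voxel_grid(array(out, tg$dim), tg$spacing, tg$origin)
}
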