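#' Convert linear attenuation coefficients to a CT number
#'
#' The CT number scale is a linear rescaling of the X-ray linear attenuation
#' coefficient, centered at 0 for pure water and calibrated so that a
#' standardized air sample maps to -1000 HU:
#' \deqn{CTN = 1000 (\mu_{object} - \mu_{water}) / (\mu_{water} - \mu_{air})}
#' Densities greater (less) than water give positive (negative) CT numbers.
#'
#' @param mu_object mean linear attenuation coefficient of the voxel
#'   (relative units).
#' @param mu_water attenuation coefficient of pure water.
#' @param mu_air attenuation coefficient of a standardized air sample;
#'   must differ from \code{mu_water}.
#' @return CT number in Hounsfield units (HU). Vectorized over
#'   \code{mu_object}.
#' @examples
#' hounsfield(1.0)          # water -> 0 HU
#' hounsfield(0.0)          # air   -> -1000 HU
#' hounsfield(1.5, 1, 0)    # +500 HU
#' @export
hounsfield <- function(mu_object, mu_water = 1, mu_air = 0) {
  if (!is.finite(mu_water) || !is.finite(mu_air) || mu_water == mu_air)
    stop("HU conversion undefined: mu_water must differ from mu_air")
  if (mu_water < mu_air)
    stop("mu_water must exceed mu_air")
  1000 * (mu_object - mu_water) / (mu_water - mu_air)
}

#' Axial extent of a reconstructed slice stack
#'
#' @param n_slices number of reconstructed slices (>= 1).
#' @param interval reconstruction interval along z, in mm.
#' @return axial extent in mm (\code{n_slices * interval}); 300 slices at
#'   0.4 mm cover 120 mm of pot depth.
#' @examples
#' stackExtent(300, 0.4)  # 120 mm
#' @export
stackExtent <- function(n_slices, interval = 0.4) {
  if (n_slices < 1) stop("n_slices must be >= 1")
  if (interval <= 0) stop("interval must be > 0 mm")
  n_slices * interval
}

#' Window HU values into 8-bit gray levels
#'
#' Maps HU linearly onto 0..255 over \code{window = c(lo, hi)}, rounding to
#' the nearest level and clamping outside the window.
#'
#' @param hu numeric HU values.
#' @param window numeric(2), HU window limits (lo < hi).
#' @return integer gray levels in 0..255.
#' @export
huToGray8 <- function(hu, window = c(-1000, 1500)) {
  if (length(window) != 2L || window[2] <= window[1])
    stop("window must be c(lo, hi) with lo < hi")
  g <- round(255 * (hu - window[1]) / (window[2] - window[1]))
  as.integer(pmin(pmax(g, 0), 255))
}

# ---- MetaImage (.mhd + .raw) ------------------------------------------------

#' Write a VoxelGrid as MetaImage
#'
#' Writes a plain-text \code{.mhd} header plus a little-endian \code{.raw}
#' payload of signed 16-bit integers (the native CT scalar type). Spacing is
#' recorded in mm under \code{ElementSpacing}.
#'
#' @param grid a \linkS4class{VoxelGrid}; values must round-trip through
#'   16-bit integers (HU do).
#' @param path path of the \code{.mhd} header; the \code{.raw} file is
#'   written next to it.
#' @return \code{path}, invisibly.
#' @export
writeMetaImage <- function(grid, path) {
  stopifnot(is(grid, "VoxelGrid"))
  v <- round(grid@values)
  if (any(v < -32768 | v > 32767))
    stop("HU values outside the signed 16-bit range")
  d <- dim(v)
  raw_name <- sub("\\.mhd$", ".raw", basename(path), ignore.case = TRUE)
  if (identical(raw_name, basename(path))) raw_name <- paste0(basename(path), ".raw")
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    paste("DimSize =", paste(d, collapse = " ")),
    paste("ElementSpacing =", paste(format(grid@spacing, trim = TRUE), collapse = " ")),
    "ElementType = MET_SHORT",
    paste("ElementDataFile =", raw_name)
  )
  writeLines(hdr, path)
  con <- file(file.path(dirname(path), raw_name), "wb")
  on.exit(close(con))
  writeBin(as.integer(v), con, size = 2L, endian = "little")
  invisible(path)
}

#' Read a MetaImage volume
#'
#' @param path path to a \code{.mhd} header whose \code{ElementDataFile}
#'   sits in the same directory.
#' @return a \linkS4class{VoxelGrid}.
#' @export
readMetaImage <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*?)\\s*$", lines))
  hdr <- list()
  for (m in kv) if (length(m) == 3L) hdr[[m[2]]] <- m[3]
  need <- c("DimSize", "ElementType", "ElementDataFile")
  for (f in need) if (is.null(hdr[[f]]))
    stop("MetaImage header missing field: ", f)
  if (!identical(hdr$ElementType, "MET_SHORT"))
    stop("unsupported ElementType: ", hdr$ElementType)
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  if (length(dims) != 3L || anyNA(dims) || any(dims < 1L))
    stop("bad DimSize field: ", hdr$DimSize)
  spacing <- c(0.35, 0.35, 0.4)
  if (!is.null(hdr$ElementSpacing))
    spacing <- as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]])
  raw_path <- file.path(dirname(path), hdr$ElementDataFile)
  n <- prod(dims)
  sz <- file.info(raw_path)$size
  if (is.na(sz) || sz < 2 * n)
    stop("payload truncated: DimSize declares ", n, " voxels but ",
         raw_path, " holds ", ifelse(is.na(sz), 0, sz %/% 2))
  con <- file(raw_path, "rb")
  on.exit(close(con))
  v <- readBin(con, "integer", n = n, size = 2L, signed = TRUE,
               endian = "little")
  VoxelGrid(array(as.numeric(v), dims), spacing = spacing)
}

# ---- TIFF slice stacks ------------------------------------------------------

#' Write a VoxelGrid as a TIFF slice stack
#'
#' One 2-D image per z slice, with the slice index as a zero-padded suffix.
#' With \code{bits = 16} the HU values are stored losslessly (offset by
#' 32768); with \code{bits = 8} slices are windowed via \code{\link{huToGray8}}.
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @param dir output directory (created if missing).
#' @param prefix filename prefix before the slice number.
#' @param bits 16 (lossless) or 8 (windowed export).
#' @param window HU window used when \code{bits = 8}.
#' @return character vector of file paths, invisibly.
#' @export
writeTiffStack <- function(grid, dir, prefix = "slice", bits = 16,
                           window = c(-1000, 1500)) {
  stopifnot(is(grid, "VoxelGrid"), bits %in% c(8, 16))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- dim(grid@values)
  v <- round(grid@values)
  if (bits == 16 && any(v < -32768 | v > 32767))
    stop("HU values outside the signed 16-bit range")
  paths <- character(d[3])
  for (k in seq_len(d[3])) {
    slab <- v[, , k, drop = TRUE]
    img <- if (bits == 16) (slab + 32768) / 65535
           else huToGray8(slab, window) / 255
    p <- file.path(dir, sprintf("%s_%04d.tif", prefix, k))
    # tiff images are row-major (row = y); transpose from (i, j) = (x, y)
    tiff::writeTIFF(t(img), p, bits.per.sample = bits)
    paths[k] <- p
  }
  invisible(paths)
}

#' Read a TIFF slice stack into a VoxelGrid
#'
#' Slices are ordered by their zero-padded numeric suffix. Only stacks
#' written by \code{\link{writeTiffStack}} with \code{bits = 16} restore HU
#' exactly; 8-bit stacks come back as gray levels 0..255.
#'
#' @param dir directory holding the slices.
#' @param prefix filename prefix used at write time.
#' @param spacing voxel spacing of the reassembled grid, mm.
#' @param bits bit depth the stack was written with.
#' @return a \linkS4class{VoxelGrid}.
#' @export
readTiffStack <- function(dir, prefix = "slice", spacing = c(0.35, 0.35, 0.4),
                          bits = 16) {
  files <- sort(list.files(dir, pattern = paste0("^", prefix, "_\\d+\\.tif$"),
                           full.names = TRUE))
  if (!length(files)) stop("no ", prefix, "_NNNN.tif slices found in ", dir)
  slabs <- lapply(files, function(p) t(tiff::readTIFF(p)))
  d2 <- dim(slabs[[1]])
  if (!all(vapply(slabs, function(s) identical(dim(s), d2), logical(1))))
    stop("slice dimensions differ across the stack")
  arr <- array(0, c(d2, length(slabs)))
  for (k in seq_along(slabs)) {
    arr[, , k] <- if (bits == 16) round(slabs[[k]] * 65535) - 32768
                  else round(slabs[[k]] * 255)
  }
  VoxelGrid(arr, spacing = spacing)
}
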