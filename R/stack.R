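#' Voxel stacks
#'
#' A `VoxelStack` is a 4D array of nonnegative intensities indexed
#' (channel, z, y, x) with physical voxel sizes in um per axis and an
#' acquisition time in minutes.
#'
#' @param values 4D numeric array `(channel, z, y, x)`, finite,
#'   nonnegative.
#' @param voxel_size_um Numeric length-3 vector `(z, y, x)` in um, all
#'   positive.
#' @param time_min Acquisition time (minutes), optional.
#' @return A `VoxelStack`.
#' @export
voxel_stack <- function(values, voxel_size_um, time_min = NA_real_) {
  if (length(dim(values)) != 4) {
    stop("values must be a 4D (channel, z, y, x) array", call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("intensities must be finite and nonnegative", call. = FALSE)
  }
  voxel_size_um <- as.numeric(voxel_size_um)
  if (length(voxel_size_um) != 3 || any(voxel_size_um <= 0)) {
    stop("voxel_size_um must be 3 positive numbers (z, y, x)",
         call. = FALSE)
  }
  structure(list(values = values, voxel_size_um = voxel_size_um,
                 time_min = time_min),
            class = "VoxelStack")
}

#' @export
print.VoxelStack <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "VoxelStack: %d channel(s), %d x %d x %d (z,y,x), voxel %s um\n",
    d[1], d[2], d[3], d[4], paste(x$voxel_size_um, collapse = " x ")))
  invisible(x)
}

## --- Minimal baseline TIFF codec ------------------------------------------
## No TIFF-capable R package is available in the target environment, so the
## package carries a minimal codec for the one dialect it writes: little-
## endian, uncompressed, one 32-bit-float grayscale IFD per (channel, z)
## plane, plane order channel-major, with a JSON ImageDescription on the
## first IFD holding the axis sizes and voxel dimensions.

.tiff_tag <- function(id, type, count, value_or_offset) {
  c(id = id, type = type, count = count, value = value_or_offset)
}

#' Write a voxel stack as a multi-page TIFF
#'
#' @param stack A [voxel_stack()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "VoxelStack"))
  d <- dim(stack$values)   # (c, z, y, x)
  nc <- d[1]; nz <- d[2]; h <- d[3]; w <- d[4]
  desc <- jsonlite::toJSON(list(channels = nc, nz = nz,
                                voxel_size_um = stack$voxel_size_um,
                                time_min = stack$time_min),
                           auto_unbox = TRUE, digits = NA)
  desc_raw <- c(charToRaw(as.character(desc)), as.raw(0))
  if (length(desc_raw) %% 2 == 1) desc_raw <- c(desc_raw, as.raw(0))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("II"), as.raw(c(42, 0))), con)   # header
  # layout: header(4) + ifd_offset(4) + description + all plane data,
  # then the IFD chain at the end
  n_planes <- nc * nz
  plane_bytes <- w * h * 4L
  desc_off <- 8L
  data_off <- desc_off + length(desc_raw)
  ifd0_off <- data_off + n_planes * plane_bytes
  writeBin(as.integer(ifd0_off), con, size = 4, endian = "little")
  writeBin(desc_raw, con)
  for (ci in seq_len(nc)) {
    for (zi in seq_len(nz)) {
      plane <- stack$values[ci, zi, , ]           # (y, x) matrix
      if (is.null(dim(plane))) plane <- matrix(plane, nrow = h, ncol = w)
      # scanline order: x fastest within each y row; coerce to double so
      # writeBin emits IEEE float32 regardless of the array's storage mode
      writeBin(as.numeric(t(plane)), con, size = 4, endian = "little")
    }
  }
  # IFDs
  for (p in seq_len(n_planes)) {
    ifd_off <- ifd0_off + (p - 1L) * (2L + 12L * 9L + 4L)
    entries <- list(
      .tiff_tag(256L, 4L, 1L, w),                        # ImageWidth
      .tiff_tag(257L, 4L, 1L, h),                        # ImageLength
      .tiff_tag(258L, 3L, 1L, 32L),                      # BitsPerSample
      .tiff_tag(259L, 3L, 1L, 1L),                       # Compression none
      .tiff_tag(262L, 3L, 1L, 1L),                       # BlackIsZero
      .tiff_tag(270L, 2L, length(desc_raw), desc_off),   # ImageDescription
      .tiff_tag(273L, 4L, 1L, data_off + (p - 1L) * plane_bytes),
      .tiff_tag(279L, 4L, 1L, plane_bytes),              # StripByteCounts
      .tiff_tag(339L, 3L, 1L, 3L)                        # SampleFormat ieee
    )
    writeBin(length(entries), con, size = 2, endian = "little")
    for (e in entries) {
      writeBin(as.integer(e[["id"]]), con, size = 2, endian = "little")
      writeBin(as.integer(e[["type"]]), con, size = 2, endian = "little")
      writeBin(as.integer(e[["count"]]), con, size = 4, endian = "little")
      writeBin(as.integer(e[["value"]]), con, size = 4, endian = "little")
    }
    next_off <- if (p < n_planes) ifd_off + 2L + 12L * 9L + 4L else 0L
    writeBin(as.integer(next_off), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a voxel stack from a TIFF written by [write_stack()]
#'
#' Reads the little-endian uncompressed 32-bit float dialect this package
#' writes. Voxel sizes come from the embedded JSON description or from
#' `voxel_size_um`.
#'
#' @param path TIFF path.
#' @param voxel_size_um Optional override / fallback when the file carries
#'   no voxel-size metadata.
#' @return A [voxel_stack()].
#' @export
read_stack <- function(path, voxel_size_um = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readBin(path, "raw", file.size(path))
  u16 <- function(off) sum(as.integer(raw[off + 1:2]) * c(1, 256))
  u32 <- function(off) sum(as.integer(raw[off + 1:4]) * 256^(0:3))
  if (rawToChar(raw[1:2]) != "II" || u16(2) != 42L) {
    stop("not a little-endian TIFF file: ", path, call. = FALSE)
  }
  ifd_off <- u32(4)
  planes <- list(); desc <- NULL; w <- NULL; h <- NULL
  while (ifd_off != 0) {
    n <- u16(ifd_off)
    tags <- list()
    for (i in seq_len(n)) {
      base <- ifd_off + 2 + (i - 1) * 12
      tags[[as.character(u16(base))]] <-
        list(type = u16(base + 2), count = u32(base + 4),
             value = u32(base + 8))
    }
    w <- tags[["256"]]$value; h <- tags[["257"]]$value
    if (tags[["259"]]$value != 1L || tags[["258"]]$value != 32L ||
        tags[["339"]]$value != 3L) {
      stop("unsupported TIFF dialect (expect uncompressed float32)",
           call. = FALSE)
    }
    if (!is.null(tags[["270"]]) && is.null(desc)) {
      doff <- tags[["270"]]$value; dcount <- tags[["270"]]$count
      dr <- raw[(doff + 1):(doff + dcount)]
      dr <- dr[dr != as.raw(0)]
      desc <- tryCatch(jsonlite::fromJSON(rawToChar(dr)),
                       error = function(e) NULL)
    }
    soff <- tags[["273"]]$value
    nb <- tags[["279"]]$value
    vals <- readBin(raw[(soff + 1):(soff + nb)], "numeric", n = nb / 4,
                    size = 4, endian = "little")
    planes[[length(planes) + 1]] <- matrix(vals, nrow = w, ncol = h)
    ifd_off <- u32(ifd_off + 2 + n * 12)
  }
  if (is.null(desc)) {
    if (is.null(voxel_size_um)) {
      stop(paste("no voxel-size metadata in", path,
                 "- supply voxel_size_um in the config"), call. = FALSE)
    }
    nc <- 1L; nz <- length(planes)
    vs <- voxel_size_um; tmin <- NA_real_
  } else {
    nc <- desc$channels; nz <- desc$nz
    vs <- if (!is.null(voxel_size_um)) voxel_size_um else desc$voxel_size_um
    tmin <- if (is.null(desc$time_min)) NA_real_ else desc$time_min
  }
  arr <- array(0, dim = c(nc, nz, ncol(planes[[1]]), nrow(planes[[1]])))
  p <- 1L
  for (ci in seq_len(nc)) {
    for (zi in seq_len(nz)) {
      arr[ci, zi, , ] <- t(planes[[p]])
      p <- p + 1L
    }
  }
  voxel_stack(arr, vs, tmin)
}
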