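#' Read an MRC2014 volume
#'
#' Reads mode-0 (int8), mode-1 (int16), mode-2 (float32) and mode-6
#' (uint16) MRC maps; the voxel size is derived from the cell dimensions
#' and the grid sampling, and the MRC2014 origin record is honoured.
#'
#' @param path path to an MRC file.
#' @return a [new_volume()] `Volume`.
#' @export
read_mrc <- function(path) {
  if (!file.exists(path)) stop("read_mrc: file does not exist: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 1024)
  if (length(hdr_raw) < 1024)
    stop("read_mrc: malformed header: file shorter than the 1024-byte header")
  int_at <- function(i) readBin(hdr_raw[(4 * (i - 1) + 1):(4 * i)], "integer",
                                size = 4, endian = "little")
  flt_at <- function(i) readBin(hdr_raw[(4 * (i - 1) + 1):(4 * i)], "double",
                                size = 4, endian = "little")
  nx <- int_at(1); ny <- int_at(2); nz <- int_at(3)
  mode <- int_at(4)
  if (any(c(nx, ny, nz) < 1) || any(c(nx, ny, nz) > 1e5))
    stop("read_mrc: malformed header: implausible grid dimensions (NX/NY/NZ)")
  mx <- int_at(8); my <- int_at(9); mz <- int_at(10)
  cella <- c(flt_at(11), flt_at(12), flt_at(13))
  nsymbt <- int_at(24)
  origin <- c(flt_at(50), flt_at(51), flt_at(52))
  n <- as.numeric(nx) * ny * nz
  if (nsymbt < 0 || nsymbt > 1e7)
    stop("read_mrc: malformed header: implausible NSYMBT")
  if (nsymbt > 0) readBin(con, "raw", n = nsymbt)
  data <- switch(as.character(mode),
    "0" = readBin(con, "integer", n = n, size = 1, signed = TRUE,
                  endian = "little"),
    "1" = readBin(con, "integer", n = n, size = 2, signed = TRUE,
                  endian = "little"),
    "2" = readBin(con, "double", n = n, size = 4, endian = "little"),
    "6" = readBin(con, "integer", n = n, size = 2, signed = FALSE,
                  endian = "little"),
    stop("read_mrc: malformed header: unsupported MODE ", mode))
  if (length(data) < n)
    stop("read_mrc: truncated file: expected ", n, " voxels, got ",
         length(data))
  voxel <- if (mx > 0 && cella[1] > 0) cella[1] / mx else 1
  new_volume(array(as.numeric(data), c(nx, ny, nz)), voxel, origin)
}

#' Write a volume as MRC2014 (mode 2, float32, little endian)
#'
#' @param volume a `Volume`.
#' @param path output path; the parent directory must exist.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(volume, path) {
  stopifnot(inherits(volume, "Volume"))
  if (!dir.exists(dirname(path)))
    stop("write_mrc: parent directory does not exist: ", dirname(path))
  d <- vol_dim(volume)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                                   # NX NY NZ
  wi(2)                                   # MODE 2: float32
  wi(c(0, 0, 0))                          # NXSTART..
  wi(d)                                   # MX MY MZ
  wf(d * volume$voxel_size)               # CELLA
  wf(c(90, 90, 90))                       # CELLB
  wi(c(1, 2, 3))                          # MAPC MAPR MAPS
  wf(c(min(volume$data), max(volume$data), mean(volume$data)))
  wi(1)                                   # ISPG
  wi(0)                                   # NSYMBT
  wi(rep(0, 25))                          # EXTRA (words 26..49, incl EXTTYP)
  wf(volume$origin)                       # ORIGIN (MRC2014)
  writeBin(charToRaw("MAP "), con)        # MAP
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST little endian
  wf(sd(as.numeric(volume$data)))         # RMS
  wi(0)                                   # NLABL
  writeBin(raw(800), con)                 # labels
  wf(as.numeric(volume$data))
  invisible(path)
}
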