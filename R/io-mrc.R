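# MRC2014 I/O on binary connections. Mode 2 (float32) only, little endian,
# which is what every modern cryo-EM tool writes. Maps are volumes
# (ispg = 1); image stacks are written with ispg = 0 and nz = n_images.

mrc_header_template <- function(nx, ny, nz, voxel_size_A, is_stack = FALSE,
                                dmin = 0, dmax = 0, dmean = 0, rms = 0) {
  list(nx = nx, ny = ny, nz = nz, mode = 2L,
       nxstart = 0L, nystart = 0L, nzstart = 0L,
       mx = nx, my = ny, mz = if (is_stack) 1L else nz,
       cella = c(nx, ny, if (is_stack) 1L else nz) * voxel_size_A,
       cellb = c(90, 90, 90),
       mapc = 1L, mapr = 2L, maps = 3L,
       dmin = dmin, dmax = dmax, dmean = dmean,
       ispg = if (is_stack) 0L else 1L, nsymbt = 0L,
       origin = c(0, 0, 0), rms = rms)
}

write_mrc_raw <- function(values, voxel_size_A, path, is_stack = FALSE) {
  d <- dim(values)
  h <- mrc_header_template(d[1], d[2], d[3], voxel_size_A, is_stack,
                           dmin = min(values), dmax = max(values),
                           dmean = mean(values), rms = sd(as.vector(values)))
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(c(h$nx, h$ny, h$nz, h$mode, h$nxstart, h$nystart, h$nzstart,
       h$mx, h$my, h$mz))
  wf(c(h$cella, h$cellb))
  wi(c(h$mapc, h$mapr, h$maps))
  wf(c(h$dmin, h$dmax, h$dmean))
  wi(c(h$ispg, h$nsymbt))
  wi(rep(0L, 25))                       # extra (incl. exttyp/nversion slots)
  wf(h$origin)
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.integer(c(0x44, 0x44, 0x00, 0x00)), con, size = 1) # little endian
  wf(h$rms)
  wi(0L)                                # nlabl
  writeBin(raw(800), con)               # labels
  wf(as.vector(values))
  invisible(path)
}

read_mrc_raw <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 1024) abort(sprintf("not an MRC file (too short): %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(k) readBin(con, "integer", k, size = 4, endian = "little")
  rf <- function(k) readBin(con, "numeric", k, size = 4, endian = "little")
  dims <- ri(3)
  mode <- ri(1)
  if (any(dims <= 0) || any(dims > 1e5))
    abort(sprintf("malformed MRC header in %s (dims %s)", path,
                  paste(dims, collapse = "x")))
  if (mode != 2)
    abort(sprintf("unsupported MRC mode %d in %s (only mode 2/float32)",
                  mode, path))
  ri(3)                                  # nstart
  m <- ri(3)                             # mx my mz
  cella <- rf(3)
  rf(3)                                  # cellb
  ri(3)                                  # mapc/mapr/maps
  rf(3)                                  # dmin dmax dmean
  ispg <- ri(1)
  nsymbt <- ri(1)
  ri(25)
  origin <- rf(3)
  readChar(con, 4, useBytes = TRUE)      # "MAP "
  readBin(con, "raw", 4)                 # machst
  rf(1)                                  # rms
  ri(1)                                  # nlabl
  readBin(con, "raw", 800)
  if (nsymbt > 0) readBin(con, "raw", nsymbt)
  nvox <- prod(dims)
  expected <- 1024 + nsymbt + 4 * nvox
  if (sz < expected)
    abort(sprintf("truncated MRC file %s: %d bytes, expected %d",
                  path, sz, expected))
  vals <- readBin(con, "numeric", nvox, size = 4, endian = "little")
  voxel <- cella[1] / m[1]
  list(values = array(vals, dims), voxel_size_A = voxel, ispg = ispg,
       origin = origin)
}

#' Write a density map to an MRC2014 file
#'
#' @param map A `density_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "density_map"))
  write_mrc_raw(map$values, map$voxel_size_A, path, is_stack = FALSE)
}

#' Read a density map from an MRC2014 file
#'
#' Mode 2 (float32) maps only; voxel size is recovered from the cell
#' dimensions. Malformed or truncated files raise a parse error naming the
#' file.
#'
#' @param path MRC file path.
#' @return A `density_map`.
#' @export
read_map <- function(path) {
  r <- read_mrc_raw(path)
  d <- dim(r$values)
  if (length(unique(d)) != 1)
    abort(sprintf("%s is not a cubic volume (%s)", path,
                  paste(d, collapse = "x")))
  density_map(r$values, r$voxel_size_A, meta = list(path = path))
}

#' Write a 2D image stack to an MRC file
#'
#' @param images n x n x k array.
#' @param voxel_size_A Pixel size, Angstroms.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(images, voxel_size_A, path) {
  write_mrc_raw(images, voxel_size_A, path, is_stack = TRUE)
}

#' Read a 2D image stack from an MRC file
#'
#' @param path MRC file path.
#' @return A list with `images` (n x n x k array) and `voxel_size_A`.
#' @export
read_stack <- function(path) {
  r <- read_mrc_raw(path)
  list(images = r$values, voxel_size_A = r$voxel_size_A)
}
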