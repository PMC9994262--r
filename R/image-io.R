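# Image IO: MRC2014 mode 2 (float32) for interchange with EM software, and
# plain TSV matrices for text-only pipelines. The in-memory convention is
# rows = helix axis; MRC stores columns fastest, so the matrix is written
# with nx = ncol, ny = nrow.

#' Write a projection image as MRC (mode 2, float32)
#'
#' @param image A [projection_image()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(image, path) {
  stopifnot(inherits(image, "projection_image"))
  d <- image$data
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wi(c(ncol(d), nrow(d), 1L))            # nx, ny, nz
  wi(2L)                                 # mode 2: float32
  wi(c(0L, 0L, 0L))                      # nxstart..nzstart
  wi(c(ncol(d), nrow(d), 1L))            # mx, my, mz
  wf(c(ncol(d), nrow(d), 1) * image$pixel)  # cell dimensions (A)
  wf(c(90, 90, 90))                      # cell angles
  wi(c(1L, 2L, 3L))                      # mapc, mapr, maps
  wf(c(min(d), max(d), mean(d)))         # dmin, dmax, dmean
  wi(c(0L, 0L))                          # ispg, nsymbt
  wi(rep(0L, 25L))                       # extra
  wf(c(0, 0, 0))                         # origin
  writeChar("MAP ", con, nchars = 4L, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(as.numeric(d)))           # rms
  wi(0L)                                 # nlabl
  writeBin(raw(800L), con)               # labels
  wf(as.numeric(t(d)))                   # row-major: x fastest
  invisible(path)
}

#' Read an MRC image (mode 2, single section)
#'
#' @param path MRC file path.
#' @return A [projection_image()].
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4L, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4L, endian = "little")
  dims <- ri(3)
  mode <- ri(1)
  if (mode != 2L) stop("only MRC mode 2 (float32) supported", call. = FALSE)
  ri(3)                                  # nxstart..nzstart
  m <- ri(3)                             # mx my mz
  cell <- rf(3)
  pixel <- if (m[1] > 0 && cell[1] > 0) cell[1] / m[1] else 1
  seek(con, 1024L)
  vals <- rf(dims[1] * dims[2] * max(dims[3], 1L))
  d <- matrix(vals[seq_len(dims[1] * dims[2])], nrow = dims[2],
              ncol = dims[1], byrow = TRUE)
  projection_image(d, pixel)
}

#' Write a projection image as a TSV matrix
#'
#' First line is a comment header carrying the pixel size; the rest is the
#' tab-separated density matrix.
#'
#' @inheritParams write_mrc
#' @return `path`, invisibly.
#' @export
write_image_tsv <- function(image, path) {
  stopifnot(inherits(image, "projection_image"))
  writeLines(sprintf("# gvshell projection_image pixel=%.10g blur=%.10g",
                     image$pixel, image$blur), path)
  utils::write.table(image$data, path, append = TRUE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a TSV projection image written by [write_image_tsv()]
#'
#' @param path File path.
#' @return A [projection_image()].
#' @export
read_image_tsv <- function(path) {
  hdr <- readLines(path, n = 1L)
  pixel <- as.numeric(sub(" .*", "", sub(".*pixel=", "", hdr)))
  blur <- suppressWarnings(as.numeric(sub(".*blur=", "", hdr)))
  if (!is.finite(pixel)) stop("missing pixel size header", call. = FALSE)
  if (!is.finite(blur)) blur <- 0
  d <- as.matrix(utils::read.table(path, sep = "\t", skip = 1L))
  dimnames(d) <- NULL
  projection_image(d, pixel, blur = blur)
}
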