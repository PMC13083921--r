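## Minimal multi-page 32-bit float TIFF codec.
##
## Radiometric maps (radians, signed Stokes components) need the full float
## range; the TIFF packages on CRAN/Bioconductor clamp float samples to
## [0, 1], so the small subset of baseline TIFF 6.0 needed here is
## implemented directly: uncompressed, single-sample, 32-bit IEEE float
## (SampleFormat = 3), strip-organised, little- or big-endian on read,
## little-endian on write. Writes are atomic (temp file + rename).

TIFF_TAGS <- c(ImageWidth = 256L, ImageLength = 257L, BitsPerSample = 258L,
               Compression = 259L, Photometric = 262L, ImageDescription = 270L,
               StripOffsets = 273L, SamplesPerPixel = 277L,
               RowsPerStrip = 278L, StripByteCounts = 279L,
               SampleFormat = 339L)

#' Write matrices as a multi-page 32-bit float TIFF
#'
#' Stores each matrix as one uncompressed 32-bit IEEE-float page
#' (SampleFormat 3), preserving the full numeric range and sign losslessly
#' (within float32 precision). An optional description string is attached to
#' the first page; the write is atomic.
#'
#' @param pages a numeric matrix or list of matrices (pages).
#' @param path output file path.
#' @param description optional ASCII metadata string for page 1.
#' @return Invisibly, `path`.
#' @seealso [read_float_tiff()]
#' @export
write_float_tiff <- function(pages, path, description = NULL) {
  if (is.matrix(pages)) pages <- list(pages)
  stopifnot(length(pages) >= 1, all(vapply(pages, is.matrix, logical(1))))
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  con <- file(tmp, "wb")
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  entry <- function(tag, type, count, value) {
    w2(tag); w2(type); w4(count)
    if (type == 3L && count == 1L) { w2(value); w2(0L) } else w4(value)
  }
  writeChar("II", con, eos = NULL); w2(42L)
  ## layout: header(8) | page data blocks | IFDs (+ description after IFD 1)
  npg <- length(pages)
  sizes <- vapply(pages, function(p) 4L * length(p), integer(1))
  data_off <- 8L + cumsum(c(0L, sizes[-npg]))
  ifd0 <- 8L + sum(sizes)
  desc <- NULL
  if (!is.null(description)) {
    desc <- c(charToRaw(as.character(description)), as.raw(0L))
    if (length(desc) %% 2L == 1L) desc <- c(desc, as.raw(0L))
  }
  n_entries <- function(i) if (i == 1L && !is.null(desc)) 11L else 10L
  ifd_size <- function(i) 2L + 12L * n_entries(i) + 4L
  ifd_off <- integer(npg)
  off <- ifd0
  for (i in seq_len(npg)) {
    ifd_off[i] <- off
    off <- off + ifd_size(i) + if (i == 1L && !is.null(desc)) length(desc) else 0L
  }
  w4(ifd0)
  for (p in pages)
    writeBin(as.numeric(t(p)), con, size = 4, endian = "little")
  for (i in seq_len(npg)) {
    p <- pages[[i]]
    h <- nrow(p); w <- ncol(p)
    w2(n_entries(i))
    entry(256L, 4L, 1L, w)
    entry(257L, 4L, 1L, h)
    entry(258L, 3L, 1L, 32L)
    entry(259L, 3L, 1L, 1L)
    entry(262L, 3L, 1L, 1L)
    if (i == 1L && !is.null(desc))
      entry(270L, 2L, length(desc), ifd_off[i] + ifd_size(i))
    entry(273L, 4L, 1L, data_off[i])
    entry(277L, 3L, 1L, 1L)
    entry(278L, 4L, 1L, h)
    entry(279L, 4L, 1L, sizes[i])
    entry(339L, 3L, 1L, 3L)
    w4(if (i < npg) ifd_off[i + 1L] else 0L)
    if (i == 1L && !is.null(desc)) writeBin(desc, con)
  }
  close(con)
  if (!file.rename(tmp, path)) stop("could not move temporary file to ", path)
  invisible(path)
}

#' Read a multi-page 32-bit float TIFF
#'
#' Reads uncompressed single-sample 32-bit float TIFF files (either byte
#' order), as written by [write_float_tiff()] or by standard scientific TIFF
#' writers. Files with other sample formats, bit depths or compression raise
#' an explicit format error.
#'
#' @param path file path.
#' @return A list of numeric matrices (one per page); attribute
#'   `description` carries the first ImageDescription found, if any.
#' @export
read_float_tiff <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 8) stop("not a TIFF file: ", path)
  bo <- rawToChar(raw[1:2])
  endian <- if (bo == "II") "little" else if (bo == "MM") "big" else
    stop("not a TIFF file (bad byte-order mark): ", path)
  rd <- function(off, n, size, what = "integer") {
    readBin(raw[(off + 1):(off + n * size)], what, n = n, size = size,
            endian = endian, signed = size > 2)
  }
  if (rd(2, 1, 2) != 42L) stop("not a TIFF file (bad magic): ", path)
  ifd <- rd(4, 1, 4)
  pages <- list()
  description <- NULL
  type_size <- c(1L, 1L, 2L, 4L, 8L)
  while (ifd != 0) {
    n <- rd(ifd, 1, 2)
    tags <- list()
    for (k in seq_len(n)) {
      e <- ifd + 2 + 12 * (k - 1)
      tag <- rd(e, 1, 2); type <- rd(e + 2, 1, 2); count <- rd(e + 4, 1, 4)
      sz <- if (type >= 1 && type <= 5) type_size[type] else 1L
      voff <- if (sz * count <= 4) e + 8 else rd(e + 8, 1, 4)
      val <- if (type == 2L) {
        bytes <- raw[(voff + 1):(voff + count)]
        rawToChar(bytes[bytes != as.raw(0)])
      } else if (type == 3L) rd(voff, count, 2)
      else if (type %in% c(4L, 5L)) rd(voff, count, 4)
      else if (type == 1L) as.integer(raw[(voff + 1):(voff + count)])
      else NULL
      tags[[as.character(tag)]] <- val
    }
    g <- function(code, default = NULL) tags[[as.character(code)]] %||% default
    w <- g(256); h <- g(257)
    if (is.null(w) || is.null(h)) stop("malformed TIFF: missing dimensions")
    if (any(g(259, 1L) != 1L))
      stop("unsupported TIFF: compressed data (expected uncompressed float)")
    if (g(277, 1L) != 1L)
      stop("unsupported TIFF: multi-sample pixels (expected one float sample)")
    if (any(g(258, 1L) != 32L) || any(g(339, 1L) != 3L))
      stop("non-float TIFF data: expected 32-bit IEEE float samples (SampleFormat 3, 32 bits)")
    offs <- g(273); cnts <- g(279)
    if (is.null(offs) || is.null(cnts)) stop("malformed TIFF: missing strips")
    vals <- unlist(lapply(seq_along(offs), function(i)
      rd(offs[i], cnts[i] / 4, 4, "numeric")))
    if (length(vals) != w * h) stop("malformed TIFF: strip size mismatch")
    pages[[length(pages) + 1L]] <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
    if (is.null(description) && !is.null(g(270))) description <- g(270)
    ifd <- rd(ifd + 2 + 12 * n, 1, 4)
  }
  attr(pages, "description") <- description
  pages
}
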