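# 16-bit grayscale PNG writing for instance label maps.
#
# The png package reads 16-bit PNGs but only writes 8-bit, which would
# truncate label maps with > 255 instances and break lossless round-trips.
# A minimal encoder is implemented here: one IHDR / IDAT / IEND chunk each,
# bit depth 16, colour type 0, filter type 0 on every scanline, zlib stream
# via memCompress().

crc32_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      t <- integer(256)
      for (n in 0:255) {
        c <- n
        for (k in 1:8) {
          c <- if (bitwAnd(c, 1L) != 0L)
            bitwXor(-306674912L, bitwShiftR(bitwAnd(c, -2L), 1)) # 0xEDB88320
          else bitwShiftR(bitwAnd(c, -2L), 1)
        }
        t[n + 1L] <- c
      }
      tab <<- t
    }
    tab
  }
})

crc32 <- function(bytes) {
  tab <- crc32_table()
  crc <- -1L # 0xFFFFFFFF
  b <- as.integer(bytes)
  for (i in seq_along(b)) {
    idx <- bitwAnd(bitwXor(crc, b[i]), 255L)
    crc <- bitwXor(tab[idx + 1L], bitwShiftR(bitwAnd(crc, -256L), 8))
  }
  bitwXor(crc, -1L)
}

int_be <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "big")

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(int_be(length(data)), body, int_be(crc32(body)))
}

#' Write an instance label map as a 16-bit grayscale PNG
#'
#' Values must be integers in `[0, 65535]`; 0 is background. The written
#' file round-trips exactly through [read_label_png()].
#'
#' @param labels integer matrix (H x W).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_label_png <- function(labels, path) {
  stopifnot(is.matrix(labels))
  v <- as.integer(labels)
  if (anyNA(v) || any(v < 0L) || any(v > 65535L))
    stop("labels must be integers in [0, 65535]")
  h <- nrow(labels); w <- ncol(labels)
  # row-major scanlines, big-endian 16-bit samples, filter byte 0 per row
  m <- t(labels)
  hi <- as.raw(m %/% 256L)
  lo <- as.raw(m %% 256L)
  samples <- as.raw(rbind(hi, lo))          # interleave hi/lo per sample
  dim(samples) <- c(2L * w, h)
  scan <- rbind(as.raw(0L), samples)        # prepend filter byte to each row
  idat <- memCompress(as.raw(scan), type = "gzip")   # zlib (RFC 1950) stream
  ihdr <- c(int_be(w), int_be(h), as.raw(c(16L, 0L, 0L, 0L, 0L)))
  out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", idat),
           png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}

#' Read an instance label map written by [write_label_png()]
#'
#' @param path PNG file path.
#' @return integer matrix (H x W).
#' @export
read_label_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1L]
  matrix(as.integer(round(x * 65535)), nrow(x), ncol(x))
}

#' Write an 8-bit RGB image PNG
#'
#' @param image H x W x 3 array with values in `[0, 255]`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(image, path) {
  image <- check_rgb(image)
  png::writePNG(clamp(image, 0, 255) / 255, path)
  invisible(path)
}

#' Read an RGB image (PNG/BMP/TIFF) as an H x W x 3 array in `[0, 255]`
#'
#' @param path image file path.
#' @return numeric H x W x 3 array.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    x <- png::readPNG(path)
  } else {
    img <- EBImage::readImage(path)
    x <- aperm(as.array(img), c(2L, 1L, 3L)[seq_len(length(dim(img)))])
  }
  if (length(dim(x)) == 2L) x <- array(rep(x, 3L), c(dim(x), 3L))
  if (dim(x)[3] == 4L) x <- x[, , 1:3]
  x * 255
}
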