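# Minimal baseline TIFF codec: uncompressed little-endian grayscale pages,
# 32-bit float samples, one strip per page. Enough to exchange calibrated
# multi-channel stacks with standard readers; pixel size is stored both in
# the resolution tags (unit = cm) and in a JSON ImageDescription.

tiff_types <- c(ASCII = 2L, SHORT = 3L, LONG = 4L, RATIONAL = 5L)

#' Write a nucleus image as a multi-page TIFF
#'
#' Pages are ordered channel-major (all z-planes of channel 1, then channel
#' 2, ...). Samples are IEEE 32-bit floats; pixel size is recorded in the
#' resolution tags and, with the channel roles, in a JSON ImageDescription.
#'
#' @param image A [nucleus_image()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(image, path) {
  stopifnot(inherits(image, "nucleus_image"))
  pages <- list()
  nz <- 1L
  for (ch in names(image$channels)) {
    a <- image$channels[[ch]]
    if (length(dim(a)) == 3L) {
      nz <- dim(a)[3L]
      for (k in seq_len(nz)) pages[[length(pages) + 1L]] <- a[, , k]
    } else pages[[length(pages) + 1L]] <- as.matrix(a)
  }
  h <- nrow(pages[[1L]]); w <- ncol(pages[[1L]])
  desc <- jsonlite::toJSON(list(pixel_size_um = image$pixel_size,
                                channels = names(image$channels), nz = nz),
                           auto_unbox = TRUE)
  desc_raw <- c(charToRaw(as.character(desc)), as.raw(0L))
  if (length(desc_raw) %% 2L) desc_raw <- c(desc_raw, as.raw(0L))
  page_bytes <- 4L * h * w
  data_off <- 8L
  desc_off <- data_off + length(pages) * page_bytes
  res_off <- desc_off + length(desc_raw)
  ifd0_off <- res_off + 8L
  n_tags <- c(14L, rep(13L, max(0L, length(pages) - 1L)))
  ifd_size <- 2L + 12L * n_tags + 4L
  ifd_off <- ifd0_off + cumsum(c(0L, head(ifd_size, -1L)))

  con <- file(path, "wb")
  on.exit(close(con))
  wbi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                    endian = "little")
  writeBin(charToRaw("II"), con)
  wbi(42L, 2L)
  wbi(ifd0_off, 4L)
  for (p in pages)
    writeBin(as.numeric(t(p)), con, size = 4L, endian = "little")
  writeBin(desc_raw, con)
  xres <- round(1e4 / image$pixel_size * 1000)
  wbi(c(xres, 1000L), 4L)
  entry <- function(tag, type, count, value) {
    wbi(tag, 2L); wbi(tiff_types[[type]], 2L); wbi(count, 4L)
    if (type == "SHORT" && count == 1L) { wbi(value, 2L); wbi(0L, 2L) }
    else wbi(value, 4L)
  }
  for (i in seq_along(pages)) {
    wbi(n_tags[i], 2L)
    entry(256L, "LONG", 1L, w)
    entry(257L, "LONG", 1L, h)
    entry(258L, "SHORT", 1L, 32L)
    entry(259L, "SHORT", 1L, 1L)
    entry(262L, "SHORT", 1L, 1L)
    if (i == 1L) entry(270L, "ASCII", length(desc_raw), desc_off)
    entry(273L, "LONG", 1L, data_off + (i - 1L) * page_bytes)
    entry(277L, "SHORT", 1L, 1L)
    entry(278L, "LONG", 1L, h)
    entry(279L, "LONG", 1L, page_bytes)
    entry(282L, "RATIONAL", 1L, res_off)
    entry(283L, "RATIONAL", 1L, res_off)
    entry(296L, "SHORT", 1L, 3L)
    entry(339L, "SHORT", 1L, 3L)
    wbi(if (i < length(pages)) ifd_off[i + 1L] else 0L, 4L)
  }
  invisible(path)
}

#' Read a TIFF written by [write_tiff()] (or a compatible grayscale file)
#'
#' Supports uncompressed little-endian grayscale pages with 8/16-bit
#' unsigned integer or 32-bit float samples. Channel roles and pixel size
#' are recovered from the JSON ImageDescription when present, else from the
#' resolution tags (`pixel_size` argument overrides both).
#'
#' @param path TIFF file path.
#' @param pixel_size Optional pixel-size override in micrometres.
#' @return A [nucleus_image()].
#' @export
read_tiff <- function(path, pixel_size = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readBin(path, "raw", file.size(path))
  rd <- function(off, what, n, size, signed = TRUE)
    readBin(raw[(off + 1L):length(raw)], what, n = n, size = size,
            endian = "little", signed = signed)
  if (rawToChar(raw[1:2]) != "II")
    stop("only little-endian TIFF supported", call. = FALSE)
  ifd_off <- rd(4L, "integer", 1L, 4L)
  pages <- list()
  desc <- NULL
  xres <- NULL
  while (ifd_off != 0L) {
    n_tags <- rd(ifd_off, "integer", 1L, 2L, signed = FALSE)
    tags <- list()
    for (i in seq_len(n_tags)) {
      e <- ifd_off + 2L + (i - 1L) * 12L
      tag <- rd(e, "integer", 1L, 2L, signed = FALSE)
      type <- rd(e + 2L, "integer", 1L, 2L, signed = FALSE)
      count <- rd(e + 4L, "integer", 1L, 4L)
      val <- if (type == 3L) rd(e + 8L, "integer", 1L, 2L, signed = FALSE)
             else rd(e + 8L, "integer", 1L, 4L)
      tags[[as.character(tag)]] <- list(type = type, count = count, val = val)
    }
    gv <- function(tag, default = NULL) {
      t <- tags[[as.character(tag)]]
      if (is.null(t)) default else t$val
    }
    w <- gv(256L); h <- gv(257L)
    bits <- gv(258L, 8L)
    if (gv(259L, 1L) != 1L) stop("compressed TIFF not supported", call. = FALSE)
    fmt <- gv(339L, 1L)
    off <- gv(273L)
    if (is.null(desc) && !is.null(tags[["270"]])) {
      t <- tags[["270"]]
      bytes <- raw[(t$val + 1L):(t$val + t$count)]
      bytes <- bytes[bytes != as.raw(0L)]
      desc <- tryCatch(jsonlite::fromJSON(rawToChar(bytes)),
                       error = function(e) NULL)
    }
    if (is.null(xres) && !is.null(tags[["282"]]) && identical(gv(296L, 2L), 3L)) {
      t <- tags[["282"]]
      num <- rd(t$val, "integer", 1L, 4L)
      den <- rd(t$val + 4L, "integer", 1L, 4L)
      if (den > 0 && num > 0) xres <- num / den
    }
    vals <- if (fmt == 3L && bits == 32L) rd(off, "numeric", w * h, 4L)
            else if (bits == 8L) rd(off, "integer", w * h, 1L, signed = FALSE)
            else if (bits == 16L) rd(off, "integer", w * h, 2L, signed = FALSE)
            else stop("unsupported sample format", call. = FALSE)
    pages[[length(pages) + 1L]] <- matrix(vals, h, w, byrow = TRUE)
    ifd_off <- rd(ifd_off + 2L + n_tags * 12L, "integer", 1L, 4L)
  }
  psz <- pixel_size %||% desc$pixel_size_um %||%
    (if (!is.null(xres)) 1e4 / xres else 1)
  ch_names <- desc$channels %||% "ch1"
  nz <- desc$nz %||% (length(pages) / length(ch_names))
  channels <- list()
  idx <- 0L
  for (ch in ch_names) {
    if (nz > 1L) {
      arr <- array(0, c(nrow(pages[[1L]]), ncol(pages[[1L]]), nz))
      for (k in seq_len(nz)) arr[, , k] <- pages[[idx + k]]
      channels[[ch]] <- arr
      idx <- idx + nz
    } else {
      channels[[ch]] <- pages[[idx + 1L]]
      idx <- idx + 1L
    }
  }
  nucleus_image(channels, psz)
}
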