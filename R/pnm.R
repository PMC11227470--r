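#' Read a portable anymap (PGM/PPM) image
#'
#' Supports the plain (P2/P3) and raw (P5/P6) variants with maxval <= 255.
#' Grayscale images are returned as an h x w numeric matrix, colour images as
#' an h x w x 3 numeric array, both on the 0--255 scale with the first array
#' index running down the image (y axis).
#'
#' @param path file path.
#' @return numeric matrix (PGM) or 3-d array (PPM).
#' @export
read_pnm <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 10L) stop("not a PNM file: ", path)
  magic <- rawToChar(raw[1:2])
  if (!magic %in% c("P2", "P3", "P5", "P6")) {
    stop("unsupported image format (expected PGM/PPM magic P2/P3/P5/P6): ", path)
  }
  # scan header tokens (width, height, maxval), skipping '#' comments
  pos <- 3L
  tokens <- integer(0)
  while (length(tokens) < 3L) {
    while (pos <= length(raw) && raw[pos] %in% as.raw(c(9L, 10L, 13L, 32L))) pos <- pos + 1L
    if (pos > length(raw)) stop("truncated PNM header: ", path)
    if (raw[pos] == as.raw(35L)) {  # '#'
      while (pos <= length(raw) && !raw[pos] %in% as.raw(c(10L, 13L))) pos <- pos + 1L
      next
    }
    start <- pos
    while (pos <= length(raw) && !raw[pos] %in% as.raw(c(9L, 10L, 13L, 32L))) pos <- pos + 1L
    tokens <- c(tokens, as.integer(rawToChar(raw[start:(pos - 1L)])))
  }
  w <- tokens[1]; h <- tokens[2]; maxval <- tokens[3]
  if (is.na(w) || is.na(h) || is.na(maxval)) stop("malformed PNM header: ", path)
  if (maxval > 255L) stop("16-bit PNM not supported")
  nch <- if (magic %in% c("P3", "P6")) 3L else 1L
  n <- w * h * nch
  vals <- if (magic %in% c("P5", "P6")) {
    pos <- pos + 1L  # single whitespace byte after maxval
    if (length(raw) < pos + n - 1L) stop("truncated PNM pixel data: ", path)
    as.integer(raw[pos:(pos + n - 1L)])
  } else {
    txt <- rawToChar(raw[pos:length(raw)])
    v <- suppressWarnings(as.integer(strsplit(trimws(txt), "[[:space:]]+")[[1]]))
    if (length(v) < n || anyNA(v[seq_len(n)])) stop("truncated PNM pixel data: ", path)
    v[seq_len(n)]
  }
  if (nch == 1L) {
    matrix(as.numeric(vals), nrow = h, ncol = w, byrow = TRUE)
  } else {
    a <- array(0, dim = c(h, w, 3L))
    m <- matrix(as.numeric(vals), ncol = 3L, byrow = TRUE)
    for (k in 1:3) a[, , k] <- matrix(m[, k], nrow = h, ncol = w, byrow = TRUE)
    a
  }
}

#' Write a portable anymap (PGM/PPM) image
#'
#' @param img h x w matrix (written as PGM) or h x w x 3 array (PPM), values
#'   0--255; values are rounded and clamped.
#' @param path output path.
#' @param ascii write the plain-text variant (P2/P3) instead of raw (P5/P6).
#' @return `path`, invisibly.
#' @export
write_pnm <- function(img, path, ascii = FALSE) {
  v <- round(img)
  v[v < 0] <- 0
  v[v > 255] <- 255
  is_rgb <- length(dim(v)) == 3L
  h <- dim(v)[1]; w <- dim(v)[2]
  if (is_rgb) {
    m <- cbind(as.vector(t(v[, , 1])), as.vector(t(v[, , 2])), as.vector(t(v[, , 3])))
    flat <- as.integer(t(m))
  } else {
    flat <- as.integer(t(v))
  }
  magic <- if (is_rgb) (if (ascii) "P3" else "P6") else (if (ascii) "P2" else "P5")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("%s\n%d %d\n255\n", magic, w, h), con, eos = NULL)
  if (ascii) {
    writeChar(paste(flat, collapse = "\n"), con, eos = NULL)
    writeChar("\n", con, eos = NULL)
  } else {
    writeBin(as.raw(flat), con)
  }
  invisible(path)
}
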