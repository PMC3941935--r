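#' Raster image container
#'
#' Minimal in-memory raster: integer intensities in \[0, 255\], one
#' (grayscale) or three (RGB) channels, origin at the top-left corner,
#' x growing rightward (columns), y growing downward (rows).
#'
#' @param values numeric matrix (height x width) for grayscale, or a
#'   3-d array (height x width x 3) for RGB.
#' @return an object of class `raster_image` with fields `width`,
#'   `height`, `channels` and `values`.
#' @export
raster_image <- function(values) {
  if (is.matrix(values)) {
    dim(values) <- c(dim(values), 1L)
  }
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("`values` must be a matrix or a height x width x channels array")
  }
  ch <- dim(values)[3]
  if (!ch %in% c(1L, 3L)) stop("channel count must be 1 or 3, got ", ch)
  if (dim(values)[1] < 1L || dim(values)[2] < 1L) {
    stop("image dimensions must be positive")
  }
  v <- round(values)
  if (anyNA(v) || min(v) < 0 || max(v) > 255) {
    stop("pixel values must lie in [0, 255]")
  }
  structure(
    list(width = dim(v)[2], height = dim(v)[1], channels = ch,
         values = v),
    class = "raster_image"
  )
}

#' @export
print.raster_image <- function(x, ...) {
  cat(sprintf("<raster_image %d x %d, %d channel(s)>\n",
              x$width, x$height, x$channels))
  invisible(x)
}

#' Extract one colour channel from an RGB image
#'
#' The analysis chain uses the blue channel of DAPI-filter fluorescence
#' images, where vascular bundles have the highest contrast.
#'
#' @param img a 3-channel [raster_image()].
#' @param channel one of `"red"`, `"green"`, `"blue"`.
#' @return a single-channel `raster_image` of identical dimensions.
#' @export
extract_channel <- function(img, channel = c("blue", "red", "green")) {
  channel <- match.arg(channel)
  stopifnot(inherits(img, "raster_image"))
  if (img$channels != 3L) {
    stop("channel extraction requires a 3-channel image; input has ",
         img$channels)
  }
  idx <- c(red = 1L, green = 2L, blue = 3L)[[channel]]
  raster_image(matrix(img$values[, , idx], img$height, img$width))
}

#' Linear brightness/contrast adjustment
#'
#' Optional linear rescale `gain * x + offset`, clamped to \[0, 255\].
#' The defaults are the identity; the original workflow adjusted
#' brightness and contrast manually before thresholding.
#'
#' @param img single- or multi-channel [raster_image()].
#' @param gain multiplicative factor (> 0).
#' @param offset additive term in intensity units.
#' @return adjusted `raster_image`.
#' @export
adjust_intensity <- function(img, gain = 1, offset = 0) {
  stopifnot(inherits(img, "raster_image"), gain > 0)
  v <- pmin(pmax(gain * img$values + offset, 0), 255)
  raster_image(v)
}

# ---- portable anymap I/O -------------------------------------------------
# PNM (P2/P3 ASCII, P5/P6 binary) keeps image fixtures plain-text capable
# and needs no external imaging library.

#' Read a PNM (PGM/PPM) image
#'
#' Supports ASCII (`P2`, `P3`) and binary (`P5`, `P6`) portable anymaps
#' with maxval 255. This is the on-disk image format of the package;
#' in-memory rasters from any other reader can be wrapped with
#' [raster_image()].
#'
#' @param path file path.
#' @return a [raster_image()].
#' @export
read_pnm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  raw_all <- readBin(con, "raw", n = file.size(path))
  txt_head <- rawToChar(raw_all[seq_len(min(length(raw_all), 512L))])
  magic <- substr(txt_head, 1, 2)
  if (!magic %in% c("P2", "P3", "P5", "P6")) {
    stop("unsupported PNM magic: ", magic)
  }
  ascii <- magic %in% c("P2", "P3")
  channels <- if (magic %in% c("P3", "P6")) 3L else 1L

  # tokenize header (magic, width, height, maxval), skipping comments
  pos <- 1L
  tokens <- character(0)
  cur <- character(0)
  while (length(tokens) < 4L && pos <= length(raw_all)) {
    ch <- rawToChar(raw_all[pos])
    pos <- pos + 1L
    if (ch == "#") {
      while (pos <= length(raw_all) && rawToChar(raw_all[pos]) != "\n") {
        pos <- pos + 1L
      }
    } else if (grepl("[[:space:]]", ch)) {
      if (length(cur)) {
        tokens <- c(tokens, paste(cur, collapse = ""))
        cur <- character(0)
      }
    } else {
      cur <- c(cur, ch)
    }
  }
  w <- as.integer(tokens[2]); h <- as.integer(tokens[3])
  maxval <- as.integer(tokens[4])
  if (is.na(w) || is.na(h) || maxval != 255L) {
    stop("malformed PNM header (only maxval 255 supported)")
  }
  n <- w * h * channels
  if (ascii) {
    body <- rawToChar(raw_all[pos:length(raw_all)])
    vals <- as.integer(scan(text = body, what = integer(), n = n,
                            quiet = TRUE))
  } else {
    vals <- as.integer(raw_all[pos:(pos + n - 1L)])
  }
  if (length(vals) != n) stop("truncated PNM body")
  if (channels == 1L) {
    m <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
    raster_image(m)
  } else {
    a <- array(0L, dim = c(h, w, 3L))
    for (k in 1:3) {
      a[, , k] <- matrix(vals[seq(k, n, by = 3L)], nrow = h, ncol = w,
                         byrow = TRUE)
    }
    raster_image(a)
  }
}

#' Write a PNM (PGM/PPM) image
#'
#' @param img a [raster_image()] (1 channel writes PGM, 3 writes PPM).
#' @param path output path.
#' @param ascii write ASCII (`P2`/`P3`, default) or binary (`P5`/`P6`).
#' @export
write_pnm <- function(img, path, ascii = TRUE) {
  stopifnot(inherits(img, "raster_image"))
  rgb <- img$channels == 3L
  magic <- if (ascii) (if (rgb) "P3" else "P2") else (if (rgb) "P6" else "P5")
  if (rgb) {
    # interleave channels row-major
    v <- aperm(img$values, c(3, 2, 1))
  } else {
    v <- t(img$values[, , 1])
  }
  vals <- as.integer(v)
  header <- sprintf("%s\n%d %d\n255\n", magic, img$width, img$height)
  if (ascii) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw(header), con)
    writeBin(charToRaw(paste0(paste(vals, collapse = "\n"), "\n")), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw(header), con)
    writeBin(as.raw(vals), con)
  }
  invisible(path)
}

#' Write a binary mask as a PGM image (debug aid)
#' @param mask a [binary_mask()].
#' @param path output path.
#' @export
write_mask_pnm <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  write_pnm(raster_image(mask$values * 255L), path)
}
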