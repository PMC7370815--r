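#' Construct an RGB image object
#'
#' The pipeline's raw raster representation: an H x W x 3 integer array of
#' 8-bit channel intensities in channel order R, G, B.
#'
#' @param pixels numeric or integer array of dimension H x W x 3 (or H x W for
#'   grayscale, which is replicated across the three channels), values in
#'   0..255.
#' @param source_id free-text identifier carried through to results.
#' @return an object of class `rgb_image` with elements `pixels`, `height`,
#'   `width`, `source_id`.
#' @export
rgb_image <- function(pixels, source_id = "") {
  if (is.matrix(pixels)) {
    pixels <- array(rep(pixels, 3L), dim = c(dim(pixels), 3L))
  }
  d <- dim(pixels)
  if (length(d) != 3L || d[3] != 3L) {
    stop("pixels must be an H x W x 3 array (or H x W matrix)")
  }
  if (d[1] < 1L || d[2] < 1L) stop("zero-area image")
  if (anyNA(pixels) || any(!is.finite(pixels))) {
    stop("non-finite pixel values")
  }
  if (min(pixels) < 0 || max(pixels) > 255) {
    stop("channel values must lie in [0, 255]")
  }
  storage.mode(pixels) <- "integer"
  structure(
    list(pixels = pixels, height = d[1], width = d[2],
         source_id = as.character(source_id)),
    class = "rgb_image"
  )
}

#' @export
print.rgb_image <- function(x, ...) {
  cat(sprintf("<rgb_image> %d x %d  id=%s\n", x$height, x$width,
              if (nzchar(x$source_id)) x$source_id else "<unset>"))
  invisible(x)
}

# Read a plain-text Netpbm image (ASCII P1/P2/P3). Used for text-only
# fixtures; binary Netpbm variants are out of scope.
read_pnm_ascii <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  magic <- toks[1]
  if (!magic %in% c("P1", "P2", "P3")) {
    stop("unsupported PNM variant (only ASCII P1/P2/P3): ", path)
  }
  vals <- as.numeric(toks[-1])
  w <- vals[1]; h <- vals[2]
  if (magic == "P1") {
    px <- vals[-(1:2)]
    px <- 255 * (1 - px)  # PBM: 1 = black
  } else {
    maxval <- vals[3]
    px <- vals[-(1:3)]
    if (maxval != 255) px <- round(px / maxval * 255)
  }
  if (magic == "P3") {
    n <- h * w
    if (length(px) != 3 * n) stop("corrupt PPM payload: ", path)
    # pixels are interleaved R,G,B in row-major order
    arr <- array(0, dim = c(h, w, 3))
    for (ch in 1:3) {
      arr[, , ch] <- matrix(px[seq(ch, 3 * n, by = 3)],
                            nrow = h, ncol = w, byrow = TRUE)
    }
    arr
  } else {
    if (length(px) != h * w) stop("corrupt PGM payload: ", path)
    matrix(px, nrow = h, ncol = w, byrow = TRUE)
  }
}

#' Load a raster image from disk
#'
#' Reads PNG (8- or 16-bit), JPEG, or ASCII PGM/PPM into the pipeline's
#' internal `rgb_image` representation. Alpha channels are dropped, grayscale
#' images are replicated to three identical channels, and 16-bit PNG sources
#' are rescaled to 0..255 by integer division (value %/% 257 on the 0..65535
#' scale, i.e. floor of value / 257).
#'
#' TIFF is not supported in this build (no TIFF decoder is available in the
#' dependency set); such files raise an error naming the path.
#'
#' @param path path to the image file.
#' @param source_id identifier to attach; defaults to the file name.
#' @return an `rgb_image`.
#' @export
load_image <- function(path, source_id = basename(path)) {
  if (!file.exists(path)) stop("image file does not exist: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(
    ext,
    png = {
      a <- tryCatch(png::readPNG(path, native = FALSE),
                    error = function(e) stop("unreadable PNG '", path, "': ",
                                             conditionMessage(e)))
      # readPNG returns [0,1] doubles; recover the stored integer codes.
      # 8-bit codes are k/255 exactly; anything off that grid is a 16-bit
      # source (k/65535), mapped to 0..255 by integer division by 257.
      if (any(abs(a * 255 - round(a * 255)) > 1e-6)) {
        round(a * 65535) %/% 257L
      } else {
        round(a * 255)
      }
    },
    jpg = ,
    jpeg = {
      a <- tryCatch(jpeg::readJPEG(path),
                    error = function(e) stop("unreadable JPEG '", path, "': ",
                                             conditionMessage(e)))
      round(a * 255)
    },
    pgm = ,
    ppm = ,
    pbm = read_pnm_ascii(path),
    tif = ,
    tiff = stop("TIFF is not supported by this build: ", path),
    stop("unrecognized image format '", ext, "': ", path)
  )
  if (length(dim(arr)) == 3L && dim(arr)[3] == 4L) {
    arr <- arr[, , 1:3, drop = FALSE]  # drop alpha
  }
  if (length(dim(arr)) == 3L && dim(arr)[3] == 2L) {
    arr <- arr[, , 1, drop = TRUE]     # gray + alpha
  }
  rgb_image(arr, source_id = source_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an `rgb_image` to a PNG file
#'
#' 8-bit lossless output; the loader round-trips it bit-identically.
#'
#' @param img an `rgb_image`.
#' @param path output path ending in .png.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(img, path) {
  stopifnot(inherits(img, "rgb_image"))
  png::writePNG(img$pixels / 255, target = path)
  invisible(path)
}

catalog_columns <- c("image_id", "order_index", "date_label", "condition", "path")

#' Load a cohort catalog
#'
#' Reads the CSV catalog describing the image cohort: one row per image with
#' its chronological rank (`order_index`, 1-based), a free-text date label,
#' the exposure condition (`low` or `high`, case-insensitive), and the image
#' file path. Rows are returned sorted ascending by `order_index`.
#'
#' @param path path to a UTF-8 CSV with header columns `image_id`,
#'   `order_index`, `date_label`, `condition`, `path`.
#' @return a data.frame of class `catalog` sorted by `order_index`, with
#'   `condition` a factor with levels `low`, `high`.
#' @export
load_catalog <- function(path) {
  if (!file.exists(path)) stop("catalog file does not exist: ", path)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8"),
    error = function(e) stop("unreadable catalog '", path, "': ",
                             conditionMessage(e))
  )
  as_catalog(df)
}

#' Validate and normalize a catalog data.frame
#'
#' @param df data.frame with the catalog columns.
#' @return a validated `catalog` data.frame sorted by `order_index`.
#' @export
as_catalog <- function(df) {
  missing_cols <- setdiff(catalog_columns, names(df))
  if (nrow(df) == 0L) stop("catalog is empty")
  if (length(missing_cols) > 0L) {
    stop("catalog missing required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  df <- df[catalog_columns]
  df$image_id <- as.character(df$image_id)
  df$order_index <- as.integer(df$order_index)
  if (anyNA(df$order_index) || any(df$order_index < 1L)) {
    stop("order_index must be positive integers")
  }
  if (anyDuplicated(df$order_index)) {
    stop("duplicate order_index values: ",
         paste(unique(df$order_index[duplicated(df$order_index)]),
               collapse = ", "))
  }
  cond <- tolower(trimws(as.character(df$condition)))
  bad <- which(!cond %in% c("low", "high"))
  if (length(bad) > 0L) {
    stop("unknown condition value(s) in row(s) ",
         paste(bad, collapse = ", "), ": ",
         paste(unique(df$condition[bad]), collapse = ", "),
         " (expected 'low' or 'high')")
  }
  df$condition <- factor(cond, levels = c("low", "high"))
  df$date_label <- as.character(df$date_label)
  df$path <- as.character(df$path)
  df <- df[order(df$order_index), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("catalog", "data.frame")
  df
}

#' Write a catalog to CSV
#'
#' Inverse of [load_catalog()]: `load_catalog(write_catalog(x, f))` returns a
#' catalog identical to `x`.
#'
#' @param catalog a `catalog` data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  df <- as.data.frame(catalog)
  df$condition <- as.character(df$condition)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
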