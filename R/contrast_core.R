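#' Convert an RGB image to a luminance field
#'
#' Per-pixel luma is the Rec.601-style weighted sum
#' \deqn{L = (0.299 R + 0.587 G + 0.114 B) / 255,}
#' applied directly to the stored 8-bit channel values (no gamma
#' linearization by default, matching how this luma is conventionally
#' computed on gamma-encoded values). Values land in [0, 1].
#'
#' @param img an `rgb_image`.
#' @param linearize_srgb if `TRUE`, decode sRGB gamma before weighting
#'   (sensitivity analyses only; default `FALSE`).
#' @return a `luminance_field`: list with `values` (H x W matrix in [0,1]) and
#'   `mean_luminance`.
#' @export
rgb_to_luminance <- function(img, linearize_srgb = FALSE) {
  stopifnot(inherits(img, "rgb_image"))
  px <- img$pixels / 255
  if (isTRUE(linearize_srgb)) {
    px <- ifelse(px <= 0.04045, px / 12.92, ((px + 0.055) / 1.055)^2.4)
  }
  L <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
  L <- matrix(L, nrow = img$height, ncol = img$width)
  luminance_field(L)
}

#' Construct a luminance field
#'
#' @param values H x W numeric matrix with entries in [0, 1].
#' @return a `luminance_field`.
#' @export
luminance_field <- function(values) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix")
  }
  if (anyNA(values) || any(!is.finite(values))) stop("non-finite luminance")
  if (min(values) < -1e-12 || max(values) > 1 + 1e-12) {
    stop("luminance values must lie in [0, 1]")
  }
  values <- pmin(pmax(values, 0), 1)
  structure(list(values = values, mean_luminance = mean(values)),
            class = "luminance_field")
}

#' Remove the mean from a luminance field
#'
#' The contrast statistic is the lag-0 autocovariance, so the field's mean
#' (the DC term) is removed before the spectral step; the output mean is 0 to
#' machine precision.
#'
#' @param field a `luminance_field`.
#' @return an H x W numeric matrix with zero mean.
#' @export
mean_center <- function(field) {
  stopifnot(inherits(field, "luminance_field"))
  field$values - field$mean_luminance
}

new_acf_field <- function(values, mode, dim_orig) {
  structure(list(values = values, mode = mode,
                 n_pixels = prod(dim_orig), dim_orig = dim_orig),
            class = "acf_field")
}

#' Spectral (Wiener-Khinchin) autocovariance estimate
#'
#' Estimates the autocovariance of a mean-centered field through the power
#' spectrum: the autocorrelation function of a wide-sense-stationary process
#' is the inverse Fourier transform of its power spectrum, so the estimate is
#' the inverse 2D FFT of the squared modulus of the 2D FFT.
#'
#' Two normalizations are offered. In `circular` mode (the default) every lag
#' is divided by the pixel count N, the biased plug-in estimate: lag (0, 0)
#' then equals the mean of squares of the input exactly (Parseval). In
#' `linear_unbiased` mode the field is zero-padded to at least
#' (2H-1) x (2W-1), so products never wrap around, and each lag is divided by
#' its overlap count (H-|a|)(W-|b|).
#'
#' @param centered mean-centered H x W numeric matrix (see [mean_center()]).
#' @param mode `"circular"` or `"linear_unbiased"`.
#' @return an `acf_field`: list with `values` (lag-indexed matrix with lag
#'   (0,0) at position [1,1] and negative lags wrapped to the far end, the
#'   native FFT layout), `mode`, `n_pixels`, `dim_orig`.
#' @export
autocorrelation_fft <- function(centered,
                                mode = c("circular", "linear_unbiased")) {
  mode <- match.arg(mode)
  if (!is.matrix(centered) || !is.numeric(centered)) {
    stop("input must be a numeric matrix")
  }
  if (anyNA(centered) || any(!is.finite(centered))) {
    stop("non-finite values in input")
  }
  h <- nrow(centered); w <- ncol(centered)
  if (mode == "circular") {
    n <- h * w
    pw <- Mod(stats::fft(centered))^2
    vals <- Re(stats::fft(pw, inverse = TRUE)) / n^2
    new_acf_field(vals, mode, c(h, w))
  } else {
    ph <- if (h > 1) 2L * h - 1L else 1L
    pw_ <- if (w > 1) 2L * w - 1L else 1L
    pad <- matrix(0, ph, pw_)
    pad[1:h, 1:w] <- centered
    n <- ph * pw_
    pw <- Mod(stats::fft(pad))^2
    sums <- Re(stats::fft(pw, inverse = TRUE)) / n
    la <- lag_of_index(seq_len(ph), ph)
    lb <- lag_of_index(seq_len(pw_), pw_)
    overlap <- outer(h - abs(la), w - abs(lb))
    new_acf_field(sums / overlap, mode, c(h, w))
  }
}

# signed lag encoded by FFT-layout index i (1-based) for period p
lag_of_index <- function(i, p) {
  l <- i - 1L
  ifelse(l > p %/% 2, l - p, l)
}

#' Look up an autocovariance value at a signed lag
#'
#' @param acf an `acf_field`.
#' @param da,db signed row/column lags.
#' @return the autocovariance estimate at lag `(da, db)` (NA if not computed,
#'   e.g. outside a direct estimate's `max_lag`).
#' @export
acf_at <- function(acf, da, db) {
  stopifnot(inherits(acf, "acf_field"))
  ph <- nrow(acf$values); pw <- ncol(acf$values)
  if (acf$mode == "linear_unbiased") {
    h <- acf$dim_orig[1]; w <- acf$dim_orig[2]
    if (abs(da) > h - 1 || abs(db) > w - 1) return(NA_real_)
  }
  acf$values[(da %% ph) + 1L, (db %% pw) + 1L]
}

#' @export
print.acf_field <- function(x, ...) {
  cat(sprintf("<acf_field> mode=%s  field %d x %d  lag(0,0)=%.6g\n",
              x$mode, x$dim_orig[1], x$dim_orig[2], x$values[1, 1]))
  invisible(x)
}

#' Direct-summation autocovariance (oracle)
#'
#' Brute-force estimate by explicit double summation over pixel pairs, the
#' independent check on the spectral route: the two agree at every shared lag
#' to within 1e-10. Lags `-max_lag..max_lag` in each dimension are computed;
#' other entries are NA.
#'
#' @param centered mean-centered numeric matrix.
#' @param max_lag largest absolute lag per dimension; must be < min(H, W).
#' @param mode `"circular"` (wraparound indexing, 1/N normalization) or
#'   `"linear_unbiased"` (overlap-count normalization).
#' @return an `acf_field` with NA outside the computed lag window.
#' @export
autocorrelation_direct <- function(centered, max_lag = min(dim(centered)) - 1L,
                                   mode = c("circular", "linear_unbiased")) {
  mode <- match.arg(mode)
  if (anyNA(centered) || any(!is.finite(centered))) {
    stop("non-finite values in input")
  }
  h <- nrow(centered); w <- ncol(centered)
  if (max_lag < 0 || max_lag >= min(h, w)) {
    stop("max_lag must satisfy 0 <= max_lag < min(H, W)")
  }
  ph <- if (mode == "circular") h else if (h > 1) 2L * h - 1L else 1L
  pw <- if (mode == "circular") w else if (w > 1) 2L * w - 1L else 1L
  vals <- matrix(NA_real_, ph, pw)
  for (da in -max_lag:max_lag) {
    for (db in -max_lag:max_lag) {
      acc <- 0
      if (mode == "circular") {
        for (i in seq_len(h)) {
          for (j in seq_len(w)) {
            acc <- acc + centered[i, j] *
              centered[((i - 1 + da) %% h) + 1, ((j - 1 + db) %% w) + 1]
          }
        }
        val <- acc / (h * w)
      } else {
        ri <- max(1, 1 - da):min(h, h - da)
        rj <- max(1, 1 - db):min(w, w - db)
        for (i in ri) {
          for (j in rj) {
            acc <- acc + centered[i, j] * centered[i + da, j + db]
          }
        }
        val <- acc / (length(ri) * length(rj))
      }
      vals[(da %% ph) + 1L, (db %% pw) + 1L] <- val
    }
  }
  new_acf_field(vals, mode, c(h, w))
}

#' Average image contrast
#'
#' The headline statistic: the autocovariance of the luminance field at lag
#' (0, 0), computed through the spectral route ([autocorrelation_fft()] of the
#' mean-centered field). This equals the plug-in variance
#' \eqn{(1/N) \sum (L - \bar L)^2} exactly (Parseval identity); its square
#' root is the RMS contrast, bounded by 0.5 for values in [0, 1].
#'
#' @param field a `luminance_field` with at least 2 pixels.
#' @param image_id identifier carried into the result.
#' @param config_digest provenance string carried into the result.
#' @return a `contrast_result`: list with `variance_contrast`,
#'   `rms_contrast`, `image_id`, `config_digest`, `height`, `width`.
#' @export
image_contrast <- function(field, image_id = "", config_digest = "") {
  stopifnot(inherits(field, "luminance_field"))
  if (length(field$values) < 2L) {
    stop("contrast undefined for single-pixel image")
  }
  acf <- autocorrelation_fft(mean_center(field), mode = "circular")
  v <- max(acf$values[1, 1], 0)  # guard FFT round-off at exact zero
  structure(
    list(variance_contrast = v, rms_contrast = sqrt(v),
         image_id = as.character(image_id),
         config_digest = as.character(config_digest),
         height = nrow(field$values), width = ncol(field$values)),
    class = "contrast_result"
  )
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf("<contrast_result> id=%s  variance=%.6g  rms=%.6g  (%d x %d)\n",
              if (nzchar(x$image_id)) x$image_id else "<unset>",
              x$variance_contrast, x$rms_contrast, x$height, x$width))
  invisible(x)
}

#' Radial autocovariance profile
#'
#' Bins the lags of an autocovariance field by Euclidean lag radius and
#' averages within bins — the isotropic summary of the full ACF shape. Bin 0
#' holds only lag (0, 0), so its value is the variance contrast; the
#' remaining `n_bins - 1` bins split (0, r_max] into equal widths. In
#' circular mode the signed lag magnitude is `min(l, P - l)` per dimension.
#'
#' @param acf an `acf_field`.
#' @param n_bins total number of bins, at least 2.
#' @return data.frame with columns `bin`, `radius` (mean lag radius in the
#'   bin), `acov` (mean autocovariance), `n_lags`.
#' @export
radial_acf_profile <- function(acf, n_bins = 16L) {
  stopifnot(inherits(acf, "acf_field"))
  if (n_bins < 2L) stop("n_bins must be >= 2")
  ph <- nrow(acf$values); pw <- ncol(acf$values)
  if (acf$mode == "circular") {
    la <- pmin(0:(ph - 1), ph - 0:(ph - 1))
    lb <- pmin(0:(pw - 1), pw - 0:(pw - 1))
  } else {
    la <- abs(lag_of_index(seq_len(ph), ph))
    lb <- abs(lag_of_index(seq_len(pw), pw))
  }
  rad <- sqrt(outer(la^2, lb^2, `+`))
  keep <- !is.na(acf$values)
  r <- rad[keep]; v <- acf$values[keep]
  rmax <- max(r)
  # bin 0: exactly lag (0,0); bins 1..n_bins-1 tile (0, rmax]
  idx <- if (rmax == 0) {
    rep(0L, length(r))
  } else {
    ifelse(r == 0, 0L, pmin(ceiling(r / rmax * (n_bins - 1L)), n_bins - 1L))
  }
  out <- data.frame(
    bin = sort(unique(idx)),
    radius = as.numeric(tapply(r, idx, mean)),
    acov = as.numeric(tapply(v, idx, mean)),
    n_lags = as.integer(tapply(v, idx, length))
  )
  rownames(out) <- NULL
  out
}
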