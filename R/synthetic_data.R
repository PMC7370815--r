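#' Specify a synthetic test image
#'
#' Describes deterministic-per-seed images of analytically known contrast:
#' \describe{
#'   \item{uniform}{constant `level`; variance contrast 0.}
#'   \item{checkerboard}{tiles of side `tile` alternating between `levels[1]`
#'     and `levels[2]`; for an even tiling the variance contrast is
#'     \eqn{((l_2-l_1)/2)^2}.}
#'   \item{grating}{\eqn{L = 0.5 + A \sin(2\pi(k x / W + k_2 y / H) + \phi)}
#'     with integer frequencies `k` (and optional cross-axis `k2`, default 0
#'     = axis-aligned), amplitude `A <= 0.5`, seeded random phase and
#'     orientation; variance contrast \eqn{A^2/2} exactly whenever
#'     \eqn{2k \not\equiv 0 \pmod W} or \eqn{2k_2 \not\equiv 0 \pmod H}. An
#'     oblique grating samples \eqn{H W} distinct phases, which averages
#'     8-bit round-off far better than the \eqn{\max(H, W)} samples of an
#'     axis-aligned one.}
#'   \item{gaussian_field}{stationary Gaussian random field, mean 0.5,
#'     standard deviation `sigma`, Gaussian correlation length `ell` (pixels);
#'     see [generate_gaussian_field()].}
#'   \item{two_tone_patches}{a seeded random half/half (or `fraction`) split
#'     of pixels between `levels`; variance contrast
#'     \eqn{p(1-p)(l_2-l_1)^2}.}
#' }
#'
#' @param kind one of `"uniform"`, `"checkerboard"`, `"grating"`,
#'   `"gaussian_field"`, `"two_tone_patches"`.
#' @param height,width pixel counts.
#' @param seed integer seed; generation is deterministic given (spec, seed).
#' @param level uniform level in [0,1].
#' @param tile checkerboard tile side in pixels.
#' @param levels two luminance levels in [0,1] (checkerboard / two-tone).
#' @param amplitude,k,k2 grating amplitude, integer cycle count, and
#'   cross-axis cycle count (0 = axis-aligned).
#' @param sigma,ell Gaussian field standard deviation and correlation length.
#' @param fraction two-tone high-level pixel fraction.
#' @return a `synth_image_spec` list.
#' @export
synthetic_image_spec <- function(kind = c("uniform", "checkerboard", "grating",
                                          "gaussian_field", "two_tone_patches"),
                                 height = 64L, width = 64L, seed = 1L,
                                 level = 0.5, tile = 8L, levels = c(0, 1),
                                 amplitude = 0.25, k = 4L, k2 = 0L,
                                 sigma = 0.1, ell = 0,
                                 fraction = 0.5) {
  kind <- match.arg(kind)
  if (height < 1L || width < 1L) stop("height and width must be >= 1")
  spec <- list(kind = kind, height = as.integer(height),
               width = as.integer(width), seed = as.integer(seed),
               level = level, tile = as.integer(tile), levels = levels,
               amplitude = amplitude, k = as.integer(k), k2 = as.integer(k2),
               sigma = sigma, ell = ell, fraction = fraction)
  if (kind == "uniform" && (level < 0 || level > 1)) {
    stop("level must lie in [0, 1]")
  }
  if (kind %in% c("checkerboard", "two_tone_patches") &&
      (min(levels) < 0 || max(levels) > 1 || length(levels) != 2L)) {
    stop("levels must be two values in [0, 1]")
  }
  if (kind == "grating" && (amplitude < 0 || amplitude > 0.5)) {
    stop("grating amplitude must lie in [0, 0.5] to keep values in [0, 1]")
  }
  if (kind == "two_tone_patches" && (fraction <= 0 || fraction >= 1)) {
    stop("fraction must lie in (0, 1)")
  }
  class(spec) <- "synth_image_spec"
  spec
}

#' Generate a stationary Gaussian random luminance field
#'
#' Spectral synthesis: white Gaussian noise is filtered in Fourier space with
#' a Gaussian kernel of spatial scale `ell` (imposing covariance
#' \eqn{\propto \exp(-r^2 / (4\ell^2))}), rescaled to plug-in standard
#' deviation `sigma` exactly, shifted to mean 0.5, and clipped to [0, 1].
#' With `sigma <= 0.15` the clipped-pixel fraction stays below 1e-3
#' (0.5/0.15 > 3.3 standard deviations). Deterministic per seed.
#'
#' @param height,width field dimensions.
#' @param sigma target standard deviation, in [0, 0.15].
#' @param ell correlation length in pixels, >= 0 (0 = white noise).
#' @param seed integer seed.
#' @return a `luminance_field`.
#' @export
generate_gaussian_field <- function(height, width, sigma, ell = 0, seed = 1L) {
  if (sigma < 0 || sigma > 0.15) {
    stop("sigma must lie in [0, 0.15]: larger values violate the ",
         "clipped-fraction < 1e-3 bound around mean 0.5")
  }
  if (ell < 0) stop("ell must be >= 0")
  h <- as.integer(height); w <- as.integer(width)
  if (sigma == 0) return(luminance_field(matrix(0.5, h, w)))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  z <- matrix(stats::rnorm(h * w), h, w)
  if (ell > 0) {
    fa <- c(0:(h %/% 2), -((h - h %/% 2 - 1):1))[1:h] / h
    fb <- c(0:(w %/% 2), -((w - w %/% 2 - 1):1))[1:w] / w
    kern <- exp(-2 * pi^2 * ell^2 * outer(fa^2, fb^2, `+`))
    z <- Re(stats::fft(stats::fft(z) * kern, inverse = TRUE)) / (h * w)
  }
  z <- z - mean(z)
  s <- sqrt(mean(z^2))
  if (s == 0) z[] <- 0 else z <- z * (sigma / s)
  luminance_field(pmin(pmax(z + 0.5, 0), 1))
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

# ideal (pre-quantization) luminance field for a spec, plus its analytic or
# realized plug-in variance contrast
synth_field <- function(spec) {
  h <- spec$height; w <- spec$width
  switch(
    spec$kind,
    uniform = list(values = matrix(spec$level, h, w), known = 0),
    checkerboard = {
      ti <- (seq_len(h) - 1L) %/% spec$tile
      tj <- (seq_len(w) - 1L) %/% spec$tile
      par <- outer(ti, tj, `+`) %% 2L
      vals <- matrix(spec$levels[1], h, w)
      vals[par == 1L] <- spec$levels[2]
      p <- mean(par == 1L)
      list(values = vals, known = p * (1 - p) * diff(spec$levels)^2)
    },
    grating = {
      old <- get_rng_state(); on.exit(restore_rng_state(old))
      set.seed(spec$seed)
      phase <- stats::runif(1, 0, 2 * pi)
      horiz <- stats::runif(1) < 0.5
      kx <- if (horiz) spec$k else spec$k2   # cycles along columns
      ky <- if (horiz) spec$k2 else spec$k   # cycles along rows
      arg <- 2 * pi * outer((0:(h - 1)) * ky / h, (0:(w - 1)) * kx / w, `+`)
      vals <- 0.5 + spec$amplitude * sin(arg + phase)
      list(values = vals, known = spec$amplitude^2 / 2)
    },
    gaussian_field = {
      fld <- generate_gaussian_field(h, w, spec$sigma, spec$ell, spec$seed)
      v <- fld$values
      list(values = v, known = mean((v - mean(v))^2))
    },
    two_tone_patches = {
      old <- get_rng_state(); on.exit(restore_rng_state(old))
      set.seed(spec$seed)
      n <- h * w
      n_hi <- round(spec$fraction * n)
      vals <- matrix(spec$levels[1], h, w)
      vals[sample.int(n, n_hi)] <- spec$levels[2]
      p <- n_hi / n
      list(values = vals, known = p * (1 - p) * diff(spec$levels)^2)
    }
  )
}

#' Generate a synthetic image with known contrast
#'
#' Realizes a [synthetic_image_spec()] as an 8-bit grayscale-replicated
#' `rgb_image` and returns the analytically (uniform / checkerboard / grating
#' / two-tone) or empirically (gaussian_field: realized pre-quantization
#' plug-in variance) known variance contrast. 8-bit quantization perturbs the
#' measured contrast by less than 1e-3.
#'
#' @param spec a `synth_image_spec`.
#' @param source_id identifier for the resulting image.
#' @return list with elements `image` (`rgb_image`) and
#'   `known_variance_contrast`.
#' @export
generate_image <- function(spec, source_id = paste0("synth_", spec$kind)) {
  stopifnot(inherits(spec, "synth_image_spec"))
  f <- synth_field(spec)
  px <- round(f$values * 255)
  list(image = rgb_image(px, source_id = source_id),
       known_variance_contrast = f$known)
}

#' Specify a synthetic two-condition cohort
#'
#' Emulates the study design the pipeline targets: a chronologically ordered
#' cohort split into a `low` and a `high` exposure condition (defaults 19 vs
#' 9, 28 images), with per-image target RMS contrast drawn per condition as
#' Normal(`contrast_low` or `contrast_high`, `within_sd`) truncated to the
#' kind's attainable range. The default image kind is a seeded random-phase
#' grating, whose realized RMS contrast equals the drawn target up to 8-bit
#' quantization (< 1e-3) for targets up to \eqn{0.5/\sqrt 2 \approx 0.354}.
#'
#' @param n_low,n_high condition sizes.
#' @param contrast_low,contrast_high mean target RMS contrast per condition.
#' @param within_sd between-image standard deviation of the target.
#' @param height,width image dimensions.
#' @param kind image kind realizing the targets: `"grating"` (default) or
#'   `"gaussian_field"` (targets then truncated to [0.005, 0.15]).
#' @param seed integer seed.
#' @return a `synth_cohort_spec` list.
#' @export
synthetic_cohort_spec <- function(n_low = 19L, n_high = 9L,
                                  contrast_low = 0.1, contrast_high = 0.1,
                                  within_sd = 0.05,
                                  height = 24L, width = 25L,
                                  kind = c("grating", "gaussian_field"),
                                  seed = 1L) {
  kind <- match.arg(kind)
  if (n_low + n_high < 2L || n_low < 0L || n_high < 0L) {
    stop("need n_low + n_high >= 2")
  }
  hi_cap <- if (kind == "grating") 0.5 / sqrt(2) else 0.15
  if (max(contrast_low, contrast_high) > hi_cap) {
    stop(sprintf("target RMS contrast above the %s kind's cap %.3f",
                 kind, hi_cap))
  }
  structure(list(n_low = as.integer(n_low), n_high = as.integer(n_high),
                 contrast_low = contrast_low, contrast_high = contrast_high,
                 within_sd = within_sd, height = as.integer(height),
                 width = as.integer(width), kind = kind,
                 seed = as.integer(seed)),
            class = "synth_cohort_spec")
}

# draw per-image target RMS contrasts; truncation bounds keep the realizing
# image kind valid
draw_targets <- function(spec) {
  lo_cap <- 0.005
  hi_cap <- if (spec$kind == "grating") 0.5 / sqrt(2) else 0.15
  n <- spec$n_low + spec$n_high
  mu <- c(rep(spec$contrast_low, spec$n_low),
          rep(spec$contrast_high, spec$n_high))
  t <- stats::rnorm(n, mu, spec$within_sd)
  pmin(pmax(t, lo_cap), hi_cap)
}

# in-memory cohort realization: catalog rows + rgb_images + truth targets.
# Used by generate_cohort() (which also writes files) and by simulation
# helpers that skip the lossless PNG round-trip for speed.
realize_cohort <- function(spec) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(spec$seed)
  n <- spec$n_low + spec$n_high
  targets <- draw_targets(spec)
  cond <- c(rep("low", spec$n_low), rep("high", spec$n_high))
  img_seeds <- sample.int(.Machine$integer.max - 1L, n)
  images <- vector("list", n)
  for (i in seq_len(n)) {
    ispec <- if (spec$kind == "grating") {
      # oblique so 8-bit round-off averages over all H*W phase samples,
      # keeping |realized - target| rms below 1e-3 even at 24x24
      synthetic_image_spec("grating", spec$height, spec$width,
                           seed = img_seeds[i],
                           amplitude = targets[i] * sqrt(2),
                           k = 3L + (img_seeds[i] %% 6L),
                           k2 = 1L + (img_seeds[i] %% 3L))
    } else {
      synthetic_image_spec("gaussian_field", spec$height, spec$width,
                           seed = img_seeds[i], sigma = targets[i], ell = 0)
    }
    images[[i]] <- generate_image(ispec, source_id = sprintf("img%02d", i))$image
  }
  catalog <- data.frame(
    image_id = sprintf("img%02d", seq_len(n)),
    order_index = seq_len(n),
    date_label = sprintf("t%02d", seq_len(n)),
    condition = cond,
    path = sprintf("img%02d.png", seq_len(n)),
    stringsAsFactors = FALSE
  )
  list(catalog = as_catalog(catalog), images = images,
       truth = data.frame(image_id = catalog$image_id,
                          condition = cond,
                          target_rms_contrast = targets,
                          stringsAsFactors = FALSE))
}

#' Generate a synthetic cohort on disk
#'
#' Writes the cohort's PNG images, the catalog CSV consumed by
#' [load_catalog()] / [run_contrast()], and a truth-table CSV recording the
#' drawn per-image target RMS contrasts (pre-quantization).
#'
#' @param spec a `synth_cohort_spec`.
#' @param dir output directory (created if needed).
#' @return list with `catalog_path`, `truth_path`, `dir`, and the in-memory
#'   `catalog` and `truth` tables.
#' @export
generate_cohort <- function(spec, dir) {
  stopifnot(inherits(spec, "synth_cohort_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  coh <- realize_cohort(spec)
  coh$catalog$path <- file.path(dir, basename(coh$catalog$path))
  for (i in seq_along(coh$images)) {
    write_image_png(coh$images[[i]], coh$catalog$path[i])
  }
  catalog_path <- file.path(dir, "catalog.csv")
  truth_path <- file.path(dir, "truth.csv")
  write_catalog(coh$catalog, catalog_path)
  utils::write.csv(coh$truth, truth_path, row.names = FALSE)
  list(catalog_path = catalog_path, truth_path = truth_path, dir = dir,
       catalog = coh$catalog, truth = coh$truth)
}
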