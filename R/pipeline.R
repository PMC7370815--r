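#' Pipeline configuration
#'
#' Collects the knobs of the end-to-end analysis. The effective
#' configuration is serialized into a canonical `config_digest` string that
#' is stamped on every per-image result and output file, so any two outputs
#' computed under different settings are distinguishable. Unknown keys are
#' rejected.
#'
#' @param catalog_path path to the catalog CSV.
#' @param output_dir directory for outputs (created if needed).
#' @param metric headline contrast scale, `"rms"` (default) or `"variance"`.
#' @param sidedness test sidedness, `"two_sided"` (default) or
#'   `"one_sided_greater"`.
#' @param acf_mode `"circular"` or `"linear_unbiased"` (affects the ACF
#'   profile only; lag-0 contrast is identical).
#' @param crop_fraction fraction in [0, 0.4] cropped from each image edge
#'   before analysis (frames/mats); default 0.
#' @param max_dim if finite, images larger than this in either dimension are
#'   box-downsampled to at most `max_dim`; default `Inf` (off).
#' @param linearize_srgb decode sRGB gamma before the luma weights
#'   (default `FALSE`).
#' @param seed integer seed recorded in outputs.
#' @param log_level `"info"` or `"quiet"`.
#' @param skip_errors if `TRUE`, unreadable images are logged and skipped
#'   instead of failing the run.
#' @param ... rejected; present to catch misspelled keys.
#' @return a `pipeline_config` list with a `config_digest` element.
#' @export
pipeline_config <- function(catalog_path = NULL, output_dir = ".",
                            metric = c("rms", "variance"),
                            sidedness = c("two_sided", "one_sided_greater"),
                            acf_mode = c("circular", "linear_unbiased"),
                            crop_fraction = 0, max_dim = Inf,
                            linearize_srgb = FALSE, seed = 1L,
                            log_level = c("info", "quiet"),
                            skip_errors = FALSE, ...) {
  extra <- list(...)
  if (length(extra) > 0L) {
    stop("unknown configuration key(s): ",
         paste(names(extra), collapse = ", "))
  }
  metric <- match.arg(metric)
  sidedness <- match.arg(sidedness)
  acf_mode <- match.arg(acf_mode)
  log_level <- match.arg(log_level)
  if (crop_fraction < 0 || crop_fraction > 0.4) {
    stop("crop_fraction must lie in [0, 0.4]")
  }
  cfg <- list(catalog_path = catalog_path, output_dir = output_dir,
              metric = metric, sidedness = sidedness, acf_mode = acf_mode,
              crop_fraction = crop_fraction, max_dim = max_dim,
              linearize_srgb = isTRUE(linearize_srgb),
              seed = as.integer(seed), log_level = log_level,
              skip_errors = isTRUE(skip_errors))
  cfg$config_digest <- config_digest(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

# canonical, deterministic serialization of the analysis-relevant settings
config_digest <- function(cfg) {
  paste(
    sprintf("metric=%s", cfg$metric),
    sprintf("sidedness=%s", cfg$sidedness),
    sprintf("acf=%s", cfg$acf_mode),
    sprintf("crop=%g", cfg$crop_fraction),
    sprintf("maxdim=%s", if (is.finite(cfg$max_dim)) cfg$max_dim else "none"),
    sprintf("srgb=%d", as.integer(cfg$linearize_srgb)),
    sprintf("seed=%d", cfg$seed),
    sep = ";"
  )
}

log_msg <- function(cfg, fmt, ...) {
  if (identical(cfg$log_level, "info")) {
    message(sprintf(paste0("[imagecontrast] ", fmt), ...))
  }
}

# crop a stated fraction from each edge, keeping at least 1 pixel each way
crop_image <- function(img, fraction) {
  if (fraction <= 0) return(img)
  h <- img$height; w <- img$width
  dh <- min(floor(h * fraction), (h - 1L) %/% 2L)
  dw <- min(floor(w * fraction), (w - 1L) %/% 2L)
  rgb_image(img$pixels[(dh + 1L):(h - dh), (dw + 1L):(w - dw), , drop = FALSE],
            source_id = img$source_id)
}

# box-average downsample so that max(H, W) <= max_dim
downsample_image <- function(img, max_dim) {
  if (!is.finite(max_dim) || max(img$height, img$width) <= max_dim) return(img)
  f <- ceiling(max(img$height, img$width) / max_dim)
  h2 <- img$height %/% f; w2 <- img$width %/% f
  px <- img$pixels[seq_len(h2 * f), seq_len(w2 * f), , drop = FALSE]
  out <- array(0, dim = c(h2, w2, 3))
  for (ch in 1:3) {
    m <- px[, , ch]
    # average f x f blocks
    m <- matrix(colMeans(matrix(m, nrow = f)), nrow = h2)        # rows
    m <- t(matrix(colMeans(matrix(t(m), nrow = f)), nrow = w2))  # cols
    out[, , ch] <- m
  }
  rgb_image(round(out), source_id = img$source_id)
}

# contrast of one rgb_image under a config
contrast_one <- function(img, cfg, image_id = img$source_id) {
  img <- crop_image(img, cfg$crop_fraction)
  img <- downsample_image(img, cfg$max_dim)
  fld <- rgb_to_luminance(img, linearize_srgb = cfg$linearize_srgb)
  image_contrast(fld, image_id = image_id, config_digest = cfg$config_digest)
}

#' Run the per-image contrast stage
#'
#' Loads every catalog image, computes its contrast, and writes one CSV row
#' per record (columns `image_id`, `order_index`, `condition`,
#' `variance_contrast`, `rms_contrast`, `height`, `width`, `config_digest`)
#' to `contrasts.csv` under the configured output directory. Deterministic
#' given the config and inputs.
#'
#' @param config a `pipeline_config` with `catalog_path` set.
#' @return the per-image results data.frame, invisibly; the CSV path is in
#'   attribute `"path"`.
#' @export
run_contrast <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$catalog_path)) stop("config$catalog_path is not set")
  catalog <- load_catalog(config$catalog_path)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", nrow(catalog))
  failed <- character()
  for (i in seq_len(nrow(catalog))) {
    rec <- catalog[i, ]
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      img <- load_image(rec$path, source_id = rec$image_id)
      contrast_one(img, config, image_id = rec$image_id)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      log_msg(config, "ERROR %s: %s", rec$image_id, conditionMessage(res))
      failed <- c(failed, rec$image_id)
      next
    }
    log_msg(config, "%s  %dx%d  rms=%.4f  (%.2fs)", rec$image_id,
            res$height, res$width, res$rms_contrast,
            proc.time()[["elapsed"]] - t0)
    rows[[i]] <- data.frame(
      image_id = rec$image_id, order_index = rec$order_index,
      condition = as.character(rec$condition),
      variance_contrast = res$variance_contrast,
      rms_contrast = res$rms_contrast,
      height = res$height, width = res$width,
      config_digest = res$config_digest,
      stringsAsFactors = FALSE
    )
  }
  if (length(failed) > 0L && !config$skip_errors) {
    stop("failed to process image(s): ", paste(failed, collapse = ", "))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  path <- file.path(config$output_dir, "contrasts.csv")
  utils::write.csv(out, path, row.names = FALSE)
  attr(out, "path") <- path
  invisible(out)
}

#' Run the two-condition comparison stage
#'
#' Reads the per-image contrast CSV produced by [run_contrast()], performs
#' the rank-based condition comparison on the configured metric, writes the
#' result to `comparison.json`, and renders the chronological timeline plot
#' (contrast vs order index, condition color-coded) to `timeline.png` (or
#' `.svg` if PNG rendering is unavailable on the host).
#'
#' @param config a `pipeline_config`.
#' @param contrasts_path path to the contrast CSV; defaults to
#'   `contrasts.csv` under the configured output directory.
#' @return the `group_comparison`, invisibly; file paths are in attributes
#'   `"json_path"` and `"plot_path"`.
#' @export
run_compare <- function(config,
                        contrasts_path = file.path(config$output_dir,
                                                   "contrasts.csv")) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!file.exists(contrasts_path)) {
    stop("contrast CSV does not exist: ", contrasts_path)
  }
  tab <- utils::read.csv(contrasts_path, stringsAsFactors = FALSE)
  cmp <- compare_conditions(tab, metric = config$metric,
                            sidedness = config$sidedness)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  json_path <- file.path(config$output_dir, "comparison.json")
  jsonlite::write_json(
    list(u_statistic = cmp$u_statistic, p_value = cmp$p_value,
         method = cmp$method, sidedness = cmp$sidedness,
         n_low = cmp$n_low, n_high = cmp$n_high,
         median_low = cmp$median_low, median_high = cmp$median_high,
         metric = config$metric, config_digest = config$config_digest),
    json_path, auto_unbox = TRUE, digits = NA)
  plot_path <- tryCatch(
    plot_timeline(tab, config, file.path(config$output_dir, "timeline")),
    error = function(e) {
      log_msg(config, "timeline plot skipped: %s", conditionMessage(e))
      NA_character_
    })
  log_msg(config, "U=%.3g p=%.4g (%s) -> %s", cmp$u_statistic, cmp$p_value,
          cmp$method, json_path)
  attr(cmp, "json_path") <- json_path
  attr(cmp, "plot_path") <- plot_path
  invisible(cmp)
}

#' Plot the chronological contrast timeline
#'
#' Ordered line-and-points plot of per-image contrast against chronological
#' rank with the two exposure conditions color-coded.
#'
#' @param tab data.frame with `order_index`, `condition`, and the contrast
#'   columns.
#' @param config a `pipeline_config` (chooses the metric).
#' @param stem output path without extension.
#' @return the written file path.
#' @export
plot_timeline <- function(tab, config, stem) {
  col <- if (config$metric == "rms") "rms_contrast" else "variance_contrast"
  tab <- tab[order(tab$order_index), , drop = FALSE]
  path <- paste0(stem, ".png")
  opened <- tryCatch({ grDevices::png(path, 900, 540); TRUE },
                     error = function(e) FALSE)
  if (!opened) {
    path <- paste0(stem, ".svg")
    grDevices::svg(path, width = 9, height = 5.4)
  }
  on.exit(grDevices::dev.off())
  cols <- ifelse(tab$condition == "high", "#d62728", "#1f77b4")
  graphics::plot(tab$order_index, tab[[col]], type = "l", col = "grey60",
                 xlab = "chronological order", ylab = paste(config$metric,
                                                            "contrast"),
                 main = "Image contrast timeline",
                 ylim = c(0, max(0.5, tab[[col]])))
  graphics::points(tab$order_index, tab[[col]], pch = 19, col = cols)
  graphics::legend("topleft", legend = c("low exposure", "high exposure"),
                   col = c("#1f77b4", "#d62728"), pch = 19, bty = "n")
  path
}
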