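#' Assemble the chronological contrast timeline
#'
#' Joins catalog records with per-image contrast results on `image_id` and
#' orders the merged table by chronological rank, producing the series the
#' timeline plot and the two-condition comparison consume.
#'
#' @param records a `catalog` data.frame (see [load_catalog()]).
#' @param contrasts list of `contrast_result` objects, one per record.
#' @return a `cohort_table` data.frame with columns `image_id`, `order_index`,
#'   `date_label`, `condition`, `variance_contrast`, `rms_contrast`, sorted
#'   ascending by `order_index`.
#' @export
assemble_timeline <- function(records, contrasts) {
  if (nrow(records) == 0L && length(contrasts) == 0L) {
    out <- data.frame(image_id = character(), order_index = integer(),
                      date_label = character(),
                      condition = factor(character(), levels = c("low", "high")),
                      variance_contrast = numeric(), rms_contrast = numeric())
    class(out) <- c("cohort_table", "data.frame")
    return(out)
  }
  ids <- vapply(contrasts, function(x) x$image_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate image_id among contrast results: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  missing_res <- setdiff(records$image_id, ids)
  if (length(missing_res) > 0L) {
    stop("no contrast result for image_id: ",
         paste(missing_res, collapse = ", "))
  }
  extra <- setdiff(ids, records$image_id)
  if (length(extra) > 0L) {
    stop("contrast result without catalog record: ",
         paste(extra, collapse = ", "))
  }
  m <- match(records$image_id, ids)
  out <- data.frame(
    image_id = records$image_id,
    order_index = records$order_index,
    date_label = records$date_label,
    condition = records$condition,
    variance_contrast = vapply(contrasts[m],
                               function(x) x$variance_contrast, numeric(1)),
    rms_contrast = vapply(contrasts[m],
                          function(x) x$rms_contrast, numeric(1)),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$order_index), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cohort_table", "data.frame")
  out
}

# ---- exact Mann-Whitney U null distribution --------------------------------
#
# Counts of rank configurations by U value for tie-free samples of sizes
# n and m, via the standard recursion
#   N(u; n, m) = N(u - m; n - 1, m) + N(u; n, m - 1),
# i.e. the coefficients of the Gaussian binomial [n + m choose n]_q.
# Counts sum to choose(n + m, n). Cached per (n, m) within the session.

.u_cache <- new.env(parent = emptyenv())

u_null_counts <- function(n, m) {
  if (n > m) { tmp <- n; n <- m; m <- tmp }  # symmetric in (n, m)
  key <- paste(n, m, sep = "_")
  hit <- .u_cache[[key]]
  if (!is.null(hit)) return(hit)
  prev <- rep(list(1), m + 1L)               # n' = 0: only U = 0
  if (n > 0L) {
    for (nn in seq_len(n)) {
      cur <- vector("list", m + 1L)
      cur[[1L]] <- 1                         # m' = 0: only U = 0
      for (mm in seq_len(m)) {
        len <- nn * mm + 1L
        av <- c(rep(0, mm), prev[[mm + 1L]]) # N(u - mm; nn - 1, mm)
        bv <- cur[[mm]]                      # N(u; nn, mm - 1)
        length(av) <- len; length(bv) <- len
        av[is.na(av)] <- 0; bv[is.na(bv)] <- 0
        cur[[mm + 1L]] <- av + bv
      }
      prev <- cur
    }
  }
  counts <- prev[[m + 1L]]
  .u_cache[[key]] <- counts
  counts
}

# P(U <= u) under the exact tie-free null
u_null_cdf <- function(u, n, m) {
  counts <- u_null_counts(n, m)
  u <- min(max(floor(u), -1), n * m)
  if (u < 0) return(0)
  sum(counts[seq_len(u + 1L)]) / sum(counts)
}

#' Mann-Whitney U test
#'
#' Rank-based two-sample comparison with a self-contained exact null
#' distribution. Ranks use mid-ranks for ties; the U statistics are
#' \eqn{U_a = R_a - n_a(n_a+1)/2} and \eqn{U_b = n_a n_b - U_a}. For tie-free
#' data with \eqn{n_a + n_b \le} `exact_threshold` the p-value is exact,
#' from the full null distribution of U obtained by the standard count
#' recursion (equivalent to enumerating all \eqn{C(n_a+n_b, n_a)} rank
#' splits); otherwise a normal approximation with tie correction and
#' continuity correction is used. The two-sided exact p is
#' \eqn{\min(1, 2 P(U \le \min(U_a, U_b)))}; the one-sided alternative is
#' that `group_b` is stochastically greater than `group_a`.
#'
#' @param group_a,group_b non-empty numeric vectors.
#' @param sidedness `"two_sided"` or `"one_sided_greater"` (b > a).
#' @param exact_threshold largest total sample size for which the exact
#'   distribution is used (default 28, covering the 19-vs-9 design exactly).
#' @return a `group_comparison`: list with `u_statistic` (min(U_a, U_b) for
#'   two-sided, U_a for one-sided), `p_value`, `method` (`"exact"` or
#'   `"normal_approx"`), `sidedness`, `n_low`/`n_high` (sizes of a/b),
#'   `median_low`/`median_high`.
#' @export
mann_whitney_u <- function(group_a, group_b,
                           sidedness = c("two_sided", "one_sided_greater"),
                           exact_threshold = 28L) {
  sidedness <- match.arg(sidedness)
  group_a <- as.numeric(group_a); group_b <- as.numeric(group_b)
  if (length(group_a) == 0L || length(group_b) == 0L) {
    stop("both groups must be non-empty")
  }
  if (anyNA(group_a) || anyNA(group_b)) stop("missing values in groups")
  na <- length(group_a); nb <- length(group_b)
  pooled <- c(group_a, group_b)
  rk <- rank(pooled)  # mid-ranks for ties
  ua <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  ub <- na * nb - ua
  ties <- anyDuplicated(pooled) > 0L
  use_exact <- !ties && (na + nb) <= exact_threshold

  if (use_exact) {
    method <- "exact"
    if (sidedness == "two_sided") {
      p <- min(1, 2 * u_null_cdf(min(ua, ub), na, nb))
    } else {
      # b > a pushes a's ranks down, so evidence is small U_a
      p <- u_null_cdf(ua, na, nb)
    }
  } else {
    method <- "normal_approx"
    n <- na + nb
    mu <- na * nb / 2
    tie_tab <- table(pooled)
    tie_term <- sum(tie_tab^3 - tie_tab)
    sigma2 <- na * nb / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      sigma <- sqrt(sigma2)
      if (sidedness == "two_sided") {
        umin <- min(ua, ub)
        z <- (umin - mu + 0.5) / sigma  # continuity correction
        p <- min(1, 2 * stats::pnorm(z))
      } else {
        z <- (ua - mu + 0.5) / sigma
        p <- stats::pnorm(z)
      }
    }
  }
  structure(
    list(u_statistic = if (sidedness == "two_sided") min(ua, ub) else ua,
         u_a = ua, u_b = ub,
         p_value = p, method = method, sidedness = sidedness,
         n_low = na, n_high = nb,
         median_low = stats::median(group_a),
         median_high = stats::median(group_b)),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "<group_comparison> U=%.4g  p=%.4g  (%s, %s; n=%d vs %d; medians %.4g vs %.4g)\n",
    x$u_statistic, x$p_value, x$method, x$sidedness,
    x$n_low, x$n_high, x$median_low, x$median_high))
  invisible(x)
}

#' Compare contrast between exposure conditions
#'
#' Splits a cohort table by condition and runs [mann_whitney_u()] on the
#' chosen contrast metric, with `low` as group a and `high` as group b. The
#' U statistic (hence the p-value) is identical for the `variance` and `rms`
#' metrics because ranks are invariant under strictly increasing transforms.
#'
#' @param table a `cohort_table` containing both condition labels.
#' @param metric `"rms"` (default headline scale) or `"variance"`.
#' @param sidedness passed to [mann_whitney_u()].
#' @param exact_threshold passed to [mann_whitney_u()].
#' @return a `group_comparison`.
#' @export
compare_conditions <- function(table, metric = c("rms", "variance"),
                               sidedness = c("two_sided", "one_sided_greater"),
                               exact_threshold = 28L) {
  metric <- match.arg(metric)
  sidedness <- match.arg(sidedness)
  stopifnot(inherits(table, "data.frame"))
  cond <- as.character(table$condition)
  missing_cond <- setdiff(c("low", "high"), unique(cond))
  if (length(missing_cond) > 0L) {
    stop("condition(s) absent from table: ",
         paste(missing_cond, collapse = ", "))
  }
  col <- if (metric == "rms") "rms_contrast" else "variance_contrast"
  if (anyNA(table[[col]])) stop("missing contrast values in table")
  mann_whitney_u(table[[col]][cond == "low"], table[[col]][cond == "high"],
                 sidedness = sidedness, exact_threshold = exact_threshold)
}
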