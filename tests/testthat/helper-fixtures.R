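# shared fixture builders; everything is generated in code at test time

fixture_catalog_path <- function() {
  system.file("extdata", "selfportraits_catalog_synthetic.csv",
              package = "imagecontrast")
}

# random mean-centered matrix
rand_centered <- function(h, w, seed) {
  set.seed(seed)
  z <- matrix(stats::rnorm(h * w), h, w)
  z - mean(z)
}

# random valid luminance field
rand_field <- function(h, w, seed) {
  set.seed(seed)
  luminance_field(matrix(stats::runif(h * w), h, w))
}

# max |fft - direct| over all lags the direct estimate computed
max_acf_diff <- function(fftf, dirf, max_lag) {
  lags <- -max_lag:max_lag
  m <- sapply(lags, function(da)
    sapply(lags, function(db) acf_at(fftf, da, db) - acf_at(dirf, da, db)))
  max(abs(m))
}

# brute-force Mann-Whitney oracle: enumerate every rank split of tie-free data
enumerate_mw_p <- function(a, b, sidedness = "two_sided") {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  rk <- rank(pooled)
  ua_obs <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  ub_obs <- na * nb - ua_obs
  splits <- utils::combn(na + nb, na)
  u_all <- apply(splits, 2, function(idx) sum(seq_len(na + nb)[idx]) -
                   na * (na + 1) / 2)
  if (sidedness == "two_sided") {
    min(1, 2 * mean(u_all <= min(ua_obs, ub_obs)))
  } else {
    mean(u_all <= ua_obs)
  }
}

# minimal hand-assembled 16-bit grayscale PNG (png::writePNG only writes
# 8-bit); k is a vector of 0..65535 samples forming a 1 x length(k) image
write_png16_gray <- function(k, path) {
  xor32 <- function(a, b) {
    bitwXor(a %/% 65536, b %/% 65536) * 65536 + bitwXor(a %% 65536, b %% 65536)
  }
  crc_tab <- local({
    t <- numeric(256)
    for (n in 0:255) {
      c <- n
      for (i in 1:8) c <- if (c %% 2) xor32(c %/% 2, 3988292384) else c %/% 2
      t[n + 1] <- c
    }
    t
  })
  crc32 <- function(bytes) {
    crc <- 4294967295
    for (b in as.integer(bytes)) {
      crc <- xor32(crc_tab[bitwXor(crc %% 256, b) + 1], crc %/% 256)
    }
    xor32(crc, 4294967295)
  }
  be <- function(x, n) as.raw((x %/% 256^((n - 1):0)) %% 256)
  chunk <- function(type, data) {
    body <- c(as.raw(utf8ToInt(type)), data)
    c(be(length(data), 4), body, be(crc32(body), 4))
  }
  ihdr <- c(be(length(k), 4), be(1, 4), as.raw(c(16, 0, 0, 0, 0)))
  scan <- as.raw(c(0, rbind(k %/% 256, k %% 256)))  # filter 0 + BE samples
  z <- memCompress(scan, "gzip")  # R quirk: "gzip" yields a zlib stream
  writeBin(c(as.raw(c(0x89, 0x50, 0x4E, 0x47, 0x0D, 0x0A, 0x1A, 0x0A)),
             chunk("IHDR", ihdr), chunk("IDAT", z), chunk("IEND", raw(0))),
           path)
  path
}

# write a tiny ASCII PPM (color) or PGM (gray) file; arr is HxWx3 or HxW, 0..255
write_ppm <- function(arr, path) {
  if (length(dim(arr)) == 3L) {
    h <- dim(arr)[1]; w <- dim(arr)[2]
    vals <- integer(0)
    for (i in seq_len(h)) for (j in seq_len(w)) vals <- c(vals, arr[i, j, ])
    writeLines(c("P3", paste(w, h), "255", paste(vals, collapse = " ")), path)
  } else {
    h <- nrow(arr); w <- ncol(arr)
    writeLines(c("P2", paste(w, h), "255",
                 paste(as.vector(t(arr)), collapse = " ")), path)
  }
  path
}
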