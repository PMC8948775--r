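# Independent brute-force oracles and simple rasterizers used across tests.
# These deliberately share nothing with the package implementation beyond
# the definitions under test (offset conventions, ring binning rule).

# explicit pixel-pair enumeration GLCM entropy: loops every pixel, tallies a
# dictionary of (i, j) counts for pairs with both pixels inside the mask
oracle_glcm_entropy <- function(q, offsets, symmetric = TRUE, base = 2) {
  counts <- new.env(parent = emptyenv())
  add <- function(i, j) {
    key <- paste(i, j)
    assign(key, (if (exists(key, counts)) get(key, counts) else 0) + 1, counts)
  }
  per_angle <- vapply(offsets, function(off) {
    rm(list = ls(counts), envir = counts)
    n_pairs <- 0
    for (r in seq_len(nrow(q))) for (cc in seq_len(ncol(q))) {
      r2 <- r + off[1]; c2 <- cc + off[2]
      if (r2 < 1 || r2 > nrow(q) || c2 < 1 || c2 > ncol(q)) next
      i <- q[r, cc]; j <- q[r2, c2]
      if (is.na(i) || is.na(j)) next
      add(i, j)
      if (symmetric) add(j, i)
      n_pairs <- n_pairs + 1
    }
    if (n_pairs == 0) return(NA_real_)
    cnt <- unlist(mget(ls(counts), envir = counts))
    p <- cnt / sum(cnt)
    -sum(p * log(p, base = base))
  }, numeric(1))
  mean(per_angle)
}

# per-pixel distance binning density profile (loop form)
oracle_ring_occupancy <- function(mask, centroid, ring_width) {
  fg <- c(); tot <- c()
  for (r in seq_len(nrow(mask))) for (cc in seq_len(ncol(mask))) {
    d <- sqrt((r - 1 - centroid[1])^2 + (cc - 1 - centroid[2])^2)
    b <- floor(d / ring_width) + 1
    if (b > length(tot)) {
      tot <- c(tot, rep(0, b - length(tot)))
      fg <- c(fg, rep(0, b - length(fg)))
    }
    tot[b] <- tot[b] + 1
    if (mask[r, cc] > 0) fg[b] <- fg[b] + 1
  }
  list(occupancy = ifelse(tot > 0, fg / tot, 0), fg = fg, total = tot)
}

# analytic rasterizers (independent of the phantom generator)
disk_mask <- function(n, radius, center = c((n - 1) / 2, (n - 1) / 2)) {
  d <- sqrt(outer(((seq_len(n) - 1) - center[1])^2,
                  ((seq_len(n) - 1) - center[2])^2, `+`))
  matrix(as.integer(d <= radius), n, n)
}

star_mask <- function(n, radius, k, amplitude, phase = 0) {
  ctr <- (n - 1) / 2
  dr <- (seq_len(n) - 1) - ctr
  d <- sqrt(outer(dr^2, dr^2, `+`))
  th <- atan2(outer(rep(1, n), dr), outer(dr, rep(1, n)))
  matrix(as.integer(d <= radius * (1 + amplitude * cos(k * th + phase))), n, n)
}

rot90_mat <- function(m) t(m[nrow(m):1, , drop = FALSE])

# quantized raster with the attribute glcm_entropy() expects
as_quantized <- function(q, levels) {
  mode(q) <- "integer"
  attr(q, "levels") <- as.integer(levels)
  q
}

expect_one_component <- function(mask) {
  m <- if (inherits(mask, "spheroid_mask")) mask$pixels else mask
  lab <- EBImage::bwlabel(m > 0)
  expect_equal(as.integer(max(lab)), 1L)
}
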