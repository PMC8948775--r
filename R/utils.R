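# Internal geometry and morphology helpers.
# Coordinate convention (documented in README): (row, col), 0-based,
# pixel centers at integer coordinates. R matrices are 1-based, so pixel
# (i, j) in a matrix sits at 0-based coordinate (i - 1, j - 1).

# 0-based foreground centroid (row, col)
mask_centroid <- function(m) {
  idx <- which(m > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask has no centroid")
  c(row = mean(idx[, 1]) - 1, col = mean(idx[, 2]) - 1)
}

# Euclidean distance of every pixel from a 0-based (row, col) point
pixel_distances <- function(nr, nc, center) {
  dr <- (seq_len(nr) - 1) - center[[1]]
  dc <- (seq_len(nc) - 1) - center[[2]]
  sqrt(outer(dr^2, dc^2, `+`))
}

# largest 4-connected component of a binary matrix (EBImage::bwlabel is
# 4-connected); returns 0/1 matrix, or NULL when the mask is empty
largest_component <- function(m) {
  if (!any(m > 0)) return(NULL)
  lab <- EBImage::bwlabel(m > 0)
  counts <- tabulate(lab[lab > 0])
  keep <- which.max(counts)
  matrix(as.integer(lab == keep), nrow(m), ncol(m))
}

n_components <- function(m) {
  if (!any(m > 0)) return(0L)
  max(EBImage::bwlabel(m > 0))
}

# circular moving average, window forced odd
circular_smooth <- function(x, window) {
  n <- length(x)
  window <- max(3L, as.integer(window))
  if (window %% 2L == 0L) window <- window + 1L
  if (window >= n) window <- if (n %% 2L == 1L) n else n - 1L
  h <- (window - 1L) %/% 2L
  xx <- c(x[(n - h + 1L):n], x, x[1L:h])
  as.numeric(stats::filter(xx, rep(1 / window, window), sides = 2))[(h + 1L):(h + n)]
}

# Local maxima of a circular series with topographic prominence.
# A candidate rises strictly from the left and does not rise to the right;
# its prominence is height minus the higher of the two key saddles (minimum
# along the path to higher ground on each side; the global minimum when no
# higher ground exists, e.g. the global maximum of the series).
circular_peaks <- function(x, min_prominence) {
  n <- length(x)
  if (n < 3L || diff(range(x)) == 0) {
    return(data.frame(index = integer(), height = numeric(),
                      prominence = numeric()))
  }
  left  <- x[c(n, seq_len(n - 1L))]
  right <- x[c(seq.int(2L, n), 1L)]
  cand <- which(x > left & x >= right)
  if (length(cand) == 0L) {
    return(data.frame(index = integer(), height = numeric(),
                      prominence = numeric()))
  }
  prom <- vapply(cand, function(p) {
    h <- x[p]
    saddle <- function(step) {
      lo <- h
      i <- p
      for (k in seq_len(n - 1L)) {
        i <- ((i - 1L + step) %% n) + 1L
        if (x[i] > h) return(lo)
        if (x[i] < lo) lo <- x[i]
      }
      lo  # wrapped all the way round: global max, saddle = global min
    }
    h - max(saddle(1L), saddle(-1L))
  }, numeric(1))
  keep <- prom >= min_prominence
  data.frame(index = cand[keep], height = x[cand[keep]],
             prominence = prom[keep])
}

# odd-sized disc structuring element for EBImage morphology
disc_brush <- function(radius) {
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}

is_binary <- function(m) all(m %in% c(0, 1))

`%||%` <- function(a, b) if (is.null(a)) b else a
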