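# internal helpers shared across modules

# evaluate `code` with a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# column-wise cumulative sums in one pass over the whole matrix (a global
# cumsum with per-column offsets removed); used where smoothing accuracy at
# the last digit is irrelevant (surface detection, ray profiles) -- the OAC
# fit itself never goes through this path
col_cumsum <- function(X) {
  m <- nrow(X); n <- ncol(X)
  v <- cumsum(as.vector(X))
  tot <- v[m * seq_len(n)]
  matrix(v - rep(c(0, tot[-n]), each = m), m, n)
}

# centered moving average of width w along the rows (first dim) of a matrix,
# truncated at the ends; NA treated as missing (excluded from the mean)
box_smooth_rows <- function(m, w) {
  if (w <= 1L) return(m)
  n <- nrow(m)
  h <- (w - 1L) %/% 2L
  v <- is.finite(m)
  m0 <- m
  m0[!v] <- 0
  cs <- rbind(0, col_cumsum(m0))
  cn <- rbind(0, col_cumsum(v + 0))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  s <- cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]
  k <- cn[hi + 1L, , drop = FALSE] - cn[lo, , drop = FALSE]
  out <- s / k
  out[k == 0] <- NA_real_
  out
}

# 3x3 median filter on a matrix, restricted to `valid` entries; invalid
# entries stay untouched (NA-aware: median over the valid neighbours only)
median3x3 <- function(m, valid = NULL) {
  nx <- nrow(m)
  ny <- ncol(m)
  if (is.null(valid)) valid <- !is.na(m)
  mm <- m
  mm[!valid] <- NA_real_
  shifts <- expand.grid(dx = -1:1, dy = -1:1)
  stack <- array(NA_real_, dim = c(nx, ny, nrow(shifts)))
  for (s in seq_len(nrow(shifts))) {
    dx <- shifts$dx[s]; dy <- shifts$dy[s]
    xs <- seq_len(nx) + dx
    ys <- seq_len(ny) + dy
    okx <- xs >= 1L & xs <= nx
    oky <- ys >= 1L & ys <= ny
    stack[which(okx), which(oky), s] <- mm[xs[okx], ys[oky]]
  }
  # NA-aware median of the 9 neighbours, vectorized: sort each 9-stack with
  # NA as +Inf, then read the middle of the valid prefix
  P <- nx * ny
  M9 <- t(matrix(stack, P, 9))
  M9[is.na(M9)] <- Inf
  S <- matrix(M9[order(col(M9), M9)], 9L, P)
  k <- colSums(is.finite(S))
  p <- seq_len(P)[k > 0]
  med <- rep(NA_real_, P)
  med[p] <- (S[cbind(floor((k[p] + 1) / 2), p)] +
               S[cbind(ceiling((k[p] + 1) / 2), p)]) / 2
  med <- matrix(med, nx, ny)
  out <- m
  out[valid & !is.na(med)] <- med[valid & !is.na(med)]
  out
}

# truncated Gaussian band matrix used for separable smoothing; rows are NOT
# normalized (normalization happens against the convolved mask so that edges
# and missing pixels are handled by renormalized weights)
gaussian_band <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- max(1L, ceiling(4 * sigma))
  i <- seq_len(n)
  d <- outer(i, i, "-")
  k <- exp(-d^2 / (2 * sigma^2))
  k[abs(d) > r] <- 0
  k
}

# bilinear interpolation of matrix m at fractional indices (xi, yi);
# returns NA where any contributing pixel is NA or out of bounds
interp2 <- function(m, xi, yi) {
  nx <- nrow(m); ny <- ncol(m)
  x0 <- floor(xi); y0 <- floor(yi)
  fx <- xi - x0; fy <- yi - y0
  ok <- x0 >= 1 & x0 + 1 <= nx & y0 >= 1 & y0 + 1 <= ny
  out <- rep(NA_real_, length(xi))
  if (!any(ok)) return(out)
  x0 <- x0[ok]; y0 <- y0[ok]; fxo <- fx[ok]; fyo <- fy[ok]
  i00 <- cbind(x0, y0); i10 <- cbind(x0 + 1, y0)
  i01 <- cbind(x0, y0 + 1); i11 <- cbind(x0 + 1, y0 + 1)
  out[ok] <- m[i00] * (1 - fxo) * (1 - fyo) + m[i10] * fxo * (1 - fyo) +
    m[i01] * (1 - fxo) * fyo + m[i11] * fxo * fyo
  out
}

# column medians via a single order() call (sorts within columns); falls
# back to apply() when NAs are present
col_medians <- function(X) {
  if (anyNA(X)) return(apply(X, 2, median, na.rm = TRUE))
  m <- nrow(X); n <- ncol(X)
  Xs <- matrix(X[order(col(X), X)], m, n)
  if (m %% 2L == 1L) Xs[(m + 1L) %/% 2L, ]
  else (Xs[m %/% 2L, ] + Xs[m %/% 2L + 1L, ]) / 2
}

fmt_num <- function(x) format(x, digits = 17, scientific = TRUE, trim = TRUE)

stop_validation <- function(...) stop(..., call. = FALSE)
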