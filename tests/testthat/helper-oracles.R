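# Brute-force reference implementations of the five texture matrices,
# written as direct pixel-by-pixel enumerations. They are deliberately
# slow and independent of the package's vectorized builders; agreement on
# random small images is the primary correctness check.

oracleOffsets <- list(`0` = c(0L, 1L), `45` = c(-1L, 1L),
                      `90` = c(-1L, 0L), `135` = c(-1L, -1L))

oracleGLCM <- function(lv, nL, direction, distance = 1L) {
  off <- oracleOffsets[[as.character(direction)]] * distance
  out <- matrix(0, nL, nL)
  for (r in seq_len(nrow(lv))) for (c in seq_len(ncol(lv))) {
    r2 <- r + off[1L]; c2 <- c + off[2L]
    if (r2 >= 1 && r2 <= nrow(lv) && c2 >= 1 && c2 <= ncol(lv)) {
      a <- lv[r, c] + 1L; b <- lv[r2, c2] + 1L
      out[a, b] <- out[a, b] + 1
      out[b, a] <- out[b, a] + 1
    }
  }
  out
}

oracleGLRLM <- function(lv, nL, direction) {
  off <- oracleOffsets[[as.character(direction)]]
  h <- nrow(lv); w <- ncol(lv)
  runs <- list()
  inImg <- function(r, c) r >= 1 && r <= h && c >= 1 && c <= w
  for (r in seq_len(h)) for (c in seq_len(w)) {
    # start of a maximal run: predecessor missing or different level
    pr <- r - off[1L]; pc <- c - off[2L]
    if (inImg(pr, pc) && lv[pr, pc] == lv[r, c]) next
    len <- 1L; cr <- r + off[1L]; cc <- c + off[2L]
    while (inImg(cr, cc) && lv[cr, cc] == lv[r, c]) {
      len <- len + 1L; cr <- cr + off[1L]; cc <- cc + off[2L]
    }
    runs[[length(runs) + 1L]] <- c(lv[r, c] + 1L, len)
  }
  maxR <- max(vapply(runs, `[`, integer(1), 2L))
  out <- matrix(0, nL, maxR)
  for (rn in runs) out[rn[1L], rn[2L]] <- out[rn[1L], rn[2L]] + 1
  out
}

oracleGLSZM <- function(lv, nL, connectivity = 8L) {
  h <- nrow(lv); w <- ncol(lv)
  seen <- matrix(FALSE, h, w)
  nb <- if (connectivity == 8L)
    expand.grid(dr = -1:1, dc = -1:1) else
    data.frame(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  nb <- nb[!(nb$dr == 0 & nb$dc == 0), ]
  zones <- list()
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (seen[r, c]) next
    g <- lv[r, c]
    stack <- list(c(r, c)); seen[r, c] <- TRUE; size <- 0L
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      size <- size + 1L
      for (k in seq_len(nrow(nb))) {
        nr <- p[1L] + nb$dr[k]; nc <- p[2L] + nb$dc[k]
        if (nr >= 1 && nr <= h && nc >= 1 && nc <= w &&
            !seen[nr, nc] && lv[nr, nc] == g) {
          seen[nr, nc] <- TRUE
          stack[[length(stack) + 1L]] <- c(nr, nc)
        }
      }
    }
    zones[[length(zones) + 1L]] <- c(g + 1L, size)
  }
  maxS <- max(vapply(zones, `[`, integer(1), 2L))
  out <- matrix(0, nL, maxS)
  for (z in zones) out[z[1L], z[2L]] <- out[z[1L], z[2L]] + 1
  out
}

oracleGLDM <- function(lv, nL, alpha = 0L, distance = 1L) {
  h <- nrow(lv); w <- ncol(lv)
  maxDep <- (2L * distance + 1L)^2 - 1L
  out <- matrix(0, nL, maxDep + 1L)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    dep <- 0L
    for (dr in -distance:distance) for (dc in -distance:distance) {
      if (dr == 0L && dc == 0L) next
      nr <- r + dr; nc <- c + dc
      if (nr >= 1 && nr <= h && nc >= 1 && nc <= w &&
          abs(lv[nr, nc] - lv[r, c]) <= alpha) dep <- dep + 1L
    }
    out[lv[r, c] + 1L, dep + 1L] <- out[lv[r, c] + 1L, dep + 1L] + 1
  }
  out
}

oracleNGTDM <- function(lv, nL, distance = 1L) {
  h <- nrow(lv); w <- ncol(lv)
  n_i <- s_i <- numeric(nL)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    vals <- c()
    for (dr in -distance:distance) for (dc in -distance:distance) {
      if (dr == 0L && dc == 0L) next
      nr <- r + dr; nc <- c + dc
      if (nr >= 1 && nr <= h && nc >= 1 && nc <= w)
        vals <- c(vals, lv[nr, nc])
    }
    g <- lv[r, c] + 1L
    n_i[g] <- n_i[g] + 1
    s_i[g] <- s_i[g] + abs(lv[r, c] - mean(vals))
  }
  cbind(n = n_i, p = n_i / (h * w), s = s_i)
}

# Random quantized test image (0-based levels), dimensions 2..maxDim.
randomQuantized <- function(seed, maxDim = 8L, nL = 4L) {
  set.seed(seed)
  h <- sample(2:maxDim, 1L); w <- sample(2:maxDim, 1L)
  lv <- matrix(sample(0:(nL - 1L), h * w, replace = TRUE), h, w)
  new("QuantizedImage", levels = lv, nLevels = as.integer(nL),
      binEdges = seq(0, 256, length.out = nL + 1))
}

# Random 8-bit image for extraction-level tests.
randomImage8 <- function(seed, h = 24L, w = 24L) {
  set.seed(seed)
  matrix(sample(0:255, h * w, replace = TRUE), h, w)
}

# Pad run-length style matrices to a common column count for comparison.
padCols <- function(m, k) {
  if (ncol(m) < k) cbind(m, matrix(0, nrow(m), k - ncol(m))) else m
}
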