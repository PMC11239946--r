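# Independent brute-force oracles. Deliberately naive implementations that
# share no code with the package internals they check.

# recursive flood fill
oracle_label <- function(mask, connectivity) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nb <- if (connectivity == 4) {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  } else {
    as.matrix(expand.grid(dr = -1:1, dc = -1:1))[-5, ]
  }
  fill <- function(i, j, id) {
    lab[i, j] <<- id
    for (k in seq_len(nrow(nb))) {
      r <- i + nb[k, 1]; cc <- j + nb[k, 2]
      if (r >= 1 && r <= nr && cc >= 1 && cc <= nc &&
          mask[r, cc] && lab[r, cc] == 0L) {
        fill(r, cc, id)
      }
    }
  }
  id <- 0L
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (mask[i, j] && lab[i, j] == 0L) {
        id <- id + 1L
        fill(i, j, id)
      }
    }
  }
  list(labels = lab, n = id)
}

# double-loop local mean with symmetric reflection padding
oracle_adaptive <- function(m, w, offset) {
  k <- (w - 1) / 2
  nr <- nrow(m); nc <- ncol(m)
  rmap <- c(k:1, 1:nr, nr:(nr - k + 1))
  cmap <- c(k:1, 1:nc, nc:(nc - k + 1))
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      s <- 0
      for (di in -k:k) {
        for (dj in -k:k) {
          s <- s + m[rmap[i + di + k], cmap[j + dj + k]]
        }
      }
      out[i, j] <- m[i, j] > s / (w * w) + offset
    }
  }
  out
}

# set-algebra Minkowski erosion/dilation with a disk
oracle_opening <- function(mask, r) {
  off <- expand.grid(dy = -r:r, dx = -r:r)
  off <- off[off$dy^2 + off$dx^2 <= r^2, ]
  nr <- nrow(mask); nc <- ncol(mask)
  ero <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      all_in <- TRUE
      for (k in seq_len(nrow(off))) {
        r2 <- i + off$dy[k]; c2 <- j + off$dx[k]
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc || !mask[r2, c2]) {
          all_in <- FALSE
          break
        }
      }
      ero[i, j] <- all_in
    }
  }
  dil <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      for (k in seq_len(nrow(off))) {
        r2 <- i + off$dy[k]; c2 <- j + off$dx[k]
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc && ero[r2, c2]) {
          dil[i, j] <- TRUE
          break
        }
      }
    }
  }
  dil
}

# pooled t with two-sided p via the regularized incomplete beta function
oracle_t_test <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  df <- n1 + n2 - 2
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / df
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- pbeta(df / (df + t^2), df / 2, 1 / 2)
  list(t = t, df = df, p = p)
}

# exhaustive minimisation of within-class variance over all candidate
# thresholds (midpoints between adjacent sorted values)
oracle_otsu_threshold <- function(logd) {
  v <- sort(logd)
  cand <- (v[-length(v)] + v[-1]) / 2
  cand <- cand[!duplicated(cand)]
  varp <- function(z) if (length(z) <= 1) 0 else mean((z - mean(z))^2)
  wcv <- vapply(cand, function(t) {
    a <- logd[logd < t]; b <- logd[logd >= t]
    (length(a) * varp(a) + length(b) * varp(b)) / length(logd)
  }, numeric(1))
  cand[which.min(wcv)]
}

# exhaustive per-pixel disk membership
oracle_disk_count <- function(r) {
  n <- 0L
  for (x in -ceiling(r):ceiling(r)) {
    for (y in -ceiling(r):ceiling(r)) {
      if (x * x + y * y <= r * r) n <- n + 1L
    }
  }
  n
}

# scalar even-odd crossing test, one pixel at a time
oracle_point_in_polygon <- function(px, py, v) {
  n <- nrow(v)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((v[i, 2] > py) != (v[j, 2] > py)) {
      xint <- (v[j, 1] - v[i, 1]) * (py - v[i, 2]) /
        (v[j, 2] - v[i, 2]) + v[i, 1]
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# all-pairs nearest-neighbour distances
oracle_nearest <- function(ox, oy, nx, ny) {
  vapply(seq_along(ox), function(i) {
    best <- Inf
    for (j in seq_along(nx)) {
      d <- sqrt((ox[i] - nx[j])^2 + (oy[i] - ny[j])^2)
      if (d < best) best <- d
    }
    best
  }, numeric(1))
}
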