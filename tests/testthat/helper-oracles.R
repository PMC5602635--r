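# Independent oracles, all deliberately written as explicit loops / dense
# linear algebra so they share no code path with the package internals.

# brute-force pixel count above threshold
pixel_area_oracle <- function(plane, thr, f) {
  count <- 0L
  for (i in seq_len(nrow(plane))) {
    for (j in seq_len(ncol(plane))) {
      if (plane[i, j] >= thr) count <- count + 1L
    }
  }
  count * f^2
}

# dense nodal analysis of the conduction problem: explicit per-cell loops,
# base::solve on the full matrix
dense_conduction_oracle <- function(sigma, dx, dy, dz, ma, mb,
                                    side_a = "bottom", side_b = "bottom",
                                    drive = 0.1) {
  d <- dim(sigma)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  dx <- dx * 1e-6; dy <- dy * 1e-6; dz <- dz * 1e-6
  n <- nx * ny * nz
  id <- function(i, j, l) i + nx * (j - 1) + nx * ny * (l - 1)
  A <- matrix(0, n, n)
  b <- numeric(n)
  ga <- numeric(n)
  va <- drive / 2
  vb <- -drive / 2
  la <- if (side_a == "bottom") 1L else nz
  lb <- if (side_b == "bottom") 1L else nz
  for (i in seq_len(nx)) for (j in seq_len(ny)) for (l in seq_len(nz)) {
    p <- id(i, j, l)
    for (q in list(c(i + 1, j, l), c(i - 1, j, l), c(i, j + 1, l),
                   c(i, j - 1, l), c(i, j, l + 1), c(i, j, l - 1))) {
      if (q[1] < 1 || q[1] > nx || q[2] < 1 || q[2] > ny ||
          q[3] < 1 || q[3] > nz) next
      s2 <- sigma[q[1], q[2], q[3]]
      if (q[1] != i) {
        ar <- dy[j] * dz[l]
        dd <- dx[i] / 2 / sigma[i, j, l] + dx[q[1]] / 2 / s2
      } else if (q[2] != j) {
        ar <- dx[i] * dz[l]
        dd <- dy[j] / 2 / sigma[i, j, l] + dy[q[2]] / 2 / s2
      } else {
        ar <- dx[i] * dy[j]
        dd <- dz[l] / 2 / sigma[i, j, l] + dz[q[3]] / 2 / s2
      }
      g <- ar / dd
      A[p, p] <- A[p, p] + g
      A[p, q[1] + nx * (q[2] - 1) + nx * ny * (q[3] - 1)] <-
        A[p, q[1] + nx * (q[2] - 1) + nx * ny * (q[3] - 1)] - g
    }
    if (l == la && ma[i, j]) {
      g <- sigma[i, j, l] * dx[i] * dy[j] / (dz[l] / 2)
      A[p, p] <- A[p, p] + g
      b[p] <- b[p] + g * va
      ga[p] <- g
    }
    if (l == lb && mb[i, j]) {
      g <- sigma[i, j, l] * dx[i] * dy[j] / (dz[l] / 2)
      A[p, p] <- A[p, p] + g
      b[p] <- b[p] + g * vb
    }
  }
  phi <- solve(A, b)
  ia <- sum(ga * (va - phi))
  drive / abs(ia)
}

# exhaustive interval scan for detachment events: every (i, j) pair is
# tested against the definition, then inclusion-maximal intervals kept
detachment_oracle <- function(time_s, dz_pct, min_drop = 5, max_window = 10,
                              step_tol = 0.2) {
  n <- length(time_s)
  qualifying <- list()
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      if (time_s[j] - time_s[i] > max_window) break
      steps_ok <- TRUE
      for (m in seq(i + 1, j)) {
        if (dz_pct[m] - dz_pct[m - 1] > step_tol) { steps_ok <- FALSE; break }
      }
      if (!steps_ok) break
      opens_falling <- dz_pct[i + 1] - dz_pct[i] < -step_tol
      closes_falling <- dz_pct[j] - dz_pct[j - 1] < -step_tol
      if (opens_falling && closes_falling &&
          dz_pct[i] - dz_pct[j] >= min_drop) {
        qualifying[[length(qualifying) + 1L]] <- c(i, j)
      }
    }
  }
  if (!length(qualifying)) {
    return(data.frame(t1 = numeric(0), t2 = numeric(0), drop = numeric(0)))
  }
  keep <- logical(length(qualifying))
  for (a in seq_along(qualifying)) {
    contained <- FALSE
    for (b in seq_along(qualifying)) {
      if (a == b) next
      if (qualifying[[b]][1] <= qualifying[[a]][1] &&
          qualifying[[b]][2] >= qualifying[[a]][2]) {
        contained <- TRUE
        break
      }
    }
    keep[a] <- !contained
  }
  kept <- unique(qualifying[keep])
  kept <- kept[order(vapply(kept, `[`, 0, 1))]
  data.frame(
    t1 = time_s[vapply(kept, `[`, 0, 1)],
    t2 = time_s[vapply(kept, `[`, 0, 2)],
    drop = dz_pct[vapply(kept, `[`, 0, 1)] - dz_pct[vapply(kept, `[`, 0, 2)]
  )
}

# textbook Pearson correlation written out
pearson_oracle <- function(x, y) {
  n <- length(x)
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}
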