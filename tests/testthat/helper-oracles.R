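# Independent brute-force oracles used to validate the implementation.

# Benjamini-Hochberg step-up by exhaustive scan over every candidate k.
bh_oracle <- function(p, q) {
  m <- length(p)
  ps <- sort(p)
  kmax <- 0L
  for (k in seq_len(m)) if (ps[k] <= k * q / m) kmax <- k
  if (kmax == 0L) rep(FALSE, m) else p <= ps[kmax]
}

# 3D connected components by BFS flood fill.
flood_fill_oracle <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  if (connectivity == 6L)
    offs <- offs[abs(offs$dx) + abs(offs$dy) + abs(offs$dz) == 1, ]
  lab <- array(0L, dim = d)
  nl <- 0L
  idx <- which(mask, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    v <- idx[r, ]
    if (lab[v[1], v[2], v[3]] > 0L) next
    nl <- nl + 1L
    queue <- list(v)
    lab[v[1], v[2], v[3]] <- nl
    while (length(queue)) {
      p <- queue[[1]]
      queue <- queue[-1]
      for (o in seq_len(nrow(offs))) {
        w <- p + c(offs$dx[o], offs$dy[o], offs$dz[o])
        if (any(w < 1L) || any(w > d)) next
        if (mask[w[1], w[2], w[3]] && lab[w[1], w[2], w[3]] == 0L) {
          lab[w[1], w[2], w[3]] <- nl
          queue <- c(queue, list(w))
        }
      }
    }
  }
  lab
}

# All-pairs minimum anisotropic distance.
min_dist_oracle <- function(A, B, spacing) {
  best <- Inf
  for (i in seq_len(nrow(A)))
    for (j in seq_len(nrow(B))) {
      d2 <- sum(((A[i, ] - B[j, ]) * spacing)^2)
      if (d2 < best) best <- d2
    }
  sqrt(best)
}

# Single-measure ICCs from the two-way ANOVA fitted by stats::aov.
icc_aov_oracle <- function(X, model) {
  n <- nrow(X)
  k <- ncol(X)
  df <- data.frame(y = as.vector(X),
                   subject = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ subject + rater, data = df))[[1]][["Mean Sq"]]
  MSR <- ms[1]; MSC <- ms[2]; MSE <- ms[3]
  if (model == "3,1") (MSR - MSE) / (MSR + (k - 1) * MSE)
  else (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
}

# Symmetric Hausdorff distance between two 2D masks, in voxels.
hausdorff2d <- function(a, b) {
  A <- which(a, arr.ind = TRUE)
  B <- which(b, arr.ind = TRUE)
  if (nrow(A) == 0L || nrow(B) == 0L) return(Inf)
  one_sided <- function(P, Q)
    max(vapply(seq_len(nrow(P)), function(i)
      min(colSums((t(Q) - P[i, ])^2)), numeric(1)))
  sqrt(max(one_sided(A, B), one_sided(B, A)))
}

# Dice overlap of two masks.
dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# A high-contrast disc slice with its ground truth.
disc_slice <- function(n = 64, center = c(n / 2, n / 2), r = 12,
                       lo = 0.2, hi = 0.8) {
  disc <- outer(seq_len(n), seq_len(n),
                function(i, j) (i - center[1])^2 + (j - center[2])^2 <= r^2)
  img <- matrix(lo, n, n)
  img[disc] <- hi
  list(img = img, truth = disc)
}

# Circular marked contour for one slice (0-based coordinates).
circle_contour <- function(cx, cy, r, n_points = 16L, articular = TRUE) {
  th <- seq(0, 2 * pi, length.out = n_points + 1L)[-(n_points + 1L)]
  data.frame(x = cx + r * cos(th), y = cy + r * sin(th),
             articular = rep_len(articular, n_points))
}
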