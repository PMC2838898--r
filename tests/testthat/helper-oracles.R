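# Independent brute-force oracles.  Each re-implements the contract of one
# operation with naive loops, sharing no code with the package internals.

# symmetric reflection with edge repetition, 1-based
refl <- function(i, n) {
  per <- 2L * n
  j <- ((i - 1L) %% per + per) %% per
  ifelse(j < n, j + 1L, per - j)
}

# per-pixel sort-and-middle median filter
naive_median_filter <- function(x, window) {
  r <- window %/% 2L
  out <- x
  for (i in seq_len(nrow(x))) {
    for (j in seq_len(ncol(x))) {
      vals <- numeric(0)
      for (di in -r:r) {
        for (dj in -r:r) {
          vals <- c(vals, x[refl(i + di, nrow(x)), refl(j + dj, ncol(x))])
        }
      }
      out[i, j] <- sort(vals)[(length(vals) + 1L) %/% 2L]
    }
  }
  out
}

# BFS flood-fill labelling, 8-connected
naive_label <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (j0 in seq_len(ncol(mask))) {
    for (i0 in seq_len(nrow(mask))) {
      if (!mask[i0, j0] || lab[i0, j0] > 0L) next
      cur <- cur + 1L
      queue <- list(c(i0, j0))
      lab[i0, j0] <- cur
      while (length(queue)) {
        p <- queue[[1L]]
        queue <- queue[-1L]
        for (di in -1:1) {
          for (dj in -1:1) {
            if (di == 0L && dj == 0L) next
            i <- p[1L] + di; j <- p[2L] + dj
            if (i < 1L || j < 1L || i > nrow(mask) || j > ncol(mask)) next
            if (mask[i, j] && lab[i, j] == 0L) {
              lab[i, j] <- cur
              queue[[length(queue) + 1L]] <- c(i, j)
            }
          }
        }
      }
    }
  }
  lab
}

# keep 8-connected components with area strictly greater than T
naive_filter_components <- function(mask, T) {
  lab <- naive_label(mask)
  if (max(lab) == 0L) return(mask & FALSE)
  keep <- which(table(factor(lab[lab > 0L], levels = seq_len(max(lab)))) > T)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

# direct 3x3 correlation with a kernel, reflect padded
naive_correlate3 <- function(x, k) {
  out <- x * 0
  for (i in seq_len(nrow(x))) {
    for (j in seq_len(ncol(x))) {
      s <- 0
      for (a in 1:3) {
        for (b in 1:3) {
          s <- s + k[a, b] * x[refl(i + a - 2L, nrow(x)), refl(j + b - 2L, ncol(x))]
        }
      }
      out[i, j] <- s
    }
  }
  out
}

# mean and population SD along one detector line by direct enumeration
naive_line_stats <- function(values, pixel, offsets) {
  v <- numeric(nrow(offsets))
  for (t in seq_len(nrow(offsets))) {
    v[t] <- values[refl(pixel[1L] + offsets[t, 1L], nrow(values)),
                   refl(pixel[2L] + offsets[t, 2L], ncol(values))]
  }
  c(mean = mean(v), sd = sqrt(mean((v - mean(v))^2)))
}

# undecimated one-level Haar modulus by explicit 2-tap filtering
naive_wavelet_modulus <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  hp_col <- x * 0; lp_col <- x * 0
  for (j in seq_len(nc)) {
    jn <- refl(j + 1L, nc)
    hp_col[, j] <- (x[, jn] - x[, j]) / 2
    lp_col[, j] <- (x[, jn] + x[, j]) / 2
  }
  wv <- hp_col * 0; wh <- hp_col * 0
  for (i in seq_len(nr)) {
    iN <- refl(i + 1L, nr)
    wv[i, ] <- (hp_col[iN, ] + hp_col[i, ]) / 2        # lowpass along rows
  }
  hp_row <- x * 0
  for (i in seq_len(nr)) {
    iN <- refl(i + 1L, nr)
    hp_row[i, ] <- (x[iN, ] - x[i, ]) / 2
  }
  for (j in seq_len(nc)) {
    jn <- refl(j + 1L, nc)
    wh[, j] <- (hp_row[, jn] + hp_row[, j]) / 2        # lowpass along cols
  }
  sqrt(wh^2 + wv^2)
}

# confusion counts over the FOV by an explicit pixel loop
naive_metrics <- function(pred, truth, fov) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(ncol(pred))) {
      if (!fov[i, j]) next
      if (pred[i, j] && truth[i, j]) tp <- tp + 1L
      else if (pred[i, j]) fp <- fp + 1L
      else if (truth[i, j]) fn <- fn + 1L
      else tn <- tn + 1L
    }
  }
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}

# rank-sum AUC of score for labels in {TRUE, FALSE}
naive_auc <- function(score, positive) {
  r <- rank(score)
  n1 <- sum(positive); n0 <- sum(!positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
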