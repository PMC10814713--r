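# Independent brute-force oracles: literal set-definition morphology
# (triple loops), flood-fill labelling, exhaustive threshold scans and
# pairwise-comparison AUC.  Deliberately slow and simple so they stay
# independent of the implementations they check.

random_mask <- function(M, N, p = 0.4) {
  matrix(as.integer(runif(M * N) < p), M, N)
}

se_offsets <- function(B) {
  c0 <- (nrow(B) + 1L) %/% 2L
  idx <- which(B == 1L, arr.ind = TRUE)
  cbind(idx[, 1] - c0, idx[, 2] - c0)
}

naive_dilate <- function(Y, B) {
  M <- nrow(Y); N <- ncol(Y)
  off <- se_offsets(B)
  out <- matrix(0L, M, N)
  for (i in seq_len(M)) for (j in seq_len(N)) {
    hit <- FALSE
    for (k in seq_len(nrow(off))) {
      a <- i + off[k, 1]; b <- j + off[k, 2]
      if (a >= 1 && a <= M && b >= 1 && b <= N && Y[a, b] == 1L) {
        hit <- TRUE; break
      }
    }
    out[i, j] <- as.integer(hit)
  }
  out
}

naive_erode <- function(Y, B) {
  M <- nrow(Y); N <- ncol(Y)
  off <- se_offsets(B)
  out <- matrix(0L, M, N)
  for (i in seq_len(M)) for (j in seq_len(N)) {
    all_in <- TRUE
    for (k in seq_len(nrow(off))) {
      a <- i + off[k, 1]; b <- j + off[k, 2]
      if (a < 1 || a > M || b < 1 || b > N || Y[a, b] == 0L) {
        all_in <- FALSE; break
      }
    }
    out[i, j] <- as.integer(all_in)
  }
  out
}

naive_close <- function(Y, B) naive_erode(naive_dilate(Y, B), B)

naive_label <- function(Y, connectivity = 8L) {
  M <- nrow(Y); N <- ncol(Y)
  lab <- matrix(0L, M, N)
  nb4 <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  nbs <- if (connectivity == 8L) {
    rbind(nb4, c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  } else nb4
  cur <- 0L
  for (i in seq_len(M)) for (j in seq_len(N)) {
    if (Y[i, j] == 1L && lab[i, j] == 0L) {
      cur <- cur + 1L
      queue <- list(c(i, j))
      lab[i, j] <- cur
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (k in seq_len(nrow(nbs))) {
          a <- p[1] + nbs[k, 1]; b <- p[2] + nbs[k, 2]
          if (a >= 1 && a <= M && b >= 1 && b <= N &&
              Y[a, b] == 1L && lab[a, b] == 0L) {
            lab[a, b] <- cur
            queue <- c(queue, list(c(a, b)))
          }
        }
      }
    }
  }
  lab
}

naive_remove_small <- function(Y, U, connectivity = 8L) {
  lab <- naive_label(Y, connectivity)
  out <- Y
  if (max(lab) > 0L) {
    for (l in seq_len(max(lab))) {
      if (sum(lab == l) <= U) out[lab == l] <- 0L
    }
  }
  out
}

# Exhaustive Otsu: try every split, maximize between-class variance.
naive_otsu <- function(X) {
  x <- as.vector(X)
  best_t <- NA_integer_; best_v <- -Inf
  for (t in 0:255) {
    lo <- x[x <= t]; hi <- x[x > t]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(x); w1 <- 1 - w0
    v <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (v > best_v + 1e-12) { best_v <- v; best_t <- t }
  }
  best_t
}

# Normalized Mann-Whitney pairwise AUC (ties count half).
naive_auc <- function(scores1, scores0) {
  tot <- 0
  for (a in scores1) for (b in scores0) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(scores1) * length(scores0))
}

subset_mask <- function(a, b) all(a[b == 0L] == 0L)
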