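# independent brute-force oracles used against the vectorized implementations

blockMeanOracle <- function(v, f) {
  nb <- nrow(v) / f; pb <- ncol(v) / f
  out <- matrix(NA_real_, nb, pb)
  for (i in seq_len(nb)) for (j in seq_len(pb)) {
    blk <- v[((i - 1) * f + 1):(i * f), ((j - 1) * f + 1):(j * f)]
    if (any(!is.na(blk))) out[i, j] <- mean(blk, na.rm = TRUE)
  }
  out
}

blockMajorOracle <- function(v, f) {
  nb <- nrow(v) / f; pb <- ncol(v) / f
  out <- matrix(NA_real_, nb, pb)
  for (i in seq_len(nb)) for (j in seq_len(pb)) {
    blk <- v[((i - 1) * f + 1):(i * f), ((j - 1) * f + 1):(j * f)]
    blk <- blk[!is.na(blk)]
    if (length(blk)) {
      counts <- table(blk)            # names sorted ascending numerically
      best <- max(counts)
      out[i, j] <- as.numeric(names(counts)[counts == best][1])
    }
  }
  out
}

dilate3x3Oracle <- function(w) {
  n <- nrow(w); p <- ncol(w)
  out <- matrix(FALSE, n, p)
  for (i in seq_len(n)) for (j in seq_len(p)) {
    if (!isTRUE(w[i, j] != 0)) next
    for (di in -1:1) for (dj in -1:1) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= n && jj >= 1 && jj <= p) out[ii, jj] <- TRUE
    }
  }
  out
}

# explicit per-pixel loop over one window's class means
windowMeansOracle <- function(classes, fieldV, row0, col0, size,
                              classA, classB, buffer = NULL) {
  a <- c(); b <- c()
  for (i in row0:(row0 + size - 1)) for (j in col0:(col0 + size - 1)) {
    if (!is.null(buffer) && buffer[i, j]) next
    if (is.na(fieldV[i, j])) next
    if (classes[i, j] == classA) a <- c(a, fieldV[i, j])
    if (classes[i, j] == classB) b <- c(b, fieldV[i, j])
  }
  list(meanA = mean(a), meanB = mean(b), nA = length(a), nB = length(b))
}

binningOracle <- function(samples, res) {
  cells <- list()
  for (k in seq_len(nrow(samples))) {
    key <- paste(floor(samples$lat[k] / res), floor(samples$lon[k] / res))
    cells[[key]] <- c(cells[[key]], samples$delta[k])
  }
  vapply(cells, mean, 0)
}

olsSlopeOracle <- function(x, y) {
  # closed-form simple regression with t-test p on the slope
  n <- length(x)
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  res <- y - a - b * x
  se <- sqrt(sum(res^2) / (n - 2) / sum((x - mean(x))^2))
  list(slope = b, intercept = a,
       p = 2 * stats::pt(-abs(b / se), df = n - 2))
}

normalEquationsOracle <- function(X, y) solve(t(X) %*% X, t(X) %*% y)
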