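# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the Otsu oracle scans all thresholds with plain
# subset means, the labelling oracle is a breadth-first flood fill, and the
# metric oracles are written directly from the defining formulas.

# Exhaustive between-class variance scan; returns sigma^2 for k = 0..255.
oracle_otsu_scan <- function(values) {
  v <- pmin(pmax(round(values), 0), 255)
  n <- length(v)
  vapply(0:255, function(k) {
    hi <- v[v > k]; lo <- v[v <= k]
    w0 <- length(hi) / n; w1 <- length(lo) / n
    mu <- mean(v)
    t0 <- if (length(hi)) w0 * (mu - mean(hi))^2 else 0
    t1 <- if (length(lo)) w1 * (mu - mean(lo))^2 else 0
    t0 + t1
  }, numeric(1))
}

oracle_otsu_k <- function(values) {
  s <- oracle_otsu_scan(values)
  (0:255)[which.max(s)]   # first maximum = smallest k
}

# BFS flood-fill labelling; returns list of pixel-index sets (sorted), one
# per component, ordered by raster-scan first pixel.
oracle_components <- function(mask, connectivity = 8) {
  H <- nrow(mask); W <- ncol(mask)
  seen <- matrix(FALSE, H, W)
  if (connectivity == 8) {
    nb <- cbind(dx = c(-1, 0, 1, -1, 1, -1, 0, 1),
                dy = c(-1, -1, -1, 0, 0, 1, 1, 1))
  } else {
    nb <- cbind(dx = c(0, -1, 1, 0), dy = c(-1, 0, 0, 1))
  }
  comps <- list()
  for (y in seq_len(H)) {
    for (x in seq_len(W)) {
      if (!mask[y, x] || seen[y, x]) next
      queue <- matrix(c(x, y), 1)
      seen[y, x] <- TRUE
      px <- integer(0)
      while (nrow(queue)) {
        cur <- queue[1, , drop = FALSE]; queue <- queue[-1, , drop = FALSE]
        px <- c(px, (cur[1] - 1) * H + cur[2])
        for (j in seq_len(nrow(nb))) {
          nx <- cur[1] + nb[j, "dx"]; ny <- cur[2] + nb[j, "dy"]
          if (nx >= 1 && nx <= W && ny >= 1 && ny <= H &&
              mask[ny, nx] && !seen[ny, nx]) {
            seen[ny, nx] <- TRUE
            queue <- rbind(queue, c(nx, ny))
          }
        }
      }
      comps[[length(comps) + 1]] <- sort(px)
    }
  }
  comps
}

# Component tibble -> list of sorted pixel-index sets (H needed to linearise)
component_pixel_sets <- function(components, H) {
  lapply(components$pixels, function(m)
    unname(sort(m[, "x"] * H + m[, "y"] + 1)))
}

# Reference count metrics straight from the formulas.
oracle_count_metrics <- function(y, yhat) {
  list(r2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2),
       rmse = sqrt(sum((yhat - y)^2) / length(y)),
       mae = sum(abs(yhat - y)) / length(y),
       avg_acc = mean((1 - abs(yhat[y > 0] - y[y > 0]) / y[y > 0])) * 100)
}

make_solid_crop <- function(rgb, label, noise_sd = 4, n = 255L) {
  px <- array(rep(rgb, each = n * n), c(n, n, 3)) +
    array(rnorm(n * n * 3, 0, noise_sd), c(n, n, 3))
  seedling_crop(array(pmin(pmax(px, 0), 255), c(n, n, 3)), label)
}
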