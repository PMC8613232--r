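#' Count 8-connected components of a binary raster
#'
#' @param grid logical matrix (or mask/skeleton object).
#' @return list with `n_components` and `labels` (integer matrix, 0 =
#'   background).
#' @export
count_mask_components <- function(grid) {
  g <- as_binary_grid(grid)
  idx <- which(g)
  n <- length(idx)
  if (n == 0L) return(list(n_components = 0L, labels = matrix(0L, nrow(g), ncol(g))))
  map <- integer(length(g))
  map[idx] <- seq_len(n)
  nr <- nrow(g)
  rc <- arrayInd(idx, dim(g))
  a <- integer(0); b <- integer(0)
  for (off in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- rc[, 1] + off[1]; c2 <- rc[, 2] + off[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= ncol(g)
    j <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- map[j] > 0L
    a <- c(a, map[idx[ok]][hit]); b <- c(b, map[j][hit])
  }
  comp <- uf_components(n, a, b, rep(TRUE, n))
  lab <- matrix(0L, nrow(g), ncol(g))
  lab[idx] <- comp$labels
  list(n_components = comp$n_components, labels = lab)
}

# 8-connected raster line between two integer pixel coordinates (inclusive).
bresenham <- function(r0, c0, r1, c1) {
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  sr <- sign(r1 - r0); sc <- sign(c1 - c0)
  n <- max(dr, dc) + 1L
  out <- matrix(0L, n, 2L)
  err <- dr - dc
  r <- r0; c <- c0
  for (i in seq_len(n)) {
    out[i, ] <- c(r, c)
    if (r == r1 && c == c1) { out <- out[seq_len(i), , drop = FALSE]; break }
    e2 <- 2L * err
    if (e2 > -dc) { err <- err - dc; r <- r + sr }
    if (e2 < dr) { err <- err + dr; c <- c + sc }
  }
  out
}
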