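# Independent reference implementations used as oracles. Deliberately written
# in a different style from the package code (pixel-by-pixel scans, explicit
# stacks) so they share no code path with what they check.

# Exhaustive depth-first flood fill, scanning pixels in column-major order so
# label numbering matches first-encounter order.
flood_label_oracle <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] > 0L) next
    cur <- cur + 1L
    lab[i, j] <- cur
    stack <- list(c(i, j))
    while (length(stack) > 0L) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0L && dc == 0L) next
        if (connectivity == 4 && abs(dr) + abs(dc) == 2L) next
        r <- p[1] + dr; c2 <- p[2] + dc
        if (r >= 1L && r <= nr && c2 >= 1L && c2 <= nc &&
            mask[r, c2] && lab[r, c2] == 0L) {
          lab[r, c2] <- cur
          stack[[length(stack) + 1L]] <- c(r, c2)
        }
      }
    }
  }
  lab
}

# Per-label area and mean intensity by an explicit pixel scan.
region_stats_oracle <- function(m, lab) {
  out <- list()
  for (k in seq_len(max(lab))) {
    s <- 0; cnt <- 0L
    for (j in seq_len(ncol(m))) for (i in seq_len(nrow(m))) {
      if (lab[i, j] == k) { s <- s + m[i, j]; cnt <- cnt + 1L }
    }
    out[[k]] <- c(area = cnt, mean = s / cnt)
  }
  do.call(rbind, out)
}

# Brute-force disk rasterization (independent of scene_masks).
disk_mask_oracle <- function(dim, center, radius) {
  mask <- matrix(FALSE, dim[1], dim[2])
  for (j in seq_len(dim[2])) for (i in seq_len(dim[1]))
    if ((i - center[1])^2 + (j - center[2])^2 <= radius^2)
      mask[i, j] <- TRUE
  mask
}

# Truth-mask partition ratio of a rendered scene (in-vivo definition): mean
# condensate pixel intensity over mean nucleus pixel intensity, from the
# noiseless render.
truth_partition_ratio <- function(scene) {
  sc0 <- scene
  sc0$noise_sd <- 0
  res <- generate_condensate_image(sc0)
  cond <- res$masks$condensate > 0L
  mean(res$image[cond]) / mean(res$image[res$masks$nucleus])
}

# standard test scene: n disjoint fold-5 condensates on a ring
test_scene <- function(n = 3, radius = 4, fold = 5, noise_sd = 0,
                       seed = NULL, dim = c(128L, 128L)) {
  scene_truth(dim = dim,
              condensates = disk_condensates(n, radius = radius, fold = fold,
                                             dim = dim),
              noise_sd = noise_sd, seed = seed)
}

# Match detected regions to truth condensates: a truth condensate counts as
# recovered if some detected centroid lies within its radius + 1 px.
count_recovered <- function(cset, truth) {
  cdf <- truth$condensates
  if (!nrow(cdf) || cset$n == 0L) return(0L)
  rec <- 0L
  for (i in seq_len(nrow(cdf))) {
    d <- sqrt((cset$regions$centroid_row - cdf$row[i])^2 +
              (cset$regions$centroid_col - cdf$col[i])^2)
    if (any(d <= cdf$radius[i] + 1)) rec <- rec + 1L
  }
  rec
}
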