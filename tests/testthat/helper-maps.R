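# build a label map from 0-based voxel index triples per label
lm_from_points <- function(points, dims = c(10, 10, 10), affine = diag(4)) {
  arr <- array(0L, dims)
  for (lab in names(points)) {
    idx <- points[[lab]]
    if (is.null(dim(idx))) idx <- matrix(idx, ncol = 3, byrow = TRUE)
    arr[idx + 1L] <- as.integer(lab)
  }
  label_map(arr, affine)
}

# marker tibble from a named list of mm points (full presence)
markers_from_points <- function(pts) {
  nm <- unname(marker_names())
  tibble::tibble(
    label = 1:5, name = nm,
    x = vapply(nm, function(n) if (n %in% names(pts)) pts[[n]][1] else NA_real_, 1),
    y = vapply(nm, function(n) if (n %in% names(pts)) pts[[n]][2] else NA_real_, 1),
    z = vapply(nm, function(n) if (n %in% names(pts)) pts[[n]][3] else NA_real_, 1),
    voxel_count = ifelse(nm %in% names(pts), 1L, 0L))
}

# brute-force centroid oracle: per-voxel affine products, plain loops
oracle_centroids <- function(labelmap) {
  dims <- dim(labelmap$labels)
  out <- list()
  for (l in 1:5) {
    acc <- c(0, 0, 0); n <- 0
    for (i in seq_len(dims[1])) for (j in seq_len(dims[2])) for (k in seq_len(dims[3])) {
      if (labelmap$labels[i, j, k] == l) {
        p <- labelmap$affine %*% c(i - 1, j - 1, k - 1, 1)
        acc <- acc + p[1:3]; n <- n + 1
      }
    }
    out[[l]] <- if (n > 0) acc / n else c(NA_real_, NA_real_, NA_real_)
  }
  out
}

random_affine <- function() {
  ang <- runif(3, -pi, pi)
  R <- rbind(c(cos(ang[1]), -sin(ang[1]), 0), c(sin(ang[1]), cos(ang[1]), 0), c(0, 0, 1)) %*%
       rbind(c(cos(ang[2]), 0, sin(ang[2])), c(0, 1, 0), c(-sin(ang[2]), 0, cos(ang[2])))
  A <- diag(4)
  A[1:3, 1:3] <- R %*% diag(runif(3, 0.4, 1.2))
  A[1:3, 4] <- runif(3, -20, 20)
  A
}
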