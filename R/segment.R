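#' Parameters for the threshold fallback segmenter
#'
#' @param hu_threshold Intensity cutoff separating metal from everything else
#'   (default 800; metal in CT far exceeds bone and soft tissue).
#' @param min_component_voxels Drop connected components smaller than this
#'   (default 3).
#' @param max_components Keep at most this many components, largest first
#'   (default 12), guarding against noise speckle.
#' @return A list of class `seg_params`.
#' @export
seg_params <- function(hu_threshold = 800, min_component_voxels = 3,
                       max_components = 12) {
  stopifnot(is.finite(hu_threshold), min_component_voxels >= 1,
            max_components >= 5)
  structure(list(hu_threshold = hu_threshold,
                 min_component_voxels = as.integer(min_component_voxels),
                 max_components = as.integer(max_components)),
            class = "seg_params")
}

# 26-connected components of a foreground voxel set; returns an integer
# component id per foreground voxel. Thin annuli need diagonal connectivity.
connected_components_26 <- function(fore_lin, dims) {
  nvox <- length(fore_lin)
  if (nvox == 0) return(integer(0))
  pos <- integer(prod(dims))        # linear voxel -> row in fore_lin (0 = bg)
  pos[fore_lin] <- seq_len(nvox)
  idx <- arrayInd(fore_lin, dims)
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  edges <- vector("list", nrow(off))
  for (k in seq_len(nrow(off))) {
    nb <- sweep(idx, 2L, off[k, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
          nb[, 2] >= 1 & nb[, 2] <= dims[2] &
          nb[, 3] >= 1 & nb[, 3] <= dims[3]
    nb_lin <- (nb[ok, 3] - 1L) * dims[1] * dims[2] +
              (nb[ok, 2] - 1L) * dims[1] + nb[ok, 1]
    hit <- pos[nb_lin] > 0L
    edges[[k]] <- cbind(which(ok)[hit], pos[nb_lin[hit]])
  }
  ed <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(ed, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nvox - igraph::vcount(g)))
  igraph::components(g)$membership[seq_len(nvox)]
}

#' Segment the five valve markers by thresholding and geometric heuristics
#'
#' Classical stand-in for a learned segmenter so the end-to-end pipeline runs
#' on phantoms: binarize at `hu_threshold`, take 26-connected components,
#' drop tiny ones, then classify by geometry — (a) the component with the
#' largest spatial extent is the rotating-construct annulus; (b) the two
#' components whose centroids are nearest the annulus centroid are the
#' magnets; (c) of the remaining components, the one nearest the annulus is
#' the RHS marker and the farthest the distal tip (when only one remains it
#' is assigned by its distance relative to the annulus extent); (d) the
#' magnet containing the highest-intensity voxel is the ball magnet — a
#' phantom-compatible proxy for the sub-millimetre tantalum ball; on real
#' data a learned segmenter provides that distinction directly.
#'
#' Unassignable scenes return a partial label map with the missing labels
#' empty; downstream frame construction then reports the setting as
#' undeterminable, the same failure mode a learned segmenter exhibits when it
#' misses a small marker.
#'
#' @param volume A [voxel_grid()].
#' @param params A [seg_params()].
#' @return A [label_map()] sharing the volume's geometry.
#' @export
segment_markers <- function(volume, params = seg_params()) {
  stopifnot(inherits(volume, "voxel_grid"))
  dims <- dim(volume$data)
  fore <- which(volume$data > params$hu_threshold)
  if (length(fore) == 0)
    abort("no markers found above intensity threshold ", params$hu_threshold,
          class = "certasdial_no_markers")
  memb <- connected_components_26(fore, dims)
  keep_sizes <- table(memb)
  comp_ids <- as.integer(names(keep_sizes))[keep_sizes >= params$min_component_voxels]
  if (length(comp_ids) == 0)
    abort("no markers found: all components below min_component_voxels",
          class = "certasdial_no_markers")
  # largest max_components by size
  sizes <- keep_sizes[as.character(comp_ids)]
  comp_ids <- comp_ids[order(-as.integer(sizes))]
  comp_ids <- head(comp_ids, params$max_components)

  world <- voxel_to_world(arrayInd(fore, dims) - 1L, volume, check = FALSE)
  comps <- lapply(comp_ids, function(id) {
    sel <- memb == id
    w <- world[sel, , drop = FALSE]
    ctr <- colMeans(w)
    list(id = id, lin = fore[sel], n = sum(sel), centroid = ctr,
         extent = 2 * sqrt(max(rowSums(sweep(w, 2L, ctr)^2))),
         max_int = max(volume$data[fore[sel]]))
  })

  ext <- vapply(comps, `[[`, numeric(1), "extent")
  annulus <- comps[[which.max(ext)]]
  rest <- comps[-which.max(ext)]
  assign <- list(`3` = annulus)
  if (length(rest) > 0) {
    d_ann <- vapply(rest, function(cm) sqrt(sum((cm$centroid - annulus$centroid)^2)),
                    numeric(1))
    ord <- order(d_ann)
    mag_idx <- head(ord, 2)
    if (length(mag_idx) == 2) {
      mags <- rest[mag_idx]
      ball <- which.max(vapply(mags, `[[`, numeric(1), "max_int"))
      assign[["1"]] <- mags[[ball]]
      assign[["2"]] <- mags[[3 - ball]]
    }
    small <- rest[setdiff(seq_along(rest), mag_idx)]
    d_small <- d_ann[setdiff(seq_along(rest), mag_idx)]
    if (length(small) >= 2) {
      assign[["4"]] <- small[[which.min(d_small)]]
      assign[["5"]] <- small[[which.max(d_small)]]
    } else if (length(small) == 1) {
      # lone small component: near the annulus it is the RHS fiducial,
      # far out along the valve body it is the distal tip
      if (d_small < 1.5 * annulus$extent / 2) assign[["4"]] <- small[[1]]
      else assign[["5"]] <- small[[1]]
    }
  }
  labels <- array(0L, dims)
  for (lab in names(assign)) labels[assign[[lab]]$lin] <- as.integer(lab)
  label_map(labels, volume$affine)
}
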