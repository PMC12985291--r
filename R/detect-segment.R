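# Organic segmentation and 3D connected-component labelling.

#' Segment organic-range material
#'
#' Thresholds the volume to the organic radiodensity range, then applies a
#' binary morphological opening (erosion followed by dilation) with a discrete
#' ball structuring element. `openingRadius = 0` is pure thresholding.
#'
#' @param volume A [ScanVolume-class].
#' @param organicRange Numeric `[low, high]` radiodensity bounds (low < high).
#' @param openingRadius Ball radius in voxels (>= 0); default 1.
#' @return Logical 3D array; a subset of the thresholded voxels.
#' @examples
#' v <- ScanVolume(array(1000, c(32, 32, 32)), 2)
#' m <- segmentOrganic(v, c(900, 1400), openingRadius = 0)
#' all(m)
#' @export
segmentOrganic <- function(volume, organicRange = c(900, 1400),
                           openingRadius = 1) {
  stopifnot(is(volume, "ScanVolume"))
  if (organicRange[1] >= organicRange[2]) stop("organicRange must satisfy low < high")
  if (openingRadius < 0) stop("openingRadius must be >= 0")
  arr <- intensities(volume)
  if (length(arr) == 0L) stop("empty volume")
  mask <- arr >= organicRange[1] & arr <= organicRange[2]
  if (openingRadius == 0) return(mask)
  offs <- ballOffsets(openingRadius)
  # erosion: voxel survives iff every ball offset is foreground
  er <- mask
  for (i in seq_len(nrow(offs))) {
    o <- offs[i, ]
    if (all(o == 0)) next
    er <- er & shiftMask(mask, -o)
  }
  # dilation of the eroded mask
  di <- er
  for (i in seq_len(nrow(offs))) {
    o <- offs[i, ]
    if (all(o == 0)) next
    di <- di | shiftMask(er, o)
  }
  di
}

#' Label 3D connected components as blobs
#'
#' Decomposes a binary mask into maximal 26-connected components and returns
#' those with at least `minBlobVoxels` voxels as [Blob-class] objects.
#' Components are found on the voxel adjacency graph.
#'
#' @param mask Logical 3D array.
#' @param spacing Voxel spacing in mm (scalar or length 3).
#' @param minBlobVoxels Minimum component size kept; default 30.
#' @param connectivity Voxel adjacency; 26 (default), 18 or 6.
#' @return List of [Blob-class] objects, largest first.
#' @examples
#' m <- array(FALSE, c(8, 8, 8)); m[2:3, 2:3, 2:3] <- TRUE
#' length(labelComponents(m, minBlobVoxels = 1))
#' @export
labelComponents <- function(mask, spacing = c(1, 1, 1), minBlobVoxels = 30L,
                            connectivity = 26L) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (!connectivity %in% c(6L, 18L, 26L)) stop("connectivity must be 6, 18 or 26")
  d <- dim(mask)
  fg <- which(mask)
  if (length(fg) == 0L) return(list())

  membership <- .componentMembership(mask, fg, d, connectivity)
  comps <- split(fg, membership)
  sizes <- lengths(comps)
  comps <- comps[sizes >= minBlobVoxels]
  comps <- comps[order(lengths(comps), decreasing = TRUE)]
  lapply(seq_along(comps), function(i) {
    new("Blob", coords = arrayInd(comps[[i]], d), spacing = spacing,
        id = as.integer(i))
  })
}

# component membership of foreground linear indices via the adjacency graph
.componentMembership <- function(mask, fg, d, connectivity) {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  nb <- as.matrix(g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ])
  ord <- rowSums(abs(nb))
  nb <- switch(as.character(connectivity),
               "6" = nb[ord == 1, , drop = FALSE],
               "18" = nb[ord <= 2, , drop = FALSE],
               "26" = nb)
  # half the offsets suffice: each undirected edge is built once
  keep <- nb[, 1] > 0 | (nb[, 1] == 0 & nb[, 2] > 0) |
    (nb[, 1] == 0 & nb[, 2] == 0 & nb[, 3] > 0)
  nb <- nb[keep, , drop = FALSE]

  coords <- arrayInd(fg, d)
  edges <- vector("list", nrow(nb))
  for (i in seq_len(nrow(nb))) {
    o <- nb[i, ]
    nc <- coords + matrix(o, nrow(coords), 3L, byrow = TRUE)
    ok <- nc[, 1] >= 1L & nc[, 1] <= d[1] & nc[, 2] >= 1L & nc[, 2] <= d[2] &
      nc[, 3] >= 1L & nc[, 3] <= d[3]
    lin <- (nc[ok, 3] - 1L) * d[1] * d[2] + (nc[ok, 2] - 1L) * d[1] + nc[ok, 1]
    hit <- match(lin, fg)
    src <- which(ok)[!is.na(hit)]
    dst <- hit[!is.na(hit)]
    if (length(src)) edges[[i]] <- cbind(src, dst)
  }
  edges <- do.call(rbind, edges)
  gph <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (!is.null(edges) && nrow(edges))
    gph <- igraph::add_edges(gph, t(edges))
  igraph::components(gph)$membership
}
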