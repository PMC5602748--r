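#' 3-D intensity volume
#'
#' Minimal container for a metal-bright (CT-like) volume: an intensity array
#' in Hounsfield units plus a voxel-to-world affine. The affine maps 0-based
#' voxel indices (NIfTI convention) to world mm.
#'
#' @param data 3-D numeric array (HU)
#' @param affine 4x4 voxel-to-world matrix
#' @return an `sd_volume`
#' @export
sd_volume <- function(data, affine) {
  stopifnot(length(dim(data)) == 3L, all(dim(affine) == c(4L, 4L)))
  if (abs(det(affine[1:3, 1:3])) < .Machine$double.eps)
    stop("affine is not invertible")
  vox <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(vox <= 0)) stop("voxel sizes must be positive")
  structure(list(data = data, affine = affine, voxel = vox), class = "sd_volume")
}

#' Read a NIfTI volume as an `sd_volume`
#' @param path NIfTI file path
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  sd_volume(as.array(img), matrix(RNifti::xform(img), 4L, 4L))
}

#' Write an `sd_volume` to NIfTI
#' @param volume an `sd_volume`
#' @param path output path (.nii or .nii.gz)
#' @export
write_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$data)
  # sform stores the full affine (qform is quaternion-based and would lose
  # anisotropic scaling unless pixdim is managed separately)
  RNifti::sform(img) <- structure(volume$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Segment metal-bright components in a volume
#'
#' Electrodes are far brighter than brain tissue (which stays in the 20-120
#' HU range while metal exceeds 3000 HU), so a single threshold isolates
#' them. Voxels above the threshold are grouped into 26-connected components
#' and each component is summarized by the world-coordinate mean of its
#' voxel centers.
#'
#' @param volume an `sd_volume`
#' @param threshold HU cutoff (default 3000)
#' @return list with `centroids` (k x 3 world mm), `sizes` (voxel counts) and
#'   `voxels` (list of 0-based voxel index matrices); empty with a warning if
#'   nothing exceeds the threshold
#' @export
segment_metal <- function(volume, threshold = 3000) {
  dm <- dim(volume$data)
  mask <- as.vector(volume$data > threshold)
  lab <- label_components_26(mask, dm[1], dm[2], dm[3])
  k <- max(lab)
  if (k == 0L) {
    warning(sprintf("no voxels above %g HU", threshold))
    return(list(centroids = matrix(numeric(0), 0, 3), sizes = integer(0),
                voxels = list()))
  }
  which_lab <- which(lab > 0L)
  grp <- lab[which_lab]
  # 0-based voxel indices
  i0 <- (which_lab - 1L) %% dm[1]
  j0 <- ((which_lab - 1L) %/% dm[1]) %% dm[2]
  k0 <- (which_lab - 1L) %/% (dm[1] * dm[2])
  cent_vox <- cbind(rowsum(i0, grp), rowsum(j0, grp), rowsum(k0, grp)) /
    as.vector(table(grp))
  world <- t(volume$affine %*% rbind(t(cent_vox), 1))[, 1:3, drop = FALSE]
  vox_list <- lapply(seq_len(k), function(g) {
    sel <- grp == g
    cbind(i0[sel], j0[sel], k0[sel])
  })
  list(centroids = world, sizes = as.integer(table(grp)), voxels = vox_list)
}

#' Snap world-coordinate centroids to mesh vertices
#'
#' Maps each electrode centroid to the mesh vertex at the smallest Euclidean
#' distance (ties broken by the smallest vertex id). Two centroids snapping
#' to the same vertex is an error: electrodes must remain distinct.
#'
#' @param centroids k x 3 matrix of world coordinates (mm)
#' @param mesh an [sd_mesh()]
#' @param labels electrode labels (default E1..Ek)
#' @param spacing nominal inter-electrode spacing in mm (metadata)
#' @return an `sd_electrodes`: list(labels, centroids, vertex, snap_distance,
#'   spacing)
#' @export
snap_to_mesh <- function(centroids, mesh, labels = NULL, spacing = 10) {
  centroids <- matrix(as.numeric(centroids), ncol = 3)
  if (nrow(centroids) < 1L) stop("need at least one centroid")
  if (nrow(mesh$vertices) == 0L) stop("empty mesh")
  if (is.null(labels)) labels <- paste0("E", seq_len(nrow(centroids)))
  if (anyDuplicated(labels)) stop("electrode labels must be unique")
  v <- mesh$vertices
  vert <- integer(nrow(centroids))
  sd_ <- numeric(nrow(centroids))
  for (i in seq_len(nrow(centroids))) {
    d2 <- (v[, 1] - centroids[i, 1])^2 + (v[, 2] - centroids[i, 2])^2 +
      (v[, 3] - centroids[i, 3])^2
    vert[i] <- which.min(d2)  # which.min returns the first (smallest id) tie
    sd_[i] <- sqrt(d2[vert[i]])
  }
  if (anyDuplicated(vert)) {
    dup <- vert[duplicated(vert)][1]
    stop(sprintf("degenerate snap: electrodes %s share vertex %d",
                 paste(labels[vert == dup], collapse = ", "), dup))
  }
  structure(list(labels = labels, centroids = centroids,
                 vertex = setNames(vert, labels),
                 snap_distance = setNames(sd_, labels), spacing = spacing),
            class = "sd_electrodes")
}

#' @export
print.sd_electrodes <- function(x, ...) {
  cat(sprintf("<sd_electrodes> %d electrodes (%s), nominal spacing %.0f mm\n",
              length(x$labels), paste(x$labels, collapse = " "), x$spacing))
  invisible(x)
}

#' Locate electrodes in a volume and snap them to a mesh
#'
#' Convenience wrapper: [segment_metal()] then [snap_to_mesh()], ordering
#' components along the strip axis (first principal component of the
#' centroids) so labels run consistently from one end to the other.
#'
#' @inheritParams segment_metal
#' @inheritParams snap_to_mesh
#' @param order `"axis"` (order centroids along their principal axis) or
#'   `"none"` (keep component discovery order)
#' @export
locate_electrodes <- function(volume, mesh, threshold = 3000, labels = NULL,
                              spacing = 10, order = c("axis", "none")) {
  order <- match.arg(order)
  seg <- segment_metal(volume, threshold)
  cen <- seg$centroids
  if (nrow(cen) == 0L) stop("no electrode components found")
  if (order == "axis" && nrow(cen) > 1L) {
    ctr <- scale(cen, scale = FALSE)
    ax <- svd(ctr)$v[, 1]
    cen <- cen[order(ctr %*% ax), , drop = FALSE]
  }
  snap_to_mesh(cen, mesh, labels = labels, spacing = spacing)
}

#' Write an electrode table (labels, centroids, snapped vertices) to CSV
#' @param electrodes an `sd_electrodes`
#' @param path output CSV path
#' @export
write_electrodes_csv <- function(electrodes, path) {
  df <- data.frame(label = electrodes$labels,
                   x = electrodes$centroids[, 1],
                   y = electrodes$centroids[, 2],
                   z = electrodes$centroids[, 3],
                   vertex = as.integer(electrodes$vertex),
                   snap_distance_mm = as.numeric(electrodes$snap_distance))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
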