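#' @keywords internal
atlas_area_scheme <- function() {
  # 24 areas per hemisphere with their per-hemisphere node counts:
  # 20 cortical areas (105 nodes) + 4 subcortical areas (18 nodes) = 123.
  data.frame(
    area = c("SFG", "MFG", "IFG", "OrG", "PrG", "PCL", "STG", "MTG", "ITG",
             "FuG", "PhG", "pSTS", "SPL", "IPL", "PCun", "PoG", "INS", "CG",
             "MVOcC", "LOcC", "Amyg", "Hipp", "BG", "Tha"),
    n_nodes = c(7, 7, 6, 6, 6, 2, 6, 4, 7, 3, 6, 2, 5, 6, 4, 4, 6, 7, 5, 6,
                2, 2, 6, 8),
    cortical = c(rep(TRUE, 20), rep(FALSE, 4)),
    stringsAsFactors = FALSE
  )
}

#' Default 246-node atlas table
#'
#' Builds the bundled atlas: 246 regions of interest, 123 per hemisphere,
#' grouped into 48 areas (24 per hemisphere, Brainnetome-style naming and
#' node counts; 210 cortical and 36 subcortical nodes). Node order is the
#' package's canonical block order: all left-hemisphere nodes (1-123)
#' followed by all right-hemisphere nodes (124-246).
#'
#' The MNI coordinates are schematic placeholders (synthetic, deterministic),
#' suitable for geometry-free analyses and for exercising the centroid and
#' lead-field machinery; they are not measured anatomical coordinates.
#'
#' @return A validated atlas data.frame (see [load_atlas()] for columns).
#' @export
default_atlas <- function() {
  scheme <- atlas_area_scheme()
  rows <- list()
  node <- 0L
  for (hemi in c("L", "R")) {
    for (a in seq_len(nrow(scheme))) {
      for (k in seq_len(scheme$n_nodes[a])) {
        node <- node + 1L
        # schematic coordinates: areas laid out anterior->posterior,
        # nodes within an area stacked inferior->superior
        y <- round(80 - 160 * (a - 0.5) / nrow(scheme), 1)
        z <- round(-40 + 100 * (k - 0.5) / scheme$n_nodes[a], 1)
        x <- if (hemi == "L") -45 else 45
        rows[[node]] <- data.frame(
          node_id = node,
          name = sprintf("%s_%s_%d", hemi, scheme$area[a], k),
          hemisphere = hemi,
          area_group = paste0(hemi, "_", scheme$area[a]),
          cortical = scheme$cortical[a],
          mni_x = x, mni_y = y, mni_z = z,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  atlas <- do.call(rbind, rows)
  validate_atlas(atlas)
  atlas
}

#' Validate an atlas table
#'
#' Checks the structural invariants: 246 unique nodes, 123 per hemisphere,
#' hemisphere codes in {L, R}, and exactly 24 distinct area groups per
#' hemisphere.
#'
#' @param atlas A data.frame as returned by [load_atlas()].
#' @return The atlas, invisibly, if valid; otherwise an error naming the
#'   violated invariant.
#' @export
validate_atlas <- function(atlas) {
  required <- c("node_id", "name", "hemisphere", "area_group", "cortical",
                "mni_x", "mni_y", "mni_z")
  missing <- setdiff(required, names(atlas))
  if (length(missing) > 0) {
    stop("atlas is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(atlas) != 246L) {
    stop("atlas must have exactly 246 rows, got ", nrow(atlas), call. = FALSE)
  }
  if (anyDuplicated(atlas$node_id)) {
    stop("atlas node_id values must be unique", call. = FALSE)
  }
  if (!setequal(atlas$node_id, 1:246)) {
    stop("atlas node_id values must cover 1..246", call. = FALSE)
  }
  if (!all(atlas$hemisphere %in% c("L", "R"))) {
    stop("atlas hemisphere codes must be 'L' or 'R'", call. = FALSE)
  }
  counts <- table(atlas$hemisphere)
  if (!identical(sort(names(counts)), c("L", "R")) ||
      counts[["L"]] != 123L || counts[["R"]] != 123L) {
    stop("atlas must have exactly 123 nodes per hemisphere", call. = FALSE)
  }
  for (h in c("L", "R")) {
    n_areas <- length(unique(atlas$area_group[atlas$hemisphere == h]))
    if (n_areas != 24L) {
      stop("atlas must have exactly 24 area groups in hemisphere ", h,
           ", got ", n_areas, call. = FALSE)
    }
  }
  invisible(atlas)
}

#' Read an atlas table from tab-separated text
#'
#' Expected header:
#' `node_id name hemisphere area_group cortical mni_x mni_y mni_z`.
#' Row order is preserved; the table is validated on load.
#'
#' @param path Path to a TSV file.
#' @return A validated atlas data.frame.
#' @export
load_atlas <- function(path) {
  atlas <- utils::read.delim(path, stringsAsFactors = FALSE)
  if ("cortical" %in% names(atlas)) atlas$cortical <- as.logical(atlas$cortical)
  validate_atlas(atlas)
  atlas
}

#' Write an atlas table as tab-separated text
#'
#' @param atlas A validated atlas data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_atlas <- function(atlas, path) {
  validate_atlas(atlas)
  utils::write.table(atlas, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Intra-hemispheric node index blocks
#'
#' Returns the node indices of the two hemispheres in canonical order
#' (ascending node id, left block then right block). These index the rows
#' and columns of a 246 x 246 adjacency in canonical atlas order, so that
#' `adj[right, right]` is the right intra-hemispheric (second-quadrant)
#' submatrix and `adj[left, left]` the left one (fourth quadrant).
#'
#' @param atlas A validated atlas data.frame.
#' @return A list with integer vectors `left` and `right`, each of length
#'   123, partitioning 1..246.
#' @export
hemisphere_blocks <- function(atlas) {
  validate_atlas(atlas)
  list(
    left = sort(atlas$node_id[atlas$hemisphere == "L"]),
    right = sort(atlas$node_id[atlas$hemisphere == "R"])
  )
}

#' Load a labeled volume
#'
#' Accepts either a NIfTI label image (requires the RNifti package) or a
#' plain-text table with columns `i j k label` giving 1-based voxel indices
#' and integer ROI labels (0 = background rows may be omitted).
#'
#' @param path Path to a `.nii`/`.nii.gz` image or a delimited text file.
#' @param voxel_size Voxel edge length in mm (default 2); ignored for NIfTI
#'   input, where it is read from the header.
#' @return A list with `labels` (3-D integer array), `grid_shape`, and
#'   `voxel_size`.
#' @export
load_labeled_volume <- function(path, voxel_size = 2) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    if (!requireNamespace("RNifti", quietly = TRUE)) {
      stop("reading NIfTI volumes requires the RNifti package", call. = FALSE)
    }
    img <- RNifti::readNifti(path)
    labels <- array(as.integer(round(img)), dim = dim(img))
    vs <- RNifti::pixdim(img)[1]
    return(list(labels = labels, grid_shape = dim(labels), voxel_size = vs))
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("i", "j", "k", "label")
  if (!all(required %in% names(tab))) {
    stop("labeled-volume text file needs columns i, j, k, label",
         call. = FALSE)
  }
  shape <- c(max(tab$i), max(tab$j), max(tab$k))
  labels <- array(0L, dim = shape)
  labels[cbind(tab$i, tab$j, tab$k)] <- as.integer(tab$label)
  list(labels = labels, grid_shape = shape, voxel_size = voxel_size)
}

#' Exact medoid centroid of a labeled ROI
#'
#' Finds the voxel of the ROI minimizing the sum of squared Euclidean
#' distances to all other voxels of the ROI (the k-medoids objective at
#' k = 1, solved exactly rather than by iterative swapping). Ties are broken
#' deterministically by the smallest linear voxel index.
#'
#' @param vol A labeled volume, as returned by [load_labeled_volume()].
#' @param roi_label Integer ROI label present in the volume.
#' @return Integer vector `(i, j, k)` of the medoid voxel (1-based indices).
#' @export
medoid_centroid <- function(vol, roi_label) {
  idx <- which(vol$labels == roi_label)
  if (length(idx) == 0L) {
    stop("label ", roi_label, " not present in volume", call. = FALSE)
  }
  coords <- arrayInd(idx, dim(vol$labels))
  storage.mode(coords) <- "double"
  n <- nrow(coords)
  # sum_j ||v_i - v_j||^2 = n ||v_i||^2 - 2 v_i . s + sum_j ||v_j||^2
  s <- colSums(coords)
  sq <- rowSums(coords^2)
  ssd <- n * sq - 2 * drop(coords %*% s) + sum(sq)
  # which.min already takes the first (= smallest linear index, since
  # arrayInd preserves the order of `which`)
  best <- which.min(round(ssd, 9))
  as.integer(coords[best, ])
}
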