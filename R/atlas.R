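#' Build a synthetic Desikan-Killiany-style ROI atlas
#'
#' Constructs a parcellation of an ellipsoidal brain mask into `n_rois`
#' contiguous regions by nearest-seed (Voronoi) assignment, with left/right
#' hemisphere ROIs as mirror-image, name-matched pairs.  Each ROI carries a
#' Braak onset stage (1-6): medial-temporal ROIs onset at stages 1-2, other
#' temporal ROIs at 3-4, and neocortical/parietal ROIs at 5-6, mirroring the
#' stereotyped entorhinal-to-neocortex spread of neurofibrillary tangles.
#' The temporal meta-ROI (used for the MetaTempTau composite) comprises the
#' amygdala, entorhinal, parahippocampal, fusiform, and inferior/middle
#' temporal ROIs, when present.
#'
#' Real label volumes (e.g. a FreeSurfer Desikan-Killiany parcellation) can
#' be supplied through [read_atlas()] instead; all downstream code only
#' consumes the `coma_atlas` container.
#'
#' @param grid integer vector of length 3, voxel counts per axis (each >= 8).
#' @param n_rois even number of regions (default 32, i.e. 16 bilateral pairs).
#' @param seed integer seed; the atlas is a pure function of (grid, n_rois,
#'   seed).
#' @return An object of class `coma_atlas`: a list with `label_volume`
#'   (3D integer array, 0 = background), `roi_table` (data.frame with columns
#'   id, name, hemisphere, lobe, braak_onset_stage, in_meta_temp, n_voxels),
#'   `meta_temp_members` (integer ROI ids), and `grid`.
#' @examples
#' atl <- build_atlas(c(16, 16, 16), n_rois = 8, seed = 1)
#' table(atl$label_volume)[-1]
#' @export
build_atlas <- function(grid, n_rois = 32L, seed = 1L) {
  grid <- as.integer(grid)
  if (length(grid) != 3L || any(grid < 8L)) {
    stop("grid must be three dimensions, each >= 8")
  }
  n_rois <- as.integer(n_rois)
  if (n_rois < 2L || n_rois %% 2L != 0L) {
    stop("n_rois must be an even count >= 2 (bilateral pairs)")
  }
  n_pairs <- n_rois %/% 2L

  coords <- voxel_coords(grid)
  mask <- brain_mask_vec(grid, coords)
  left <- coords[, 1] < (grid[1] + 1) / 2
  left_mask_idx <- which(mask & left)
  if (length(left_mask_idx) < n_pairs) {
    stop("grid too small to host ", n_rois, " non-empty regions")
  }

  roi_defs <- roi_name_pool(n_pairs)

  with_seed(seed, {
    seed_idx <- sample(left_mask_idx, n_pairs)
  })
  # order seeds so early (low Braak onset) ROIs sit medial and inferior
  sc <- coords[seed_idx, , drop = FALSE]
  medial_inferior <- abs(sc[, 1] - (grid[1] + 1) / 2) + sc[, 3]
  seed_idx <- seed_idx[order(medial_inferior)]
  sc <- coords[seed_idx, , drop = FALSE]

  # nearest-seed assignment within each hemisphere
  lab <- integer(prod(grid))
  for (hemi in c("left", "right")) {
    vox <- which(mask & (if (hemi == "left") left else !left))
    pts <- coords[vox, , drop = FALSE]
    seeds <- sc
    if (hemi == "right") seeds[, 1] <- grid[1] + 1 - seeds[, 1]
    d2 <- outer(rowSums(pts^2), rowSums(seeds^2), "+") -
      2 * pts %*% t(seeds)
    nearest <- max.col(-d2, ties.method = "first")
    lab[vox] <- (nearest - 1L) * 2L + if (hemi == "left") 1L else 2L
  }

  ids <- seq_len(n_rois)
  pair_of <- (ids + 1L) %/% 2L
  hemi_of <- ifelse(ids %% 2L == 1L, "left", "right")
  roi_table <- data.frame(
    id = ids,
    name = paste0(roi_defs$name[pair_of], "_", hemi_of),
    hemisphere = hemi_of,
    lobe = roi_defs$lobe[pair_of],
    braak_onset_stage = roi_defs$stage[pair_of],
    in_meta_temp = roi_defs$meta[pair_of],
    stringsAsFactors = FALSE
  )
  counts <- tabulate(lab, nbins = n_rois)
  if (any(counts == 0L)) {
    stop("grid too small to host ", n_rois, " non-empty regions")
  }
  roi_table$n_voxels <- counts

  label_volume <- array(lab, dim = grid)
  atl <- structure(
    list(label_volume = label_volume,
         roi_table = roi_table,
         meta_temp_members = ids[roi_table$in_meta_temp],
         grid = grid),
    class = "coma_atlas"
  )
  validate_atlas(atl)
  atl
}

# voxel coordinates (n_vox x 3), column-major
voxel_coords <- function(grid) {
  cbind(rep(seq_len(grid[1]), times = grid[2] * grid[3]),
        rep(rep(seq_len(grid[2]), each = grid[1]), times = grid[3]),
        rep(seq_len(grid[3]), each = grid[1] * grid[2]))
}

brain_mask_vec <- function(grid, coords = voxel_coords(grid)) {
  ctr <- (grid + 1) / 2
  semi <- 0.45 * grid
  rowSums(sweep(sweep(coords, 2, ctr), 2, semi, "/")^2) <= 1
}

#' Brain mask of an atlas
#'
#' Logical 3D array marking voxels assigned to any ROI.
#' @param atlas a `coma_atlas`.
#' @return logical array on the atlas grid.
#' @export
atlas_mask <- function(atlas) atlas$label_volume > 0L

# name pool for bilateral ROI pairs (DK-style); recycled with a numeric
# suffix if more pairs are requested than named regions
roi_name_pool <- function(n_pairs) {
  pool <- data.frame(
    name = c("entorhinal", "parahippocampal", "amygdala", "hippocampus",
             "fusiform", "inferior_temporal", "middle_temporal",
             "superior_temporal", "temporal_pole", "banks_sts",
             "inferior_parietal", "precuneus", "supramarginal",
             "posterior_cingulate", "superior_parietal", "lateral_occipital"),
    lobe = c(rep("medial_temporal", 4L), rep("temporal", 6L),
             rep("parietal", 5L), "occipital"),
    stage = c(1L, 2L, 2L, 2L, 3L, 3L, 4L, 4L, 4L, 4L,
              5L, 5L, 5L, 5L, 6L, 6L),
    meta = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE,
             FALSE, FALSE, FALSE, rep(FALSE, 6L)),
    stringsAsFactors = FALSE
  )
  reps <- ceiling(n_pairs / nrow(pool))
  out <- pool[rep(seq_len(nrow(pool)), reps)[seq_len(n_pairs)], ]
  dup <- duplicated(out$name)
  if (any(dup)) {
    cyc <- (rep(seq_len(reps), each = nrow(pool))[seq_len(n_pairs)])
    out$name <- ifelse(cyc > 1L, paste0(out$name, "_", cyc), out$name)
  }
  rownames(out) <- NULL
  out
}

validate_atlas <- function(atlas) {
  lab <- atlas$label_volume
  ids <- atlas$roi_table$id
  if (!all(dim(lab) == atlas$grid)) stop("label volume does not match grid")
  u <- unique(as.vector(lab))
  if (!all(u %in% c(0L, ids))) stop("label volume contains unknown ROI ids")
  counts <- tabulate(as.vector(lab), nbins = max(ids))
  if (any(counts[ids] == 0L)) stop("every ROI must have at least one voxel")
  if (!all(atlas$meta_temp_members %in% ids)) {
    stop("meta_temp_members must be a subset of ROI ids")
  }
  invisible(atlas)
}

#' Per-ROI mean SUVR of a volume
#'
#' Arithmetic mean of the voxel values within each ROI of the atlas;
#' background voxels are excluded.
#'
#' @param volume 3D numeric array on the atlas grid.
#' @param atlas a `coma_atlas`.
#' @return named numeric vector, one mean per ROI id (names = ROI ids).
#' @export
regional_suvr <- function(volume, atlas) {
  if (!all(dim(volume) == atlas$grid)) {
    stop("volume grid ", paste(dim(volume), collapse = "x"),
         " does not match atlas grid ", paste(atlas$grid, collapse = "x"))
  }
  lab <- as.vector(atlas$label_volume)
  keep <- lab > 0L
  sums <- rowsum(as.vector(volume)[keep], lab[keep], reorder = TRUE)
  ids <- atlas$roi_table$id
  counts <- atlas$roi_table$n_voxels
  out <- as.vector(sums[match(ids, as.integer(rownames(sums))), 1L]) / counts
  names(out) <- ids
  out
}

#' Temporal meta-ROI composite SUVR (MetaTempTau)
#'
#' Voxel-count-weighted average of the regional means over the meta-ROI
#' member regions; equivalent to the mean SUVR over the union of the member
#' masks.
#'
#' @param regional_means named numeric vector as returned by
#'   [regional_suvr()] (names = ROI ids); must cover all meta-ROI members.
#' @param atlas a `coma_atlas`.
#' @return scalar SUVR.
#' @export
meta_temp_tau <- function(regional_means, atlas) {
  members <- atlas$meta_temp_members
  m <- regional_means[as.character(members)]
  if (anyNA(m) || length(m) < length(members)) {
    stop("regional_means is missing meta-ROI members: ",
         paste(setdiff(members, as.integer(names(regional_means))),
               collapse = ", "))
  }
  w <- atlas$roi_table$n_voxels[match(members, atlas$roi_table$id)]
  sum(w * m) / sum(w)
}

#' @export
print.coma_atlas <- function(x, ...) {
  cat("Synthetic ROI atlas (", paste(x$grid, collapse = " x "), " grid)\n",
      sep = "")
  cat("  ", nrow(x$roi_table), " ROIs (",
      sum(x$roi_table$hemisphere == "left"), " bilateral pairs), ",
      sum(x$roi_table$n_voxels), " brain voxels\n", sep = "")
  cat("  meta-temporal composite: ", length(x$meta_temp_members),
      " member ROIs\n", sep = "")
  invisible(x)
}

#' Write / read an atlas as NIfTI + CSV
#'
#' The label volume is stored as an integer NIfTI image and the ROI table as
#' a CSV with columns id, name, hemisphere, lobe, braak_onset_stage,
#' in_meta_temp.
#'
#' @param atlas a `coma_atlas`.
#' @param label_path path of the NIfTI label volume.
#' @param table_path path of the ROI table CSV.
#' @return `write_atlas` the paths, invisibly; `read_atlas` a `coma_atlas`.
#' @export
write_atlas <- function(atlas, label_path, table_path) {
  write_volume(atlas$label_volume, label_path)
  tab <- atlas$roi_table[, c("id", "name", "hemisphere", "lobe",
                             "braak_onset_stage", "in_meta_temp")]
  utils::write.csv(tab, table_path, row.names = FALSE)
  invisible(c(label_path, table_path))
}

#' @rdname write_atlas
#' @export
read_atlas <- function(label_path, table_path) {
  vol <- read_volume(label_path)
  lab <- array(as.integer(round(vol$data)), dim = dim(vol$data))
  tab <- utils::read.csv(table_path, stringsAsFactors = FALSE)
  need <- c("id", "name", "hemisphere", "lobe", "braak_onset_stage",
            "in_meta_temp")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("roi_table is missing columns: ",
                         paste(miss, collapse = ", "))
  tab$in_meta_temp <- as.logical(tab$in_meta_temp)
  tab$n_voxels <- tabulate(as.vector(lab), nbins = max(tab$id))[tab$id]
  atl <- structure(
    list(label_volume = lab, roi_table = tab,
         meta_temp_members = tab$id[tab$in_meta_temp],
         grid = dim(lab)),
    class = "coma_atlas"
  )
  validate_atlas(atl)
  atl
}

# run code with a local, restored RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  code
}
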