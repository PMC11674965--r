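#' Visual-stream ROI atlas
#'
#' Loads the packaged fourteen-region atlas of the dorsal visual stream (DVS),
#' ventral visual stream (VVS) and primary visual-stream (VS) connections,
#' with MNI coordinates in millimetres. Each region carries one or more
#' subsystem tags; the superior and inferior occipital gyri are shared between
#' a stream and the primary VS connections from the calcarine.
#'
#' @return A data frame with columns `name`, `x`, `y`, `z` (MNI mm) and
#'   `subsystems` (a list column of character vectors drawn from
#'   `c("DVS", "VVS", "VS")`).
#' @export
#' @examples
#' atlas <- visual_stream_atlas()
#' nrow(atlas)  # 14
visual_stream_atlas <- function() {
  path <- system.file("extdata", "atlas.csv", package = "dvsconn",
                      mustWork = TRUE)
  atlas <- utils::read.csv(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  atlas$subsystems <- strsplit(atlas$subsystems, ";", fixed = TRUE)
  stopifnot(!anyDuplicated(atlas$name),
            all(lengths(atlas$subsystems) >= 1L))
  atlas
}

#' Look up one ROI definition
#'
#' @param atlas Atlas data frame from [visual_stream_atlas()].
#' @param name ROI name, e.g. `"L SPL"`.
#' @return A one-row data frame (coordinates in mm, subsystem tags).
#' @export
atlas_lookup <- function(atlas, name) {
  i <- match(name, atlas$name)
  if (is.na(i)) stop("ROI not in atlas: ", name)
  atlas[i, , drop = FALSE]
}

# Connection template: within each subsystem, source -> target pairs applied
# bilaterally. DVS: occipito-parietal; VVS: occipito-temporal; VS: the primary
# connections out of the calcarine.
.connection_template <- list(
  DVS = list(c("SOG", "IPL"), c("SOG", "SPL")),
  VVS = list(c("IOG", "ITG"), c("IOG", "FG")),
  VS  = list(c("Calc", "IOG"), c("Calc", "SOG"))
)

#' Enumerate the twelve visual-stream connections
#'
#' Builds the fixed set of 12 region pairs composing the three subsystems:
#' four dorsal (SOG to IPL and SPL, bilaterally), four ventral (IOG to ITG and
#' FG, bilaterally) and four primary visual-stream connections (calcarine to
#' IOG and SOG, bilaterally). The listing order is deterministic
#' (DVS, VVS, VS; left before right; template order within hemisphere) so that
#' Holm families are reproducible.
#'
#' @param atlas Atlas data frame from [visual_stream_atlas()]; a subset atlas
#'   yields only the connections whose members are present, and an atlas
#'   missing one member of a required pair raises an error naming the ROI if
#'   the other member is present.
#' @return A data frame with columns `roi_a`, `roi_b`, `subsystem` and
#'   `connection` (a stable `"A--B"` label).
#' @export
stream_connections <- function(atlas) {
  rows <- list()
  for (subsystem in names(.connection_template)) {
    for (hemi in c("L", "R")) {
      for (pair in .connection_template[[subsystem]]) {
        a <- paste(hemi, pair[1])
        b <- paste(hemi, pair[2])
        have_a <- a %in% atlas$name
        have_b <- b %in% atlas$name
        if (have_a && have_b) {
          rows[[length(rows) + 1L]] <- data.frame(
            roi_a = a, roi_b = b, subsystem = subsystem,
            stringsAsFactors = FALSE)
        } else if (have_a != have_b) {
          stop("atlas is missing ROI ", if (have_a) b else a,
               " required for a ", subsystem, " connection")
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(roi_a = character(), roi_b = character(),
                      subsystem = character(), connection = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$connection <- connection_label(out$roi_a, out$roi_b)
  out
}

#' @rdname stream_connections
#' @param roi_a,roi_b ROI names.
#' @export
connection_label <- function(roi_a, roi_b) {
  if (length(roi_a)) paste(roi_a, roi_b, sep = "--") else character()
}

#' Default 2 mm isotropic MNI sampling grid
#'
#' The standard 91 x 109 x 91 MNI152 grid with its voxel-to-mm affine
#' (0-based voxel indices). ROI extraction is grid-agnostic; this is the
#' default used when no acquisition grid is supplied.
#'
#' @return A list with `affine` (4 x 4) and `dim` (length-3 integer).
#' @export
mni_grid_2mm <- function() {
  affine <- rbind(c(-2, 0, 0,   90),
                  c( 0, 2, 0, -126),
                  c( 0, 0, 2,  -72),
                  c( 0, 0, 0,    1))
  list(affine = affine, dim = c(91L, 109L, 91L))
}

#' Spherical voxel mask around an MNI coordinate
#'
#' A voxel belongs to the mask iff the Euclidean distance from its centre's
#' mm coordinates to `center` is at most `radius` (voxel-centre convention;
#' partial-overlap voxels whose centres fall outside are excluded). The mask
#' is clipped to the grid bounds.
#'
#' @param center Numeric length-3 MNI coordinate (mm).
#' @param radius Sphere radius in mm (> 0).
#' @param grid List with `affine` (4 x 4 voxel-to-mm, 0-based indices) and
#'   `dim`; defaults to [mni_grid_2mm()].
#' @return A logical array of dimension `grid$dim`.
#' @export
sphere_mask <- function(center, radius, grid = mni_grid_2mm()) {
  stopifnot(length(center) == 3, radius > 0)
  affine <- grid$affine
  if (abs(det(affine)) < .Machine$double.eps) stop("affine is singular")
  dm <- as.integer(grid$dim)

  # bound the search box in voxel space to avoid touching the whole grid
  inv <- solve(affine)
  vox_center <- (inv %*% c(center, 1))[1:3]
  # conservative per-axis half-width: radius / smallest singular value
  sv <- svd(affine[1:3, 1:3])$d
  half <- ceiling(radius / min(sv)) + 1L
  lo <- pmax(floor(vox_center) - half, 0)
  hi <- pmin(ceiling(vox_center) + half, dm - 1L)

  mask <- array(FALSE, dim = dm)
  if (any(lo > hi)) {
    warning("ROI centre at (", paste(center, collapse = ", "),
            ") lies entirely outside the grid; mask is empty")
    return(mask)
  }
  idx <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2],
                               k = lo[3]:hi[3]))
  mm <- idx %*% t(affine[1:3, 1:3]) +
    matrix(affine[1:3, 4], nrow(idx), 3, byrow = TRUE)
  d2 <- rowSums(sweep(mm, 2, center)^2)
  keep <- idx[d2 <= radius^2 + 1e-9, , drop = FALSE]
  if (nrow(keep) == 0) {
    warning("ROI centre at (", paste(center, collapse = ", "),
            ") produced an empty mask on this grid")
    return(mask)
  }
  mask[keep + 1L] <- TRUE
  mask
}

#' Extract a voxel-averaged, detrended, normalized ROI time series
#'
#' The fixed processing order per run segment is: voxel average over the mask,
#' removal of the least-squares linear trend, then z-normalization to zero
#' mean and unit variance. Run segments are processed independently.
#'
#' @param volume4d A 4D numeric array (x, y, z, time).
#' @param mask Logical 3D array matching the spatial dimensions.
#' @param runs Optional integer vector of length `dim(volume4d)[4]` assigning
#'   each volume to a run; default one run.
#' @return Numeric vector of length `dim(volume4d)[4]`.
#' @export
extract_roi_series <- function(volume4d, mask, runs = NULL) {
  stopifnot(length(dim(volume4d)) == 4,
            identical(dim(volume4d)[1:3], dim(mask)))
  if (!any(mask)) stop("mask is empty")
  nt <- dim(volume4d)[4]
  if (nt < 3) stop("time series too short (need >= 3 samples)")
  if (is.null(runs)) runs <- rep(1L, nt)
  stopifnot(length(runs) == nt)

  vmat <- matrix(volume4d, ncol = nt)[as.vector(mask), , drop = FALSE]
  avg <- colMeans(vmat)
  out <- numeric(nt)
  for (r in unique(runs)) {
    seg <- avg[runs == r]
    out[runs == r] <- detrend_normalize(seg)
  }
  out
}

# detrend (least-squares line) then z-normalize one run segment
detrend_normalize <- function(x) {
  t_idx <- seq_along(x)
  resid <- stats::.lm.fit(cbind(1, t_idx), x)$residuals
  s <- stats::sd(resid)
  if (!is.finite(s) || s < 1e-12 * max(1, mean(abs(x))))
    stop("degenerate signal: zero variance after detrending")
  (resid - mean(resid)) / s
}
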