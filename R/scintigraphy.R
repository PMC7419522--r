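# Scintigraphy mimicry: map a solved deposition field onto an isotropic
# voxel grid (default 5 mm) and integrate along the ventral-dorsal (y)
# axis into a 2D coronal projection. Voxel membership is a
# center-in-cylinder test with per-segment renormalization so each
# segment's voxels sum exactly to its capture probability (the raw
# volume-ratio rule under-fills segments thinner than the grid); a voxel
# center inside two segments goes to the deeper generation. Escaped mass
# is spread uniformly over a 3x3x3 voxel cube at each terminal's distal
# end; overlapping cubes accumulate additively.

#' Voxelize a deposition field
#'
#' @param tree The [airway_tree()] the deposition was computed on.
#' @param deposition A `deposition_result` or `policy_evaluation` holding
#'   per-segment `capture` and `escape_by_terminal`.
#' @param voxel_edge Isotropic voxel edge, m (default 0.005 = 5 mm).
#' @return An object of class `voxel_grid`: list with the 3D `values`
#'   array (x, y, z), `origin` (corner of voxel `[1,1,1]`), `edge`.
#' @export
voxelize <- function(tree, deposition, voxel_edge = 0.005) {
  if (!is.numeric(voxel_edge) || voxel_edge <= 0) {
    stop("voxel_edge must be positive")
  }
  capture <- deposition$capture
  ebt <- deposition$escape_by_terminal
  if (is.null(capture) || is.null(ebt)) {
    stop("deposition must carry `capture` and `escape_by_terminal`")
  }
  h <- voxel_edge
  pts <- rbind(as.matrix(tree[, c("x0", "y0", "z0")]),
               as.matrix(tree[, c("x1", "y1", "z1")]))
  pad <- max(tree$diameter) / 2 + 2.5 * h
  lo <- unname(apply(pts, 2, min)) - pad
  hi <- unname(apply(pts, 2, max)) + pad
  origin <- floor(lo / h) * h
  dims <- as.integer(pmax(ceiling((hi - origin) / h), 1))
  vals <- array(0, dim = dims)
  owner <- array(0L, dim = dims)

  axes <- .tree_axes(tree)
  # deeper generations processed later overwrite junction-straddling voxels
  for (k in order(tree$generation)) {
    idx <- .cylinder_voxels(tree[k, ], axes[k, ], origin, h, dims)
    if (nrow(idx)) owner[idx] <- k
  }
  for (k in seq_len(nrow(tree))) {
    if (capture[k] == 0) next
    cells <- which(owner == k)
    if (length(cells)) {
      vals[cells] <- vals[cells] + capture[k] / length(cells)
    } else {
      # segment thinner/shorter than the grid: assign its mass to the
      # voxel containing its midpoint to preserve probability
      mid <- c(tree$x0[k] + tree$x1[k], tree$y0[k] + tree$y1[k],
               tree$z0[k] + tree$z1[k]) / 2
      ijk <- pmin(pmax(floor((mid - origin) / h) + 1L, 1L), dims)
      vals[ijk[1], ijk[2], ijk[3]] <- vals[ijk[1], ijk[2], ijk[3]] + capture[k]
    }
  }
  # 3x3x3 escape cubes at terminal distal ends
  for (t in as.integer(names(ebt))) {
    if (ebt[as.character(t)] == 0) next
    end <- c(tree$x1[t], tree$y1[t], tree$z1[t])
    ctr <- floor((end - origin) / h) + 1L
    share <- ebt[as.character(t)] / 27
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      ijk <- pmin(pmax(ctr + c(dx, dy, dz), 1L), dims)
      vals[ijk[1], ijk[2], ijk[3]] <- vals[ijk[1], ijk[2], ijk[3]] + share
    }
  }
  structure(list(values = vals, origin = origin, edge = h),
            class = "voxel_grid")
}

# voxel indices (matrix of i,j,k rows) whose centers lie inside the
# cylinder of segment `seg` with unit axis `ax`
.cylinder_voxels <- function(seg, ax, origin, h, dims) {
  r <- seg$diameter / 2
  lo <- pmin(c(seg$x0, seg$y0, seg$z0), c(seg$x1, seg$y1, seg$z1)) - r
  hi <- pmax(c(seg$x0, seg$y0, seg$z0), c(seg$x1, seg$y1, seg$z1)) + r
  i0 <- pmax(floor((lo - origin) / h) + 1L, 1L)
  i1 <- pmin(ceiling((hi - origin) / h), dims)
  if (any(i1 < i0)) return(matrix(integer(0), 0, 3))
  gx <- origin[1] + (seq.int(i0[1], i1[1]) - 0.5) * h
  gy <- origin[2] + (seq.int(i0[2], i1[2]) - 0.5) * h
  gz <- origin[3] + (seq.int(i0[3], i1[3]) - 0.5) * h
  cen <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  w <- sweep(cen, 2, c(seg$x0, seg$y0, seg$z0))
  t_ax <- as.vector(w %*% ax)
  rad2 <- rowSums(w^2) - t_ax^2
  inside <- t_ax >= 0 & t_ax <= seg$length & rad2 <= r^2 + 1e-15
  if (!any(inside)) return(matrix(integer(0), 0, 3))
  ijk <- as.matrix(expand.grid(i = seq.int(i0[1], i1[1]),
                               j = seq.int(i0[2], i1[2]),
                               k = seq.int(i0[3], i1[3])))
  ijk[inside, , drop = FALSE]
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel grid: %d x %d x %d voxels, edge %g mm, total = %.6f\n",
              dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
              x$edge * 1000, sum(x$values)))
  invisible(x)
}

#' Coronal projection of a voxel grid
#'
#' Integrates the 3D probability field along the ventral-dorsal (y) axis;
#' each pixel holds the probability per unit projected area.
#'
#' @param grid A [voxelize()] result.
#' @return An object of class `coronal_projection`: list with the 2D
#'   `values` matrix (x by z, probability per m^2), `edge` (pixel edge,
#'   m), `origin` (x, z of the corner pixel).
#' @export
coronal_projection <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  m <- apply(grid$values, c(1, 3), sum) / grid$edge^2
  structure(list(values = m, edge = grid$edge,
                 origin = grid$origin[c(1, 3)]),
            class = "coronal_projection")
}

#' @export
print.coronal_projection <- function(x, ...) {
  cat(sprintf(
    "coronal projection: %d x %d pixels, edge %g mm, total probability = %.6f\n",
    nrow(x$values), ncol(x$values), x$edge * 1000,
    sum(x$values) * x$edge^2))
  invisible(x)
}

#' @export
plot.coronal_projection <- function(x, ...) {
  graphics::image(z = x$values, useRaster = TRUE, asp = 1,
                  col = grDevices::hcl.colors(64, "inferno"), ...)
  invisible(x)
}

#' Write a coronal projection to CSV (and optionally PNG)
#'
#' The CSV matrix carries the full-precision probabilities per unit area.
#' The optional PNG is intensity-scaled to the maximum pixel; a sidecar
#' JSON records the scale so values can be recovered.
#'
#' @param proj A [coronal_projection()].
#' @param csv Path for the CSV matrix.
#' @param png_path Optional path for a PNG rendering.
#' @return `csv`, invisibly.
#' @export
write_projection <- function(proj, csv, png_path = NULL) {
  utils::write.table(proj$values, csv, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  if (!is.null(png_path)) {
    mx <- max(proj$values)
    img <- if (mx > 0) proj$values / mx else proj$values
    # image rows run along x; transpose so x is horizontal in the PNG
    png::writePNG(t(img)[rev(seq_len(ncol(img))), , drop = FALSE], png_path)
    jsonlite::write_json(
      list(scale_max_probability_per_m2 = mx, pixel_edge_m = proj$edge),
      paste0(png_path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(csv)
}
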