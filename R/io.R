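# Export/import of field maps, geometry and trajectories.
# VTK files are legacy-ASCII so everything stays plain text.

#' Export a placed field map sampled on a 3-D box (CSV)
#'
#' Samples B and grad(H^2) on a regular world-coordinate grid and writes
#' columns `x,y,z,Bx,By,Bz,gHx,gHy,gHz` (SI units: m, T, A^2/m^3). The
#' format is read back by [import_field_csv()].
#'
#' @param pf a `placed_field`.
#' @param path output path.
#' @param box `list(lo =, hi =)` world bounds (m).
#' @param spacing sample spacing (m).
#' @return the path, invisibly.
#' @export
export_field_csv <- function(pf, path, box, spacing = 2e-3) {
  xs <- seq(box$lo[1], box$hi[1], by = spacing)
  ys <- seq(box$lo[2], box$hi[2], by = spacing)
  zs <- seq(box$lo[3], box$hi[3], by = spacing)
  g <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  q <- query_field(pf, g, clip = TRUE)
  write.csv(data.frame(x = g[, 1], y = g[, 2], z = g[, 3],
                       Bx = q$B[, 1], By = q$B[, 2], Bz = q$B[, 3],
                       gHx = q$gradH2[, 1], gHy = q$gradH2[, 2],
                       gHz = q$gradH2[, 3]),
            path, row.names = FALSE)
  invisible(path)
}

#' Import a sampled field map from CSV
#'
#' Reads a grid written by [export_field_csv()] and returns an object with
#' the same [query_field()] contract (trilinear interpolation).
#'
#' @param path CSV path.
#' @return object of class `grid_field`.
#' @export
import_field_csv <- function(path) {
  df <- read.csv(path)
  need <- c("x", "y", "z", "Bx", "By", "Bz", "gHx", "gHy", "gHz")
  .chk(all(need %in% names(df)), "field CSV must have columns x,y,z,Bx..gHz")
  xs <- sort(unique(df$x)); ys <- sort(unique(df$y)); zs <- sort(unique(df$z))
  .chk(nrow(df) == length(xs) * length(ys) * length(zs),
       "field CSV is not a full regular grid")
  o <- order(df$z, df$y, df$x)
  arr <- function(v) array(v[o], dim = c(length(xs), length(ys), length(zs)))
  structure(list(xs = xs, ys = ys, zs = zs,
                 B = lapply(c("Bx", "By", "Bz"), function(k) arr(df[[k]])),
                 g = lapply(c("gHx", "gHy", "gHz"), function(k) arr(df[[k]]))),
            class = "grid_field")
}

# trilinear interpolation of one grid_field array
.gf_interp <- function(gf, A, X) {
  n <- nrow(X)
  ix <- findInterval(X[, 1], gf$xs, all.inside = TRUE)
  iy <- findInterval(X[, 2], gf$ys, all.inside = TRUE)
  iz <- findInterval(X[, 3], gf$zs, all.inside = TRUE)
  fx <- pmin(pmax((X[, 1] - gf$xs[ix]) / (gf$xs[ix + 1] - gf$xs[ix]), 0), 1)
  fy <- pmin(pmax((X[, 2] - gf$ys[iy]) / (gf$ys[iy + 1] - gf$ys[iy]), 0), 1)
  fz <- pmin(pmax((X[, 3] - gf$zs[iz]) / (gf$zs[iz + 1] - gf$zs[iz]), 0), 1)
  v <- numeric(n)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
      (if (dz) fz else 1 - fz)
    v <- v + w * A[cbind(ix + dx, iy + dy, iz + dz)]
  }
  v
}

#' Query an imported grid field
#' @param gf a `grid_field` from [import_field_csv()].
#' @param x points (3-vector or n x 3 matrix).
#' @return list with `B` and `gradH2` matrices.
#' @export
query_grid_field <- function(gf, x) {
  X <- .as_points(x)
  comp <- function(arrs)
    do.call(cbind, lapply(arrs, function(A) .gf_interp(gf, A, X)))
  list(B = comp(gf$B), gradH2 = comp(gf$g))
}

# minimal legacy-VTK ASCII writers ------------------------------------------

.vtk_header <- function(con, title) {
  writeLines(c("# vtk DataFile Version 3.0", title, "ASCII"), con)
}

#' Export a placed field map as legacy VTK structured points
#'
#' Vector arrays `B` (T) and `gradH2` (A^2/m^3) on a regular box grid,
#' loadable in ParaView/VisIt.
#'
#' @inheritParams export_field_csv
#' @export
export_field_vtk <- function(pf, path, box, spacing = 2e-3) {
  xs <- seq(box$lo[1], box$hi[1], by = spacing)
  ys <- seq(box$lo[2], box$hi[2], by = spacing)
  zs <- seq(box$lo[3], box$hi[3], by = spacing)
  g <- as.matrix(expand.grid(x = xs, y = ys, z = zs))  # x fastest: VTK order
  q <- query_field(pf, g, clip = TRUE)
  con <- file(path, "w"); on.exit(close(con))
  .vtk_header(con, "mdtsim field map")
  writeLines(c("DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", length(xs), length(ys), length(zs)),
               sprintf("ORIGIN %g %g %g", xs[1], ys[1], zs[1]),
               sprintf("SPACING %g %g %g", spacing, spacing, spacing),
               sprintf("POINT_DATA %d", nrow(g)),
               "VECTORS B double"), con)
  write.table(q$B, con, row.names = FALSE, col.names = FALSE)
  writeLines("VECTORS gradH2 double", con)
  write.table(q$gradH2, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export the airway surface as a legacy VTK triangle mesh
#'
#' Triangulated branch cylinders plus the tumor sphere, with a cell scalar
#' `tumor` tagging tumor triangles 1 and airway wall 0.
#'
#' @param tree a `lung_tree`.
#' @param path output path.
#' @param n_phi azimuthal facets per cylinder.
#' @param n_xi axial facets per cylinder.
#' @return the path, invisibly.
#' @export
export_tree_vtk <- function(tree, path, n_phi = 24, n_xi = 12) {
  verts <- NULL; tris <- NULL; tags <- NULL
  add_cyl <- function(start, dir, L, R) {
    e2 <- c(-dir[2], dir[1], 0); e2 <- e2 / sqrt(sum(e2^2))
    e3 <- c(dir[2] * e2[3] - dir[3] * e2[2],
            dir[3] * e2[1] - dir[1] * e2[3],
            dir[1] * e2[2] - dir[2] * e2[1])
    phi <- seq(0, 2 * pi, length.out = n_phi + 1)[-(n_phi + 1)]
    xi <- seq(0, L, length.out = n_xi + 1)
    base <- nrow(verts) %||% 0
    for (x in xi) for (p in phi)
      verts <<- rbind(verts, start + dir * x + R * (cos(p) * e2 + sin(p) * e3))
    for (i in seq_len(n_xi)) for (j in seq_len(n_phi)) {
      j2 <- j %% n_phi + 1
      a <- base + (i - 1) * n_phi + j - 1
      b <- base + (i - 1) * n_phi + j2 - 1
      c2 <- base + i * n_phi + j - 1
      d <- base + i * n_phi + j2 - 1
      tris <<- rbind(tris, c(a, b, d), c(a, d, c2))
      tags <<- c(tags, 0L, 0L)
    }
  }
  for (i in seq_len(tree$n_seg))
    add_cyl(tree$start[i, ], tree$dir[i, ], tree$L_seg[i], tree$R_seg[i])
  if (!is.null(tree$tumor)) {
    tum <- tree$tumor
    nt <- 16
    th <- seq(0, pi, length.out = nt + 1); ph <- seq(0, 2 * pi, length.out = nt + 1)[-(nt + 1)]
    base <- nrow(verts)
    for (t in th) for (p in ph)
      verts <- rbind(verts, tum$center +
                       tum$r * c(sin(t) * cos(p), sin(t) * sin(p), cos(t)))
    for (i in seq_len(nt)) for (j in seq_len(nt)) {
      j2 <- j %% nt + 1
      a <- base + (i - 1) * nt + j - 1; b <- base + (i - 1) * nt + j2 - 1
      c2 <- base + i * nt + j - 1; d <- base + i * nt + j2 - 1
      tris <- rbind(tris, c(a, b, d), c(a, d, c2))
      tags <- c(tags, 1L, 1L)
    }
  }
  con <- file(path, "w"); on.exit(close(con))
  .vtk_header(con, "mdtsim airway surface")
  writeLines(c("DATASET POLYDATA",
               sprintf("POINTS %d double", nrow(verts))), con)
  write.table(verts, con, row.names = FALSE, col.names = FALSE)
  writeLines(sprintf("POLYGONS %d %d", nrow(tris), 4 * nrow(tris)), con)
  write.table(cbind(3L, tris), con, row.names = FALSE, col.names = FALSE)
  writeLines(c(sprintf("CELL_DATA %d", nrow(tris)),
               "SCALARS tumor int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(tags), con)
  invisible(path)
}

#' Export final particle states (and trajectories) as CSV
#'
#' One row per particle: id, final time, position, status. If the states
#' carry trajectory snapshots (from `integrate_particles(record = TRUE)`),
#' those are appended as extra rows with a `snapshot` column.
#'
#' @param states integrated `particle_states`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
export_particles_csv <- function(states, path) {
  df <- data.frame(id = seq_len(states$n), t = states$t,
                   x = states$pos[, 1], y = states$pos[, 2],
                   z = states$pos[, 3], status = states$status,
                   snapshot = NA_integer_)
  traj <- attr(states, "trajectory")
  if (!is.null(traj)) {
    for (k in seq_along(traj)) {
      s <- traj[[k]]
      df <- rbind(df, data.frame(id = s[, 1], t = s[, 2],
                                 x = s[, 3], y = s[, 4], z = s[, 5],
                                 status = NA_character_, snapshot = k))
    }
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export recorded trajectories as VTK polylines
#'
#' Requires states integrated with `record = TRUE`.
#'
#' @param states integrated `particle_states` carrying trajectory snapshots.
#' @param path output path.
#' @return the path, invisibly.
#' @export
export_trajectories_vtk <- function(states, path) {
  traj <- attr(states, "trajectory")
  .chk(!is.null(traj), "states carry no trajectory (use record = TRUE)")
  nsnap <- length(traj); n <- states$n
  pts <- do.call(rbind, lapply(traj, function(s) s[, 3:5]))
  con <- file(path, "w"); on.exit(close(con))
  .vtk_header(con, "mdtsim particle trajectories")
  writeLines(c("DATASET POLYDATA",
               sprintf("POINTS %d double", nrow(pts))), con)
  write.table(pts, con, row.names = FALSE, col.names = FALSE)
  writeLines(sprintf("LINES %d %d", n, n * (nsnap + 1)), con)
  for (i in seq_len(n))
    writeLines(paste(c(nsnap, (seq_len(nsnap) - 1) * n + i - 1),
                     collapse = " "), con)
  invisible(path)
}
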