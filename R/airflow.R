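#' Solve the laminar flow surrogate on an airway tree
#'
#' Branch flow rates come from a Hagen-Poiseuille resistance network
#' (resistance `8 eta L / (pi R^4)`, with the tumor's reduced open area
#' raising the host branch's resistance through a local constriction
#' integral), driven by the inlet volumetric rate with equal outlet
#' pressures. Within each branch the velocity is a fully developed
#' parabolic profile carrying that branch's flow; daughter-branch profiles
#' are skewed toward the inner (carinal) wall, relaxing downstream over one
#' branch length. Near the tumor the profile is multiplied by the
#' area-constriction speed-up and a potential-flow sphere correction makes
#' the normal velocity vanish on the tumor cap so that tracer streamlines
#' divert around it (deposition then requires inertia or magnetic drift).
#'
#' @param tree a finalized [build_weibel_tree()] tree (tumor included).
#' @param Q_lpm inlet volumetric flow rate (L/min).
#' @param skew carinal skew amplitude in `[0, 1]` (dimensionless profile
#'   bias, 0 = symmetric parabola).
#' @param rho_a air density (kg/m^3).
#' @param eta air dynamic viscosity (Pa s).
#' @return object of class `flow_field` with per-branch flows (m^3/s).
#' @export
solve_flow <- function(tree, Q_lpm = 15, skew = 0.3,
                       rho_a = 1.22, eta = 1.78e-5) {
  stopifnot(inherits(tree, "lung_tree"))
  .chk(Q_lpm > 0, "Q must be positive")
  .chk(skew >= 0 && skew <= 1, "skew must be in [0, 1]")
  Q <- Q_lpm / 60000          # L/min -> m^3/s
  n <- tree$n_seg
  # branch resistance; the tumor host integrates 1/r_eq^4 over the cap
  res <- 8 * eta * tree$L_seg / (pi * tree$R_seg^4)
  if (!is.null(tree$tumor)) {
    h <- tree$tumor$host
    L <- tree$L_seg[h]; R <- tree$R_seg[h]
    xi <- seq(0, L, length.out = 400)
    frac <- open_area_fraction(tree, xi)
    .chk(min(frac) > 1e-3, "branch fully occluded: no flow solution")
    r_eq4 <- (R * sqrt(frac))^4
    res[h] <- 8 * eta / pi * pracma::trapz(xi, 1 / r_eq4)
  }
  # equivalent resistance bottom-up, flow split top-down
  req <- numeric(n)
  order_deep <- order(tree$gen, decreasing = TRUE)
  for (i in order_deep) {
    ch <- tree$segments[[i]]$children
    req[i] <- res[i] + if (length(ch) == 0) 0 else
      1 / sum(1 / req[ch])
  }
  Qb <- numeric(n)
  Qb[1] <- Q
  for (i in order(tree$gen)) {
    ch <- tree$segments[[i]]$children
    if (length(ch) > 0) {
      w <- (1 / req[ch]) / sum(1 / req[ch])
      Qb[ch] <- Qb[i] * w
    }
  }
  # carinal direction of each daughter branch: the in-plane unit vector from
  # the branch axis toward its sibling (parent direction minus its axial
  # projection)
  carina <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    p <- tree$segments[[i]]$parent
    if (p > 0) {
      pd <- tree$dir[p, ]; d <- tree$dir[i, ]
      v <- pd - sum(pd * d) * d
      nv <- sqrt(sum(v * v))
      if (nv > 1e-12) carina[i, ] <- v / nv
    }
  }
  structure(list(tree = tree, Q = Q, Q_lpm = Q_lpm, Qb = Qb,
                 resistance = res, skew = skew, rho_a = rho_a, eta = eta,
                 carina = carina),
            class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  tr <- x$tree
  cat(sprintf("<flow_field> Q = %g L/min, mean inlet speed %.3f m/s, Re = %.0f\n",
              x$Q_lpm, x$Q / (pi * tr$R_seg[1]^2),
              inlet_reynolds(x)))
  invisible(x)
}

#' Inlet Reynolds number of a flow field
#'
#' `Re = rho_a * u_mean * 2 R_G0 / eta`, a laminar-regime consistency check.
#' @param flow a `flow_field`.
#' @return Reynolds number (dimensionless).
#' @export
inlet_reynolds <- function(flow) {
  R <- flow$tree$R_seg[1]
  u <- flow$Q / (pi * R^2)
  flow$rho_a * u * 2 * R / flow$eta
}

# Air velocity for particles already located in branches: loc is the output
# of .locate_particles (branch id + local coordinates). Returns n x 3.
.flow_velocity_located <- function(flow, X, loc) {
  tree <- flow$tree
  n <- nrow(X)
  U <- matrix(0, n, 3)
  tum <- tree$tumor
  for (i in unique(loc$seg)) {
    if (i == 0) next
    idx <- which(loc$seg == i)
    R <- tree$R_seg[i]; L <- tree$L_seg[i]
    xi <- pmin(pmax(loc$xi[idx], 0), L)
    # conical contraction toward the daughters over the last own-radius of
    # an internal branch: the local tube radius R_t shrinks to the daughter
    # radius, the axial speed rises as 1/R_t^2 and streamlines move inward
    # with u_r/u_ax = rho R_t'/R_t (rho / R_t is conserved)
    Rt <- rep(R, length(idx))
    dRt <- 0
    if (!is.na(tree$R_child[i])) {
      lt <- R
      s <- pmax(xi - (L - lt), 0) / lt
      dRt <- (tree$R_child[i] - R) / lt
      Rt <- R + (tree$R_child[i] - R) * s
    }
    # developing entrance profile: a flat core of speed Uc surrounded by a
    # parabolic boundary layer of thickness delta growing downstream
    # (Blasius-like, delta = 5 sqrt(nu x / U)); when delta reaches the tube
    # radius the profile is exactly the fully developed Poiseuille parabola
    nu <- flow$eta / flow$rho_a
    ub <- flow$Qb[i] / (pi * R^2)
    delta <- pmin(Rt, 5 * sqrt(nu * (xi + 2e-3) / ub))
    cc <- Rt - delta
    denom <- cc^2 / 2 + (2 / 3) * Rt * delta - (5 / 12) * delta^2
    Uc <- flow$Qb[i] / (2 * pi * denom)
    rho_r <- sqrt(pmax(loc$d2[idx], 0))
    s_bl <- pmin(pmax((Rt - rho_r) / delta, 0), 1)
    prof <- Uc * (2 * s_bl - s_bl^2)
    # carinal skew, daughters only, decaying downstream
    if (flow$skew > 0 && any(flow$carina[i, ] != 0)) {
      rel <- X[idx, , drop = FALSE] - .rowvec(tree$start[i, ], length(idx))
      perp <- rel - outer(loc$xi[idx], tree$dir[i, ])
      proj <- drop(perp %*% flow$carina[i, ]) / R   # signed, in [-1, 1]
      s <- flow$skew * exp(-3 * xi / L)
      prof <- prof * (1 + s * pmin(pmax(proj, -1), 1))
    }
    u <- outer(prof, tree$dir[i, ])
    if (!identical(dRt, 0)) {
      rel <- X[idx, , drop = FALSE] - .rowvec(tree$start[i, ], length(idx))
      perp <- rel - outer(loc$xi[idx], tree$dir[i, ])
      u <- u + perp * (prof * (dRt / Rt) * (Rt < R))
    }
    if (!is.null(tum) && i == tum$host) {
      # area-constriction speed-up within the cap's axial shadow
      af <- open_area_fraction(tree, xi)
      u <- u * (1 / af)
      # channel-contraction diversion around the cap: streamlines compress
      # into the open region below the cap's lower edge, conserving the
      # cross-sectional area quantile. Tracer particles dive under the cap
      # and recover behind it; deposition then requires the inertial lag
      # or magnetic drift that keeps a particle from following the dive.
      # unclamped axial coordinate: the dive ceiling must extend smoothly
      # into the branch's upstream extension for proximal tumor stations
      dax <- loc$xi[idx] - tum$xi0
      act <- which(abs(dax) < 2.5 * tum$r)
      if (length(act) > 0) {
        rel <- X[idx[act], , drop = FALSE] - .rowvec(tree$start[i, ], length(act))
        perp <- rel - outer(loc$xi[idx[act]], tree$dir[i, ])
        et <- (tum$center - tree$start[i, ] - tree$dir[i, ] * tum$xi0) / R
        h <- drop(perp %*% et)                       # height toward the tumor
        yy <- drop(perp %*% .cross3(tree$dir[i, ], et))  # lateral offset
        # each particle dives under its own column of the dome (columns
        # beside it, |yy| > r, are unconstrained and pass around the side).
        # The diving ceiling is the sphere underside minus a standoff near
        # the apex, continued upstream/downstream by its tangent line of
        # slope s_r (a C1 ceiling): tracers can follow it exactly, so
        # zero-inertia particles are never deposited by construction.
        # Inertial lag on the curved apex section and magnetophoretic drift
        # are then the only deposition routes, as in the real flow.
        stand <- 0.05 * tum$r
        s_r <- 0.5
        gam <- sqrt(1 + s_r^2)
        r_col <- sqrt(pmax(tum$r^2 - yy^2, 0))
        d_t <- r_col * s_r / gam                     # tangency |dax|
        on_arc <- abs(dax[act]) <= d_t & r_col > 0
        root <- sqrt(pmax(r_col^2 - dax[act]^2, 0))
        z_pt <- R - r_col / gam - stand              # ceiling at tangency
        z_t <- ifelse(on_arc, R - root - stand,
                      z_pt + s_r * (abs(dax[act]) - d_t))
        slope <- ifelse(on_arc,
                        dax[act] / pmax(root, 0.2 * tum$r),
                        s_r * sign(dax[act]))
        slope[z_t >= R | r_col == 0] <- 0
        z_t <- pmin(z_t, R)
        area_below <- function(x) {
          x <- pmin(pmax(x, -R), R)
          pi * R^2 / 2 + R^2 * asin(x / R) + x * sqrt(pmax(R^2 - x^2, 0))
        }
        chord <- function(x) pmax(2 * sqrt(pmax(R^2 - x^2, 0)), 0.3 * R)
        w <- prof[act] * (area_below(h) / pmax(area_below(z_t), 0.05 * pi * R^2)) *
          (chord(z_t) / chord(h)) * slope
        w <- pmin(pmax(w, -2.5 * abs(prof[act])), 2.5 * abs(prof[act]))
        u[act, ] <- u[act, ] + outer(w, et)
      }
      # no-slip on the cap: a Blasius-scale shear layer (thickness
      # 5 sqrt(nu r / u_mean), ~1.3 mm at study conditions) damps the speed
      # toward zero at the tumor surface. A scalar factor leaves tracer
      # streamlines unchanged; it only stretches the time spent near the
      # cap, which is what lets inertial lag and magnetic drift deposit.
      relc <- X[idx, , drop = FALSE] - .rowvec(tum$center, length(idx))
      sdist <- sqrt(rowSums(relc * relc)) - tum$r
      bl <- 5 * sqrt(nu * tum$r / ub)
      u <- u * pmin(pmax(sdist / bl, 0), 1)
    }
    U[idx, ] <- u
  }
  U
}

#' Air velocity at arbitrary points
#'
#' Evaluates the surrogate velocity field; zero outside the lumen and on
#' walls (no-slip). Points in a junction sphere but outside every branch
#' cylinder use the parent branch profile with the radial coordinate capped
#' just inside the wall, which keeps particles moving through the carina.
#'
#' @param flow a `flow_field`.
#' @param x 3-vector or n x 3 matrix (m).
#' @return n x 3 matrix of velocities (m/s).
#' @export
flow_velocity <- function(flow, x) {
  X <- .as_points(x)
  loc <- .locate_particles(flow$tree, X)
  U <- .flow_velocity_located(flow, X, loc)
  U[loc$seg == 0, ] <- 0
  if (length(x) == 3 && is.null(dim(x))) drop(U) else U
}

# Assign each point to a branch. Deeper generations take priority where
# cylinders overlap (the daughter claims the shared junction volume,
# including its upstream extension); among same-generation candidates the
# branch with the smallest scaled radial distance wins, keeping the
# carina hand-off symmetric. seg = 0 marks points outside the lumen (or
# inside the tumor sphere).
.locate_particles <- function(tree, X) {
  X <- .as_points(X)
  n <- nrow(X)
  seg <- integer(n)
  xi_out <- numeric(n)
  d2_out <- numeric(n)
  best <- rep(Inf, n)      # (gen-priority, scaled radius) merit, lower wins
  for (i in seq_len(tree$n_seg)) {
    sc <- .seg_coords(tree, i, X)
    inside <- sc$xi >= -tree$ext_up[i] & sc$xi <= tree$L_seg[i] &
      sc$d2 <= tree$R_seg[i]^2
    merit <- -tree$gen[i] + sqrt(pmax(sc$d2, 0)) / tree$R_seg[i]
    take <- inside & merit < best
    seg[take] <- i
    xi_out[take] <- sc$xi[take]
    d2_out[take] <- sc$d2[take]
    best[take] <- merit[take]
  }
  if (!is.null(tree$tumor)) {
    tum <- tree$tumor
    # the dome's influence zone belongs to the host branch's flow field:
    # points there inside the host cylinder stay host-assigned even where
    # a daughter's upstream extension overlaps (distal tumor stations)
    sc <- .seg_coords(tree, tum$host, X)
    reclaim <- seg != tum$host & seg != 0L &
      abs(sc$xi - tum$xi0) < 2.5 * tum$r &
      sc$xi >= 0 & sc$xi <= tree$L_seg[tum$host] &
      sc$d2 <= tree$R_seg[tum$host]^2
    if (any(reclaim)) {
      seg[reclaim] <- tum$host
      xi_out[reclaim] <- sc$xi[reclaim]
      d2_out[reclaim] <- sc$d2[reclaim]
    }
    # tumor interior is solid
    ct <- tum$center
    dt2 <- (X[, 1] - ct[1])^2 + (X[, 2] - ct[2])^2 + (X[, 3] - ct[3])^2
    seg[dt2 <= tum$r^2] <- 0L
  }
  list(seg = seg, xi = xi_out, d2 = d2_out)
}

#' Import an externally computed velocity field
#'
#' Reads a velocity field sampled on a regular grid (CSV with columns
#' x,y,z,ux,uy,uz in SI units, as written by [export_flow_csv()]) and wraps
#' it in the same query contract as the analytic surrogate, using trilinear
#' interpolation masked by the lumen. Flux conservation of the imported
#' field is checked and reported as an attribute, not enforced.
#'
#' @param path CSV file path.
#' @param tree the airway tree used for lumen masking.
#' @return a `flow_field_grid` object usable with [flow_velocity_grid()].
#' @export
import_flow <- function(path, tree) {
  df <- read.csv(path)
  need <- c("x", "y", "z", "ux", "uy", "uz")
  .chk(all(need %in% names(df)), "flow CSV must have columns x,y,z,ux,uy,uz")
  xs <- sort(unique(df$x)); ys <- sort(unique(df$y)); zs <- sort(unique(df$z))
  .chk(nrow(df) == length(xs) * length(ys) * length(zs),
       "flow CSV is not a full regular grid")
  o <- order(df$z, df$y, df$x)
  arr <- function(v) array(v[o], dim = c(length(xs), length(ys), length(zs)))
  out <- structure(list(xs = xs, ys = ys, zs = zs,
                        ux = arr(df$ux), uy = arr(df$uy), uz = arr(df$uz),
                        tree = tree),
                   class = "flow_field_grid")
  # conservation diagnostic: mean absolute divergence over interior nodes
  hx <- diff(xs)[1]; hy <- diff(ys)[1]; hz <- diff(zs)[1]
  d <- dim(out$ux)
  if (all(d >= 3)) {
    ix <- 2:(d[1] - 1); iy <- 2:(d[2] - 1); iz <- 2:(d[3] - 1)
    div <- (out$ux[ix + 1, iy, iz] - out$ux[ix - 1, iy, iz]) / (2 * hx) +
      (out$uy[ix, iy + 1, iz] - out$uy[ix, iy - 1, iz]) / (2 * hy) +
      (out$uz[ix, iy, iz + 1] - out$uz[ix, iy, iz - 1]) / (2 * hz)
    umag <- sqrt(out$ux[ix, iy, iz]^2 + out$uy[ix, iy, iz]^2 + out$uz[ix, iy, iz]^2)
    attr(out, "divergence_report") <-
      c(mean_abs_div = mean(abs(div)),
        mean_scaled_div = mean(abs(div)) * min(hx, hy, hz) / max(mean(umag), 1e-12))
  }
  out
}

#' Query an imported grid flow field
#'
#' @param gf a `flow_field_grid` from [import_flow()].
#' @param x points (3-vector or n x 3 matrix).
#' @return n x 3 velocity matrix; zero outside the lumen or grid.
#' @export
flow_velocity_grid <- function(gf, x) {
  X <- .as_points(x)
  n <- nrow(X)
  interp1 <- function(A) {
    v <- numeric(n)
    ix <- findInterval(X[, 1], gf$xs, all.inside = TRUE)
    iy <- findInterval(X[, 2], gf$ys, all.inside = TRUE)
    iz <- findInterval(X[, 3], gf$zs, all.inside = TRUE)
    fx <- (X[, 1] - gf$xs[ix]) / (gf$xs[ix + 1] - gf$xs[ix])
    fy <- (X[, 2] - gf$ys[iy]) / (gf$ys[iy + 1] - gf$ys[iy])
    fz <- (X[, 3] - gf$zs[iz]) / (gf$zs[iz + 1] - gf$zs[iz])
    fx <- pmin(pmax(fx, 0), 1); fy <- pmin(pmax(fy, 0), 1); fz <- pmin(pmax(fz, 0), 1)
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) * (if (dz) fz else 1 - fz)
      v <- v + w * A[cbind(ix + dx, iy + dy, iz + dz)]
    }
    v
  }
  U <- cbind(interp1(gf$ux), interp1(gf$uy), interp1(gf$uz))
  U[!.in_lumen(gf$tree, X), ] <- 0
  if (length(x) == 3 && is.null(dim(x))) drop(U) else U
}

#' Export the surrogate flow sampled on a regular grid (CSV)
#'
#' Writes columns x,y,z,ux,uy,uz (SI units) on a regular grid covering the
#' lumen bounding box; the format read back by [import_flow()].
#'
#' @param flow a `flow_field`.
#' @param path output CSV path.
#' @param spacing grid spacing (m).
#' @return the path, invisibly.
#' @export
export_flow_csv <- function(flow, path, spacing = 2e-3) {
  tree <- flow$tree
  bb <- .tree_bbox(tree)
  xs <- seq(bb$lo[1], bb$hi[1], by = spacing)
  ys <- seq(bb$lo[2], bb$hi[2], by = spacing)
  zs <- seq(bb$lo[3], bb$hi[3], by = spacing)
  g <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  U <- flow_velocity(flow, g)
  write.csv(data.frame(x = g[, 1], y = g[, 2], z = g[, 3],
                       ux = U[, 1], uy = U[, 2], uz = U[, 3]),
            path, row.names = FALSE)
  invisible(path)
}

# bounding box of the tree (with margin of max radius)
.tree_bbox <- function(tree, margin = NULL) {
  ends <- tree$start + tree$dir * tree$L_seg
  pts <- rbind(tree$start, ends)
  m <- margin %||% max(tree$R_seg)
  list(lo = apply(pts, 2, min) - m, hi = apply(pts, 2, max) + m)
}
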