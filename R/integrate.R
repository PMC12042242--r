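#' Integrate particle motion to an absorbing state
#'
#' Advances every in-flight particle under Schiller-Naumann drag and
#' magnetophoresis until it sticks to a wall, sticks to the tumor surface,
#' exits an outlet (frozen) or exceeds the time budget (counted as
#' suspended). The integrator is semi-implicit: over a step the drag term
#' is integrated exactly (exponential relaxation toward the effective
#' velocity `u + F_m tau_eff / m_p`), which stays stable for the stiff
#' response times of micron particles. Steps are limited by a
#' cell-crossing condition and refined near the tumor surface; boundary
#' crossings are located by bisection of the step chord to `bisect_tol`.
#' Because the carrier flow and magnetic field are steady and coupling is
#' one-way, particles carry independent clocks and may take different step
#' sizes.
#'
#' @param states a [seed_particles()] result.
#' @param flow a [solve_flow()] result.
#' @param field a `placed_field` from [place_magnet()], or `NULL` for the
#'   no-magnet case.
#' @param spec a [particle_spec()].
#' @param dt_max maximum step (s).
#' @param t_max time budget (s); default 3x the convective transit time of
#'   the deepest path at the given flow.
#' @param bisect_tol boundary location tolerance (m).
#' @param record if `TRUE`, store trajectory snapshots (positions of all
#'   particles every `record_every` accepted steps); intended for small n.
#' @param record_every snapshot interval in steps.
#' @return the updated `particle_states` with final statuses, deposition
#'   positions (`dep_pos`), per-particle times, and (optionally) a
#'   `trajectory` attribute.
#' @export
integrate_particles <- function(states, flow, field = NULL, spec,
                                dt_max = 2e-4, t_max = NULL,
                                bisect_tol = 1e-6,
                                record = FALSE, record_every = 10) {
  stopifnot(inherits(states, "particle_states"), inherits(flow, "flow_field"),
            inherits(spec, "particle_spec"))
  tree <- flow$tree
  if (is.null(t_max)) t_max <- 3 * .transit_time(flow)
  tau <- stokes_time(spec, flow$eta)
  tum <- tree$tumor
  pos <- states$pos; vel <- states$vel
  status <- states$status; tclock <- states$t
  visited <- states$visited
  dep_pos <- matrix(NA_real_, states$n, 3)
  traj <- if (record) list() else NULL
  step <- 0L
  active <- which(status == "in_flight")
  # particles seeded outside the lumen (e.g. on the wall) deposit at once
  if (length(active) > 0) {
    bad <- active[!.in_lumen(tree, pos[active, , drop = FALSE])]
    if (length(bad) > 0) {
      status[bad] <- "deposited_wall"
      dep_pos[bad, ] <- pos[bad, , drop = FALSE]
      active <- setdiff(active, bad)
    }
  }
  loc <- .locate_particles(tree, pos[active, , drop = FALSE])
  while (length(active) > 0) {
    step <- step + 1L
    X <- pos[active, , drop = FALSE]
    V <- vel[active, , drop = FALSE]
    na <- length(active)
    visited[cbind(active[loc$seg > 0], loc$seg[loc$seg > 0])] <- TRUE
    U <- .flow_velocity_located(flow, X, loc)
    # magnetophoretic acceleration
    if (!is.null(field)) {
      qf <- query_field(field, X)
      A <- magnetophoretic_force(spec, qf$gradH2) / spec$m_p
    } else A <- matrix(0, na, 3)
    rel <- U - V
    Re <- flow$rho_a * .norm3(rel) * spec$d_p / flow$eta
    tau_eff <- tau / (1 + 0.15 * Re^0.687)
    u_eff <- U + A * tau_eff
    speed <- pmax(.norm3(V), .norm3(u_eff), 1e-3)
    Rb <- ifelse(loc$seg > 0, tree$R_seg[pmax(loc$seg, 1)], min(tree$R_seg))
    dt <- pmin(dt_max, 0.3 * Rb / speed)
    if (!is.null(tum)) {
      dsurf <- .norm3(X - .rowvec(tum$center, na)) - tum$r
      near <- dsurf < 0.5 * tum$r
      if (any(near))
        dt[near] <- pmin(dt[near],
                         pmax(0.3 * pmax(dsurf[near], 0), 0.01 * tum$r) /
                           speed[near])
    }
    e <- exp(-dt / tau_eff)
    Xn <- X + u_eff * dt + (V - u_eff) * (tau_eff * (1 - e))
    Vn <- u_eff + (V - u_eff) * e
    loc2 <- .locate_particles(tree, Xn)
    inl <- loc2$seg > 0L
    if (any(!inl)) {
      ci <- which(!inl)                       # crossing subset
      lo <- X[ci, , drop = FALSE]             # inside
      hi <- Xn[ci, , drop = FALSE]            # outside
      nb <- ceiling(log2(max(.norm3(hi - lo)) / bisect_tol + 1)) + 2
      for (k in seq_len(max(nb, 8))) {
        mid <- (lo + hi) / 2
        mi <- .in_lumen(tree, mid)
        lo[mi, ] <- mid[mi, , drop = FALSE]
        hi[!mi, ] <- mid[!mi, , drop = FALSE]
      }
      cause <- rep("deposited_wall", length(ci))
      if (!is.null(tum)) {
        dtm <- .norm3(hi - .rowvec(tum$center, length(ci)))
        cause[dtm <= tum$r + 10 * bisect_tol] <- "deposited_tumor"
      }
      for (i in which(tree$is_leaf)) {
        sc <- .seg_coords(tree, i, hi)
        isout <- sc$xi >= tree$L_seg[i] - 10 * bisect_tol &
          sc$d2 <= tree$R_seg[i]^2 & cause != "deposited_tumor"
        cause[isout] <- "exited_outlet"
      }
      gi <- active[ci]
      status[gi] <- cause
      dep_pos[gi, ] <- hi
      pos[gi, ] <- hi
      vel[gi, ] <- Vn[ci, , drop = FALSE]
      tclock[gi] <- tclock[gi] + dt[ci]
    }
    ok <- which(inl)
    gi <- active[ok]
    pos[gi, ] <- Xn[ok, , drop = FALSE]
    vel[gi, ] <- Vn[ok, , drop = FALSE]
    tclock[gi] <- tclock[gi] + dt[ok]
    over <- gi[tclock[gi] > t_max]
    if (length(over) > 0) status[over] <- "suspended"
    if (record && step %% record_every == 0)
      traj[[length(traj) + 1]] <- cbind(id = seq_len(states$n),
                                        t = tclock, pos)
    new_active <- which(status == "in_flight")
    if (any(!is.finite(pos[new_active, ]))) {
      bad <- new_active[rowSums(!is.finite(pos[new_active, , drop = FALSE])) > 0]
      status[bad] <- "error"
      new_active <- setdiff(new_active, bad)
    }
    keep <- match(new_active, active)
    loc <- list(seg = loc2$seg[keep], xi = loc2$xi[keep], d2 = loc2$d2[keep])
    active <- new_active
  }
  states$pos <- pos; states$vel <- vel
  states$status <- status; states$t <- tclock
  states$visited <- visited
  states$dep_pos <- dep_pos
  states$steps <- step
  states$t_max <- t_max
  if (record) attr(states, "trajectory") <- traj
  states
}

# Convective transit time: sum of length / mean-speed along the deepest
# path (following the first child at every bifurcation).
.transit_time <- function(flow) {
  tree <- flow$tree
  i <- 1L; tt <- 0
  repeat {
    u <- flow$Qb[i] / (pi * tree$R_seg[i]^2)
    tt <- tt + tree$L_seg[i] / u
    ch <- tree$segments[[i]]$children
    if (length(ch) == 0) return(tt)
    i <- ch[1]
  }
}
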