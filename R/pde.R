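#' Particle deposition efficiency from final particle states
#'
#' `PDE = 100 * (particles deposited on the tumor surface) / denominator`.
#' The denominator is either every particle released at the inlet
#' (`"released"`, default) or only the particles whose path visited the
#' tumor's host branch (`"host_branch"`).
#'
#' @param states integrated [particle_states][integrate_particles()].
#' @param tree the airway tree (for the host-branch denominator).
#' @param denominator `"released"` or `"host_branch"`.
#' @return object of class `pde_record`: deposition counts and the PDE (%).
#' @export
compute_pde <- function(states, tree,
                        denominator = c("released", "host_branch")) {
  denominator <- match.arg(denominator)
  st <- states$status
  n_tumor <- sum(st == "deposited_tumor")
  host <- if (!is.null(tree$tumor)) tree$tumor$host else NA_integer_
  n_host <- if (!is.na(host)) sum(states$visited[, host]) else NA_integer_
  den <- switch(denominator, released = states$n, host_branch = n_host)
  rec <- list(n_released = states$n,
              n_tumor = n_tumor,
              n_wall = sum(st == "deposited_wall"),
              n_exited = sum(st == "exited_outlet"),
              n_suspended = sum(st %in% c("suspended", "in_flight")),
              n_error = sum(st == "error"),
              n_host_branch = n_host,
              denominator = denominator)
  if (is.na(den) || den == 0) {
    rec$pde <- NA_real_
    rec$error <- "zero denominator: PDE undefined"
  } else {
    rec$pde <- 100 * n_tumor / den
  }
  structure(rec, class = "pde_record")
}

#' @export
print.pde_record <- function(x, ...) {
  cat(sprintf("<pde_record> PDE = %.2f%% (%d / %d, %s)\n  wall %d, exited %d, suspended %d\n",
              x$pde, x$n_tumor,
              switch(x$denominator, released = x$n_released, host_branch = x$n_host_branch),
              x$denominator, x$n_wall, x$n_exited, x$n_suspended))
  invisible(x)
}

# resolve the magnet of a config: list(a, t, B_T, jc, label) or NULL
.case_magnet <- function(cfg) {
  m <- cfg$magnet
  if (!isTRUE(m$enabled)) return(NULL)
  if (!is.null(m$preset)) {
    pr <- make_presets()
    row <- pr[pr$label == m$preset, ]
    .chk(nrow(row) == 1, paste("unknown magnet preset:", m$preset))
    a <- row$a_mm / 1000; t <- row$t_mm / 1000; BT <- row$B_T
    label <- m$preset
  } else {
    a <- m$a_mm / 1000; t <- m$t_mm / 1000; BT <- m$B_T
    label <- sprintf("a%g_t%g", m$a_mm, m$t_mm)
  }
  jc <- calibrate_jc(BT, a, t, model = m$jc_model %||% "constant",
                     B0 = m$kim_B0 %||% 1.5)
  list(a = a, t = t, B_T = BT, jc = jc, label = label)
}

# build the airway tree of a config
.case_tree <- function(cfg) {
  dims <- as.data.frame(cfg$lung$dims)
  tree <- build_weibel_tree(dims, cfg$lung$half_angle_deg)
  if (isTRUE(cfg$tumor$enabled))
    tree <- add_tumor(tree, cfg$tumor$r_ratio, cfg$tumor$location,
                      cfg$tumor$alpha_deg, host = cfg$tumor$host_branch)
  tree
}

#' Build the magnet-frame field map for a configuration
#'
#' Magnetizes the configured magnet and tabulates its field on an
#' axisymmetric grid wide enough to cover the whole airway tree at every
#' magnet distance in `d_values_mm` (default: the configured distance).
#' The same map can then be reused across magnet-distance and particle
#' sweeps since it lives in the magnet frame.
#'
#' @param cfg an `mdt_config` with an enabled magnet.
#' @param d_values_mm magnet distances the map must cover (mm).
#' @return a `field_map`, or `NULL` when the magnet is disabled.
#' @export
build_case_field_map <- function(cfg, d_values_mm = NULL) {
  mg <- .case_magnet(cfg)
  if (is.null(mg)) return(NULL)
  tree <- .case_tree(cfg)
  d_values_mm <- d_values_mm %||% cfg$magnet$d_mm
  magnet <- bulk_magnet(mg$a, mg$t, mg$jc)
  cur <- magnetize(magnet, nr = 8, nz = 8, pr = 2, pz = 2)
  # radial extent: whole tree seen from the magnet axis (anchored over the
  # tumor) plus margin; axial: all requested distances plus the tree height
  anchor <- if (!is.null(tree$tumor)) tree$tumor$center else
    tree$start[1, ] + tree$dir[1, ] * tree$L_seg[1] / 2
  bb <- .tree_bbox(tree)
  corners <- as.matrix(expand.grid(x = c(bb$lo[1], bb$hi[1]),
                                   y = c(bb$lo[2], bb$hi[2]), z = 0))
  rho_max <- max(sqrt((corners[, 1] - anchor[1])^2 +
                        (corners[, 2] - anchor[2])^2)) + 0.015
  zlim <- max(abs(c(bb$lo[3], bb$hi[3]))) + 0.004
  d <- range(d_values_mm) / 1000
  zeta_range <- c(max(d[1] - zlim, 5e-4), d[2] + zlim)
  build_field_map(magnet, cur, spacing = cfg$magnet$map_spacing_mm / 1000,
                  rho_max = rho_max, zeta_range = zeta_range)
}

#' Run one complete MDT case
#'
#' Executes the full pipeline for one parameter set: magnetize and map the
#' field, build the airway tree and tumor, solve the flow surrogate, seed
#' the particles, integrate to absorbing states and compute the PDE.
#' Deterministic for a fixed `run.seed`.
#'
#' @param cfg an `mdt_config` (see [default_config()], [make_toy_case()]).
#' @param field_map optional precomputed magnet-frame [build_case_field_map()]
#'   result to reuse across a sweep.
#' @param return_states if `TRUE`, also return the tree, flow, field and
#'   final particle states.
#' @param record passed to [integrate_particles()] (trajectory snapshots).
#' @return a one-row data.frame (sweep-point parameters, deposition counts,
#'   `pde` and `pde_host` in percent) or, with `return_states`, a list.
#' @export
run_case <- function(cfg, field_map = NULL, return_states = FALSE,
                     record = FALSE) {
  t0 <- unname(proc.time()[3])
  tree <- .case_tree(cfg)
  flow <- solve_flow(tree, cfg$flow$Q_lpm, cfg$flow$skew,
                     cfg$flow$rho_a, cfg$flow$eta)
  placed <- NULL
  mg_label <- "none"; BT <- NA_real_
  if (isTRUE(cfg$magnet$enabled)) {
    if (is.null(field_map)) field_map <- build_case_field_map(cfg)
    mg <- .case_magnet(cfg)
    mg_label <- mg$label
    BT <- mg$B_T
    # magnet axis through the tumor's axial station on the magnet-facing
    # (+z) wall line: the tumor angle alpha deflects the tumor away from
    # this line while the magnet stays put
    anchor <- if (!is.null(tree$tumor)) {
      tum <- tree$tumor
      tree$start[tum$host, ] + tree$dir[tum$host, ] * tum$xi0 +
        c(0, 0, tree$R_seg[tum$host])
    } else c(tree$start[1, 1] + tree$L_seg[1] / 2, 0, 0)
    off <- (cfg$magnet$offset_xy_mm %||% c(0, 0)) / 1000
    center <- c(anchor[1] + off[1], anchor[2] + off[2], cfg$magnet$d_mm / 1000)
    placed <- place_magnet(field_map, center, axis = c(0, 0, -1))
  }
  spec <- particle_spec(cfg$particles$d_p_um * 1e-6, cfg$particles$rho_p,
                        cfg$particles$mu_r_p)
  states <- seed_particles(cfg$particles$n, tree, flow, seed = cfg$run$seed,
                           weighting = cfg$particles$seeding)
  states <- integrate_particles(states, flow, placed, spec,
                                dt_max = cfg$run$dt_max,
                                t_max = cfg$run$t_max_factor * .transit_time(flow),
                                bisect_tol = cfg$run$bisect_tol,
                                record = record)
  rec <- compute_pde(states, tree, cfg$run$denominator)
  rec_host <- compute_pde(states, tree, "host_branch")
  row <- data.frame(
    magnet = mg_label, magnet_enabled = isTRUE(cfg$magnet$enabled),
    B_T = BT, d_mm = cfg$magnet$d_mm,
    d_p_um = cfg$particles$d_p_um, mu_r_p = cfg$particles$mu_r_p,
    Q_lpm = cfg$flow$Q_lpm, skew = cfg$flow$skew,
    r_ratio = cfg$tumor$r_ratio, location = cfg$tumor$location,
    alpha_deg = cfg$tumor$alpha_deg,
    n = cfg$particles$n, seed = cfg$run$seed,
    n_tumor = rec$n_tumor, n_wall = rec$n_wall, n_exited = rec$n_exited,
    n_suspended = rec$n_suspended,
    pde = rec$pde, pde_host = rec_host$pde,
    runtime_s = unname(proc.time()[3]) - t0,
    stringsAsFactors = FALSE)
  if (return_states)
    list(record = row, states = states, tree = tree, flow = flow,
         field = placed, field_map = field_map, pde = rec)
  else row
}

#' Run a one-parameter sweep of MDT cases
#'
#' Repeats [run_case()] over a list of values for one dotted configuration
#' key (for example `"particles.d_p_um"`, `"magnet.d_mm"`, `"flow.Q_lpm"`,
#' `"tumor.r_ratio"`, `"tumor.alpha_deg"`, `"magnet.preset"`). Each point
#' gets a fresh deterministic sub-seed derived from the master seed by
#' counter (logged in the output). The magnet-frame field map is built once
#' and reused whenever the sweep axis does not change the magnet itself.
#'
#' @param cfg base `mdt_config`.
#' @param axis dotted config key to vary.
#' @param values vector of values for `axis`.
#' @param csv optional path: write the sweep table as CSV.
#' @return data.frame with one row per sweep point (failed points carry NA
#'   results and an `error` message).
#' @export
run_sweep <- function(cfg, axis, values, csv = NULL) {
  .chk(length(values) >= 1, "empty sweep")
  magnet_axis <- grepl("^magnet\\.", axis) && !axis %in% c("magnet.d_mm", "magnet.offset_xy_mm")
  fmap <- NULL
  if (isTRUE(cfg$magnet$enabled) && !magnet_axis) {
    dvals <- if (axis == "magnet.d_mm") values else cfg$magnet$d_mm
    fmap <- build_case_field_map(cfg, d_values_mm = dvals)
  }
  rows <- vector("list", length(values))
  for (i in seq_along(values)) {
    ci <- set_config(cfg, axis, values[i])
    ci$run$seed <- (cfg$run$seed * 1009 + i) %% 2147483647L
    rows[[i]] <- tryCatch({
      r <- run_case(ci, field_map = fmap)
      r$axis <- axis; r$value <- values[i]; r$error <- NA_character_
      r
    }, error = function(e) {
      data.frame(axis = axis, value = values[i], pde = NA_real_,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    miss <- setdiff(unique(unlist(lapply(rows, names))), names(r))
    for (m in miss) r[[m]] <- NA
    r
  }))
  rownames(out) <- NULL
  # wall-clock timing is excluded so a rerun under the same seeds is
  # bit-identical
  if (!is.null(csv))
    write.csv(out[, setdiff(names(out), "runtime_s")], csv, row.names = FALSE)
  out
}

#' Plot a PDE sweep
#'
#' Simple base-graphics line plot of PDE (%) against the sweep value.
#'
#' @param df a [run_sweep()] table (or several rbound together; one line
#'   per `magnet` label).
#' @param xlab x-axis label (defaults to the sweep axis key).
#' @param file optional PNG path; when given the plot is written there.
#' @return invisibly, `df`.
#' @export
plot_pde_sweep <- function(df, xlab = NULL, file = NULL) {
  if (!is.null(file)) { png(file, width = 800, height = 600); on.exit(dev.off()) }
  xlab <- xlab %||% df$axis[1]
  groups <- unique(df$magnet)
  plot(range(df$value), range(df$pde, na.rm = TRUE), type = "n",
       xlab = xlab, ylab = "PDE (%)")
  for (k in seq_along(groups)) {
    sub <- df[df$magnet == groups[k], ]
    lines(sub$value, sub$pde, type = "b", pch = k, lty = k)
  }
  legend("topright", legend = groups, pch = seq_along(groups),
         lty = seq_along(groups), bty = "n")
  invisible(df)
}
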