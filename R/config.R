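#' Default study configuration
#'
#' The baseline conditions of the simulated MDT study: Weibel G0-G3 tree,
#' mid-branch tumor with `r/R_G1 = 0.8` facing the magnet, a 32.5 x 19 mm
#' bulk magnet calibrated to a 3.42 T peak surface field at `d = 40` mm,
#' air at rest-breathing 15 L/min (density 1.22 kg/m^3, viscosity
#' 1.78e-5 Pa s), and 10,000 particles of 4 um diameter, density
#' 5230 kg/m^3, relative permeability 9.
#'
#' @return nested configuration list of class `mdt_config`.
#' @export
default_config <- function() {
  structure(list(
    lung = list(dims = as.list(weibel_dims()), half_angle_deg = 35),
    tumor = list(enabled = TRUE, r_ratio = 0.8, location = "P1",
                 alpha_deg = 0, host_branch = NULL),
    magnet = list(enabled = TRUE, preset = "M1_77K",
                  a_mm = NULL, t_mm = NULL, B_T = NULL,
                  jc_model = "constant", kim_B0 = 1.5,
                  d_mm = 40, offset_xy_mm = c(0, 0),
                  map_spacing_mm = 1),
    flow = list(Q_lpm = 15, skew = 0.3, rho_a = 1.22, eta = 1.78e-5),
    particles = list(n = 10000, d_p_um = 4, rho_p = 5230, mu_r_p = 9,
                     seeding = "flux"),
    run = list(seed = 42, dt_max = 2e-4, t_max_factor = 3,
               bisect_tol = 1e-6, denominator = "released")
  ), class = "mdt_config")
}

#' Get or set a configuration value by dotted key
#'
#' @param cfg an `mdt_config` list.
#' @param key dotted key such as `"particles.d_p_um"` or `"magnet.d_mm"`.
#' @param value replacement value (for `set_config`).
#' @return `get_config`: the value; `set_config`: the modified config.
#' @export
set_config <- function(cfg, key, value) {
  parts <- strsplit(key, ".", fixed = TRUE)[[1]]
  .chk(length(parts) == 2 && parts[1] %in% names(cfg),
       paste("unknown config key:", key))
  cfg[[parts[1]]][[parts[2]]] <- value
  cfg
}

#' @rdname set_config
#' @export
get_config <- function(cfg, key) {
  parts <- strsplit(key, ".", fixed = TRUE)[[1]]
  cfg[[parts[1]]][[parts[2]]]
}

#' Read and write configurations as YAML
#'
#' @param cfg an `mdt_config`.
#' @param path file path.
#' @return `write_config`: the path invisibly; `read_config`: the config.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "mdt_config")
}

#' Named bulk-magnet presets
#'
#' The magnet configurations of the study: five sizes at 77 K operation
#' (radius/thickness pairs 15/9, 25/15, 32.5/19, 40/23, 50/29 mm with peak
#' surface fields 2.11, 3.02, 3.42, 3.70 and 3.99 T) and the reference
#' 32.5/19 mm bulk at three operating temperatures (77 K: 3.42 T, 60 K:
#' 6.95 T, 50 K: 10.80 T). Each preset carries the constant critical
#' current density calibrated so that the magnetized bulk reproduces its
#' peak field.
#'
#' @return data.frame with columns `label`, `a_mm`, `t_mm`, `B_T`, `Jc0`.
#' @export
make_presets <- function() {
  df <- data.frame(
    label = c("size_15", "size_25", "size_32.5", "size_40", "size_50",
              "M1_77K", "M2_60K", "M2_50K"),
    a_mm = c(15, 25, 32.5, 40, 50, 32.5, 32.5, 32.5),
    t_mm = c(9, 15, 19, 23, 29, 19, 19, 19),
    B_T = c(2.11, 3.02, 3.42, 3.70, 3.99, 3.42, 6.95, 10.80),
    stringsAsFactors = FALSE)
  df$Jc0 <- vapply(seq_len(nrow(df)), function(i) {
    calibrate_jc(df$B_T[i], df$a_mm[i] / 1000, df$t_mm[i] / 1000,
                 model = "constant")$Jc0
  }, numeric(1))
  df
}

#' Reduced toy case for fast end-to-end runs
#'
#' A single straight duct (40 mm long, 5 mm radius) with a mid-duct wall
#' tumor, a small 10 x 6 mm magnet calibrated to 2 T at 15 mm distance,
#' 200 particles and a 2 mm field-map grid. The full pipeline completes in
#' seconds; used by the test suite and as a quick-start example.
#'
#' @return an `mdt_config`.
#' @export
make_toy_case <- function() {
  cfg <- default_config()
  cfg$lung$dims <- list(generation = 0L, length_mm = 40, radius_mm = 5)
  cfg$tumor$r_ratio <- 0.8
  cfg$magnet$preset <- NULL
  cfg$magnet$a_mm <- 10; cfg$magnet$t_mm <- 6; cfg$magnet$B_T <- 2
  cfg$magnet$d_mm <- 15
  cfg$magnet$map_spacing_mm <- 2
  cfg$flow$Q_lpm <- 4.7
  cfg$particles$n <- 200
  cfg$run$seed <- 7
  cfg
}
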