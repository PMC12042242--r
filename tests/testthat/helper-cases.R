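# Shared fixtures, built in code. Heavier objects are created once per test
# run and reused across files.

mu0 <- 4e-7 * pi

vnorm <- function(m) {
  if (is.null(dim(m))) m <- matrix(m, ncol = 3)
  sqrt(rowSums(m * m))
}

table3_dims <- function() {
  data.frame(a_mm = c(15, 25, 32.5, 40, 50),
             t_mm = c(9, 15, 19, 23, 29),
             B_T = c(2.11, 3.02, 3.42, 3.70, 3.99))
}

# default M1 magnet (32.5 x 19 mm, 3.42 T) magnetized accurately
m1_magnet <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      jc <- calibrate_jc(3.42, 0.0325, 0.019, model = "constant")
      m <- bulk_magnet(0.0325, 0.019, jc)
      cache <<- list(magnet = m, current = magnetize(m))
    }
    cache
  }
})

default_tree <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- add_tumor(build_weibel_tree())
    cache
  }
})

default_flow <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- solve_flow(default_tree())
    cache
  }
})
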