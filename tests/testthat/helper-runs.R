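# Shared desk-scale simulation fixtures, computed once per test session.
# The small phantom (1 mm voxels, ~1100 brain hexes) keeps the explicit
# solver runs to seconds; the acceptance tests build the default-resolution
# phantom themselves.

.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .run_cache)) {
    assign(key, force(expr), envir = .run_cache)
  }
  get(key, envir = .run_cache)
}

small_mesh <- function() {
  cached("small_mesh", {
    vol <- make_phantom(phantom_spec(voxel_size = 1))
    smooth_surface(voxel_to_hex(vol), 5, 0.2)
  })
}

small_run <- function(depth, ...) {
  key <- paste0("run_", depth, "_", paste(c(...), collapse = "_"))
  cached(key, {
    run_cci(small_mesh(), default_materials(),
            impactor_spec(depth = depth), sim_config(...))
  })
}

# one-hex mesh with the bottom face pinned, used for unit checks
unit_hex_mesh <- function(h = 1) {
  data <- array(0L, dim = c(3, 3, 3)); data[2, 2, 2] <- 1L
  vol <- label_volume(data, rep(h, 3), origin = -c(h, h, h))
  voxel_to_hex(vol, tissues = "grey")
}

# default-resolution phantom runs shared by the acceptance checks and the
# post-stop wave property (built once per session; several minutes)
default_runs <- function() {
  cached("default_runs", {
    vol <- make_phantom()
    mesh <- smooth_surface(voxel_to_hex(vol), 5, 0.2)
    runs <- lapply(c(1, 2), function(d) {
      run_cci(mesh, default_materials(), impactor_spec(depth = d),
              sim_config())
    })
    names(runs) <- c("mild", "moderate")
    mask <- make_cc_mask(vol, coronal_index(vol, 0))
    list(vol = vol, mesh = mesh, runs = runs, segs = split_cc(mask))
  })
}

# ten ipsilateral (severity, segment) strain covariates from the runs
segment_covariates <- function(dr = default_runs()) {
  out <- do.call(rbind, lapply(names(dr$runs), function(sev) {
    sf <- reduce_history(dr$runs[[sev]])
    sm <- cc_segment_summary(sf, dr$segs)
    ip <- sm[sm$hemisphere == "ipsi", ]
    data.frame(severity = sev, segment = ip$segment[ip$quantity == "strain"],
               strain = ip$mean[ip$quantity == "strain"],
               strain_rate = ip$mean[ip$quantity == "strain_rate"])
  }))
  out
}
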