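# shared fixture builders; everything is generated in code at test time

# binary mask set over an inclusive 0-based voxel index box
box_mask <- function(dims, affine, lo, hi) {
  g <- array(FALSE, dims)
  g[(lo[1] + 1):(hi[1] + 1), (lo[2] + 1):(hi[2] + 1),
    (lo[3] + 1):(hi[3] + 1)] <- TRUE
  binary_mask(g, affine)
}

# scalar volume whose value at each voxel is f(x, y, z) of the voxel centre
field_volume <- function(f, dims, affine, units = "a.u.") {
  centers <- as.matrix(expand.grid(i = 0:(dims[1] - 1), j = 0:(dims[2] - 1),
                                   k = 0:(dims[3] - 1)))
  w <- voxel_to_world(centers, affine)
  scalar_volume(array(f(w[, 1], w[, 2], w[, 3]), dims), affine, units = units)
}

# straight streamline between two points
straight_streamline <- function(from, to, n = 20) {
  t <- seq(0, 1, length.out = n)
  cbind(from[1] + t * (to[1] - from[1]),
        from[2] + t * (to[2] - from[2]),
        from[3] + t * (to[3] - from[3]))
}

# a reduced longitudinal design: 3 subjects seen at all three timepoints
small_sessions <- function() {
  rbind(
    data.frame(subject = c("P1", "P2", "P3"), age_days = c(8L, 10L, 12L),
               timepoint = "0m"),
    data.frame(subject = c("P1", "P2", "P3"), age_days = c(98L, 100L, 102L),
               timepoint = "3m"),
    data.frame(subject = c("P1", "P2", "P3"), age_days = c(188L, 190L, 192L),
               timepoint = "6m"))
}

small_phantom_config <- function(seed = 42L, ...) {
  phantom_config(seed = seed, streamlines_per_bundle = 12L,
                 n_distractors = 50L, sessions = small_sessions(), ...)
}

# cache expensive deterministic fixtures across test files (one R session)
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

small_phantom_static <- function() {
  cached("small_static", phantom_static(small_phantom_config()))
}

# the shared small phantom with its segmentation
small_phantom <- function() {
  cached("small_phantom", {
    cfg <- small_phantom_config()
    ph <- generate_phantom(cfg, metrics = "r1",
                           static = small_phantom_static())
    bundles <- segment_all(ph$streamlines, ph$atlas)
    list(cfg = cfg, ph = ph, bundles = bundles)
  })
}

# long profile table of the small phantom across all sessions
small_phantom_profiles <- function() {
  cached("small_profiles", {
    sp <- small_phantom()
    tabs <- lapply(sp$ph$sessions, function(s) {
      profs <- lapply(Filter(function(b) length(b$member_indices) > 0,
                             sp$bundles), function(b)
        compute_profile(b, s$r1, set = sp$ph$streamlines, metric = "r1"))
      profile_table(profs, s$meta)
    })
    do.call(rbind, tabs)
  })
}
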