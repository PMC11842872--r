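# Shared fixture builders for the test suite. Everything is generated in
# code; no binary data.

# regular polygon approximating a circle
circle_poly <- function(r = 1, center = c(0, 0), n = 64) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

# localization table for molecules following given per-frame positions
locs_from_paths <- function(paths, dt = 0.0117) {
  # paths: list of n x 2 matrices (one row per frame, NA row = missed)
  out <- do.call(rbind, lapply(paths, function(p) {
    f <- which(!is.na(p[, 1]))
    data.frame(frame = f - 1L, t_s = (f - 1L) * dt, x_um = p[f, 1],
               y_um = p[f, 2])
  }))
  out[order(out$frame), ]
}

# stationary molecule detected in the given frames of a scheme
stationary_track <- function(id, frames, x, y, scheme) {
  ft <- frame_table(scheme)
  data.frame(track_id = id, frame = frames,
             t_s = ft$t_s[match(frames, ft$frame)],
             x_um = x, y_um = y)
}

# truth with essentially permanent specific binding (dwell >> movie)
long_binder_truth <- function(loc_error_um = 0) {
  ground_truth(
    diffusion_components = data.frame(fraction = c(0.999, 0.001),
                                      D_um2_s = c(1e-4, 2.5)),
    k_on_u = 1e-6, k_on_s = 10, k_off_u = 10, k_off_s = 1e-6,
    loc_error_um = loc_error_um, per_frame_loss = 0)
}

# truth whose molecules bind only briefly (dwell ~0.5 s << 4 s dark times)
# and wander off between binding events (slow rebinding, large nucleus), so
# that an unbound molecule never mimics dark-time survival
short_binder_truth <- function(loc_error_um = 0) {
  ground_truth(
    diffusion_components = data.frame(fraction = c(0.1, 0.9),
                                      D_um2_s = c(1e-4, 2.5)),
    k_on_u = 0.3, k_on_s = 1e-9, k_off_u = 2, k_off_s = 1,
    loc_error_um = loc_error_um, per_frame_loss = 0,
    nucleus_radius_um = 10)
}
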