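# Compact phantom configurations used across the suite: full anatomy on
# a 64x64 grid (the epicardium still fits at 1.3 mm spacing), noiseless
# unless stated.
small_config <- function(..., snr = Inf) {
  phantom_config(matrix_size = c(64L, 64L), snr = snr, ...)
}

# nearest-neighbour upsampling of a logical mask, for interpolated runs
upsample_mask <- function(mask, target) {
  d <- dim(mask)
  out <- array(FALSE, dim = c(target, d[3]))
  for (k in seq_len(d[3]))
    out[, , k] <- interpolate_to_matrix(mask[, , k] * 1, target,
                                        method = "nearest")$image > 0.5
  out
}

# fabricate a t2_map directly from a value array (all voxels valid
# unless listed in `invalid`)
fake_t2_map <- function(values, spacing_mm = c(1.3, 1.3, 6),
                        invalid = integer(0), t_min = 0) {
  flag <- array(0L, dim = dim(values))
  flag[invalid] <- 1L
  structure(list(t2 = values, a = values * 0 + 1, c = values * 0,
                 residual = values * 0, flag = flag,
                 spacing_mm = spacing_mm, t_min = t_min,
                 n_fitted = sum(flag == 0L), noise_sd = 0),
            class = "t2_map")
}
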