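#' Fit the 3-parameter T2 decay model to one voxel
#'
#' Fits `S(TE) = A * exp(-TE / T2) + C` to magnitude signals by bounded
#' Levenberg-Marquardt least squares with an analytic Jacobian,
#' initialized from a log-linear fit of `signal - min(signal)`. The
#' constant offset absorbs the magnitude-image noise floor. Voxels whose
#' signal carries no identifiable decay (non-decreasing signal, or a
#' non-negative log-linear slope) or whose relative residual exceeds
#' `max_rel_resid` are flagged invalid rather than given a default T2.
#'
#' @param signal magnitude signal at each echo time.
#' @param TEs echo times (ms), strictly increasing; at least 3 samples
#'   are required (4 in routine use).
#' @param t2_bounds allowed T2 range (ms), default `c(1, 500)`.
#' @param max_rel_resid validity ceiling on `||residual|| / ||signal||`.
#' @param noise_sd Gaussian channel noise sigma of the magnitude data.
#'   When positive, the second-moment Rician correction
#'   `sqrt(max(S^2 - 2 * sigma^2, 0))` is applied to the signal before
#'   fitting, removing the noise-floor contribution to the decay tail.
#' @return list with elements `a`, `t2`, `c`, `residual` (residual RMS),
#'   `valid` (logical) and `reason` (`NA` when valid).
#' @export
fit_t2_voxel <- function(signal, TEs, t2_bounds = c(1, 500),
                         max_rel_resid = 0.25, noise_sd = 0) {
  if (length(signal) != length(TEs))
    stop("signal and TEs must have equal length", call. = FALSE)
  if (length(TEs) < 3)
    stop("at least 3 echo times are required to fit the 3-parameter model",
         call. = FALSE)
  if (any(diff(TEs) <= 0))
    stop("TEs must be strictly increasing", call. = FALSE)
  invalid <- function(reason)
    list(a = NA_real_, t2 = NA_real_, c = NA_real_, residual = NA_real_,
         valid = FALSE, reason = reason)
  if (any(!is.finite(signal)) || all(signal <= 0))
    return(invalid("no signal"))
  if (noise_sd > 0)
    signal <- sqrt(pmax(signal^2 - 2 * noise_sd^2, 0))
  if (all(diff(signal) >= 0))
    return(invalid("signal non-decreasing"))

  ## log-linear initialization on the offset-subtracted signal
  y <- signal - min(signal)
  pos <- y > 0
  if (sum(pos) < 2) return(invalid("degenerate decay"))
  ll <- stats::lm.fit(cbind(1, TEs[pos]), log(y[pos]))
  slope <- ll$coefficients[2]
  if (!is.finite(slope) || slope >= 0)
    return(invalid("no decay identified"))
  t2_0 <- min(max(-1 / slope, t2_bounds[1]), t2_bounds[2])
  a_0 <- max(exp(ll$coefficients[1]), max(signal) * 1e-3)
  c_0 <- max(min(signal), 0)

  resid_fn <- function(p) p[1] * exp(-TEs / p[2]) + p[3] - signal
  jac_fn <- function(p) {
    e <- exp(-TEs / p[2])
    cbind(e, p[1] * TEs * e / p[2]^2, 1)
  }
  fit <- try(minpack.lm::nls.lm(
    par = c(a_0, t2_0, c_0),
    lower = c(0, t2_bounds[1], 0), upper = c(Inf, t2_bounds[2], Inf),
    fn = resid_fn, jac = jac_fn,
    control = minpack.lm::nls.lm.control(maxiter = 200, ptol = 1e-10,
                                         ftol = 1e-10)), silent = TRUE)
  if (inherits(fit, "try-error")) return(invalid("solver failure"))
  p <- fit$par
  r <- resid_fn(p)
  rel <- sqrt(sum(r^2)) / sqrt(sum(signal^2))
  if (!is.finite(rel) || rel > max_rel_resid)
    return(invalid("residual above threshold"))
  list(a = p[1], t2 = p[2], c = p[3],
       residual = sqrt(mean(r^2)), valid = TRUE, reason = NA_character_)
}

## flag codes used in T2 maps
FLAG_VALID <- 0L
FLAG_INVALID <- 1L
FLAG_NOT_FITTED <- 2L

#' Fit a T2 map over a masked region of a multi-echo series
#'
#' Applies [fit_t2_voxel()] to every voxel of the mask. Out-of-mask
#' voxels are flagged not-fitted; in-mask voxels without an identifiable
#' decay are flagged invalid. An empty mask yields a map with zero
#' fitted voxels, which is not an error.
#'
#' @param series an `image_series` with TE contrast (a TI series is a
#'   contract violation).
#' @param mask logical array matching the series grid, or `NULL` to fit
#'   every voxel with non-zero first-echo signal.
#' @param noise_sd `"auto"` (default) estimates the Gaussian channel
#'   sigma from the darkest out-of-mask (background) voxels by the
#'   Rayleigh second moment and applies the Rician noise-floor
#'   correction of [fit_t2_voxel()]; a number fixes sigma; 0 disables
#'   the correction.
#' @param ... passed to [fit_t2_voxel()].
#' @return A `t2_map`: list with arrays `t2`, `a`, `c`, `residual`
#'   (`NA` outside valid voxels), integer `flag` (0 valid, 1 invalid,
#'   2 not fitted), `spacing_mm`, `t_min`, `n_fitted`, `noise_sd`.
#' @export
fit_t2_map <- function(series, mask = NULL, noise_sd = "auto", ...) {
  stopifnot(inherits(series, "image_series"))
  if (!identical(series$contrast, "TE"))
    stop("fit_t2_map requires a T2-prepared (TE) series; got contrast '",
         series$contrast, "'", call. = FALSE)
  dims <- dim(series$data)[1:3]
  if (is.null(mask)) mask <- array(series$data[, , , 1] > 0, dim = dims)
  stopifnot(identical(dim(mask), as.integer(dims)) ||
              identical(dim(mask), dims))
  nv <- prod(dims)
  sig <- matrix(series$data, nrow = nv)
  if (identical(noise_sd, "auto"))
    noise_sd <- estimate_noise_sd(sig, which(!mask))
  t2 <- a <- cc <- res <- array(NA_real_, dim = dims)
  flag <- array(FLAG_NOT_FITTED, dim = dims)
  idx <- which(mask)
  for (v in idx) {
    f <- fit_t2_voxel(sig[v, ], series$values, noise_sd = noise_sd, ...)
    if (f$valid) {
      t2[v] <- f$t2; a[v] <- f$a; cc[v] <- f$c; res[v] <- f$residual
      flag[v] <- FLAG_VALID
    } else {
      flag[v] <- FLAG_INVALID
    }
  }
  structure(list(t2 = t2, a = a, c = cc, residual = res, flag = flag,
                 spacing_mm = series$spacing_mm, t_min = series$t_min,
                 n_fitted = sum(flag == FLAG_VALID), noise_sd = noise_sd),
            class = "t2_map")
}

## Gaussian channel sigma from background (air) voxels, where the
## magnitude is Rayleigh with E[M^2] = 2 sigma^2. Background voxels are
## the out-of-mask voxels whose across-echo maximum stays below twice
## the out-of-mask median, which keeps tissue and blood out while
## retaining essentially the whole air population.
estimate_noise_sd <- function(sig, bg_idx) {
  if (length(bg_idx) < 50) return(0)
  mx <- apply(sig[bg_idx, , drop = FALSE], 1, max)
  dark <- bg_idx[mx <= 2 * median(mx)]
  if (length(dark) < 20) return(0)
  sqrt(mean(sig[dark, ]^2) / 2)
}

#' @export
print.t2_map <- function(x, ...) {
  cat("<t2_map> ", paste(dim(x$t2), collapse = "x"), ", ", x$n_fitted,
      " fitted voxels @ t = ", x$t_min, " min\n", sep = "")
  invisible(x)
}

#' Mean T2 over a region of interest
#'
#' @param map a `t2_map`.
#' @param mask logical array; only voxels with a valid fit contribute.
#' @return mean T2 in ms (`NaN` for an empty valid set).
#' @export
roi_mean_t2 <- function(map, mask) {
  stopifnot(inherits(map, "t2_map"))
  mean(map$t2[mask & map$flag == FLAG_VALID])
}

#' Interpolate a 2D slice to a target matrix size
#'
#' Bilinear interpolation (via EBImage) with the voxel spacing rescaled
#' so the physical field of view is preserved; volumes computed after
#' interpolation must use the rescaled spacing.
#'
#' @param image 2D numeric matrix.
#' @param target integer c(nx, ny), e.g. `c(256, 256)`.
#' @param spacing_mm in-plane spacing of the input (mm).
#' @param method `"bilinear"` for images, `"nearest"` for label masks.
#' @return list with `image` (target-size matrix) and `spacing_mm`.
#' @export
interpolate_to_matrix <- function(image, target = c(256L, 256L),
                                  spacing_mm = c(1, 1),
                                  method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  stopifnot(is.matrix(image))
  if (any(target <= 0)) stop("target matrix size must be positive",
                             call. = FALSE)
  if (all(dim(image) == target))
    return(list(image = image, spacing_mm = spacing_mm))
  out <- EBImage::resize(image, w = target[1], h = target[2],
                         filter = if (method == "bilinear") "bilinear"
                                  else "none")
  list(image = matrix(out, target[1], target[2]),
       spacing_mm = spacing_mm * dim(image) / target)
}

#' Interpolate every slice and contrast of an image series
#'
#' @param series an `image_series`.
#' @param target in-plane target matrix size.
#' @return a new `image_series` on the target grid with rescaled spacing.
#' @export
interpolate_series <- function(series, target = c(256L, 256L)) {
  stopifnot(inherits(series, "image_series"))
  d <- dim(series$data)
  out <- array(0, dim = c(target, d[3], d[4]))
  sp <- series$spacing_mm
  for (k in seq_len(d[3])) for (i in seq_len(d[4])) {
    r <- interpolate_to_matrix(series$data[, , k, i], target, sp[1:2])
    out[, , k, i] <- r$image
    sp2 <- r$spacing_mm
  }
  new_image_series(out, series$contrast, series$values, series$t_min,
                   c(sp[1:2] * d[1:2] / target, sp[3]), series$snr)
}
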