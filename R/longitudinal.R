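#' @importFrom dplyr group_by mutate ungroup filter arrange summarise
#'   bind_rows n
#' @importFrom tibble tibble as_tibble
NULL

#' Default post-ablation analysis intervals (min)
#'
#' The three windows used for interval-wise summaries: 0-25 min
#' (initial measurements), 60-80 min (lesion progression) and
#' 80-185 min (towards the end of the study). Observations between 25
#' and 60 min fall in no interval and are excluded from interval-wise
#' analyses; the gap is respected, not bridged.
#'
#' @return list of `c(lower, upper)` bounds.
#' @export
default_intervals <- function() list(c(0, 25), c(60, 80), c(80, 185))

interval_label <- function(iv) sprintf("%g-%g", iv[1], iv[2])

## assign each time to an interval label (NA outside all intervals);
## bounds are (lower, upper], with the lower bound included when it is 0
assign_interval <- function(t, intervals = default_intervals()) {
  out <- rep(NA_character_, length(t))
  for (iv in intervals) {
    inside <- (t > iv[1] & t <= iv[2]) | (iv[1] == 0 & t >= 0 & t <= iv[2])
    out[inside & is.na(out)] <- interval_label(iv)
  }
  out
}

#' Normalize lesion volumes to their baseline measurement
#'
#' The baseline for each (lesion, contrast) series is the row with the
#' minimum post-ablation time; ties are broken deterministically by row
#' order (with a message). All times are measured from the start of
#' ablation.
#'
#' @param table data frame with columns `lesion_id`, `contrast`,
#'   `t_min`, `volume_mL` (and optionally `animal_id`).
#' @return the table with a `normalized_volume` column; the baseline
#'   row of every series is exactly 1.
#' @export
normalize_to_baseline <- function(table) {
  stopifnot(all(c("lesion_id", "contrast", "t_min", "volume_mL") %in%
                  names(table)))
  tbl <- as_tibble(table)
  tbl$.row <- seq_len(nrow(tbl))
  tbl <- tbl |>
    group_by(.data$lesion_id, .data$contrast) |>
    mutate(.baseline = {
      i <- which(.data$t_min == min(.data$t_min))
      if (length(i) > 1)
        message(sprintf("tied baseline times for lesion %s (%s); using first row",
                        .data$lesion_id[1], .data$contrast[1]))
      .data$volume_mL[i[1]]
    }) |>
    ungroup()
  if (any(tbl$.baseline <= 0))
    stop("baseline volume must be positive for every (lesion, contrast)",
         call. = FALSE)
  tbl$normalized_volume <- tbl$volume_mL / tbl$.baseline
  tbl$.baseline <- NULL
  tbl$.row <- NULL
  tbl
}

#' Fit the longitudinal linear mixed model of normalized volume
#'
#' Fits `normalized_volume ~ t_min + (1 | animal_id)` by REML: a fixed
#' linear time trend with a random per-animal intercept accounting for
#' clustering of lesions within animals. Baseline normalization already
#' anchors each lesion's series at 1, so no random slope is used.
#'
#' @param table data frame with columns `animal_id`, `lesion_id`,
#'   `contrast`, `t_min`, `normalized_volume`.
#' @param contrast optional contrast label to filter on (e.g.
#'   `"T2-edema"`).
#' @return An `lmm_fit`: fixed effects (`beta0`, `beta1`) with standard
#'   errors and Satterthwaite p-values, random-intercept and residual
#'   variances, sample sizes, and the underlying `lmerMod`.
#' @export
fit_lmm <- function(table, contrast = NULL) {
  tbl <- as_tibble(table)
  if (!is.null(contrast)) tbl <- tbl[tbl$contrast == contrast, ]
  stopifnot(all(c("animal_id", "lesion_id", "t_min",
                  "normalized_volume") %in% names(tbl)))
  n_lesions <- length(unique(tbl$lesion_id))
  n_animals <- length(unique(tbl$animal_id))
  if (n_animals < 2)
    stop("random-intercept grouping is degenerate: at least 2 animals ",
         "are required", call. = FALSE)
  if (n_lesions < 3)
    stop("at least 3 lesions are required to fit the longitudinal model",
         call. = FALSE)
  times_per <- table(tbl$lesion_id)
  if (mean(times_per >= 2) < 0.5)
    stop("at least half the lesions must have 2 or more time points",
         call. = FALSE)
  tbl$animal_id <- factor(tbl$animal_id)
  m <- tryCatch(
    lmerTest::lmer(normalized_volume ~ t_min + (1 | animal_id),
                   data = tbl, REML = TRUE),
    error = function(e)
      stop("linear mixed model failed to converge: ",
           conditionMessage(e), call. = FALSE))
  co <- stats::coef(summary(m))
  vc <- as.data.frame(lme4::VarCorr(m))
  structure(list(
    beta0 = co["(Intercept)", "Estimate"],
    beta0_se = co["(Intercept)", "Std. Error"],
    beta0_p = co["(Intercept)", "Pr(>|t|)"],
    beta1 = co["t_min", "Estimate"],
    beta1_se = co["t_min", "Std. Error"],
    beta1_p = co["t_min", "Pr(>|t|)"],
    var_animal = vc$vcov[vc$grp == "animal_id"],
    var_resid = vc$vcov[vc$grp == "Residual"],
    n_lesions = n_lesions, n_animals = n_animals, n_obs = nrow(tbl),
    model = m), class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("<lmm_fit> normalized_volume ~ t_min + (1 | animal_id), REML\n")
  cat(sprintf("  intercept %.4f +/- %.4f (p = %.3g)\n",
              x$beta0, x$beta0_se, x$beta0_p))
  cat(sprintf("  slope     %.5f +/- %.5f per min (p = %.3g)\n",
              x$beta1, x$beta1_se, x$beta1_p))
  cat(sprintf("  var(animal) = %.4g, var(resid) = %.4g; %d lesions / %d animals / %d obs\n",
              x$var_animal, x$var_resid, x$n_lesions, x$n_animals,
              x$n_obs))
  invisible(x)
}

#' Population-level prediction from the mixed model
#'
#' Fixed-effect (population) prediction `beta0 + beta1 * t` with random
#' effects at zero; e.g. the expected normalized volume at 180 min
#' post-ablation.
#'
#' @param fit an `lmm_fit`.
#' @param t time post-ablation (min); vectorized.
#' @return predicted normalized volume.
#' @export
predict_fixed <- function(fit, t) {
  stopifnot(inherits(fit, "lmm_fit"))
  fit$beta0 + fit$beta1 * t
}

#' Interval-wise edema-to-lesion volume ratios
#'
#' Pairs T2-derived edema and T1-derived lesion observations of the same
#' lesion within each analysis interval (nearest in time within the
#' interval), forms the volume ratio, and summarizes per interval with a
#' one-sided one-sample t-test of ratio > 1 and a Welch ANOVA across
#' intervals. Intervals with fewer than 2 pairs are excluded with a
#' message. Ratios are scale invariant by construction.
#'
#' @param edema,lesion data frames with columns `lesion_id`, `t_min`,
#'   `volume_mL`.
#' @param intervals list of `c(lower, upper)` windows,
#'   default [default_intervals()].
#' @return list with `pairs` (matched observations and ratios),
#'   `summary` (per-interval n, mean, sd, 95% CI, p for ratio > 1) and
#'   `anova_p` (Welch test across intervals, `NA` with < 2 usable
#'   intervals).
#' @export
interval_ratio <- function(edema, lesion, intervals = default_intervals()) {
  stopifnot(all(c("lesion_id", "t_min", "volume_mL") %in% names(edema)),
            all(c("lesion_id", "t_min", "volume_mL") %in% names(lesion)))
  pairs <- list()
  for (iv in intervals) {
    lab <- interval_label(iv)
    for (id in intersect(unique(edema$lesion_id), unique(lesion$lesion_id))) {
      e <- edema[edema$lesion_id == id &
                   !is.na(assign_interval(edema$t_min, list(iv))), ]
      l <- lesion[lesion$lesion_id == id &
                    !is.na(assign_interval(lesion$t_min, list(iv))), ]
      if (nrow(e) == 0 || nrow(l) == 0) next
      dt <- abs(outer(e$t_min, l$t_min, "-"))
      best <- which(dt == min(dt), arr.ind = TRUE)[1, ]
      pairs[[length(pairs) + 1L]] <- tibble(
        interval = lab, lesion_id = id,
        t_edema = e$t_min[best[1]], t_lesion = l$t_min[best[2]],
        edema_mL = e$volume_mL[best[1]], lesion_mL = l$volume_mL[best[2]],
        ratio = e$volume_mL[best[1]] / l$volume_mL[best[2]])
    }
  }
  pairs <- if (length(pairs)) bind_rows(pairs) else
    tibble(interval = character(), lesion_id = integer(),
           t_edema = numeric(), t_lesion = numeric(),
           edema_mL = numeric(), lesion_mL = numeric(), ratio = numeric())
  summary_rows <- list()
  for (iv in intervals) {
    lab <- interval_label(iv)
    r <- pairs$ratio[pairs$interval == lab]
    if (length(r) < 2) {
      if (length(r) > 0)
        message(sprintf("interval %s min has %d pair(s); excluded (< 2)",
                        lab, length(r)))
      next
    }
    s <- sd(r)
    se <- s / sqrt(length(r))
    tq <- qt(0.975, length(r) - 1)
    p_gt1 <- if (s == 0) {
      if (mean(r) > 1) 0 else 1
    } else t.test(r, mu = 1, alternative = "greater")$p.value
    summary_rows[[length(summary_rows) + 1L]] <- tibble(
      interval = lab, n = length(r), mean = mean(r), sd = s,
      ci_lower = mean(r) - tq * se, ci_upper = mean(r) + tq * se,
      p_greater_than_1 = p_gt1)
  }
  summ <- if (length(summary_rows)) bind_rows(summary_rows) else
    tibble(interval = character(), n = integer(), mean = numeric(),
           sd = numeric(), ci_lower = numeric(), ci_upper = numeric(),
           p_greater_than_1 = numeric())
  anova_p <- NA_real_
  usable <- pairs[pairs$interval %in% summ$interval, ]
  if (length(unique(usable$interval)) >= 2 &&
      all(tapply(usable$ratio, usable$interval, sd) > 0)) {
    anova_p <- oneway.test(ratio ~ interval, data = usable)$p.value
  }
  list(pairs = pairs, summary = summ, anova_p = anova_p)
}

#' ROI-mean T2 time course for one lesion
#'
#' Computes the ROI-mean fitted T2 in the three key regions (healthy
#' tissue, T1-derived lesion, largest edematous region) for a sequence
#' of T2 maps. Masks are fixed across time so a consistent tissue
#' region is examined.
#'
#' @param maps list of `t2_map`s.
#' @param times acquisition times (min), one per map.
#' @param masks named list of logical arrays; typical names `healthy`,
#'   `lesion`, `edema`.
#' @param intervals analysis windows, default [default_intervals()].
#' @param lesion_id identifier recorded in the output.
#' @return tibble with columns `lesion_id`, `t_min`, `interval`,
#'   `region`, `mean_t2`.
#' @export
roi_t2_timecourse <- function(maps, times, masks,
                              intervals = default_intervals(),
                              lesion_id = 1L) {
  stopifnot(length(maps) == length(times), length(masks) >= 1,
            !is.null(names(masks)))
  rows <- list()
  for (i in seq_along(maps)) {
    for (rg in names(masks)) {
      rows[[length(rows) + 1L]] <- tibble(
        lesion_id = lesion_id, t_min = times[i],
        interval = assign_interval(times[i], intervals),
        region = rg, mean_t2 = roi_mean_t2(maps[[i]], masks[[rg]]))
    }
  }
  bind_rows(rows)
}

#' Summarize T2 time courses across lesions
#'
#' Aggregates stacked [roi_t2_timecourse()] samples into per-region,
#' per-interval means and SDs, with paired t-tests between intervals
#' (paired on lesion) and paired comparisons of each region against
#' healthy tissue within intervals. Intervals without samples for a
#' region are dropped for that region.
#'
#' @param samples tibble from one or more [roi_t2_timecourse()] calls.
#' @return list with `summary` and `tests` tibbles.
#' @export
t2_timecourse_stats <- function(samples) {
  stopifnot(all(c("lesion_id", "t_min", "interval", "region", "mean_t2")
                %in% names(samples)))
  samples <- samples[!is.na(samples$interval) & !is.na(samples$mean_t2), ]
  ## one value per lesion-interval-region (average repeated maps)
  cell <- samples |>
    group_by(.data$region, .data$interval, .data$lesion_id) |>
    summarise(mean_t2 = mean(.data$mean_t2), .groups = "drop")
  summ <- cell |>
    group_by(.data$region, .data$interval) |>
    summarise(n = n(), mean = mean(.data$mean_t2),
              sd = sd(.data$mean_t2), .groups = "drop")
  tests <- list()
  paired_p <- function(a, b) {
    d <- a - b
    if (length(d) < 2 || sd(d) == 0) return(NA_real_)
    t.test(a, b, paired = TRUE)$p.value
  }
  ivs <- unique(cell$interval)
  for (rg in unique(cell$region)) {
    sub <- cell[cell$region == rg, ]
    if (length(ivs) >= 2) {
      cmb <- utils::combn(sort(ivs), 2)
      for (ci in seq_len(ncol(cmb))) {
        a <- sub[sub$interval == cmb[1, ci], ]
        b <- sub[sub$interval == cmb[2, ci], ]
        ids <- intersect(a$lesion_id, b$lesion_id)
        if (length(ids) < 2) next
        tests[[length(tests) + 1L]] <- tibble(
          comparison = sprintf("%s: %s vs %s", rg, cmb[1, ci], cmb[2, ci]),
          n = length(ids),
          p = paired_p(a$mean_t2[match(ids, a$lesion_id)],
                       b$mean_t2[match(ids, b$lesion_id)]))
      }
    }
    if (rg != "healthy" && "healthy" %in% cell$region) {
      for (iv in ivs) {
        a <- cell[cell$region == rg & cell$interval == iv, ]
        h <- cell[cell$region == "healthy" & cell$interval == iv, ]
        ids <- intersect(a$lesion_id, h$lesion_id)
        if (length(ids) < 2) next
        tests[[length(tests) + 1L]] <- tibble(
          comparison = sprintf("%s vs healthy: %s", rg, iv),
          n = length(ids),
          p = paired_p(a$mean_t2[match(ids, a$lesion_id)],
                       h$mean_t2[match(ids, h$lesion_id)]))
      }
    }
  }
  list(summary = summ,
       tests = if (length(tests)) bind_rows(tests) else
         tibble(comparison = character(), n = integer(), p = numeric()))
}

#' Bland-Altman agreement analysis
#'
#' Paired-difference agreement between two measurement methods: bias
#' (mean difference), SD of differences, 95% limits of agreement
#' `bias +/- 1.96 * SD`, and a paired t-test p-value. Swapping the
#' inputs negates the bias and the limits.
#'
#' @param a,b paired measurements (equal length, at least 3).
#' @return list of class `agreement_result` with `bias`, `sd_diff`,
#'   `loa` (lower, upper), `p`, `n`.
#' @export
bland_altman <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (length(a) < 3)
    stop("Bland-Altman analysis requires at least 3 pairs", call. = FALSE)
  d <- a - b
  bias <- mean(d)
  sdd <- sd(d)
  p <- if (sdd == 0) {
    if (bias == 0) NA_real_ else 0
  } else t.test(a, b, paired = TRUE)$p.value
  structure(list(bias = bias, sd_diff = sdd,
                 loa = c(bias - 1.96 * sdd, bias + 1.96 * sdd),
                 p = p, n = length(a)), class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("<agreement_result> bias %.4g (SD %.4g), 95%% LoA [%.4g, %.4g], p = %.3g, n = %d\n",
              x$bias, x$sd_diff, x$loa[1], x$loa[2], x$p, x$n))
  invisible(x)
}

#' Correlation between paired measurements
#'
#' Pearson correlation with the least-squares regression line, or
#' Spearman rank correlation. Zero-variance input is flagged undefined
#' rather than an error.
#'
#' @param x,y paired measurements (equal length, at least 3).
#' @param method `"pearson"` or `"spearman"`.
#' @return list with `r`, `p`, `slope`, `intercept` (Pearson only),
#'   `method`, `flagged`.
#' @export
correlate_volumes <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  if (length(x) < 3)
    stop("correlation requires at least 3 pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, slope = NA_real_,
                intercept = NA_real_, method = method, flagged = TRUE))
  ct <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE))
  out <- list(r = unname(ct$estimate), p = ct$p.value,
              slope = NA_real_, intercept = NA_real_,
              method = method, flagged = FALSE)
  if (method == "pearson") {
    fit <- lm(y ~ x)
    out$slope <- unname(coef(fit)[2])
    out$intercept <- unname(coef(fit)[1])
  }
  out
}

#' Simulate normalized-volume tables from the longitudinal model
#'
#' Draws repeated studies directly from the random-intercept model
#' `y_it = beta0 + beta1 * t + b_animal + eps`, mirroring the design of
#' the in-vivo study (13 lesions clustered in 11 animals, about 5
#' imaging times per lesion between 10 and 180 min). Used for
#' parameter-recovery and coverage simulations of [fit_lmm()].
#'
#' @param n_lesions,n_animals study design; lesions are assigned to
#'   animals cyclically so some animals carry two lesions.
#' @param times_per_lesion imaging time points per lesion.
#' @param t_range window (min) the imaging times are drawn from.
#' @param beta0,beta1 true fixed effects (intercept, slope per min).
#' @param sd_animal,sd_resid random-intercept and residual SDs.
#' @param contrast contrast label for the output table.
#' @param seed RNG seed (`NULL` uses the current RNG state).
#' @return tibble with `animal_id`, `lesion_id`, `contrast`, `t_min`,
#'   `volume_mL`, `normalized_volume`.
#' @export
simulate_lmm_study <- function(n_lesions = 13, n_animals = 11,
                               times_per_lesion = 5, t_range = c(10, 180),
                               beta0 = 1.20, beta1 = 0.003,
                               sd_animal = 0.1, sd_resid = 0.15,
                               contrast = "T2-edema", seed = NULL) {
  gen <- function() {
    animal <- ((seq_len(n_lesions) - 1) %% n_animals) + 1L
    b <- rnorm(n_animals, 0, sd_animal)
    rows <- lapply(seq_len(n_lesions), function(i) {
      t <- sort(runif(times_per_lesion, t_range[1], t_range[2]))
      y <- beta0 + beta1 * t + b[animal[i]] +
        rnorm(times_per_lesion, 0, sd_resid)
      tibble(animal_id = animal[i], lesion_id = i, contrast = contrast,
             t_min = t, volume_mL = y, normalized_volume = y)
    })
    bind_rows(rows)
  }
  if (is.null(seed)) gen() else withr::with_seed(as.integer(seed), gen())
}
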