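# Downstream regressions on per-clade summaries: partition-rate integration
# and the age-dependence of divergence-time precision.

#' Ordinary least-squares regression of matched per-clade values
#'
#' @param x,y numeric vectors of equal length (n >= 3), matched by clade.
#' @return list with `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
regress <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop2("need at least 3 matched finite pairs")
  if (stats::sd(x) == 0) stop2("zero variance in x: slope undefined")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  p <- if (nrow(sm$coefficients) > 1) sm$coefficients[2, 4] else NA_real_
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared, p_value = p, n = length(x))
}

#' Pairwise partition-rate regressions (integration report)
#'
#' Regresses median relative evolutionary rates of each partition pair over
#' the clades shared by all partitions. High `r_squared` between two
#' partitions signals integrated (correlated) evolution; statistics are
#' reported without a thresholded verdict.
#'
#' @param rate_frames named list (one per partition) of data frames with
#'   columns `clade` and `median_rel_rate` (e.g. from
#'   [relative_branch_rates()]).
#' @return data frame with one row per unordered pair: `partition_x`,
#'   `partition_y`, `slope`, `r_squared`, `p_value`, `n`.
#' @export
integration_report <- function(rate_frames) {
  if (length(rate_frames) < 2L) stop2("need >= 2 partitions")
  labs <- names(rate_frames)
  shared <- Reduce(intersect, lapply(rate_frames, function(f) f$clade))
  if (length(shared) < 3L) stop2("fewer than 3 clades shared by all partitions")
  dropped <- sum(vapply(rate_frames, function(f)
    sum(!(f$clade %in% shared)), numeric(1)))
  if (dropped > 0)
    message(dropped, " clade rows outside the shared set were dropped")
  vals <- lapply(rate_frames, function(f)
    f$median_rel_rate[match(shared, f$clade)])
  rows <- list()
  for (i in seq_len(length(labs) - 1L)) for (j in seq.int(i + 1L, length(labs))) {
    r <- regress(vals[[i]], vals[[j]])
    rows[[length(rows) + 1L]] <- data.frame(
      partition_x = labs[i], partition_y = labs[j],
      slope = r$slope, r_squared = r$r_squared, p_value = r$p_value, n = r$n)
  }
  do.call(rbind, rows)
}

#' Age-dependence of divergence-time precision
#'
#' Per model, regresses the 95% HPD range of each clade's age on its median
#' age. A positive slope means older nodes are estimated less precisely —
#' the usual depth bias of tip-dated morphological clocks.
#'
#' @param summaries named list of `summary_tree` objects (one per model).
#' @param min_pp only clades at or above this posterior probability enter
#'   the regression.
#' @return data frame with `model`, `slope`, `r_squared`, `p_value`, `n`.
#' @export
depth_bias_report <- function(summaries, min_pp = 0) {
  rows <- lapply(names(summaries), function(lab) {
    cl <- summaries[[lab]]$clades
    cl <- cl[cl$pp >= min_pp, ]
    r <- regress(cl$median_age, cl$hpd_range)
    data.frame(model = lab, slope = r$slope, r_squared = r$r_squared,
               p_value = r$p_value, n = r$n)
  })
  do.call(rbind, rows)
}
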