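## Calibration cross-validation: each calibration in turn ("focal") is used
## alone (plus the root soft maximum) to date the tree; the resulting mean
## ages at the other calibrated nodes are scored against those nodes'
## fossil constraints. Statistics follow the leave-one-calibration-in
## scheme: D-bar (mean deviation), SS (sum of squared deviations) and the
## pooled deviation s = sum(SS) / (n(n-1)).
##
## Sign conventions: minimum-only deviations are (estimate - minimum), so
## positive values mean estimates predate minima. The min-max deviation is
## 0 inside [min, max], (estimate - max) > 0 above, (estimate - min) < 0
## below. (The published account of the min-max variant describes a range
## of "slightly negative" values printed without the sign; the convention
## here is explicit.)

#' Mean deviation of estimates from fossil minima
#'
#' `D-bar = mean(MA_i - FA_i)` over the non-focal calibrated nodes:
#' positive values mean molecular estimates predate the minima.
#'
#' @param estimates numeric vector of molecular mean age estimates (Ma).
#' @param minima matching numeric vector of fossil minimum ages (Ma).
#' @return Ma.
#' @examples
#' dbar_min(c(60, 30), c(50, 25))  # 7.5
#' @export
dbar_min <- function(estimates, minima) {
  stopifnot(length(estimates) == length(minima), length(estimates) >= 1L)
  mean(estimates - minima)
}

#' Sum of squared deviations from fossil minima
#'
#' `SS = sum((MA_i - FA_i)^2)` over the non-focal calibrated nodes.
#'
#' @inheritParams dbar_min
#' @return Ma^2.
#' @examples
#' ss_min(c(60, 30), c(50, 25))  # 125
#' @export
ss_min <- function(estimates, minima) {
  stopifnot(length(estimates) == length(minima), length(estimates) >= 1L)
  sum((estimates - minima)^2)
}

#' Signed deviation relative to a minimum-maximum interval
#'
#' Zero inside `[minimum, maximum]`; `estimate - maximum` (positive, too
#' old) above; `estimate - minimum` (negative, too young) below.
#'
#' @param estimates molecular mean ages (Ma).
#' @param minima,maxima fossil bounds (Ma), `minima < maxima` elementwise.
#' @return signed deviations (Ma).
#' @export
discrepancy_minmax <- function(estimates, minima, maxima) {
  stopifnot(length(estimates) == length(minima),
            length(minima) == length(maxima))
  if (any(minima >= maxima)) stop("each minimum must be below its maximum")
  ifelse(estimates > maxima, estimates - maxima,
         ifelse(estimates < minima, estimates - minima, 0))
}

#' @rdname dbar_min
#' @param maxima fossil maximum ages (Ma) for the min-max variant.
#' @export
dbar_minmax <- function(estimates, minima, maxima) {
  mean(discrepancy_minmax(estimates, minima, maxima))
}

#' @rdname ss_min
#' @param maxima fossil maximum ages (Ma) for the min-max variant.
#' @export
ss_minmax <- function(estimates, minima, maxima) {
  sum(discrepancy_minmax(estimates, minima, maxima)^2)
}

#' Pooled average squared deviation
#'
#' `s = sum(SS) / (n (n - 1))` where `n` is the number of calibrations and
#' each round contributes its SS over the `n - 1` other nodes.
#'
#' @param ss numeric vector of per-round SS values (length `n`).
#' @param n number of calibrations (`>= 2`).
#' @return Ma^2.
#' @examples
#' pooled_s(c(125, 80, 45), 3)  # 250 / 6
#' @export
pooled_s <- function(ss, n) {
  if (n < 2L) stop("pooled s requires at least two calibrations")
  if (length(ss) != n) stop("expected one SS value per calibration")
  sum(ss) / (n * (n - 1))
}

#' Run one cross-validation round
#'
#' Dates the tree using ONLY the focal calibration — as a uniform prior
#' with hard minimum and soft maximum — plus the root's soft maximum, and
#' records the mean age estimate at every other calibrated node.
#'
#' @param tree a [timetree].
#' @param calibrations the full [calibration_set]; every member must have
#'   both a minimum and a maximum. The set must calibrate the root.
#' @param focal node label of the focal calibration (not the root unless
#'   the root calibration itself carries a maximum).
#' @param engine `"prior"` (date without data: prior-only MCMC),
#'   `"posterior"` (requires `alignment`), or `"stub"` (take mean ages from
#'   `stub`, for testing or externally computed summaries).
#' @param alignment a [dna_alignment] for `engine = "posterior"`.
#' @param stub data frame `focal_node`, `target_node`, `mean_age` for
#'   `engine = "stub"`.
#' @param params,construction,mcmc,seed passed to the sampler.
#' @param clock a [clock_model()] for the posterior engine.
#' @return an `xval_round`: `focal`, `estimates` (named, focal excluded),
#'   `minima`, `maxima`, `dbar_min`, `ss_min`, `dbar_minmax`, `ss_minmax`.
#' @export
run_round <- function(tree, calibrations, focal,
                      engine = c("prior", "posterior", "stub"),
                      alignment = NULL, stub = NULL,
                      params = tree_prior_params(),
                      construction = "conditional",
                      mcmc = mcmc_settings(n_iter = 2e5), seed = 1L,
                      clock = clock_model()) {
  engine <- match.arg(engine)
  stopifnot(inherits(calibrations, "calibration_set"))
  if (!focal %in% names(calibrations)) {
    stop("focal calibration '", focal, "' is not in the set")
  }
  root_lab <- tree$labels[root_node(tree) - n_tips(tree)]
  if (is.na(root_lab) || !root_lab %in% names(calibrations)) {
    stop("the calibration set must calibrate the root")
  }
  root_cal <- calibrations[[root_lab]]
  if (focal == root_lab && !cal_has_upper(root_cal)) {
    stop("focal calibration is the root but no root maximum is available")
  }
  others <- setdiff(names(calibrations), focal)
  minima <- vapply(calibrations[others], `[[`, numeric(1), "t_l")
  maxima <- vapply(calibrations[others], function(cal) {
    if (cal_has_upper(cal)) cal$t_u else NA_real_
  }, numeric(1))

  if (engine == "stub") {
    if (is.null(stub)) stop("engine = 'stub' requires a stub table")
    rows <- stub[stub$focal_node == focal, , drop = FALSE]
    est <- stats::setNames(rows$mean_age, rows$target_node)
    if (!all(others %in% names(est))) {
      stop("stub table lacks estimates for: ",
           paste(setdiff(others, names(est)), collapse = ", "))
    }
    est <- est[others]
  } else {
    foc <- calibrations[[focal]]
    if (!cal_has_upper(foc)) {
      stop("round calibrations must provide a maximum for the focal node")
    }
    round_cal <- calibration(focal, "uniform", t_l = foc$t_l, t_u = foc$t_u,
                             tail_l = foc$tail_l, tail_r = foc$tail_r)
    # the round's only other constraint is the soft maximum at the root:
    # a diffuse uniform from near the present up to the root maximum
    round_set <- if (focal == root_lab) {
      calibration_set(list(round_cal))
    } else {
      root_max_cal <- calibration(root_lab, "uniform", t_l = 1e-3,
                                  t_u = root_cal$t_u,
                                  tail_r = root_cal$tail_r)
      calibration_set(list(round_cal, root_max_cal))
    }
    smp <- if (engine == "prior") {
      sample_prior(tree, round_set, params, construction, mcmc, seed)
    } else {
      if (is.null(alignment)) stop("engine = 'posterior' needs an alignment")
      sample_posterior(tree, round_set, alignment, clock, params,
                       construction, mcmc, seed)
    }
    est <- colMeans(smp$draws)[others]
  }

  structure(
    list(focal = focal, estimates = est, minima = minima, maxima = maxima,
         dbar_min = dbar_min(est, minima),
         ss_min = ss_min(est, minima),
         dbar_minmax = if (anyNA(maxima)) NA_real_
                       else dbar_minmax(est, minima, maxima),
         ss_minmax = if (anyNA(maxima)) NA_real_
                     else ss_minmax(est, minima, maxima)),
    class = "xval_round"
  )
}

#' @export
print.xval_round <- function(x, ...) {
  cat(sprintf(
    "Cross-validation round [%s]: D-bar(min) %.3f Ma, SS(min) %.3f Ma^2\n",
    x$focal, x$dbar_min, x$ss_min))
  invisible(x)
}

#' Run every cross-validation round
#'
#' @inheritParams run_round
#' @param seed base seed; round `k` uses `seed + k`.
#' @return named list of [run_round()] results, one per calibration.
#' @export
run_all_rounds <- function(tree, calibrations, engine = "prior",
                           alignment = NULL, stub = NULL,
                           params = tree_prior_params(),
                           construction = "conditional",
                           mcmc = mcmc_settings(n_iter = 2e5), seed = 1L,
                           clock = clock_model()) {
  root_lab <- tree$labels[root_node(tree) - n_tips(tree)]
  focals <- names(calibrations)
  res <- lapply(seq_along(focals), function(k) {
    run_round(tree, calibrations, focals[k], engine, alignment, stub,
              params, construction, mcmc, seed + k, clock)
  })
  stats::setNames(res, focals)
}

## internal: per-round SS restricted to a surviving calibration set
.restricted_ss <- function(rounds, keep, variant) {
  vapply(keep, function(x) {
    r <- rounds[[x]]
    tgt <- intersect(names(r$estimates), setdiff(keep, x))
    est <- r$estimates[tgt]
    if (variant == "min") {
      ss_min(est, r$minima[tgt])
    } else {
      ss_minmax(est, r$minima[tgt], r$maxima[tgt])
    }
  }, numeric(1))
}

#' Sequential removal of the most inconsistent calibrations
#'
#' Iteratively removes the calibration with the largest SS under the
#' chosen variant, recomputing every round's statistics restricted to the
#' surviving calibration set at each step. The pooled deviation
#' `s = sum(SS) / (n(n-1))` can *rise* after a removal whenever the
#' denominator `n(n-1)` shrinks faster than the numerator `sum(SS)` — the
#' percent-change columns expose exactly that mechanism. A nonparametric
#' bootstrap over the surviving rounds' SS values attaches an interval to
#' each change in s (this package's own significance heuristic; the trace
#' is reported regardless).
#'
#' @param rounds named list of `xval_round` objects (>= 3).
#' @param variant `"min"` or `"minmax"`.
#' @param n_boot bootstrap resamples for the delta-s intervals (default
#'   `1e4`; 0 disables).
#' @return a `removal_trace` data frame: one row per state (step 0 = full
#'   set), columns `step`, `removed`, `n`, `sum_ss`, `denom`, `s`,
#'   `pct_change_sum_ss`, `pct_change_denom`, `pct_change_s`,
#'   `ds_lower`, `ds_upper`. Ties are broken by node label order.
#' @export
sequential_removal <- function(rounds, variant = c("min", "minmax"),
                               n_boot = 1e4) {
  variant <- match.arg(variant)
  if (length(rounds) < 3L) stop("sequential removal needs >= 3 calibrations")
  keep <- sort(names(rounds))
  out <- list()
  step <- 0L
  prev <- NULL
  while (length(keep) >= 2L) {
    ss <- .restricted_ss(rounds, keep, variant)
    n <- length(keep)
    denom <- n * (n - 1)
    s <- sum(ss) / denom
    row <- data.frame(
      step = step, removed = NA_character_, n = n, sum_ss = sum(ss),
      denom = denom, s = s,
      pct_change_sum_ss = NA_real_, pct_change_denom = NA_real_,
      pct_change_s = NA_real_, ds_lower = NA_real_, ds_upper = NA_real_
    )
    if (!is.null(prev)) {
      row$removed <- prev$removed
      row$pct_change_sum_ss <- 100 * (sum(ss) - prev$sum_ss) / prev$sum_ss
      row$pct_change_denom <- 100 * (denom - prev$denom) / prev$denom
      row$pct_change_s <- if (prev$s != 0) 100 * (s - prev$s) / prev$s
                          else NA_real_
      if (n_boot > 0) {
        ds <- replicate(n_boot, {
          sb_prev <- sum(sample(prev$ss, length(prev$ss), replace = TRUE)) /
            prev$denom
          sb_now <- sum(sample(ss, n, replace = TRUE)) / denom
          sb_now - sb_prev
        })
        qs <- stats::quantile(ds, c(0.025, 0.975), type = 7)
        row$ds_lower <- qs[1L]
        row$ds_upper <- qs[2L]
      }
    }
    out[[length(out) + 1L]] <- row
    if (length(keep) == 2L) break
    # remove the largest-SS calibration; ties broken by label order (keep
    # is sorted, which.max takes the first)
    worst <- keep[which.max(ss)]
    prev <- list(removed = worst, ss = ss, sum_ss = sum(ss),
                 denom = denom, s = s)
    keep <- setdiff(keep, worst)
    step <- step + 1L
  }
  trace <- do.call(rbind, out)
  class(trace) <- c("removal_trace", "data.frame")
  trace
}

#' Revision of fossil minima between calibration eras
#'
#' Percent revision per node of the minimum constraint from an earlier
#' consistency-assessed set to a revised, evidence-vetted set:
#' `100 * (min_old - min_revised) / min_old`. Positive values mean the
#' revision made the minimum younger.
#'
#' @param minima_old named numeric vector (Ma) of the earlier minima.
#' @param minima_revised matching vector of revised minima; names are
#'   aligned with `minima_old`.
#' @return list with `per_node` data frame (`node`, `old`, `revised`,
#'   `percent`) and `max_abs_percent`.
#' @export
revision_percentages <- function(minima_old, minima_revised) {
  if (!is.null(names(minima_old)) && !is.null(names(minima_revised))) {
    common <- intersect(names(minima_old), names(minima_revised))
    minima_old <- minima_old[common]
    minima_revised <- minima_revised[common]
  }
  stopifnot(length(minima_old) == length(minima_revised))
  ok <- !is.na(minima_old) & !is.na(minima_revised)
  minima_old <- minima_old[ok]
  minima_revised <- minima_revised[ok]
  if (length(minima_old) < 1L) stop("no complete pairs of minima")
  if (any(minima_old == 0)) stop("zero minima cannot be revised in percent")
  pct <- 100 * (minima_old - minima_revised) / minima_old
  list(
    per_node = data.frame(
      node = if (is.null(names(minima_old))) seq_along(minima_old)
             else names(minima_old),
      old = as.numeric(minima_old), revised = as.numeric(minima_revised),
      percent = as.numeric(pct), row.names = NULL
    ),
    max_abs_percent = max(abs(pct))
  )
}

#' Read a stub estimate table
#'
#' TSV with columns `focal_node`, `target_node`, `mean_age` — posterior
#' mean summaries brought from an external engine, or frozen for tests.
#'
#' @param path file path.
#' @export
read_stub_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("focal_node", "target_node", "mean_age")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  df
}
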