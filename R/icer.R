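# Incremental cost-effectiveness ----------------------------------------------

#' Cost per QALY
#'
#' The incremental cost-effectiveness ratio: incremental cost divided by QALYs
#' gained. Undefined (dominance or no benefit) when QALYs gained is not
#' strictly positive; this is signalled as a classed error
#' (`hipcea_undefined_icer`), never returned as infinity or a sentinel.
#'
#' @param cost incremental cost, GBP.
#' @param qalys QALYs gained, must be > 0.
#' @return exact quotient, GBP/QALY (unrounded; use [round_gbp()] to render).
#' @export
#' @examples
#' round_gbp(cost_per_qaly(1516, 1.5470))  # 980
cost_per_qaly <- function(cost, qalys) {
  check_nonneg(cost, "cost")
  if (!is.numeric(qalys) || length(qalys) != 1L || is.na(qalys) || qalys <= 0) {
    cea_error(
      sprintf("cost per QALY is undefined for non-positive QALYs gained (%s)",
              format(qalys)),
      "hipcea_undefined_icer"
    )
  }
  cost / qalys
}

icer_result <- function(cost, qaly_res, volume, horizon_label, discounted) {
  structure(
    list(
      incremental_cost = cost$total_per_case,
      qalys_gained = qaly_res$qalys_gained,
      cost_per_qaly = cost_per_qaly(cost$total_per_case, qaly_res$qalys_gained),
      volume = volume,
      horizon_label = horizon_label,
      discounted = discounted,
      policy_used = qaly_res$policy_used
    ),
    class = "icer_result"
  )
}

#' @export
print.icer_result <- function(x, ...) {
  cat(sprintf(
    "<icer_result> %s, %s, %d cases/year\n",
    x$horizon_label, if (x$discounted) "discounted" else "undiscounted",
    x$volume
  ))
  cat(sprintf("  incremental cost GBP %s | QALYs gained %.4f | GBP %s per QALY\n",
              formatC(round_gbp(x$incremental_cost), format = "d", big.mark = ","),
              x$qalys_gained,
              formatC(round_gbp(x$cost_per_qaly), format = "d", big.mark = ",")))
  invisible(x)
}

base_case_policies <- function(params) {
  names <- c("ten_year_undiscounted", "ten_year_discounted",
             "lifetime_undiscounted", "lifetime_discounted")
  if (!params$discount$enabled) {
    names <- c("ten_year_undiscounted", "lifetime_undiscounted")
  }
  stats::setNames(lapply(names, default_accrual_policy, params = params), names)
}

#' Base-case ICERs at a given annual volume
#'
#' Computes the four base-case incremental cost-effectiveness ratios (10-year
#' and lifetime horizon, each undiscounted and discounted) using the
#' calibrated default accrual policies. When discounting is disabled in the
#' bundle only the two undiscounted rows are produced.
#'
#' @param params a `model_parameters` bundle.
#' @param volume annual rTHA case volume (default 100, the base case).
#' @return a data frame of class `base_case` with one row per scenario and
#'   columns `horizon`, `discounted`, `incremental_cost`, `qalys_gained`,
#'   `cost_per_qaly` (unrounded) and `cost_per_qaly_gbp` (whole pounds);
#'   the underlying `icer_result` objects are in `attr(, "results")`.
#' @export
#' @examples
#' run_base_case(default_parameters(), 100)
run_base_case <- function(params, volume = 100) {
  stopifnot(inherits(params, "model_parameters"))
  cost <- incremental_cost(params$costs, volume)
  uplift <- params$effect$adjusted_uplift
  policies <- base_case_policies(params)
  results <- lapply(names(policies), function(nm) {
    icer_result(
      cost, qalys_gained(uplift, policies[[nm]]), volume,
      horizon_label = if (startsWith(nm, "ten_year")) "ten_year" else "lifetime",
      discounted = endsWith(nm, "_discounted")
    )
  })
  df <- data.frame(
    horizon = vapply(results, `[[`, "", "horizon_label"),
    discounted = vapply(results, `[[`, NA, "discounted"),
    incremental_cost = vapply(results, `[[`, 0, "incremental_cost"),
    qalys_gained = vapply(results, `[[`, 0, "qalys_gained"),
    cost_per_qaly = vapply(results, `[[`, 0, "cost_per_qaly"),
    stringsAsFactors = FALSE
  )
  df$cost_per_qaly_gbp <- round_gbp(df$cost_per_qaly)
  structure(df, results = results, class = c("base_case", "data.frame"))
}

#' Cost per QALY across a grid of annual volumes
#'
#' The data behind the volume-sensitivity figure: as volume grows the fixed
#' robot rental is shared across more cases, so cost per QALY falls
#' monotonically towards `(consumables + CT) / QALYs`.
#'
#' @param params a `model_parameters` bundle.
#' @param grid integer vector of annual volumes (default 10 to 250 by 10).
#' @param horizon `"ten_year"` or `"lifetime"`.
#' @param discounted logical.
#' @return a data frame of class `volume_sweep` with columns `volume`,
#'   `horizon`, `discounted`, `incremental_cost`, `qalys_gained`,
#'   `cost_per_qaly`.
#' @export
volume_sweep <- function(params, grid = seq(10L, 250L, by = 10L),
                         horizon = c("ten_year", "lifetime"),
                         discounted = FALSE) {
  stopifnot(inherits(params, "model_parameters"))
  horizon <- match.arg(horizon)
  check_flag(discounted, "discounted")
  if (length(grid) < 1L) validation_error("`grid` must be non-empty")
  policy_name <- paste0(horizon, if (discounted) "_discounted" else "_undiscounted")
  q <- qalys_gained(params$effect$adjusted_uplift,
                    default_accrual_policy(policy_name, params))
  rows <- lapply(grid, function(v) {
    cost <- incremental_cost(params$costs, v)
    data.frame(
      volume = as.integer(v), horizon = horizon, discounted = discounted,
      incremental_cost = cost$total_per_case,
      qalys_gained = q$qalys_gained,
      cost_per_qaly = cost_per_qaly(cost$total_per_case, q$qalys_gained),
      stringsAsFactors = FALSE
    )
  })
  structure(do.call(rbind, rows), class = c("volume_sweep", "data.frame"))
}

#' Smallest annual volume at which cost per QALY falls to a threshold
#'
#' Cost per QALY is strictly decreasing in volume, so the crossing is unique;
#' it is bracketed by bisection over integer volumes.
#'
#' @param params a `model_parameters` bundle.
#' @param threshold willingness-to-pay bound, GBP/QALY.
#' @param horizon,discounted scenario selectors as in [volume_sweep()].
#' @param max_volume upper bracket for the search.
#' @return the smallest integer volume with cost per QALY <= threshold, or
#'   `NA_integer_` if the asymptotic (infinite-volume) cost per QALY already
#'   exceeds the threshold.
#' @export
break_even_volume <- function(params, threshold,
                              horizon = c("ten_year", "lifetime"),
                              discounted = FALSE, max_volume = 100000L) {
  horizon <- match.arg(horizon)
  check_positive(threshold, "threshold")
  cpq_at <- function(v) volume_sweep(params, v, horizon, discounted)$cost_per_qaly
  if (cpq_at(max_volume) > threshold) return(NA_integer_)
  lo <- 1L
  if (cpq_at(lo) <= threshold) return(lo)
  hi <- max_volume
  while (hi - lo > 1L) {
    mid <- lo + (hi - lo) %/% 2L
    if (cpq_at(mid) <= threshold) hi <- mid else lo <- mid
  }
  hi
}

#' Lifetime cost per QALY under an alternative uplift
#'
#' Sensitivity analysis replacing the adjusted uplift (e.g. with the smaller
#' 0.017 gain reported by an earlier comparative study) and recomputing the
#' lifetime undiscounted cost per QALY.
#'
#' @param params a `model_parameters` bundle.
#' @param alternative_uplift replacement annual utility gain, must be > 0.
#' @param volume annual case volume (default 100).
#' @return an `icer_result` (lifetime horizon, undiscounted).
#' @export
#' @examples
#' res <- sensitivity_uplift(default_parameters(), 0.017)
#' round_gbp(res$cost_per_qaly)  # 5246
sensitivity_uplift <- function(params, alternative_uplift, volume = 100) {
  stopifnot(inherits(params, "model_parameters"))
  if (!is.numeric(alternative_uplift) || length(alternative_uplift) != 1L ||
      is.na(alternative_uplift) || alternative_uplift <= 0) {
    cea_error("`alternative_uplift` must be > 0 (no benefit: ICER undefined)",
              "hipcea_undefined_icer")
  }
  cost <- incremental_cost(params$costs, volume)
  q <- qalys_gained(alternative_uplift,
                    default_accrual_policy("lifetime_undiscounted", params))
  icer_result(cost, q, volume, "lifetime", discounted = FALSE)
}

#' Threshold and context checks
#'
#' Compares the model's results against published decision thresholds:
#' the incremental per-patient cost against the threshold prices derived from
#' a 50% revision-rate reduction (GBP 1,347) and a 5% quality-of-life
#' improvement (GBP 10,578); the worst base-case cost per QALY against the
#' willingness-to-pay bound (GBP 20,000/QALY); the uplift as a percentage of
#' the mean mTHA improvement; and the lifetime ICERs added to user-supplied
#' published lifetime cost-per-QALY figures for mTHA itself.
#'
#' @param params a `model_parameters` bundle.
#' @param volume annual case volume (default 100).
#' @param published named numeric vector with elements `undiscounted` and
#'   `discounted`: published lifetime cost per QALY of mTHA, GBP/QALY
#'   (defaults 1372 / 3763, the Scottish-tariff estimates).
#' @param cost_thresholds named numeric vector of per-patient cost thresholds.
#' @return an object of class `threshold_checks` (a list; all comparisons use
#'   unrounded values, rendered figures are whole pounds).
#' @export
threshold_checks <- function(params, volume = 100,
                             published = c(undiscounted = 1372,
                                           discounted = 3763),
                             cost_thresholds = c(revision_benefit = 1347,
                                                 qol_benefit = 10578)) {
  stopifnot(inherits(params, "model_parameters"))
  base <- run_base_case(params, volume)
  cost <- base$incremental_cost[1]
  worst_cpq <- max(base$cost_per_qaly)
  life <- base[base$horizon == "lifetime", ]
  combined <- c(
    undiscounted = unname(
      life$cost_per_qaly[!life$discounted] + published[["undiscounted"]]),
    discounted = if (any(life$discounted)) unname(
      life$cost_per_qaly[life$discounted] + published[["discounted"]])
    else NA_real_
  )
  rel_pct <- round_gbp(
    100 * params$effect$adjusted_uplift / params$effect$mtha_mean_change
  )
  structure(
    list(
      volume = volume,
      incremental_cost = cost,
      cost_thresholds = cost_thresholds,
      cost_below_threshold = cost < cost_thresholds,
      wtp_threshold = params$effect$wtp_threshold,
      worst_cost_per_qaly = worst_cpq,
      below_wtp = worst_cpq < params$effect$wtp_threshold,
      relative_improvement_pct = rel_pct,
      published_mtha = published,
      combined_cost_per_qaly = combined
    ),
    class = "threshold_checks"
  )
}

#' @export
print.threshold_checks <- function(x, ...) {
  gbp <- function(v) formatC(round_gbp(v), format = "d", big.mark = ",")
  cat(sprintf("Threshold checks at %d cases/year\n", x$volume))
  cat(sprintf("  Incremental cost per patient: GBP %s\n", gbp(x$incremental_cost)))
  for (nm in names(x$cost_thresholds)) {
    cat(sprintf("    vs %s threshold GBP %s: %s\n", nm,
                gbp(x$cost_thresholds[[nm]]),
                if (x$cost_below_threshold[[nm]]) "below" else "NOT below"))
  }
  cat(sprintf("  Worst base-case cost per QALY: GBP %s (WTP GBP %s): %s\n",
              gbp(x$worst_cost_per_qaly), gbp(x$wtp_threshold),
              if (x$below_wtp) "cost-effective" else "NOT cost-effective"))
  cat(sprintf("  Relative improvement vs mTHA change: %d%%\n",
              as.integer(x$relative_improvement_pct)))
  cat(sprintf("  Combined with published mTHA cost/QALY: GBP %s (undiscounted), GBP %s (discounted)\n",
              gbp(x$combined_cost_per_qaly[["undiscounted"]]),
              if (is.na(x$combined_cost_per_qaly[["discounted"]])) "NA"
              else gbp(x$combined_cost_per_qaly[["discounted"]])))
  invisible(x)
}
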