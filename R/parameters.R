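# Model parameters ------------------------------------------------------------
#
# Every numeric constant of the economic model lives here, in four validated
# S3 records bundled into a `model_parameters` object: the cost schedule, the
# epidemiology (mortality / revision / life expectancy), the discounting
# policy, and the effect parameters (the adjusted EQ-5D uplift and its
# companions). All downstream modules take this bundle; nothing else hard-codes
# a constant.

#' Cost schedule for the incremental costing of rTHA
#'
#' Holds the per-case and fixed costs of robotic arm-assisted THA relative to
#' manual THA, plus revision-episode costs. All amounts in GBP. The robot is
#' costed at its annual rental (12 x 9,600 GBP/month = 115,200 GBP/year,
#' maintenance included), amortised per case by [incremental_cost()].
#'
#' @param robot_annual_rental annual robot rental, GBP/year.
#' @param consumables_per_case robotic consumables per case, GBP.
#' @param ct_scan_per_case preoperative CT scan (three regions), GBP.
#' @param mtha_tariff NHS tariff for a manual THA, GBP. Stored for reference;
#'   it cancels from the incremental analysis and is unused by default.
#' @param revision_cost_aseptic cost of an aseptic revision, GBP.
#' @param revision_cost_septic cost of a septic revision, GBP.
#' @param septic_fraction fraction of revisions that are septic (the remainder
#'   are aseptic).
#' @return an object of class `cost_schedule`.
#' @export
cost_schedule <- function(robot_annual_rental = 115200,
                          consumables_per_case = 278,
                          ct_scan_per_case = 86,
                          mtha_tariff = 6207,
                          revision_cost_aseptic = 11897,
                          revision_cost_septic = 21937,
                          septic_fraction = 0.13) {
  check_nonneg(robot_annual_rental, "robot_annual_rental")
  check_nonneg(consumables_per_case, "consumables_per_case")
  check_nonneg(ct_scan_per_case, "ct_scan_per_case")
  check_nonneg(mtha_tariff, "mtha_tariff")
  check_nonneg(revision_cost_aseptic, "revision_cost_aseptic")
  check_nonneg(revision_cost_septic, "revision_cost_septic")
  check_proportion(septic_fraction, "septic_fraction")
  structure(
    list(
      robot_annual_rental = robot_annual_rental,
      consumables_per_case = consumables_per_case,
      ct_scan_per_case = ct_scan_per_case,
      mtha_tariff = mtha_tariff,
      revision_cost_aseptic = revision_cost_aseptic,
      revision_cost_septic = revision_cost_septic,
      septic_fraction = septic_fraction
    ),
    class = "cost_schedule"
  )
}

#' Epidemiological parameters
#'
#' Mortality, revision and life-expectancy constants for a reference THA
#' population (average age 69). Both annual and 10-year forms of the mortality
#' and revision rates are stored because the model is quoted in both; their
#' consistency (`annual x 10 = ten-year`) is validated here.
#'
#' The 10-year revision rate is the sex-weighted registry rate:
#' `male_fraction * male_10yr_revision + (1 - male_fraction) *
#' female_10yr_revision` (0.40 x 4.28% + 0.60 x 3.63% = 3.89% at defaults),
#' see [weighted_revision_rate()].
#'
#' @param ten_year_mortality,annual_mortality 10-year and per-year mortality
#'   proportions; must satisfy `annual_mortality * 10 == ten_year_mortality`.
#' @param ten_year_revision,annual_revision 10-year and per-year revision
#'   proportions; must satisfy `annual_revision * 10 == ten_year_revision`.
#' @param male_fraction proportion of males in the reference population.
#' @param male_10yr_revision,female_10yr_revision sex-specific 10-year
#'   revision proportions.
#' @param life_expectancy_years mean remaining life expectancy (years) of the
#'   reference 69-year-old patient; must equal the mean of the sex-specific
#'   values.
#' @param male_life_expectancy,female_life_expectancy sex-specific remaining
#'   life expectancies, years.
#' @param reference_age reference patient age, years.
#' @return an object of class `epidemiology_parameters`.
#' @export
epidemiology_parameters <- function(ten_year_mortality = 0.25,
                                    annual_mortality = 0.025,
                                    annual_revision = 0.00389,
                                    ten_year_revision = 0.0389,
                                    male_fraction = 0.40,
                                    male_10yr_revision = 0.0428,
                                    female_10yr_revision = 0.0363,
                                    life_expectancy_years = 17,
                                    male_life_expectancy = 16,
                                    female_life_expectancy = 18,
                                    reference_age = 69) {
  for (nm in c("ten_year_mortality", "annual_mortality", "annual_revision",
               "ten_year_revision", "male_fraction", "male_10yr_revision",
               "female_10yr_revision")) {
    check_proportion(get(nm), nm)
  }
  check_positive(life_expectancy_years, "life_expectancy_years")
  check_positive(male_life_expectancy, "male_life_expectancy")
  check_positive(female_life_expectancy, "female_life_expectancy")
  check_positive(reference_age, "reference_age")

  tol <- 1e-8
  if (abs(annual_mortality * 10 - ten_year_mortality) > tol) {
    validation_error(sprintf(
      "inconsistent mortality rates: annual_mortality x 10 = %s but ten_year_mortality = %s",
      format(annual_mortality * 10), format(ten_year_mortality)
    ))
  }
  if (abs(annual_revision * 10 - ten_year_revision) > tol) {
    validation_error(sprintf(
      "inconsistent revision rates: annual_revision x 10 = %s but ten_year_revision = %s",
      format(annual_revision * 10), format(ten_year_revision)
    ))
  }
  if (abs((male_life_expectancy + female_life_expectancy) / 2 -
          life_expectancy_years) > tol) {
    validation_error(
      "life_expectancy_years must equal the mean of male_life_expectancy and female_life_expectancy"
    )
  }
  structure(
    list(
      ten_year_mortality = ten_year_mortality,
      annual_mortality = annual_mortality,
      annual_revision = annual_revision,
      ten_year_revision = ten_year_revision,
      male_fraction = male_fraction,
      male_10yr_revision = male_10yr_revision,
      female_10yr_revision = female_10yr_revision,
      life_expectancy_years = life_expectancy_years,
      male_life_expectancy = male_life_expectancy,
      female_life_expectancy = female_life_expectancy,
      reference_age = reference_age
    ),
    class = "epidemiology_parameters"
  )
}

#' Discounting policy
#'
#' @param annual_rate annual discount rate applied to future health gain
#'   (default 5%/year), in `[0, 1)`.
#' @param enabled whether discounted results are produced at all.
#' @return an object of class `discount_policy`.
#' @export
discount_policy <- function(annual_rate = 0.05, enabled = TRUE) {
  check_proportion(annual_rate, "annual_rate", upper_open = TRUE)
  check_flag(enabled, "enabled")
  structure(list(annual_rate = annual_rate, enabled = enabled),
            class = "discount_policy")
}

#' Effect parameters
#'
#' @param adjusted_uplift covariate-adjusted extra EQ-5D improvement of rTHA
#'   over mTHA ("uplift"), utility units/year.
#' @param mtha_mean_change mean EQ-5D improvement after mTHA, utility units.
#' @param eq5d_mcid minimal clinically important difference of the EQ-5D.
#' @param eq5d_sd assumed SD of EQ-5D change, used by the power calculation.
#' @param wtp_threshold willingness-to-pay threshold, GBP/QALY (the NICE
#'   20,000 GBP upper bound by default).
#' @return an object of class `effect_parameters`.
#' @export
effect_parameters <- function(adjusted_uplift = 0.091,
                              mtha_mean_change = 0.370,
                              eq5d_mcid = 0.08,
                              eq5d_sd = 0.30,
                              wtp_threshold = 20000) {
  for (nm in c("adjusted_uplift", "mtha_mean_change")) {
    x <- get(nm)
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      validation_error(sprintf("`%s` must be a single finite number", nm))
    }
  }
  check_positive(eq5d_mcid, "eq5d_mcid")
  check_positive(eq5d_sd, "eq5d_sd")
  check_positive(wtp_threshold, "wtp_threshold")
  structure(
    list(
      adjusted_uplift = adjusted_uplift,
      mtha_mean_change = mtha_mean_change,
      eq5d_mcid = eq5d_mcid,
      eq5d_sd = eq5d_sd,
      wtp_threshold = wtp_threshold
    ),
    class = "effect_parameters"
  )
}

# Flat-config plumbing ---------------------------------------------------------

# Canonical flat keys and the bundle component each belongs to.
config_key_map <- function() {
  list(
    costs = c("robot_annual_rental", "consumables_per_case", "ct_scan_per_case",
              "mtha_tariff", "revision_cost_aseptic", "revision_cost_septic",
              "septic_fraction"),
    epi = c("ten_year_mortality", "annual_mortality", "annual_revision",
            "ten_year_revision", "male_fraction", "male_10yr_revision",
            "female_10yr_revision", "life_expectancy_years",
            "male_life_expectancy", "female_life_expectancy", "reference_age"),
    discount = c("discount_rate", "discount_enabled"),
    effect = c("adjusted_uplift", "mtha_mean_change", "eq5d_mcid", "eq5d_sd",
               "wtp_threshold")
  )
}

CONFIG_SCHEMA_VERSION <- "1"

#' Load the full model-parameter bundle
#'
#' Builds a validated `model_parameters` bundle from a flat key-value
#' configuration, filling every omitted key with the base-case default. The
#' configuration may be `NULL` (all defaults), a named list, or the path to a
#' flat JSON document; an optional `schema_version` key is accepted. Unknown
#' keys are rejected by name.
#'
#' Paired rates are kept consistent: if only one of an
#' (annual, ten-year) mortality/revision pair is supplied the other is
#' derived (`ten-year = 10 x annual`); if both are supplied they must agree.
#' `ten_year_revision`, when not supplied, is derived from the sex-specific
#' registry rates via [weighted_revision_rate()]; `life_expectancy_years`,
#' when not supplied, is the mean of the sex-specific values.
#'
#' @param config `NULL`, a named list of flat keys, or a file path to a JSON
#'   config.
#' @return an object of class `model_parameters` with components `costs`,
#'   `epi`, `discount`, `effect` and a `schema_version` string.
#' @seealso [as_config()], [write_parameters()] for the inverse operation.
#' @export
#' @examples
#' p <- load_parameters()
#' p$costs$robot_annual_rental   # 115200
#' p <- load_parameters(list(discount_rate = 0))
load_parameters <- function(config = NULL) {
  cfg <- read_flat_config(config)
  km <- config_key_map()
  known <- c(unlist(km, use.names = FALSE), "schema_version")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    parse_error(sprintf("unknown configuration key(s): %s",
                        paste(sQuote(unknown), collapse = ", ")))
  }
  if (!is.null(cfg$schema_version) &&
      as.character(cfg$schema_version) != CONFIG_SCHEMA_VERSION) {
    parse_error(sprintf("unsupported schema_version %s (expected %s)",
                        sQuote(cfg$schema_version), CONFIG_SCHEMA_VERSION))
  }
  supplied <- names(cfg)

  # epidemiology: merge over defaults, then derive the unsupplied member of
  # each consistent pair from the supplied one.
  epi_defaults <- formals(epidemiology_parameters)
  epi <- lapply(epi_defaults, eval)
  for (k in intersect(supplied, km$epi)) epi[[k]] <- cfg[[k]]

  if ("annual_mortality" %in% supplied && !("ten_year_mortality" %in% supplied)) {
    epi$ten_year_mortality <- epi$annual_mortality * 10
  }
  if ("ten_year_mortality" %in% supplied && !("annual_mortality" %in% supplied)) {
    epi$annual_mortality <- epi$ten_year_mortality / 10
  }
  if (!("ten_year_revision" %in% supplied) &&
      any(c("male_fraction", "male_10yr_revision", "female_10yr_revision")
          %in% supplied)) {
    epi$ten_year_revision <- weighted_revision_rate(
      epi$male_fraction, epi$male_10yr_revision, epi$female_10yr_revision
    )
  }
  if ("ten_year_revision" %in% supplied && !("annual_revision" %in% supplied) ||
      (!("annual_revision" %in% supplied) &&
       !isTRUE(all.equal(epi$annual_revision * 10, epi$ten_year_revision)))) {
    epi$annual_revision <- epi$ten_year_revision / 10
  }
  if ("annual_revision" %in% supplied && !("ten_year_revision" %in% supplied) &&
      !any(c("male_fraction", "male_10yr_revision", "female_10yr_revision")
           %in% supplied)) {
    epi$ten_year_revision <- epi$annual_revision * 10
  }
  if (!("life_expectancy_years" %in% supplied) &&
      any(c("male_life_expectancy", "female_life_expectancy") %in% supplied)) {
    epi$life_expectancy_years <-
      (epi$male_life_expectancy + epi$female_life_expectancy) / 2
  }

  costs_args <- cfg[intersect(supplied, km$costs)]
  effect_args <- cfg[intersect(supplied, km$effect)]
  disc_args <- list()
  if ("discount_rate" %in% supplied) disc_args$annual_rate <- cfg$discount_rate
  if ("discount_enabled" %in% supplied) disc_args$enabled <- cfg$discount_enabled

  structure(
    list(
      costs = do.call(cost_schedule, costs_args),
      epi = do.call(epidemiology_parameters, epi),
      discount = do.call(discount_policy, disc_args),
      effect = do.call(effect_parameters, effect_args),
      schema_version = CONFIG_SCHEMA_VERSION
    ),
    class = "model_parameters"
  )
}

read_flat_config <- function(config) {
  if (is.null(config)) return(list())
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      parse_error(sprintf("configuration file not found: %s", sQuote(config)))
    }
    config <- tryCatch(
      jsonlite::read_json(config, simplifyVector = TRUE),
      error = function(e) parse_error(
        sprintf("could not parse configuration file: %s", conditionMessage(e))
      )
    )
  }
  if (!is.list(config)) parse_error("config must be NULL, a named list, or a file path")
  if (length(config) && (is.null(names(config)) || any(names(config) == ""))) {
    parse_error("all configuration entries must be named")
  }
  # JSON whole numbers arrive as integers; the bundle stores doubles
  lapply(config, function(x) if (is.integer(x)) as.double(x) else x)
}

#' Default (base-case) parameter bundle
#'
#' Shorthand for `load_parameters(NULL)`.
#' @return a `model_parameters` bundle.
#' @export
default_parameters <- function() load_parameters(NULL)

#' Serialise a parameter bundle to a flat configuration
#'
#' @param params a `model_parameters` bundle.
#' @return a named list of flat keys (including `schema_version`) that
#'   [load_parameters()] maps back to an identical bundle.
#' @export
as_config <- function(params) {
  stopifnot(inherits(params, "model_parameters"))
  km <- config_key_map()
  out <- c(
    params$costs[km$costs],
    params$epi[km$epi],
    list(discount_rate = params$discount$annual_rate,
         discount_enabled = params$discount$enabled),
    params$effect[km$effect]
  )
  c(list(schema_version = params$schema_version), out)
}

#' Write a parameter bundle as flat JSON
#'
#' @param params a `model_parameters` bundle.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  jsonlite::write_json(as_config(params), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Sex-weighted 10-year revision rate
#'
#' Registry revision rates are reported by sex; the model uses the mixture
#' rate `male_fraction * male_rate + (1 - male_fraction) * female_rate`
#' (0.40 x 4.28% + 0.60 x 3.63% = 3.89% at defaults).
#'
#' @param male_fraction proportion of males in the population.
#' @param male_rate,female_rate sex-specific 10-year revision proportions.
#' @return the weighted revision proportion.
#' @export
#' @examples
#' weighted_revision_rate(0.40, 0.0428, 0.0363)  # 0.0389
weighted_revision_rate <- function(male_fraction, male_rate, female_rate) {
  check_proportion(male_fraction, "male_fraction")
  check_proportion(male_rate, "male_rate")
  check_proportion(female_rate, "female_rate")
  male_fraction * male_rate + (1 - male_fraction) * female_rate
}

#' @export
print.model_parameters <- function(x, ...) {
  gbp <- function(v) formatC(round_gbp(v), format = "d", big.mark = ",")
  cat("Health economic model parameters (schema ", x$schema_version, ")\n",
      sep = "")
  cat("Utility\n")
  cat(sprintf("  rTHA uplift (EQ-5D/year)            %.3f\n",
              x$effect$adjusted_uplift))
  cat(sprintf("  mTHA mean EQ-5D change              %.3f\n",
              x$effect$mtha_mean_change))
  cat("Mortality\n")
  cat(sprintf("  10-year mortality rate              %.0f%%\n",
              100 * x$epi$ten_year_mortality))
  cat(sprintf("  Remaining life expectancy (age %.0f)  %g years\n",
              x$epi$reference_age, x$epi$life_expectancy_years))
  cat("Financial costs\n")
  cat(sprintf("  Cost of mTHA (NHS tariff)           GBP %s\n",
              gbp(x$costs$mtha_tariff)))
  cat(sprintf("  Robot annual rental                 GBP %s\n",
              gbp(x$costs$robot_annual_rental)))
  cat(sprintf("  Consumables per case                GBP %s\n",
              gbp(x$costs$consumables_per_case)))
  cat(sprintf("  CT scan per case                    GBP %s\n",
              gbp(x$costs$ct_scan_per_case)))
  cat("Rate and cost of revision\n")
  cat(sprintf("  Annual revision rate                %.3f%%\n",
              100 * x$epi$annual_revision))
  cat(sprintf("  Aseptic (%.0f%% of cases)             GBP %s\n",
              100 * (1 - x$costs$septic_fraction),
              gbp(x$costs$revision_cost_aseptic)))
  cat(sprintf("  Septic (%.0f%% of cases)              GBP %s\n",
              100 * x$costs$septic_fraction, gbp(x$costs$revision_cost_septic)))
  cat("Discounting\n")
  cat(sprintf("  Annual rate                         %.0f%% (%s)\n",
              100 * x$discount$annual_rate,
              if (x$discount$enabled) "enabled" else "disabled"))
  invisible(x)
}
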