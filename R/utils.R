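#' @keywords internal
"_PACKAGE"

# Condition helpers -----------------------------------------------------------

cea_error <- function(msg, class) {
  stop(structure(
    class = c(class, "hipcea_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

validation_error <- function(msg) cea_error(msg, "hipcea_validation_error")
parse_error <- function(msg) cea_error(msg, "hipcea_parse_error")

#' Round to whole pounds, half away from zero
#'
#' Monetary values are carried unrounded through every computation; rounding
#' to whole pounds happens only when a figure is reported. Half-up rounding
#' (1431.5 -> 1432) matches how the printed tables of the costing model are
#' rendered, and differs from [base::round()]'s round-half-to-even.
#'
#' @param x numeric vector of amounts in GBP.
#' @return integer-valued numeric vector.
#' @export
#' @examples
#' round_gbp(1431.5)   # 1432
#' round_gbp(980.09)   # 980
round_gbp <- function(x) {
  stopifnot(is.numeric(x))
  sign(x) * floor(abs(x) + 0.5)
}

# Argument checks -------------------------------------------------------------

check_proportion <- function(x, name, upper_open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    validation_error(sprintf("`%s` must be a single non-missing number", name))
  }
  hi_ok <- if (upper_open) x < 1 else x <= 1
  if (x < 0 || !hi_ok) {
    validation_error(sprintf(
      "`%s` must be a proportion in [0, 1%s]; got %s",
      name, if (upper_open) ")" else "", format(x)
    ))
  }
  x
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0) {
    validation_error(sprintf("`%s` must be a single non-negative number", name))
  }
  x
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    validation_error(sprintf("`%s` must be a single positive number", name))
  }
  x
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    validation_error(sprintf("`%s` must be TRUE or FALSE", name))
  }
  x
}

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Truncated normal ------------------------------------------------------------
# Small, exact primitives used by the cohort generator: inverse-CDF sampling
# and the closed-form mean of N(mean, sd) truncated to [lower, upper].

rtnorm <- function(n, mean, sd, lower, upper) {
  stopifnot(sd >= 0, lower <= upper)
  if (sd == 0) {
    if (mean < lower || mean > upper) {
      validation_error("degenerate truncated normal: mean outside [lower, upper]")
    }
    return(rep(mean, n))
  }
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n, plo, phi)
  pmin(pmax(stats::qnorm(u, mean, sd), lower), upper)
}

etnorm <- function(mean, sd, lower, upper) {
  if (sd == 0) return(mean)
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  mean + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}
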