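#' Epidemiological parameters of the disorder
#'
#' Validates and bundles the two population constants every persistence
#' computation depends on: the prevalence `p` of the disorder and the
#' selection coefficient `s` (one minus the mean relative reproductive
#' fitness of affected individuals). The defaults are the cohort-derived
#' estimates for schizophrenia, `p = 1.29e-2` and `s = 6.54e-1`.
#'
#' @param p Prevalence, a proportion strictly inside (0, 1).
#' @param s Selection coefficient, in (0, 1]. `s = 1` means affected
#'   individuals leave no offspring.
#'
#' @return A list of class `"pop_params"` with elements `p` and `s`.
#' @examples
#' pop_params()
#' pop_params(p = 0.007, s = 0.5)
#' @export
pop_params <- function(p = 1.29e-2, s = 6.54e-1) {
  stopifnot(is.numeric(p), length(p) == 1, is.numeric(s), length(s) == 1)
  if (!(p > 0 && p < 1)) {
    stop("`p` must lie strictly inside (0, 1), got ", p, call. = FALSE)
  }
  if (!(s > 0 && s <= 1)) {
    stop("`s` must lie in (0, 1], got ", s, call. = FALSE)
  }
  if (s * p >= 1) {
    stop("`s * p` must be < 1 for the balance equations to be defined",
         call. = FALSE)
  }
  structure(list(p = p, s = s), class = "pop_params")
}

#' @export
print.pop_params <- function(x, ...) {
  cat("<pop_params> p =", format(x$p), " s =", format(x$s), "\n")
  invisible(x)
}

#' Per-locus mutation-rate presets
#'
#' Nuclear per-locus per-generation mutation rates span roughly 1e-6 to
#' 1e-4; scaling the canonical 1e-4 upper bound by the observed mean
#' parental age (~29.6 years against a 20-year generation) gives the
#' working upper bound 1.48e-4. The three presets used throughout are the
#' average (1.48e-5), highest (1.48e-4) and a relatively low (1.48e-6)
#' rate.
#'
#' @return A named numeric vector with elements `average`, `highest`, `low`.
#' @examples
#' mu_presets()
#' mu_presets()[["highest"]]
#' @export
mu_presets <- function() {
  c(average = 1.48e-5, highest = 1.48e-4, low = 1.48e-6)
}

#' Upper bound on the per-locus mutation rate from parental age
#'
#' Mutation rates rise roughly linearly with parental age, so a base rate
#' quoted per generation-equivalent of parental age scales by
#' `mean_parental_age / generation_years`.
#'
#' @param mean_parental_age Mean parental age in years (e.g. 29.6).
#' @param generation_years Years per generation; default 20.
#' @param base_rate Per-locus per-generation rate at one
#'   generation-equivalent of parental age; default `1e-4`, the canonical
#'   upper bound for autosomes and the X chromosome.
#'
#' @return The scaled rate, `mean_parental_age / generation_years * base_rate`.
#' @examples
#' mu_upper_bound(29.6) # 1.48e-4
#' @export
mu_upper_bound <- function(mean_parental_age, generation_years = 20,
                           base_rate = 1e-4) {
  stopifnot(is.numeric(mean_parental_age), is.numeric(generation_years),
            is.numeric(base_rate))
  if (any(mean_parental_age <= 0) || any(generation_years <= 0) ||
      any(base_rate <= 0)) {
    stop("all inputs to mu_upper_bound() must be positive", call. = FALSE)
  }
  mean_parental_age / generation_years * base_rate
}

#' Persistence threshold for a susceptibility allele
#'
#' Under mutation-selection balance without heterozygote advantage, a
#' nuclear susceptibility allele for a disorder of prevalence `p` and
#' selection coefficient `s` can only be sustained if its case-control
#' allele-frequency difference `d = mA - mU` satisfies `0 < d < nu`, where
#'
#'   `nu = (1 - s * p) * mu / ((1 - p) * s * p)`
#'
#' and `mu` is the per-locus per-generation mutation rate. `nu` is carried
#' at full floating precision; classification must never use a rounded
#' value (a catalog row with d = 0.0176 meets the criterion only because
#' `nu` at the highest mutation rate is 0.017622, not 0.0176).
#'
#' @param mu Mutation rate in (0, 1), or the name of a preset from
#'   [mu_presets()] (`"average"`, `"highest"`, `"low"`).
#' @param params A [pop_params()] object (defaults to the packaged
#'   estimates).
#'
#' @return An object of class `"persistence_threshold"`: a list with
#'   elements `nu`, `mu`, `p`, `s`. `tidy()` and `glance()` methods return
#'   tibbles.
#' @examples
#' persistence_threshold("average")   # nu ~ 1.76e-3
#' persistence_threshold(1.48e-4)     # nu ~ 1.76e-2
#' @export
persistence_threshold <- function(mu, params = pop_params()) {
  if (is.character(mu)) {
    mu <- rlang::arg_match(mu, names(mu_presets()))
    mu <- mu_presets()[[mu]]
  }
  stopifnot(is.numeric(mu), length(mu) == 1)
  if (!(mu > 0 && mu < 1)) {
    stop("`mu` must lie strictly inside (0, 1), got ", mu, call. = FALSE)
  }
  if (!inherits(params, "pop_params")) {
    params <- do.call(pop_params, as.list(params))
  }
  p <- params$p
  s <- params$s
  nu <- (1 - s * p) * mu / ((1 - p) * s * p)
  structure(list(nu = nu, mu = mu, p = p, s = s),
            class = "persistence_threshold")
}

#' @export
print.persistence_threshold <- function(x, ...) {
  cat("<persistence_threshold>\n")
  cat("  nu =", format(signif(x$nu, 3)),
      sprintf("(full precision %.10g)\n", x$nu))
  cat("  p  =", format(x$p), " s =", format(x$s), " mu =", format(x$mu), "\n")
  invisible(x)
}

#' @rdname persistence_threshold
#' @param x A `persistence_threshold` object.
#' @param ... Unused.
#' @method tidy persistence_threshold
#' @export
tidy.persistence_threshold <- function(x, ...) {
  tibble::tibble(
    term = c("nu", "p", "s", "mu"),
    estimate = c(x$nu, x$p, x$s, x$mu)
  )
}

#' @rdname persistence_threshold
#' @method glance persistence_threshold
#' @export
glance.persistence_threshold <- function(x, ...) {
  tibble::tibble(nu = x$nu, p = x$p, s = x$s, mu = x$mu)
}

# accept either a threshold object or a bare positive number wherever a
# nu is needed
nu_value <- function(threshold) {
  if (inherits(threshold, "persistence_threshold")) {
    return(threshold$nu)
  }
  stopifnot(is.numeric(threshold), length(threshold) == 1)
  if (threshold <= 0) stop("`nu` must be positive", call. = FALSE)
  threshold
}

#' Expected number of affected individuals worldwide
#'
#' @param world_population Total population size.
#' @param prevalence Proportion affected.
#' @param digits Significant digits for the reported value (default 2,
#'   matching the headline style of such estimates).
#'
#' @return `signif(world_population * prevalence, digits)`.
#' @examples
#' expected_affected_total(7e9, 0.007) # ~4.9e7
#' @export
expected_affected_total <- function(world_population, prevalence, digits = 2) {
  stopifnot(is.numeric(world_population), is.numeric(prevalence))
  if (any(world_population <= 0) || any(prevalence <= 0)) {
    stop("inputs must be positive", call. = FALSE)
  }
  signif(world_population * prevalence, digits)
}
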