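#' Upper-tail standard-normal quantile
#'
#' Returns `z` with `P(Z > z) = upper_tail_prob`. This is the convention
#' association-study sample-size formulas are written in: the two-sided
#' genome-wide significance term is `normal_quantile(alpha / 2)` and the
#' power term is `normal_quantile(1 - power)`. Accurate to well below
#' 1e-9 across the far tails (the 5.16 deviate at alpha/2 = 1.25e-7 is
#' load-bearing).
#'
#' @param upper_tail_prob Probability strictly inside (0, 1).
#' @return The upper-tail deviate.
#' @examples
#' normal_quantile(0.5)  # 0
#' normal_quantile(0.2)  # 0.8416
#' @export
normal_quantile <- function(upper_tail_prob) {
  stopifnot(is.numeric(upper_tail_prob))
  if (any(upper_tail_prob <= 0 | upper_tail_prob >= 1)) {
    stop("`upper_tail_prob` must lie strictly inside (0, 1)", call. = FALSE)
  }
  qnorm(upper_tail_prob, lower.tail = FALSE)
}

z_alpha_two_sided <- function(alpha) normal_quantile(alpha / 2)
z_beta <- function(power) normal_quantile(1 - power)

#' Standard-deviation factor of the allelic difference test
#'
#' `gamma^2 = mA(1-mA) + mU(1-mU) = 2x(1-x) - d^2/2`, with
#' `x = (mA + mU)/2`. For differences of the size the persistence
#' criterion allows, dropping the `d^2/2` term changes gamma by less than
#' 0.2%, which is why the collapsed sample-size formula uses
#' `sqrt(2x(1-x))`.
#'
#' @param x Population frequency of the allele, `(mA + mU)/2`.
#' @param d Case-control frequency difference.
#' @param approximate If `TRUE` return the approximate form
#'   `sqrt(2x(1-x))`.
#' @return Numeric vector.
#' @examples
#' gamma_factor(0.5, 0)            # sqrt(0.5)
#' gamma_factor(0.5, 1.76e-3, approximate = TRUE)
#' @export
gamma_factor <- function(x, d, approximate = FALSE) {
  stopifnot(is.numeric(x), is.numeric(d))
  if (approximate) {
    return(sqrt(2 * x * (1 - x)))
  }
  g2 <- 2 * x * (1 - x) - d^2 / 2
  if (any(g2 <= 0 & d != 0)) {
    stop("d^2/2 >= 2x(1-x): gamma is not defined for this design",
         call. = FALSE)
  }
  sqrt(pmax(g2, 0))
}

#' Required case-control pairs for an allelic association test
#'
#' The number of case-control pairs `N` needed to detect a risk-allele
#' frequency difference `d` at two-sided level `alpha` with the given
#' power, for an allele of population frequency `x`. The default
#' (`form = "collapsed"`) is
#'
#'   `N = (z_{alpha/2} + z_beta)^2 * x * (1 - x) / d^2`,
#'
#' the form obtained after the gamma approximation (see
#' [gamma_factor()]); `form = "split"` keeps the exact gamma in the power
#' term, `N = ((z_{alpha/2} * sqrt(2x(1-x)) + z_beta * gamma)^2) / (2 d^2)`.
#' The two agree to within the 0.2% approximation bound for criterion-scale
#' d. `N` is maximized over `x` at `x = 0.5`, the worst-case frequency used
#' for headline bounds.
#'
#' @param d Difference to detect (> 0).
#' @param alpha Two-sided type-I error rate; default `2.5e-7`, a
#'   genome-wide significance level.
#' @param power Target power `1 - beta`; default 0.8.
#' @param x Population allele frequency; default the worst case 0.5.
#' @param form `"collapsed"` (default) or `"split"`.
#'
#' @return A one-row tibble with `n_pairs` (real-valued), `n_pairs_2sf`
#'   (rounded to two significant figures, the presentation value),
#'   `z_alpha`, `z_beta` and the design parameters.
#' @examples
#' nu <- persistence_threshold("highest")
#' required_pairs(nu$nu)        # ~29,000 pairs
#' required_pairs(persistence_threshold("average")$nu) # ~2.9 million
#' @export
required_pairs <- function(d, alpha = 2.5e-7, power = 0.8, x = 0.5,
                           form = c("collapsed", "split")) {
  form <- rlang::arg_match(form)
  if (inherits(d, "persistence_threshold")) d <- d$nu
  stopifnot(is.numeric(d), length(d) == 1)
  if (d <= 0) stop("`d` must be positive", call. = FALSE)
  if (!(alpha > 0 && alpha < 1)) stop("`alpha` must be in (0, 1)",
                                      call. = FALSE)
  if (!(power > 0 && power < 1)) stop("`power` must be in (0, 1)",
                                      call. = FALSE)
  if (!(x > 0 && x < 1)) stop("`x` must be in (0, 1)", call. = FALSE)
  za <- z_alpha_two_sided(alpha)
  zb <- z_beta(power)
  n <- if (form == "collapsed") {
    (za + zb)^2 * x * (1 - x) / d^2
  } else {
    (za * sqrt(2 * x * (1 - x)) + zb * gamma_factor(x, d))^2 / (2 * d^2)
  }
  tibble::tibble(
    n_pairs = n, n_pairs_2sf = signif(n, 2),
    z_alpha = za, z_beta = zb,
    alpha = alpha, power = power, x = x, d = d, form = form
  )
}

#' Minimum detectable difference at a given sample size
#'
#' Inverse of [required_pairs()] (collapsed form):
#' `d = (z_{alpha/2} + z_beta) * sqrt(x(1-x)/N)`.
#'
#' @param n_pairs Number of case-control pairs (> 0).
#' @inheritParams required_pairs
#' @return The minimum detectable `d`.
#' @examples
#' min_detectable_d(2.9e6)  # ~1.76e-3
#' @export
min_detectable_d <- function(n_pairs, alpha = 2.5e-7, power = 0.8, x = 0.5) {
  stopifnot(is.numeric(n_pairs))
  if (any(n_pairs <= 0)) stop("`n_pairs` must be positive", call. = FALSE)
  (z_alpha_two_sided(alpha) + z_beta(power)) * sqrt(x * (1 - x) / n_pairs)
}

#' Analytic power of the allelic test at a given sample size
#'
#' Normal-approximation power of the two-sided allelic test:
#' `power = Phi(d * sqrt(N / (x(1-x))) - z_{alpha/2})`. Round-trips with
#' [required_pairs()].
#'
#' @inheritParams min_detectable_d
#' @param d True frequency difference.
#' @return Power in (0, 1).
#' @examples
#' analytic_power(660, alpha = 0.05, x = 0.3, d = 0.05) # ~0.8
#' @export
analytic_power <- function(n_pairs, alpha = 2.5e-7, x = 0.5, d) {
  stopifnot(n_pairs > 0, d >= 0)
  pnorm(d * sqrt(n_pairs / (x * (1 - x))) - z_alpha_two_sided(alpha))
}
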