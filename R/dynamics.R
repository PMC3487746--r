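#' Allele-frequency state of the nuclear model
#'
#' One generation's state: risk-allele frequency in the affected (`mA`),
#' unaffected (`mU`) and general (`mG`) population, where
#' `mG = p * mA + (1 - p) * mU` by construction (frequency conservation),
#' together with the prevalence `p` and a generation counter.
#'
#' @param mA,mU Allele frequencies in affected / unaffected individuals.
#' @param p Disease prevalence.
#' @param generation Integer generation index.
#' @return A list of class `"ngm_state"` with fields `mA`, `mU`, `mG`,
#'   `d`, `p`, `generation`.
#' @examples
#' ngm_state(0.1, 0.08, p = 0.0129)
#' @export
ngm_state <- function(mA, mU, p, generation = 0L) {
  stopifnot(mA >= 0, mA <= 1, mU >= 0, mU <= 1, p > 0, p < 1)
  structure(list(
    mA = mA, mU = mU, mG = p * mA + (1 - p) * mU,
    d = mA - mU, p = p, generation = as.integer(generation)
  ), class = "ngm_state")
}

#' @export
print.ngm_state <- function(x, ...) {
  cat(sprintf("<ngm_state> gen %d: mA = %.6g, mU = %.6g, mG = %.6g (d = %.6g)\n",
              x$generation, x$mA, x$mU, x$mG, x$d))
  invisible(x)
}

#' One generation of selection on a risk allele
#'
#' Negative selection of strength `sM` acting on affected carriers moves
#' the population frequency to
#'
#'   `mG' = (mG - sM * p * mA) / (1 - sM * p)`.
#'
#' The case-control gap is carried forward under a
#' constant-proportional-effect model (`d' = d * mG'/mG`, i.e. a fixed
#' per-copy contribution to liability), and `mA'`, `mU'` are
#' reconstructed from `(mG', d', p)` so that frequency conservation holds
#' exactly at every generation.
#'
#' @param state An [ngm_state()].
#' @param sM Selection coefficient in the affected subpopulation carrying
#'   the allele, in `[0, 1)` with `sM * p < 1`.
#' @return The next [ngm_state()], generation incremented.
#' @examples
#' st <- ngm_state(0.1, 0.08, p = 0.0129)
#' next_generation_freq(st, sM = 0.654)
#' @export
next_generation_freq <- function(state, sM) {
  stopifnot(inherits(state, "ngm_state"), sM >= 0, sM < 1)
  p <- state$p
  if (sM * p >= 1) stop("sM * p must be < 1", call. = FALSE)
  mG_new <- (state$mG - sM * p * state$mA) / (1 - sM * p)
  d_new <- if (state$mG > 0) state$d * mG_new / state$mG else 0
  mA_new <- mG_new + (1 - p) * d_new
  mU_new <- mG_new - p * d_new
  ngm_state(mA_new, mU_new, p, state$generation + 1L)
}

#' Per-generation allele loss to selection
#'
#' The reduction of the population frequency per generation,
#' `-dmG = p * (1 - p) * d * sM / (1 - sM * p)`. Strictly increasing in
#' `sM` for fixed `d > 0`; at `d = nu` and `sM = s` the loss equals the
#' mutation rate `mu` exactly — that identity is the persistence
#' criterion.
#'
#' @param p Prevalence.
#' @param d Case-control frequency difference.
#' @param sM Selection coefficient among affected carriers.
#' @return The per-generation loss.
#' @examples
#' th <- persistence_threshold("average")
#' loss_per_generation(th$p, th$nu, th$s) # equals mu = 1.48e-5
#' @export
loss_per_generation <- function(p, d, sM) {
  stopifnot(p > 0, p < 1, sM >= 0, sM < 1)
  if (any(sM * p >= 1)) stop("sM * p must be < 1", call. = FALSE)
  p * (1 - p) * d * sM / (1 - sM * p)
}

#' Iterate the nuclear recurrence to mutation-selection balance
#'
#' Alternates the selection step of [next_generation_freq()] with uniform
#' mutational replenishment of the population frequency (`mG <- mG + mu`
#' per generation) and runs until the case-control gap stabilizes. Under
#' the constant-proportional-effect closure (`d = c * mG` with `c` fixed
#' by the initial state) the recurrence is linear and its fixed point is
#' the `d` at which the selective loss equals `mu` — i.e. the persistence
#' threshold `nu`, independent of the initial state.
#'
#' Convergence is declared when the estimated distance to the fixed point
#' (`|delta d|` divided by the contraction rate of the linear map) falls
#' below `tol`; non-convergence within `max_gen` is reported via the
#' `converged` flag, not an error.
#'
#' @param p,s Prevalence and selection coefficient.
#' @param mu Per-generation mutational replenishment (may be 0).
#' @param init An [ngm_state()] giving the starting frequencies; defaults
#'   to `ngm_state(mA = 2 * nu-scale guess, ...)` is not attempted — an
#'   explicit state is required.
#' @param tol Absolute tolerance on the estimated distance of `d` from
#'   the fixed point; default `1e-10`.
#' @param max_gen Maximum generations; default `1e6`.
#' @param record If `TRUE` (default) keep the full trajectory.
#' @return A list of class `"ngm_equilibrium"`: `equilibrium_d`,
#'   `converged`, `generations`, and (if recorded) `trajectory`, a tibble
#'   with columns `generation`, `mG`, `mA`, `mU`, `d`.
#' @examples
#' eq <- iterate_ngm(p = 1.29e-2, s = 0.654, mu = 1.48e-5,
#'                   init = ngm_state(0.05, 0.04, p = 1.29e-2))
#' eq$equilibrium_d # ~1.76e-3
#' @export
iterate_ngm <- function(p, s, mu, init, tol = 1e-10, max_gen = 1e6,
                        record = TRUE) {
  stopifnot(inherits(init, "ngm_state"), tol > 0, mu >= 0,
            s > 0, s < 1 || s == 1)
  if (s * p >= 1) stop("s * p must be < 1", call. = FALSE)
  if (init$mG <= 0 || init$d <= 0) {
    stop("`init` must have positive mG and positive d", call. = FALSE)
  }
  c_eff <- init$d / init$mG # fixed per-copy effect
  lambda <- p * (1 - p) * c_eff * s / (1 - s * p) # contraction rate
  mG <- init$mG
  n_alloc <- 4096L
  traj_mG <- numeric(n_alloc)
  gen <- 0L
  converged <- FALSE
  repeat {
    gen <- gen + 1L
    d <- c_eff * mG
    mG_new <- mG - loss_per_generation(p, d, s) + mu
    if (record) {
      if (gen > n_alloc) {
        n_alloc <- n_alloc * 2L
        traj_mG <- c(traj_mG, numeric(n_alloc / 2L))
      }
      traj_mG[gen] <- mG_new
    }
    delta_d <- c_eff * (mG_new - mG)
    mG <- mG_new
    if (abs(delta_d) / lambda < tol) {
      converged <- TRUE
      break
    }
    if (gen >= max_gen) break
  }
  d_final <- c_eff * mG
  out <- list(
    equilibrium_d = d_final,
    converged = converged,
    generations = gen,
    p = p, s = s, mu = mu
  )
  if (record) {
    mG_seq <- c(init$mG, traj_mG[seq_len(gen)])
    d_seq <- c_eff * mG_seq
    out$trajectory <- tibble::tibble(
      generation = 0:gen,
      mG = mG_seq,
      mA = mG_seq + (1 - p) * d_seq,
      mU = mG_seq - p * d_seq,
      d = d_seq
    )
  }
  structure(out, class = "ngm_equilibrium")
}

#' @export
print.ngm_equilibrium <- function(x, ...) {
  cat("<ngm_equilibrium>", if (x$converged) "converged" else "NOT converged",
      "after", x$generations, "generations\n")
  cat("  equilibrium d =", format(x$equilibrium_d, digits = 8),
      " (nu =", format((1 - x$s * x$p) * x$mu / ((1 - x$p) * x$s * x$p),
                       digits = 8), ")\n")
  invisible(x)
}

#' @rdname iterate_ngm
#' @param object An `ngm_equilibrium` object.
#' @param ... Unused.
#' @method autoplot ngm_equilibrium
#' @export
autoplot.ngm_equilibrium <- function(object, ...) {
  stopifnot(!is.null(object$trajectory))
  ggplot2::ggplot(object$trajectory,
                  ggplot2::aes(x = .data$generation, y = .data$d)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$equilibrium_d,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "generation", y = "case-control difference d",
                  title = "Approach to mutation-selection balance") +
    ggplot2::theme_minimal()
}

#' One generation of the maternal-lineage carrier model
#'
#' Two-class model of females carrying pathogenic mitochondrial DNA: a
#' carrier is affected with probability `penetrance` (relative fitness
#' `fitness_affected_female`) or an unaffected carrier (relative fitness
#' `fitness_unaffected_carrier_female`; non-carrier females have fitness
#' 1). Because transmission is exclusively maternal, elevated fitness of
#' unaffected carrier females (heterozygote advantage) directly offsets
#' the selective loss from affected carriers. After selection, de novo
#' pathogenic mutation converts non-carriers at rate `de_novo_rate`:
#'
#'   `f' = f * w_c / w_bar + de_novo_rate * (1 - f)`,
#'
#' with `w_c = penetrance * w_aff + (1 - penetrance) * w_unaff` and
#' `w_bar = f * w_c + (1 - f)` the mean female fitness.
#'
#' Defaults: affected-female fitness 0.45 and unaffected-carrier fitness
#' 1.05 (midpoints of the cohort-reported ranges 0.4-0.5 and 1.02-1.08),
#' de novo rate 4.3e-3 (the average reported per-locus mitochondrial
#' rate), and penetrance 0.5 so that with a carrier frequency of 1.4% the
#' affected fraction matches a 0.7% prevalence.
#'
#' @param carrier_freq Proportion of females carrying pathogenic mtDNA.
#' @param penetrance Probability a carrier is affected.
#' @param fitness_affected_female,fitness_unaffected_carrier_female
#'   Relative fitness values (non-carrier female = 1).
#' @param de_novo_rate Per-generation rate of new pathogenic mtDNA.
#' @return A list with `carrier_freq` (next generation) and `delta` (the
#'   per-generation change).
#' @examples
#' mgm_carrier_step(0.014)
#' @export
mgm_carrier_step <- function(carrier_freq,
                             penetrance = 0.5,
                             fitness_affected_female = 0.45,
                             fitness_unaffected_carrier_female = 1.05,
                             de_novo_rate = 4.3e-3) {
  stopifnot(carrier_freq >= 0, carrier_freq <= 1,
            penetrance >= 0, penetrance <= 1,
            fitness_affected_female >= 0,
            fitness_unaffected_carrier_female >= 0,
            de_novo_rate >= 0, de_novo_rate <= 1)
  w_c <- penetrance * fitness_affected_female +
    (1 - penetrance) * fitness_unaffected_carrier_female
  w_bar <- carrier_freq * w_c + (1 - carrier_freq)
  if (w_bar <= 0) stop("mean female fitness is zero", call. = FALSE)
  f_new <- carrier_freq * w_c / w_bar + de_novo_rate * (1 - carrier_freq)
  list(carrier_freq = f_new, delta = f_new - carrier_freq)
}

#' De novo rate that balances the maternal-lineage carrier model
#'
#' The per-generation de novo mutation rate at which the carrier
#' frequency is exactly stationary: the selective loss divided by the
#' non-carrier fraction it acts on.
#'
#' @inheritParams mgm_carrier_step
#' @return The balancing `de_novo_rate`.
#' @examples
#' r <- mgm_equilibrium_de_novo(0.014)
#' mgm_carrier_step(0.014, de_novo_rate = r)$delta # ~0
#' @export
mgm_equilibrium_de_novo <- function(carrier_freq,
                                    penetrance = 0.5,
                                    fitness_affected_female = 0.45,
                                    fitness_unaffected_carrier_female = 1.05) {
  sel <- mgm_carrier_step(carrier_freq, penetrance,
                          fitness_affected_female,
                          fitness_unaffected_carrier_female,
                          de_novo_rate = 0)
  if (carrier_freq >= 1) stop("carrier_freq must be < 1", call. = FALSE)
  (carrier_freq - sel$carrier_freq) / (1 - carrier_freq)
}

#' Simulate the maternal-lineage carrier model
#'
#' Runs [mgm_carrier_step()] forward. The default deterministic mode
#' iterates expectations; the optional stochastic mode draws the number
#' of carrier daughters binomially each generation among `n_females`
#' females and requires an explicit `seed`.
#'
#' @inheritParams mgm_carrier_step
#' @param generations Number of generations to simulate.
#' @param stochastic Draw binomially instead of iterating expectations.
#' @param n_females Female population size (stochastic mode only).
#' @param seed Integer seed (mandatory in stochastic mode).
#' @return A tibble with columns `generation`, `carrier_freq`, `delta`.
#' @examples
#' simulate_mgm(0.014, generations = 10)
#' @export
simulate_mgm <- function(carrier_freq, generations,
                         penetrance = 0.5,
                         fitness_affected_female = 0.45,
                         fitness_unaffected_carrier_female = 1.05,
                         de_novo_rate = 4.3e-3,
                         stochastic = FALSE, n_females = NULL, seed = NULL) {
  stopifnot(generations >= 1)
  if (stochastic) {
    if (is.null(seed) || is.null(n_females)) {
      stop("stochastic mode requires explicit `seed` and `n_females`",
           call. = FALSE)
    }
    set.seed(as.integer(seed))
  }
  f <- carrier_freq
  out_f <- numeric(generations)
  out_delta <- numeric(generations)
  for (g in seq_len(generations)) {
    step <- mgm_carrier_step(f, penetrance, fitness_affected_female,
                             fitness_unaffected_carrier_female, de_novo_rate)
    f_next <- step$carrier_freq
    if (stochastic) {
      f_next <- rbinom(1, n_females, min(max(f_next, 0), 1)) / n_females
    }
    out_f[g] <- f_next
    out_delta[g] <- f_next - f
    f <- f_next
  }
  tibble::tibble(
    generation = seq_len(generations),
    carrier_freq = out_f,
    delta = out_delta
  )
}

#' Expected fraction of sporadic (de novo) cases
#'
#' If new pathogenic mitochondrial variants arise at `de_novo_rate` per
#' generation and the disorder's prevalence is `prevalence`, the expected
#' proportion of affected individuals who are de novo sporadic cases is
#' their ratio, reported capped at 1.
#'
#' @param de_novo_rate Per-generation de novo mutation rate.
#' @param prevalence Disease prevalence.
#' @return `min(de_novo_rate / prevalence, 1)`.
#' @examples
#' sporadic_fraction(4.3e-3, 7e-3) # ~0.61
#' @export
sporadic_fraction <- function(de_novo_rate, prevalence) {
  stopifnot(is.numeric(de_novo_rate), is.numeric(prevalence))
  if (any(de_novo_rate < 0) || any(prevalence <= 0)) {
    stop("`de_novo_rate` must be >= 0 and `prevalence` > 0", call. = FALSE)
  }
  pmin(de_novo_rate / prevalence, 1)
}

#' Exact binomial test for excess female transmission
#'
#' Upper-tail probability of observing at least `n_via_female`
#' transmissions through females out of `n_transmitting` transmitting
#' parents when each transmission is female with probability `null_prob`
#' (1/2 under autosomal expectation). Exact binomial tail, e.g. 12 of 14
#' discordant-twin transmissions via females gives
#' 106/16384 = 0.00647 < 0.007.
#'
#' @param n_transmitting Number of transmitting parents.
#' @param n_via_female Number transmitting via the female line.
#' @param null_prob Null probability of a female transmission; default 0.5.
#' @return The exact upper-tail probability `P(K >= n_via_female)`.
#' @examples
#' maternal_excess_test(14, 12) # 0.00647
#' @export
maternal_excess_test <- function(n_transmitting, n_via_female,
                                 null_prob = 0.5) {
  stopifnot(n_transmitting >= 0, n_via_female >= 0,
            n_via_female <= n_transmitting,
            null_prob > 0, null_prob < 1)
  pbinom(n_via_female - 1, n_transmitting, null_prob, lower.tail = FALSE)
}
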