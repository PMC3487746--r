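#' Specification for a synthetic variant catalog
#'
#' Describes a catalog with known ground truth, emulating the statistical
#' structure of a curated candidate-gene table: a set of genes scattered
#' over chromosome arms, each contributing one to a few variants whose
#' case-control differences either fall inside the persistence window
#' `(0, nu)`, exceed it, or are non-positive. A chosen fraction of genes
#' is given at least one criterion-meeting variant; the rest get only
#' exceeding or negative differences.
#'
#' @param n_genes Number of genes.
#' @param threshold A [persistence_threshold()] object or bare nu; used
#'   to place the default difference ranges.
#' @param variants_per_gene Length-2 integer range (inclusive) of
#'   variants per gene.
#' @param arm_pool Character vector of chromosome arms genes are placed
#'   on.
#' @param fraction_meeting Fraction of genes given a MEETS variant.
#' @param d_meeting_range Interval strictly inside `(0, nu)` the MEETS
#'   differences are drawn from; default `(0.1, 0.9) * nu`.
#' @param d_exceeding_range Interval at or above nu for EXCEEDS
#'   differences; default `(1.05, 3) * nu`.
#' @param fraction_nonpositive Probability that a non-meeting variant is
#'   drawn with a negative difference instead of an exceeding one.
#' @param freq_range Range the control frequency `mU` is drawn from.
#' @param seed Integer root seed. Per-gene streams are derived as
#'   `(seed + 10007 * gene_index) mod (2^31 - 1)`, so a gene's rows do
#'   not change when other genes are added.
#' @return A list of class `"synthetic_catalog_spec"`.
#' @examples
#' synthetic_catalog_spec(20, persistence_threshold("highest"), seed = 1)
#' @export
synthetic_catalog_spec <- function(n_genes,
                                   threshold,
                                   variants_per_gene = c(1L, 3L),
                                   arm_pool = c("1p", "1q", "2q", "5q", "6p",
                                                "8p", "11p", "11q", "13q",
                                                "16p", "19q", "22q", "Xq"),
                                   fraction_meeting = 0.4,
                                   d_meeting_range = NULL,
                                   d_exceeding_range = NULL,
                                   fraction_nonpositive = 0.1,
                                   freq_range = c(0.1, 0.8),
                                   seed = 1L) {
  nu <- nu_value(threshold)
  if (is.null(d_meeting_range)) d_meeting_range <- c(0.1, 0.9) * nu
  if (is.null(d_exceeding_range)) d_exceeding_range <- c(1.05, 3) * nu
  stopifnot(n_genes >= 1, length(variants_per_gene) == 2,
            variants_per_gene[1] >= 1,
            variants_per_gene[2] >= variants_per_gene[1],
            fraction_meeting >= 0, fraction_meeting <= 1,
            fraction_nonpositive >= 0, fraction_nonpositive <= 1,
            length(freq_range) == 2, freq_range[1] < freq_range[2])
  if (!(d_meeting_range[1] > 0 && d_meeting_range[2] < nu)) {
    stop("`d_meeting_range` must lie strictly inside (0, nu)", call. = FALSE)
  }
  if (d_exceeding_range[1] < nu) {
    stop("`d_exceeding_range` must start at or above nu", call. = FALSE)
  }
  if (freq_range[2] + max(d_exceeding_range) >= 1 ||
      freq_range[1] - max(d_meeting_range) <= 0) {
    stop("infeasible spec: difference ranges exceed the frequency headroom ",
         "left by `freq_range`", call. = FALSE)
  }
  structure(list(
    n_genes = as.integer(n_genes), nu = nu,
    variants_per_gene = as.integer(variants_per_gene),
    arm_pool = arm_pool, fraction_meeting = fraction_meeting,
    d_meeting_range = d_meeting_range,
    d_exceeding_range = d_exceeding_range,
    fraction_nonpositive = fraction_nonpositive,
    freq_range = freq_range, seed = as.integer(seed)
  ), class = "synthetic_catalog_spec")
}

#' Generate a synthetic catalog with known ground truth
#'
#' Draws a catalog according to a [synthetic_catalog_spec()] and emits
#' truth tables alongside it: the intended class of every variant and the
#' implied gene- and arm-level meeting status. By construction the
#' generated frequencies reproduce the truth labels when classified
#' against the spec's nu, which makes the generator a drift guard for the
#' classifier.
#'
#' @param spec A [synthetic_catalog_spec()].
#' @return A list of class `"synthetic_catalog"` with elements `catalog`
#'   (a tibble in the [read_catalog()] schema) and `truth` (a list of
#'   tibbles `variants`, `genes`, `arms`).
#' @examples
#' spec <- synthetic_catalog_spec(10, persistence_threshold("highest"),
#'                                seed = 42)
#' generate_catalog(spec)$catalog
#' @export
generate_catalog <- function(spec) {
  stopifnot(inherits(spec, "synthetic_catalog_spec"))
  n_meeting <- round(spec$fraction_meeting * spec$n_genes)
  gene_rows <- purrr::map(seq_len(spec$n_genes), function(i) {
    set.seed((spec$seed + 10007L * i) %% 2147483647L)
    gene <- sprintf("SYN%03d", i)
    arm <- sample(spec$arm_pool, 1)
    location <- paste0(substr(arm, 1, nchar(arm) - 1),
                       substr(arm, nchar(arm), nchar(arm)),
                       sample(10:39, 1), ".", sample(1:3, 1))
    n_var <- sample(seq(spec$variants_per_gene[1],
                        spec$variants_per_gene[2]), 1)
    meets_gene <- i <= n_meeting
    classes <- character(n_var)
    if (meets_gene) classes[1] <- "MEETS"
    for (j in seq_len(n_var)) {
      if (classes[j] == "") {
        classes[j] <- if (runif(1) < spec$fraction_nonpositive)
          "NONPOSITIVE" else "EXCEEDS"
      }
    }
    d <- vapply(classes, function(cl) {
      switch(cl,
        MEETS = runif(1, spec$d_meeting_range[1], spec$d_meeting_range[2]),
        EXCEEDS = runif(1, spec$d_exceeding_range[1],
                        spec$d_exceeding_range[2]),
        NONPOSITIVE = -runif(1, spec$d_meeting_range[1],
                             spec$d_meeting_range[2])
      )
    }, numeric(1))
    mU <- runif(n_var, spec$freq_range[1], spec$freq_range[2])
    tibble::tibble(
      gene = gene,
      variant_id = sprintf("rs%03d%04d", i, seq_len(n_var)),
      location = location,
      freq_cases = mU + d,
      freq_controls = mU,
      true_class = classes,
      arm_label = arm,
      d_true = d
    )
  })
  rows <- dplyr::bind_rows(gene_rows)
  catalog <- dplyr::select(rows, "gene", "variant_id", "location",
                           "freq_cases", "freq_controls")
  truth_variants <- dplyr::select(rows, "gene", "variant_id", "arm_label",
                                  "d_true", "true_class")
  truth_genes <- truth_variants |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(arm_label = .data$arm_label[1],
                     gene_meets = any(.data$true_class == "MEETS"),
                     n_exceeds = sum(.data$true_class == "EXCEEDS"),
                     .groups = "drop")
  truth_arms <- truth_genes |>
    dplyr::group_by(.data$arm_label) |>
    dplyr::summarise(arm_meets = any(.data$gene_meets), .groups = "drop")
  structure(list(
    catalog = catalog,
    truth = list(variants = truth_variants, genes = truth_genes,
                 arms = truth_arms),
    spec = spec
  ), class = "synthetic_catalog")
}

#' @export
print.synthetic_catalog <- function(x, ...) {
  cat("<synthetic_catalog>", nrow(x$catalog), "variants in",
      x$spec$n_genes, "genes (seed", x$spec$seed, ")\n")
  invisible(x)
}

#' Sample allele counts for a case-control design
#'
#' Binomial allele sampling, two alleles per subject: the risk-allele
#' count in cases is `Binomial(2 * n_pairs, mA)` and in controls
#' `Binomial(2 * n_pairs, mU)`, independently.
#'
#' @param mA,mU Risk-allele frequencies in cases and controls, in (0, 1).
#' @param n_pairs Number of case-control pairs.
#' @param seed Optional integer seed.
#' @return A tibble with one row per group (`case`, `control`) and
#'   columns `risk_count`, `other_count`, `n_alleles`.
#' @examples
#' sample_case_control(0.325, 0.275, n_pairs = 500, seed = 7)
#' @export
sample_case_control <- function(mA, mU, n_pairs, seed = NULL) {
  stopifnot(mA > 0, mA < 1, mU > 0, mU < 1, n_pairs > 0)
  if (!is.null(seed)) set.seed(as.integer(seed))
  n_alleles <- 2L * as.integer(n_pairs)
  k_case <- rbinom(1, n_alleles, mA)
  k_ctrl <- rbinom(1, n_alleles, mU)
  tibble::tibble(
    group = c("case", "control"),
    risk_count = c(k_case, k_ctrl),
    other_count = n_alleles - c(k_case, k_ctrl),
    n_alleles = n_alleles
  )
}

#' Monte-Carlo power of the allelic two-proportion z-test
#'
#' Repeatedly samples case and control risk-allele counts, applies the
#' pooled two-proportion z-test (the test the closed-form sample-size
#' formula implicitly assumes) at two-sided level `alpha`, and reports
#' the rejection fraction with a 95% binomial confidence interval. With
#' `mA == mU` this calibrates the type-I error.
#'
#' @inheritParams sample_case_control
#' @param alpha Two-sided significance level.
#' @param reps Number of replicates (at least 100).
#' @param seed Integer seed.
#' @return A one-row tibble: `power`, `ci_low`, `ci_high`, `reps`,
#'   `n_pairs`, `alpha`, `mA`, `mU`.
#' @examples
#' empirical_power(0.325, 0.275, n_pairs = 660, alpha = 0.05,
#'                 reps = 500, seed = 1)
#' @export
empirical_power <- function(mA, mU, n_pairs, alpha = 0.05, reps = 2000,
                            seed = NULL) {
  stopifnot(mA > 0, mA < 1, mU > 0, mU < 1, n_pairs > 0,
            alpha > 0, alpha < 1, reps >= 100)
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- 2L * as.integer(n_pairs) # alleles per group
  k1 <- rbinom(reps, n, mA)
  k2 <- rbinom(reps, n, mU)
  p1 <- k1 / n
  p2 <- k2 / n
  pbar <- (k1 + k2) / (2 * n)
  se <- sqrt(pbar * (1 - pbar) * 2 / n)
  z <- ifelse(se > 0, (p1 - p2) / se, 0)
  reject <- abs(z) >= qnorm(1 - alpha / 2)
  pw <- mean(reject)
  half <- 1.96 * sqrt(pw * (1 - pw) / reps)
  tibble::tibble(
    power = pw,
    ci_low = max(0, pw - half),
    ci_high = min(1, pw + half),
    reps = reps, n_pairs = n_pairs, alpha = alpha, mA = mA, mU = mU
  )
}
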