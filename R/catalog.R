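required_catalog_cols <- c("gene", "variant_id", "location",
                           "freq_cases", "freq_controls")

check_catalog <- function(catalog) {
  missing <- setdiff(required_catalog_cols, names(catalog))
  if (length(missing) > 0) {
    stop("catalog is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- which(is.na(catalog$freq_cases) | is.na(catalog$freq_controls) |
                 catalog$freq_cases < 0 | catalog$freq_cases > 1 |
                 catalog$freq_controls < 0 | catalog$freq_controls > 1)
  if (length(bad) > 0) {
    stop("invalid or missing allele frequencies in row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  invisible(catalog)
}

#' Read and write case-control variant catalogs
#'
#' A catalog is a delimited text table with one row per variant and
#' columns `gene`, `variant_id`, `location` (cytogenetic band),
#' `freq_cases` (`mA`, the frequency of the risk-marked allele in cases),
#' `freq_controls` (`mU`, the same allele in controls), plus optional
#' `allele_minor`, `allele_major`, `risk_allele`, `n_cases`, `n_controls`,
#' `reported_or` and `printed_d` columns. Frequencies are always oriented
#' to the risk-marked allele as published, even when that allele is the
#' major one.
#'
#' @param path File path. `read_catalog()` infers the delimiter from the
#'   extension (`.tsv` means tab, anything else comma) unless `delim` is
#'   given.
#' @param delim Field delimiter; `NULL` to infer.
#'
#' @return `read_catalog()` returns a tibble, schema-checked; an error
#'   names any missing required column. `write_catalog()` writes at full
#'   precision and returns `path` invisibly, so write/read round trips are
#'   lossless.
#' @examples
#' cat <- read_catalog(pcrit_example_catalog())
#' nrow(cat) # 64
#' @export
read_catalog <- function(path, delim = NULL) {
  if (is.null(delim)) {
    delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  }
  catalog <- readr::read_delim(
    path, delim = delim, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      gene = readr::col_character(),
      variant_id = readr::col_character(),
      location = readr::col_character(),
      .default = readr::col_guess()
    )
  )
  check_catalog(catalog)
  catalog
}

#' @rdname read_catalog
#' @param catalog A catalog tibble.
#' @export
write_catalog <- function(catalog, path, delim = ",") {
  check_catalog(catalog)
  readr::write_delim(catalog, path, delim = delim, na = "")
  invisible(path)
}

#' Packaged variant-catalog fixture
#'
#' Path to the packaged 64-row schizophrenia case-control catalog: the top
#' 45 candidate genes of the SZGene meta-analysis database (December 2011
#' snapshot) with risk-allele frequencies in cases and controls, locations
#' as published (including unconventional entries kept verbatim), the
#' published odds ratio and rounded d, and a `printed_meets` flag marking
#' the rows the source tables highlighted as criterion-meeting.
#'
#' @return A file path.
#' @examples
#' read_catalog(pcrit_example_catalog())
#' @export
pcrit_example_catalog <- function() {
  system.file("extdata", "szgene_top45.csv", package = "pcrit",
              mustWork = TRUE)
}

#' Risk-allele frequency difference
#'
#' `d = mA - mU`, computed from the stored (four-to-five decimal)
#' frequencies at full precision — never from a published rounded d
#' column, since classification at the threshold is sensitive below the
#' rounding step.
#'
#' @param freq_cases,freq_controls Risk-allele frequencies in cases and
#'   controls, each in \[0, 1\].
#' @return Numeric vector of differences.
#' @examples
#' allele_diff(0.3532, 0.3211) # 0.0321
#' @export
allele_diff <- function(freq_cases, freq_controls) {
  if (any(is.na(freq_cases)) || any(is.na(freq_controls))) {
    stop("missing allele frequencies", call. = FALSE)
  }
  stopifnot(all(freq_cases >= 0 & freq_cases <= 1),
            all(freq_controls >= 0 & freq_controls <= 1))
  freq_cases - freq_controls
}

#' Allelic odds ratio from frequencies
#'
#' Diagnostic helper: `(mA/(1-mA)) / (mU/(1-mU))`. Published catalog odds
#' ratios are typically meta-analytic and are not generally reproducible
#' from the pooled frequencies, so this is a sanity check, not a
#' re-derivation.
#'
#' @param mA,mU Frequencies strictly inside (0, 1).
#' @return Numeric vector of odds ratios.
#' @examples
#' odds_ratio_from_freqs(0.03069, 0.01735) # ~1.79
#' @export
odds_ratio_from_freqs <- function(mA, mU) {
  if (any(mA <= 0 | mA >= 1) || any(mU <= 0 | mU >= 1)) {
    stop("frequencies must lie strictly inside (0, 1)", call. = FALSE)
  }
  (mA / (1 - mA)) / (mU / (1 - mU))
}

#' Classify allele-frequency differences against the persistence threshold
#'
#' A variant MEETS the persistence criterion iff `0 < d < nu` strictly;
#' `d >= nu` is EXCEEDS (under mutation-selection balance such an allele
#' must be protective, not causal); `d <= 0` is NONPOSITIVE. A tie
#' `d == nu` classifies EXCEEDS (the criterion is a strict inequality).
#'
#' @param d Numeric vector of frequency differences.
#' @param threshold A [persistence_threshold()] object or a bare positive
#'   number.
#' @return A factor with levels `MEETS`, `EXCEEDS`, `NONPOSITIVE`.
#' @examples
#' nu <- persistence_threshold("highest")
#' classify_d(c(0.0176, 0.0179, -0.0115), nu)
#' @export
classify_d <- function(d, threshold) {
  nu <- nu_value(threshold)
  stopifnot(is.numeric(d), all(is.finite(d)))
  cls <- ifelse(d <= 0, "NONPOSITIVE", ifelse(d < nu, "MEETS", "EXCEEDS"))
  factor(cls, levels = c("MEETS", "EXCEEDS", "NONPOSITIVE"))
}

#' Classify every variant of a catalog
#'
#' Adds the computed difference `d`, its class, and the parsed chromosome
#' arm to a catalog.
#'
#' @param catalog A catalog tibble (see [read_catalog()]).
#' @param threshold A [persistence_threshold()] object or bare nu.
#' @return The catalog with columns `d`, `class`, `chromosome`, `arm`,
#'   `arm_label` appended.
#' @examples
#' read_catalog(pcrit_example_catalog()) |>
#'   classify_catalog(persistence_threshold("highest"))
#' @export
classify_catalog <- function(catalog, threshold) {
  check_catalog(catalog)
  bands <- parse_cytoband(catalog$location)
  catalog |>
    dplyr::mutate(
      d = allele_diff(.data$freq_cases, .data$freq_controls),
      class = classify_d(.data$d, threshold),
      chromosome = bands$chromosome,
      arm = bands$arm,
      arm_label = bands$arm_label
    )
}
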