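#' Summarize a catalog against the persistence criterion
#'
#' Classifies every variant, then rolls up to genes (a gene meets iff at
#' least one of its variants MEETS) and to chromosome arms (an arm meets
#' iff at least one resident gene meets). The headline quantities are the
#' number of MEETS variants, the number of meeting genes ("loci"), and the
#' number of protective loci *outside* the meeting regions: genes with no
#' MEETS variant and at least one EXCEEDS variant that sit on arms where
#' no gene meets. Under a purely nuclear model such protective loci should
#' cluster near susceptibility loci; finding them scattered over arms with
#' no meeting variant is the observation the classifier quantifies.
#'
#' Pseudo-loci (e.g. `GWA_`-named association regions) count as genes in
#' every rollup. A gene must sit on exactly one arm; duplicated-arm input
#' is an error.
#'
#' @param catalog A catalog tibble (see [read_catalog()]). An empty
#'   catalog yields all-zero counts.
#' @param threshold A [persistence_threshold()] object or bare nu.
#'
#' @return An object of class `"catalog_summary"`: a list with tibbles
#'   `variants` (per-variant d and class), `genes` (per-gene rollup),
#'   `arms` (per-arm rollup), `outside` (the protective loci on
#'   non-meeting arms), a `counts` list (`n_variants`,
#'   `n_meeting_variants`, `n_meeting_loci`, `n_protective_loci_outside`)
#'   and the `nu` used. Methods: `print()`, `tidy()` (per-variant table),
#'   `glance()` (one-row counts), `autoplot()`.
#' @examples
#' summary <- read_catalog(pcrit_example_catalog()) |>
#'   summarize_catalog(persistence_threshold("highest"))
#' summary
#' glance(summary)
#' @export
summarize_catalog <- function(catalog, threshold) {
  nu <- nu_value(threshold)
  if (nrow(catalog) == 0) {
    empty <- structure(list(
      variants = tibble::tibble(),
      genes = tibble::tibble(),
      arms = tibble::tibble(),
      outside = tibble::tibble(),
      counts = list(n_variants = 0L, n_meeting_variants = 0L,
                    n_meeting_loci = 0L, n_protective_loci_outside = 0L),
      nu = nu
    ), class = "catalog_summary")
    return(empty)
  }
  variants <- classify_catalog(catalog, threshold)

  genes <- variants |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      # n_arms must be computed before arm_label is overwritten: summarise
      # evaluates sequentially against the updated mask
      n_arms = dplyr::n_distinct(.data$arm_label),
      arm_label = unique(.data$arm_label)[1],
      n_variants = dplyr::n(),
      n_meets = sum(.data$class == "MEETS"),
      n_exceeds = sum(.data$class == "EXCEEDS"),
      gene_meets = any(.data$class == "MEETS"),
      .groups = "drop"
    )
  if (any(genes$n_arms > 1)) {
    stop("gene(s) mapped to more than one chromosome arm: ",
         paste(genes$gene[genes$n_arms > 1], collapse = ", "),
         call. = FALSE)
  }
  genes <- dplyr::select(genes, -"n_arms")

  arms <- genes |>
    dplyr::group_by(.data$arm_label) |>
    dplyr::summarise(
      n_genes = dplyr::n(),
      n_meeting_genes = sum(.data$gene_meets),
      arm_meets = any(.data$gene_meets),
      .groups = "drop"
    )

  outside <- genes |>
    dplyr::left_join(dplyr::select(arms, "arm_label", "arm_meets"),
                     by = "arm_label") |>
    dplyr::filter(!.data$gene_meets, .data$n_exceeds >= 1,
                  !.data$arm_meets) |>
    dplyr::arrange(.data$arm_label, .data$gene)

  counts <- list(
    n_variants = nrow(variants),
    n_meeting_variants = sum(variants$class == "MEETS"),
    n_meeting_loci = sum(genes$gene_meets),
    n_protective_loci_outside = nrow(outside)
  )
  structure(list(variants = variants, genes = genes, arms = arms,
                 outside = outside, counts = counts, nu = nu),
            class = "catalog_summary")
}

#' @export
print.catalog_summary <- function(x, ...) {
  cat("<catalog_summary> nu =", format(signif(x$nu, 3)), "\n")
  cat(sprintf("  %d variants: %d meet the criterion (0 < d < nu) on %d loci\n",
              x$counts$n_variants, x$counts$n_meeting_variants,
              x$counts$n_meeting_loci))
  cat(sprintf("  %d protective loci (d >= nu) on arms with no meeting variant\n",
              x$counts$n_protective_loci_outside))
  if (nrow(x$outside) > 0) {
    by_arm <- split(x$outside$gene, x$outside$arm_label)
    for (arm in names(by_arm)) {
      cat("    ", arm, ": ", paste(by_arm[[arm]], collapse = ", "), "\n",
          sep = "")
    }
  }
  invisible(x)
}

#' @rdname summarize_catalog
#' @param x A `catalog_summary` object.
#' @param ... Unused.
#' @method tidy catalog_summary
#' @export
tidy.catalog_summary <- function(x, ...) {
  x$variants
}

#' @rdname summarize_catalog
#' @method glance catalog_summary
#' @export
glance.catalog_summary <- function(x, ...) {
  tibble::tibble(
    n_variants = x$counts$n_variants,
    n_meeting_variants = x$counts$n_meeting_variants,
    n_meeting_loci = x$counts$n_meeting_loci,
    n_protective_loci_outside = x$counts$n_protective_loci_outside,
    nu = x$nu
  )
}

#' @rdname summarize_catalog
#' @param object A `catalog_summary` object.
#' @method autoplot catalog_summary
#' @export
autoplot.catalog_summary <- function(object, ...) {
  stopifnot(nrow(object$variants) > 0)
  ggplot2::ggplot(object$variants,
                  ggplot2::aes(x = .data$arm_label, y = .data$d,
                               colour = .data$class)) +
    ggplot2::geom_hline(yintercept = c(0, object$nu),
                        linetype = c("solid", "dashed"),
                        colour = "grey40") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = "chromosome arm",
      y = "case-control allele-frequency difference d",
      colour = NULL,
      title = "Variants against the persistence threshold",
      subtitle = sprintf("dashed line: nu = %.3g", object$nu)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
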