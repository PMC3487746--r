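#' Parse cytogenetic band strings
#'
#' Splits location strings such as `"1p36.22"` or `"Xq28"` into chromosome,
#' arm and sub-band. The split happens at the first `p` or `q` after the
#' chromosome label; whatever follows the arm letter is preserved verbatim
#' as `sub_band` (it may be empty). The chromosome label must be 1-22 or X.
#'
#' @param location Character vector of band strings.
#'
#' @return A tibble with columns `location`, `chromosome` (character, "1"
#'   to "22" or "X"), `arm` ("p" or "q"), `sub_band` (character, possibly
#'   "") and `arm_label` (chromosome + arm, e.g. `"1p"` — the unit of
#'   "region" used for co-location rollups).
#' @examples
#' parse_cytoband(c("1p36.22", "10q26.11", "Xq28"))
#' @export
parse_cytoband <- function(location) {
  stopifnot(is.character(location))
  if (any(is.na(location) | location == "")) {
    stop("cytogenetic locations must be non-empty strings", call. = FALSE)
  }
  m <- regexec("^([0-9]{1,2}|X)([pq])(.*)$", location)
  parts <- regmatches(location, m)
  bad <- lengths(parts) != 4
  if (any(bad)) {
    stop("cannot parse cytogenetic location(s): ",
         paste(unique(location[bad]), collapse = ", "), call. = FALSE)
  }
  chrom <- vapply(parts, `[[`, character(1), 2)
  arm <- vapply(parts, `[[`, character(1), 3)
  sub <- vapply(parts, `[[`, character(1), 4)
  num <- suppressWarnings(as.integer(chrom))
  bad_chrom <- chrom != "X" & (is.na(num) | num < 1 | num > 22)
  if (any(bad_chrom)) {
    stop("invalid chromosome label(s): ",
         paste(unique(chrom[bad_chrom]), collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    location = location,
    chromosome = chrom,
    arm = arm,
    sub_band = sub,
    arm_label = paste0(chrom, arm)
  )
}
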