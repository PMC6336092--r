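#' Shannon-Wiener diversity index
#'
#' Computes H' = -sum(p_k log p_k) over species proportions, using the
#' natural logarithm. This is the usual degree-of-diversity indicator for
#' benthic community surveys; species with zero counts contribute nothing.
#'
#' @param counts Non-negative species counts (a numeric vector; names are
#'   ignored).
#' @return H' in nats; 0 for a single-species community, at most
#'   `log(length(counts))` (reached when all species are equally
#'   abundant).
#' @section Errors: An all-zero community raises an error of class
#'   `cei_empty_community`.
#' @export
#' @examples
#' shannon_diversity(c(10, 10, 20))
shannon_diversity <- function(counts) {
  counts <- as.numeric(counts)
  if (any(is.na(counts)) || any(counts < 0)) {
    abort("counts must be non-negative and non-missing",
          class = "cei_indicator_error")
  }
  total <- sum(counts)
  if (total <= 0) {
    abort("EMPTY_COMMUNITY: all counts are zero",
          class = "cei_empty_community")
  }
  p <- counts[counts > 0] / total
  -sum(p * log(p))
}

#' Weighted rare-species count
#'
#' The rare-species indicator: the number of threatened species weighted
#' by endangered-category type, `sum(weight[c] * count[c])`. The category
#' weights are user configuration (typically larger weights for more
#' severe categories, e.g. CR > EN > VU).
#'
#' @param count_by_category Named non-negative counts per category; an
#'   empty vector yields 0.
#' @param weights Named positive weights covering every category present
#'   in the counts; an uncovered category is an error naming it.
#' @return The weighted count.
#' @export
#' @examples
#' weighted_rare_species(c(CR = 1, VU = 2), c(CR = 3, EN = 2, VU = 1))
weighted_rare_species <- function(count_by_category, weights) {
  if (length(count_by_category) == 0) return(0)
  counts <- as.numeric(count_by_category)
  if (is.null(names(count_by_category)) || any(names(count_by_category) == "")) {
    abort("counts must be named by category", class = "cei_indicator_error")
  }
  if (any(is.na(counts)) || any(counts < 0)) {
    abort("counts must be non-negative and non-missing",
          class = "cei_indicator_error")
  }
  missing <- setdiff(names(count_by_category), names(weights))
  if (length(missing) > 0) {
    abort(sprintf("no weight supplied for category '%s'", missing[1]),
          class = "cei_indicator_error")
  }
  w <- as.numeric(weights[names(count_by_category)])
  if (any(is.na(w)) || any(w <= 0)) {
    abort("weights must be positive", class = "cei_indicator_error")
  }
  sum(w * counts)
}
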