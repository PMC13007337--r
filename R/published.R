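#' Published population summaries
#'
#' Reported per-preparation summaries of the surface- and cave-population
#' imaging data sets (16 preparations per population): the mean number of
#' neurons preferring each of the seven odor-panel stimuli, and the mean
#' total classified neurons per preparation (61.4 surface, 73.6 cave, with
#' SEM). Because the preferred-stimulus categories partition each
#' preparation's classified cells, the seven per-category means of a
#' population must sum to its mean total — the internal-consistency check
#' exercised by [check_category_consistency()].
#'
#' @return List with data frames `category_means` (`group`, `stimulus`,
#'   `mean_count`) and `totals` (`group`, `mean_total`, `sem`,
#'   `n_preparations`).
#' @export
published_population_summary <- function() {
  list(
    category_means = utils::read.csv(
      system.file("extdata", "published_category_means.csv",
                  package = "odortrace"), stringsAsFactors = FALSE),
    totals = utils::read.csv(
      system.file("extdata", "published_population_totals.csv",
                  package = "odortrace"), stringsAsFactors = FALSE))
}

#' Category-count internal consistency
#'
#' For each group, sums the per-category mean preferred-neuron counts and
#' compares the sum with the reported mean total neurons per preparation.
#' Since every classified neuron belongs to exactly one category and the
#' mean is linear, the two must agree up to the rounding of the published
#' values.
#'
#' @param category_means Data frame `group`, `stimulus`, `mean_count`
#'   (default: the bundled published table).
#' @param totals Data frame `group`, `mean_total` (default: bundled).
#' @return Data frame per group: `sum_of_category_means`,
#'   `reported_mean_total`, `difference`.
#' @export
check_category_consistency <- function(category_means = NULL, totals = NULL) {
  pub <- published_population_summary()
  if (is.null(category_means)) category_means <- pub$category_means
  if (is.null(totals)) totals <- pub$totals
  sums <- stats::aggregate(mean_count ~ group, category_means, sum)
  out <- merge(sums, totals[c("group", "mean_total")], by = "group")
  names(out) <- c("group", "sum_of_category_means", "reported_mean_total")
  out$difference <- out$sum_of_category_means - out$reported_mean_total
  out <- out[order(out$group, decreasing = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}
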