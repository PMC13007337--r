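#' Odor response magnitude
#'
#' The magnitude of cell i's response to stimulus j is the mean dF/F over
#' the first `n_stim` frames of odor stimulation minus the mean over the
#' `n_pre` frames immediately preceding the stimulus (defaults 30 and 10
#' frames). The value is signed: negative magnitudes are suppressed
#' responses.
#'
#' @param trace A dF/F [trace_matrix()] (trial-averaged) or a numeric
#'   vector for a single cell.
#' @param protocol A [stim_protocol()].
#' @param n_stim Frames of the stimulation window entering the mean.
#' @param n_pre Pre-stimulus frames entering the reference mean.
#' @return Named numeric vector of magnitudes, one per cell.
#' @export
response_magnitude <- function(trace, protocol, n_stim = 30L, n_pre = 10L) {
  m <- if (is.matrix(trace)) unclass(trace) else matrix(trace, nrow = 1)
  on <- onset_frame(protocol)
  if (on + n_stim > ncol(m))
    stop("trial too short: magnitude window [", on, ", ", on + n_stim,
         ") exceeds ", ncol(m), " frames", call. = FALSE)
  pre <- f0_window(protocol, n_pre)
  rowMeans(m[, .win_idx(c(on, on + n_stim)), drop = FALSE]) -
    rowMeans(m[, .win_idx(pre), drop = FALSE])
}

#' Significance of an odor response
#'
#' A response is significant when the peak of the dF/F signal during the
#' stimulus window is at least `threshold` (default 6) standard deviations
#' above the pre-stimulus period. The baseline mean and SD are taken over
#' the full pre-stimulus window `[0, onset)`; `peak_z` is
#' `(max over stimulus frames - baseline mean) / baseline SD`.
#'
#' A zero baseline SD (e.g. a noiseless synthetic trace) is a degenerate
#' baseline and an error: significance is a statement about noise.
#'
#' @inheritParams response_magnitude
#' @param threshold Significance threshold in baseline SD units.
#' @return List with numeric `peak_z` and logical `significant`, each one
#'   entry per cell.
#' @export
is_significant <- function(trace, protocol, threshold = 6) {
  m <- if (is.matrix(trace)) unclass(trace) else matrix(trace, nrow = 1)
  bw <- baseline_window(protocol)
  sw <- stimulus_window(protocol)
  if (bw[2] - bw[1] < 2L)
    stop("baseline window must contain at least 2 frames", call. = FALSE)
  base <- m[, .win_idx(bw), drop = FALSE]
  mu <- rowMeans(base)
  sd_ <- apply(base, 1, stats::sd)
  if (any(sd_ == 0))
    stop("degenerate baseline (SD = 0) for cell(s): ",
         paste(rownames(m)[sd_ == 0], collapse = ", "), call. = FALSE)
  peak <- apply(m[, .win_idx(sw), drop = FALSE], 1, max)
  z <- (peak - mu) / sd_
  list(peak_z = z, significant = z >= threshold)
}

#' Lifetime sparseness
#'
#' Tuning-selectivity index of a cell over its m stimulus responses:
#' `LS = (sum(r) / m)^2 / (sum(r^2) / m)`. Values near `1/m` indicate a
#' cell driven by a single stimulus; 1 indicates identical responses to
#' every stimulus. Negative (suppressed) magnitudes are rectified to 0
#' before the formula — with mixed signs the ratio is not confined to
#' (0, 1] — and a vector that is all-zero after rectification has no
#' defined selectivity and yields `NA`.
#'
#' @param r Numeric vector of m signed response magnitudes (m >= 2).
#' @param rectify Set negative entries to 0 first (default `TRUE`).
#' @return LS in `(0, 1]`, or `NA_real_` when undefined.
#' @examples
#' lifetime_sparseness(c(1, 0, 0, 0, 0, 0, 0))   # 1/7
#' lifetime_sparseness(rep(0.3, 7))              # 1
#' @export
lifetime_sparseness <- function(r, rectify = TRUE) {
  if (length(r) < 2L)
    stop("lifetime sparseness needs at least 2 stimuli", call. = FALSE)
  if (any(!is.finite(r)))
    stop("magnitudes must be finite", call. = FALSE)
  if (rectify) r <- pmax(r, 0)
  if (all(r == 0)) return(NA_real_)
  mean(r)^2 / mean(r^2)
}

#' Preferred stimulus of one cell
#'
#' A cell with at least one significant response is assigned to the
#' stimulus with the largest signed magnitude; cells with no significant
#' response get no preference (`NA`). Exact ties go to the earlier
#' stimulus in protocol order, with a warning.
#'
#' @param magnitudes Named numeric vector of signed magnitudes, ordered by
#'   protocol stimulus order.
#' @param significant Logical vector parallel to `magnitudes`.
#' @return Stimulus label, or `NA_character_`.
#' @export
assign_preference <- function(magnitudes, significant) {
  stopifnot(length(magnitudes) == length(significant))
  if (!any(significant)) return(NA_character_)
  top <- which(magnitudes == max(magnitudes))
  if (length(top) > 1L)
    warning("preference tie between ",
            paste(names(magnitudes)[top], collapse = ", "),
            "; keeping the first in protocol order", call. = FALSE)
  names(magnitudes)[top[1]]
}

#' Per-cell odor response table
#'
#' The central analysis step: from trial-averaged, low-pass filtered dF/F
#' traces (one [trace_matrix()] per stimulus) it computes, for every cell
#' and stimulus, the signed response magnitude and peak z-score, flags
#' significant responses by the `threshold`-SD rule, assigns each cell a
#' preferred stimulus (cells with no significant response stay
#' unclassified) and computes each cell's lifetime sparseness from its
#' rectified magnitudes.
#'
#' @param traces Named list of dF/F (filtered) [trace_matrix()] objects,
#'   one per stimulus of the protocol; names must match the protocol's
#'   stimulus labels.
#' @param protocol A [stim_protocol()].
#' @param threshold Significance threshold in baseline SD units.
#' @param n_stim,n_pre Magnitude windows, see [response_magnitude()].
#' @return Object of class `odor_responses` with matrices `magnitude`,
#'   `peak_z`, `significant` (cells x stimuli) and a per-cell data frame
#'   `cells` (`cell_id`, `preferred`, `ls`).
#' @seealso [sort_population_heatmap()], [category_counts()],
#'   [write_table()]
#' @export
odor_responses <- function(traces, protocol, threshold = 6,
                           n_stim = 30L, n_pre = 10L) {
  stopifnot(inherits(protocol, "stim_protocol"), is.list(traces))
  labs <- protocol$stimulus_labels
  miss <- setdiff(labs, names(traces))
  if (length(miss))
    stop("missing traces for stimulus(es): ", paste(miss, collapse = ", "),
         call. = FALSE)
  traces <- traces[labs]
  ids <- rownames(traces[[1]])
  n <- nrow(traces[[1]])
  mag <- pz <- matrix(NA_real_, n, length(labs), dimnames = list(ids, labs))
  sig <- matrix(NA, n, length(labs), dimnames = list(ids, labs))
  for (lab in labs) {
    tr <- traces[[lab]]
    if (!identical(rownames(tr), ids))
      stop("cell ids differ between stimuli", call. = FALSE)
    mag[, lab] <- response_magnitude(tr, protocol, n_stim, n_pre)
    s <- is_significant(tr, protocol, threshold)
    pz[, lab] <- s$peak_z
    sig[, lab] <- s$significant
  }
  preferred <- vapply(seq_len(n), function(i)
    assign_preference(mag[i, ], sig[i, ]), character(1))
  ls <- vapply(seq_len(n), function(i)
    lifetime_sparseness(mag[i, ]), numeric(1))
  structure(list(magnitude = mag, peak_z = pz, significant = sig,
                 cells = data.frame(cell_id = ids, preferred = preferred,
                                    ls = ls, stringsAsFactors = FALSE),
                 protocol = protocol, threshold = threshold),
            class = "odor_responses")
}

#' @export
as.data.frame.odor_responses <- function(x, ...) {
  labs <- colnames(x$magnitude)
  ids <- rownames(x$magnitude)
  d <- data.frame(
    cell_id = rep(ids, times = length(labs)),
    stimulus = rep(labs, each = length(ids)),
    magnitude = as.vector(x$magnitude),
    peak_z = as.vector(x$peak_z),
    significant = as.vector(x$significant),
    preferred = rep(x$cells$preferred, times = length(labs)),
    LS = rep(x$cells$ls, times = length(labs)),
    stringsAsFactors = FALSE)
  d <- d[order(match(d$cell_id, ids)), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' @export
print.odor_responses <- function(x, ...) {
  n <- nrow(x$cells)
  cls <- sum(!is.na(x$cells$preferred))
  cat("Odor responses: ", n, " cells x ", ncol(x$magnitude), " stimuli; ",
      cls, " cells classified (>=1 response above ", x$threshold,
      " SD)\n", sep = "")
  if (cls) {
    tab <- table(factor(x$cells$preferred,
                        levels = x$protocol$stimulus_labels))
    print(tab)
  }
  invisible(x)
}

#' @export
summary.odor_responses <- function(object, ...) {
  cells <- object$cells
  out <- data.frame(
    stimulus = object$protocol$stimulus_labels,
    n_preferring = as.integer(table(factor(cells$preferred,
                                           levels = object$protocol$stimulus_labels))),
    mean_ls = vapply(object$protocol$stimulus_labels, function(s) {
      v <- cells$ls[!is.na(cells$preferred) & cells$preferred == s]
      if (length(v)) mean(v, na.rm = TRUE) else NA_real_
    }, numeric(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Population heat-map ordering
#'
#' Orders cells the way population heat maps are drawn: grouped by
#' preferred stimulus in protocol order, within each group by descending
#' magnitude of the response to the preferred stimulus, with the cell id
#' as the final (deterministic) tie-break. Unclassified cells are placed
#' after all groups, ordered by cell id.
#'
#' @param responses An [odor_responses()] object.
#' @return List of class `population_heatmap`: `cell_order` (cell ids),
#'   `matrix` (reordered cells x stimuli magnitudes) and `preferred`.
#' @export
sort_population_heatmap <- function(responses) {
  stopifnot(inherits(responses, "odor_responses"))
  labs <- colnames(responses$magnitude)
  cells <- responses$cells
  pref_rank <- match(cells$preferred, labs)            # NA = unclassified
  r_pref <- vapply(seq_len(nrow(cells)), function(i)
    if (is.na(pref_rank[i])) -Inf else
      responses$magnitude[i, pref_rank[i]], numeric(1))
  grp <- ifelse(is.na(pref_rank), length(labs) + 1L, pref_rank)
  o <- order(grp, -r_pref, cells$cell_id, method = "radix")
  structure(list(cell_order = cells$cell_id[o],
                 matrix = responses$magnitude[o, , drop = FALSE],
                 preferred = cells$preferred[o]),
            class = "population_heatmap")
}

#' @export
print.population_heatmap <- function(x, ...) {
  cat("Population heat map:", nrow(x$matrix), "cells x",
      ncol(x$matrix), "stimuli (sorted)\n")
  invisible(x)
}

#' @export
plot.population_heatmap <- function(x, main = "Population responses", ...) {
  m <- x$matrix[rev(seq_len(nrow(x$matrix))), , drop = FALSE]
  lim <- max(abs(m), 1e-12)
  graphics::image(x = seq_len(ncol(m)), y = seq_len(nrow(m)), z = t(m),
                  zlim = c(-lim, lim),
                  col = grDevices::hcl.colors(101, "Blue-Red 3"),
                  xlab = "stimulus", ylab = "cell", axes = FALSE,
                  main = main, ...)
  graphics::axis(1, at = seq_len(ncol(m)), labels = colnames(m), las = 2)
  graphics::box()
  invisible(x)
}

#' @export
plot.odor_responses <- function(x, ...) plot(sort_population_heatmap(x), ...)

#' Preferred-category counts across preparations
#'
#' Counts, for every preparation, how many cells prefer each stimulus, and
#' summarizes per group (e.g. surface vs cave populations) as the mean
#' count per preparation with its SEM. Unclassified cells are excluded,
#' so each preparation's category counts sum to its number of classified
#' cells.
#'
#' @param preparations Named list, one entry per preparation: either an
#'   [odor_responses()] object or a data frame with columns `cell_id` and
#'   `preferred`.
#' @param groups Character vector parallel to `preparations` giving each
#'   preparation's group label.
#' @param stimulus_labels Category order; defaults to the first
#'   preparation's protocol labels.
#' @return Object of class `category_counts` with `counts` (long, per
#'   preparation), `summary` (per group x stimulus mean and SEM) and
#'   `totals` (classified cells per preparation).
#' @export
category_counts <- function(preparations, groups, stimulus_labels = NULL) {
  stopifnot(length(preparations) == length(groups), length(preparations) >= 1)
  if (is.null(names(preparations)))
    names(preparations) <- sprintf("prep%02d", seq_along(preparations))
  cells_of <- function(p) if (inherits(p, "odor_responses")) p$cells else p
  if (is.null(stimulus_labels)) {
    p1 <- preparations[[1]]
    stimulus_labels <- if (inherits(p1, "odor_responses"))
      p1$protocol$stimulus_labels else sort(unique(cells_of(p1)$preferred))
  }
  counts <- do.call(rbind, lapply(seq_along(preparations), function(k) {
    cells <- cells_of(preparations[[k]])
    tab <- table(factor(cells$preferred, levels = stimulus_labels))
    data.frame(preparation = names(preparations)[k], group = groups[k],
               stimulus = stimulus_labels, count = as.integer(tab),
               stringsAsFactors = FALSE)
  }))
  totals <- stats::aggregate(count ~ preparation + group, counts, sum)
  names(totals)[names(totals) == "count"] <- "classified_cells"
  summ <- do.call(rbind, lapply(unique(groups), function(g) {
    do.call(rbind, lapply(stimulus_labels, function(s) {
      v <- counts$count[counts$group == g & counts$stimulus == s]
      data.frame(group = g, stimulus = s, mean = mean(v),
                 sem = if (length(v) >= 2) sem(v) else NA_real_,
                 n_preparations = length(v), stringsAsFactors = FALSE)
    }))
  }))
  rownames(summ) <- NULL
  structure(list(counts = counts, summary = summ, totals = totals,
                 stimulus_labels = stimulus_labels),
            class = "category_counts")
}

#' @export
print.category_counts <- function(x, ...) {
  cat("Preferred-category counts over", length(unique(x$counts$preparation)),
      "preparations\n")
  print(x$summary, digits = 4)
  invisible(x)
}
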