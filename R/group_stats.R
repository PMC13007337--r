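#' Standard error of the mean
#'
#' Sample standard deviation divided by the square root of the sample size.
#'
#' @param x Numeric vector with at least 2 values.
#' @return The SEM.
#' @export
sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L)
    stop("SEM needs at least 2 values", call. = FALSE)
  stats::sd(x) / sqrt(length(x))
}

#' Normalize cell counts to structure volume
#'
#' Per-sample ratio `cell_count / ob_volume` (cells per cubic micrometer).
#' Group summaries are means of the per-sample ratios — never the ratio of
#' summed counts to summed volumes — with SEM across samples.
#'
#' @param table A [count_volume_table()] (or data frame with its columns).
#' @return List with `samples` (the table plus a `ratio` column) and
#'   `summary` (per group, and per timepoint when present: mean ratio,
#'   SEM, n).
#' @export
normalize_counts <- function(table) {
  d <- count_volume_table(as.data.frame(table))
  d$ratio <- d$cell_count / d$ob_volume
  by_cols <- intersect(c("group", "timepoint_dpf"), names(d))
  key <- interaction(d[by_cols], drop = TRUE)
  summ <- do.call(rbind, lapply(levels(key), function(k) {
    sub <- d[key == k, , drop = FALSE]
    cbind(sub[1, by_cols, drop = FALSE],
          data.frame(mean_ratio = mean(sub$ratio),
                     sem_ratio = if (nrow(sub) >= 2) sem(sub$ratio) else NA_real_,
                     n = nrow(sub)))
  }))
  rownames(summ) <- NULL
  list(samples = d, summary = summ)
}

#' Holm-Sidak step-down adjustment
#'
#' Step-down Sidak adjustment of a family of k raw p-values: sort p
#' ascending, adjust `p_(i)` to `1 - (1 - p_(i))^(k - i + 1)`, and enforce
#' monotonicity by taking the running maximum, capping at 1. `NA` entries
#' are left `NA` and do not count toward k. With k = 1 the adjusted value
#' equals the raw value.
#'
#' @param p Numeric vector of raw p-values.
#' @return Adjusted p-values, same order as `p`.
#' @export
holm_sidak_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  k <- length(ok)
  if (k == 0L) return(out)
  o <- order(p[ok])
  ps <- p[ok][o]
  adj <- cummax(1 - (1 - ps)^(k - seq_len(k) + 1))
  adj <- pmin(adj, 1)
  out[ok[o]] <- adj
  out
}

#' Family of unpaired t-tests with Holm-Sidak correction
#'
#' Runs a two-sided unpaired Student t-test (pooled variance, so a
#' comparison of groups of sizes n1 and n2 has n1 + n2 - 2 degrees of
#' freedom) for every comparison in the family and adjusts the p-values by
#' the Holm-Sidak step-down. A degenerate comparison (a group with fewer
#' than 2 values, or zero variance in both groups with equal means in a way
#' the t-test cannot handle) gets `NA` results and drops out of the family
#' size; the rest of the family is still tested.
#'
#' @param comparisons Named list; each element is a list/pair of two
#'   numeric vectors (the two groups).
#' @param alpha Significance level for the convenience flag.
#' @return Data frame of class `comparison_family`: one row per comparison
#'   with group means, `t`, `df`, `p_raw`, `p_adj`, `significant`.
#' @examples
#' fam <- holm_sidak_family(list(
#'   a = list(rnorm(8), rnorm(8, 1)),
#'   b = list(rnorm(8), rnorm(8))))
#' @export
holm_sidak_family <- function(comparisons, alpha = 0.05) {
  stopifnot(is.list(comparisons), length(comparisons) >= 1)
  if (is.null(names(comparisons)))
    names(comparisons) <- sprintf("cmp%02d", seq_along(comparisons))
  one <- function(pair) {
    x <- as.numeric(pair[[1]]); y <- as.numeric(pair[[2]])
    if (length(x) < 2 || length(y) < 2)
      return(list(mx = mean(x), my = mean(y), t = NA_real_, df = NA_real_,
                  p = NA_real_, note = "degenerate: group n < 2"))
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      if (mean(x) == mean(y))
        return(list(mx = mean(x), my = mean(y), t = 0,
                    df = length(x) + length(y) - 2, p = 1, note = ""))
      return(list(mx = mean(x), my = mean(y), t = NA_real_, df = NA_real_,
                  p = NA_real_, note = "degenerate: zero variance"))
    }
    tt <- stats::t.test(x, y, var.equal = TRUE)
    list(mx = mean(x), my = mean(y), t = unname(tt$statistic),
         df = unname(tt$parameter), p = tt$p.value, note = "")
  }
  rows <- lapply(comparisons, one)
  out <- data.frame(
    comparison = names(comparisons),
    mean_1 = vapply(rows, `[[`, numeric(1), "mx"),
    mean_2 = vapply(rows, `[[`, numeric(1), "my"),
    t = vapply(rows, `[[`, numeric(1), "t"),
    df = vapply(rows, `[[`, numeric(1), "df"),
    p_raw = vapply(rows, `[[`, numeric(1), "p"),
    stringsAsFactors = FALSE)
  out$p_adj <- holm_sidak_adjust(out$p_raw)
  out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
  out$note <- vapply(rows, `[[`, character(1), "note")
  rownames(out) <- NULL
  class(out) <- c("comparison_family", "data.frame")
  out
}

#' @export
print.comparison_family <- function(x, ...) {
  cat("Unpaired t-test family (Holm-Sidak corrected), k =",
      sum(!is.na(x$p_raw)), "\n")
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Two-way repeated-measures ANOVA with Sidak post-hoc comparisons
#'
#' Mixed-design ANOVA for a between-subject factor (`group`) crossed with a
#' within-subject factor (`within`), subjects as the random blocking
#' factor. With a complete, balanced design the classical sums-of-squares
#' decomposition is used (the between effect tested against
#' subject-within-group, the within effect and interaction against the
#' subject-by-within residual). When subjects are missing within-factor
#' cells the balanced decomposition is undefined and the model is refit by
#' REML (`lmerTest`, Satterthwaite denominator df) — `method` in the result
#' records which route ran.
#'
#' Post-hoc: at every within-factor level the two groups are compared by an
#' unpaired Student t-test, Sidak-adjusted for the number of levels
#' (`p_adj = 1 - (1 - p_raw)^k`).
#'
#' @param data Long-format data frame.
#' @param value,subject,group,within Column names (strings).
#' @param alpha Significance level for convenience flags.
#' @return Object of class `rm_anova`: `anova_table` (effect, F, df1, df2,
#'   p), `posthoc` (per within level), `method` (`"aov"` or `"reml"`).
#' @export
rm_anova_sidak <- function(data, value = "value", subject = "subject",
                           group = "group", within = "stimulus",
                           alpha = 0.05) {
  need <- c(value, subject, group, within)
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  d <- data.frame(y = as.numeric(data[[value]]),
                  subject = factor(data[[subject]]),
                  group = factor(data[[group]]),
                  within = factor(data[[within]]))
  if (anyNA(d$y)) {
    keep <- !is.na(d$y)
    d <- d[keep, , drop = FALSE]
  }
  tab <- table(d$subject, d$within)
  balanced <- all(tab == 1)
  one_group <- nlevels(d$group) == 1L
  gsz <- table(d$group[!duplicated(d$subject)])
  if (any(gsz < 2))
    stop("need >= 2 subjects per group", call. = FALSE)

  rhs <- if (one_group) y ~ within + Error(subject) else
    y ~ group * within + Error(subject)
  if (balanced) {
    fit <- stats::aov(rhs, data = d)
    s <- summary(fit)
    bt <- s[["Error: subject"]][[1]]
    wt <- s[["Error: Within"]][[1]]
    get_row <- function(tabl, name) {
      i <- match(name, trimws(rownames(tabl)))
      resid <- tabl[trimws(rownames(tabl)) == "Residuals", , drop = FALSE]
      f <- tabl[i, "F value"]; p <- tabl[i, "Pr(>F)"]
      # an effect whose sum of squares is numerically zero (e.g. an
      # identically-constant response) carries no evidence: F = 0, p = 1
      ss_eff <- tabl[i, "Sum Sq"]
      # rounding-noise sums of squares (constant or effect-free responses)
      # carry no evidence; judge against the scale of the data themselves
      ss_scale <- max(sum(d$y^2), .Machine$double.eps)
      if (!is.finite(f) || ss_eff <= 1e-10 * ss_scale) { f <- 0; p <- 1 }
      data.frame(effect = name, F = f, df1 = tabl[i, "Df"],
                 df2 = resid[1, "Df"], p = p, stringsAsFactors = FALSE)
    }
    atab <- if (one_group) get_row(wt, "within") else
      rbind(get_row(bt, "group"),
            get_row(wt, "within"),
            get_row(wt, "group:within"))
    method <- "aov"
  } else {
    lform <- if (one_group) y ~ within + (1 | subject) else
      y ~ group * within + (1 | subject)
    fit <- lmerTest::lmer(lform, data = d, REML = TRUE)
    a <- stats::anova(fit)
    atab <- data.frame(effect = rownames(a), F = a[, "F value"],
                       df1 = a[, "NumDF"], df2 = a[, "DenDF"],
                       p = a[, "Pr(>F)"], stringsAsFactors = FALSE)
    method <- "reml"
  }
  rownames(atab) <- NULL

  levs <- levels(d$within)
  k <- length(levs)
  if (one_group) {
    return(structure(list(anova_table = atab, posthoc = NULL,
                          method = method, groups = levels(d$group),
                          alpha = alpha),
                     class = "rm_anova"))
  }
  g12 <- levels(d$group)[1:2]
  posthoc <- do.call(rbind, lapply(levs, function(lv) {
    x <- d$y[d$within == lv & d$group == g12[1]]
    y <- d$y[d$within == lv & d$group == g12[2]]
    if (length(x) < 2 || length(y) < 2 ||
        (stats::sd(x) == 0 && stats::sd(y) == 0))
      return(data.frame(level = lv, mean_1 = mean(x), mean_2 = mean(y),
                        t = NA_real_, df = NA_real_, p_raw = NA_real_,
                        stringsAsFactors = FALSE))
    tt <- stats::t.test(x, y, var.equal = TRUE)
    data.frame(level = lv, mean_1 = mean(x), mean_2 = mean(y),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_raw = tt$p.value, stringsAsFactors = FALSE)
  }))
  posthoc$p_adj <- pmin(1, 1 - (1 - posthoc$p_raw)^k)
  posthoc$significant <- !is.na(posthoc$p_adj) & posthoc$p_adj < alpha
  rownames(posthoc) <- NULL
  structure(list(anova_table = atab, posthoc = posthoc, method = method,
                 groups = g12, alpha = alpha),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat("Two-way repeated-measures ANOVA (", x$method, "), groups: ",
      paste(x$groups, collapse = " vs "), "\n", sep = "")
  print(x$anova_table, digits = 4)
  if (!is.null(x$posthoc)) {
    cat("Sidak post-hoc per within-factor level:\n")
    print(x$posthoc, digits = 4)
  }
  invisible(x)
}
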