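test_that("sem matches the textbook formula", {
  expect_equal(sem(c(4, 6)), 1)
  expect_equal(sem(rep(3.2, 10)), 0)
  expect_error(sem(5), "at least 2")
  set.seed(53)
  x <- rnorm(31)
  expect_equal(sem(x), sd(x) / sqrt(31), tolerance = 1e-12)
})

test_that("count normalization uses per-sample ratios, not ratio of sums", {
  d <- data.frame(sample_id = c("s1", "s2"), group = "surface",
                  cell_count = c(100L, 300L), ob_volume = c(1e6, 3e6))
  out <- normalize_counts(d)
  expect_equal(out$samples$ratio, c(1e-4, 1e-4))
  expect_equal(out$summary$mean_ratio, 1e-4)

  one <- normalize_counts(data.frame(sample_id = "s", group = "g",
                                     cell_count = 100L, ob_volume = 2e6))
  expect_equal(one$samples$ratio, 5e-5)

  bad <- d; bad$ob_volume[1] <- -1
  expect_error(normalize_counts(bad), "positive")
})

test_that("a planted density is recovered as the group mean ratio", {
  set.seed(59)
  rho <- 4.5e-5
  vols <- runif(12, 1e6, 4e6)
  d <- data.frame(sample_id = sprintf("s%d", 1:12), group = "cave",
                  cell_count = round(rho * vols), ob_volume = vols)
  out <- normalize_counts(d)
  expect_equal(out$summary$mean_ratio, rho,
               tolerance = 3 * out$summary$sem_ratio / rho)
})

test_that("Holm-Sidak step-down reproduces the hand-executed example", {
  p_raw <- c(0.01, 0.04, 0.03)
  adj <- holm_sidak_adjust(p_raw)
  expect_equal(adj, c(1 - 0.99^3, 1 - 0.97^2, 1 - 0.97^2),
               tolerance = 1e-12)
  expect_equal(holm_sidak_adjust(0.037), 0.037)          # k = 1
  expect_true(all(holm_sidak_adjust(c(0.9, 0.95, 0.99)) <= 1))
})

test_that("Holm-Sidak adjustment is monotone and never below raw", {
  set.seed(61)
  for (i in 1:100) {
    p <- runif(sample(2:10, 1))
    adj <- holm_sidak_adjust(p)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-15))
  }
})

test_that("t-test families pool variance and carry degenerate comparisons", {
  set.seed(67)
  fam <- holm_sidak_family(list(
    shift = list(rnorm(10), rnorm(12, 3)),
    null = list(rnorm(10), rnorm(10)),
    tiny = list(c(1), c(2, 3))))
  expect_equal(fam$df[1], 20)                    # n1 + n2 - 2
  expect_true(is.na(fam$p_adj[3]))
  expect_match(fam$note[3], "degenerate")
  # family size excludes the degenerate row: k = 2 for the others
  valid <- !is.na(fam$p_raw)
  ps <- sort(fam$p_raw[valid])
  expect_equal(sort(fam$p_adj[valid]),
               pmin(1, cummax(1 - (1 - ps)^c(2, 1))), tolerance = 1e-12)

  same <- holm_sidak_family(list(id = list(rep(2, 5), rep(2, 6))))
  expect_equal(same$t, 0)
  expect_equal(same$p_adj, 1)

  single <- holm_sidak_family(list(a = list(rnorm(6), rnorm(6))))
  expect_equal(single$p_adj, single$p_raw)
})

test_that("familywise type-I error stays controlled under a global null", {
  # k = 7 two-group comparisons, n = 8 per group, many replicates;
  # t statistics computed in closed form, adjusted by the step-down
  set.seed(71)
  n <- 8; k <- 7; reps <- 10000
  any_sig <- logical(reps)
  crit <- 0.05
  for (r in seq_len(reps)) {
    x <- matrix(rnorm(n * k), n); y <- matrix(rnorm(n * k), n)
    sp2 <- (apply(x, 2, var) + apply(y, 2, var)) / 2
    tt <- (colMeans(x) - colMeans(y)) / sqrt(sp2 * 2 / n)
    p <- 2 * pt(-abs(tt), df = 2 * n - 2)
    any_sig[r] <- any(holm_sidak_adjust(p) < crit)
  }
  expect_lte(mean(any_sig), 0.055)
})

test_that("balanced mixed ANOVA handles degenerate and shifted designs", {
  d <- expand.grid(subject = sprintf("s%d", 1:8),
                   stimulus = c("w", "a", "n"), KEEP.OUT.ATTRS = FALSE)
  d$group <- ifelse(d$subject %in% sprintf("s%d", 1:4), "surface", "cave")
  d$value <- 1                                   # identically constant
  res <- rm_anova_sidak(d)
  expect_equal(res$method, "aov")
  expect_true(all(res$anova_table$F == 0))
  expect_true(all(res$anova_table$p == 1))

  # constant between-group shift, subject intercepts, no level variation
  d2 <- d
  subj_eff <- seq(0, 0.7, length.out = 8)[match(d2$subject,
                                                sprintf("s%d", 1:8))]
  d2$value <- ifelse(d2$group == "cave", 10, 0) + subj_eff
  res2 <- rm_anova_sidak(d2)
  at <- res2$anova_table
  expect_gt(at$F[at$effect == "group"], 100)
  expect_lt(at$p[at$effect == "group"], 0.001)
  expect_equal(at$F[at$effect == "group:within"], 0)
  expect_equal(at$p[at$effect == "group:within"], 1)
})

test_that("with one group and two levels the within F equals the paired t squared", {
  set.seed(73)
  d <- data.frame(subject = rep(sprintf("s%d", 1:10), 2),
                  stimulus = rep(c("pre", "post"), each = 10),
                  group = "only", value = rnorm(20))
  res <- rm_anova_sidak(d)
  tt <- t.test(d$value[d$stimulus == "pre"], d$value[d$stimulus == "post"],
               paired = TRUE)
  expect_equal(res$anova_table$F[res$anova_table$effect == "within"],
               unname(tt$statistic^2), tolerance = 1e-10)
})

test_that("a planted group-by-stimulus interaction is detected", {
  set.seed(79)
  levs <- sprintf("odor%d", 1:7)
  d <- expand.grid(subject = sprintf("s%d", 1:32), stimulus = levs,
                   KEEP.OUT.ATTRS = FALSE)
  d$group <- ifelse(d$subject %in% sprintf("s%d", 1:16), "surface", "cave")
  noise_sd <- 1
  d$value <- rnorm(nrow(d), sd = noise_sd)
  sel <- d$group == "cave" & d$stimulus == "odor1"
  d$value[sel] <- d$value[sel] + 2 * noise_sd    # 2-SD effect at one level
  res <- rm_anova_sidak(d)
  at <- res$anova_table
  expect_lt(at$p[at$effect == "group:within"], 0.05)
  # Sidak post-hoc flags the planted level
  ph <- res$posthoc
  expect_equal(ph$p_adj, pmin(1, 1 - (1 - ph$p_raw)^7), tolerance = 1e-12)
  expect_true(ph$significant[ph$level == "odor1"])
})

test_that("missing within-factor cells trigger the REML route", {
  set.seed(83)
  d <- expand.grid(subject = sprintf("s%d", 1:10),
                   stimulus = c("w", "a", "n"), KEEP.OUT.ATTRS = FALSE)
  d$group <- ifelse(d$subject %in% sprintf("s%d", 1:5), "surface", "cave")
  d$value <- rnorm(nrow(d))
  d <- d[-5, ]                                   # drop one cell
  res <- rm_anova_sidak(d)
  expect_equal(res$method, "reml")
  expect_true(all(is.finite(res$anova_table$F)))
  expect_setequal(res$anova_table$effect, c("group", "within", "group:within"))
})
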