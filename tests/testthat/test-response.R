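test_that("response magnitude is the stimulus-window mean minus the pre-stimulus mean", {
  p <- small_protocol()
  n <- n_frames(p)
  zero <- as_dff(matrix(0, 1, n), p)
  expect_equal(unname(response_magnitude(zero, p)), 0)

  step <- matrix(0, 1, n)
  step[, 76:n] <- 0.5
  expect_equal(unname(response_magnitude(as_dff(step, p), p)), 0.5)

  short <- as_dff(matrix(0, 1, 80), p)
  expect_error(response_magnitude(short, p), "too short")
})

test_that("magnitudes on noiseless simulator traces match the ideal-trace oracle", {
  p <- small_protocol(n_trials = 1)
  gt <- sample_ground_truth(
    8, p, seed = 41,
    tuning = small_tuning(noise_sd = 0, min_center_dist = 12))
  ideal <- render_ideal_traces(gt, p)
  rois <- rois_from_truth(gt)
  on <- onset_frame(p)
  for (s in p$stimulus_labels) {
    mv <- render_movie(gt, ideal, p, s, 1)
    dff <- process_trials(list(mv), rois, p, stimulus = s, filter = FALSE)
    r <- response_magnitude(dff, p)
    oracle <- rowMeans(ideal$traces[[s]][, (on + 1):(on + 30), drop = FALSE])
    expect_equal(unname(r), unname(oracle), tolerance = 1e-6)
  }
})

test_that("the 6-SD peak rule separates 5-SD from 10-SD responses", {
  p <- small_protocol()
  n <- n_frames(p)
  base <- c(rep(c(-0.01, 0.01), 37), 0)   # 75 frames, mean exactly 0
  sd0 <- sd(base)
  tr <- matrix(0, 2, n, dimnames = list(c("weak", "strong"), NULL))
  tr[, 1:75] <- rep(base, each = 2)
  tr["weak", 100] <- 5 * sd0
  tr["strong", 100] <- 10 * sd0
  res <- is_significant(as_dff(tr, p), p)
  expect_equal(unname(res$peak_z), c(5, 10), tolerance = 1e-9)
  expect_equal(unname(res$significant), c(FALSE, TRUE))

  flat <- as_dff(matrix(0, 1, n, dimnames = list("flat", NULL)), p)
  expect_error(is_significant(flat, p), "degenerate baseline")
})

test_that("lifetime sparseness matches its closed forms exactly", {
  expect_equal(lifetime_sparseness(c(1, 0, 0, 0, 0, 0, 0)), 1 / 7,
               tolerance = 1e-12)
  expect_equal(lifetime_sparseness(rep(0.37, 7)), 1, tolerance = 1e-12)
  expect_equal(lifetime_sparseness(c(0.5, 0.25, 0, 0, 0, 0, 0)), 9 / 35,
               tolerance = 1e-12)
  expect_true(is.na(lifetime_sparseness(c(0, 0, -1, 0))))
  expect_error(lifetime_sparseness(0.5), "at least 2")
})

test_that("lifetime sparseness is scale-invariant and bounded on random vectors", {
  set.seed(19)
  for (i in 1:200) {
    m <- sample(2:9, 1)
    r <- runif(m, 0, 2)
    ls <- lifetime_sparseness(r)
    expect_gt(ls, 0)
    expect_lte(ls, 1)
    expect_gte(ls, 1 / m)
    expect_equal(lifetime_sparseness(3.7 * r), ls, tolerance = 1e-12)
    # rectification: signed input gives the LS of its positive part
    signed <- r * sample(c(-1, 1), m, replace = TRUE)
    if (any(signed > 0))
      expect_equal(lifetime_sparseness(signed),
                   lifetime_sparseness(pmax(signed, 0)), tolerance = 1e-15)
  }
  # extremes are attained exactly on one-hot and uniform vectors
  expect_equal(lifetime_sparseness(c(0, 0, 0, 0, 2)), 1 / 5)
  expect_equal(lifetime_sparseness(rep(1e-3, 9)), 1)
})

test_that("preference goes to the largest significant response, ties to protocol order", {
  mags <- c(water = 0.1, alanine = 0.5, NaCl = 0.2)
  expect_equal(assign_preference(mags, c(FALSE, TRUE, FALSE)), "alanine")
  expect_true(is.na(assign_preference(mags, c(FALSE, FALSE, FALSE))))
  tied <- c(water = 0.5, alanine = 0.5, NaCl = 0.1)
  expect_warning(pref <- assign_preference(tied, c(TRUE, TRUE, FALSE)),
                 "tie")
  expect_equal(pref, "water")
})

test_that("heat-map ordering equals the brute-force lexicographic oracle", {
  p <- small_protocol()
  set.seed(29)
  n <- 40
  nf <- n_frames(p)
  traces <- lapply(p$stimulus_labels, function(s) {
    m <- matrix(rnorm(n * nf, 0, 0.005), n, nf)
    amp <- runif(n, 0, 0.6) * rbinom(n, 1, 0.8)
    m[, 76:200] <- m[, 76:200] + amp
    as_dff(m, p)
  })
  names(traces) <- p$stimulus_labels
  resp <- odor_responses(traces, p)
  hm <- sort_population_heatmap(resp)

  labs <- p$stimulus_labels
  cells <- resp$cells
  pref_rank <- match(cells$preferred, labs)
  r_pref <- vapply(seq_len(n), function(i)
    if (is.na(pref_rank[i])) -Inf else resp$magnitude[i, pref_rank[i]],
    numeric(1))
  key <- data.frame(g = ifelse(is.na(pref_rank), length(labs) + 1, pref_rank),
                    r = -r_pref, id = cells$cell_id)
  oracle <- cells$cell_id[order(key$g, key$r, key$id)]
  expect_identical(hm$cell_order, oracle)

  # simple two-cell case: same preference, stronger response first
  two <- resp$magnitude[1:2, , drop = FALSE]
  two[1, ] <- c(0.2, 0.01, 0.01); two[2, ] <- c(0.5, 0.01, 0.01)
  tr2 <- lapply(seq_along(labs), function(j) {
    m <- matrix(rnorm(2 * nf, 0, 0.004), 2, nf,
                dimnames = list(c("cA", "cB"), NULL))
    m[, 76:200] <- m[, 76:200] + two[, j]
    as_dff(m, p)
  })
  names(tr2) <- labs
  hm2 <- sort_population_heatmap(odor_responses(tr2, p))
  expect_identical(hm2$cell_order, c("cB", "cA"))
})

test_that("category counts aggregate preparations with mean and SEM", {
  mk_prep <- function(prefs)
    data.frame(cell_id = sprintf("c%d", seq_along(prefs)), preferred = prefs,
               stringsAsFactors = FALSE)
  one <- category_counts(list(p1 = mk_prep(rep("water", 3))),
                         groups = "surface",
                         stimulus_labels = c("water", "alanine"))
  expect_equal(one$summary$mean[one$summary$stimulus == "water"], 3)
  expect_equal(one$summary$mean[one$summary$stimulus == "alanine"], 0)

  two <- category_counts(
    list(p1 = mk_prep(rep("water", 4)), p2 = mk_prep(rep("water", 6))),
    groups = c("surface", "surface"),
    stimulus_labels = c("water", "alanine"))
  w <- two$summary[two$summary$stimulus == "water", ]
  expect_equal(w$mean, 5)
  expect_equal(w$sem, 1)
})

test_that("per-preparation category counts always sum to classified totals", {
  set.seed(37)
  labs <- c("water", "NaCl", "LCA", "alanine")
  preps <- lapply(1:6, function(k) {
    n <- sample(10:40, 1)
    prefs <- sample(c(labs, NA), n, replace = TRUE)
    data.frame(cell_id = sprintf("c%d", 1:n), preferred = prefs,
               stringsAsFactors = FALSE)
  })
  cc <- category_counts(preps, groups = rep(c("surface", "cave"), 3),
                        stimulus_labels = labs)
  sums <- tapply(cc$counts$count, cc$counts$preparation, sum)
  expect_equal(as.integer(sums[cc$totals$preparation]),
               cc$totals$classified_cells)
  for (k in seq_along(preps))
    expect_equal(
      cc$totals$classified_cells[cc$totals$preparation == sprintf("prep%02d", k)],
      sum(!is.na(preps[[k]]$preferred)))
  # aggregation is linear: per-group category means sum to mean total
  for (g in c("surface", "cave")) {
    s <- sum(cc$summary$mean[cc$summary$group == g])
    tot <- mean(cc$totals$classified_cells[cc$totals$group == g])
    expect_equal(s, tot, tolerance = 1e-12)
  }
})
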