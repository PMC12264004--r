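make_table <- function(frame, x, y, precision = 30) {
  tab <- data.frame(frame = frame, x_nm = x, y_nm = y, photons = 350,
                    background = 33.7, sigma_nm = 102,
                    precision_nm = precision, quality = 1, converged = TRUE)
  class(tab) <- c("localization_table", "data.frame")
  tab
}

test_that("consecutive localizations of one molecule form one event", {
  tab <- make_table(1:3, c(1000, 1010, 995), c(2000, 1990, 2005))
  ev <- merge_into_events(tab, radius = 100, max_dark_frames = 2)
  expect_equal(nrow(ev$events), 1)
  expect_equal(ev$events$n_locs, 3L)
  expect_equal(ev$events$first_frame, 1L)
  expect_equal(ev$events$last_frame, 3L)
})

test_that("a gap beyond max_dark_frames opens a second event", {
  tab <- make_table(c(1, 2, 6, 7), rep(1000, 4), rep(1000, 4))
  ev <- merge_into_events(tab, radius = 100, max_dark_frames = 2)
  expect_equal(nrow(ev$events), 2)
  ev2 <- merge_into_events(tab, radius = 100, max_dark_frames = 3)
  expect_equal(nrow(ev2$events), 1)
})

test_that("events match ground-truth ON spells for well-separated emitters", {
  # sparse emitters, ideal localizations with small scatter
  g <- rumposome_geometry(lattice_pitch_nm = 400, band_width_nm = 1200)
  em <- build_rumposome_lattice(g, 25)
  p <- photophysics_params(n_frames = 2000)
  tr <- simulate_states(em, p, reactivation_controller(target_rate = 0.05),
                        seed = 9)
  set.seed(10)
  on <- tr$on
  tab <- make_table(on$frame,
                    em$x_nm[on$molecule_id] + rnorm(nrow(on), 0, 5),
                    em$y_nm[on$molecule_id] + rnorm(nrow(on), 0, 5))
  ord <- order(tab$frame)
  tab <- tab[ord, ]
  ev <- merge_into_events(tab, radius = 50, max_dark_frames = 2)
  sp <- on_spells(tr)
  expect_equal(nrow(ev$events), nrow(sp))
  # every event maps to exactly one spell with identical frame span
  key_ev <- paste(ev$events$first_frame, ev$events$last_frame)
  key_sp <- paste(sp$first_frame, sp$last_frame)
  expect_setequal(key_ev, key_sp)
})

test_that("event counting modes behave as documented", {
  tab <- make_table(1:3, c(0, 500, 1000), c(0, 0, 0))
  ev <- merge_into_events(tab, radius = 100, max_dark_frames = 2)
  expect_equal(count_molecules(ev), 3)
  ev$events <- ev$events[rep(1, 120), ]
  expect_equal(count_molecules(ev, "recurrence_corrected",
                               recurrence_mean = 1.2), 100)
  empty <- ev; empty$events <- ev$events[0, ]
  expect_warning(n0 <- count_molecules(empty), "empty")
  expect_equal(n0, 0L)
})

test_that("cohort summaries use the sample SD and flag singletons", {
  s1 <- summarize_cohort(5)
  expect_equal(s1$mean, 5)
  expect_equal(s1$sd, 0)
  expect_false(s1$sd_defined)
  s3 <- summarize_cohort(c(2, 4, 6))
  expect_equal(s3$mean, 4)
  expect_equal(s3$sd, 2)
  expect_equal(s3$n, 3)
})

test_that("a simulated cohort recovers the generating mean", {
  set.seed(23)
  truth <- pmax(round(rnorm(23, 3417, 1543)), 0)
  s <- summarize_cohort(truth)
  expect_lt(abs(s$mean - 3417), 2 * 1543 / sqrt(23))
  expect_equal(s$n, 23)
})

test_that("increasing the dark-frame tolerance never increases the count", {
  sim <- tiny_sim(seed = 7)
  set.seed(7)
  on <- sim$trajectory$on
  tab <- make_table(on$frame,
                    sim$emitters$x_nm[on$molecule_id] + rnorm(nrow(on), 0, 30),
                    sim$emitters$y_nm[on$molecule_id] + rnorm(nrow(on), 0, 30))
  tab <- tab[order(tab$frame), ]
  counts <- sapply(c(0, 1, 2, 4, 8), function(md)
    nrow(merge_into_events(tab, radius = 96, max_dark_frames = md)$events))
  expect_true(all(diff(counts) <= 0))
})

test_that("shuffling equal-frame order changes counts by less than 1 percent", {
  sim <- simulate_zoospore(simulation_config(
    n_molecules = 500, seed = 8, sensor_px = 48, n_frames = 2500,
    target_rate = 0.3))
  set.seed(8)
  on <- sim$trajectory$on
  tab <- make_table(on$frame,
                    sim$emitters$x_nm[on$molecule_id] + rnorm(nrow(on), 0, 30),
                    sim$emitters$y_nm[on$molecule_id] + rnorm(nrow(on), 0, 30))
  tab <- tab[order(tab$frame), ]
  n1 <- nrow(merge_into_events(tab, radius = 96, max_dark_frames = 2)$events)
  set.seed(99)
  perm <- order(tab$frame, runif(nrow(tab)))
  n2 <- nrow(merge_into_events(tab[perm, ], radius = 96,
                               max_dark_frames = 2)$events)
  expect_lt(abs(n1 - n2) / n1, 0.01)
})

test_that("event members stay within the linkage radius of their centroid", {
  sim <- tiny_sim(seed = 9)
  set.seed(9)
  on <- sim$trajectory$on
  tab <- make_table(on$frame,
                    sim$emitters$x_nm[on$molecule_id] + rnorm(nrow(on), 0, 20),
                    sim$emitters$y_nm[on$molecule_id] + rnorm(nrow(on), 0, 20))
  tab <- tab[order(tab$frame), ]
  ev <- merge_into_events(tab, radius = 96, max_dark_frames = 2)
  for (i in seq_along(ev$members)) {
    m <- ev$members[[i]]
    d <- sqrt((tab$x_nm[m] - ev$events$x_nm[i])^2 +
              (tab$y_nm[m] - ev$events$y_nm[i])^2)
    expect_lt(max(d), 96 * 1.25)
    # within-event frame gaps respect the dark tolerance
    expect_true(all(diff(sort(tab$frame[m])) <= 3))
  }
  # events are disjoint
  expect_false(any(duplicated(unlist(ev$members))))
})
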