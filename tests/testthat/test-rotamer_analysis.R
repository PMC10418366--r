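test_that("rotamer windows must be disjoint on the circle and cover the
           defaults", {
  w <- rotamer_windows()
  expect_identical(w$native, "in_site")
  expect_error(
    rotamer_windows(data.frame(label = c("a", "b"),
                               center = c(0, 60), halfwidth = c(40, 40))),
    class = "chisno_config_error")
  # straddling 0/360 is fine as long as windows stay disjoint
  w2 <- rotamer_windows(data.frame(label = c("a", "b"),
                                   center = c(350, 120),
                                   halfwidth = c(30, 30)), native = "a")
  tr <- classify_states(series_from_angles(c(355, 5, 345, 120, 200)), w2)
  expect_identical(tr$labels, c("a", "a", "a", "b", "other"))
})

test_that("constant traces classify entirely into their window", {
  tr_native <- classify_states(series_from_angles(rep(190, 50)))
  expect_identical(unique(tr_native$labels), "in_site")
  tr_out <- classify_states(series_from_angles(rep(285, 50)))
  expect_identical(unique(tr_out$labels), "out_site")
})

test_that("classification recovers generator truth away from boundaries", {
  draw <- sample_regime(two_well_regime(n_frames = 5000, seed = 9))
  tr <- classify_states(draw$series)
  mu <- c(in_site = 190, out_site = 285)
  sigma <- c(in_site = 9, out_site = 12)
  a <- draw$series$angles
  near_center <- abs(((a - mu[draw$states] + 180) %% 360) - 180) <=
    3 * sigma[draw$states]
  expect_true(all(tr$labels[near_center] == draw$states[near_center]))
  expect_gt(mean(near_center), 0.95)  # 3-sigma covers nearly everything
})

test_that("occupancy partitions every frame and sums to one", {
  tr <- classify_states(series_from_angles(c(rep(190, 25), rep(285, 25))))
  occ <- occupancy(tr)
  expect_equal(sum(occ), 1)
  expect_equal(unname(occ["in_site"]), 0.5)
  expect_equal(unname(occ["out_site"]), 0.5)
  expect_equal(unname(occ["other"]), 0)
})

test_that("occupancy of a Markov trace matches the stationary distribution
           within three standard errors", {
  spec <- two_well_regime(n_frames = 10000, seed = 13)
  draw <- sample_regime(spec)
  tr <- classify_states(draw$series)
  pi_stat <- stationary_occupancy(spec)
  # autocorrelation-corrected standard error of the occupancy of a 2-state
  # chain: var = pi(1-pi)(1+rho)/(1-rho)/n with rho = 1 - p12 - p21
  p12 <- spec$transition[1, 2]; p21 <- spec$transition[2, 1]
  rho <- 1 - p12 - p21
  n <- spec$n_frames
  se <- sqrt(pi_stat["out_site"] * (1 - pi_stat["out_site"]) *
               (1 + rho) / (1 - rho) / n)
  expect_lt(abs(occupancy(tr)[["out_site"]] - pi_stat[["out_site"]]), 3 * se)
})

test_that("violation counts equal brute-force run enumeration on random
           traces", {
  set.seed(17)
  for (i in 1:100) {
    labels <- sample(c("in_site", "out_site", "other"), 60, replace = TRUE,
                     prob = c(0.6, 0.3, 0.1))
    tr <- classify_states(series_from_angles(angles_for_labels(labels)))
    expect_identical(tr$labels, labels)
    md <- sample(c(0, 0.1, 0.25, 1), 1)
    expect_equal(count_violations(tr, min_dwell = md),
                 brute_force_violations(labels, tr$times, "in_site", md))
  }
})

test_that("all-native traces have zero violations; a single long excursion
           counts once; short flicker is ignored", {
  all_native <- classify_states(series_from_angles(rep(190, 100)))
  expect_equal(count_violations(all_native, 1), 0)

  labels <- c(rep("in_site", 40), rep("out_site", 15), rep("in_site", 45))
  tr <- classify_states(series_from_angles(angles_for_labels(labels)))
  expect_equal(count_violations(tr, min_dwell = 1), 1)  # 1.5 ns excursion

  flicker <- rep(c(rep("in_site", 9), "out_site"), 10)  # 0.1-ns blips
  trf <- classify_states(series_from_angles(angles_for_labels(flicker)))
  expect_equal(count_violations(trf, min_dwell = 1), 0)
  expect_equal(count_violations(trf, min_dwell = 0.1), 10)
})

test_that("violation count is non-increasing in min_dwell and unaffected by
           extra native frames inside native runs", {
  set.seed(19)
  labels <- sample(c("in_site", "out_site"), 200, replace = TRUE,
                   prob = c(0.7, 0.3))
  tr <- classify_states(series_from_angles(angles_for_labels(labels)))
  counts <- vapply(c(0, 0.1, 0.3, 0.5, 1, 2),
                   function(md) count_violations(tr, md), numeric(1))
  expect_true(all(diff(counts) <= 0))

  base <- c(rep("in_site", 10), rep("out_site", 12), rep("in_site", 10))
  padded <- c(rep("in_site", 25), rep("out_site", 12), rep("in_site", 10))
  for (md in c(0, 0.5, 1, 1.3)) {
    expect_equal(
      count_violations(classify_states(
        series_from_angles(angles_for_labels(base))), md),
      count_violations(classify_states(
        series_from_angles(angles_for_labels(padded))), md))
  }
})

test_that("summarize_stability reports occupancy, violations and dwell per
           trace and orders high- vs low-switching kinetics", {
  wt_spec <- two_well_regime(seed = NULL)        # frequent excursions
  va_spec <- two_well_regime(p_out = 0.01, p_in = 0.09, seed = NULL)
  traces <- list(); meta <- list()
  for (k in 1:3) {
    wt_spec$seed <- 100 + k; va_spec$seed <- 200 + k
    traces[[k]] <- classify_states(sample_regime(wt_spec)$series)
    traces[[3 + k]] <- classify_states(sample_regime(va_spec)$series)
    meta[[k]] <- data.frame(variant = "WT", condition = "pH2", replicate = k)
    meta[[3 + k]] <- data.frame(variant = "V277A", condition = "pH2",
                                replicate = k)
  }
  sm <- summarize_stability(traces, do.call(rbind, meta))
  expect_equal(nrow(sm$per_trace), 6)
  wt_viol <- sm$by_group$mean_violations[sm$by_group$variant == "WT"]
  va_viol <- sm$by_group$mean_violations[sm$by_group$variant == "V277A"]
  expect_gt(wt_viol, va_viol)
  wt_occ <- sm$by_group$native_occupancy[sm$by_group$variant == "WT"]
  va_occ <- sm$by_group$native_occupancy[sm$by_group$variant == "V277A"]
  expect_lt(wt_occ, va_occ)

  single <- summarize_stability(list(
    classify_states(series_from_angles(rep(190, 100)))))
  expect_equal(single$per_trace$native_occupancy, 1)
  expect_equal(single$per_trace$n_violations, 0)
})

test_that("matched seeds give reproducible stability summaries", {
  spec <- two_well_regime(seed = 77)
  s1 <- summarize_stability(list(classify_states(sample_regime(spec)$series)))
  s2 <- summarize_stability(list(classify_states(sample_regime(spec)$series)))
  expect_identical(s1$per_trace$n_violations, s2$per_trace$n_violations)
  expect_identical(s1$per_trace$native_occupancy, s2$per_trace$native_occupancy)
})
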