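test_that("make_density builds unit-area histograms with delta and flat cases", {
  # 100 identical angles: one occupied bin of height 1/binwidth
  d <- make_density(stack_angles(series_from_angles(rep(190, 100))), 5)
  expect_equal(sum(d$heights * d$binwidth), 1)
  expect_equal(sum(d$heights > 0), 1)
  expect_equal(max(d$heights), 1 / 5)

  # uniform grid: flat density, unit area
  grid <- seq(0, 359.5, by = 0.5)
  du <- make_density(stack_angles(series_from_angles(grid),
                                  window_start = 0), 5)
  expect_equal(sum(du$heights * du$binwidth), 1)
  expect_lt(max(du$heights) - min(du$heights), 1e-12)

  expect_error(make_density(stack_angles(series_from_angles(1:10)), 7),
               class = "chisno_config_error")
})

test_that("the density mode localizes a von Mises well", {
  set.seed(5)
  ang <- rvonmises(20000, 190, 1 / (9 * pi / 180)^2)
  d <- make_density(stack_angles(series_from_angles(ang)), 5)
  mode_bin <- which.max(d$heights)
  expect_true(d$edges[mode_bin] <= 190 && 190 <= d$edges[mode_bin + 1])
})

test_that("S_NO is 0 for identical, 1 for disjoint, 0.5 for half-overlapping
           uniforms", {
  p <- density_from_counts(c(2, 3, 0, 0, 1, 0, 4, 2))
  expect_equal(sno(p, p), 0)

  left <- density_from_counts(c(5, 5, 5, 5, 0, 0, 0, 0))
  right <- density_from_counts(c(0, 0, 0, 0, 5, 5, 5, 5))
  expect_equal(sno(left, right), 1)

  # uniform on [0,180) vs uniform on [90,270): overlap coefficient 1/2
  u1 <- density_from_counts(c(1, 1, 1, 1, 0, 0, 0, 0))
  u2 <- density_from_counts(c(0, 0, 1, 1, 1, 1, 0, 0))
  expect_equal(sno(u1, u2), 0.5)
})

test_that("S_NO equals one minus the overlap coefficient on random
           histograms and is symmetric and bounded", {
  set.seed(21)
  for (i in 1:200) {
    nb <- sample(2:8, 1)
    bw <- 360 / nb
    cp <- pmax(rpois(nb, 2), c(1, rep(0, nb - 1)))  # at least one frame
    cq <- pmax(rpois(nb, 2), c(1, rep(0, nb - 1)))
    p <- density_from_counts(cp, binwidth = bw)
    q <- density_from_counts(cq, binwidth = bw)
    v <- sno(p, q)
    oracle <- 1 - sum(pmin(p$heights, q$heights)) * bw
    expect_equal(v, oracle, tolerance = 1e-12)
    expect_equal(v, sno(q, p))
    expect_gte(v, 0)
    expect_lte(v, 1)
  }
})

test_that("S_NO of the two catalytic-histidine wells matches the analytic
           overlap integral", {
  # in-site 190 +/- 9 vs out-of-site 285 +/- 12: quadrature of min(f, g)
  f <- function(t) pmin(vm_density_deg(t, 190, 9), vm_density_deg(t, 285, 12))
  ovl <- integrate(f, 0, 360, subdivisions = 2000, rel.tol = 1e-8)$value
  expected <- 1 - ovl
  expect_gt(expected, 0.99)  # wells separated far beyond their spreads

  set.seed(31)
  a <- series_from_angles(rvonmises(20000, 190, 1 / (9 * pi / 180)^2))
  b <- series_from_angles(rvonmises(20000, 285, 1 / (12 * pi / 180)^2))
  expect_equal(pair_sno(a, b, binwidth = 5), expected, tolerance = 0.01)
})

test_that("S_NO requires a common binning", {
  p <- density_from_counts(c(1, 1, 1, 1, 1, 1, 1, 1), binwidth = 45)
  q <- density_from_counts(rep(1, 4), binwidth = 90)
  expect_error(sno(p, q), class = "chisno_binning_error")
  q2 <- density_from_counts(c(1, 1, 1, 1, 1, 1, 1, 1), binwidth = 45,
                            window_start = 10)
  expect_error(sno(p, q2), class = "chisno_binning_error")
})

test_that("S_NO is invariant under a common rotation, within binning
           tolerance", {
  set.seed(41)
  a0 <- rvonmises(4000, 190, 1 / (9 * pi / 180)^2)
  b0 <- rvonmises(4000, 240, 1 / (12 * pi / 180)^2)
  base <- pair_sno(series_from_angles(a0), series_from_angles(b0))
  for (delta in c(37, 118.5, 263)) {
    rot <- pair_sno(series_from_angles((a0 + delta) %% 360),
                    series_from_angles((b0 + delta) %% 360))
    expect_equal(rot, base, tolerance = 0.05)
  }
})

test_that("halving the binwidth moves S_NO by less than 0.05 on smooth data", {
  set.seed(51)
  a <- series_from_angles(rvonmises(10000, 190, 1 / (9 * pi / 180)^2))
  b <- series_from_angles(rvonmises(10000, 230, 1 / (12 * pi / 180)^2))
  expect_lt(abs(pair_sno(a, b, 5) - pair_sno(a, b, 2.5)), 0.05)
})

test_that("pairwise_sno honors pairing modes and flags mismatches", {
  s <- sample_regime(single_well_regime(n_frames = 200, seed = 1))$series
  one <- list(`275` = list(s))
  tab <- pairwise_sno(one, one)
  expect_equal(unname(tab$values[1, 1]), 0)
  expect_equal(dim(tab$values), c(1, 1))

  reps_a <- lapply(1:3, function(k)
    sample_regime(single_well_regime(n_frames = 200, seed = k))$series)
  reps_b <- lapply(4:6, function(k)
    sample_regime(single_well_regime(n_frames = 200, seed = k))$series)
  tab9 <- pairwise_sno(list(`275` = reps_a), list(`275` = reps_b),
                       pairing = "all_pairs")
  expect_equal(ncol(tab9$values), 9)
  expect_true(all(tab9$values >= 0 & tab9$values <= 1))

  expect_error(pairwise_sno(list(`275` = reps_a),
                            list(`275` = reps_b[1:2])),
               class = "chisno_pairing_error")
})

test_that("responsive residues outscore unresponsive ones in every matched
           pair", {
  ds <- make_study_set(n_residues = 2, responsive_ids = 1, base_seed = 5)
  tab <- pairwise_sno(condition_series(ds, "pH7"), condition_series(ds, "pH2"))
  resp <- tab$values[as.character(1) == rownames(tab$values), ]
  flat <- tab$values[as.character(2) == rownames(tab$values), ]
  expect_true(all(resp > max(flat)))
})

test_that("select_responsive applies the strict >threshold, >=min_pairs rule", {
  fake_table <- function(vals) {
    structure(list(residues = seq_len(nrow(vals)),
                   residue_names = rep("HIS", nrow(vals)),
                   pairs = data.frame(rep_a = 1:3, rep_b = 1:3),
                   values = vals),
              class = "pair_sno_table")
  }
  expect_identical(select_responsive(fake_table(matrix(0, 2, 3))), integer(0))
  expect_identical(select_responsive(fake_table(rbind(c(0.6, 0.7, 0.2)))), 1L)
  expect_identical(select_responsive(fake_table(rbind(c(0.6, 0.4, 0.4)))),
                   integer(0))
  # exactly at the threshold does not count (strict inequality)
  expect_identical(select_responsive(fake_table(rbind(c(0.5, 0.5, 0.5)))),
                   integer(0))
  expect_identical(
    select_responsive(fake_table(rbind(c(0.9, 0.9, 0.9), c(0.51, 0.52, 0.1))),
                      min_pairs = 2),
    c(1L, 2L))
  expect_error(select_responsive(fake_table(matrix(0, 1, 3)), n_pairs = 4),
               class = "chisno_pairing_error")
})

test_that("aggregate_sno returns mean and sample s.d. and needs two values", {
  expect_equal(aggregate_sno(c(0.5, 0.5, 0.5)), c(mean = 0.5, sd = 0))
  expect_equal(aggregate_sno(c(0, 1)), c(mean = 0.5, sd = sqrt(0.5)),
               tolerance = 1e-12)
  v <- c(0.2, 0.6, 0.7)
  agg <- aggregate_sno(v)
  expect_gte(agg[["mean"]], min(v))
  expect_lte(agg[["mean"]], max(v))
  expect_error(aggregate_sno(0.5), class = "chisno_config_error")
})
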