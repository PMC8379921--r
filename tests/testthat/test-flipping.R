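# build a focus table realizing a given per-frame orientation sign pattern
signs_to_table <- function(signs, cell_id = 1L) {
  n <- length(signs)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    s <- signs[i]
    if (is.na(s)) next
    out[[i]] <- make_focus(cell_id, i - 1L, c("L3", "R3"),
                           if (s > 0) c(-0.5, 0.5) else c(0.5, -0.5))
  }
  data.table::rbindlist(out)
}

signs_to_cells <- function(signs, cell_id = 1L) {
  data.table::data.table(cell_id = cell_id, mother_id = NA_integer_,
                         channel = 1L, frame = seq_along(signs) - 1L,
                         time_min = (seq_along(signs) - 1) * 10,
                         length_um = 3, end_low_um = 0, end_high_um = 3)
}

test_that("debounced flip detection matches the stated cases", {
  cases <- list(
    list(s = c(1, 1, 1, -1, -1, -1), flips = 1L),          # clean flip
    list(s = c(1, -1, 1, 1, 1), flips = 0L),               # transient rejected
    list(s = c(1, 1, -1, -1, 1, 1), flips = 2L),           # there and back
    list(s = c(1, 1, NA, NA, -1, -1), flips = 1L),         # short gap bridged
    list(s = c(1, 1, NA, NA, NA, -1, -1), flips = 0L),     # long gap censors
    list(s = c(-1, -1, -1, -1), flips = 0L))               # no change
  for (cs in cases) {
    tr <- orientation_trace(signs_to_table(cs$s), signs_to_cells(cs$s),
                            persistence = 2, max_gap = 2)
    expect_equal(nrow(tr$flips), cs$flips, info = paste(cs$s, collapse = ","))
  }
  # flip counts invariant under global sign convention flip
  s <- c(1, 1, -1, -1, 1, 1, 1, -1, -1)
  t1 <- orientation_trace(signs_to_table(s), signs_to_cells(s))
  t2 <- orientation_trace(signs_to_table(-s), signs_to_cells(-s))
  expect_equal(nrow(t1$flips), nrow(t2$flips))
  # debounced count never exceeds the raw sign-change count
  set.seed(11)
  for (i in 1:20) {
    s <- sample(c(-1, 1), 12, replace = TRUE)
    raw <- sum(diff(s) != 0)
    tr <- orientation_trace(signs_to_table(s), signs_to_cells(s))
    expect_lte(nrow(tr$flips), raw)
  }
})

test_that("traces recover ground-truth flips from ideal simulated detection", {
  sim <- dmatp_mm_sim()
  tr <- orientation_trace(sim$focus_table, sim$cell_table)
  f <- build_forest(sim$cell_table, 10)
  fpc <- flips_per_cycle(tr, f, "pre_duplication")
  tc <- sim$truth_cells[!is.na(mother_id) & !is.na(division_frame)]
  cmp <- merge(fpc$per_cycle, tc[, .(cell_id, n_flips_pre)], by = "cell_id")
  expect_gt(nrow(cmp), 300)
  expect_gt(mean(cmp$N == cmp$n_flips_pre), 0.97)
  # duplication frames close to truth
  d <- merge(tr$dup, sim$truth_cells[, .(cell_id, dup_frame_true = dup_frame)],
             by = "cell_id")
  d <- d[!is.na(dup_frame) & !is.na(dup_frame_true)]
  expect_gt(mean(abs(d$dup_frame - d$dup_frame_true) <= 1), 0.95)
})

test_that("flip probability vs length recovers flat and sloped hazards", {
  # constant hazard -> flat profile
  flat <- strain_preset("flat", "mechanistic", flip_hazard_base = 0.003,
                        flip_hazard_length_slope = 0, p_translational = 1)
  sf <- simulate_experiment(flat, "mother_machine", 40, 2160, 10, seed = 51)
  trf <- orientation_trace(sf$focus_table, sf$cell_table)
  pf <- flip_probability_vs_length(trf, sf$cell_table, length_bin = 0.4)
  pf <- pf[n_frames > 500]
  expect_gt(nrow(pf), 2)
  # debounce-corrected oracle: a flip is observed only if the new sign holds
  # for `persistence` further frames, so the detected per-frame probability
  # is h*dt*(1 - h*dt)^persistence (plus a small end-of-window loss)
  h_obs <- 0.003 * 10 * (1 - 0.003 * 10)^2
  for (i in seq_len(nrow(pf))) {
    se <- sqrt(h_obs / pf$n_frames[i])
    expect_lt(abs(pf$probability[i] - h_obs), 4 * se + 0.002)
  }
  # linear hazard doubling by duplication -> end/start ratio ~ 2
  stp <- preset("deltaMatP", mode = "mechanistic")
  ss <- simulate_experiment(stp, "mother_machine", 60, 2160, 10, seed = 52)
  trs <- orientation_trace(ss$focus_table, ss$cell_table)
  ps <- flip_probability_vs_length(trs, ss$cell_table, length_bin = 0.4)
  ps <- ps[n_frames > 1000 & n_flips > 0]
  ratio <- ps$probability[nrow(ps)] / ps$probability[1]
  expect_gt(ratio, 1.3)
  expect_lt(ratio, 3.2)
  # no flips -> all-zero profile
  none <- strain_preset("none", "mechanistic", flip_hazard_base = 0,
                        flip_hazard_length_slope = 0, p_translational = 1)
  sn <- simulate_experiment(none, "mother_machine", 5, 1200, 10, seed = 53)
  trn <- orientation_trace(sn$focus_table, sn$cell_table)
  pn <- flip_probability_vs_length(trn, sn$cell_table)
  expect_true(all(pn$probability == 0))
})

test_that("mother-daughter retention: faithful limit and parameter recovery", {
  faithful <- strain_preset("faithful", "phenomenological",
                            p_orientation_retained_mother_daughter = 1,
                            p_lrlr = 1, flips_per_cycle_mean = 0,
                            p_postdup_change = 0)
  sf <- simulate_experiment(faithful, "mother_machine", 10, 1500, 10, seed = 54)
  f <- build_forest(sf$cell_table, 10)
  tr <- orientation_trace(sf$focus_table, sf$cell_table)
  mdr <- mother_daughter_retention(f, sf$focus_table, tr)
  expect_equal(mdr$fraction, 1)
  # WT preset recovery within 3 binomial SE
  sim <- wt_mm_sim()
  fw <- build_forest(sim$cell_table, 10)
  trw <- orientation_trace(sim$focus_table, sim$cell_table)
  mw <- mother_daughter_retention(fw, sim$focus_table, trw)
  p0 <- preset("WT")$p_orientation_retained_mother_daughter
  expect_lt(abs(mw$fraction - p0), 3 * sqrt(p0 * (1 - p0) / mw$n_pairs))
})

test_that("post-duplication stability: stable limit and parameter recovery", {
  stable <- strain_preset("stable", "phenomenological", p_postdup_change = 0)
  ss <- simulate_experiment(stable, "mother_machine", 8, 1500, 10, seed = 55)
  f <- build_forest(ss$cell_table, 10)
  tr <- orientation_trace(ss$focus_table, ss$cell_table)
  expect_equal(post_duplication_stability(tr, ss$focus_table, f)$fraction_stable, 1)
  # a preset with frequent post-duplication changes is detected
  wobbly <- strain_preset("wobbly", "phenomenological", p_postdup_change = 0.3)
  sw <- simulate_experiment(wobbly, "mother_machine", 25, 1500, 10, seed = 56)
  fw <- build_forest(sw$cell_table, 10)
  trw <- orientation_trace(sw$focus_table, sw$cell_table)
  r <- post_duplication_stability(trw, sw$focus_table, fw)
  se <- sqrt(0.7 * 0.3 / r$n_cycles)
  # the detector requires the change to persist and to fit before division,
  # so a small shortfall against the raw parameter is expected; assert the
  # recovered change rate is in the right range
  expect_gt(1 - r$fraction_stable, 0.3 - 4 * se - 0.05)
  expect_lt(1 - r$fraction_stable, 0.3 + 4 * se)
})
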