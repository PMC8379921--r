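test_that("orient_cells applies the sign rule with deterministic ties", {
  ft <- make_focus(1L, 0L, c("L3", "R3"), c(0.4, -0.2))
  o <- orient_cells(ft, "L3_negative")
  expect_equal(unique(o$orient_sign), -1L)
  expect_equal(o[marker == "L3", position_oriented], -0.4)
  # L3 exactly at 0 -> sign +1 (tie rule)
  o0 <- orient_cells(make_focus(1L, 0L, c("L3", "R3"), c(0, 0.3)))
  expect_equal(unique(o0$orient_sign), 1L)
  # cells lacking the reference marker are flagged unoriented
  onr <- orient_cells(make_focus(1L, 0L, "R3", 0.3))
  expect_false(any(onr$oriented))
  # property: after orientation the reference marker mean is <= 0 everywhere
  sim <- wt_mm_sim()
  ori <- orient_cells(sim$focus_table, "L3_negative")
  ref <- ori[marker == "L3" & oriented == TRUE,
             .(m = mean(position_oriented)), by = .(cell_id, frame)]
  expect_true(all(ref$m <= 0))
})

test_that("demograph bins, normalizes per column, and rejects bad rows", {
  d1 <- demograph(0.1, 3.0)
  expect_equal(max(d1$matrix), 1)
  expect_equal(sum(d1$matrix), 1)
  # positions beyond half-length are rejected with a tally
  d2 <- demograph(c(0.1, 5), c(3, 3))
  expect_equal(d2$n_rejected, 1L)
  # column with zero counts stays zero; normalization is idempotent
  set.seed(1)
  pos <- runif(5000, -1.4, 1.4); len <- rep(3, 5000)
  d3 <- demograph(pos, len, normalize = TRUE)
  nonempty <- colSums(d3$matrix) > 0
  expect_true(all(apply(d3$matrix[, nonempty, drop = FALSE], 2, max) == 1))
  expect_true(all(d3$matrix[, !nonempty] == 0))
  expect_equal(normalize_demograph_matrix(d3$matrix), d3$matrix)
  # uniform positions give near-flat columns: no normalized bin far below
  # the multinomial-noise floor
  main <- d3$matrix[abs(d3$pos_edges[-1] - 0.025) < 1.3, nonempty]
  expect_gt(min(main), 0.4)
  # TSV export round-trips the matrix
  f <- tempfile(fileext = ".tsv")
  write_demograph(d3, f)
  back <- data.table::fread(f, sep = "\t")
  expect_equal(as.matrix(back[, -1]), d3$matrix, ignore_attr = TRUE)
  unlink(f)
})

test_that("arm distance is exact on constructed cases and excludes multi-focus cells", {
  ft <- rbind(make_focus(1L, 0L, c("L3", "R3"), c(-0.8, 0.7)),
              make_focus(2L, 0L, c("L3", "R3"), c(0.2, 0.2)),
              make_focus(3L, 0L, c("L3", "L3", "R3"), c(-0.5, 0.5, 0.1)))
  ad <- arm_distance(ft)
  expect_equal(sort(ad$distances$distance_um), c(0, 1.5))
  expect_equal(ad$n_excluded, 1L)
  # deltaMatP preset with halved arm offsets: distance ratio ~2 against an
  # identical preset at full scale (recovery of the configured scale)
  half <- strain_preset("half", "phenomenological", arm_half_scale = 0.5,
                        p_opposite_halves = 0.978)
  full <- strain_preset("full", "phenomenological", arm_half_scale = 1,
                        p_opposite_halves = 0.978)
  sh <- simulate_experiment(half, "mother_machine", 10, 1500, 10, seed = 41)
  sf <- simulate_experiment(full, "mother_machine", 10, 1500, 10, seed = 42)
  ratio <- arm_distance(sf$focus_table)$mean / arm_distance(sh$focus_table)$mean
  expect_lt(abs(ratio - 2), 0.15)
})

test_that("opposite-halves fraction handles ties and recovers its parameter", {
  ft <- rbind(make_focus(1L, 0L, c("L3", "R3"), c(-0.3, 0.3)),
              make_focus(2L, 0L, c("L3", "R3"), c(-0.2, -0.4)))
  r <- opposite_halves_fraction(ft)
  expect_equal(r$fraction, 0.5)
  # a focus exactly at 0 with no previous frame goes to the negative half
  ft0 <- make_focus(1L, 0L, c("L3", "R3"), c(0, -0.4))
  expect_false(opposite_halves_fraction(ft0)$table$opposite)
  # invariance under global sign flip (orientation rule choice)
  sim <- wt_mm_sim()
  sub <- sim$focus_table[marker %in% c("L3", "R3")]
  flip <- data.table::copy(sub)[, position_um := -position_um]
  expect_equal(opposite_halves_fraction(sub)$fraction,
               opposite_halves_fraction(flip)$fraction)
})

test_that("configuration classifier matches the definitional cases", {
  tr <- make_focus(1L, 0L, c("L3", "R3", "L3", "R3"), c(-0.9, -0.4, 0.3, 0.8))
  mi <- make_focus(2L, 0L, c("L3", "R3", "R3", "L3"), c(-0.9, -0.4, 0.3, 0.8))
  cc <- classify_configuration(rbind(tr, mi))
  expect_equal(cc[cell_id == 1, label], "TRANSLATIONAL")
  expect_equal(cc[cell_id == 1, identity], 1L)
  expect_equal(cc[cell_id == 2, label], "MIRROR")
  # tie within the 10 nm position resolution -> UNDETERMINED
  tie <- make_focus(3L, 0L, c("L3", "R3", "L3", "R3"),
                    c(-0.9, -0.4, 0.3, 0.305))
  expect_equal(classify_configuration(tie)$label, "UNDETERMINED")
  # 3 foci of one marker -> UNDETERMINED, tallied
  tri <- make_focus(4L, 0L, c("L3", "L3", "L3", "R3", "R3"),
                    c(-0.9, -0.4, 0.3, 0.1, 0.8))
  expect_equal(classify_configuration(tri)$label, "UNDETERMINED")
  # invariance under global sign flip
  flipped <- data.table::copy(rbind(tr, mi))[, position_um := -position_um]
  cf <- classify_configuration(flipped)
  expect_equal(cf[cell_id == 1, label], "TRANSLATIONAL")
  expect_equal(cf[cell_id == 1, identity], -1L)
  expect_equal(cf[cell_id == 2, label], "MIRROR")
})

test_that("random sister orientations give 50 percent translational calls", {
  # brute-force oracle: two sisters choose arm order independently and
  # fairly; of the 4 equally likely stacked arrangements (LR|LR, LR|RL,
  # RL|LR, RL|RL) exactly 2 read L-R-L-R or R-L-R-L
  orders <- expand.grid(bottom = c("LR", "RL"), top = c("LR", "RL"),
                        stringsAsFactors = FALSE)
  seqs <- paste0(orders$bottom, orders$top)
  oracle <- mean(seqs %in% c("LRLR", "RLRL"))
  expect_equal(oracle, 0.5)
  # simulation with independent fair sister orientations reproduces it
  set.seed(7)
  n <- 4000
  pick <- sample(seqs, n, replace = TRUE)
  ft <- data.table::data.table(
    cell_id = rep(seq_len(n), each = 4), frame = 0L,
    marker = ifelse(unlist(strsplit(pick, "")) == "L", "L3", "R3"),
    position_um = rep(c(-0.9, -0.4, 0.3, 0.8), n), intensity = 1000)
  cc <- classify_configuration(ft)
  p <- mean(cc$label == "TRANSLATIONAL")
  expect_lt(abs(p - 0.5), 3 * sqrt(0.25 / n))
  expect_true(all(cc$label %in% c("TRANSLATIONAL", "MIRROR")))
})
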