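#' @import data.table
NULL

# Truncated normal via rejection-free clamping of rare tails; adequate for the
# small jitters used here (truncation at ~2 sd of the stated noise).
.rtnorm <- function(n, mean = 0, sd = 1, lo = -Inf, hi = Inf) {
  pmin(pmax(rnorm(n, mean, sd), lo), hi)
}

.other_end <- function(end) ifelse(end == "low", "high", "low")

#' Simulate a mother-machine or agarose-pad time-lapse experiment
#'
#' Generates tracked-cell and fluorescent-focus tables with full ground truth
#' for one strain preset.  Cells grow exponentially and divide near midcell
#' with Gaussian septum noise; divisions create two age-0 poles at the septum
#' while the distal poles age by one generation; chromosome replication,
#' orientation flipping, sister-segregation choice, semiconservative strand
#' bookkeeping, optional pulse labeling, polar chemoreceptor (Tsr)
#' intensities, and the observation model (position jitter, focus merging
#' below the diffraction limit, detection misses) are applied per frame.
#'
#' Layouts: `"mother_machine"` keeps the cell at the closed channel end
#' indefinitely and tracks its sibling for `daughter_track_frames` frames
#' before washout; `"pad"` retains the complete division tree.
#'
#' Determinism: each lineage consumes an independent substream seeded from
#' `seed` and the lineage index, so increasing `n_lineages` extends the
#' output without reshuffling existing lineages.
#'
#' @param preset a [strain_preset].
#' @param layout `"mother_machine"` or `"pad"`.
#' @param n_lineages number of channels (mother machine) or founder cells
#'   (pad).
#' @param duration total simulated time, minutes; must be at least two mean
#'   generation times.
#' @param frame_interval imaging interval, minutes (default 5 for the mother
#'   machine, 10 for the pad).
#' @param seed integer root seed.
#' @param daughter_track_frames frames a washed-out sibling remains observed.
#' @param edu_pulse `NULL`, or `list(start, duration)` in minutes: strands
#'   synthesized while the pulse is active are labeled (see
#'   [apply_edu_pulse_chase]).
#' @return A `sim_output` object: `cell_table` (cell_id, mother_id, channel,
#'   frame, time_min, length_um, end_low_um, end_high_um), `focus_table`
#'   (cell_id, frame, marker, position_um, intensity), `truth_cells` (one row
#'   per cell cycle with all latent state), `truth_frames` (per cell per
#'   frame phase and orientation), and the call parameters.
#' @examples
#' sim <- simulate_experiment(preset("WT"), "mother_machine",
#'                            n_lineages = 2, duration = 700,
#'                            frame_interval = 5, seed = 1)
#' nrow(sim$cell_table)
#' @export
simulate_experiment <- function(preset, layout = c("mother_machine", "pad"),
                                n_lineages = 1, duration = NULL,
                                frame_interval = NULL, seed = 1,
                                daughter_track_frames = 8, edu_pulse = NULL) {
  layout <- match.arg(layout)
  validate_preset(preset)
  if (is.null(frame_interval))
    frame_interval <- if (layout == "mother_machine") 5 else 10
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stop("frame_interval must be > 0")
  if (is.null(duration)) duration <- 4 * preset$generation_time_mean
  if (duration < 2 * preset$generation_time_mean)
    stop("duration must be at least 2 * generation_time_mean (",
         2 * preset$generation_time_mean, " min)")
  if (!is.numeric(n_lineages) || n_lineages < 1) stop("n_lineages must be >= 1")
  if (!is.null(edu_pulse)) {
    if (!is.list(edu_pulse) || is.null(edu_pulse$start) || is.null(edu_pulse$duration))
      stop("edu_pulse must be list(start, duration)")
    if (edu_pulse$duration <= 0) stop("edu_pulse duration must be > 0")
    if (edu_pulse$start < 0 || edu_pulse$start + edu_pulse$duration > duration)
      stop("edu_pulse window outside simulation duration")
  }
  out <- vector("list", n_lineages)
  for (l in seq_len(n_lineages)) {
    set.seed((as.integer(seed) %% 1000003L) * 2011L + 7919L * l)
    out[[l]] <- .sim_lineage(preset, layout, l, duration, frame_interval,
                             daughter_track_frames, edu_pulse)
  }
  cell_table <- rbindlist(lapply(out, `[[`, "cells"))
  # a cell whose mother divided before recording started has no resolvable
  # mother in the emitted table: emit it as a root, like a real tracker would
  if (nrow(cell_table))
    cell_table[!mother_id %in% unique(cell_id), mother_id := NA_integer_]
  res <- list(
    cell_table  = cell_table,
    focus_table = rbindlist(lapply(out, `[[`, "foci")),
    truth_cells = rbindlist(lapply(out, `[[`, "truth_cells")),
    truth_frames = rbindlist(lapply(out, `[[`, "truth_frames")),
    params = list(preset = preset, layout = layout, n_lineages = n_lineages,
                  duration = duration, frame_interval = frame_interval,
                  seed = seed, daughter_track_frames = daughter_track_frames,
                  edu_pulse = edu_pulse)
  )
  class(res) <- "sim_output"
  res
}

#' @export
print.sim_output <- function(x, ...) {
  p <- x$params
  cat("<sim_output> preset=", p$preset$name, " [", p$preset$mode, "] layout=",
      p$layout, "\n  lineages=", p$n_lineages, " duration=", p$duration,
      " min, frame interval=", p$frame_interval, " min, seed=", p$seed, "\n",
      "  cells=", nrow(x$truth_cells), " cell-frames=", nrow(x$cell_table),
      " foci=", nrow(x$focus_table),
      if (!is.null(p$edu_pulse)) sprintf("  [pulse %g+%g min]",
                                         p$edu_pulse$start, p$edu_pulse$duration),
      "\n", sep = "")
  invisible(x)
}

#' Apply a pulse-chase labeling protocol to a simulated experiment
#'
#' Re-runs the stored simulation call with a label pulse active during
#' `[pulse_start, pulse_start + pulse_duration)`.  Because every latent draw
#' in the simulator is made unconditionally, the lineages, divisions and all
#' non-label observables are identical to the input simulation; only the
#' label bookkeeping and the resulting nucleoid-label (EdU channel) foci are
#' added.  Strands synthesized while the pulse is active are flagged; after
#' one further replication round exactly one of a cell's two sister
#' nucleoids carries the label, and label foci are emitted only for labeled
#' nucleoids (alongside the DAPI nucleoid channel).
#'
#' @param sim a `sim_output` from [simulate_experiment].
#' @param pulse_start pulse onset, minutes.
#' @param pulse_duration pulse length, minutes (> 0).
#' @param chase_duration label-free growth after the pulse, minutes; must be
#'   at least one mean generation time, and the simulation must cover
#'   `pulse_start + pulse_duration + chase_duration`.
#' @return a new `sim_output` with the label channel populated and a
#'   `scoring_frame` element (the frame at the end of the chase).
#' @export
apply_edu_pulse_chase <- function(sim, pulse_start, pulse_duration,
                                  chase_duration) {
  stopifnot(inherits(sim, "sim_output"))
  p <- sim$params
  if (pulse_duration <= 0) stop("pulse_duration must be > 0")
  if (chase_duration < p$preset$generation_time_mean)
    stop("chase_duration must cover at least one mean generation time")
  t_end <- pulse_start + pulse_duration + chase_duration
  if (pulse_start < 0 || t_end > p$duration)
    stop("pulse window outside simulation duration: needs ", t_end,
         " min, simulation has ", p$duration)
  out <- simulate_experiment(p$preset, p$layout, p$n_lineages, p$duration,
                             p$frame_interval, p$seed,
                             p$daughter_track_frames,
                             edu_pulse = list(start = pulse_start,
                                              duration = pulse_duration))
  out$scoring_frame <- floor(t_end / p$frame_interval)
  out
}

# ---------------------------------------------------------------------------
# One lineage: cycle-level engine, then frame expansion and focus emission.
# All randomness for the lineage is consumed here in deterministic order.
.sim_lineage <- function(preset, layout, lineage, duration, dt,
                         daughter_frames, pulse) {
  mech <- preset$mode == "mechanistic"
  gmean <- preset$generation_time_mean
  Lb0 <- preset$birth_length_mean
  dupf <- .marker_dup_frac[["L3"]]
  bF <- .phase_fracs[["B"]]; cF <- .phase_fracs[["C"]]
  max_cells <- 20000L

  cells <- list()
  nid <- 0L
  new_id <- function() { nid <<- nid + 1L; lineage * 100000L + nid }

  # founder: a cell at a random point of its cycle (asynchronous population),
  # with a hidden pre-history pole age; its birth predates the recording
  founder <- list(id = new_id(), mother_id = NA_integer_, key = 0.5, w = 1,
                  birth_time = -runif(1, 0, 0.95) * gmean,
                  birth_length = Lb0 * exp(.rtnorm(1, 0, 0.07, -0.2, 0.2)),
                  old_end = sample(c("low", "high"), 1),
                  old_age = 1L + rgeom(1, 0.5), pole_known = FALSE,
                  o_birth = sample(c(-1L, 1L), 1), n_chrom = 1L,
                  binucleate_born = FALSE, anucleate = FALSE,
                  s1_age = 1L + rgeom(1, 0.5), s2_age = 0L,
                  s1_edu = FALSE, s2_edu = FALSE,
                  s1b_age = NA_integer_, s2b_age = NA_integer_,
                  s1b_edu = FALSE, s2b_edu = FALSE,
                  edu_gen = NA_integer_, mother_line = TRUE,
                  censor_time = duration)
  queue <- list(founder)
  done <- list()

  while (length(queue) > 0 && length(done) < max_cells) {
    cell <- queue[[1]]; queue <- queue[-1]
    cyc <- .sim_cycle(cell, preset, layout, duration, dt, daughter_frames,
                      pulse, mech, dupf, bF, cF, Lb0)
    done[[length(done) + 1L]] <- cyc$record
    for (d in cyc$daughters) {
      d$id <- new_id()
      if (d$birth_time < duration - dt) queue[[length(queue) + 1L]] <- d
    }
  }

  .expand_lineage(done, preset, lineage, duration, dt, pulse, mech)
}

# Simulate one cell cycle: division timing, flip schedule, configuration,
# segregation and strand bookkeeping.  Returns the cycle record plus the
# daughter seeds (possibly none: censored or anucleate cells).
.sim_cycle <- function(cell, preset, layout, duration, dt, daughter_frames,
                       pulse, mech, dupf, bF, cF, Lb0) {
  rec <- cell
  birth_frame <- ceiling(cell$birth_time / dt)
  rec$birth_frame <- as.integer(birth_frame)

  if (cell$anucleate) {
    # non-growing, never divides, observed until its censor time
    rec[c("gen_time", "growth_rate", "death_time")] <- list(NA_real_, 0, Inf)
    rec[c("dup_time", "dup_frame", "n_flips_pre", "flip_frames")] <-
      list(NA_real_, NA_integer_, NA_integer_, list(integer()))
    rec[c("config_trans", "config_id_dup", "postdup_changed", "change_frame",
          "config_final")] <- list(NA, NA_integer_, NA, NA_integer_, NA_integer_)
    rec[c("anuc_division", "anuc_side", "frac_low", "ori_merged")] <-
      list(FALSE, NA_character_, NA_real_, NA)
    rec[c("opp_draw", "same_side", "mL", "mR")] <-
      list(NA, NA_integer_, NA_real_, NA_real_)
    rec[c("ret_draw", "anc_side", "ancestral_at_old_pole", "edu_side")] <-
      list(NA, NA_character_, NA, NA_character_)
    rec <- .tsr_cycle(rec, preset, mech)
    rec$division_frame <- NA_integer_
    return(list(record = rec, daughters = list()))
  }

  gsd <- preset$generation_time_sd
  Tg <- .rtnorm(1, preset$generation_time_mean, gsd,
                max(4 * dt, preset$generation_time_mean - 3 * gsd,
                    0.3 * preset$generation_time_mean),
                preset$generation_time_mean + 3 * gsd)
  if (cell$binucleate_born) Tg <- Tg * preset$binucleate_gen_time_factor
  Ldiv <- 2 * Lb0 * exp(.rtnorm(1, 0, 0.04, -0.12, 0.12))
  r <- log(Ldiv / cell$birth_length) / Tg
  death <- cell$birth_time + Tg
  division_frame <- as.integer(ceiling(death / dt))
  dup_time <- cell$birth_time + dupf * Tg
  dup_frame <- as.integer(ceiling(dup_time / dt))

  rec$gen_time <- Tg; rec$growth_rate <- r; rec$death_time <- death
  rec$dup_time <- dup_time; rec$dup_frame <- dup_frame
  rec$division_frame <- division_frame

  # --- orientation flips prior to arm-locus duplication -------------------
  if (mech) {
    fr <- seq.int(birth_frame + 1L, max(birth_frame, dup_frame - 1L))
    if (length(fr) && fr[1] > birth_frame) {
      len <- cell$birth_length * exp(r * (fr * dt - cell$birth_time))
      hz <- pmax(0, preset$flip_hazard_base +
                   preset$flip_hazard_length_slope * (len - Lb0))
      hit <- rbinom(length(fr), 1, pmin(1, hz * dt)) == 1
      flips <- fr[hit]
    } else flips <- integer()
  } else {
    k <- rpois(1, preset$flips_per_cycle_mean)
    lo <- birth_frame + 1L; hi <- dup_frame - 2L
    adm <- if (hi >= lo) seq.int(lo, hi) else integer()
    m <- length(adm)
    kmax <- if (m == 0) 0L else as.integer(floor((m + 1) / 2))
    k <- min(k, kmax)
    if (k > 0) {
      # k frames from adm with pairwise spacing >= 2
      x <- sort(sample.int(m - (k - 1L), k))
      flips <- adm[x + seq_len(k) - 1L]
    } else flips <- integer()
  }
  rec$n_flips_pre <- length(flips)
  rec$flip_frames <- list(as.integer(flips))
  o_dup <- cell$o_birth * (-1L)^length(flips)

  # --- post-duplication configuration -------------------------------------
  trans <- if (mech) rbinom(1, 1, preset$p_translational) == 1
           else rbinom(1, 1, preset$p_lrlr) == 1
  pchg <- if (mech) 0 else preset$p_postdup_change
  changed <- rbinom(1, 1, pchg) == 1
  chg_lo <- dup_frame + 1L; chg_hi <- division_frame - 2L
  change_frame <- if (changed && chg_hi >= chg_lo)
    as.integer(sample(seq.int(chg_lo, chg_hi), 1)) else NA_integer_
  changed <- !is.na(change_frame)
  config_final <- o_dup * if (changed) -1L else 1L
  rec$config_trans <- trans; rec$config_id_dup <- o_dup
  rec$postdup_changed <- changed; rec$change_frame <- change_frame
  rec$config_final <- config_final

  # --- single-focus L3/R3 geometry draws ----------------------------------
  rec$opp_draw <- if (mech) TRUE else rbinom(1, 1, preset$p_opposite_halves) == 1
  rec$same_side <- sample(c(-1L, 1L), 1)
  rec$mL <- runif(1, 0.10, 0.40); rec$mR <- runif(1, 0.10, 0.40)

  # --- anucleate / septum placement ---------------------------------------
  p_an <- if (cell$binucleate_born) preset$p_anucleate_given_binucleate
          else preset$p_anucleate
  anuc <- rbinom(1, 1, p_an) == 1
  new_end <- .other_end(cell$old_end)
  anuc_new <- rbinom(1, 1, preset$p_anucleate_newpole) == 1  # drawn always
  anuc_side <- if (anuc) (if (anuc_new) new_end else cell$old_end)
               else NA_character_
  if (anuc) {
    fa <- .rtnorm(1, preset$anucleate_daughter_frac, preset$anucleate_frac_sd,
                  0.3, 0.7)
    frac_low <- if (anuc_side == "low") fa else 1 - fa
  } else {
    frac_low <- 0.5 + .rtnorm(1, 0, preset$division_asymmetry_sd, -0.25, 0.25) / Ldiv
  }
  rec$anuc_division <- anuc; rec$anuc_side <- anuc_side; rec$frac_low <- frac_low
  rec$ori_merged <- rbinom(1, 1, if (anuc) preset$p_ori_single_anucleate
                                 else preset$p_ori_single_normal) == 1

  # --- strand bookkeeping and segregation ---------------------------------
  rep_start <- cell$birth_time + bF * Tg
  rep_end <- cell$birth_time + (bF + cF) * Tg
  labeled_now <- !is.null(pulse) &&
    (pulse$start < rep_end) && (pulse$start + pulse$duration > rep_start)

  ret_draw <- rbinom(1, 1, if (mech) 0.5 else preset$p_retention_old_pole) == 1

  if (cell$n_chrom == 1L) {
    # sisters: A = (s1 template, new), B = (s2 template, new); strand ages
    # advance at replication (rounds survived), so templates strictly
    # outrank the age-0 strand they just primed
    A <- list(t_age = cell$s1_age + 1L, t_edu = cell$s1_edu,
              n_age = 0L, n_edu = labeled_now)
    B <- list(t_age = cell$s2_age + 1L, t_edu = cell$s2_edu,
              n_age = 0L, n_edu = labeled_now)
    if (mech) {
      # Translational symmetric segregation preserves strand-polarity
      # continuity: the sister templated by the older strand returns to the
      # old-pole half, and every orientation flip of the nucleoid inverts
      # that polarity.  Mirror segregation breaks the symmetry: coin flip.
      if (trans) {
        even <- length(flips) %% 2L == 0L
        anc_side <- if (even) cell$old_end else new_end
        a_low <- (anc_side == "low")      # A holds the older template
      } else {
        a_low <- rbinom(1, 1, 0.5) == 1
        anc_side <- if (a_low) "low" else "high"
      }
      low_sis <- if (a_low) A else B; high_sis <- if (a_low) B else A
    } else {
      anc_side <- if (ret_draw) cell$old_end else new_end
      a_low <- (anc_side == "low")
      low_sis <- if (a_low) A else B; high_sis <- if (a_low) B else A
    }
  } else {
    # binucleate: each daughter resolves one duplex (no further replication
    # before resolution -- documented simplification)
    A <- list(t_age = cell$s1_age, t_edu = cell$s1_edu,
              n_age = cell$s2_age, n_edu = cell$s2_edu)
    B <- list(t_age = cell$s1b_age, t_edu = cell$s1b_edu,
              n_age = cell$s2b_age, n_edu = cell$s2b_edu)
    a_low <- rbinom(1, 1, 0.5) == 1
    low_sis <- if (a_low) A else B; high_sis <- if (a_low) B else A
    anc_side <- if (a_low == (max(A$t_age, A$n_age, na.rm = TRUE) >=
                              max(B$t_age, B$n_age, na.rm = TRUE))) "low" else "high"
  }
  rec$ret_draw <- ret_draw
  rec$anc_side <- anc_side
  rec$ancestral_at_old_pole <- (anc_side == cell$old_end)

  # --- pulse label lineage (phenomenological token) -----------------------
  if (mech) {
    edu_low <- isTRUE(low_sis$t_edu) || isTRUE(low_sis$n_edu)
    edu_high <- isTRUE(high_sis$t_edu) || isTRUE(high_sis$n_edu)
    edu_side <- if (edu_low && !edu_high) "low"
                else if (edu_high && !edu_low) "high"
                else if (edu_low && edu_high) "both" else NA_character_
    rec$edu_gen <- NA_integer_
  } else {
    gen <- cell$edu_gen
    if (labeled_now && is.na(gen)) gen <- 0L
    rec$edu_gen <- gen
    edu_side <- if (is.na(gen)) NA_character_
                else if (gen == 0L) "both"
                else if (gen == 1L) .other_end(anc_side)  # label on newer template
                else anc_side
  }
  rec$edu_side <- edu_side

  rec <- .tsr_cycle(rec, preset, mech)

  # --- daughters ----------------------------------------------------------
  if (death >= duration || death >= cell$censor_time)
    return(list(record = .censor(rec), daughters = list()))

  ret_d <- rbinom(2, 1, if (mech) 1
                  else preset$p_orientation_retained_mother_daughter) == 1
  rand_o <- sample(c(-1L, 1L), 2, replace = TRUE)
  o_low <- if (mech) { if (trans) config_final else config_final }
           else if (trans) config_final * (if (ret_d[1]) 1L else -1L)
           else rand_o[1]
  o_high <- if (mech) { if (trans) config_final else -config_final }
            else if (trans) config_final * (if (ret_d[2]) 1L else -1L)
            else rand_o[2]

  make_d <- function(side) {
    Llow <- Ldiv * frac_low
    is_low <- side == "low"
    anuc_d <- anuc && !is.na(anuc_side) && anuc_side == side
    sis <- if (is_low) low_sis else high_sis
    d <- list(
      mother_id = rec$id, key = cell$key + (if (is_low) -1 else 1) * cell$w / 4,
      w = cell$w / 2, birth_time = death,
      birth_length = if (is_low) Llow else Ldiv - Llow,
      old_end = if (is_low) "low" else "high",
      old_age = (if (is_low) .pole_age(cell, "low") else .pole_age(cell, "high")) + 1L,
      pole_known = TRUE,
      o_birth = if (is_low) o_low else o_high,
      n_chrom = if (anuc_d) 0L else if (anuc) 2L else 1L,
      binucleate_born = (!anuc_d) && anuc, anucleate = anuc_d,
      s1_age = NA_integer_, s2_age = NA_integer_,
      s1_edu = FALSE, s2_edu = FALSE,
      s1b_age = NA_integer_, s2b_age = NA_integer_,
      s1b_edu = FALSE, s2b_edu = FALSE,
      edu_gen = NA_integer_, mother_line = FALSE, censor_time = duration)
    if (d$n_chrom >= 1L) {
      d$s1_age <- sis$t_age; d$s2_age <- sis$n_age
      d$s1_edu <- isTRUE(sis$t_edu); d$s2_edu <- isTRUE(sis$n_edu)
    }
    if (d$n_chrom == 2L) {
      other <- if (is_low) high_sis else low_sis
      d$s1b_age <- other$t_age; d$s2b_age <- other$n_age
      d$s1b_edu <- isTRUE(other$t_edu); d$s2b_edu <- isTRUE(other$n_edu)
    }
    if (!mech && !is.na(rec$edu_gen)) {
      g <- rec$edu_gen
      if (g == 0L) d$edu_gen <- 1L
      else if (!is.na(edu_side) && edu_side == side) d$edu_gen <- g + 1L
    }
    d
  }
  dl <- make_d("low"); dh <- make_d("high")

  if (layout == "mother_machine") {
    if (cell$mother_line) {
      dl$mother_line <- TRUE
      dh$censor_time <- min(duration, death + daughter_frames * dt)
      dh$mother_line <- FALSE
    } else {
      # washed-out branch: should not divide within its tracking window
      dl$censor_time <- dh$censor_time <- death
    }
  }
  daughters <- Filter(function(d) d$censor_time > d$birth_time + dt,
                      list(dl, dh))
  list(record = rec, daughters = daughters)
}

.pole_age <- function(cell, end) {
  if (cell$old_end == end) cell$old_age else 0L
}

.censor <- function(rec) {
  rec$death_time <- Inf
  rec$division_frame <- NA_integer_
  rec$anuc_division <- FALSE; rec$anuc_side <- NA_character_
  rec
}

# Polar chemoreceptor intensities for one cycle.  Phenomenological mode uses
# the direct accuracy parameter (rank swap with prob 1 - p_tsr_correct);
# mechanistic mode adds Gaussian noise to the linear pole-age model.
.tsr_cycle <- function(rec, preset, mech) {
  age_low <- .pole_age(rec, "low"); age_high <- .pole_age(rec, "high")
  base <- preset$tsr_baseline; rate <- preset$tsr_rate
  if (mech) {
    I_low <- base + rate * age_low + rnorm(1, 0, preset$tsr_noise_sd)
    I_high <- base + rate * age_high + rnorm(1, 0, preset$tsr_noise_sd)
    correct <- (age_low > age_high) == (I_low > I_high)
  } else {
    jit <- .rtnorm(2, 0, min(2, rate / 10), -rate / 3, rate / 3)
    Io <- base + rate * max(age_low, age_high) + jit[1]
    In <- base + rate * min(age_low, age_high) + jit[2]
    if (Io <= In) Io <- In + rate / 2
    swap <- rbinom(1, 1, 1 - preset$p_tsr_correct) == 1
    old_is_low <- rec$old_end == "low"
    I_low <- if (old_is_low != swap) Io else In
    I_high <- if (old_is_low != swap) In else Io
    correct <- !swap
  }
  rec$tsr_I_low <- I_low; rec$tsr_I_high <- I_high; rec$tsr_correct <- correct
  rec
}
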