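# Frame expansion and the focus observation model for one lineage.
# Everything here is vectorized over the lineage's cell-frames; all RNG is
# consumed inside the per-lineage substream opened by simulate_experiment().

.expand_lineage <- function(recs, preset, lineage, duration, dt, pulse, mech) {
  n_frames <- floor(duration / dt)           # frame indices 0 .. n_frames
  tc <- .records_to_dt(recs, lineage)

  # observed frame window per cell
  end_f <- pmin(ifelse(is.na(tc$division_frame), n_frames,
                       tc$division_frame - 1L),
                ceiling(tc$censor_time / dt) - 1L, n_frames)
  start_f <- pmax(0L, tc$birth_frame)   # founder birth predates the recording
  nobs <- pmax(0L, end_f - start_f + 1L)
  obs <- tc[rep(seq_len(nrow(tc)), nobs)]
  obs[, frame := unlist(lapply(which(nobs > 0),
                               function(i) seq.int(start_f[i], end_f[i])),
                        use.names = FALSE)]
  if (nrow(obs) == 0) return(.empty_lineage(tc, lineage))
  obs[, time_min := frame * dt]
  obs[, length_um := ifelse(anucleate, birth_length,
                            birth_length * exp(growth_rate * (time_min - birth_time)))]
  obs[, u := ifelse(anucleate, NA_real_, (time_min - birth_time) / gen_time)]

  # orientation / configuration per frame
  flip_dt <- tc[n_flips_pre > 0 & !anucleate,
                .(flip_frame = as.integer(unlist(flip_frames))), by = cell_id]
  obs[, n_flips_before := 0L]
  if (nrow(flip_dt)) {
    cnt <- flip_dt[obs, on = .(cell_id, flip_frame <= frame), .N,
                   by = .EACHI]$N
    obs[, n_flips_before := cnt]
  }
  obs[, orient := ifelse(anucleate, NA_integer_, as.integer(
        ifelse(binucleate_born, config_final,
        ifelse(!is.na(dup_frame) & frame >= dup_frame,
               ifelse(postdup_changed & frame >= change_frame,
                      config_final, config_id_dup),
               o_birth * (-1L)^n_flips_before))))]
  obs[, n_nuc := ifelse(anucleate, 0L,
                 ifelse(binucleate_born | (!is.na(u) & u >= 0.70), 2L, 1L))]
  obs[, phase := ifelse(anucleate, NA_character_,
                 ifelse(binucleate_born, "D",
                 ifelse(u < 0.25, "B", ifelse(u < 0.70, "C", "D"))))]

  # channel geometry: stack cells bottom-up in key order
  setorder(obs, frame, key)
  obs[, end_high_um := cumsum(length_um), by = frame]
  obs[, end_low_um := end_high_um - length_um]
  setorder(obs, cell_id, frame)

  foci <- .emit_foci(obs, preset, mech)
  foci <- .observe_foci(foci, obs, preset)

  cells <- obs[, .(cell_id, mother_id, channel = lineage, frame, time_min,
                   length_um, end_low_um, end_high_um)]
  truth_frames <- obs[, .(cell_id, frame, phase, orientation = orient,
                          n_nucleoids = n_nuc, length_um)]
  tc[, flip_frames := vapply(flip_frames, paste, "", collapse = ",")]
  tc[, channel := lineage]
  list(cells = cells, foci = foci, truth_cells = tc,
       truth_frames = truth_frames)
}

.records_to_dt <- function(recs, lineage) {
  scal <- lapply(recs, function(r) {
    r$flip_frames <- NULL
    r[!vapply(r, is.list, TRUE)]
  })
  tc <- rbindlist(scal, fill = TRUE)
  setnames(tc, "id", "cell_id")
  tc[, flip_frames := lapply(recs, function(r) r$flip_frames[[1]])]
  tc
}

.empty_lineage <- function(tc, lineage) {
  tc[, flip_frames := vapply(flip_frames, paste, "", collapse = ",")]
  tc[, channel := lineage]
  list(cells = data.table(cell_id = integer(), mother_id = integer(),
                          channel = integer(), frame = integer(),
                          time_min = numeric(), length_um = numeric(),
                          end_low_um = numeric(), end_high_um = numeric()),
       foci = data.table(cell_id = integer(), frame = integer(),
                         marker = character(), position_um = numeric(),
                         intensity = numeric()),
       truth_cells = tc,
       truth_frames = data.table(cell_id = integer(), frame = integer(),
                                 phase = character(), orientation = integer(),
                                 n_nucleoids = integer(), length_um = numeric()))
}

# --- true focus emission ---------------------------------------------------

.emit_foci <- function(obs, preset, mech) {
  out <- list()
  add <- function(id, frame, marker, pos, L) {
    out[[length(out) + 1L]] <<- data.table(
      cell_id = id, frame = frame, marker = marker,
      position_um = pmin(pmax(pos, -L / 2 + 0.005), L / 2 - 0.005))
  }
  scl <- preset$arm_half_scale
  jit <- function(n, sd, cap) .rtnorm(n, 0, sd, -cap, cap)

  ## arm loci, single-focus stage -----------------------------------------
  s1 <- obs[!anucleate & n_chrom == 1L & !binucleate_born & frame < dup_frame]
  if (nrow(s1)) {
    L <- s1$length_um; o <- s1$orient
    m_lo <- ifelse(s1$opp_draw, s1$mL,
                   0.10 + (pmin(s1$mL, s1$mR) - 0.10) * 0.27) * scl
    m_hi <- ifelse(s1$opp_draw, s1$mR,
                   0.24 + (pmax(s1$mL, s1$mR) - 0.10) * 0.53) * scl
    sideA <- ifelse(s1$opp_draw, -1, s1$same_side)
    sideB <- ifelse(s1$opp_draw, 1, s1$same_side)
    pA <- sideA * ifelse(s1$opp_draw | s1$same_side < 0, m_hi, m_lo) * L
    pB <- sideB * ifelse(s1$opp_draw | s1$same_side < 0, m_lo, m_hi) * L
    # enforce pA < pB, then map: orientation +1 puts L3 at the lower slot
    lo <- pmin(pA, pB); hi <- pmax(pA, pB)
    jl <- jit(nrow(s1), 0.008 * scl, 0.018 * scl) * L
    jh <- jit(nrow(s1), 0.008 * scl, 0.018 * scl) * L
    add(s1$cell_id, s1$frame, "L3", ifelse(o == 1L, lo + jl, hi + jh), L)
    add(s1$cell_id, s1$frame, "R3", ifelse(o == 1L, hi + jh, lo + jl), L)
  }

  ## arm loci, duplicated (2+2) stage ---------------------------------------
  s2 <- obs[!anucleate & n_chrom >= 1L &
              (binucleate_born | (!is.na(dup_frame) & frame >= dup_frame))]
  if (nrow(s2)) {
    L <- s2$length_um; cid <- s2$orient; tr <- s2$config_trans
    tr[is.na(tr)] <- TRUE
    slots <- c(-0.375, -0.125, 0.125, 0.375)
    for (k in 1:4) {
      mk <- .slot_marker(k, cid, tr)
      pos <- slots[k] * L * scl + jit(nrow(s2), 0.012 * scl, 0.030 * scl) * L
      add(s2$cell_id[mk == "L3"], s2$frame[mk == "L3"], "L3",
          pos[mk == "L3"], L[mk == "L3"])
      add(s2$cell_id[mk == "R3"], s2$frame[mk == "R3"], "R3",
          pos[mk == "R3"], L[mk == "R3"])
    }
  }

  ## replication origin ----------------------------------------------------
  o1 <- obs[!anucleate & n_chrom == 1L & !binucleate_born & u < 0.25]
  if (nrow(o1))
    add(o1$cell_id, o1$frame, "ori1",
        jit(nrow(o1), 0.05, 0.15) * o1$length_um, o1$length_um)
  o2 <- obs[!anucleate & n_chrom == 1L & !binucleate_born & u >= 0.25]
  if (nrow(o2)) {
    L <- o2$length_um
    sep <- ifelse(o2$ori_merged, 0.12,
                  pmax(0.12, 0.55 * L * (o2$u - 0.25) / 0.75))
    ctr <- jit(nrow(o2), 0.04, 0.10) * L
    add(o2$cell_id, o2$frame, "ori1", ctr - sep / 2, L)
    add(o2$cell_id, o2$frame, "ori1", ctr + sep / 2, L)
  }
  ob <- obs[!anucleate & binucleate_born]
  if (nrow(ob)) {
    L <- ob$length_um
    add(ob$cell_id, ob$frame, "ori1", -0.25 * L + jit(nrow(ob), 0.04, 0.1) * L, L)
    add(ob$cell_id, ob$frame, "ori1",  0.25 * L + jit(nrow(ob), 0.04, 0.1) * L, L)
  }

  ## terminus region: migrates from the new pole to midcell ----------------
  t1 <- obs[!anucleate & n_chrom >= 1L]
  if (nrow(t1)) {
    L <- t1$length_um
    sgn_new <- ifelse(t1$old_end == "low", 1, -1)
    mag <- pmax(0.02, 0.35 - 0.45 * pmin(ifelse(is.na(t1$u), 0.5, t1$u), 0.75))
    add(t1$cell_id, t1$frame, "ter3",
        sgn_new * mag * L + jit(nrow(t1), 0.05, 0.12) * L, L)
  }

  ## replisome (DnaQ), helicase (DnaB), clamp (DnaN) -----------------------
  rp <- obs[!anucleate & n_chrom == 1L & !binucleate_born & phase == "C"]
  if (nrow(rp)) {
    L <- rp$length_um
    d_half <- L * (0.10 + 0.5 * (rp$u - 0.25))
    keep <- d_half >= 0.5 & 0.47 * L > 0.52
    rp <- rp[keep]; L <- L[keep]; d_half <- d_half[keep]
    if (nrow(rp)) {
      p_col <- preset$p_colocal %||% 0.588
      co <- preset$colocal_offset
      for (sgn in c(-1, 1)) {
        q <- sgn * pmin(pmax(d_half + jit(nrow(rp), 0.08, 0.18), 0.5),
                        0.47 * L)
        add(rp$cell_id, rp$frame, "DnaQ", q, L)
        add(rp$cell_id, rp$frame, "DnaB",
            q + jit(nrow(rp), 0.04, 0.10), L)
        coloc <- rbinom(nrow(rp), 1, p_col) == 1
        delta <- .rtnorm(nrow(rp), 0, co$coloc_sd, -co$coloc_cap, co$coloc_cap)
        # displaced clamps sit near midcell (the lagging strands are directed
        # to the cell center), in [0.16, min(0.40, |q| - 0.31)] um from it:
        # the floor keeps the cell's two DnaN foci outside one merge radius,
        # and the 0.31 offset (with the 0.5 um fork-separation gate) keeps
        # their distance to every replisome focus beyond the 0.3 um
        # diffraction threshold, so the colocal mixture is observed exactly.
        u_ctr <- runif(nrow(rp), 0.16, pmin(0.40, abs(q) - 0.31))
        add(rp$cell_id, rp$frame, "DnaN",
            ifelse(coloc, q + delta, sign(q) * u_ctr), L)
      }
    }
  }

  ## nucleoids (DAPI) -------------------------------------------------------
  d1 <- obs[!anucleate & n_nuc == 1L]
  if (nrow(d1))
    add(d1$cell_id, d1$frame, "DAPI",
        jit(nrow(d1), 0.04, 0.10) * d1$length_um, d1$length_um)
  d2 <- obs[!anucleate & n_nuc == 2L]
  if (nrow(d2)) {
    L <- d2$length_um
    add(d2$cell_id, d2$frame, "DAPI", -0.25 * L + jit(nrow(d2), 0.03, 0.07) * L, L)
    add(d2$cell_id, d2$frame, "DAPI",  0.25 * L + jit(nrow(d2), 0.03, 0.07) * L, L)
  }

  ## pulse label foci on labeled nucleoids ----------------------------------
  ed <- obs[!anucleate & n_nuc == 2L & !is.na(edu_side)]
  if (nrow(ed)) {
    for (side in c("low", "high")) {
      e <- ed[edu_side == side | edu_side == "both"]
      if (nrow(e)) {
        ctr <- (if (side == "low") -0.25 else 0.25) * e$length_um
        add(e$cell_id, e$frame, "EdU", ctr - 0.07 * e$length_um, e$length_um)
        add(e$cell_id, e$frame, "EdU", ctr + 0.07 * e$length_um, e$length_um)
      }
    }
  }

  ## polar chemoreceptor intensities ----------------------------------------
  ts <- obs[anucleate == FALSE]
  if (nrow(ts)) {
    L <- ts$length_um
    jlo <- jit(nrow(ts), 0.5, 1.5); jhi <- jit(nrow(ts), 0.5, 1.5)
    tsr <- data.table(
      cell_id = rep(ts$cell_id, 2L), frame = rep(ts$frame, 2L),
      marker = "Tsr",
      position_um = c(-L / 2, L / 2),
      intensity = c(ts$tsr_I_low + jlo, ts$tsr_I_high + jhi))
    out[[length(out) + 1L]] <- tsr
  }

  foci <- rbindlist(out, fill = TRUE)
  if (!"intensity" %in% names(foci)) foci[, intensity := NA_real_]
  foci[is.na(intensity),
       intensity := .rtnorm(sum(is.na(intensity)), 1000, 100, 500, 1500)]
  foci
}

# marker occupying stacked slot k (bottom-up) for configuration id `cid`
# (+1: left arm at the lowest slot) and arrangement `tr` (TRUE translational):
# cid = +1 gives L,R,L,R (translational) or L,R,R,L (mirror); cid = -1 swaps
# the arms, giving R,L,R,L / R,L,L,R.
.slot_marker <- function(k, cid, tr) {
  base <- ifelse(tr, c("L3", "R3", "L3", "R3")[k], c("L3", "R3", "R3", "L3")[k])
  ifelse(cid == 1L, base, ifelse(base == "L3", "R3", "L3"))
}

# --- detection: misses, then diffraction-limited merging -------------------

.observe_foci <- function(foci, obs, preset) {
  if (nrow(foci) == 0) return(foci)
  if (preset$detection_miss_rate > 0) {
    keep <- rbinom(nrow(foci), 1, 1 - preset$detection_miss_rate) == 1
    keep[foci$marker == "Tsr"] <- TRUE   # pole intensities are not point foci
    foci <- foci[keep]
  }
  pt <- foci[marker != "Tsr"]
  tsr <- foci[marker == "Tsr"]
  if (nrow(pt)) {
    setorder(pt, cell_id, frame, marker, position_um)
    pt[, gap := position_um - shift(position_um, fill = -Inf),
       by = .(cell_id, frame, marker)]
    pt[, cluster := cumsum(gap >= preset$merge_radius | is.infinite(gap))]
    pt <- pt[, .(position_um = sum(position_um * intensity) / sum(intensity),
                 intensity = sum(intensity)),
             by = .(cell_id, frame, marker, cluster)][, cluster := NULL]
  }
  res <- rbindlist(list(pt, tsr), use.names = TRUE, fill = TRUE)
  setorder(res, cell_id, frame, marker, position_um)
  res[]
}

#' Write a simulated experiment to CSV
#'
#' Emits `cell_table.csv`, `focus_table.csv`, `truth_cells.csv` and
#' `truth_frames.csv` (UTF-8, "." decimal, header row; positions in
#' micrometres, times in minutes, 0-based frame indices) plus
#' `params.json` describing the generating call.
#'
#' @param sim a `sim_output`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_sim_output <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_output"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fwrite(sim$cell_table, file.path(dir, "cell_table.csv"))
  fwrite(sim$focus_table, file.path(dir, "focus_table.csv"))
  fwrite(sim$truth_cells, file.path(dir, "truth_cells.csv"))
  fwrite(sim$truth_frames, file.path(dir, "truth_frames.csv"))
  pj <- sim$params
  pj$preset <- unclass(pj$preset)
  jsonlite::write_json(pj, file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
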