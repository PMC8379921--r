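#' Per-cell orientation traces with debounced flip detection
#'
#' The chromosome orientation of a cell-frame is `sign(pos(R3) - pos(L3))`
#' when both arm markers show exactly one focus, and `UNDEFINED` (NA)
#' otherwise.  A sign change counts as a flip only when the new sign
#' persists for at least `persistence` consecutive frames (debouncing
#' against detection noise).  Gaps of undefined orientation up to `max_gap`
#' frames do not break a flip if the flanking signs differ; longer gaps
#' censor the interval.  The duplication frame of the arm loci is the first
#' frame opening a run of at least `persistence` frames in which a marker
#' shows two or more foci.
#'
#' Cells in which both markers are observed in fewer than half of the
#' frames are excluded and tallied.
#'
#' @param focus_table focus observations.
#' @param cell_table tracked-cell table (provides the frame range and length
#'   per cell-frame).
#' @param persistence frames a new state must persist (default 2).
#' @param max_gap longest bridged undefined gap (default 2).
#' @param markers the two arm markers.
#' @return an `orientation_traces` object: `signs` (cell_id, frame, sign),
#'   `flips` (cell_id, frame, length_um, pre_duplication), `dup` (cell_id,
#'   dup_frame), `n_excluded`.
#' @export
orientation_trace <- function(focus_table, cell_table, persistence = 2,
                              max_gap = 2, markers = c("L3", "R3")) {
  ft <- as.data.table(focus_table)
  ct <- as.data.table(cell_table)
  sub <- ft[marker %in% markers]
  per <- sub[, .(nL = sum(marker == markers[1]),
                 nR = sum(marker == markers[2]),
                 pL = mean(position_um[marker == markers[1]]),
                 pR = mean(position_um[marker == markers[2]])),
             by = .(cell_id, frame)]
  frames <- ct[, .(cell_id, frame, length_um)]
  per <- merge(frames, per, by = c("cell_id", "frame"), all.x = TRUE)
  per[, sign := ifelse(!is.na(nL) & nL == 1L & nR == 1L,
                       sign(pR - pL), NA_real_)]
  per[!is.na(sign) & sign == 0, sign := NA_real_]

  cover <- per[, .(frac = mean(!is.na(nL) & nL >= 1L & nR >= 1L), .N),
               by = cell_id]
  keep <- cover[frac >= 0.5, cell_id]
  n_excluded <- nrow(cover) - length(keep)
  per <- per[cell_id %in% keep]
  setorder(per, cell_id, frame)

  # duplication frame: first frame of a persistent >=2-focus run
  per[, two := !is.na(nL) & (nL >= 2L | nR >= 2L)]
  dup <- per[, .(dup_frame = .persistent_onset(two, frame, persistence)),
             by = cell_id]

  fl <- per[, .debounce_flips(sign, frame, length_um, persistence, max_gap),
            by = cell_id]
  fl <- merge(fl, dup, by = "cell_id", all.x = TRUE)
  fl[, pre_duplication := is.na(dup_frame) | frame < dup_frame]
  structure(list(signs = per[, .(cell_id, frame, sign)],
                 flips = fl[, .(cell_id, frame, length_um, pre_duplication)],
                 dup = dup, n_excluded = n_excluded,
                 persistence = persistence),
            class = "orientation_traces")
}

#' @export
print.orientation_traces <- function(x, ...) {
  cat("<orientation_traces> ", length(unique(x$signs$cell_id)), " cells, ",
      nrow(x$flips), " flips (", sum(x$flips$pre_duplication),
      " pre-duplication); excluded cells: ", x$n_excluded, "\n", sep = "")
  invisible(x)
}

# first frame index opening a run of >= persistence TRUEs; NA if none
.persistent_onset <- function(flag, frame, persistence) {
  if (!any(flag)) return(NA_integer_)
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  i <- which(r$values & r$lengths >= persistence)
  if (!length(i)) return(NA_integer_)
  frame[ends[i[1]] - r$lengths[i[1]] + 1L]
}

# debounced sign-change detection over one cell's trace
.debounce_flips <- function(sgn, frame, len, persistence, max_gap) {
  def <- which(!is.na(sgn))
  out <- list(frame = integer(), length_um = numeric())
  if (length(def) < 2) return(out)
  cur <- sgn[def[1]]
  i <- 2L
  while (i <= length(def)) {
    j <- def[i]
    gap <- frame[j] - frame[def[i - 1L]] - 1L
    if (gap > max_gap) {           # censored interval: reset without a flip
      cur <- sgn[j]
      i <- i + 1L
      next
    }
    if (sgn[j] != cur) {
      # persistence: the new sign must hold for `persistence` consecutive
      # defined frames with contiguous frame indices
      run <- 1L
      k <- i
      while (k < length(def) && run < persistence) {
        if (frame[def[k + 1L]] == frame[def[k]] + 1L &&
            sgn[def[k + 1L]] == sgn[j]) {
          run <- run + 1L; k <- k + 1L
        } else break
      }
      if (run >= persistence) {
        out$frame <- c(out$frame, frame[j])
        out$length_um <- c(out$length_um, len[j])
        cur <- sgn[j]
      }
      # a rejected transient does not update the current sign
    }
    i <- i + 1L
  }
  out
}

#' Mean orientation flips per cell cycle
#'
#' Counts debounced flips per complete cell cycle, optionally restricted to
#' the window before arm-locus duplication.
#'
#' @param traces an [orientation_trace] result.
#' @param forest a [build_forest] result (defines complete cycles: observed
#'   birth and division).
#' @param scope `"pre_duplication"` or `"full"`.
#' @return list with `mean`, `sd` (across cycles), `se` (Monte-Carlo SE of
#'   the mean), `n_cycles`, and `per_cycle` counts.
#' @export
flips_per_cycle <- function(traces, forest,
                            scope = c("pre_duplication", "full")) {
  scope <- match.arg(scope)
  stopifnot(inherits(traces, "orientation_traces"),
            inherits(forest, "lineage_forest"))
  complete <- forest$cells[!is.na(mother_id) & divided == TRUE, cell_id]
  traced <- intersect(complete, unique(traces$signs$cell_id))
  if (length(traced) == 0)
    return(list(mean = NA_real_, sd = NA_real_, se = NA_real_,
                n_cycles = 0L, per_cycle = data.table()))
  fl <- traces$flips
  if (scope == "pre_duplication") fl <- fl[pre_duplication == TRUE]
  cnt <- fl[cell_id %in% traced, .N, by = cell_id]
  per <- data.table(cell_id = traced)
  per <- merge(per, cnt, by = "cell_id", all.x = TRUE)
  per[is.na(N), N := 0L]
  m <- mean(per$N); s <- sd(per$N)
  list(mean = m, sd = s, se = s / sqrt(nrow(per)), n_cycles = nrow(per),
       per_cycle = per[])
}

#' Flip probability as a function of cell length
#'
#' Per length bin, the number of flip events divided by the number of
#' observed cell-frames in that bin: a per-observation hazard estimate.
#' Empty bins are reported as missing, not zero.
#'
#' @param traces an [orientation_trace] result.
#' @param cell_table tracked-cell table (cell-frame lengths).
#' @param length_bin bin width in micrometres.
#' @param scope restrict to pre-duplication flips (default) or all.
#' @return data.table: `bin_mid`, `n_flips`, `n_frames`, `probability`.
#' @export
flip_probability_vs_length <- function(traces, cell_table, length_bin = 0.25,
                                       scope = c("pre_duplication", "full")) {
  scope <- match.arg(scope)
  stopifnot(length_bin > 0)
  ct <- as.data.table(cell_table)
  fl <- traces$flips
  if (scope == "pre_duplication") fl <- fl[pre_duplication == TRUE]
  brk <- function(x) floor(x / length_bin)
  frames <- ct[cell_id %in% unique(traces$signs$cell_id)]
  if (scope == "pre_duplication") {
    # denominator: only frames in which a flip could still occur
    frames <- merge(frames, traces$dup, by = "cell_id", all.x = TRUE)
    frames <- frames[is.na(dup_frame) | frame < dup_frame]
  }
  nf <- frames[, .(n_frames = .N), by = .(bin = brk(length_um))]
  nfl <- fl[, .(n_flips = .N), by = .(bin = brk(length_um))]
  out <- merge(nf, nfl, by = "bin", all.x = TRUE)
  out[is.na(n_flips), n_flips := 0L]
  out[, `:=`(bin_mid = (bin + 0.5) * length_bin,
             probability = n_flips / n_frames)]
  setorder(out, bin_mid)
  out[, .(bin_mid, n_flips, n_frames, probability)]
}

#' Mother-to-daughter configuration retention
#'
#' Fraction of daughters whose first determinate orientation, mapped into
#' the mother's spatial frame via the shared pole, matches the mother's last
#' pre-division translational configuration identity.  Pairs with an
#' undetermined mother configuration (mirror or unclassifiable) or no
#' determinate daughter orientation are excluded and tallied.
#'
#' @param forest a [build_forest] result.
#' @param focus_table focus observations.
#' @param traces an [orientation_trace] result (daughter orientations).
#' @param config optional precomputed [classify_configuration] table.
#' @return list with `fraction`, `se`, `n_pairs`, `n_excluded`, `pairs`.
#' @export
mother_daughter_retention <- function(forest, focus_table, traces,
                                      config = NULL) {
  stopifnot(inherits(forest, "lineage_forest"))
  cells <- forest$cells
  if (is.null(config)) config <- classify_configuration(focus_table)
  # mother's last determinate translational identity before division
  mothers <- cells[divided == TRUE, .(cell_id, last_frame)]
  mcfg <- merge(config[label == "TRANSLATIONAL"], mothers, by = "cell_id")
  mcfg <- mcfg[frame <= last_frame]
  mcfg <- mcfg[order(cell_id, -frame)][, .SD[1], by = cell_id]
  mcfg <- mcfg[, .(mother_id = cell_id, m_identity = identity)]

  # daughter's first determinate orientation
  sg <- traces$signs[!is.na(sign)]
  dfirst <- sg[order(cell_id, frame)][, .SD[1], by = cell_id]
  kids <- cells[!is.na(mother_id),
                .(cell_id, mother_id, birth_end_low, birth_end_high)]
  # spatial frame mapping: +1 when the daughter's axis runs the same way as
  # the mother's (it inherited the mother's low end as its own low end or
  # the high end as its high end)
  mg <- cells[, .(mother_id = cell_id, m_low = last_end_low,
                  m_high = last_end_high)]
  kids <- merge(kids, mg, by = "mother_id")
  kids[, mapping := ifelse(pmin(abs(birth_end_low - m_low),
                                abs(birth_end_high - m_high)) <=
                             pmin(abs(birth_end_low - m_high),
                                  abs(birth_end_high - m_low)), 1L, -1L)]

  pairs <- merge(kids[, .(cell_id, mother_id, mapping)], mcfg,
                 by = "mother_id")
  pairs <- merge(pairs, dfirst[, .(cell_id, d_sign = sign)], by = "cell_id")
  n_total <- nrow(merge(kids[, .(cell_id, mother_id)], mothers,
                        by.x = "mother_id", by.y = "cell_id"))
  pairs[, retained := (d_sign * mapping) == m_identity]
  n <- nrow(pairs); p <- mean(pairs$retained)
  list(fraction = p, se = sqrt(p * (1 - p) / max(n, 1)), n_pairs = n,
       n_excluded = n_total - n, pairs = pairs[])
}

#' Post-duplication configuration stability
#'
#' Fraction of complete cycles in which the translational configuration
#' identity does not change between arm-locus duplication and division.
#' A change must persist for at least `persistence` determinate frames to
#' count (same debouncing as the flip detector).
#'
#' @param traces an [orientation_trace] result (provides duplication
#'   frames).
#' @param focus_table focus observations.
#' @param forest a [build_forest] result.
#' @param persistence frames a changed configuration must persist.
#' @return list with `fraction_stable`, `se`, `n_cycles`, `per_cycle`.
#' @export
post_duplication_stability <- function(traces, focus_table, forest,
                                       persistence = 2) {
  stopifnot(inherits(traces, "orientation_traces"),
            inherits(forest, "lineage_forest"))
  config <- classify_configuration(focus_table)
  complete <- forest$cells[!is.na(mother_id) & divided == TRUE, cell_id]
  cfg <- config[!is.na(identity) & cell_id %in% complete]
  cfg <- merge(cfg, traces$dup, by = "cell_id")
  cfg <- cfg[!is.na(dup_frame) & frame >= dup_frame]
  if (nrow(cfg) == 0)
    return(list(fraction_stable = NA_real_, se = NA_real_, n_cycles = 0L,
                per_cycle = data.table()))
  setorder(cfg, cell_id, frame)
  per <- cfg[, {
    fl <- .debounce_flips(as.numeric(identity), frame,
                          rep(1, .N), persistence, max_gap = 2)
    list(changed = length(fl$frame) > 0)
  }, by = cell_id]
  n <- nrow(per); p <- mean(!per$changed)
  list(fraction_stable = p, se = sqrt(p * (1 - p) / max(n, 1)),
       n_cycles = n, per_cycle = per[])
}
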