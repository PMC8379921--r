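#' Call the older cell pole from polar chemoreceptor intensities
#'
#' The serine chemoreceptor (Tsr) accumulates approximately linearly with
#' pole age, so the pole with the greater summed polar intensity is called
#' older.  The margin is `|I_low - I_high| / (I_low + I_high)`; exact ties
#' give `UNDETERMINED`.
#'
#' @param focus_table focus observations containing the `tsr_marker`
#'   channel (foci at the two cell ends with intensities).
#' @param frames optional frame whitelist; the latest available frame per
#'   cell is used.
#' @param tsr_marker channel name (default `"Tsr"`).
#' @return data.table: `cell_id`, `frame`, `I_low`, `I_high`, `older_end`
#'   in {"low", "high", "UNDETERMINED"}, `margin`.
#' @export
call_older_pole <- function(focus_table, frames = NULL, tsr_marker = "Tsr") {
  ft <- as.data.table(focus_table)
  ts <- ft[marker == tsr_marker]
  if (!is.null(frames)) ts <- ts[frame %in% frames]
  if (nrow(ts) == 0)
    return(data.table(cell_id = integer(), frame = integer(),
                      I_low = numeric(), I_high = numeric(),
                      older_end = character(), margin = numeric()))
  pick <- ts[, .(frame = max(frame)), by = cell_id]
  ts <- merge(ts, pick, by = c("cell_id", "frame"))
  out <- ts[, .(I_low = intensity[which.min(position_um)],
                I_high = intensity[which.max(position_um)],
                n_pole = .N), by = .(cell_id, frame)]
  out[, older_end := ifelse(n_pole < 2 | is.na(I_low) | is.na(I_high),
                            "UNDETERMINED",
                     ifelse(I_low > I_high, "low",
                     ifelse(I_high > I_low, "high", "UNDETERMINED")))]
  out[, margin := ifelse(older_end == "UNDETERMINED", NA_real_,
                         abs(I_low - I_high) / (I_low + I_high))]
  out[, n_pole := NULL]
  out[]
}

#' Score ancestral-strand retention at the older pole
#'
#' For cells with exactly two segregated nucleoids (D period) and
#' pulse-label foci confined to exactly one of them, the cell is called
#' `ANCESTRAL_AT_OLD_POLE` when the label-free nucleoid (the one carrying
#' the ancestral template strand) lies nearer the called older pole, and
#' `ANCESTRAL_AT_NEW_POLE` otherwise.  Cells with label in both or neither
#' nucleoid, fewer or more than two nucleoids, equidistant nucleoids, or an
#' undetermined pole call are `UNDETERMINED` and tallied.
#'
#' @param focus_table focus observations containing the nucleoid
#'   (`nucleoid_marker`) and label (`label_marker`) channels.
#' @param pole_calls a [call_older_pole] table.
#' @param frame the scoring frame (typically the end of the chase); scoring
#'   uses each cell's observations at this frame.
#' @param nucleoid_marker,label_marker channel names.
#' @return list with `calls` (per-cell RetentionCall), `fraction`
#'   (ANCESTRAL_AT_OLD_POLE among determinate calls), `se`, `n`,
#'   `n_undetermined`.
#' @export
score_retention <- function(focus_table, pole_calls, frame = NULL,
                            nucleoid_marker = "DAPI", label_marker = "EdU") {
  ft <- as.data.table(focus_table)
  if (!is.null(frame)) { fr <- frame; ft <- ft[frame == fr] }
  nuc <- ft[marker == nucleoid_marker,
            .(n_nuc = .N, nuc_lo = min(position_um), nuc_hi = max(position_um)),
            by = .(cell_id, frame)]
  lab <- ft[marker == label_marker, .(cell_id, frame, lab_pos = position_um)]
  d <- merge(nuc, lab, by = c("cell_id", "frame"), all.x = TRUE)
  per <- d[, {
    if (n_nuc[1] != 2L || all(is.na(lab_pos))) {
      list(call = "UNDETERMINED", edu_nucleoid = NA_character_)
    } else {
      near_lo <- abs(lab_pos - nuc_lo[1]) < abs(lab_pos - nuc_hi[1])
      if (all(near_lo)) list(call = "SCORABLE", edu_nucleoid = "low")
      else if (all(!near_lo)) list(call = "SCORABLE", edu_nucleoid = "high")
      else list(call = "UNDETERMINED", edu_nucleoid = NA_character_)
    }
  }, by = .(cell_id, frame)]
  per <- merge(per, nuc[, .(cell_id, frame, nuc_lo, nuc_hi)],
               by = c("cell_id", "frame"))
  per <- merge(per, pole_calls[, .(cell_id, older_end)], by = "cell_id",
               all.x = TRUE)
  per[is.na(older_end), older_end := "UNDETERMINED"]
  per[, call := ifelse(call != "SCORABLE" | older_end == "UNDETERMINED",
                       "UNDETERMINED", call)]
  # nucleoid centroids: the lower-position nucleoid is strictly nearer the
  # low pole; coincident centroids are equidistant -> UNDETERMINED
  per[call == "SCORABLE" & abs(nuc_hi - nuc_lo) < 1e-9, call := "UNDETERMINED"]
  # the label-free nucleoid carries the ancestral template strand
  per[, anc_nucleoid := ifelse(edu_nucleoid == "low", "high", "low")]
  per[call == "SCORABLE",
      call := ifelse(anc_nucleoid == older_end,
                     "ANCESTRAL_AT_OLD_POLE", "ANCESTRAL_AT_NEW_POLE")]
  det <- per[call %in% c("ANCESTRAL_AT_OLD_POLE", "ANCESTRAL_AT_NEW_POLE")]
  n <- nrow(det)
  p <- if (n) mean(det$call == "ANCESTRAL_AT_OLD_POLE") else NA_real_
  list(calls = per[], fraction = p,
       se = if (n) sqrt(p * (1 - p) / n) else NA_real_, n = n,
       n_undetermined = nrow(per) - n)
}

#' Statistical assessment of a retention fraction
#'
#' Bundles the three tests used for strand-retention data: a two-tailed
#' binomial test of the pooled fraction against 0.5 (normal approximation
#' with an exact fallback for n < 100), a pooled two-proportion two-tailed
#' z-test against a reference strain, and the replicate-dispersion check
#' comparing the observed between-replicate SD with the binomial SD
#' `sqrt(p (1 - p) / n_bar)` at the mean replicate size.
#'
#' @param k successes (cells with the ancestral strand at the old pole).
#' @param n total determinate cells.
#' @param per_replicate optional numeric vector of per-replicate fractions.
#' @param per_replicate_n optional vector of per-replicate sizes.
#' @param reference_k,reference_n optional reference strain counts for the
#'   z-test.
#' @return list with `binomial` ([binomial_two_tailed] result), `z_test`
#'   (or NULL), and `dispersion` (observed_sd, binomial_sd, ratio; or NULL).
#' @export
retention_tests <- function(k, n, per_replicate = NULL,
                            per_replicate_n = NULL,
                            reference_k = NULL, reference_n = NULL) {
  stopifnot(n >= 1, k >= 0, k <= n)
  bt <- binomial_two_tailed(k, n, p0 = 0.5)
  zt <- if (!is.null(reference_k) && !is.null(reference_n))
    two_proportion_z(k, n, reference_k, reference_n) else NULL
  disp <- NULL
  if (!is.null(per_replicate) && length(per_replicate) >= 2) {
    nbar <- if (!is.null(per_replicate_n)) mean(per_replicate_n)
            else n / length(per_replicate)
    p <- k / n
    disp <- list(observed_sd = sd(per_replicate),
                 binomial_sd = sqrt(p * (1 - p) / nbar),
                 ratio = sd(per_replicate) / sqrt(p * (1 - p) / nbar))
  }
  list(binomial = bt, z_test = zt, dispersion = disp)
}
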