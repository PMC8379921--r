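#' Nearest-focus distances between two markers
#'
#' For every focus of the source marker, the 1D long-axis distance to the
#' nearest focus of the target marker in the same cell and frame.  The
#' relation is directional (source to target and target to source differ);
#' cell-frames with source foci but no target focus contribute censored
#' entries, not zeros.
#'
#' @param focus_table focus observations.
#' @param source,target marker names.
#' @param frames optional frame whitelist (e.g. replication-gated frames).
#' @return a `distance_pairs` object: `pairs` (cell_id, frame,
#'   source_position, distance_um), `source`, `target`, `n_censored`.
#' @export
nearest_distances <- function(focus_table, source, target, frames = NULL) {
  ft <- as.data.table(focus_table)
  if (!is.null(frames)) ft <- ft[frame %in% frames]
  src <- ft[marker == source, .(cell_id, frame, src_pos = position_um)]
  tgt <- ft[marker == target, .(cell_id, frame, tgt_pos = position_um)]
  if (nrow(src) == 0)
    return(structure(list(pairs = data.table(), source = source,
                          target = target, n_censored = 0L),
                     class = "distance_pairs"))
  j <- merge(src, tgt, by = c("cell_id", "frame"), allow.cartesian = TRUE,
             all.x = TRUE)
  res <- j[, .(distance_um = if (all(is.na(tgt_pos))) NA_real_
               else min(abs(src_pos - tgt_pos))),
           by = .(cell_id, frame, src_pos)]
  n_censored <- sum(is.na(res$distance_um))
  structure(list(pairs = res[!is.na(distance_um),
                             .(cell_id, frame, source_position = src_pos,
                               distance_um)],
                 source = source, target = target, n_censored = n_censored),
            class = "distance_pairs")
}

#' @export
print.distance_pairs <- function(x, ...) {
  cat("<distance_pairs> ", x$source, " -> ", x$target, ": ", nrow(x$pairs),
      " pairs, ", x$n_censored, " censored\n", sep = "")
  invisible(x)
}

#' Colocalization fraction at a distance threshold
#'
#' Fraction of nearest-focus pairs at or below `threshold` (default 0.3 um,
#' the diffraction limit), with the empirical cumulative distance
#' distribution.  Monotone nondecreasing in the threshold by construction.
#'
#' @param pairs a [nearest_distances] result.
#' @param threshold micrometres.
#' @return list with `fraction`, `se` (binomial), `n`, and `cdf`
#'   (a function: threshold -> fraction).
#' @export
colocal_fraction <- function(pairs, threshold = 0.3) {
  stopifnot(inherits(pairs, "distance_pairs"))
  d <- pairs$pairs$distance_um
  if (length(d) == 0) stop("empty pair set: colocalization undefined")
  p <- mean(d <= threshold)
  list(fraction = p, se = sqrt(p * (1 - p) / length(d)), n = length(d),
       cdf = stats::ecdf(d))
}

#' Localization profile and FWHM at selected cell lengths
#'
#' Histogram of signed focus positions for one marker over cells whose
#' length lies in `length_window`, and the full width at half maximum of
#' the (lightly smoothed) histogram obtained by linear interpolation across
#' the half-maximum crossings.  If the smoothed histogram crosses the half
#' maximum more than twice (multimodal profile) the widest span is reported
#' and flagged.
#'
#' @param focus_table focus observations (uses `position_oriented` when
#'   present).
#' @param cell_table tracked-cell table (provides cell-frame lengths).
#' @param marker focus channel.
#' @param length_window `c(min, max)` cell length in micrometres.
#' @param pos_bin histogram bin width (default 0.05 um).
#' @param smooth moving-average window in bins (default 3).
#' @return list with `mids`, `counts`, `smoothed`, `fwhm_um`, `n_foci`,
#'   `multimodal`.
#' @export
profile_at_lengths <- function(focus_table, cell_table, marker,
                               length_window = c(3.3, 3.7), pos_bin = 0.05,
                               smooth = 3) {
  stopifnot(length(length_window) == 2, length_window[1] < length_window[2])
  ft <- as.data.table(focus_table)
  ct <- as.data.table(cell_table)
  pcol <- if ("position_oriented" %in% names(ft) &&
              !all(is.na(ft$position_oriented))) "position_oriented"
          else "position_um"
  mkr <- marker
  sub <- ft[marker == mkr]
  sub[, pos := get(pcol)]
  sub <- merge(sub[!is.na(pos)], ct[, .(cell_id, frame, length_um)],
               by = c("cell_id", "frame"))
  sub <- sub[length_um >= length_window[1] & length_um <= length_window[2]]
  if (nrow(sub) == 0) stop("no foci of '", marker, "' in the length window")
  if (nrow(sub) < 100)
    warning("only ", nrow(sub), " foci in window: FWHM may be unstable")
  half_span <- length_window[2] / 2
  edges <- seq(-(ceiling(half_span / pos_bin) + 1) * pos_bin,
               (ceiling(half_span / pos_bin) + 1) * pos_bin, by = pos_bin)
  h <- hist(sub$pos, breaks = edges, plot = FALSE)
  counts <- h$counts
  sm <- if (smooth > 1)
    as.numeric(stats::filter(counts, rep(1 / smooth, smooth), sides = 2))
  else counts
  sm[is.na(sm)] <- 0
  fw <- .fwhm(h$mids, sm)
  list(mids = h$mids, counts = counts, smoothed = sm, fwhm_um = fw$width,
       n_foci = nrow(sub), multimodal = fw$multimodal)
}

#' @importFrom graphics hist
.fwhm <- function(mids, y) {
  half <- max(y) / 2
  above <- y >= half
  idx <- which(above)
  if (!length(idx)) return(list(width = NA_real_, multimodal = FALSE))
  crossings <- which(diff(above) != 0)
  interp <- function(i) {     # crossing between bins i and i+1
    mids[i] + (half - y[i]) * (mids[i + 1] - mids[i]) / (y[i + 1] - y[i])
  }
  lo <- if (above[1]) mids[1] else interp(crossings[1])
  hi <- if (above[length(above)]) mids[length(mids)]
        else interp(crossings[length(crossings)])
  list(width = hi - lo, multimodal = length(crossings) > 2)
}
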