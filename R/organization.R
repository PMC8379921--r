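#' Orient cells along the long axis by a reference marker
#'
#' Applies a per-cell-frame sign `s` in {+1, -1} to every focus position so
#' that the reference marker's mean position is at or below zero
#' (`L3_negative`: the left-arm locus toward the negative pole;
#' `ter3_negative`: the terminus toward the negative pole, used for origin
#' data).  A reference exactly at 0 keeps `s = +1` (deterministic tie rule).
#' Cell-frames lacking the reference marker are left unoriented and flagged.
#'
#' @param focus_table focus observations (`cell_id`, `frame`, `marker`,
#'   `position_um`).
#' @param rule orientation rule.
#' @return the focus table with added columns `orient_sign`, `oriented`
#'   (logical) and `position_oriented` (`NA` where unoriented).
#' @export
orient_cells <- function(focus_table, rule = c("L3_negative", "ter3_negative")) {
  rule <- match.arg(rule)
  ref <- if (rule == "L3_negative") "L3" else "ter3"
  ft <- copy(as.data.table(focus_table))
  refpos <- ft[marker == ref, .(ref_mean = mean(position_um)),
               by = .(cell_id, frame)]
  ft <- merge(ft, refpos, by = c("cell_id", "frame"), all.x = TRUE)
  ft[, orient_sign := ifelse(is.na(ref_mean), NA_integer_,
                             ifelse(ref_mean > 0, -1L, 1L))]
  ft[, oriented := !is.na(orient_sign)]
  ft[, position_oriented := orient_sign * position_um]
  ft[, ref_mean := NULL]
  ft[]
}

#' Locus demograph
#'
#' Two-dimensional histogram of signed long-axis focus positions stacked by
#' cell length, optionally max-normalized within each cell-length bin (every
#' nonempty length-bin column then has maximum exactly 1; empty columns stay
#' all-zero).  Positions outside `[-L/2, L/2]` are rejected and tallied.
#'
#' @param positions signed focus positions, micrometres.
#' @param lengths cell length for each focus, micrometres.
#' @param length_bin,pos_bin bin widths, micrometres.
#' @param normalize max-normalize each length-bin column.
#' @return a `demograph`: list with `matrix` (rows = position bins, columns
#'   = length bins), `pos_edges`, `length_edges`, `normalized`, `n_rejected`.
#' @export
demograph <- function(positions, lengths, length_bin = 0.1, pos_bin = 0.05,
                      normalize = TRUE) {
  stopifnot(length(positions) == length(lengths),
            length_bin > 0, pos_bin > 0)
  ok <- is.finite(positions) & is.finite(lengths) &
    abs(positions) <= lengths / 2
  n_rejected <- sum(!ok)
  positions <- positions[ok]; lengths <- lengths[ok]
  if (length(positions) == 0) {
    return(structure(list(matrix = matrix(0, 0, 0), pos_edges = numeric(),
                          length_edges = numeric(), normalized = normalize,
                          n_rejected = n_rejected), class = "demograph"))
  }
  le <- seq(floor(min(lengths) / length_bin) * length_bin,
            ceiling(max(lengths) / length_bin) * length_bin + length_bin,
            by = length_bin)
  pmax_ <- max(lengths) / 2
  pe <- seq(-(ceiling(pmax_ / pos_bin) + 0.5) * pos_bin,
            (ceiling(pmax_ / pos_bin) + 0.5) * pos_bin, by = pos_bin)
  li <- findInterval(lengths, le, rightmost.closed = TRUE)
  pi_ <- findInterval(positions, pe, rightmost.closed = TRUE)
  m <- matrix(0, nrow = length(pe) - 1L, ncol = length(le) - 1L)
  tab <- table(factor(pi_, levels = seq_len(nrow(m))),
               factor(li, levels = seq_len(ncol(m))))
  m[] <- as.numeric(tab)
  if (normalize) m <- normalize_demograph_matrix(m)
  structure(list(matrix = m, pos_edges = pe, length_edges = le,
                 normalized = normalize, n_rejected = n_rejected),
            class = "demograph")
}

#' @rdname demograph
#' @param m a count matrix (rows = position bins, columns = length bins).
#' @export
normalize_demograph_matrix <- function(m) {
  cm <- apply(m, 2, max)
  nz <- cm > 0
  m[, nz] <- sweep(m[, nz, drop = FALSE], 2, cm[nz], "/")
  m
}

#' @rdname demograph
#' @param x a `demograph`.
#' @param path output file; the matrix is written as TSV with position-bin
#'   midpoints as row names and length-bin midpoints as column names.
#' @export
write_demograph <- function(x, path) {
  stopifnot(inherits(x, "demograph"))
  m <- x$matrix
  out <- data.table(pos_mid = utils::head(x$pos_edges, -1) +
                      diff(x$pos_edges) / 2)
  if (ncol(m)) {
    cn <- sprintf("L%.3g", utils::head(x$length_edges, -1) +
                    diff(x$length_edges) / 2)
    out <- cbind(out, as.data.table(m))
    setnames(out, c("pos_mid", cn))
  }
  fwrite(out, path, sep = "\t")
  invisible(path)
}

#' @export
print.demograph <- function(x, ...) {
  cat("<demograph> ", nrow(x$matrix), " position bins x ", ncol(x$matrix),
      " length bins", if (x$normalized) ", column max-normalized",
      "; rejected rows: ", x$n_rejected, "\n", sep = "")
  invisible(x)
}

#' Inter-arm marker distance
#'
#' `|pos(L3) - pos(R3)|` for every cell-frame with exactly one focus of each
#' arm marker; multi-focus cell-frames are excluded and tallied.
#'
#' @param focus_table focus observations (orientation-invariant: raw or
#'   oriented positions).
#' @param markers the two arm markers.
#' @return list with `distances` (cell_id, frame, distance_um), `mean`,
#'   `sd`, `n`, `n_excluded`.
#' @export
arm_distance <- function(focus_table, markers = c("L3", "R3")) {
  ft <- as.data.table(focus_table)
  sub <- ft[marker %in% markers]
  wide <- sub[, .(n1 = sum(marker == markers[1]),
                  n2 = sum(marker == markers[2]),
                  p1 = mean(position_um[marker == markers[1]]),
                  p2 = mean(position_um[marker == markers[2]])),
              by = .(cell_id, frame)]
  good <- wide[n1 == 1L & n2 == 1L]
  d <- good[, .(cell_id, frame, distance_um = abs(p1 - p2))]
  list(distances = d[], mean = mean(d$distance_um), sd = sd(d$distance_um),
       n = nrow(d), n_excluded = nrow(wide) - nrow(d))
}

#' Fraction of cells with the two arm markers in opposite halves
#'
#' Over cell-frames with exactly one focus of each arm marker, the fraction
#' in which the markers fall on opposite sides of midcell.  A focus exactly
#' at 0 is assigned to the half it occupied in the cell's nearest previous
#' frame, else to the negative half (deterministic tie rule).  The result is
#' invariant under the orientation rule since both positions flip together.
#'
#' @param focus_table focus observations; uses `position_oriented` when
#'   present, else `position_um`.
#' @param markers the two arm markers.
#' @return list with `fraction`, `se` (binomial), `n`, and the per-cell-frame
#'   `table` (logical `opposite`).
#' @export
opposite_halves_fraction <- function(focus_table, markers = c("L3", "R3")) {
  ft <- as.data.table(focus_table)
  pcol <- if ("position_oriented" %in% names(ft) &&
              !all(is.na(ft$position_oriented))) "position_oriented"
          else "position_um"
  sub <- ft[marker %in% markers]
  sub[, pos := get(pcol)]
  sub <- sub[!is.na(pos)]
  setorder(sub, cell_id, marker, frame)
  # deterministic tie rule for a focus exactly at midcell
  sub[, half := sign(pos)]
  sub[, prev_half := shift(half), by = .(cell_id, marker)]
  sub[half == 0, half := ifelse(!is.na(prev_half) & prev_half != 0,
                                prev_half, -1)]
  wide <- sub[, .(n1 = sum(marker == markers[1]),
                  n2 = sum(marker == markers[2]),
                  h1 = half[marker == markers[1]][1],
                  h2 = half[marker == markers[2]][1]),
              by = .(cell_id, frame)]
  good <- wide[n1 == 1L & n2 == 1L]
  good[, opposite := h1 != h2]
  n <- nrow(good); p <- mean(good$opposite)
  list(fraction = p, se = sqrt(p * (1 - p) / max(n, 1)), n = n,
       table = good[, .(cell_id, frame, opposite)])
}

#' Classify the sister-chromosome arm configuration
#'
#' For every cell-frame with exactly two foci of each arm marker, sorts the
#' four foci along the long axis and labels the marker sequence:
#' L-R-L-R / R-L-R-L is `TRANSLATIONAL`, L-R-R-L / R-L-L-R is `MIRROR`; any
#' two foci closer than `tol` (position resolution) or any other pattern
#' (including merge artifacts) is `UNDETERMINED`.  Cell-frames with other
#' focus counts (for example three foci of a marker) are returned as
#' `UNDETERMINED` and tallied separately.  The label is invariant under a
#' global sign flip; `identity` (+1 when the sequence starts with the first
#' marker at the lowest position) flips sign.
#'
#' @param focus_table focus observations; positions may be raw or oriented.
#' @param markers the two arm markers.
#' @param tol tie resolution in micrometres (default 0.01 = 10 nm).
#' @return data.table: `cell_id`, `frame`, `label` in
#'   {TRANSLATIONAL, MIRROR, UNDETERMINED}, `identity` (+1/-1/NA).
#' @export
classify_configuration <- function(focus_table, markers = c("L3", "R3"),
                                   tol = 0.01) {
  ft <- as.data.table(focus_table)
  pcol <- if ("position_oriented" %in% names(ft) &&
              !all(is.na(ft$position_oriented))) "position_oriented"
          else "position_um"
  sub <- ft[marker %in% markers]
  sub[, pos := get(pcol)]
  sub <- sub[!is.na(pos)]
  counts <- sub[, .(n1 = sum(marker == markers[1]),
                    n2 = sum(marker == markers[2])), by = .(cell_id, frame)]
  four <- counts[n1 == 2L & n2 == 2L, .(cell_id, frame)]
  other <- counts[!(n1 == 2L & n2 == 2L), .(cell_id, frame)]
  res_other <- if (nrow(other))
    other[, .(cell_id, frame, label = "UNDETERMINED", identity = NA_integer_)]
  else data.table(cell_id = integer(), frame = integer(),
                  label = character(), identity = integer())
  if (nrow(four) == 0) return(res_other[])
  sub4 <- merge(sub, four, by = c("cell_id", "frame"))
  setorder(sub4, cell_id, frame, pos)
  cls <- sub4[, {
    p <- pos; mk <- marker
    if (any(diff(p) < tol)) {
      list(label = "UNDETERMINED", identity = NA_integer_)
    } else {
      seqc <- paste(ifelse(mk == markers[1], "L", "R"), collapse = "")
      lab <- if (seqc %in% c("LRLR", "RLRL")) "TRANSLATIONAL"
             else if (seqc %in% c("LRRL", "RLLR")) "MIRROR"
             else "UNDETERMINED"
      idt <- if (lab == "UNDETERMINED") NA_integer_
             else if (substr(seqc, 1, 1) == "L") 1L else -1L
      list(label = lab, identity = idt)
    }
  }, by = .(cell_id, frame)]
  out <- rbindlist(list(cls, res_other), use.names = TRUE)
  setorder(out, cell_id, frame)
  out[]
}

#' Keep one frame per cell
#'
#' Snapshot-style subsetting: selects a single frame per cell from a focus
#' table so that cell-level fractions are computed over independent cells
#' (as in high-throughput still imaging) rather than over autocorrelated
#' frames of the same cell.
#'
#' @param focus_table focus observations.
#' @param which `"first"` or `"last"` observed frame per cell among `frames`.
#' @param frames optional frame whitelist applied before selection.
#' @return the subsetted focus table.
#' @export
one_frame_per_cell <- function(focus_table, which = c("last", "first"),
                               frames = NULL) {
  which <- match.arg(which)
  ft <- as.data.table(focus_table)
  if (!is.null(frames)) ft <- ft[frame %in% frames]
  pick <- ft[, .(frame = if (which == "last") max(frame) else min(frame)),
             by = cell_id]
  merge(ft, pick, by = c("cell_id", "frame"))
}
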