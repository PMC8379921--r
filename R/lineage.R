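#' Build a division forest from a tracked-cell table
#'
#' Assembles mother-daughter links and propagates pole identities and ages.
#' At every observed division two age-0 poles are created at the septum and
#' each daughter's distal end inherits the corresponding mother pole, one
#' generation older.  Cells whose birth is not observed (present in the first
#' frame, or with an unresolvable mother) carry `UNKNOWN` (NA) pole identity;
#' pole ages become numeric as soon as the ancestry chain is anchored at an
#' observed division.
#'
#' @param cell_table data.frame/data.table with columns `cell_id`,
#'   `mother_id`, `channel`, `frame`, `time_min`, `length_um`, `end_low_um`,
#'   `end_high_um` (one row per cell per frame).
#' @param frame_interval minutes between frames (recorded for metric
#'   conversion).
#' @return a `lineage_forest`: list with `cells` (one annotated row per
#'   cell: birth/last frames and lengths, daughter ids, `old_pole_end`,
#'   `old_pole_age`, `pole_known`), `edges` (mother, daughter), and
#'   `frame_interval`.
#' @export
build_forest <- function(cell_table, frame_interval = NULL) {
  ct <- as.data.table(cell_table)
  req <- c("cell_id", "mother_id", "frame", "length_um",
           "end_low_um", "end_high_um")
  miss <- setdiff(req, names(ct))
  if (length(miss))
    stop("cell_table lacks required column(s): ", paste(miss, collapse = ", "))
  if (nrow(ct) == 0) {
    warning("empty cell table: returning empty forest")
    cells <- data.table(cell_id = integer(), mother_id = integer(),
                        channel = integer(), birth_frame = integer(),
                        last_frame = integer(), n_frames = integer(),
                        birth_length = numeric(), last_length = numeric(),
                        birth_end_low = numeric(), birth_end_high = numeric(),
                        old_pole_end = character(), old_pole_age = integer(),
                        pole_known = logical(), division_frame = integer(),
                        divided = logical())
    return(structure(list(cells = cells,
                          edges = data.table(mother_id = integer(),
                                             cell_id = integer()),
                          frame_interval = frame_interval),
                     class = "lineage_forest"))
  }
  if (!"channel" %in% names(ct)) ct[, channel := 1L]
  setorder(ct, cell_id, frame)
  cells <- ct[, .(mother_id = mother_id[1], channel = channel[1],
                  birth_frame = frame[1], last_frame = frame[.N],
                  n_frames = .N, birth_length = length_um[1],
                  last_length = length_um[.N],
                  birth_end_low = end_low_um[1],
                  birth_end_high = end_high_um[1],
                  last_end_low = end_low_um[.N],
                  last_end_high = end_high_um[.N]),
              by = cell_id]

  kids <- cells[!is.na(mother_id)]
  orphan <- setdiff(kids$mother_id, cells$cell_id)
  if (length(orphan))
    stop("mother id(s) not present in table: ",
         paste(utils::head(orphan, 5), collapse = ", "))
  nk <- kids[, .N, by = mother_id]
  if (any(nk$N > 2))
    stop("cell(s) with more than two daughters: ",
         paste(utils::head(nk[N > 2, mother_id], 5), collapse = ", "))
  mlast <- cells[, .(cell_id, m_last = last_frame)]
  chk <- kids[mlast, on = c(mother_id = "cell_id"), nomatch = 0L]
  bad <- chk[birth_frame <= m_last, cell_id]
  if (length(bad))
    stop("daughter(s) born before mother's division: ",
         paste(utils::head(bad, 5), collapse = ", "))

  # division frame of the mother = the daughters' birth frame
  div <- kids[, .(division_frame = min(birth_frame)), by = mother_id]
  cells <- merge(cells, div[, .(cell_id = mother_id, division_frame)],
                 by = "cell_id", all.x = TRUE)
  cells[, divided := !is.na(division_frame)]

  # which mother end did each daughter inherit (its distal, older pole):
  # the low daughter shares the mother's low end, the high daughter the high
  kids2 <- cells[!is.na(mother_id),
                 .(cell_id, mother_id, birth_end_low, birth_end_high)]
  kids2 <- merge(kids2,
                 cells[, .(mother_id = cell_id, m_low = last_end_low,
                           m_high = last_end_high)],
                 by = "mother_id")
  kids2[, inherited_end := ifelse(abs(birth_end_low - m_low) <=
                                    abs(birth_end_high - m_high),
                                  "low", "high")]
  cells <- merge(cells, kids2[, .(cell_id, inherited_end)],
                 by = "cell_id", all.x = TRUE)

  # pole identity: the distal (inherited) end is the old pole of every cell
  # with an observed birth; ages propagate along observed chains
  cells[, old_pole_end := inherited_end]
  cells[, pole_known := !is.na(old_pole_end)]
  cells[, old_pole_age := NA_integer_]
  setorder(cells, birth_frame, cell_id)
  age_env <- new.env(parent = emptyenv())
  m_old_end <- setNames(as.list(cells$old_pole_end), as.character(cells$cell_id))
  for (i in seq_len(nrow(cells))) {
    mid <- cells$mother_id[i]
    if (is.na(mid)) next
    key <- as.character(mid)
    m_end <- m_old_end[[key]]
    if (is.null(m_end) || is.na(m_end)) next      # root mother: age unknown
    if (cells$inherited_end[i] == m_end) {
      ma <- age_env[[key]]
      if (!is.null(ma) && !is.na(ma))
        age_env[[as.character(cells$cell_id[i])]] <- ma + 1L
    } else {
      age_env[[as.character(cells$cell_id[i])]] <- 1L
    }
  }
  ages <- unlist(as.list(age_env))
  if (length(ages))
    cells[match(as.integer(names(ages)), cell_id), old_pole_age := ages]
  cells[, inherited_end := NULL]

  structure(list(cells = cells,
                 edges = kids[, .(mother_id, cell_id)],
                 frame_interval = frame_interval),
            class = "lineage_forest")
}

#' @export
print.lineage_forest <- function(x, ...) {
  cat("<lineage_forest> ", nrow(x$cells), " cells, ", nrow(x$edges),
      " division edges, ", sum(x$cells$divided), " observed divisions\n",
      sep = "")
  invisible(x)
}

#' Detect anucleate divisions and attribute them to a mother pole
#'
#' A daughter is called anucleate when it shows no focus in any chromosomal
#' (FROS) channel over its observation window and no net growth (relative
#' length change below `growth_threshold`).  The flagged daughter's distal
#' pole identifies which mother pole it abuts: `old`, `new`, or `UNKNOWN`
#' when the mother's pole identity is itself unknown.  Divisions whose
#' daughters are observed for fewer than `min_observation` frames are
#' excluded and tallied, not guessed.
#'
#' @param forest a [build_forest] result.
#' @param focus_table focus observations (`cell_id`, `frame`, `marker`,
#'   `position_um`).
#' @param min_observation minimum observed frames per daughter (default 3).
#' @param fros_markers channels whose absence defines "no chromosomal foci".
#' @param growth_threshold relative length change below which a daughter
#'   counts as non-growing (default 2 percent).
#' @return list with `records` (one row per eligible division: mother, the
#'   two daughters, frame, daughter birth lengths, anucleate flag and side),
#'   `rate` (flagged / eligible), `n_eligible`, `n_excluded`.
#' @export
detect_anucleate_divisions <- function(forest, focus_table,
                                       min_observation = 3,
                                       fros_markers = c("L3", "R3", "ori1", "ter3"),
                                       growth_threshold = 0.02) {
  stopifnot(inherits(forest, "lineage_forest"))
  ft <- as.data.table(focus_table)
  cells <- forest$cells
  kids <- cells[!is.na(mother_id)]
  div <- kids[, .(d1 = cell_id[1], d2 = cell_id[2], n_d = .N,
                  frame = min(birth_frame)), by = mother_id]
  div <- div[n_d == 2L]
  if (nrow(div) == 0)
    return(list(records = data.table(), rate = NA_real_, n_eligible = 0L,
                n_excluded = 0L))
  info <- cells[, .(cell_id, n_frames, birth_length, last_length,
                    old_pole_end, mother_id)]
  has_foci <- ft[marker %in% fros_markers, .(any_foci = .N > 0), by = cell_id]
  info <- has_foci[info, on = "cell_id"]
  info[is.na(any_foci), any_foci := FALSE]
  info[, anucleate := !any_foci &
         abs(last_length - birth_length) / birth_length < growth_threshold]

  d1i <- info[match(div$d1, cell_id)]
  d2i <- info[match(div$d2, cell_id)]
  eligible <- d1i$n_frames >= min_observation & d2i$n_frames >= min_observation
  n_excluded <- sum(!eligible)
  div <- div[eligible]; d1i <- d1i[eligible]; d2i <- d2i[eligible]
  both <- d1i$anucleate & d2i$anucleate
  rec <- data.table(
    mother_id = div$mother_id, daughter1 = div$d1, daughter2 = div$d2,
    frame = div$frame,
    d1_birth_length = d1i$birth_length, d2_birth_length = d2i$birth_length,
    d1_anucleate = d1i$anucleate & !both, d2_anucleate = d2i$anucleate & !both)
  rec[, anucleate := d1_anucleate | d2_anucleate]
  # side: the anucleate daughter's old (inherited) pole end vs the mother's
  mother_old <- cells[match(rec$mother_id, cell_id), old_pole_end]
  an_end <- ifelse(rec$d1_anucleate,
                   cells[match(rec$daughter1, cell_id), old_pole_end],
                   ifelse(rec$d2_anucleate,
                          cells[match(rec$daughter2, cell_id), old_pole_end],
                          NA_character_))
  rec[, pole_side := ifelse(!anucleate, NA_character_,
                     ifelse(is.na(mother_old) | is.na(an_end), "UNKNOWN",
                     ifelse(an_end == mother_old, "old", "new")))]
  list(records = rec[], rate = mean(rec$anucleate),
       n_eligible = nrow(rec), n_excluded = n_excluded,
       n_double_flagged = sum(both))
}

#' Count origin foci in the frames just before division
#'
#' For every observed division, counts the mother's detected foci of
#' `marker` in the last `window` frames before the division (merge-aware:
#' the observation model reports unresolvable focus pairs as one focus).
#' Feeds the conditional statistic P(unsegregated origin | division class).
#'
#' @param forest a [build_forest] result.
#' @param focus_table focus observations.
#' @param marker focus channel to count (default `"ori1"`).
#' @param window frames before division to inspect (default 1: the last
#'   frame).
#' @return data.table: `mother_id`, `frame` (division), `n_foci` (count in
#'   the latest pre-division frame where the marker is visible).
#' @export
count_ori_foci_prior_division <- function(forest, focus_table,
                                          marker = "ori1", window = 1) {
  stopifnot(inherits(forest, "lineage_forest"), window >= 1)
  ft <- as.data.table(focus_table)
  if (!marker %in% unique(ft$marker))
    stop("marker '", marker, "' absent from focus table")
  mothers <- forest$cells[divided == TRUE,
                          .(cell_id, division_frame, last_frame)]
  if (nrow(mothers) == 0) return(data.table())
  mkr <- marker
  mk <- ft[marker == mkr & cell_id %in% mothers$cell_id]
  mk <- mothers[mk, on = "cell_id", nomatch = 0L]
  mk <- mk[frame > last_frame - window & frame <= last_frame]
  cnt <- mk[, .N, by = .(cell_id, frame)]
  cnt <- cnt[order(cell_id, -frame)][, .SD[1], by = cell_id]
  out <- cnt[mothers, on = "cell_id"]
  out[is.na(N), N := 0L]
  out[, .(mother_id = cell_id, frame = division_frame, n_foci = N)]
}

#' Per-cell cycle metrics
#'
#' Generation time, birth and division lengths, and division symmetry for
#' every cell whose birth and division are both observed; censored cells are
#' excluded and tallied.
#'
#' @param forest a [build_forest] result.
#' @param frame_interval minutes per frame; defaults to the value stored in
#'   the forest.
#' @return list with `metrics` (cell_id, generation_time_min, birth/division
#'   length, daughter birth lengths ordered small-large) and `n_censored`.
#' @export
cycle_metrics <- function(forest, frame_interval = NULL) {
  stopifnot(inherits(forest, "lineage_forest"))
  dt <- frame_interval %||% forest$frame_interval
  if (is.null(dt)) stop("frame_interval not provided")
  cells <- forest$cells
  # birth observed: cell has a mother (frame-0 founders have no observed birth)
  complete <- cells[!is.na(mother_id) & divided == TRUE]
  n_censored <- nrow(cells) - nrow(complete)
  if (nrow(complete) == 0)
    return(list(metrics = data.table(), n_censored = n_censored))
  kids <- cells[!is.na(mother_id), .(cell_id, mother_id, birth_length)]
  dl <- kids[, .(d_small = min(birth_length), d_large = max(birth_length)),
             by = mother_id]
  m <- complete[, .(cell_id, birth_frame, division_frame, birth_length,
                    division_length = last_length)]
  m[, generation_time_min := (division_frame - birth_frame) * dt]
  m <- dl[m, on = c(mother_id = "cell_id")]
  setnames(m, "mother_id", "cell_id")
  m[, asymmetry_um := d_large - d_small]
  list(metrics = m[], n_censored = n_censored)
}
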