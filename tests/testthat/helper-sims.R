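# Shared small simulations, built once per test run.  Everything is seeded;
# scales are desk-sized so the whole suite stays well inside its budget.
.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(key, builder) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- builder()
  .sim_cache[[key]]
}

wt_mm_sim <- function() cached_sim("wt_mm", function() {
  simulate_experiment(preset("WT"), "mother_machine", n_lineages = 30,
                      duration = 2160, frame_interval = 10, seed = 101)
})

dmukb_mm_sim <- function() cached_sim("dmukb_mm", function() {
  simulate_experiment(preset("deltaMukB"), "mother_machine", n_lineages = 40,
                      duration = 1080, frame_interval = 5, seed = 102)
})

dmatp_mm_sim <- function() cached_sim("dmatp_mm", function() {
  simulate_experiment(preset("deltaMatP"), "mother_machine", n_lineages = 40,
                      duration = 2160, frame_interval = 10, seed = 103)
})

wt_pad_edu_sim <- function() cached_sim("wt_pad_edu", function() {
  simulate_experiment(preset("WT"), "pad", n_lineages = 120, duration = 300,
                      frame_interval = 10, seed = 104,
                      edu_pulse = list(start = 60, duration = 15))
})

# a tiny hand-written tracked-cell table: one mother (frames 0-2) dividing
# into two daughters (frames 3-5)
toy_cell_table <- function() {
  data.table::data.table(
    cell_id   = c(1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L),
    mother_id = c(NA, NA, NA, 1L, 1L, 1L, 1L, 1L, 1L),
    channel = 1L,
    frame  = c(0L, 1L, 2L, 3L, 4L, 5L, 3L, 4L, 5L),
    time_min = c(0, 10, 20, 30, 40, 50, 30, 40, 50),
    length_um = c(4.0, 4.2, 4.4, 2.2, 2.3, 2.4, 2.3, 2.4, 2.5),
    end_low_um = c(0, 0, 0, 0, 0, 0, 2.25, 2.3, 2.4),
    end_high_um = c(4.0, 4.2, 4.4, 2.2, 2.3, 2.4, 4.55, 4.7, 4.9))
}

make_focus <- function(cell_id, frame, marker, pos, intensity = 1000) {
  data.table::data.table(cell_id = cell_id, frame = frame, marker = marker,
                         position_um = pos, intensity = intensity)
}
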