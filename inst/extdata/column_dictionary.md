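# Column dictionary

Conventions: CSV with header row, UTF-8, "." decimal; positions in
micrometres (um) signed from midcell (negative pole = smaller coordinate);
times in minutes; frame indices 0-based, mapping to minutes through the
run's frame_interval (see params.json / manifest.json). Unknown columns in
input tables are preserved, never dropped.

## cell_table.csv  (one row per cell per frame)
- cell_id      integer; unique per tracked cell
- mother_id    integer; NA for cells whose birth was not observed
- channel      integer; mother-machine channel or pad field id
- frame        integer; 0-based imaging frame
- time_min     minutes since recording start
- length_um    cell length along the long axis
- end_low_um   absolute coordinate of the cell's lower (closed/negative) end
- end_high_um  absolute coordinate of the upper end

## focus_table.csv  (one row per detected focus)
- cell_id, frame  as above; every row references an existing cell-frame
- marker       channel name: L3, R3 (arm loci), ori1, ter3, DnaQ, DnaB,
               DnaN, DAPI (nucleoid centroid), EdU (pulse label),
               Tsr (polar intensity, one row per pole at +/- length/2)
- position_um  signed long-axis position within [-length/2, +length/2]
- intensity    arbitrary units; for same-marker foci merged below the
               diffraction limit, the sum of the merged intensities

## truth_cells.csv  (simulator ground truth, one row per cell cycle)
Key columns: birth_time/birth_frame, death_time/division_frame (NA if
censored), gen_time, growth_rate, birth_length, old_end + old_age (true
pole identity/age), pole_known, o_birth (orientation at birth), n_flips_pre
+ flip_frames, dup_frame, config_trans (translational arrangement),
config_final (identity at division), postdup_changed + change_frame,
anuc_division + anuc_side, binucleate_born, s1_age/s2_age + *_edu (strand
ages and label flags; ages advance at replication), ret_draw, anc_side,
ancestral_at_old_pole, edu_gen + edu_side (label token), tsr_I_low/high +
tsr_correct, opp_draw / same_side / mL / mR / ori_merged (per-cycle
geometry draws).

## truth_frames.csv  (ground truth, one row per cell per frame)
- phase        B, C or D
- orientation  +1/-1 (arm order along the axis; configuration identity
               after duplication); NA for anucleate cells
- n_nucleoids  0 (anucleate), 1, or 2
- length_um    true length
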