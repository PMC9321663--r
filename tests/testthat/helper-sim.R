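# Shared fixtures for the simulation-driven tests. Unit tests use a reduced
# cell load per well (the statistics under test are per-well fractions, which
# are insensitive to the absolute count); calibration checks in the
# acceptance suite use the full default configuration.

small_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, cells_per_well_mean = 300, ...)
}

# A layout whose interior wells all carry one chemical across the default
# concentration series with n_rep replicates.
one_chem_layout <- function(chemical_id = "chemA", n_rep = 4L,
                            conc = default_conc_series(), plate_id = "P01",
                            n_control = 12L) {
  trt <- tidyr::crossing(rep = seq_len(n_rep), conc_uM = conc)
  trt$chemical_id <- chemical_id
  plate_layout(plate_id, treatments = trt[c("chemical_id", "conc_uM")],
               n_control = n_control)
}

# Layout with every well assigned a single role (e.g. a whole plate of
# endoderm controls), for pooled-control checks.
single_role_layout <- function(role, plate_id = "R01") {
  grid <- tidyr::crossing(row = LETTERS[1:16], col = 1:24)
  tibble::tibble(
    plate_id = plate_id,
    well_id = sprintf("%s%02d", grid$row, grid$col),
    row = grid$row, col = grid$col,
    role = role, chemical_id = NA_character_, conc_uM = NA_real_
  )
}
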