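# Small in-code fixtures shared across test files.

# one-plate map with the standard control layout
toy_plate_map <- function(screen = 1L, session = 1L, plate = "P001",
                          dose = 0, arm = "mock") {
  wells <- radscreen::well_grid()
  role <- rep("sample", 96L)
  role[wells %in% c("A1", "H12")] <- "neg_control"
  role[wells %in% c("A12", "H1")] <- "pos_control"
  data.frame(screen = screen, session = session, plate = plate,
             well = wells,
             sirna = ifelse(role == "sample", paste0("si", seq_along(wells)),
                            ifelse(role == "neg_control", "siNT", "siPRKDC")),
             role = role, dose = dose, arm = arm,
             stringsAsFactors = FALSE)
}

# a tiny effect-free screen design; any default can be overridden
quiet_params <- function(...) {
  args <- list(n_screens = 1L, n_sessions = 1L, n_plates = 2L,
               viability_sd = 0, sensitizer_frac = 0,
               pos_viability = 0, pos_interaction = 0,
               plate_sd = 0, session_sd = 0, screen_sd = 0,
               noise_sd = 0)
  override <- list(...)
  args[names(override)] <- override
  do.call(radscreen::sim_params, args)
}
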