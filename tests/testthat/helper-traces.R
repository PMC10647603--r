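# Build a ca_traces object carrying exactly the given dff vectors, by
# constructing a raw table with constant background 100 and
# F_cell = 100 * (1 + dff): normalization then returns dff bit-exactly.
make_traces <- function(dff_list, duration_s) {
  if (!is.list(dff_list)) dff_list <- list(Cell1 = dff_list)
  cols <- lapply(dff_list, function(d) 100 * (1 + d))
  cols$Background <- rep(100, length(dff_list[[1]]))
  tbl <- intensity_table(tibble::as_tibble(cols), duration_s = duration_s,
                         background = "Background")
  normalize_to_background(tbl)
}

# Symmetric triangular pulse: baseline 0, amplitude 1, rising over `rise`
# seconds and falling over the same, centred at `centre`.
triangle_dff <- function(time_s, centre = 1, rise = 0.5) {
  pmax(1 - abs(time_s - centre) / rise, 0)
}
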