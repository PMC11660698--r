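# Small in-code fixtures used across test files.

mini_schema <- function() {
  labeling_schema(
    phases = c("p1", "p2"),
    items = c("i1", "i2", "i3", "g1"),
    global_items = "g1"
  )
}

# quick record builder with defaults
rr <- function(rater = "R1", video = "V1", phase = "p1", item = "i1",
               round = 1L, value = 10, na = FALSE) {
  tibble::tibble(
    rater_id = rater, video_id = video, phase = phase, item = item,
    round = as.integer(round),
    value = if (na) NA_real_ else as.numeric(value),
    not_assessable = na
  )
}

# a complete 2-rater x 2-video x mini-schema x 2-round dataset
mini_dataset <- function(value = 10) {
  grid <- tidyr::expand_grid(
    rater_id = c("R1", "R2"), video_id = c("V1", "V2"),
    phase = c("p1", "p2"), item = c("i1", "i2", "i3", "g1"),
    round = 1:2
  )
  dplyr::mutate(grid,
    round = as.integer(round),
    value = as.numeric(value), not_assessable = FALSE
  )
}

# single-phase, single-item schema: the fitted likelihood matches the
# generator exactly, which is what calibration studies need
scalar_schema <- function() {
  labeling_schema(phases = "phase1", items = "overall")
}
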