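test_that("default drinking-task schema has the 5 x 11 field grid", {
  sch <- drinking_task_schema()
  expect_length(sch$phases, 5)
  expect_length(sch$items, 11)
  expect_equal(length(sch$phases) * length(sch$items), 55)
  expect_true(all(sch$global_items %in% sch$items))
  expect_setequal(
    sch$global_items, c("smoothness", "interjoint_coordination")
  )
  expect_length(phase_items(sch), 9)
})

test_that("schema constructor rejects malformed grids", {
  expect_error(labeling_schema(c("a", "a"), "i"), "duplicate phase")
  expect_error(labeling_schema("a", c("i", "i")), "duplicate item")
  expect_error(
    labeling_schema("a", "i", global_items = "other"),
    "subset"
  )
})

test_that("schema round-trips through a JSON config file", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(
    list(phases = c("p1", "p2"), items = c("i1", "g1"), global_items = "g1"),
    path, auto_unbox = TRUE
  )
  sch <- read_schema(path)
  expect_s3_class(sch, "labeling_schema")
  expect_equal(sch$phases, c("p1", "p2"))
  expect_equal(sch$global_items, "g1")
})

test_that("write -> read round-trips a dataset key-by-key, including the
           not-assessable token", {
  d <- dplyr::bind_rows(
    rr(value = 12.5),
    rr(item = "i2", value = 0),
    rr(item = "i3", na = TRUE)
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_ratings(d, path)
  txt <- readLines(path)
  expect_true(any(grepl("NA_not_assessable", txt)))
  d2 <- read_ratings(path, mini_schema())
  expect_equal(as.data.frame(d2), as.data.frame(d))
  expect_equal(sum(d2$not_assessable), 1)
  expect_equal(nrow(d2), 3)
})

test_that("reading validates structure and values with row-level errors", {
  sch <- mini_schema()
  tf <- function(lines) {
    p <- tempfile(fileext = ".csv")
    writeLines(lines, p)
    p
  }
  hdr <- "rater_id,video_id,phase,item,round,value"
  expect_error(
    read_ratings(tf(hdr), sch), "no records"
  )
  expect_error(
    read_ratings(tf("rater_id,video_id,phase,round,value\nR1,V1,p1,1,5"), sch),
    "missing required column"
  )
  expect_error(
    read_ratings(tf(c(hdr, "R1,V1,p1,i1,1,150")), sch),
    "outside \\[0, 100\\]"
  )
  expect_error(
    read_ratings(tf(c(hdr, "R1,V1,bad_phase,i1,1,5")), sch),
    "unknown phase"
  )
  expect_error(
    read_ratings(tf(c(hdr, "R1,V1,p1,bad_item,1,5")), sch),
    "unknown item"
  )
  expect_error(
    read_ratings(tf(c(hdr, "R1,V1,p1,i1,1,5", "R1,V1,p1,i1,1,6")), sch),
    "duplicate"
  )
  expect_error(
    read_ratings(tf(c(hdr, "R1,V1,p1,i1,1,maybe")), sch),
    "neither a number"
  )
})

test_that("row order does not change downstream aggregation", {
  d <- mini_dataset(value = 25)
  d$value <- seq_len(nrow(d))
  shuffled <- d[sample.int(nrow(d)), ]
  agg1 <- aggregate_phase_scores(d, mini_schema()) |>
    dplyr::arrange(rater_id, video_id, phase, round)
  agg2 <- aggregate_phase_scores(shuffled, mini_schema()) |>
    dplyr::arrange(rater_id, video_id, phase, round)
  expect_equal(agg1, agg2)
})

test_that("not-assessable exclusion removes both rounds of flagged cells", {
  # no flags: identity
  d <- mini_dataset()
  expect_equal(exclude_not_assessable(d), d)

  # a cell flagged in round 1 only loses its round-2 record too
  d2 <- dplyr::bind_rows(
    rr(round = 1, na = TRUE), rr(round = 2, value = 30),
    rr(item = "i2", round = 1, value = 5), rr(item = "i2", round = 2, value = 6)
  )
  kept <- exclude_not_assessable(d2)
  expect_equal(nrow(kept), 2)
  expect_true(all(kept$item == "i2"))

  # 10 cells (20 records); 3 cells flagged in round 1, 1 other in round 2:
  # 4 cells x 2 records removed -> 12 remain
  cells <- tidyr::expand_grid(video = c("V1", "V2"), item = paste0("i", 1:5))
  d3 <- purrr::pmap_dfr(cells, function(video, item) {
    dplyr::bind_rows(
      rr(video = video, item = item, round = 1),
      rr(video = video, item = item, round = 2)
    )
  })
  flag <- function(d, video, item, round) {
    i <- d$video_id == video & d$item == item & d$round == round
    d$value[i] <- NA_real_
    d$not_assessable[i] <- TRUE
    d
  }
  d3 <- d3 |>
    flag("V1", "i1", 1) |>
    flag("V1", "i2", 1) |>
    flag("V2", "i3", 1) |>
    flag("V2", "i4", 2)
  expect_equal(nrow(exclude_not_assessable(d3)), 12)

  # idempotent
  expect_equal(
    exclude_not_assessable(exclude_not_assessable(d3)),
    exclude_not_assessable(d3)
  )
})

test_that("phase means average available items and skip global ones", {
  sch <- mini_schema()
  d <- dplyr::bind_rows(
    rr(item = "i1", value = 10), rr(item = "i2", value = 20),
    rr(item = "i3", value = 30), rr(item = "g1", value = 90)
  )
  agg <- aggregate_phase_scores(d, sch)
  expect_equal(agg$score, 20) # mean(10, 20, 30); g1 not counted
  expect_equal(agg$n_items, 3)
  agg_g <- aggregate_phase_scores(d, sch, include_global = TRUE)
  expect_equal(agg_g$score, mean(c(10, 20, 30, 90)))

  # all-zero items give mean zero
  expect_equal(
    aggregate_phase_scores(mini_dataset(value = 0), sch)$score |> unique(), 0
  )

  # an excluded item drops out of the mean
  d_na <- dplyr::bind_rows(
    rr(item = "i1", round = 1, value = 10),
    rr(item = "i1", round = 2, na = TRUE),
    rr(item = "i2", round = 1, value = 40),
    rr(item = "i2", round = 2, value = 50)
  )
  agg_na <- aggregate_phase_scores(exclude_not_assessable(d_na), sch)
  expect_equal(sort(agg_na$score), c(40, 50))

  # row count bound: raters x videos x phases x rounds
  full <- mini_dataset()
  expect_lte(
    nrow(aggregate_phase_scores(full, sch)),
    2 * 2 * 2 * 2
  )
})

test_that("global-domain aggregation pools one item across phases", {
  sch <- mini_schema()
  d <- dplyr::bind_rows(
    rr(item = "g1", phase = "p1", value = 10),
    rr(item = "g1", phase = "p2", value = 30),
    rr(item = "i1", phase = "p1", value = 99)
  )
  g <- aggregate_global_scores(d, "g1", sch)
  expect_equal(g$score, 20)
  expect_equal(g$phase, "g1")
  expect_error(aggregate_global_scores(d, "i1", sch), "not a global item")
})

test_that("dataset dimensions are counted per sheet and in total", {
  d1 <- rr()
  dims <- dataset_dimensions(d1)
  expect_equal(
    unlist(dims),
    c(n_raters = 1, n_videos = 1, n_rounds = 1,
      fields_per_sheet = 1, n_records = 1)
  )
  full <- mini_dataset()
  dims2 <- dataset_dimensions(full)
  expect_equal(dims2$fields_per_sheet, 8) # 2 phases x 4 items
  expect_equal(dims2$n_records, 2 * 2 * 2 * 4 * 2)
})

test_that("wide export round-trips to the canonical long layout", {
  d <- dplyr::bind_rows(
    rr(value = 1.5), rr(item = "i2", na = TRUE),
    rr(round = 2, value = 7)
  )
  w <- ratings_to_wide(d, mini_schema())
  expect_equal(nrow(w), 2) # (R1,V1) x rounds 1, 2
  back <- ratings_to_long(w, mini_schema()) |>
    dplyr::arrange(item, round)
  expect_equal(
    as.data.frame(back),
    as.data.frame(dplyr::arrange(d, item, round))
  )
})
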