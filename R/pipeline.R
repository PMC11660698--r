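#' Configuration for an end-to-end reliability run
#'
#' Exactly one of `input` (path to a rating CSV) or `preset` (generator
#' parameters for a simulated dataset) must be given.
#'
#' @param input Optional path to a long-format rating CSV.
#' @param preset Optional [generator_params()] object.
#' @param schema A [labeling_schema()].
#' @param model_spec A [zib_spec()].
#' @param design A named list passed to [design_summary()] (or `NULL` to
#'   skip the design stage).
#' @param out_dir Output directory (created if missing).
#' @param seed Integer master seed; reseeds the generator and sampler.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(input = NULL, preset = NULL,
                            schema = drinking_task_schema(),
                            model_spec = zib_spec(),
                            design = list(
                              expected_icc = 0.85, ci_width = 0.3,
                              alpha = 0.05, n_subjects = 7,
                              dropout_rate = 0.25
                            ),
                            out_dir = tempfile("zibicc_run_"),
                            seed = 1L) {
  if (is.null(input) == is.null(preset)) {
    stop("exactly one of 'input' and 'preset' must be set", call. = FALSE)
  }
  stopifnot(
    inherits(schema, "labeling_schema"), inherits(model_spec, "zib_spec")
  )
  structure(
    list(
      input = input, preset = preset, schema = schema,
      model_spec = model_spec, design = design,
      out_dir = out_dir, seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Run the full reliability pipeline
#'
#' Simulate (or load) ratings, validate, apply the not-assessable
#' exclusion, aggregate phase and global-domain scores, fit the
#' zero-inflated beta mixed model per scope, summarise ICCs, compute the
#' descriptive tables and (optionally) the design arithmetic, and write
#' everything plus a run manifest to `config$out_dir`.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress sampler progress?
#' @return Invisibly, a list with elements `data`, `icc`, `fits`,
#'   `descriptives`, `design`, `manifest`.
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
        call. = FALSE
      )
    })
  }

  data <- stage("input", {
    if (!is.null(config$input)) {
      read_ratings(config$input, config$schema)
    } else {
      p <- config$preset
      p$seed <- config$seed
      d <- simulate_ratings(p)
      write_ratings(d, file.path(config$out_dir, "ratings.csv"))
      jsonlite::write_json(
        c(
          p[setdiff(names(p), "schema")],
          list(true_icc_latent = as.list(true_icc_latent(p)[1, 1:2]))
        ),
        file.path(config$out_dir, "generator_params.json"),
        auto_unbox = TRUE, digits = NA
      )
      d
    }
  })

  config$model_spec$seed <- config$seed
  analysis <- stage(
    "fit",
    icc_analysis(data, config$model_spec, config$schema, quiet = quiet)
  )
  readr::write_csv(
    analysis$icc, file.path(config$out_dir, "icc_estimates.csv"),
    progress = FALSE
  )
  readr::write_csv(
    icc_report(analysis$icc),
    file.path(config$out_dir, "icc_report.csv"),
    progress = FALSE
  )
  draws_all <- purrr::imap_dfr(
    analysis$fits, ~ dplyr::mutate(.x$draws, scope = .y)
  )
  readr::write_csv(
    draws_all, file.path(config$out_dir, "posterior_draws.csv"),
    progress = FALSE
  )
  diag_all <- purrr::imap_dfr(
    analysis$fits, ~ dplyr::mutate(.x$diagnostics, scope = .y)
  )
  jsonlite::write_json(
    diag_all, file.path(config$out_dir, "diagnostics.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA
  )

  descr <- stage("descriptives", {
    clean <- exclude_not_assessable(data)
    list(
      zero_concordance = zero_concordance(clean),
      round_deviation = round_deviation_summary(clean),
      not_assessable = not_assessable_tally(data)
    )
  })
  readr::write_csv(
    descr$zero_concordance,
    file.path(config$out_dir, "zero_concordance.csv"),
    progress = FALSE
  )
  readr::write_csv(
    descr$round_deviation,
    file.path(config$out_dir, "round_deviation.csv"),
    progress = FALSE
  )
  readr::write_csv(
    descr$not_assessable$by_round,
    file.path(config$out_dir, "not_assessable_by_round.csv"),
    progress = FALSE
  )

  design <- if (!is.null(config$design)) {
    d <- stage("design", do.call(design_summary, config$design))
    readr::write_csv(d, file.path(config$out_dir, "design.csv"),
      progress = FALSE
    )
    d
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("zibicc")),
    seed = config$seed,
    input = config$input %||% "simulated",
    schema = config$schema[c("phases", "items", "global_items")],
    sampler = config$model_spec[c(
      "chains", "warmup", "draws", "thin", "seed", "rhat_threshold",
      "squeeze_epsilon"
    )],
    conventions = list(
      icc_scale = "latent (logit) variance components",
      interval = "equal-tailed 95% credible interval",
      categories = "poor <0.5 <= moderate <0.75 <= good <0.90 <= excellent",
      phase_means_exclude_global_items = TRUE
    ),
    converged = all(vapply(analysis$fits, `[[`, TRUE, "converged"))
  )
  jsonlite::write_json(
    manifest, file.path(config$out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )

  invisible(list(
    data = data, icc = analysis$icc, fits = analysis$fits,
    descriptives = descr, design = design, manifest = manifest
  ))
}
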