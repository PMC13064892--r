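#' Default full-pipeline run configuration
#'
#' Returns the nested parameter list consumed by [run_pipeline()]:
#' simulation design (field configuration, condition multipliers,
#' replicate structure), quantification parameters (segmentation,
#' detection, measurement), EdU gating, and statistics settings. Any
#' entry can be overridden via `...` using the same nesting, or by
#' editing the returned list; [read_run_config()] loads the same
#' structure from a YAML file.
#'
#' @param ... Named top-level sections to override (`simulate`,
#'   `segment`, `detect`, `measure`, `gate`, `stats`, `seed`).
#' @return A nested list of class `run_config`.
#' @export
default_run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    simulate = list(
      field = list(image_height = 448, image_width = 448, n_cells = 12,
                   nucleus_radius_range = c(21, 25), foci_per_nucleus = 46,
                   spot_sigma = 1.0, background_level = 100,
                   background_gradient = 0.02, read_noise_sd = 3,
                   n_z = 1),
      conditions = c(cycling = 1, quiescent = 0.25),
      n_fields_per_condition = 3,
      n_replicates = 3,
      replicate_effect_sd = 0.05,
      edu = TRUE,
      edu_positive_fractions = c(cycling = 0.95, quiescent = 0.002)),
    segment = list(smooth_sigma = 2, min_area = 200, clear_border = TRUE),
    detect = list(log_sigma = 1.0, min_separation = 3),
    measure = list(disk_radius = 3, annulus_inner = 4, annulus_outer = 7),
    gate = list(enabled = TRUE, grid_points = 1000,
                fit_scale = "linear"),
    stats = list(reference_condition = "cycling",
                 mode = "per_replicate"))
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- utils::modifyList(
    if (is.list(cfg[[nm]])) cfg[[nm]] else list(), over[[nm]])
  class(cfg) <- "run_config"
  cfg
}

## Named vectors must become YAML maps (write_yaml drops vector names).
config_to_serializable <- function(cfg) {
  cfg <- unclass(cfg)
  if (!is.null(cfg$simulate$conditions))
    cfg$simulate$conditions <- as.list(cfg$simulate$conditions)
  if (!is.null(cfg$simulate$edu_positive_fractions))
    cfg$simulate$edu_positive_fractions <-
      as.list(cfg$simulate$edu_positive_fractions)
  cfg
}

#' Write a run configuration to a YAML file
#'
#' The written file round-trips through [read_run_config()], preserving
#' condition names.
#'
#' @param config A `run_config`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config_to_serializable(config), path)
  invisible(path)
}

#' Read a run configuration from a YAML file
#'
#' Values present in the file override the defaults of
#' [default_run_config()]; everything else keeps its default.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- unclass(default_run_config())
  cfg <- utils::modifyList(cfg, user)
  ## YAML turns named vectors into lists; restore the ones we need
  if (is.list(cfg$simulate$conditions))
    cfg$simulate$conditions <- unlist(cfg$simulate$conditions)
  if (is.list(cfg$simulate$edu_positive_fractions))
    cfg$simulate$edu_positive_fractions <-
      unlist(cfg$simulate$edu_positive_fractions)
  if (is.list(cfg$simulate$field$nucleus_radius_range))
    cfg$simulate$field$nucleus_radius_range <-
      unlist(cfg$simulate$field$nucleus_radius_range)
  if (is.null(names(cfg$simulate$conditions)))
    stop("'simulate: conditions' must be a YAML map of ",
         "condition name -> target multiplier")
  class(cfg) <- "run_config"
  cfg
}

#' Run the full quantification pipeline
#'
#' Executes simulate (or load) -> project -> segment -> detect ->
#' measure -> gate -> stats and writes result tables to `out_dir`:
#' `cells.csv` (per-cell records with normalized values and gate
#' labels), `foci.csv` (per-focus measurements),
#' `replicate_means.csv`, `comparisons.csv`
#' (pairwise Welch tests on replicate means; flagged missing when a
#' condition has fewer than two replicates), `gate_report.yaml` (mixture
#' parameters, threshold, percent positive per condition), and
#' `manifest.yaml` (config, seed, package version, per-stage counts).
#' A rerun with an identical config writes byte-identical tables.
#'
#' @param config A `run_config` (see [default_run_config()]), or a path
#'   to a YAML config file.
#' @param out_dir Output directory (created if needed).
#' @param fields Optional list of `image_field` objects (or
#'   `list(field =, truth =)` pairs) to quantify instead of simulating.
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list with `cells`, `foci`, `rep_means`,
#'   `comparisons`, `gate`, and `manifest`.
#' @export
run_pipeline <- function(config = default_run_config(),
                         out_dir = tempfile("centroquant_run_"),
                         fields = NULL, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[centroquant] ", ...)

  stage <- "simulate"
  res <- tryCatch({
    if (is.null(fields)) {
      fc <- do.call(field_config, config$simulate$field)
      say("simulate: ", length(config$simulate$conditions),
          " conditions x ", config$simulate$n_replicates, " replicates x ",
          config$simulate$n_fields_per_condition, " fields")
      sims <- generate_condition_set(
        fc, conditions = config$simulate$conditions,
        n_fields_per_condition = config$simulate$n_fields_per_condition,
        n_replicates = config$simulate$n_replicates,
        replicate_effect_sd = config$simulate$replicate_effect_sd,
        edu = isTRUE(config$simulate$edu),
        edu_positive_fractions =
          if (is.list(config$simulate$edu_positive_fractions))
            unlist(config$simulate$edu_positive_fractions)
          else config$simulate$edu_positive_fractions,
        seed = config$seed)
    } else {
      sims <- lapply(fields, function(f)
        if (inherits(f, "image_field")) list(field = f, truth = NULL)
        else f)
    }

    stage <- "quantify"
    all_cells <- list(); all_foci <- list()
    for (s in sims) {
      q <- quantify_field(s$field, segment = config$segment,
                          detect = config$detect,
                          measure = config$measure)
      all_cells[[length(all_cells) + 1L]] <- q$cells
      if (nrow(q$foci) > 0)
        all_foci[[length(all_foci) + 1L]] <- q$foci
    }
    cells <- do.call(rbind, all_cells)
    foci <- if (length(all_foci)) do.call(rbind, all_foci) else NULL
    say("quantify: ", nrow(cells), " cells, ",
        if (is.null(foci)) 0 else nrow(foci), " foci from ",
        length(sims), " fields")

    stage <- "gate"
    gate <- NULL
    if (isTRUE(config$gate$enabled) &&
        any(is.finite(cells$mean_nuclear_edu))) {
      g <- fit_gmm_em(cells$mean_nuclear_edu,
                      fit_scale = config$gate$fit_scale)
      thr <- find_threshold(g, grid_points = config$gate$grid_points)
      gr <- classify_cells(cells, thr)
      cells <- gr$cells
      by_cond <- vapply(split(gr$cells$edu_label, gr$cells$condition),
                        function(l) 100 * mean(l == "positive",
                                               na.rm = TRUE),
                        numeric(1))
      gate <- list(gmm = g, threshold = thr,
                   percent_positive = gr$percent_positive,
                   percent_positive_by_condition = as.list(by_cond))
      say("gate: threshold ", signif(thr$threshold_intensity, 4), ", ",
          signif(gr$percent_positive, 4), "% EdU-positive overall")
    }

    stage <- "stats"
    norm <- normalize_to_reference(
      cells, config$stats$reference_condition,
      mode = config$stats$mode)
    rep_means <- replicate_means(norm)
    comparisons <- pairwise_welch(rep_means)
    say("stats: ", nrow(rep_means), " replicate means, ",
        nrow(comparisons), " pairwise comparisons")

    list(cells = norm, foci = foci, rep_means = rep_means,
         comparisons = comparisons, gate = gate, sims = sims)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })

  write_table <- function(d, file)
    utils::write.csv(d, file.path(out_dir, file), row.names = FALSE)
  write_table(res$cells, "cells.csv")
  if (!is.null(res$foci)) write_table(res$foci, "foci.csv")
  write_table(res$rep_means, "replicate_means.csv")
  write_table(res$comparisons, "comparisons.csv")
  if (!is.null(res$gate))
    yaml::write_yaml(list(
      fit_scale = res$gate$gmm$fit_scale,
      weights = res$gate$gmm$weights,
      means = res$gate$gmm$means,
      variances = res$gate$gmm$variances,
      threshold = res$gate$threshold$threshold_intensity,
      grid_step = res$gate$threshold$grid_step,
      percent_positive = res$gate$percent_positive,
      percent_positive_by_condition =
        res$gate$percent_positive_by_condition),
      file.path(out_dir, "gate_report.yaml"))

  manifest <- list(
    package = "centroquant",
    version = as.character(utils::packageVersion("centroquant")),
    seed = config$seed,
    config = config_to_serializable(config),
    counts = list(fields = length(res$sims), cells = nrow(res$cells),
                  foci = if (is.null(res$foci)) 0L else nrow(res$foci)))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))

  res$manifest <- manifest
  res$out_dir <- out_dir
  res$sims <- NULL
  invisible(res)
}
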