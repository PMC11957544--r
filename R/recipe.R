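# Recipe-style pipelines: a YAML document lists an input, an ordered stage
# chain and a global seed; every stage resolves to a registered operation
# with a declared input/output data kind, so recipes can be validated before
# anything is computed. Bundled recipes under inst/recipes/ translate the
# published parameter sets (nuclei head/body, neuron, anterior fiber).

.stage_registry <- function() {
  list(
    gaussian_smooth = list(input = "volume", output = "volume",
      run = function(g, p, seed) gaussianSmooth(g, p$sigma %||% 1)),
    anisotropic_diffusion = list(input = "volume", output = "volume",
      run = function(g, p, seed)
        anisotropicDiffusion(g, n_iterations = p$n_iterations %||% 5,
                             kappa = p$kappa, lambda = p$lambda %||% 1 / 6)),
    unsharp_mask = list(input = "volume", output = "volume",
      run = function(g, p, seed)
        unsharpMask3D(g, sigma = p$sigma %||% 2, amount = p$amount %||% 1)),
    edge_enhance = list(input = "volume", output = "volume",
      run = function(g, p, seed)
        edgeEnhance(g, p$inner_sigma %||% 1, p$outer_sigma %||% 3)),
    ballness = list(input = "volume", output = "volume",
      run = function(g, p, seed)
        ballness(g, c(p$stddev_min %||% 1, p$stddev_max %||% 3,
                      p$stddev_step %||% 1),
                 polarity = p$polarity %||% "bright")),
    rodness = list(input = "volume", output = "volume",
      run = function(g, p, seed)
        rodness(g, c(p$stddev_min %||% 1, p$stddev_max %||% 1,
                     p$stddev_step %||% 1),
                polarity = p$polarity %||% "bright")),
    binarize = list(input = "volume", output = "binary",
      run = function(g, p, seed) binarize(g, p$threshold %||% "auto")),
    remove_small_spots = list(input = "binary", output = "binary",
      run = function(g, p, seed)
        removeSmallSpots(g, p$min_voxels %||% 10,
                         connectivity = p$connectivity %||% 26)),
    fill_small_holes = list(input = "binary", output = "binary",
      run = function(g, p, seed)
        fillSmallHoles(g, p$max_voxels %||% 100,
                       connectivity = p$connectivity %||% 6)),
    watershed = list(input = "binary", output = "labels",
      run = function(g, p, seed)
        watershedLabel(g, h = p$h %||% 1,
                       connectivity = p$connectivity %||% 6)),
    count_labels = list(input = "labels", output = "table",
      run = function(g, p, seed) {
        regions <- NULL
        if (!is.null(p$regions)) {
          regions <- lapply(p$regions, function(r)
            RegionBox(unlist(r$lower), unlist(r$upper),
                      r$name %||% NA_character_))
        }
        countLabels(g, regions, priority = isTRUE(p$priority))
      }),
    cylinder_correlate = list(input = "volume", output = "corrfield",
      run = function(g, p, seed)
        cylinderCorrelate(g, CylinderTemplate(
          p$length %||% 18, p$outer_radius %||% 2.8,
          p$mask_radius %||% 3, p$angular_step %||% 5),
          min_intensity = p$min_intensity)),
    trace_correlation_lines = list(input = "corrfield", output = "fibers",
      run = function(g, p, seed) {
        st <- p$seed_threshold %||% 0.5
        traceCorrelationLines(g, seed_threshold = st,
          continue_threshold = p$continue_threshold %||% (0.6 * st),
          step_size = p$step_size %||% 1,
          min_length = p$min_length %||% 0,
          turn_limit = p$turn_limit %||% 30)
      }),
    classify_orientation = list(input = "fibers", output = "fibers",
      run = function(g, p, seed) {
        bf <- if (!is.null(p$body_frame))
          matrix(unlist(p$body_frame), 3, 3, byrow = TRUE)
        else rbind(c(0, 0, 1), c(0, 1, 0), c(1, 0, 0))
        classifyOrientation(g, bf)
      }),
    body_mask = list(input = "volume", output = "binary",
      run = function(g, p, seed)
        bodyMask(g, budget = p$budget,
                 threshold = p$threshold %||% "auto",
                 diffusion_iterations = p$diffusion_iterations %||% 15,
                 closing_radius = p$closing_radius %||% 5)),
    crop = list(input = "volume", output = "volume",
      run = function(g, p, seed)
        cropVolume(g, RegionBox(unlist(p$lower), unlist(p$upper)))),
    count_nuclei = list(input = "volume", output = "table",
      run = function(g, p, seed)
        countNuclei(g,
          scales = c(p$stddev_min %||% 1, p$stddev_max %||% 3,
                     p$stddev_step %||% 1),
          smooth_sigma = p$smooth_sigma %||% 1,
          response_threshold = p$response_threshold %||% 0.05,
          min_voxels = p$min_voxels %||% 20,
          h_fraction = p$h_fraction %||% 0.1)$table)
  )
}

#' Validate a recipe
#'
#' Checks a recipe (a list, or the path of a YAML file) without running it:
#' every stage must name a registered operation, and the data kind flowing
#' between stages must match each operation's declared input (e.g. watershed
#' requires a binary predecessor). Problems are returned, not raised.
#'
#' @param recipe list with `input`, `stages` (list of `list(op = ..., ...)`)
#'   and optionally `seed`, `output`; or a YAML file path.
#' @return character vector of problems; empty means valid.
#' @export
validateRecipe <- function(recipe) {
  if (is.character(recipe)) recipe <- yaml::read_yaml(recipe)
  reg <- .stage_registry()
  problems <- character()
  if (is.null(recipe$stages) || !length(recipe$stages)) {
    return("recipe has no stages")
  }
  if (is.null(recipe$input))
    problems <- c(problems, "recipe has no input block")
  kind <- "volume"
  for (i in seq_along(recipe$stages)) {
    st <- recipe$stages[[i]]
    op <- st$op
    if (is.null(op) || !op %in% names(reg)) {
      problems <- c(problems,
                    sprintf("stage %d: unknown operation '%s'", i,
                            op %||% "<missing>"))
      next
    }
    need <- reg[[op]]$input
    if (!identical(kind, need)) {
      problems <- c(problems, sprintf(
        "stage %d (%s): requires %s input but receives %s", i, op, need,
        kind))
    }
    kind <- reg[[op]]$output
  }
  problems
}

#' Run a recipe
#'
#' Executes the stage chain on the declared input (a TIFF path or a bundled
#' phantom description), logging every stage's resolved parameters —
#' including auto-chosen thresholds — as line-delimited JSON. The global
#' seed is fanned out per stage by a stable hash of the stage name, so runs
#' are reproducible end to end: identical recipe + input + seed give
#' byte-identical output tables.
#'
#' @param recipe list or YAML path (see [validateRecipe()]).
#' @param output_dir where result tables and the log are written (default
#'   `recipe$output` or a temp directory).
#' @return list with the final `result`, the per-stage `log`, and the paths
#'   of written artifacts.
#' @export
runRecipe <- function(recipe, output_dir = NULL) {
  if (is.character(recipe)) recipe <- yaml::read_yaml(recipe)
  problems <- validateRecipe(recipe)
  if (length(problems))
    stop("recipe validation failed:\n  ", paste(problems, collapse = "\n  "))
  output_dir <- output_dir %||% recipe$output %||% tempfile("recipe_run_")
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- recipe$seed %||% 1L

  obj <- .recipe_input(recipe$input, seed)
  log <- list()
  prev_threshold <- NULL
  for (i in seq_along(recipe$stages)) {
    st <- recipe$stages[[i]]
    op <- st$op
    entry <- .stage_registry()[[op]]
    stage_seed <- (seed + .stable_hash(paste0(op, "#", i))) %% 2147483647L
    set.seed(stage_seed)
    params <- st[setdiff(names(st), "op")]
    msgs <- character()
    obj <- withCallingHandlers(
      entry$run(obj, params, stage_seed),
      message = function(m) {
        msgs <<- c(msgs, conditionMessage(m))
        invokeRestart("muffleMessage")
      })
    resolved <- params
    cur_threshold <- if (is(obj, "VoxelGrid")) obj@meta$threshold else NULL
    if (!is.null(cur_threshold) && !identical(cur_threshold, prev_threshold))
      resolved$threshold_used <- cur_threshold
    prev_threshold <- cur_threshold
    log[[i]] <- list(stage = i, op = op, seed = stage_seed,
                     params = resolved,
                     messages = if (length(msgs)) msgs else NULL)
  }

  paths <- character()
  if (is.data.frame(obj)) {
    f <- file.path(output_dir, "counts.csv")
    write.csv(obj, f, row.names = FALSE)
    paths <- c(paths, f)
  } else if (is(obj, "FiberSet")) {
    f <- file.path(output_dir, "fibers.csv")
    write.csv(as.data.frame(obj), f, row.names = FALSE)
    paths <- c(paths, f)
  } else if (is(obj, "LabelGrid")) {
    f <- file.path(output_dir, "counts.csv")
    write.csv(countLabels(obj), f, row.names = FALSE)
    paths <- c(paths, f)
  }
  logfile <- file.path(output_dir, "log.jsonl")
  writeLines(vapply(log, function(e)
    jsonlite::toJSON(e, auto_unbox = TRUE, null = "null", digits = NA),
    character(1)), logfile)
  paths <- c(paths, logfile)
  list(result = obj, log = log, paths = paths)
}

.recipe_input <- function(input, seed) {
  if (is.character(input)) return(readVolume(input))
  if (!is.null(input$path)) {
    return(readVolume(input$path, spacing = unlist(input$spacing),
                      expansion = input$expansion))
  }
  if (!is.null(input$phantom)) {
    ph <- switch(input$phantom,
      nuclei = makeNucleiPhantom(
        n = input$n %||% 100, dim = unlist(input$dim) %||% c(128, 128, 128),
        radius_range = unlist(input$radius_range) %||% c(3, 5),
        touching_fraction = input$touching_fraction %||% 0,
        snr = input$snr %||% 10, seed = input$seed %||% seed),
      fibers = makeFiberPhantom(
        fibers = input$n %||% 20, dim = unlist(input$dim) %||% c(128, 128, 128),
        snr = input$snr %||% 5, seed = input$seed %||% seed),
      body = makeBodyPhantom(
        shape = input$shape %||% "capsule",
        dims = unlist(input$dims) %||% c(20, 80),
        fill = input$fill %||% "solid", seed = input$seed %||% seed),
      stop("unknown phantom kind: ", input$phantom))
    return(ph$grid)
  }
  stop("recipe input must give a path or a phantom block")
}
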