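#' Read a z-stack from disk
#'
#' Accepts a multi-page grayscale TIFF (page order = z order, bottom plane
#' first) or a directory of single-plane images (PNG or TIFF) read in
#' lexicographic name order. Intensities are coerced to 8-bit levels; data
#' with a wider range (e.g. 16-bit acquisitions) are rescaled so the maximum
#' maps to 255, with a warning. RGB pages are collapsed to their first
#' channel with a warning.
#'
#' @param path TIFF file or directory.
#' @param pixel_pitch lateral pixel size, micrometres per pixel.
#' @param delta_z axial step, micrometres.
#' @return a [z_stack()].
#' @export
read_stack <- function(path, pixel_pitch = 0.33, delta_z = 0.5) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (!length(files)) abort(sprintf("no PNG/TIFF planes found in directory '%s'", path))
    planes <- lapply(files, read_plane_file)
  } else if (file.exists(path)) {
    pages <- tryCatch(
      tiff::readTIFF(path, all = TRUE, as.is = TRUE),
      error = function(e) abort(sprintf("cannot read TIFF '%s': %s", path, conditionMessage(e)))
    )
    if (!is.list(pages)) pages <- list(pages)
    planes <- lapply(pages, drop_channels)
  } else {
    abort(sprintf("'%s' does not exist", path))
  }
  shapes <- vapply(planes, function(p) paste(dim(p), collapse = "x"), "")
  if (length(unique(shapes)) > 1L) {
    abort(sprintf("planes have mixed shapes: %s", paste(unique(shapes), collapse = ", ")))
  }
  arr <- array(unlist(planes, use.names = FALSE),
               dim = c(dim(planes[[1]]), length(planes)))
  z_stack(arr, pixel_pitch = pixel_pitch, delta_z = delta_z)
}

read_plane_file <- function(file) {
  lower <- tolower(file)
  img <- if (grepl("\\.png$", lower)) {
    # readPNG returns [0, 1]; bring back to stored 8-bit levels
    round(png::readPNG(file) * 255)
  } else {
    tiff::readTIFF(file, as.is = TRUE)
  }
  drop_channels(img)
}

drop_channels <- function(img) {
  if (length(dim(img)) == 3L) {
    warn("multi-channel plane: keeping the first channel")
    img <- img[, , 1]
  }
  img
}

#' Write a z-stack as a multi-page 8-bit grayscale TIFF
#'
#' @param stack a [z_stack()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "z_stack"))
  pages <- lapply(seq_len(n_planes(stack)),
                  function(i) stack$intensity[, , i] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read an impedance trace CSV
#'
#' Expects columns `time_s`, `freq_hz`, `zmag_ohm` (additional columns are
#' ignored). Multi-frequency logs are filtered to the working frequency;
#' times must come out strictly increasing.
#'
#' @param path CSV file.
#' @param frequency working frequency, Hz (150 kHz by default).
#' @return a tibble (`time_s`, `zmag_ohm`) with attribute `frequency`.
#' @export
read_trace <- function(path, frequency = 150e3) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("time_s", "freq_hz", "zmag_ohm")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort(sprintf("trace file lacks column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  df <- df[abs(df$freq_hz - frequency) <= frequency * 1e-6, , drop = FALSE]
  if (!nrow(df)) abort(sprintf("no rows at the working frequency (%g Hz)", frequency))
  if (any(diff(df$time_s) <= 0)) {
    abort("times are not strictly increasing at the working frequency")
  }
  if (any(df$zmag_ohm <= 0)) abort("impedance magnitudes must be positive")
  out <- tibble(time_s = df$time_s, zmag_ohm = df$zmag_ohm)
  attr(out, "frequency") <- frequency
  out
}

#' Write an impedance trace CSV
#'
#' @param series tibble with `time_s` and `zmag_ohm`.
#' @param path output file.
#' @param frequency frequency recorded in the `freq_hz` column.
#' @return the path, invisibly.
#' @export
write_trace <- function(series, path, frequency = attr(series, "frequency") %||% 150e3) {
  readr::write_csv(
    tibble(time_s = series$time_s, freq_hz = frequency, zmag_ohm = series$zmag_ohm),
    path
  )
  invisible(path)
}

#' Run configuration
#'
#' Assembles (or loads from JSON/YAML) the full configuration of a pipeline
#' run: acquisition constants, channel geometry, electrode layout,
#' conductivity model, solver grid and monitor thresholds. Every physical
#' value is validated on construction.
#'
#' @param pixel_pitch lateral pixel size, um/px.
#' @param delta_z axial step, um.
#' @param geometry,layout,model named lists overriding [channel_geometry()],
#'   [electrode_layout()] and [conductivity_model()] defaults.
#' @param voxel_xy solver lateral cell size, um.
#' @param monitor named list of monitor thresholds (`level`, `min_drop`,
#'   `max_window`).
#' @param seed integer seed recorded in manifests.
#' @return an object of class `run_config`.
#' @export
run_config <- function(pixel_pitch = 0.33, delta_z = 0.5,
                       geometry = list(), layout = list(), model = list(),
                       voxel_xy = 10,
                       monitor = list(level = 10, min_drop = 5, max_window = 10),
                       seed = 1L) {
  if (pixel_pitch <= 0 || delta_z <= 0 || voxel_xy <= 0) {
    abort("pixel_pitch, delta_z and voxel_xy must be positive")
  }
  geom <- do.call(channel_geometry, geometry)
  lay <- do.call(electrode_layout, layout)
  mod <- do.call(conductivity_model, model)
  mon <- modifyList(list(level = 10, min_drop = 5, max_window = 10), monitor)
  if (any(unlist(mon) <= 0)) abort("monitor thresholds must be positive")
  structure(
    list(
      pixel_pitch = pixel_pitch, delta_z = delta_z,
      geometry = geom, layout = lay, model = mod,
      voxel_xy = voxel_xy, monitor = mon, seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param path JSON (`.json`) or YAML (`.yml`/`.yaml`) configuration file;
#'   top-level keys match the `run_config()` arguments.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file '%s' does not exist", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(run_config, raw)
}

# stable content hash (31-bit polynomial rolling hash) of the
# JSON-serialized configuration; enough to fingerprint a run in a manifest
config_hash <- function(config) {
  bytes <- utf8ToInt(jsonlite::toJSON(unclass_deep(config), auto_unbox = TRUE,
                                      digits = NA))
  hash <- 0
  for (b in bytes) hash <- (hash * 131 + b) %% 2147483647
  sprintf("%08x", hash)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' Run the full analysis pipeline
#'
#' Mirrors one complete experiment: classify the perfusion trace and scan it
#' for detachment events, quantify the end-of-perfusion volume optically
#' from the z-stack, invert the measured impedance into the
#' impedance-derived volume, and check the two volumes for metrological
#' compatibility. Inputs are optional: sections for missing inputs are
#' reported as absent with a reason. Any stage failure is re-raised with a
#' stage tag.
#'
#' @param config a [run_config()].
#' @param stack_path z-stack file/directory (optional).
#' @param image_path projection image file, PNG or TIFF (optional; required
#'   with `z_measured`).
#' @param trace_path impedance trace CSV (optional).
#' @param z_measured end-of-perfusion impedance magnitude, ohms; defaults to
#'   the last trace sample when a trace is supplied.
#' @param out optional path for the JSON report.
#' @return the report as a nested list (also written to `out` if given).
#' @export
run_pipeline <- function(config = run_config(), stack_path = NULL,
                         image_path = NULL, trace_path = NULL,
                         z_measured = NULL, out = NULL) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("[stage %s] %s", name, conditionMessage(e)), class = "thrombovol_stage_error")
    })
  }
  report <- list(
    manifest = list(
      package = "thrombovol",
      version = as.character(utils::packageVersion("thrombovol")),
      config_hash = config_hash(config),
      seed = config$seed,
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    ),
    warnings = list()
  )
  note <- function(msg) report$warnings[[length(report$warnings) + 1L]] <<- msg

  if (!is.null(trace_path)) {
    report$monitor <- stage("perfusion_monitor", {
      series <- read_trace(trace_path, config$model$working_frequency)
      dz <- withCallingHandlers(
        delta_z(series),
        warning = function(w) { note(conditionMessage(w)); invokeRestart("muffleWarning") }
      )
      cls <- withCallingHandlers(
        classify_trace(dz),
        warning = function(w) { note(conditionMessage(w)); invokeRestart("muffleWarning") }
      )
      ev <- detect_detachment(dz, config$monitor$min_drop, config$monitor$max_window)
      if (is.null(z_measured)) z_measured <- tail(series$zmag_ohm, 1)
      list(
        classification = as.list(cls),
        events = lapply(seq_len(nrow(ev)), function(i) as.list(ev[i, ])),
        baseline_ohm = attr(dz, "baseline_ohm")
      )
    })
  } else {
    report$monitor <- list(absent = "no impedance trace supplied")
  }

  if (!is.null(stack_path)) {
    report$optical <- stage("optical_volumetry", {
      stack <- read_stack(stack_path, config$pixel_pitch, config$delta_z)
      fit <- ot_volumetry(stack)
      list(
        v_ot = fit$volume,
        relative_uncertainty = 0.15,
        propagated_uncertainty = fit$relative_uncertainty,
        threshold = fit$threshold,
        h_zstack = fit$h_zstack,
        n_planes = fit$n_planes
      )
    })
  } else {
    report$optical <- list(absent = "no z-stack supplied")
  }

  if (!is.null(image_path) && !is.null(z_measured)) {
    report$impedance <- stage("fuseit_inversion", {
      image <- read_plane_file(image_path)
      image <- coerce_8bit(image)
      grid <- solver_grid(config$geometry, config$layout, voxel_xy = config$voxel_xy)
      fit <- withCallingHandlers(
        invert_scale_factor(image, z_measured, config$geometry, config$layout,
                            config$model, grid, config$pixel_pitch),
        warning = function(w) { note(conditionMessage(w)); invokeRestart("muffleWarning") }
      )
      list(
        v_im = fit$v_im,
        relative_uncertainty = fit$relative_uncertainty,
        scale_factor = fit$scale_factor,
        residual = fit$residual,
        iterations = fit$iterations,
        baseline_ohm = fit$baseline,
        z_measured = z_measured,
        saturation_fraction = fit$saturation_fraction
      )
    })
  } else {
    report$impedance <- list(absent = "no projection image and measured impedance supplied")
  }

  if (!is.null(report$optical$v_ot) && !is.null(report$impedance$v_im)) {
    v_ot <- report$optical$v_ot
    v_im <- report$impedance$v_im
    tol <- 2 * sqrt((0.15 * v_ot)^2 + (0.10 * v_im)^2)
    report$comparison <- list(
      v_ot = v_ot, v_im = v_im, tolerance = tol,
      compatible = abs(v_ot - v_im) <= tol
    )
  } else {
    report$comparison <- list(absent = "needs both optical and impedance volumes")
  }

  if (!is.null(out)) {
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(report)
}

#' Validate a pipeline report against the shipped schema
#'
#' Structural validation against the JSON schema in
#' `system.file("schema/report.schema.json", package = "thrombovol")`:
#' required keys must be present and of the declared type. Returns `TRUE`
#' invisibly or aborts with the list of violations.
#'
#' @param report a report list (from [run_pipeline()]) or a JSON file path.
#' @export
validate_report <- function(report) {
  if (is.character(report)) report <- jsonlite::read_json(report, simplifyVector = FALSE)
  schema <- jsonlite::read_json(
    system.file("schema", "report.schema.json", package = "thrombovol"),
    simplifyVector = FALSE
  )
  problems <- character(0)
  check <- function(node, sch, where) {
    req <- sch$required %||% list()
    for (key in req) {
      if (is.null(node[[key]])) {
        problems <<- c(problems, sprintf("missing required key '%s' at %s", key, where))
      }
    }
    props <- sch$properties %||% list()
    for (key in names(props)) {
      val <- node[[key]]
      if (is.null(val)) next
      type <- props[[key]]$type
      ok <- switch(
        type %||% "any",
        object = is.list(val),
        array = is.list(val) || is.vector(val),
        string = is.character(val),
        number = is.numeric(val),
        integer = is.numeric(val) && all(val == round(val)),
        boolean = is.logical(val),
        TRUE
      )
      if (!ok) {
        problems <<- c(problems, sprintf("key '%s' at %s is not of type %s", key, where, type))
      }
      if (identical(type, "object") && is.list(val) && is.null(val$absent)) {
        check(val, props[[key]], paste0(where, ".", key))
      }
    }
  }
  check(report, schema, "$")
  if (length(problems)) {
    abort(paste0("report fails schema validation:\n", paste("-", problems, collapse = "\n")))
  }
  invisible(TRUE)
}

#' Emit a complete synthetic fixture directory
#'
#' Writes one generated experiment to disk in the external formats the rest
#' of the toolchain reads: multi-page TIFF stack, PNG projection image,
#' trace CSV, ground-truth JSON and a manifest with the seed and
#' configuration hash. The trace is made physically consistent with the
#' imaged aggregate: its baseline is the forward model's thrombus-free
#' impedance and its final value the forward impedance of the projection
#' image at the generative scale factor, so the pipeline can take the
#' end-of-perfusion measurement straight from the trace. The behavior group
#' follows from the resulting relative rise.
#'
#' @param dir output directory (created if needed).
#' @param seed RNG seed.
#' @param config a [run_config()].
#' @param k_true generative height scale factor, um per intensity level.
#' @return the directory path, invisibly.
#' @export
write_fixture <- function(dir, seed = 1, config = run_config(seed = seed),
                          k_true = 0.12) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  field <- make_thrombus_field(n_thrombi = 2, dim = c(256, 256),
                               base_range = c(40, 90),
                               height_range = c(8, 28),
                               pixel_pitch = config$pixel_pitch)
  hmap <- field$height + 1   # ~monolayer adhesion carpet under the aggregates
  stack <- render_zstack(hmap, delta_z = config$delta_z,
                         pixel_pitch = config$pixel_pitch)
  image <- render_projection_image(hmap, k_true = k_true)
  grid <- solver_grid(config$geometry, config$layout, voxel_xy = config$voxel_xy)
  z0 <- baseline_impedance(config$geometry, config$layout, config$model, grid)
  z_true <- forward_impedance(
    build_field(image, k_true, config$geometry, config$layout, config$model,
                grid, config$pixel_pitch)
  )
  final_dz <- 100 * (z_true - z0) / z0
  bands <- group_bands()
  group <- bands$group[final_dz >= bands$lower & final_dz < bands$upper]
  crossing <- group_archetypes()$crossing_time[group]
  trace <- make_trace(group, final_dz = final_dz, crossing_time = crossing,
                      baseline_ohm = z0)
  # a borderline final rise can land the realized noisy trace across a band
  # edge; the truth label describes the trace actually written
  group <- classify_trace(delta_z(trace))$group
  write_stack(stack, file.path(dir, "stack.tif"))
  png::writePNG(image / 255, file.path(dir, "projection.png"))
  write_trace(trace, file.path(dir, "trace.csv"),
              frequency = config$model$working_frequency)
  truth <- list(
    volume_analytic = field$volume +
      prod(dim(field$height)) * config$pixel_pitch^2,
    volume_rendered = attr(stack, "truth")$volume_rendered,
    k_true = k_true,
    z_true = z_true,
    baseline_ohm = z0,
    group = group,
    seed = seed
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(seed = seed, config_hash = config_hash(config),
         package = "thrombovol",
         version = as.character(utils::packageVersion("thrombovol"))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
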