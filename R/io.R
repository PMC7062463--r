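# Directory-bundle persistence: every on-disk artifact is a directory with
# a JSON manifest describing shapes/attributes plus flat little-endian
# float64 arrays, and plain-text spike files. Versioned for forward checks.

BUNDLE_VERSION <- "1"

write_array <- function(x, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(x), con, size = 8, endian = "little")
}

read_array <- function(path, n) {
  con <- file(path, "rb")
  on.exit(close(con))
  out <- readBin(con, "numeric", n = n, size = 8, endian = "little")
  if (length(out) != n)
    stop(sprintf("array file '%s' holds %d values, expected %d",
                 basename(path), length(out), n))
  out
}

#' Write a recording container
#'
#' Stores raw stimulus frames, per-cell spike counts and recording
#' metadata as a directory bundle: `manifest.json`, `stimulus.bin`
#' (float64, row-major frames) and one `spikes_<cell>.txt` per cell.
#'
#' @param path directory to create (overwritten if present).
#' @param stimulus T x D raw frames.
#' @param spikes named list of spike-count vectors (or `spike_counts`).
#' @param bin_width_s,pixel_size_um,seed,contrast recording attributes.
#' @param grid_shape optional `c(rows, cols)`.
#' @return `path`, invisibly.
#' @export
write_container <- function(path, stimulus, spikes, bin_width_s = 1 / 120,
                            pixel_size_um = NA, seed = NA, contrast = NA,
                            grid_shape = NULL) {
  stimulus <- as_frames(stimulus)
  if (is.null(names(spikes)) || any(names(spikes) == ""))
    names(spikes) <- paste0("cell", seq_along(spikes))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(spikes)) {
    y <- as_counts(spikes[[nm]])
    if (length(y) != nrow(stimulus))
      stop(sprintf("spike vector '%s' length %d does not match %d stimulus frames",
                   nm, length(y), nrow(stimulus)))
    writeLines(as.character(y), file.path(path, paste0("spikes_", nm, ".txt")))
  }
  write_array(t(stimulus), file.path(path, "stimulus.bin"))  # row-major
  manifest <- list(version = BUNDLE_VERSION, kind = "recording",
                   T_frames = nrow(stimulus), D = ncol(stimulus),
                   grid_shape = grid_shape, cells = names(spikes),
                   bin_width_s = bin_width_s, pixel_size_um = pixel_size_um,
                   seed = seed, contrast = contrast)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a recording container
#'
#' @param path directory written by [write_container()].
#' @return List with `stimulus` (T x D), `spikes` (named list of
#'   [spike_counts()]), `metadata` (manifest fields).
#' @export
read_container <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop(sprintf("missing manifest: %s", mf))
  m <- jsonlite::read_json(mf, simplifyVector = TRUE)
  for (req in c("version", "T_frames", "D", "cells", "bin_width_s"))
    if (is.null(m[[req]])) stop(sprintf("manifest missing required field '%s'", req))
  if (m$version != BUNDLE_VERSION)
    stop(sprintf("unsupported container version '%s'", m$version))
  sb <- file.path(path, "stimulus.bin")
  if (!file.exists(sb)) stop("missing dataset: stimulus.bin")
  stim <- matrix(read_array(sb, m$T_frames * m$D), m$T_frames, m$D, byrow = TRUE)
  spikes <- list()
  for (nm in m$cells) {
    f <- file.path(path, paste0("spikes_", nm, ".txt"))
    if (!file.exists(f)) stop(sprintf("missing dataset: spikes_%s.txt", nm))
    y <- as.numeric(readLines(f))
    if (length(y) != m$T_frames)
      stop(sprintf("length mismatch for cell '%s': %d counts vs %d frames",
                   nm, length(y), m$T_frames))
    spikes[[nm]] <- spike_counts(y, bin_width = m$bin_width_s)
  }
  extra <- setdiff(list.files(path), c("manifest.json", "stimulus.bin",
                                       paste0("spikes_", m$cells, ".txt")))
  if (length(extra) > 0)
    warning(sprintf("ignoring unknown files in container: %s",
                    paste(extra, collapse = ", ")))
  list(stimulus = stim, spikes = spikes, metadata = m)
}

#' Serialize a fitted subunit model
#'
#' Directory bundle: JSON manifest (N, nonlinearity, grid, bin width, seed,
#' regularization) plus float64 arrays `K.bin`, `w.bin` and optionally
#' `time_course.bin`. The round trip preserves arrays to full precision.
#'
#' @param model a [subunit_model()].
#' @param path directory to create.
#' @param seed,reg optional provenance fields stored in the manifest.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, seed = NA, reg = NULL) {
  if (!inherits(model, "subunit_model")) stop("model must be a subunit_model")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  K <- model$bank$K
  write_array(t(K), file.path(path, "K.bin"))         # row-major
  write_array(model$bank$w, file.path(path, "w.bin"))
  if (!is.null(model$time_course))
    write_array(model$time_course, file.path(path, "time_course.bin"))
  manifest <- list(version = BUNDLE_VERSION, kind = "subunit_model",
                   N = nrow(K), D = ncol(K),
                   a = model$nonlinearity$a, b = model$nonlinearity$b,
                   grid_shape = model$grid_shape,
                   bin_width_s = model$bin_width,
                   L = if (is.null(model$time_course)) NULL
                       else length(model$time_course),
                   seed = seed, reg = reg)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a serialized subunit model
#'
#' @param path directory written by [write_model()].
#' @return A [subunit_model()]; manifest provenance in attribute
#'   `manifest`.
#' @export
read_model <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop(sprintf("missing manifest: %s", mf))
  m <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (is.null(m$version) || m$version != BUNDLE_VERSION)
    stop("unsupported or missing model bundle version")
  if (is.null(m$kind) || m$kind != "subunit_model") stop("not a subunit model bundle")
  K <- matrix(read_array(file.path(path, "K.bin"), m$N * m$D), m$N, m$D,
              byrow = TRUE)
  w <- read_array(file.path(path, "w.bin"), m$N)
  tc <- if (!is.null(m$L))
    read_array(file.path(path, "time_course.bin"), m$L) else NULL
  model <- subunit_model(subunit_bank(K, w), output_nonlinearity(m$a, m$b),
                         time_course = tc,
                         grid_shape = m$grid_shape, bin_width = m$bin_width_s)
  attr(model, "manifest") <- m
  model
}

# known config keys, their sections, types and defaults
config_schema <- function() list(
  data = list(container = list(type = "character", default = NULL)),
  fit = list(n_subunits = list(type = "numeric", default = 5),
             max_iter = list(type = "numeric", default = 100),
             tol = list(type = "numeric", default = 1e-6),
             seed = list(type = "numeric", default = 1),
             init = list(type = "character", default = "sta-noise")),
  reg = list(kind = list(type = "character", default = "none"),
             lam = list(type = "numeric", default = 0, min = 0),
             eps = list(type = "numeric", default = 0.01, min = 1e-12),
             connectivity = list(type = "numeric", default = 4)),
  select = list(n_grid_max = list(type = "numeric", default = 12),
                lam_grid = list(type = "numeric", default = 0),
                repeats = list(type = "numeric", default = 3),
                test_frac = list(type = "numeric", default = 0.1),
                val_frac = list(type = "numeric", default = 0.1)),
  sim = list(preset = list(type = "character", default = "rgc64"),
             minutes = list(type = "numeric", default = 24),
             pixel_gu = list(type = "numeric", default = 6),
             contrast = list(type = "numeric", default = 0.48, min = 0),
             target_rate = list(type = "numeric", default = 19),
             seed = list(type = "numeric", default = 1)),
  null = list(contrast = list(type = "numeric", default = 0.48, min = 0),
              mode = list(type = "character", default = "spatial"),
              tol = list(type = "numeric", default = 1e-8),
              max_iter = list(type = "numeric", default = 200))
)

#' Load and validate a run configuration
#'
#' Reads a sectioned YAML key-value file, rejects unknown sections or keys,
#' type-checks every value, fills defaults for everything unspecified, and
#' (optionally) echoes the fully resolved configuration so runs are
#' reproducible from logs alone.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @param echo print the resolved configuration.
#' @return Nested named list of validated settings.
#' @export
run_config <- function(path = NULL, echo = FALSE) {
  schema <- config_schema()
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (!is.list(user)) stop("config must be a mapping of sections")
  bad_sec <- setdiff(names(user), names(schema))
  if (length(bad_sec) > 0)
    stop(sprintf("unknown config section(s): %s", paste(bad_sec, collapse = ", ")))
  out <- list()
  for (sec in names(schema)) {
    out[[sec]] <- list()
    usec <- user[[sec]] %||% list()
    bad <- setdiff(names(usec), names(schema[[sec]]))
    if (length(bad) > 0)
      stop(sprintf("unknown key(s) in [%s]: %s", sec, paste(bad, collapse = ", ")))
    for (key in names(schema[[sec]])) {
      rule <- schema[[sec]][[key]]
      val <- usec[[key]] %||% rule$default
      if (!is.null(val)) {
        if (rule$type == "numeric" && !is.numeric(val))
          stop(sprintf("[%s] %s must be numeric", sec, key))
        if (rule$type == "character" && !is.character(val))
          stop(sprintf("[%s] %s must be a string", sec, key))
        if (!is.null(rule$min) && any(val < rule$min))
          stop(sprintf("[%s] %s must be >= %g", sec, key, rule$min))
      }
      out[[sec]][[key]] <- val
    }
  }
  if (isTRUE(echo)) {
    cat("# resolved configuration\n")
    cat(yaml::as.yaml(out))
  }
  out
}
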