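## Readers and writers. Trace files are delimited text with '#'-prefixed
## key: value metadata header lines, two numeric columns, 17 significant
## digits -- enough for a bit-exact round trip of doubles, which makes the
## synthetic fixtures hashable. Image stacks are multi-page TIFF with a
## sidecar '#'-keyed .meta text file carrying the pixel size and count scale.

format_meta_value <- function(v) {
  if (is.numeric(v)) sprintf("%.17g", v) else as.character(v)
}

TRACE_KEY_ORDER <- c("kind", "delta_pi_mosm", "delta_ph", "solute",
                     "dead_time_s", "temperature_k", "composition", "seed")

#' Write a trace file
#'
#' Delimited text: '#'-prefixed `key: value` metadata header, then a
#' two-column body (`time_s`, `intensity_au`), tab-separated, 17 significant
#' digits. [read_trace()] followed by [write_trace()] reproduces the file
#' byte for byte.
#'
#' @param trace An `"of_trace"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "of_trace"))
  meta <- trace$meta
  keys <- c(intersect(TRACE_KEY_ORDER, names(meta)),
            sort(setdiff(names(meta), TRACE_KEY_ORDER)))
  header <- vapply(keys, function(k) {
    sprintf("# %s: %s", k, format_meta_value(meta[[k]]))
  }, character(1))
  body <- paste(sprintf("%.17g", trace$times),
                sprintf("%.17g", trace$intensities), sep = "\t")
  writeLines(c(header, "time_s\tintensity_au", body), path)
  invisible(path)
}

parse_meta_lines <- function(lines) {
  meta <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L) stop_format("malformed metadata line: ", ln)
    key <- trimws(m[2])
    val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(val))
    meta[[key]] <- if (!is.na(num) && grepl("^[-+0-9.eEinfINF]+$", val)) {
      num
    } else {
      val
    }
  }
  meta
}

#' Read a trace file
#'
#' Parses the metadata header and the two-column body written by
#' [write_trace()]. The header must carry `delta_pi_mosm`, `dead_time_s`,
#' `temperature_k` and `composition`; fluorescence traces
#' (`kind: fluorescence`) additionally require `delta_ph`. A missing key
#' raises a schema error naming it; a non-increasing time column raises a
#' format error.
#'
#' @param path File path.
#' @return An `"of_trace"`.
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  is_meta <- grepl("^#", lines)
  n_head <- match(FALSE, is_meta) - 1L
  meta <- parse_meta_lines(lines[seq_len(n_head)])
  kind <- if (!is.null(meta$kind)) meta$kind else "shrinkage"
  required <- c("delta_pi_mosm", "dead_time_s", "temperature_k", "composition")
  if (identical(kind, "fluorescence")) required <- c(required, "delta_ph")
  missing_keys <- setdiff(required, names(meta))
  if (length(missing_keys)) {
    stop_schema("missing metadata key(s): ", paste(missing_keys, collapse = ", "))
  }
  body <- lines[-seq_len(n_head + 1L)]  # skip the column-name line too
  if (!identical(lines[n_head + 1L], "time_s\tintensity_au")) {
    stop_format("expected column header 'time_s\\tintensity_au'")
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  times <- as.numeric(vapply(parts, `[[`, character(1), 1))
  intens <- as.numeric(vapply(parts, `[[`, character(1), 2))
  if (anyNA(times) || anyNA(intens)) stop_format("non-numeric trace body")
  if (any(diff(times) <= 0)) {
    stop_format("time column must be strictly increasing")
  }
  new_trace(times, intens, meta)
}

#' Write a contour series as a delimited text table
#'
#' Header carries the angle grid size, mean radius and pixel size; the body
#' is one row per (frame, angle): `frame`, `angle_rad`, `radius_um`, `flag`.
#'
#' @param contours A `"contour_series"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_contours <- function(contours, path) {
  stopifnot(inherits(contours, "contour_series"))
  n_f <- nrow(contours$radii)
  n_a <- length(contours$angles)
  header <- c(sprintf("# mean_radius_um: %.17g", contours$mean_radius),
              sprintf("# pixel_size_um: %.17g", contours$pixel_size),
              sprintf("# n_frames: %d", n_f),
              sprintf("# n_angles: %d", n_a))
  frame_col <- rep(seq_len(n_f), each = n_a)
  angle_col <- rep(contours$angles, times = n_f)
  radius_col <- as.numeric(t(contours$radii))
  flag_col <- rep(as.integer(contours$flags), each = n_a)
  body <- paste(frame_col, sprintf("%.17g", angle_col),
                sprintf("%.17g", radius_col), flag_col, sep = "\t")
  writeLines(c(header, "frame\tangle_rad\tradius_um\tflag", body), path)
  invisible(path)
}

#' Read a contour series table written by [write_contours()]
#'
#' @param path File path.
#' @return A `"contour_series"`.
#' @export
read_contours <- function(path) {
  lines <- readLines(path)
  is_meta <- grepl("^#", lines)
  n_head <- match(FALSE, is_meta) - 1L
  meta <- parse_meta_lines(lines[seq_len(n_head)])
  for (k in c("mean_radius_um", "pixel_size_um", "n_frames", "n_angles")) {
    if (is.null(meta[[k]])) stop_schema("missing metadata key(s): ", k)
  }
  body <- lines[-seq_len(n_head + 1L)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  frame <- as.integer(vapply(parts, `[[`, character(1), 1))
  angle <- as.numeric(vapply(parts, `[[`, character(1), 2))
  ## rejected frames may carry NA radii where no ridge peak was found
  radius_str <- vapply(parts, `[[`, character(1), 3)
  radius <- suppressWarnings(as.numeric(radius_str))
  if (any(is.na(radius) & radius_str != "NA")) {
    stop_format("non-numeric radius in contour table")
  }
  flag <- as.integer(vapply(parts, `[[`, character(1), 4))
  n_f <- meta$n_frames
  n_a <- meta$n_angles
  if (length(frame) != n_f * n_a) stop_format("contour table size mismatch")
  radii <- matrix(radius, nrow = n_f, ncol = n_a, byrow = TRUE)
  flags <- as.logical(flag[seq(1, length(flag), by = n_a)])
  new_contour_series(radii, angle[seq_len(n_a)], meta$mean_radius_um,
                     meta$pixel_size_um, flags = flags, meta = meta)
}

#' Write a rendered frame stack as a multi-page TIFF
#'
#' Counts are scaled into \[0, 1\] 16-bit samples; the scale, pixel size and
#' geometry go into a '#'-keyed sidecar text file `<path>.meta` (the TIFF
#' writer exposes no pixel-size tag).
#'
#' @param stack A `"frame_stack"`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_framestack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  scale <- max(1, max(vapply(stack$frames, max, numeric(1))))
  imgs <- lapply(stack$frames, function(f) f / scale)
  tiff::writeTIFF(imgs, path, bits.per.sample = 16, compression = "deflate")
  meta <- c(sprintf("# pixel_size_um: %.17g", stack$pixel_size),
            sprintf("# count_scale: %.17g", scale),
            sprintf("# center_x_px: %d", stack$center[1]),
            sprintf("# center_y_px: %d", stack$center[2]),
            sprintf("# size_px: %d", stack$size))
  writeLines(meta, paste0(path, ".meta"))
  invisible(path)
}

#' Read a frame stack written by [write_framestack()]
#'
#' @param path TIFF path (expects the `<path>.meta` sidecar).
#' @return A `"frame_stack"` (counts restored approximately to the 16-bit
#'   quantization).
#' @export
read_framestack <- function(path) {
  meta_path <- paste0(path, ".meta")
  if (!file.exists(meta_path)) stop_schema("missing sidecar file: ", meta_path)
  meta <- parse_meta_lines(readLines(meta_path))
  imgs <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(imgs)) imgs <- list(imgs)
  frames <- lapply(imgs, function(f) f * meta$count_scale)
  structure(
    list(frames = frames, pixel_size = meta$pixel_size_um,
         center = c(meta$center_x_px, meta$center_y_px),
         size = meta$size_px),
    class = "frame_stack"
  )
}

RUN_CONFIG_SCHEMA <- list(
  master_seed = "numeric",
  log_level = "character",
  paths = list(out_dir = "character", trace_dir = "character",
               flicker_dir = "character", proton_dir = "character"),
  design = list(delta_pi_mosm = "numeric", temperatures_k = "numeric",
                solutes = "character", replicates = "numeric",
                compositions = "character", n_frames = "numeric"),
  estimators = list(smooth_window = "numeric", stage2_rise_fraction = "numeric",
                    flicker_n_min = "numeric", flicker_n_max = "numeric",
                    flicker_l_max = "numeric", bootstrap_count = "numeric")
)

check_config_keys <- function(cfg, schema, prefix = "") {
  unknown <- setdiff(names(cfg), names(schema))
  if (length(unknown)) {
    stop_schema("unknown config key(s): ",
                paste0(prefix, unknown, collapse = ", "))
  }
  for (k in names(cfg)) {
    if (is.list(schema[[k]]) && !is.null(names(schema[[k]]))) {
      if (!is.list(cfg[[k]])) stop_schema("config key ", prefix, k,
                                          " must be a section")
      check_config_keys(cfg[[k]], schema[[k]], paste0(prefix, k, "."))
    }
  }
  invisible(TRUE)
}

#' Read a run configuration file
#'
#' YAML with nested sections (`paths`, `design`, `estimators`) plus
#' `master_seed` and `log_level`. All physical quantities carry explicit unit
#' suffixes in their key names (e.g. `delta_pi_mosm`, `temperatures_k`).
#' Unknown keys are rejected with a schema error.
#'
#' @param path YAML file path.
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  check_config_keys(cfg, RUN_CONFIG_SCHEMA)
  cfg
}
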