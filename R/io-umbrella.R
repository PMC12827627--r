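#' Umbrella-sampling window tables
#'
#' Umbrella windows are held in a tibble with one row per window:
#' `center` (bias centre, nm), `force_constant` (kJ mol^-1 nm^-2),
#' `samples` (list-column of reaction-coordinate series, nm) and
#' `sample_spacing` (ns between samples).  [umbrella_windows()] builds and
#' validates such a table.
#'
#' @param center Numeric bias centres, nm.
#' @param force_constant Harmonic bias force constants, kJ mol^-1 nm^-2
#'   (recycled).
#' @param samples List of numeric reaction-coordinate series, nm.
#' @param sample_spacing Time between samples, ns (recycled).
#'
#' @return A tibble of class `umbrella_windows`.
#' @export
umbrella_windows <- function(center, force_constant, samples,
                             sample_spacing = 1) {
  tb <- tibble::tibble(
    center = as.numeric(center),
    force_constant = as.numeric(force_constant),
    samples = samples,
    sample_spacing = as.numeric(sample_spacing)
  )
  if (any(!is.finite(tb$center))) stop("window centers must be finite",
                                       call. = FALSE)
  if (any(tb$force_constant <= 0)) {
    stop("force constants must be positive", call. = FALSE)
  }
  for (i in seq_len(nrow(tb))) {
    s <- tb$samples[[i]]
    if (length(s) == 0 || any(!is.finite(s))) {
      stop("window ", i, " has empty or non-finite samples", call. = FALSE)
    }
  }
  class(tb) <- c("umbrella_windows", class(tibble::tibble()))
  tb
}

#' Read umbrella windows from a manifest file
#'
#' The manifest is whitespace-separated text with one row per window:
#' `path center force_constant` (path relative to the manifest's
#' directory unless absolute).  Window files are two-column time/coordinate
#' text; comment lines starting with `#` or `@` (the dialect emitted by
#' common pulling codes) are skipped.  Coordinates are taken to be in nm.
#'
#' @param manifest Path to the manifest file.
#' @return An [umbrella_windows()] tibble, rows in manifest order.
#' @export
read_umbrella_manifest <- function(manifest) {
  if (!file.exists(manifest)) stop("no such file: ", manifest, call. = FALSE)
  lines <- readLines(manifest)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) stop("empty manifest: ", manifest, call. = FALSE)
  parts <- strsplit(lines, "\\s+")
  bad <- which(lengths(parts) < 3)
  if (length(bad) > 0) {
    stop("manifest row ", bad[1], " does not have 3 fields", call. = FALSE)
  }
  base <- dirname(manifest)
  paths <- vapply(parts, `[`, character(1), 1)
  paths <- ifelse(grepl("^(/|[A-Za-z]:)", paths), paths,
                  file.path(base, paths))
  centers <- as.numeric(vapply(parts, `[`, character(1), 2))
  ks <- as.numeric(vapply(parts, `[`, character(1), 3))
  if (any(!is.finite(centers)) || any(!is.finite(ks))) {
    stop("non-numeric center or force constant in manifest", call. = FALSE)
  }
  samples <- lapply(seq_along(paths), function(i) {
    read_window_series(paths[i])
  })
  spacing <- vapply(samples, function(s) s$spacing, numeric(1))
  umbrella_windows(centers, ks, lapply(samples, `[[`, "values"),
                   sample_spacing = spacing)
}

read_window_series <- function(path) {
  if (!file.exists(path)) {
    stop("window file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "@")]
  if (length(lines) == 0) stop("empty window file: ", path, call. = FALSE)
  parts <- strsplit(lines, "\\s+")
  t <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 1)))
  v <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 2)))
  if (any(is.na(t)) || any(is.na(v))) {
    stop("non-numeric sample in window file: ", path, call. = FALSE)
  }
  spacing <- if (length(t) > 1) stats::median(diff(t)) else 1
  if (!is.finite(spacing) || spacing <= 0) spacing <- 1
  list(values = v, spacing = spacing)
}

#' Write umbrella windows and their manifest
#'
#' Emits one two-column (time, coordinate) text file per window plus a
#' manifest in the three-column format [read_umbrella_manifest()] reads.
#'
#' @param windows An [umbrella_windows()] tibble.
#' @param dir Output directory (created if absent).
#' @param prefix File-name prefix for the per-window files.
#' @return The manifest path, invisibly.
#' @export
write_umbrella_windows <- function(windows, dir, prefix = "window") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- sprintf("%s_%03d.xvg", prefix, seq_len(nrow(windows)))
  for (i in seq_len(nrow(windows))) {
    s <- windows$samples[[i]]
    t <- (seq_along(s) - 1) * windows$sample_spacing[i]
    writeLines(
      c("@ reaction coordinate series (time ns, position nm)",
        sprintf("%.6f %.8f", t, s)),
      file.path(dir, files[i])
    )
  }
  manifest <- file.path(dir, paste0(prefix, "_manifest.txt"))
  writeLines(
    c("# path center_nm force_constant_kJ_mol_nm2",
      sprintf("%s %.6f %.6f", files, windows$center,
              windows$force_constant)),
    manifest
  )
  invisible(manifest)
}
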