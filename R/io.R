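# Plain-text I/O: multi-frame XYZ-style trajectories, key = value run
# configuration files, and feature tables.

#' Write a trajectory as multi-frame XYZ text
#'
#' Each frame is written as an XYZ block: a record count line (20), a
#' comment line carrying the frame index, save interval and (when known)
#' the truth label, and 20 coordinate records labeled `s<strand>b<base>`.
#' Units are nm and ns.
#'
#' @param trajectory a `duplex_trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_xyz_trajectory <- function(trajectory, path) {
  fr <- trajectory$frames
  n <- dim(fr)[1L]
  labs <- trajectory$truth_labels
  con <- file(path, "w")
  on.exit(close(con))
  names_sb <- paste0("s", rep(1:2, times = 10), "b",
                     sprintf("%02d", rep(1:10, each = 2)))
  for (t in seq_len(n)) {
    cat("20\n", file = con)
    cat(sprintf("frame %d dt_save=%g%s\n", t, trajectory$dt_save,
                if (!is.null(labs)) paste0(" label=", labs[t]) else ""),
        file = con)
    X <- matrix(fr[t, , , ], nrow = 20L)   # rows: (strand, base) pairs
    for (r in seq_len(20L))
      cat(sprintf("%s %.6f %.6f %.6f\n", names_sb[r],
                  X[r, 1L], X[r, 2L], X[r, 3L]), file = con)
  }
  invisible(path)
}

#' Read a multi-frame XYZ trajectory written by [write_xyz_trajectory()]
#'
#' @param path input file.
#' @return A `duplex_trajectory` (with `truth_labels` when present).
#' @export
read_xyz_trajectory <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 22L != 0L)
    stop("malformed XYZ trajectory: expected 22 lines per frame")
  n <- length(lines) %/% 22L
  coords <- matrix(0, n, 60L)
  labs <- character(n)
  dt <- NA_real_
  for (t in seq_len(n)) {
    base <- (t - 1L) * 22L
    hdr <- lines[base + 2L]
    dt <- as.numeric(sub(".*dt_save=([0-9.eE+-]+).*", "\\1", hdr))
    labs[t] <- if (grepl("label=", hdr))
      sub(".*label=(\\S+).*", "\\1", hdr) else NA_character_
    rec <- strsplit(lines[base + 2L + seq_len(20L)], "\\s+")
    X <- t(vapply(rec, function(r) as.numeric(r[2:4]), numeric(3)))
    # rows are (strand, base) in strand-fastest order; reshape to n x 60
    coords[t, ] <- as.vector(X)
  }
  new_trajectory(coords, dt, NA_integer_,
                 if (all(is.na(labs))) NULL else labs)
}

#' Write / read a simple `key = value` configuration file
#'
#' Values are stored with `deparse`; vectors and strings round-trip.
#'
#' @param config named list.
#' @param path file path.
#' @return `write_run_config`: `path` invisibly; `read_run_config`: the
#'   named list.
#' @export
write_run_config <- function(config, path) {
  stopifnot(!is.null(names(config)), all(nzchar(names(config))))
  lines <- vapply(names(config), function(k)
    paste0(k, " = ", paste(deparse(config[[k]]), collapse = "")),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    key <- trimws(parts[1L])
    val <- trimws(paste(parts[-1L], collapse = "="))
    out[[key]] <- eval(parse(text = val), envir = baseenv())
  }
  out
}

#' Write a feature series as a TSV table with a header comment
#'
#' One row per frame, 100 columns in row-major `(i, j)` order over the
#' strand-1 x strand-2 base indices, units 1/nm.
#'
#' @param features a `feature_series` matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_feature_series <- function(features, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cat("# symmetrized reciprocal interbase distances (1/nm)\n", file = con)
  cat("# column order: row-major over (strand1 base i, strand2 base j)\n",
      file = con)
  cat(sprintf("# dt_save=%g\n", attr(features, "dt_save")), file = con)
  utils::write.table(unclass(features), con, sep = "\t",
                     row.names = FALSE,
                     col.names = paste0("f", sprintf("%02d_%02d",
                                                     rep(1:10, each = 10),
                                                     rep(1:10, times = 10))))
  invisible(path)
}

#' Serialize a slow-mode model to structured JSON
#'
#' Writes lag, mean, projection components, eigenvalues and retained
#' feature indices so a model fitted on one data set can be applied to
#' unseen data later.
#'
#' @param model a [slow_mode_model][fit_linear_slow_modes].
#' @param path file path.
#' @return `write_slow_modes`: `path` invisibly; `read_slow_modes`: the
#'   model.
#' @export
write_slow_modes <- function(model, path) {
  stopifnot(inherits(model, "slow_mode_model"))
  payload <- list(lag = model$lag, mean = model$mean,
                  components = model$components,
                  eigenvalues = model$eigenvalues,
                  n_modes = model$n_modes, kept = model$kept,
                  reg = model$reg, dt = model$dt)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_slow_modes
#' @export
read_slow_modes <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  p$components <- matrix(p$components, nrow = p$n_modes)
  structure(p, class = "slow_mode_model")
}

#' @rdname write_feature_series
#' @export
read_feature_series <- function(path) {
  hdr <- readLines(path, n = 5L)
  dt <- as.numeric(sub("# dt_save=", "",
                       grep("^# dt_save=", hdr, value = TRUE)[1L]))
  f <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   comment.char = "#"))
  dimnames(f) <- NULL
  attr(f, "dt_save") <- dt
  class(f) <- c("feature_series", class(f))
  f
}
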