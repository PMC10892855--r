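# Readers/writers: delimited signal files with a sampling-rate header,
# fuzzy-system YAML documents, and session configs.

#' Write an EMG signal to a delimited text file
#'
#' Two-column whitespace-delimited text `(time_s, amplitude)` preceded
#' by a one-line header `# fs=<Hz>`. Amplitudes are written with full
#' double precision so a write/read round trip is bit-preserving.
#'
#' @param signal An [emg_signal()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_emg_signal <- function(signal, path) {
  stopifnot(inherits(signal, "emg_signal"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.17g channel=%s", signal$sampling_rate,
                     signal$channel_label), con)
  t <- signal_times(signal)
  writeLines(sprintf("%.17g %.17g", t, signal$samples), con)
  invisible(path)
}

#' Read an EMG signal from a delimited text file
#'
#' Expects the format written by [write_emg_signal()]. The time column
#' must be uniform at the header rate to within 1 ppm; a skipped sample
#' is reported with the offending line number.
#'
#' @param path Input file path.
#' @return An [emg_signal()].
#' @export
read_emg_signal <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L || !grepl("^#\\s*fs=", lines[1])) {
    stop_input("read_emg_signal: ", path, ": line 1: missing '# fs=<Hz>' header")
  }
  fs <- as.numeric(sub("^#\\s*fs=(\\S+).*$", "\\1", lines[1]))
  if (!is.finite(fs) || fs <= 0) {
    stop_input("read_emg_signal: ", path, ": line 1: invalid sampling rate")
  }
  channel <- if (grepl("channel=", lines[1])) {
    sub("^.*channel=(\\S+).*$", "\\1", lines[1])
  } else "EMG"
  body <- lines[-1]
  if (length(body) == 0L) {
    stop_input("read_emg_signal: ", path, ": no data rows after the header")
  }
  parts <- strsplit(trimws(body), "\\s+")
  bad <- which(vapply(parts, length, integer(1)) != 2L)
  if (length(bad)) {
    stop_input("read_emg_signal: ", path, ": line ", bad[1] + 1L,
               ": expected two numeric columns")
  }
  m <- matrix(as.numeric(unlist(parts)), ncol = 2, byrow = TRUE)
  if (any(!is.finite(m))) {
    bad <- which(!is.finite(m[, 1]) | !is.finite(m[, 2]))[1]
    stop_input("read_emg_signal: ", path, ": line ", bad + 1L, ": non-numeric row")
  }
  if (nrow(m) > 1L) {
    dt <- diff(m[, 1])
    bad <- which(abs(dt - 1 / fs) > 1e-6 / fs)
    if (length(bad)) {
      stop_input("read_emg_signal: ", path, ": line ", bad[1] + 2L,
                 ": time step ", format(dt[bad[1]]),
                 " s deviates from 1/fs = ", format(1 / fs),
                 " s (non-uniform or skipped sample)")
    }
  }
  emg_signal(m[, 2], fs, channel)
}

#' Write a per-window feature table
#'
#' Delimited text with columns `start_time`, the four raw features and
#' their normalized twins.
#'
#' @param features Matrix/data frame of raw features (rows = windows).
#' @param start_times Window start times in seconds.
#' @param map A [fit_normalization()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, start_times, map, path) {
  features <- as.data.frame(features)[, feature_names]
  norm <- t(apply(features, 1, normalize_features, map = map))
  colnames(norm) <- paste0(feature_names, "_norm")
  out <- cbind(start_time = start_times, features, norm)
  utils::write.table(format(out, digits = 10), path, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

fuzzy_system_to_list <- function(system) {
  var_list <- function(v) {
    list(name = v$name, range = as.list(v$range),
         mfs = lapply(v$mfs, function(m) {
           list(label = m$label, center = m$center, sigma = m$sigma)
         }))
  }
  list(
    inputs = lapply(unname(system$inputs), var_list),
    output = var_list(system$output),
    grid_points = system$grid_points,
    # one compact string per rule: "var=label & var=label => consequent"
    rules = vapply(system$rules, function(r) {
      paste0(paste(names(r$antecedent), r$antecedent, sep = "=", collapse = " & "),
             " => ", r$consequent)
    }, character(1))
  )
}

parse_rule_string <- function(s) {
  parts <- strsplit(s, "=>", fixed = TRUE)[[1]]
  if (length(parts) != 2L) stop_config("malformed rule string: '", s, "'")
  terms <- strsplit(trimws(strsplit(parts[1], "&", fixed = TRUE)[[1]]), "=", fixed = TRUE)
  if (any(vapply(terms, length, integer(1)) != 2L)) {
    stop_config("malformed antecedent in rule: '", s, "'")
  }
  ante <- vapply(terms, `[`, character(1), 2)
  names(ante) <- vapply(terms, `[`, character(1), 1)
  fuzzy_rule(ante, trimws(parts[2]))
}

fuzzy_system_from_list <- function(x) {
  var_from <- function(v) {
    fuzzy_variable(v$name, unlist(v$range),
                   mfs = lapply(v$mfs, function(m) {
                     gaussian_mf(m$label, m$center, m$sigma)
                   }))
  }
  inputs <- lapply(x$inputs, var_from)
  output <- var_from(x$output)
  rules <- lapply(x$rules, parse_rule_string)
  fuzzy_system(inputs, output, rules, x$grid_points)
}

#' Serialize a fuzzy system to a YAML document
#'
#' The document carries every variable (name, range, MF centers and
#' sigmas) and every rule as label tuples; [load_fuzzy_system()] reads
#' it back losslessly, so shipped defaults can be hand-edited.
#'
#' @param system A [fuzzy_system()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
dump_fuzzy_system <- function(system, path) {
  stopifnot(inherits(system, "fuzzy_system"))
  yaml::write_yaml(fuzzy_system_to_list(system), path, precision = 15)
  invisible(path)
}

#' Load a fuzzy system from a YAML document
#'
#' Validation failures (unknown labels or variables in a rule,
#' malformed ranges) raise configuration errors naming the offending
#' rule or variable.
#'
#' @param path Input file path.
#' @return A [fuzzy_system()].
#' @export
load_fuzzy_system <- function(path) {
  x <- yaml::read_yaml(path)
  tryCatch(fuzzy_system_from_list(x), error = function(e) {
    stop_config("load_fuzzy_system: ", path, ": ", conditionMessage(e))
  })
}

#' Load a session configuration from a YAML document
#'
#' Keys mirror the arguments of [session_config()]; unknown keys raise
#' a configuration error naming them.
#'
#' @param path Input file path.
#' @return A [session_config()].
#' @export
load_session_config <- function(path) {
  x <- yaml::read_yaml(path)
  allowed <- names(formals(session_config))
  unknown <- setdiff(names(x), allowed)
  if (length(unknown)) {
    stop_config("load_session_config: ", path, ": unknown key(s): ",
                paste(unknown, collapse = ", "))
  }
  do.call(session_config, x)
}

#' Write the session log and summary
#'
#' The per-iteration records go to `<dir>/session_log.tsv` (delimited
#' text), a line-delimited event stream to `<dir>/events.ndjson`-style
#' `events.log`, and the summary (initial/final RoM, recovery percent,
#' activation counts) to `<dir>/summary.yaml`.
#'
#' @param log A [run_session()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_session_log <- function(log, dir) {
  stopifnot(inherits(log, "session_log"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.table(log$records, file.path(dir, "session_log.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  events <- apply(log$records, 1, function(r) {
    paste0("iteration=", trimws(r[["iteration"]]),
           " stimulation=", r[["active_stimulation"]],
           " pain=", trimws(r[["pain_level"]]))
  })
  writeLines(events, file.path(dir, "events.log"))
  yaml::write_yaml(log$summary, file.path(dir, "summary.yaml"))
  invisible(dir)
}
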