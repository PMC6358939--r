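# Delimited-text readers and writers for every pipeline artifact. All files
# are plain text: a small comment header carrying the tool version and a
# config hash, then the data section. Writes are atomic (write to a
# temporary file in the target directory, then rename).

pkg_version <- function() {
  as.character(utils::packageVersion("seatbeat"))
}

artifact_header <- function(config_string = "") {
  c(sprintf("# seatbeat %s", pkg_version()),
    sprintf("# config_hash %s", fnv1a32(config_string)))
}

atomic_write_lines <- function(lines, path) {
  dir <- dirname(path)
  tmp <- tempfile(tmpdir = if (nzchar(dir)) dir else ".", fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  if (!file.rename(tmp, path)) stop_domain("could not write ", path)
  invisible(path)
}

fmt17 <- function(x) sprintf("%.17g", x)

read_data_lines <- function(path) {
  if (!file.exists(path)) stop_domain("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], line_no = which(keep))
}

#' Read and write pressure recordings
#'
#' Recordings are stored as delimited text with header
#' `time_s,s001,...,s256` (sensors row-major, sensor 1 at row 1 / column 1 of
#' the mat), one row per sample, values serialized with 17 significant
#' digits so a write/read round trip is exact. Comment lines start with `#`.
#' Malformed headers, ragged rows, an empty data section or a non-monotone
#' time column are parse errors naming the offending line.
#'
#' @param recording A `pressure_recording`.
#' @param path File path.
#' @return `read_recording` returns a `pressure_recording`;
#'   `write_recording` returns `path` invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "pressure_recording"))
  n <- nrow(recording$samples)
  t <- (seq_len(n) - 1) / recording$sample_rate
  header <- paste(c("time_s", sprintf("s%03d", seq_len(MAT_NSENSOR))),
                  collapse = ",")
  body <- vapply(seq_len(n), function(i) {
    paste(fmt17(c(t[i], recording$samples[i, ])), collapse = ",")
  }, character(1))
  cfg <- sprintf("recording rate=%.17g duration=%.17g posture=%s",
                 recording$sample_rate, recording$duration,
                 as.character(recording$posture_id %||% NA))
  atomic_write_lines(c(artifact_header(cfg), header, body), path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  dat <- read_data_lines(path)
  if (length(dat$lines) < 2L) {
    stop_domain("empty data section in ", path)
  }
  expected <- paste(c("time_s", sprintf("s%03d", seq_len(MAT_NSENSOR))),
                    collapse = ",")
  if (trimws(dat$lines[1]) != expected) {
    stop_domain(sprintf("line %d: header must be `time_s,s001..s256`",
                        dat$line_no[1]))
  }
  rows <- strsplit(dat$lines[-1L], ",", fixed = TRUE)
  widths <- lengths(rows)
  if (any(widths != MAT_NSENSOR + 1L)) {
    bad <- which(widths != MAT_NSENSOR + 1L)[1]
    stop_domain(sprintf("line %d: expected %d fields, found %d",
                        dat$line_no[1 + bad], MAT_NSENSOR + 1L, widths[bad]))
  }
  vals <- matrix(as.numeric(unlist(rows)), nrow = length(rows), byrow = TRUE)
  if (anyNA(vals)) {
    bad <- which(apply(vals, 1, anyNA))[1]
    stop_domain(sprintf("line %d: non-numeric field", dat$line_no[1 + bad]))
  }
  t <- vals[, 1]
  if (length(t) > 1L && any(diff(t) <= 0)) {
    bad <- which(diff(t) <= 0)[1] + 1L
    stop_domain(sprintf("line %d: time column must be strictly increasing",
                        dat$line_no[1 + bad]))
  }
  sample_rate <- if (length(t) > 1L) 1 / mean(diff(t)) else 1
  samples <- vals[, -1L, drop = FALSE]
  colnames(samples) <- sprintf("s%03d", seq_len(MAT_NSENSOR))
  structure(
    list(samples = samples, sample_rate = sample_rate,
         duration = nrow(samples) / sample_rate, posture_id = NA_integer_),
    class = "pressure_recording"
  )
}

#' Read and write 16x16 frame files
#'
#' A frame file is 16 comma-delimited rows of 16 values (optionally preceded
#' by `#` comment lines).
#'
#' @param frame 16x16 numeric matrix.
#' @param path File path.
#' @export
write_frame <- function(frame, path) {
  check_frame(frame)
  body <- apply(frame, 1, function(r) paste(fmt17(r), collapse = ","))
  atomic_write_lines(c(artifact_header("frame"), body), path)
}

#' @rdname write_frame
#' @export
read_frame <- function(path) {
  dat <- read_data_lines(path)
  if (length(dat$lines) != MAT_NROW) {
    stop_domain(sprintf("frame file must have %d data rows, found %d",
                        MAT_NROW, length(dat$lines)))
  }
  rows <- strsplit(dat$lines, ",", fixed = TRUE)
  if (any(lengths(rows) != MAT_NCOL)) {
    stop_domain("every frame row must have 16 fields")
  }
  matrix(as.numeric(unlist(rows)), MAT_NROW, MAT_NCOL, byrow = TRUE)
}

#' Read and write a univariate series (e.g. the ECG reference)
#'
#' Stored as delimited text with header `time_s,value`.
#'
#' @param x Numeric series.
#' @param sample_rate Sampling rate in Hz.
#' @param path File path.
#' @export
write_series <- function(x, sample_rate, path) {
  t <- (seq_along(x) - 1) / sample_rate
  body <- paste(fmt17(t), fmt17(x), sep = ",")
  atomic_write_lines(c(artifact_header("series"), "time_s,value", body), path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  dat <- read_data_lines(path)
  if (length(dat$lines) < 2L || trimws(dat$lines[1]) != "time_s,value") {
    stop_domain("series file must start with header `time_s,value` and contain data")
  }
  rows <- strsplit(dat$lines[-1L], ",", fixed = TRUE)
  if (any(lengths(rows) != 2L)) stop_domain("series rows must have 2 fields")
  vals <- matrix(as.numeric(unlist(rows)), ncol = 2L, byrow = TRUE)
  t <- vals[, 1]
  rate <- if (nrow(vals) > 1L) 1 / mean(diff(t)) else 1
  list(value = vals[, 2], sample_rate = rate)
}

# --- key-value files ------------------------------------------------------

write_kv <- function(kv, path, config_string = "kv") {
  lines <- c(artifact_header(config_string),
             paste(names(kv), vapply(kv, as.character, character(1)),
                   sep = " = "))
  atomic_write_lines(lines, path)
}

read_kv <- function(path) {
  dat <- read_data_lines(path)
  parts <- regmatches(dat$lines,
                      regexec("^\\s*([^=[:space:]]+)\\s*=\\s*(.*)$",
                              dat$lines))
  bad <- vapply(parts, length, integer(1)) != 3L
  if (any(bad)) {
    stop_domain(sprintf("line %d: expected `key = value`",
                        dat$line_no[which(bad)[1]]))
  }
  vals <- vapply(parts, `[`, character(1), 3L)
  names(vals) <- vapply(parts, `[`, character(1), 2L)
  as.list(vals)
}

#' Write / read the simulation ground truth sidecar
#'
#' Key-value text recording the true best sensor, heart rate, posture and
#' seed of a synthetic recording.
#'
#' @param truth A `synthetic_truth`.
#' @param path File path.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  write_kv(list(true_best_sensor = truth$true_best_sensor,
                heart_rate = truth$config$heart_rate,
                posture_id = truth$config$posture_id,
                seed = truth$config$seed),
           path, "truth")
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  kv <- read_kv(path)
  list(true_best_sensor = as.integer(kv$true_best_sensor),
       heart_rate = as.numeric(kv$heart_rate),
       posture_id = as.integer(kv$posture_id),
       seed = as.integer(kv$seed))
}

# --- feature tables -------------------------------------------------------

#' Read and write labelled feature tables
#'
#' Delimited text with the 19 named feature columns followed by `label` and
#' `subject` columns.
#'
#' @param features Numeric matrix with the 19 feature columns.
#' @param labels Integer labels (one per row).
#' @param subject Integer subject ids (one per row, optional).
#' @param path File path.
#' @export
write_features <- function(features, labels, path,
                           subject = rep(NA_integer_, length(labels))) {
  features <- rbind(features)
  stopifnot(nrow(features) == length(labels))
  header <- paste(c(colnames(features) %||% FEATURE_NAMES, "label", "subject"),
                  collapse = ",")
  body <- vapply(seq_len(nrow(features)), function(i) {
    paste(c(fmt17(features[i, ]), labels[i], subject[i]), collapse = ",")
  }, character(1))
  atomic_write_lines(c(artifact_header("features"), header, body), path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  dat <- read_data_lines(path)
  if (length(dat$lines) < 2L) stop_domain("empty feature table in ", path)
  cols <- strsplit(dat$lines[1], ",", fixed = TRUE)[[1]]
  rows <- strsplit(dat$lines[-1L], ",", fixed = TRUE)
  if (any(lengths(rows) != length(cols))) {
    stop_domain("ragged rows in feature table ", path)
  }
  vals <- matrix(as.numeric(unlist(rows)), nrow = length(rows), byrow = TRUE)
  colnames(vals) <- cols
  fcols <- setdiff(cols, c("label", "subject"))
  list(features = vals[, fcols, drop = FALSE],
       labels = as.integer(vals[, "label"]),
       subject = if ("subject" %in% cols) as.integer(vals[, "subject"]) else NULL)
}

#' Serialize a posture dataset as one frame-per-row table
#'
#' Each row holds one flattened 16x16 frame (row-major cells `s001..s256`)
#' with its posture label and subject id.
#'
#' @param dataset A `posture_dataset`.
#' @param path File path.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "posture_dataset"))
  header <- paste(c("label", "subject", sprintf("s%03d", seq_len(MAT_NSENSOR))),
                  collapse = ",")
  body <- vapply(seq_along(dataset$labels), function(i) {
    paste(c(dataset$labels[i], dataset$subject[i],
            fmt17(grid_to_sensor_vector(dataset$frames[, , i]))),
          collapse = ",")
  }, character(1))
  atomic_write_lines(c(artifact_header("dataset"), header, body), path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  dat <- read_data_lines(path)
  if (length(dat$lines) < 2L) stop_domain("empty dataset file ", path)
  expected <- paste(c("label", "subject",
                      sprintf("s%03d", seq_len(MAT_NSENSOR))), collapse = ",")
  if (trimws(dat$lines[1]) != expected) {
    stop_domain("dataset header must be `label,subject,s001..s256`")
  }
  rows <- strsplit(dat$lines[-1L], ",", fixed = TRUE)
  if (any(lengths(rows) != MAT_NSENSOR + 2L)) {
    stop_domain("ragged rows in dataset file ", path)
  }
  vals <- matrix(as.numeric(unlist(rows)), nrow = length(rows), byrow = TRUE)
  n <- nrow(vals)
  frames <- array(NA_real_, c(MAT_NROW, MAT_NCOL, n))
  for (i in seq_len(n)) {
    frames[, , i] <- sensor_vector_to_grid(vals[i, -(1:2)])
  }
  structure(list(frames = frames, labels = as.integer(vals[, 1]),
                 subject = as.integer(vals[, 2])),
            class = "posture_dataset")
}

# --- model files ----------------------------------------------------------

#' Serialize / deserialize an ELM model as text
#'
#' Key-value metadata plus decimal matrix blocks (17 significant digits), so
#' a write/read round trip reproduces the model exactly.
#'
#' @param model An `elm_model`.
#' @param path File path.
#' @export
write_elm_model <- function(model, path) {
  stopifnot(inherits(model, "elm_model"))
  mat_block <- function(name, m) {
    m <- rbind(m)
    c(sprintf("@%s %d %d", name, nrow(m), ncol(m)),
      apply(m, 1, function(r) paste(fmt17(r), collapse = ",")))
  }
  lines <- c(
    artifact_header("elm_model"),
    sprintf("activation = %s", model$activation),
    sprintf("n_hidden = %d", model$n_hidden),
    sprintf("n_classes = %d", model$n_classes),
    sprintf("seed = %s", model$seed),
    sprintf("feature_order = %s",
            paste(model$feature_order %||% character(0), collapse = ",")),
    mat_block("A", model$A),
    mat_block("B", matrix(model$B, nrow = 1)),
    mat_block("beta", model$beta)
  )
  if (!is.null(model$scaler)) {
    lines <- c(lines, mat_block("scaler",
                                matrix(model$scaler$denominators, nrow = 1)))
  }
  atomic_write_lines(lines, path)
}

#' @rdname write_elm_model
#' @export
read_elm_model <- function(path) {
  dat <- read_data_lines(path)
  lines <- dat$lines
  at <- grep("^@", lines)
  kv_lines <- lines[setdiff(seq_along(lines), c(at, unlist(mapply(
    function(s) {
      hdr <- strsplit(lines[s], " ")[[1]]
      s + seq_len(as.integer(hdr[2]))
    }, at, SIMPLIFY = FALSE))))]
  kv <- list()
  for (l in kv_lines) {
    p <- regmatches(l, regexec("^\\s*([^=[:space:]]+)\\s*=\\s*(.*)$", l))[[1]]
    if (length(p) == 3L) kv[[p[2]]] <- p[3]
  }
  blocks <- list()
  for (s in at) {
    hdr <- strsplit(lines[s], " ")[[1]]
    name <- sub("^@", "", hdr[1])
    nr <- as.integer(hdr[2]); nc <- as.integer(hdr[3])
    rows <- strsplit(lines[s + seq_len(nr)], ",", fixed = TRUE)
    blocks[[name]] <- matrix(as.numeric(unlist(rows)), nr, nc, byrow = TRUE)
  }
  feature_order <- strsplit(kv$feature_order %||% "", ",")[[1]]
  scaler <- if (!is.null(blocks$scaler)) {
    den <- as.vector(blocks$scaler)
    if (length(feature_order) == length(den)) names(den) <- feature_order
    structure(list(denominators = den), class = "feature_scaler")
  } else {
    NULL
  }
  structure(
    list(A = blocks$A, B = as.vector(blocks$B), beta = blocks$beta,
         activation = kv$activation, n_hidden = as.integer(kv$n_hidden),
         n_classes = as.integer(kv$n_classes),
         seed = suppressWarnings(as.integer(kv$seed)),
         feature_order = if (length(feature_order)) feature_order else NULL,
         scaler = scaler),
    class = "elm_model"
  )
}

# --- correlation maps / selection ----------------------------------------

#' Write a correlation map as an indexed table
#'
#' 256-row delimited table with columns `sensor,rho,lag`.
#'
#' @param map A `correlation_map`.
#' @param path File path.
#' @export
write_correlation_map <- function(map, path) {
  stopifnot(inherits(map, "correlation_map"))
  body <- paste(seq_along(map$rho), fmt17(map$rho), map$lag, sep = ",")
  atomic_write_lines(c(artifact_header("correlation_map"), "sensor,rho,lag",
                       body), path)
}

#' Write a posture-sweep / selection table
#'
#' Delimited text mirroring the monitoring-point table layout:
#' `posture,extractable,monitoring_point,correlation`.
#'
#' @param table Data frame as returned by [posture_sweep()].
#' @param path File path.
#' @export
write_sweep_table <- function(table, path) {
  body <- vapply(seq_len(nrow(table)), function(i) {
    paste(c(table$posture[i],
            if (table$extractable[i]) "yes" else "no",
            if (is.na(table$monitoring_point[i])) "x"
            else table$monitoring_point[i],
            fmt17(table$correlation[i])),
          collapse = ",")
  }, character(1))
  atomic_write_lines(c(artifact_header("sweep"),
                       "posture,extractable,monitoring_point,correlation",
                       body), path)
}
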