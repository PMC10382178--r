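# Reading/writing motion time-series tables. Two text dialects are
# supported: the OpenSim Storage dialect (.sto/.mot: header lines `name`,
# `nRows=`, `nColumns=`, optional `inDegrees=`, `endheader` sentinel, then
# a tab-delimited column-name row and data rows, first column `time`) and
# RFC-4180 CSV. Angles are radians internally; tables may be written in
# degrees with an explicit unit flag, following the .mot convention.

#' Construct a motion time-series table
#'
#' @param data data.frame whose first column is `time` (seconds, strictly
#'   increasing and uniform within tolerance) followed by numeric signal
#'   columns.
#' @param units unit tag for the non-time columns (free-form, e.g.
#'   `"radians"`, `"N*m"`, `"m"`); used for the degrees round-trip flag.
#' @param name table name written into storage headers.
#' @return object of class `"motion_table"` (a data.frame subclass with
#'   `units` and `table_name` attributes).
#' @export
motion_table <- function(data, units = "radians", name = "motion") {
  data <- as.data.frame(data)
  if (names(data)[1] != "time") stop("first column must be 'time'")
  if (nrow(data) < 2L) stop("a motion table needs at least 2 rows")
  validate_time(data$time)
  structure(data, units = units, table_name = name,
            class = c("motion_table", "data.frame"))
}

validate_time <- function(time, tol = 1e-6) {
  dt <- diff(time)
  if (any(dt <= 0)) stop("time column must be strictly increasing")
  if (length(dt) > 1 && (max(dt) - min(dt)) > tol * stats::median(dt))
    stop("time column must be uniformly sampled")
  invisible(time)
}

fmt_num <- function(x) formatC(x, digits = 17, format = "g")

#' Write a time-series table
#'
#' @param table a [motion_table()] (or plain data.frame with a leading
#'   `time` column).
#' @param path output file path.
#' @param dialect `"storage"` (OpenSim .sto/.mot) or `"csv"`.
#' @param in_degrees if `TRUE`, non-time columns are converted from the
#'   internal radians to degrees on write (and flagged `inDegrees=yes` in
#'   storage headers).
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path, dialect = c("storage", "csv"),
                        in_degrees = FALSE) {
  dialect <- match.arg(dialect)
  if (!inherits(table, "motion_table")) table <- motion_table(table)
  df <- as.data.frame(table)
  if (in_degrees) df[-1] <- df[-1] * 180 / pi
  ok <- tryCatch({
    if (dialect == "storage") {
      con <- file(path, "w")
      on.exit(close(con))
      writeLines(c(attr(table, "table_name") %||% "motion",
                   sprintf("nRows=%d", nrow(df)),
                   sprintf("nColumns=%d", ncol(df)),
                   sprintf("inDegrees=%s", if (in_degrees) "yes" else "no"),
                   "endheader",
                   paste(names(df), collapse = "\t")), con)
      writeLines(apply(df, 1, function(r) paste(fmt_num(r), collapse = "\t")), con)
    } else {
      out <- df
      out[] <- lapply(out, fmt_num)
      write.csv(out, path, row.names = FALSE, quote = FALSE)
    }
    TRUE
  }, error = function(e) stop("failed writing '", path, "': ", conditionMessage(e)))
  invisible(path)
}

#' Read a time-series table
#'
#' Header counts (`nRows`, `nColumns`) are validated against the data
#' block; degree-flagged tables are converted back to radians so the
#' in-memory representation is always radians.
#'
#' @param path input file path.
#' @param dialect `"storage"` or `"csv"`.
#' @return a [motion_table()].
#' @export
read_table <- function(path, dialect = c("storage", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "storage") {
    lines <- readLines(path)
    end <- match("endheader", trimws(lines))
    if (is.na(end)) stop("storage format error: missing 'endheader' sentinel in ", path)
    header <- lines[seq_len(end - 1L)]
    grab <- function(key) {
      hit <- grep(paste0("^", key, "="), header, value = TRUE)
      if (!length(hit)) return(NA_character_)
      sub(paste0("^", key, "="), "", hit[1])
    }
    n_rows <- suppressWarnings(as.integer(grab("nRows")))
    n_cols <- suppressWarnings(as.integer(grab("nColumns")))
    in_degrees <- identical(tolower(grab("inDegrees")), "yes")
    name <- trimws(lines[1])
    cols <- strsplit(lines[end + 1L], "\t", fixed = TRUE)[[1]]
    body <- lines[-seq_len(end + 1L)]
    body <- body[nzchar(trimws(body))]
    if (!is.na(n_rows) && length(body) != n_rows)
      stop(sprintf("storage format error at line %d: header declares nRows=%d but %d data rows found",
                   end + 2L, n_rows, length(body)))
    grid <- lapply(body, function(l) as.numeric(strsplit(l, "\t", fixed = TRUE)[[1]]))
    widths <- lengths(grid)
    if (!is.na(n_cols) && any(widths != n_cols)) {
      bad <- which(widths != n_cols)[1]
      stop(sprintf("storage format error at line %d: header declares nColumns=%d but row has %d fields",
                   end + 1L + bad, n_cols, widths[bad]))
    }
    df <- as.data.frame(do.call(rbind, grid))
    names(df) <- cols
  } else {
    df <- read.csv(path, check.names = FALSE)
    in_degrees <- FALSE
    name <- sub("\\.[^.]+$", "", basename(path))
  }
  if (in_degrees) df[-1] <- df[-1] * pi / 180
  motion_table(df, units = if (in_degrees) "radians" else "unknown", name = name)
}

#' Write a motion trajectory as a directory of tables plus metadata
#'
#' One table per signal family (`angles`, `velocities`, `accelerations`,
#' `torques`, `markers`) plus a `meta.json` carrying the phase labels,
#' class label, ids and ground-truth rest frames.
#'
#' @param traj a [synthesize_trajectory()] result.
#' @param dir output directory (created if needed).
#' @param dialect table dialect, `"storage"` or `"csv"`.
#' @param in_degrees write angle-family tables in degrees.
#' @return `dir`, invisibly.
#' @export
write_trajectory <- function(traj, dir, dialect = "storage", in_degrees = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (dialect == "storage") ".sto" else ".csv"
  fams <- list(angles = traj$q, velocities = traj$qd, accelerations = traj$qdd,
               torques = traj$tau, markers = traj$markers)
  for (fam in names(fams)) {
    tab <- motion_table(data.frame(time = traj$time, fams[[fam]], check.names = FALSE),
                        name = fam)
    write_table(tab, file.path(dir, paste0(fam, ext)), dialect,
                in_degrees = in_degrees && fam == "angles")
  }
  meta <- list(id = traj$id %||% NA, participant = traj$participant,
               task = traj$task, condition = traj$condition, y = traj$y,
               true_compensating_dofs = traj$true_compensating_dofs,
               phase = traj$phase, rest_frames = traj$rest_frames,
               sample_rate = traj$sample_rate, seed = traj$seed,
               dialect = dialect)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a motion trajectory written by [write_trajectory()]
#'
#' @param dir trajectory directory.
#' @return a `"motion_trajectory"` object.
#' @export
read_trajectory <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  dialect <- meta$dialect %||% "storage"
  ext <- if (dialect == "storage") ".sto" else ".csv"
  rd <- function(fam) {
    tab <- read_table(file.path(dir, paste0(fam, ext)), dialect)
    m <- as.matrix(as.data.frame(tab)[-1])
    rownames(m) <- NULL
    m
  }
  q <- rd("angles")
  structure(
    list(time = as.data.frame(read_table(file.path(dir, paste0("angles", ext)), dialect))$time,
         q = q, qd = rd("velocities"), qdd = rd("accelerations"),
         tau = rd("torques"), markers = rd("markers"),
         phase = meta$phase, rest_frames = meta$rest_frames, y = meta$y,
         true_compensating_dofs = meta$true_compensating_dofs %||% character(0),
         participant = meta$participant, task = meta$task,
         condition = meta$condition, sample_rate = meta$sample_rate,
         seed = meta$seed, id = meta$id),
    class = "motion_trajectory")
}

#' Write a dataset to disk (trajectory directories + JSON manifest)
#'
#' @param dataset a [generate_dataset()] result.
#' @param dir output directory.
#' @param dialect table dialect.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir, dialect = "storage") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(dataset$trajectories))
    write_trajectory(dataset$trajectories[[id]], file.path(dir, id), dialect)
  jsonlite::write_json(dataset$manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
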