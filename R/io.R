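#' Write a stress-stretch curve to a delimited text file
#'
#' Plain CSV with a commented header carrying the metadata (stress unit,
#' label, cation, program definition). Deterministic formatting; the
#' [read_curve()] round trip is the identity up to float formatting.
#'
#' @param curve a `"stress_stretch_curve"`.
#' @param path output file path.
#' @param digits significant digits for numeric columns.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path, digits = 12) {
  stopifnot(inherits(curve, "stress_stretch_curve"))
  prog <- attr(curve, "program")
  hdr <- c(
    "# dnhfit stress-stretch curve",
    sprintf("# stress_unit: %s", attr(curve, "stress_unit") %||% "kPa"),
    sprintf("# label: %s", attr(curve, "label") %||% ""),
    sprintf("# cation: %s", attr(curve, "cation") %||% "")
  )
  if (!is.null(prog)) {
    hdr <- c(hdr,
             sprintf("# program_kind: %s", prog$kind),
             sprintf("# program_targets: %s",
                     paste(format(prog$targets, digits = digits), collapse = " ")),
             sprintf("# program_points: %s",
                     paste(prog$points_per_segment, collapse = " ")))
  }
  df <- as.data.frame(curve)
  cols <- intersect(c("stretch", "stress", "branch", "cycle"), names(df))
  df <- df[, cols, drop = FALSE]
  for (nm in intersect(c("stretch", "stress"), cols)) {
    df[[nm]] <- formatC(df[[nm]], digits = digits, format = "g")
  }
  tmp <- paste0(path, ".tmp")
  con <- file(tmp, "w")
  writeLines(hdr, con)
  writeLines(paste(cols, collapse = ","), con)
  if (nrow(df) > 0L) {
    writeLines(do.call(paste, c(unname(as.list(df)), sep = ",")), con)
  }
  close(con)
  file.rename(tmp, path)
  invisible(path)
}

#' Read a stress-stretch curve from a delimited text file
#'
#' Parses the format written by [write_curve()]: `#`-commented metadata
#' header, then CSV columns `stretch`, `stress` and optionally `branch`,
#' `cycle`. Malformed rows are reported with their line numbers; curves must
#' be tension-only (stretch >= 1).
#'
#' @param path input file path.
#' @param stress_unit expected stress unit; if given and the file declares a
#'   different one, a unit-mismatch error is raised.
#' @return a `"stress_stretch_curve"`.
#' @export
read_curve <- function(path, stress_unit = NULL) {
  if (!file.exists(path)) stop("no such curve file: ", path)
  lines <- readLines(path)
  is_hdr <- grepl("^#", lines)
  hdr <- lines[is_hdr]
  meta <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z_]+):\\s*(.*)$", h))[[1L]]
    if (length(m) == 3L) meta[[m[2L]]] <- trimws(m[3L])
  }
  body_idx <- which(!is_hdr & nzchar(trimws(lines)))
  if (length(body_idx) < 1L) stop("curve file has no column header: ", path)
  cols <- strsplit(trimws(lines[body_idx[1L]]), ",")[[1L]]
  if (!all(c("stretch", "stress") %in% cols)) {
    stop("curve file must have `stretch` and `stress` columns; found: ",
         paste(cols, collapse = ", "))
  }
  rows <- body_idx[-1L]
  parse_row <- function(i) {
    fields <- strsplit(lines[i], ",")[[1L]]
    if (length(fields) != length(cols)) {
      stop(sprintf("malformed row at line %d: expected %d fields, got %d",
                   i, length(cols), length(fields)))
    }
    fields
  }
  mat <- lapply(rows, parse_row)
  get_col <- function(nm) vapply(mat, function(f) f[[match(nm, cols)]], character(1L))
  num_col <- function(nm) {
    v <- suppressWarnings(as.numeric(get_col(nm)))
    if (any(is.na(v))) {
      stop(sprintf("non-numeric `%s` value at line %d", nm, rows[which(is.na(v))[1L]]))
    }
    v
  }
  stretch <- if (length(rows)) num_col("stretch") else numeric(0)
  stress <- if (length(rows)) num_col("stress") else numeric(0)
  if (any(stretch < 1)) {
    stop(sprintf("tension-only violation: stretch %.6g < 1 at line %d",
                 stretch[which(stretch < 1)[1L]], rows[which(stretch < 1)[1L]]))
  }
  file_unit <- meta$stress_unit %||% "kPa"
  if (!is.null(stress_unit) && !identical(stress_unit, file_unit)) {
    stop(sprintf("stress unit mismatch: file declares '%s', expected '%s'",
                 file_unit, stress_unit))
  }
  branch <- if ("branch" %in% cols && length(rows)) get_col("branch") else NULL
  cycle <- if ("cycle" %in% cols && length(rows)) as.integer(get_col("cycle")) else NULL
  if (!is.null(branch)) {
    # within a declared branch segment the path must be monotone
    runs <- rle(branch)
    pos <- c(0L, cumsum(runs$lengths))
    for (k in seq_along(runs$values)) {
      seg <- stretch[(pos[k] + 1L):pos[k + 1L]]
      d <- diff(seg)
      ok <- if (runs$values[k] == "load") all(d >= 0) else all(d <= 0)
      if (!ok) {
        stop(sprintf("non-monotone path within `%s` branch starting at line %d",
                     runs$values[k], rows[pos[k] + 1L]))
      }
    }
  }
  prog <- NULL
  if (!is.null(meta$program_targets)) {
    prog <- loading_program(
      as.numeric(strsplit(meta$program_targets, "\\s+")[[1L]]),
      points_per_segment = as.integer(strsplit(meta$program_points %||% "25", "\\s+")[[1L]]),
      kind = meta$program_kind,
      label = meta$label %||% "", cation = meta$cation %||% ""
    )
  }
  stress_stretch_curve(stretch, stress, branch = branch, cycle = cycle,
                       program = prog, stress_unit = file_unit,
                       label = meta$label %||% "", cation = meta$cation %||% "")
}
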