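#' Construct a raw load-displacement trace
#'
#' Container for one fascicle specimen's raw tensile record in the five-column
#' "mtt" dialect: time (ms), displacement transducer signal (mV), load-cell
#' signal (mV), converted displacement (mm) and converted load (gram-force).
#' The mV channels are carried untouched; all analysis uses the converted
#' mm/gram columns.
#'
#' @param time_ms numeric, strictly increasing time stamps in milliseconds.
#' @param disp_mv numeric, displacement transducer signal (mV).
#' @param load_mv numeric, load-cell signal (mV).
#' @param disp_mm numeric, grip-to-grip displacement in mm (non-decreasing:
#'   the crosshead only travels forward).
#' @param load_g numeric, load in gram-force.
#' @param specimen_id specimen identifier, conventionally `mttNN_X_tYZ`.
#'
#' @return A data frame of class `mtt_trace` with attribute `specimen_id`.
#' @export
mtt_trace <- function(time_ms, disp_mv, load_mv, disp_mm, load_g,
                      specimen_id = NA_character_) {
  n <- length(time_ms)
  lens <- c(length(disp_mv), length(load_mv), length(disp_mm), length(load_g))
  if (any(lens != n))
    stop_tm("all five channels must have equal length", "format")
  if (n < 2L)
    stop_tm("a trace needs at least 2 samples", "insufficient_data")
  if (any(diff(time_ms) <= 0))
    stop_tm("time must be strictly increasing", "format")
  if (any(diff(disp_mm) < 0))
    stop_tm("displacement (mm) must be non-decreasing", "format")
  out <- data.frame(time_ms = as.numeric(time_ms),
                    disp_mv = as.numeric(disp_mv),
                    load_mv = as.numeric(load_mv),
                    disp_mm = as.numeric(disp_mm),
                    load_g  = as.numeric(load_g))
  attr(out, "specimen_id") <- specimen_id
  class(out) <- c("mtt_trace", "data.frame")
  out
}

#' @export
print.mtt_trace <- function(x, ...) {
  cat(sprintf("mtt trace '%s': %d samples, %.1f-%.1f ms, max load %.3f g\n",
              attr(x, "specimen_id"), nrow(x),
              x$time_ms[1], x$time_ms[nrow(x)], max(x$load_g)))
  invisible(x)
}

#' Parse a specimen identifier
#'
#' Identifiers follow `mttNN_X_tYZ`: `NN` the age-group id, `X` the sample
#' (mouse) id, `Y` the fascicle number and `Z` a letter naming the segment cut
#' from that fascicle. Malformed ids are kept as opaque text with a warning
#' rather than rejected, since file naming in deposited archives is not
#' perfectly uniform.
#'
#' @param id character identifier.
#' @return A list with `id`, `parsed` (logical) and, when parsed, `age_group`
#'   (e.g. `"01M"`), `sample`, `fascicle`, `segment`.
#' @export
parse_specimen_id <- function(id) {
  m <- regmatches(id, regexec("^mtt([0-9]{2})_([0-9]+)_t([0-9]+)([A-Za-z])(\\.txt)?$", id))[[1]]
  if (length(m) == 0) {
    warn_tm(sprintf("specimen id '%s' does not follow mttNN_X_tYZ; kept as opaque text", id),
            "malformed_id")
    return(list(id = id, parsed = FALSE))
  }
  list(id = id, parsed = TRUE,
       age_group = paste0(m[2], "M"),
       sample = as.integer(m[3]),
       fascicle = as.integer(m[4]),
       segment = m[5])
}

#' Age group identifiers
#'
#' The eight age groups in the study design, `01M` through `35M`,
#' corresponding to 1.6, 2.6, 4.0, 11.5, 23.0, 29.0, 31.5 and 35.3 months.
#' @export
age_group_ids <- function() {
  c("01M", "02M", "04M", "11M", "23M", "29M", "31M", "35M")
}

#' Read a raw load-displacement trace
#'
#' Reads one tab-delimited five-column trace (time ms, displacement mV, load
#' mV, displacement mm, load grams). A single non-numeric leading row is
#' treated as a header and skipped. Rows with non-parsable numeric fields are
#' dropped with a warning. Time monotonicity is validated, never repaired.
#'
#' @param source path to a file, a connection, or a character vector of lines.
#' @param id specimen id; defaults to the file name without extension.
#' @return An [mtt_trace()].
#' @export
read_mtt_trace <- function(source, id = NULL) {
  if (is.character(source) && length(source) == 1L && file.exists(source)) {
    if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(source))
    lines <- readLines(source, warn = FALSE)
  } else if (inherits(source, "connection")) {
    lines <- readLines(source, warn = FALSE)
  } else {
    lines <- unlist(strsplit(as.character(source), "\n", fixed = TRUE))
  }
  if (is.null(id)) id <- NA_character_
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    stop_tm("empty input", "insufficient_data")

  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  bad <- which(ncols < 5L)
  if (length(bad) > 0L)
    stop_tm(sprintf("line %d has %d tab-delimited columns; at least 5 required",
                    bad[1], ncols[bad[1]]), "format")

  num <- function(f) suppressWarnings(as.numeric(f[1:5]))
  first <- num(fields[[1]])
  start <- if (anyNA(first)) 2L else 1L  # header detected by non-numeric first row
  if (length(fields) - start + 1L < 2L)
    stop_tm("fewer than 2 data rows", "insufficient_data")

  mat <- t(vapply(fields[start:length(fields)], num, numeric(5)))
  keep <- stats::complete.cases(mat)
  if (any(!keep)) {
    warn_tm(sprintf("dropped %d row(s) with non-parsable numeric fields",
                    sum(!keep)), "bad_rows")
    mat <- mat[keep, , drop = FALSE]
  }
  if (nrow(mat) < 2L)
    stop_tm("fewer than 2 parsable data rows", "insufficient_data")

  mtt_trace(mat[, 1], mat[, 2], mat[, 3], mat[, 4], mat[, 5], specimen_id = id)
}

#' Write a load-displacement trace in the mtt dialect
#'
#' @param trace an [mtt_trace()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mtt_trace <- function(trace, path) {
  stopifnot(inherits(trace, "mtt_trace"))
  header <- paste(c("Time", "Displacement", "Load", "mm", "grams"),
                  collapse = "\t")
  rows <- apply(trace[, c("time_ms", "disp_mv", "load_mv", "disp_mm", "load_g")],
                1L, function(r) paste(fmt_num(r), collapse = "\t"))
  writeLines(c(header, rows), path)
  invisible(path)
}

# ---- property sheets ------------------------------------------------------

# Column layouts mirroring the deposited workbook worksheets.
prop_names <- c("sY", "eY", "E", "sU", "eU",
                "uY", "uP", "uR", "uF", "u0", "uY_sY", "uF_sU")
mean_props <- c("sY", "sU", "E", "uY", "uP", "uR", "uF", "u0", "uY_sY", "uF_sU")

sheet_columns <- function(level) {
  switch(level,
    specimen  = c("age_group", "sample", "file", prop_names),
    tail      = c("age_group", "sample", mean_props),
    age_group = c("age_group", paste0("mean_", mean_props), paste0("sem_", mean_props)),
    stop_tm(sprintf("unknown sheet level '%s'", level), "contract"))
}

#' Write a mechanical-property sheet
#'
#' Writes a CSV mirroring the deposited workbook layouts: per-specimen derived
#' parameters (15 columns: age group, sample, file name, then the twelve
#' derived quantities), per-mouse means, or per-age-group means followed by
#' SEMs.
#'
#' @param records a data frame with the columns of the requested level (see
#'   [property_sheet_columns()]), or an empty data frame/list for a
#'   header-only file. If the data frame carries a `level` attribute it must
#'   agree with `level`.
#' @param level one of `"specimen"`, `"tail"`, `"age_group"`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_property_sheet <- function(records, level = c("specimen", "tail", "age_group"),
                                 path) {
  level <- match.arg(level)
  cols <- sheet_columns(level)
  if (is.null(records) || (is.list(records) && !is.data.frame(records) &&
                           length(records) == 0L)) {
    records <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)), cols))
  }
  if (!is.data.frame(records))
    stop_tm("`records` must be a data frame of homogeneous level", "contract")
  lev_attr <- attr(records, "level")
  if (!is.null(lev_attr) && !identical(lev_attr, level))
    stop_tm(sprintf("records carry level '%s' but '%s' was requested",
                    lev_attr, level), "contract")
  if ("level" %in% names(records) && length(unique(records$level)) > 1L)
    stop_tm("mixed record levels in one sheet", "contract")
  missing_cols <- setdiff(cols, names(records))
  if (length(missing_cols) > 0L)
    stop_tm(paste0("missing mandatory column(s): ",
                   paste(missing_cols, collapse = ", ")), "contract")
  out <- records[, cols, drop = FALSE]
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], fmt_num)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Column layout of a property sheet level
#' @param level one of `"specimen"`, `"tail"`, `"age_group"`.
#' @return character vector of column names in deposited order.
#' @export
property_sheet_columns <- function(level = c("specimen", "tail", "age_group")) {
  sheet_columns(match.arg(level))
}

#' Read a mechanical-property sheet written by [write_property_sheet()]
#' @inheritParams write_property_sheet
#' @return data frame with the level's columns, numeric where appropriate.
#' @export
read_property_sheet <- function(path, level = c("specimen", "tail", "age_group")) {
  level <- match.arg(level)
  cols <- sheet_columns(level)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols) > 0L)
    stop_tm(paste0("sheet lacks column(s): ", paste(missing_cols, collapse = ", ")),
            "format")
  df <- df[, cols, drop = FALSE]
  text_cols <- intersect(c("age_group", "sample", "file"), cols)
  for (nm in setdiff(cols, text_cols)) df[[nm]] <- as.numeric(df[[nm]])
  attr(df, "level") <- level
  df
}

# ---- structural sheets ----------------------------------------------------

#' Write per-image fibril area fractions
#'
#' Wide layout mirroring the deposited 'Fibril area fraction' worksheet: one
#' column per age group, one row per sampled image, ragged groups padded with
#' blanks.
#'
#' @param fractions data frame with columns `group`, `image_id`, `rho`.
#' @param path output CSV path.
#' @export
write_area_fraction_sheet <- function(fractions, path) {
  stopifnot(is.data.frame(fractions),
            all(c("group", "rho") %in% names(fractions)))
  if (any(fractions$rho < 0, na.rm = TRUE))
    stop_tm("negative area fraction", "data")
  groups <- unique(fractions$group)
  per <- lapply(groups, function(g) fractions$rho[fractions$group == g])
  nmax <- max(lengths(per))
  mat <- vapply(per, function(v) c(fmt_num(v), rep("", nmax - length(v))),
                character(nmax))
  mat <- matrix(mat, nrow = nmax, dimnames = list(NULL, groups))
  utils::write.csv(as.data.frame(mat, check.names = FALSE), path,
                   row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Write group diameter-frequency histograms
#'
#' One `bin` column (lower bin edges, nm), then raw `freq_<group>` columns and
#' `norm_<group>` normalised-frequency columns, mirroring the deposited
#' 'Fibril diameter' worksheet. All histograms must share bin edges.
#'
#' @param histograms named list of [fibril_histogram()] objects.
#' @param path output CSV path.
#' @export
write_fibril_histogram_sheet <- function(histograms, path) {
  stopifnot(length(histograms) > 0L)
  if (is.null(names(histograms)) || any(!nzchar(names(histograms))))
    stop_tm("histograms must be a named list (names = group ids)", "contract")
  edges <- histograms[[1]]$bin_edges
  for (h in histograms) {
    if (!isTRUE(all.equal(h$bin_edges, edges)))
      stop_tm("all histograms in one sheet must share bin edges", "contract")
  }
  lower <- edges[-length(edges)]
  df <- data.frame(bin = fmt_num(lower), check.names = FALSE)
  for (g in names(histograms)) df[[paste0("freq_", g)]] <- fmt_num(histograms[[g]]$freq)
  for (g in names(histograms)) df[[paste0("norm_", g)]] <- fmt_num(histograms[[g]]$norm_freq)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read the structural sheets
#'
#' Reads the per-image area-fraction sheet and/or the diameter-frequency
#' histogram sheet back into R objects.
#'
#' @param area_path CSV from [write_area_fraction_sheet()], or `NULL`.
#' @param hist_path CSV from [write_fibril_histogram_sheet()], or `NULL`.
#' @param empty_groups `"error"` to fail on an all-zero frequency column,
#'   `"flag"` to keep the group and record it in the `empty_groups` attribute.
#' @return list with `area_fractions` (long data frame `group`, `rho`) and
#'   `histograms` (named list of [fibril_histogram()]). Normalised
#'   frequencies are checked to sum to 1 within 1e-6 per group.
#' @export
read_fibril_tables <- function(area_path = NULL, hist_path = NULL,
                               empty_groups = c("error", "flag")) {
  empty_groups <- match.arg(empty_groups)
  out <- list(area_fractions = NULL, histograms = NULL)

  if (!is.null(area_path)) {
    wide <- utils::read.csv(area_path, stringsAsFactors = FALSE, check.names = FALSE)
    long <- do.call(rbind, lapply(names(wide), function(g) {
      v <- suppressWarnings(as.numeric(wide[[g]]))
      v <- v[!is.na(v)]
      if (length(v) == 0L) return(NULL)
      data.frame(group = g, rho = v, stringsAsFactors = FALSE)
    }))
    if (any(long$rho < 0)) stop_tm("negative area fraction in sheet", "data")
    out$area_fractions <- long
  }

  if (!is.null(hist_path)) {
    df <- utils::read.csv(hist_path, stringsAsFactors = FALSE, check.names = FALSE)
    if (!"bin" %in% names(df)) stop_tm("histogram sheet lacks 'bin' column", "format")
    lower <- as.numeric(df$bin)
    freq_cols <- grep("^freq_", names(df), value = TRUE)
    if (length(freq_cols) == 0L)
      stop_tm("histogram sheet lacks freq_<group> columns", "format")
    width <- if (length(lower) > 1L) diff(lower)[1] else
      stop_tm("histogram needs at least 2 bins", "format")
    edges <- c(lower, lower[length(lower)] + width)
    hists <- list()
    empties <- character(0)
    for (fc in freq_cols) {
      g <- sub("^freq_", "", fc)
      freq <- as.numeric(df[[fc]])
      if (any(freq < 0)) stop_tm(sprintf("negative frequency in group %s", g), "data")
      if (sum(freq) == 0) {
        if (empty_groups == "error")
          stop_tm(sprintf("group %s has all-zero frequencies", g), "data")
        empties <- c(empties, g)
        next
      }
      h <- fibril_histogram(edges, freq, group_id = g)
      nc <- paste0("norm_", g)
      if (nc %in% names(df)) {
        norm <- as.numeric(df[[nc]])
        if (abs(sum(norm) - 1) > 1e-6)
          stop_tm(sprintf("normalised frequencies of group %s sum to %g, not 1",
                          g, sum(norm)), "data")
        h$norm_freq <- norm
      }
      hists[[g]] <- h
    }
    attr(hists, "empty_groups") <- empties
    out$histograms <- hists
  }
  out
}

#' Write the fitted-subpopulation summary sheet
#'
#' Per-group two-component mixture results (means, SDs, amplitudes, residual),
#' mirroring the subpopulation summary columns of the deposited structural
#' workbook.
#'
#' @param fits named list of `mixture_fit` objects (names = group ids).
#' @param path output CSV path.
#' @export
write_subpopulation_sheet <- function(fits, path) {
  rows <- lapply(names(fits), function(g) {
    f <- fits[[g]]
    data.frame(group = g,
               D_D1 = f$mu[1], sd_D1 = f$sigma[1], amp_D1 = f$amplitude[1],
               D_D2 = f$mu[2], sd_D2 = f$sigma[2], amp_D2 = f$amplitude[2],
               objective = f$objective, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

# ---- run log --------------------------------------------------------------

log_mandatory_keys <- c("specimen", "diameter", "laststrainpt",
                        "orderpoly", "loadat1percent")

#' Append an analysis entry to the run log
#'
#' One timestamped, machine-parsable `key=value` line per analysis, in the
#' spirit of the original pipeline's `logfile.txt`. The entry must carry the
#' specimen id and the four analysis inputs (`diameter`, `laststrainpt`,
#' `orderpoly`, `loadat1percent`).
#'
#' @param entry named list/vector of parameters.
#' @param path log file path (created if absent).
#' @param timestamp optional POSIXct; defaults to `Sys.time()`.
#' @return the formatted line, invisibly.
#' @export
append_run_log <- function(entry, path, timestamp = Sys.time()) {
  entry <- as.list(entry)
  missing_keys <- setdiff(log_mandatory_keys, names(entry))
  if (length(missing_keys) > 0L)
    stop_tm(paste0("run-log entry lacks mandatory key(s): ",
                   paste(missing_keys, collapse = ", ")), "contract")
  vals <- vapply(entry, function(v) {
    s <- if (is.numeric(v)) fmt_num(v) else as.character(v)
    utils::URLencode(s, reserved = TRUE)
  }, character(1))
  line <- paste0("timestamp=", format(timestamp, "%Y-%m-%dT%H:%M:%S"), " ",
                 paste(names(vals), vals, sep = "=", collapse = " "))
  cat(line, "\n", sep = "", file = path, append = TRUE)
  invisible(line)
}

#' Parse a run log back into entry maps
#' @param path log file path.
#' @return list of named lists, one per line, values type-converted.
#' @export
parse_run_log <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(ln) {
    kv <- strsplit(strsplit(ln, " ", fixed = TRUE)[[1]], "=", fixed = TRUE)
    vals <- lapply(kv, function(p) {
      v <- utils::URLdecode(paste(p[-1], collapse = "="))
      utils::type.convert(v, as.is = TRUE)
    })
    stats::setNames(vals, vapply(kv, `[`, character(1), 1))
  })
}
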