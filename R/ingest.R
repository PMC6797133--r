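#' Parse free-form population-size reports to integer counts
#'
#' Field records often report population size as a range ("50-100"), a
#' qualified number ("75+", ">30", "ca. 50", "~50"), or a plain integer.
#' This routine applies the conservative-maximum convention used when
#' auditing occurrence databases: for a range, the upper bound is taken;
#' for a qualified single number, the embedded integer itself; plain
#' integers pass through unchanged.
#'
#' Accepted range delimiters are the ASCII hyphen, en-dash, em-dash, and
#' the word "to". Accepted qualifier tokens are `+`, `>`, `>=`, the Unicode
#' greater-or-equal sign, `~`, `ca.`, `c.`, `about`, and `approx.`
#' (case-insensitive). Anything else is a parse error naming the offending
#' token.
#'
#' @param text character vector of size reports (non-empty strings).
#' @return integer vector of the same length; every value is >= 1.
#' @examples
#' parse_population_size(c("50-100", "75+", ">30", "ca. 50", "42"))
#' @export
parse_population_size <- function(text) {
  if (length(text) == 0L) return(integer(0))
  text <- as.character(text)
  vapply(text, parse_one_size, integer(1), USE.NAMES = FALSE)
}

parse_one_size <- function(token) {
  raw <- token
  if (is.na(token) || !nzchar(trimws(token))) {
    stop("population size report is empty or missing", call. = FALSE)
  }
  x <- trimws(token)
  # normalise unicode dashes and comparison signs to ASCII
  x <- gsub("–|—|−", "-", x)
  x <- gsub("≥", ">=", x)
  # thousands separators inside digit groups ("1,084")
  x <- gsub("(?<=[0-9]),(?=[0-9]{3})", "", x, perl = TRUE)

  if (grepl("^[0-9]+$", x)) {
    return(size_checked(as.integer(x), raw))
  }
  # range: two integers separated by a dash or "to" -> upper bound
  m <- regmatches(x, regexec("^([0-9]+)[[:space:]]*(?:-|to)[[:space:]]*([0-9]+)$",
                             x, ignore.case = TRUE))[[1]]
  if (length(m) == 3L) {
    return(size_checked(max(as.integer(m[2:3])), raw))
  }
  # qualified single number: strip leading/trailing qualifier tokens
  y <- x
  y <- sub("^(?:ca\\.?|c\\.|about|approx\\.?|~|>=|>)[[:space:]]*", "", y,
           ignore.case = TRUE)
  y <- sub("[[:space:]]*\\+$", "", y)
  if (grepl("^[0-9]+$", y)) {
    return(size_checked(as.integer(y), raw))
  }
  stop(sprintf("cannot parse population size from '%s'", raw), call. = FALSE)
}

size_checked <- function(n, raw) {
  if (is.na(n) || n < 1L) {
    stop(sprintf("population size '%s' parses to %s; sizes must be >= 1",
                 raw, n), call. = FALSE)
  }
  as.integer(n)
}

#' Default column mappings for input tables
#'
#' Column matching is case-insensitive with surrounding whitespace trimmed,
#' so `"Elevation "` in a header matches the `elevation` slot. Override any
#' slot to adapt to a particular database export.
#'
#' @param record_id,elevation,years,status,oldsize,lastsize header names in
#'   the resurvey CSV. `record_id` and `lastsize` are optional columns.
#' @return named list of expected header names.
#' @export
resurvey_columns <- function(record_id = "record_id", elevation = "elevation",
                             years = "years", status = "status",
                             oldsize = "oldsize", lastsize = "lastsize") {
  list(record_id = record_id, elevation = elevation, years = years,
       status = status, oldsize = oldsize, lastsize = lastsize)
}

#' @rdname resurvey_columns
#' @param size,year,years_since,group,extinct header names in the occurrence
#'   CSV. Exactly one of `year` / `years_since` must be present in the file;
#'   `group` and `extinct` (an already-extinct flag) are optional.
#' @export
occurrence_columns <- function(record_id = "record_id", size = "size",
                               elevation = "elevation", year = "year",
                               years_since = "years_since", group = "group",
                               extinct = "extinct") {
  list(record_id = record_id, size = size, elevation = elevation,
       year = year, years_since = years_since, group = group,
       extinct = extinct)
}

# locate mapped columns in a header, case-insensitively
match_columns <- function(header, col_map) {
  canon <- tolower(trimws(header))
  idx <- lapply(col_map, function(nm) {
    hit <- which(canon == tolower(trimws(nm)))
    if (length(hit)) hit[1] else NA_integer_
  })
  names(idx) <- names(col_map)
  idx
}

require_columns <- function(idx, required, col_map, path) {
  missing <- required[vapply(required, function(f) is.na(idx[[f]]), logical(1))]
  if (length(missing)) {
    stop(sprintf("file '%s' is missing required column(s): %s", path,
                 paste(unlist(col_map[missing]), collapse = ", ")),
         call. = FALSE)
  }
}

# interpret an extinct/extant status column; 1/extinct/absent/no -> extinct
parse_status <- function(x) {
  s <- tolower(trimws(as.character(x)))
  extinct <- s %in% c("1", "extinct", "absent", "0 plants", "no", "dead")
  extant  <- s %in% c("0", "extant", "present", "yes", "alive")
  bad <- !extinct & !extant
  if (any(bad)) {
    stop(sprintf("unrecognised status value(s): %s",
                 paste(unique(s[bad]), collapse = ", ")), call. = FALSE)
  }
  as.integer(extinct)
}

#' Read and validate a resurvey table
#'
#' Reads a CSV of repeated-survey records (one row per revisited
#' population), routes non-integer size reports through
#' [parse_population_size()], and validates the record invariants:
#' initial size >= 1, years between surveys >= 1, elevation > 0, and,
#' when a last-survey size is present, agreement between the extinct flag
#' and a zero count.
#'
#' The status column accepts `extinct`/`extant`, `absent`/`present`,
#' `yes`/`no`, or `1`/`0` (1 = extinct, i.e. no plants found at the most
#' recent visit).
#'
#' @param path CSV file with a header row.
#' @param col_map column mapping from [resurvey_columns()].
#' @param permissive if `TRUE`, rows failing validation are dropped with a
#'   warning instead of aborting the read.
#' @param quiet suppress the record-count message.
#' @return a `data.frame` with canonical columns `record_id`,
#'   `elevation_m`, `years_between`, `initial_size`, `final_size`
#'   (`NA` when absent), and `extinct` (integer 0/1).
#' @export
read_resurvey_table <- function(path, col_map = resurvey_columns(),
                                permissive = FALSE, quiet = FALSE) {
  raw <- read_csv_checked(path)
  idx <- match_columns(names(raw), col_map)
  require_columns(idx, c("elevation", "years", "status", "oldsize"),
                  col_map, path)

  n <- nrow(raw)
  rec <- data.frame(
    record_id = if (!is.na(idx$record_id)) as.character(raw[[idx$record_id]])
                else sprintf("R%04d", seq_len(n)),
    elevation_m = as.numeric(raw[[idx$elevation]]),
    years_between = as.numeric(raw[[idx$years]]),
    initial_size = parse_population_size(raw[[idx$oldsize]]),
    final_size = if (!is.na(idx$lastsize)) {
      suppressWarnings(as.numeric(raw[[idx$lastsize]]))
    } else rep(NA_real_, n),
    extinct = parse_status(raw[[idx$status]]),
    stringsAsFactors = FALSE
  )

  problems <- validate_resurvey(rec)
  rec <- resolve_problems(rec, problems, permissive, path)
  if (!quiet) {
    message(sprintf("read_resurvey_table: %d record(s) from '%s'",
                    nrow(rec), path))
  }
  rec
}

validate_resurvey <- function(rec) {
  bad <- character(nrow(rec))
  flag <- function(cond, msg) {
    cond[is.na(cond)] <- TRUE
    ifelse(cond, paste0(msg, "; "), "")
  }
  bad <- paste0(bad,
    flag(rec$initial_size < 1, "initial_size < 1"),
    flag(rec$years_between < 1, "years_between < 1"),
    flag(rec$elevation_m <= 0, "elevation_m <= 0"),
    flag(!rec$extinct %in% c(0L, 1L), "status not 0/1"))
  has_final <- !is.na(rec$final_size)
  mismatch <- has_final & (rec$extinct != as.integer(rec$final_size == 0))
  bad <- paste0(bad, ifelse(mismatch, "final_size contradicts status; ", ""))
  bad
}

resolve_problems <- function(rec, problems, permissive, path) {
  bad_rows <- which(nzchar(problems))
  if (!length(bad_rows)) return(rec)
  detail <- paste(sprintf("row %d: %s", bad_rows,
                          sub("; $", "", problems[bad_rows])),
                  collapse = "\n  ")
  if (!permissive) {
    stop(sprintf("invalid record(s) in '%s':\n  %s", path, detail),
         call. = FALSE)
  }
  warning(sprintf("dropping %d invalid record(s) from '%s':\n  %s",
                  length(bad_rows), path, detail), call. = FALSE)
  rec[-bad_rows, , drop = FALSE]
}

#' Read and validate an occurrence-database table
#'
#' Reads a CSV of occurrence records (one row per database population).
#' If the file carries an observation-year column instead of a
#' years-since-observation column, `years_since` is computed against
#' `reference_year` (default 2016, the database snapshot year of the
#' motivating audit). Size reports go through [parse_population_size()].
#'
#' @param path CSV file with a header row.
#' @param col_map column mapping from [occurrence_columns()].
#' @param reference_year year against which `years_since` is computed when
#'   only an observation year is present.
#' @inheritParams read_resurvey_table
#' @return a `data.frame` with canonical columns `record_id`, `size`,
#'   `elevation_m`, `years_since`, `group` (`NA` when absent), and
#'   `already_extinct` (logical; `FALSE` when the file has no flag).
#' @export
read_occurrence_table <- function(path, col_map = occurrence_columns(),
                                  reference_year = 2016,
                                  permissive = FALSE, quiet = FALSE) {
  raw <- read_csv_checked(path)
  if (nrow(raw) == 0L) {
    warning(sprintf("'%s' has a header but no data rows", path),
            call. = FALSE)
  }
  idx <- match_columns(names(raw), col_map)
  require_columns(idx, c("size", "elevation"), col_map, path)
  if (is.na(idx$year) && is.na(idx$years_since)) {
    stop(sprintf("file '%s' needs either a '%s' or a '%s' column", path,
                 col_map$year, col_map$years_since), call. = FALSE)
  }

  n <- nrow(raw)
  years_since <- if (!is.na(idx$years_since)) {
    as.numeric(raw[[idx$years_since]])
  } else {
    reference_year - as.numeric(raw[[idx$year]])
  }
  rec <- data.frame(
    record_id = if (!is.na(idx$record_id)) as.character(raw[[idx$record_id]])
                else sprintf("D%05d", seq_len(n)),
    size = if (n) parse_population_size(raw[[idx$size]]) else integer(0),
    elevation_m = as.numeric(raw[[idx$elevation]]),
    years_since = years_since,
    group = if (!is.na(idx$group)) as.character(raw[[idx$group]])
            else rep(NA_character_, n),
    already_extinct = if (!is.na(idx$extinct)) {
      as.logical(parse_status(raw[[idx$extinct]]))
    } else rep(FALSE, n),
    stringsAsFactors = FALSE
  )

  problems <- validate_occurrence(rec)
  rec <- resolve_problems(rec, problems, permissive, path)
  if (!quiet) {
    message(sprintf("read_occurrence_table: %d record(s) from '%s'",
                    nrow(rec), path))
  }
  rec
}

validate_occurrence <- function(rec) {
  if (!nrow(rec)) return(character(0))
  flag <- function(cond, msg) {
    cond[is.na(cond)] <- TRUE
    ifelse(cond, paste0(msg, "; "), "")
  }
  paste0(
    flag(rec$size < 1, "size < 1"),
    flag(rec$years_since < 0, "years_since < 0"),
    flag(rec$elevation_m <= 0, "elevation_m <= 0"))
}

#' Filter occurrence records for extrapolation
#'
#' Retains records with at least one reported plant that are not flagged as
#' already extinct in the source database; the numbers removed on each
#' ground are reported in the log. Extrapolation of extant counts only
#' makes sense over records the database itself still considers live.
#'
#' @param records occurrence records from [read_occurrence_table()] or
#'   [generate_database()].
#' @param quiet suppress the removal-count message.
#' @return the retained subset, row order preserved.
#' @export
filter_occurrences <- function(records, quiet = FALSE) {
  size <- if ("size" %in% names(records)) records$size else integer(0)
  flagged <- if ("already_extinct" %in% names(records)) {
    records$already_extinct %in% TRUE
  } else rep(FALSE, nrow(records))
  keep <- size >= 1 & !flagged
  if (!quiet) {
    message(sprintf(
      "filter_occurrences: kept %d of %d (removed %d with size < 1, %d flagged already extinct)",
      sum(keep), nrow(records), sum(size < 1), sum(flagged)))
  }
  records[keep, , drop = FALSE]
}

#' Write canonical tables back to CSV
#'
#' Writes the canonical-column form produced by the readers, so that
#' reading the file back yields identical records (round-trip property).
#'
#' @param records canonical records.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_resurvey_table <- function(records, path) {
  out <- records
  rename <- c(elevation_m = "elevation", years_between = "years",
              initial_size = "oldsize", final_size = "lastsize",
              extinct = "status")
  hit <- names(out) %in% names(rename)
  names(out)[hit] <- rename[names(out)[hit]]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_resurvey_table
#' @export
write_occurrence_table <- function(records, path) {
  out <- records
  names(out)[names(out) == "elevation_m"] <- "elevation"
  names(out)[names(out) == "already_extinct"] <- "extinct"
  out$extinct <- as.integer(out$extinct)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

read_csv_checked <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("input file not found: '%s'", path), call. = FALSE)
  }
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}
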