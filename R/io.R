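#' Cohort CSV schema
#'
#' Describes how a cohort CSV maps onto the package's canonical record
#' layout. The canonical columns are `subject_id`, `age`, `sex`, `diagnosis`,
#' `tool`, `left_hv`, `right_hv`, `tiv_value`; a file may name them
#' differently, remapped through `columns`. The TIV unit is explicit
#' metadata — `"ml"` or `"mm3"` — and is never guessed from magnitudes.
#'
#' @param columns Named character vector mapping canonical names to the
#'   column names used in the file. Only names you want to override need to
#'   be supplied.
#' @param tiv_unit Unit of the TIV column: `"ml"` or `"mm3"`.
#' @param default_tool Tool label (`"FS"` or `"AA"`) applied when the file
#'   has no tool column.
#' @return A list of class `hn_schema`.
#' @export
cohort_schema <- function(columns = character(), tiv_unit = c("ml", "mm3"),
                          default_tool = "FS") {
  tiv_unit <- match.arg(tiv_unit)
  canonical <- c(subject_id = "subject_id", age = "age", sex = "sex",
                 diagnosis = "diagnosis", tool = "tool",
                 left_hv = "left_hv", right_hv = "right_hv",
                 tiv_value = "tiv_value")
  if (length(columns) > 0) {
    bad <- setdiff(names(columns), names(canonical))
    if (length(bad) > 0) {
      abort(sprintf("Unknown canonical column(s) in schema: %s",
                    paste(bad, collapse = ", ")))
    }
    canonical[names(columns)] <- columns
  }
  structure(list(columns = canonical, tiv_unit = tiv_unit,
                 default_tool = default_tool),
            class = "hn_schema")
}

#' @rdname cohort_schema
#' @param path Path to a YAML file with optional keys `columns` (a mapping),
#'   `tiv_unit` and `default_tool`.
#' @export
cohort_schema_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  cohort_schema(
    columns = unlist(cfg$columns %||% list()),
    tiv_unit = cfg$tiv_unit %||% "ml",
    default_tool = cfg$default_tool %||% "FS"
  )
}

#' Read a per-subject cohort table
#'
#' Reads a comma-delimited, headered cohort file into the canonical record
#' layout. Malformed rows never fail the whole read: rows with a missing or
#' unparseable age, with both hippocampal volumes missing or unparseable, or
#' with a non-positive volume are set aside with a reason and retrievable via
#' [hn_rejected()]. Records whose TIV falls outside the plausible
#' 800-2,200 ml window are kept but flagged in `tiv_implausible`.
#'
#' @param path Path to a CSV file (comma-delimited, UTF-8, header row).
#' @param schema A [cohort_schema()] describing column names and the TIV
#'   unit.
#' @return A tibble of accepted records with columns `subject_id`, `age`,
#'   `sex`, `diagnosis`, `tool`, `left_hv`, `right_hv`, `tiv_value`,
#'   `tiv_unit`, `tiv_implausible`; rejected rows (with `reason`) attached as
#'   the `"rejected"` attribute.
#' @export
read_cohort <- function(path, schema = cohort_schema()) {
  stopifnot(inherits(schema, "hn_schema"))
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  cols <- schema$columns
  mandatory <- c("subject_id", "age", "left_hv", "right_hv", "tiv_value")
  missing_cols <- mandatory[!cols[mandatory] %in% names(raw)]
  if (length(missing_cols) > 0) {
    abort(sprintf("Mandatory column(s) absent from %s: %s",
                  path, paste(cols[missing_cols], collapse = ", ")))
  }
  pick <- function(canon, default = NA_character_) {
    if (cols[[canon]] %in% names(raw)) raw[[cols[[canon]]]]
    else rep(default, nrow(raw))
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  age <- num(pick("age"))
  left <- num(pick("left_hv"))
  right <- num(pick("right_hv"))
  tiv <- num(pick("tiv_value"))
  reason <- rep(NA_character_, nrow(raw))
  age_raw <- pick("age")
  left_raw <- pick("left_hv")
  right_raw <- pick("right_hv")
  blank <- function(x) is.na(x) | trimws(x) == ""
  reason[is.na(age) & !blank(age_raw)] <- "non-numeric age"
  reason[blank(age_raw)] <- "missing age"
  ok_age <- is.na(reason)
  reason[ok_age & (age < 18 | age > 110)] <- "age out of range [18, 110]"
  bad_left <- is.na(left) & !blank(left_raw)
  bad_right <- is.na(right) & !blank(right_raw)
  reason[is.na(reason) & (bad_left | bad_right)] <- "non-numeric volume"
  reason[is.na(reason) & is.na(left) & is.na(right)] <- "missing both volumes"
  nonpos <- (!is.na(left) & left <= 0) | (!is.na(right) & right <= 0)
  reason[is.na(reason) & nonpos] <- "non-positive volume"

  records <- tibble::tibble(
    subject_id = pick("subject_id"),
    age = age,
    sex = dplyr::coalesce(pick("sex"), "unknown"),
    diagnosis = dplyr::coalesce(pick("diagnosis"), "unknown"),
    tool = dplyr::coalesce(pick("tool"), schema$default_tool),
    left_hv = left, right_hv = right,
    tiv_value = tiv, tiv_unit = schema$tiv_unit
  )
  tiv_ml <- tiv_to_mm3(records$tiv_value, records$tiv_unit) / 1000
  records$tiv_implausible <- !is.na(tiv_ml) &
    (tiv_ml < TIV_PLAUSIBLE_ML[1] | tiv_ml > TIV_PLAUSIBLE_ML[2])

  accepted <- records[is.na(reason), , drop = FALSE]
  rejected <- records[!is.na(reason), , drop = FALSE]
  rejected$reason <- reason[!is.na(reason)]
  attr(accepted, "rejected") <- rejected
  accepted
}

#' Parse hippocampal volumes and eTIV from a FreeSurfer aseg.stats file
#'
#' Extracts the `Left-Hippocampus` / `Right-Hippocampus` `Volume_mm3` entries
#' and the `EstimatedTotalIntraCranialVol` measure from a FreeSurfer
#' `aseg.stats` text file (`# Measure ...` header lines plus a
#' whitespace-delimited segment table with the structure name in the fifth
#' column).
#'
#' @param path Path to an `aseg.stats` file.
#' @return A one-row tibble with `left_hv`, `right_hv` (mm3), `tiv_value`
#'   (mm3) and `tiv_unit = "mm3"`.
#' @export
read_aseg_stats <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readr::read_lines(path, progress = FALSE)
  measure <- grep("^#\\s*Measure\\s+EstimatedTotalIntraCranialVol", lines,
                  value = TRUE)
  if (length(measure) == 0) {
    abort("EstimatedTotalIntraCranialVol not found in aseg.stats header.")
  }
  fields <- strsplit(measure[1], ",")[[1]]
  tiv <- suppressWarnings(as.numeric(trimws(fields[length(fields) - 1L])))
  if (!is.finite(tiv)) {
    abort("EstimatedTotalIntraCranialVol measure line could not be parsed.")
  }
  body <- lines[!startsWith(trimws(lines), "#") & trimws(lines) != ""]
  seg_volume <- function(name) {
    for (ln in body) {
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(f) >= 5 && f[5] == name) {
        v <- suppressWarnings(as.numeric(f[4]))
        if (!is.finite(v)) abort(sprintf("%s row has a non-numeric Volume_mm3.", name))
        return(v)
      }
    }
    abort(sprintf("%s not found in aseg.stats segment table.", name))
  }
  tibble::tibble(
    left_hv = seg_volume("Left-Hippocampus"),
    right_hv = seg_volume("Right-Hippocampus"),
    tiv_value = tiv,
    tiv_unit = "mm3"
  )
}

# ---- percentile tables -----------------------------------------------------

#' Construct and validate a percentile threshold table
#'
#' A percentile table holds, for one tool and hemisphere, the volume
#' thresholds (mm3) of a set of percentile levels over a grid of ages. The
#' constructor enforces that thresholds strictly increase with level at every
#' age (no quantile crossing) and, for published anchors, that every level's
#' threshold at age 90 does not exceed its value at age 56.
#'
#' @param data A data frame with columns `age`, `level`, `threshold`.
#' @param tool `"FS"` or `"AA"`.
#' @param hemisphere `"left"` or `"right"`.
#' @param provenance `"fitted"` or `"published_anchor"`.
#' @return A tibble of class `hn_percentile_table` with columns `tool`,
#'   `hemisphere`, `age`, `level`, `threshold` and a `provenance` attribute.
#' @export
percentile_table <- function(data, tool, hemisphere,
                             provenance = c("fitted", "published_anchor")) {
  provenance <- match.arg(provenance)
  tool <- match.arg(tool, c("FS", "AA"))
  hemisphere <- match.arg(hemisphere, c("left", "right"))
  stopifnot(is.data.frame(data),
            all(c("age", "level", "threshold") %in% names(data)))
  out <- tibble::tibble(
    tool = tool, hemisphere = hemisphere,
    age = as.numeric(data$age), level = as.numeric(data$level),
    threshold = as.numeric(data$threshold)
  )
  out <- dplyr::arrange(out, .data$age, .data$level)
  check_level_monotone(out)
  if (provenance == "published_anchor" && all(c(56, 90) %in% out$age)) {
    for (lv in unique(out$level)) {
      t56 <- out$threshold[out$age == 56 & out$level == lv]
      t90 <- out$threshold[out$age == 90 & out$level == lv]
      if (length(t56) == 1 && length(t90) == 1 && t90 > t56) {
        abort(sprintf("Published anchors must not increase with age (level %g).", lv))
      }
    }
  }
  attr(out, "provenance") <- provenance
  class(out) <- c("hn_percentile_table", class(out))
  out
}

check_level_monotone <- function(tbl) {
  for (a in unique(tbl$age)) {
    sub <- tbl[tbl$age == a, ]
    sub <- sub[order(sub$level), ]
    if (nrow(sub) > 1 && any(diff(sub$threshold) <= 0)) {
      i <- which(diff(sub$threshold) <= 0)[1] + 1L
      abort(sprintf(
        "Thresholds must strictly increase with level: violation at age %g, level %g.",
        a, sub$level[i]))
    }
  }
  invisible(tbl)
}

#' Provenance of a percentile table
#' @param table An `hn_percentile_table`.
#' @return `"fitted"` or `"published_anchor"`.
#' @export
table_provenance <- function(table) attr(table, "provenance", exact = TRUE)

#' Published 5th-percentile anchor thresholds
#'
#' Returns the packaged normative anchors: the 5th-percentile hippocampal
#' volume thresholds at ages 56 and 90 years for each tool and hemisphere
#' (FS left/right 3,223/3,456 mm3 at 56 and 2,506/2,415 mm3 at 90; AA
#' left/right 4,583/4,873 mm3 at 56 and 3,831/3,870 mm3 at 90). Only these
#' printed anchors are shipped; queries at other ages fail explicitly rather
#' than silently interpolating — intermediate ages require a model fitted
#' with [fit_normative()].
#'
#' @return A named list of four [percentile_table()] objects
#'   (`FS_left`, `FS_right`, `AA_left`, `AA_right`), provenance
#'   `"published_anchor"`.
#' @examples
#' norms <- load_published_norms()
#' threshold_at(norms$FS_left, age = 56, level = 5)
#' @export
load_published_norms <- function() {
  path <- system.file("extdata", "published_norms.csv", package = "hippnorm",
                      mustWork = TRUE)
  raw <- readr::read_csv(path, col_types = "ccddd", progress = FALSE)
  keys <- dplyr::distinct(raw, .data$tool, .data$hemisphere)
  tables <- purrr::pmap(keys, function(tool, hemisphere) {
    sub <- raw[raw$tool == tool & raw$hemisphere == hemisphere, ]
    percentile_table(sub[, c("age", "level", "threshold")],
                     tool = tool, hemisphere = hemisphere,
                     provenance = "published_anchor")
  })
  setNames(tables, paste(keys$tool, keys$hemisphere, sep = "_"))
}

#' Look up a threshold in a percentile table
#'
#' Exact-match lookup: the (age, level) pair must be present in the table.
#' Published-anchor tables are deliberately sparse, so a query at an
#' unanchored age is an error, never an interpolation.
#'
#' @param table An `hn_percentile_table`.
#' @param age Age in years.
#' @param level Percentile level (e.g. 5).
#' @return The threshold in mm3 (length-1 numeric).
#' @export
threshold_at <- function(table, age, level) {
  stopifnot(inherits(table, "hn_percentile_table"))
  hit <- table$threshold[table$age == age & table$level == level]
  if (length(hit) == 0) {
    if (identical(table_provenance(table), "published_anchor")) {
      abort(sprintf("No published anchor at this age/level (age %g, level %g); fit a model for intermediate ages.",
                    age, level))
    }
    abort(sprintf("No threshold at age %g, level %g in this table.", age, level))
  }
  hit[1]
}

#' Write a percentile table to delimited text
#'
#' Writes one row per age and one column per level (`p5`, `p10`, ...),
#' preceded by `#` header lines identifying tool, hemisphere and provenance.
#' Values are printed at a fixed decimal precision so that
#' [read_percentile_table()] reproduces the file's values exactly.
#'
#' @param table An `hn_percentile_table` satisfying its invariants.
#' @param path Output path.
#' @param digits Decimal places printed (default 3).
#' @return `path`, invisibly.
#' @export
write_percentile_table <- function(table, path, digits = 3L) {
  stopifnot(inherits(table, "hn_percentile_table"))
  check_level_monotone(table)
  wide <- tidyr::pivot_wider(
    tibble::as_tibble(table)[, c("age", "level", "threshold")],
    names_from = "level", values_from = "threshold", names_prefix = "p")
  wide <- dplyr::arrange(wide, .data$age)
  header <- c(
    "# hippnorm percentile table",
    sprintf("# tool: %s", table$tool[1]),
    sprintf("# hemisphere: %s", table$hemisphere[1]),
    sprintf("# provenance: %s", table_provenance(table))
  )
  fmt <- function(x) sprintf(paste0("%.", digits, "f"), x)
  body <- vapply(seq_len(nrow(wide)), function(i) {
    paste(c(format(wide$age[i], scientific = FALSE),
            fmt(unlist(wide[i, -1]))), collapse = ",")
  }, character(1))
  readr::write_lines(c(header, paste(names(wide), collapse = ","), body), path)
  invisible(path)
}

#' Read back a percentile table written by [write_percentile_table()]
#'
#' @param path Path to the file.
#' @return An `hn_percentile_table`.
#' @export
read_percentile_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readr::read_lines(path, progress = FALSE)
  meta_line <- function(key) {
    ln <- grep(sprintf("^#\\s*%s:", key), lines, value = TRUE)
    if (length(ln) == 0) abort(sprintf("Missing '# %s:' header line.", key))
    trimws(sub(sprintf("^#\\s*%s:", key), "", ln[1]))
  }
  tool <- meta_line("tool")
  hemisphere <- meta_line("hemisphere")
  provenance <- meta_line("provenance")
  body <- lines[!startsWith(lines, "#")]
  wide <- readr::read_csv(I(paste(body, collapse = "\n")),
                          col_types = readr::cols(.default = readr::col_double()),
                          progress = FALSE)
  long <- tidyr::pivot_longer(wide, -"age", names_to = "level",
                              values_to = "threshold")
  long$level <- as.numeric(sub("^p", "", long$level))
  percentile_table(long, tool = tool, hemisphere = hemisphere,
                   provenance = provenance)
}
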