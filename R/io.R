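#' Construct / validate an event matrix
#'
#' An event matrix holds one tube of one patient: one row per event (cell)
#' and seven columns in the canonical channel order of [flow_channels()].
#'
#' @param x Numeric matrix (or object coercible to one) with 7 columns.
#' @return A numeric matrix with canonical column names, validated to be
#'   finite and free of missing values.
#' @export
event_matrix <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) != 7L) {
    stop("an event matrix must have exactly 7 channel columns, got ",
         ncol(x), call. = FALSE)
  }
  storage.mode(x) <- "double"
  if (anyNA(x) || !all(is.finite(x))) {
    stop("event matrix contains missing or non-finite values",
         call. = FALSE)
  }
  colnames(x) <- flow_channels()
  x
}

#' Read one tube's event table from delimited text
#'
#' Reads an events-by-channels table (CSV by default).  If the file has a
#' header whose names match the canonical channel names (case-insensitive,
#' in any order) the columns are reordered accordingly; a headerless file
#' with 7 numeric columns is taken to already be in canonical order.  A
#' `col_map` can rename nonstandard headers.
#'
#' @param path Path to the delimited file.
#' @param sep Field separator, default `","`.
#' @param col_map Optional named character vector mapping file column names
#'   to canonical channel names, e.g. `c("FSC-A" = "FS")`.
#' @return An [event_matrix()] with one row per data line.
#' @export
read_tube_table <- function(path, sep = ",", col_map = NULL) {
  if (!file.exists(path)) {
    stop("tube file does not exist: ", path, call. = FALSE)
  }
  dt <- data.table::fread(path, sep = sep, header = "auto",
                          data.table = FALSE, colClasses = "character")
  if (ncol(dt) != 7L) {
    stop("wrong column count in tube file '", path, "': expected 7, got ",
         ncol(dt), call. = FALSE)
  }
  nms <- names(dt)
  if (!is.null(col_map)) {
    hit <- match(nms, names(col_map))
    nms[!is.na(hit)] <- col_map[hit[!is.na(hit)]]
  }
  canon <- flow_channels()
  if (all(toupper(canon) %in% toupper(nms))) {
    dt <- dt[match(toupper(canon), toupper(nms))]
  }
  vals <- suppressWarnings(vapply(dt, as.numeric, numeric(nrow(dt))))
  vals <- matrix(vals, nrow = nrow(dt), ncol = 7L)
  if (anyNA(vals)) {
    bad <- which(apply(is.na(vals), 1L, any))[1L]
    stop("non-numeric cell in tube file '", path, "' at data row ", bad,
         call. = FALSE)
  }
  event_matrix(vals)
}

#' Write one tube's event table as CSV
#'
#' Full double precision is kept so that a write/read round trip
#' reproduces the matrix to numeric-text precision.
#'
#' @param m An [event_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tube_table <- function(m, path) {
  m <- event_matrix(m)
  data.table::fwrite(as.data.frame(m), path)
  invisible(path)
}

#' Construct a patient sample
#'
#' @param patient_id Character identifier.
#' @param label `1` (AML-positive), `0` (healthy) or `NA` (unknown; not
#'   usable for training).
#' @param tubes Named list of [event_matrix()] objects; names are tube ids
#'   within `"1"`..`"7"`.
#' @return An object of class `patient_sample`.
#' @export
patient_sample <- function(patient_id, label, tubes) {
  if (!is.list(tubes) || is.null(names(tubes))) {
    stop("`tubes` must be a named list of event matrices", call. = FALSE)
  }
  ids <- suppressWarnings(as.integer(names(tubes)))
  if (anyNA(ids) || !all(ids %in% 1:7)) {
    stop("tube ids must be within 1..7", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate tube ids for patient ", patient_id, call. = FALSE)
  }
  tubes <- lapply(tubes, event_matrix)
  names(tubes) <- as.character(ids)
  if (!is.na(label) && !label %in% c(0, 1)) {
    stop("label must be 0 (healthy), 1 (AML) or NA", call. = FALSE)
  }
  structure(
    list(patient_id = as.character(patient_id),
         label = label,
         tubes = tubes[order(ids)]),
    class = "patient_sample"
  )
}

#' @export
print.patient_sample <- function(x, ...) {
  ev <- vapply(x$tubes, nrow, integer(1))
  cat("<patient_sample> ", x$patient_id,
      "  label=", ifelse(is.na(x$label), "?", x$label),
      "  tubes=", paste(names(x$tubes), collapse = ","),
      "  events=", paste(ev, collapse = ","), "\n", sep = "")
  invisible(x)
}

#' Assemble patients into a cohort
#'
#' @param patients List of [patient_sample()] objects with distinct ids.
#' @return An object of class `aml_cohort`.
#' @export
as_cohort <- function(patients) {
  stopifnot(is.list(patients), length(patients) > 0L)
  ids <- vapply(patients, function(p) p$patient_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate patient ids in cohort", call. = FALSE)
  }
  names(patients) <- ids
  structure(list(patients = patients), class = "aml_cohort")
}

#' @export
print.aml_cohort <- function(x, ...) {
  lab <- cohort_labels(x)
  cat("<aml_cohort> ", length(x$patients), " patients (",
      sum(lab == 1, na.rm = TRUE), " AML, ",
      sum(lab == 0, na.rm = TRUE), " healthy",
      if (anyNA(lab)) paste0(", ", sum(is.na(lab)), " unlabeled"), ")\n",
      sep = "")
  invisible(x)
}

#' Cohort labels, in patient order
#' @param cohort An `aml_cohort`.
#' @return Numeric vector of 0/1/NA labels named by patient id.
#' @export
cohort_labels <- function(cohort) {
  vapply(cohort$patients, function(p) as.numeric(p$label), numeric(1))
}

#' Subset a cohort by patient id or position
#' @param cohort An `aml_cohort`.
#' @param ids Character ids or integer positions.
#' @return The sub-cohort.
#' @export
subset_cohort <- function(cohort, ids) {
  as_cohort(cohort$patients[ids])
}

#' Read a cohort manifest
#'
#' The manifest is a CSV with columns `patient_id`, `tube`, `path`,
#' `label`.  Paths are resolved relative to the manifest's directory
#' unless absolute.
#'
#' @param path Manifest file path.
#' @return A `data.frame` manifest with resolved paths.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) {
    stop("manifest does not exist: ", path, call. = FALSE)
  }
  man <- data.table::fread(path, data.table = FALSE)
  need <- c("patient_id", "tube", "path", "label")
  if (!all(need %in% names(man))) {
    stop("manifest must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  man$patient_id <- as.character(man$patient_id)
  man$tube <- as.integer(man$tube)
  base <- dirname(normalizePath(path))
  rel <- !grepl("^(/|[A-Za-z]:)", man$path)
  man$path[rel] <- file.path(base, man$path[rel])
  man
}

#' Write a cohort manifest
#' @param manifest Data frame with columns `patient_id`, `tube`, `path`,
#'   `label`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  data.table::fwrite(
    manifest[, c("patient_id", "tube", "path", "label")], path)
  invisible(path)
}

#' Load a cohort from a manifest
#'
#' Builds one [patient_sample()] per distinct `patient_id`.  Rows for the
#' control tube (tube 8) are accepted but excluded from the cohort with a
#' message, since the control tube carries no diagnostic panel.  Patients
#' missing any of tubes 1-7 are kept but flagged.
#'
#' @param manifest A manifest `data.frame` (see [read_manifest()]) or a
#'   path to one.
#' @param sep Field separator of the tube files.
#' @param col_map Passed to [read_tube_table()].
#' @return An `aml_cohort`; the attribute `"incomplete"` lists patients
#'   missing tubes.
#' @export
load_cohort <- function(manifest, sep = ",", col_map = NULL) {
  if (is.character(manifest)) {
    manifest <- read_manifest(manifest)
  }
  ctrl <- manifest$tube == 8L
  if (any(ctrl)) {
    message("excluding ", sum(ctrl),
            " control-tube (tube 8) rows: the control tube is not used ",
            "for prediction")
    manifest <- manifest[!ctrl, , drop = FALSE]
  }
  if (!all(manifest$tube %in% 1:7)) {
    stop("manifest tube ids must be within 1..8", call. = FALSE)
  }
  key <- paste(manifest$patient_id, manifest$tube)
  if (anyDuplicated(key)) {
    stop("duplicate (patient_id, tube) rows in manifest: ",
         paste(unique(key[duplicated(key)]), collapse = "; "),
         call. = FALSE)
  }
  missing_files <- !file.exists(manifest$path)
  if (any(missing_files)) {
    stop("manifest references missing files: ",
         paste(manifest$path[missing_files], collapse = "; "),
         call. = FALSE)
  }
  ids <- sort(unique(manifest$patient_id))
  patients <- lapply(ids, function(id) {
    rows <- manifest[manifest$patient_id == id, , drop = FALSE]
    rows <- rows[order(rows$tube), , drop = FALSE]
    lab <- unique(rows$label)
    if (length(lab) != 1L) {
      stop("inconsistent labels for patient ", id, call. = FALSE)
    }
    tubes <- lapply(rows$path, read_tube_table, sep = sep,
                    col_map = col_map)
    names(tubes) <- as.character(rows$tube)
    patient_sample(id, lab, tubes)
  })
  cohort <- as_cohort(patients)
  incomplete <- vapply(cohort$patients,
                       function(p) length(p$tubes) < 7L, logical(1))
  if (any(incomplete)) {
    warning("patients missing tubes: ",
            paste(names(which(incomplete)), collapse = ", "),
            call. = FALSE)
  }
  attr(cohort, "incomplete") <- names(which(incomplete))
  cohort
}

#' Write a cohort to disk as per-tube CSV files plus a manifest
#'
#' @param cohort An `aml_cohort`.
#' @param dir Output directory (created if needed).
#' @return The manifest `data.frame`, invisibly; the manifest file is
#'   written to `file.path(dir, "manifest.csv")`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (p in cohort$patients) {
    for (tid in names(p$tubes)) {
      fn <- sprintf("%s_tube%s.csv", p$patient_id, tid)
      write_tube_table(p$tubes[[tid]], file.path(dir, fn))
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = p$patient_id, tube = as.integer(tid),
        path = fn, label = p$label, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}
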