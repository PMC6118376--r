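#' Construct a cohort table
#'
#' One row per patient: positive follow-up time in years, a 0/1 event flag,
#' and mixed continuous/categorical/binary covariates in which `NA` marks a
#' missing cell. Variable metadata records each variable's kind, category
#' labels and provenance tag (`"expert"` or `"extended"`).
#'
#' @param patient_id character identifiers (unique).
#' @param time positive follow-up times, years.
#' @param event integer 0/1 (1 = died).
#' @param values data frame of covariates (factors for categoricals).
#' @param meta named list of per-variable metadata lists
#'   (`name`, `kind`, `labels`, `source`).
#' @return an object of class `cohort`.
#' @export
new_cohort <- function(patient_id, time, event, values, meta) {
  n <- length(patient_id)
  stopifnot(length(time) == n, length(event) == n, nrow(values) == n)
  if (anyDuplicated(patient_id)) stop_sm("patient ids must be unique")
  if (any(time <= 0)) stop_sm("all follow-up times must be positive")
  if (!all(event %in% c(0L, 1L))) stop_sm("event must be 0 or 1")
  if (anyDuplicated(names(values))) stop_sm("variable names must be unique")
  if (!setequal(names(values), names(meta)))
    stop_sm("metadata must cover exactly the cohort variables")
  for (v in names(values)) {
    if (meta[[v]]$kind == "categorical") {
      if (!is.factor(values[[v]]))
        values[[v]] <- factor(values[[v]], levels = meta[[v]]$labels)
      if (any(!levels(values[[v]]) %in% meta[[v]]$labels))
        stop_sm("variable '%s' has labels outside its declared set", v)
    }
  }
  structure(list(patient_id = as.character(patient_id),
                 time = as.numeric(time), event = as.integer(event),
                 values = values, meta = meta),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  kinds <- table(vapply(x$meta, `[[`, character(1), "kind"))
  cat(sprintf("<cohort> %d patients, %d variables (%s); %d events (%.1f%%)\n",
              length(x$time), ncol(x$values),
              paste(sprintf("%s %s", kinds, names(kinds)), collapse = ", "),
              sum(x$event), 100 * mean(x$event)))
  invisible(x)
}

#' Subset a cohort by row index or by variables
#'
#' @param cohort a `cohort`.
#' @param rows integer/logical row index (default all).
#' @param variables character vector of variables to keep (default all).
#' @return a `cohort`.
#' @export
cohort_subset <- function(cohort, rows = NULL, variables = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  if (is.null(rows)) rows <- seq_along(cohort$time)
  vars <- variables %||% names(cohort$values)
  miss <- setdiff(vars, names(cohort$values))
  if (length(miss)) stop_sm("unknown variables: %s", paste(miss, collapse = ", "))
  new_cohort(cohort$patient_id[rows], cohort$time[rows], cohort$event[rows],
             cohort$values[rows, vars, drop = FALSE], cohort$meta[vars])
}

#' Per-variable missing fractions
#'
#' @param cohort a `cohort`.
#' @return named numeric vector of missing fractions.
#' @export
missing_fraction <- function(cohort) {
  vapply(cohort$values, function(v) mean(is.na(v)), numeric(1))
}

#' Write / read a cohort as CSV plus a JSON metadata sidecar
#'
#' The CSV holds `patient_id`, `time`, `event` and one column per variable,
#' with missing cells written as empty strings; variable kinds, labels and
#' source tags go to `<path>.meta.json`.
#'
#' @param cohort a `cohort`.
#' @param path CSV file path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` a `cohort`.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  df <- data.frame(patient_id = cohort$patient_id, time = cohort$time,
                   event = cohort$event, cohort$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, na = "")
  jsonlite::write_json(cohort$meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE,
                              simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  meta <- lapply(meta, function(m) {
    m$labels <- if (is.null(m$labels)) NULL else unlist(m$labels)
    m
  })
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                 na.strings = "")
  values <- df[, setdiff(names(df), c("patient_id", "time", "event")),
               drop = FALSE]
  for (v in names(values)) {
    if (meta[[v]]$kind == "categorical")
      values[[v]] <- factor(values[[v]], levels = meta[[v]]$labels)
    else values[[v]] <- as.numeric(values[[v]])
  }
  new_cohort(df$patient_id, df$time, df$event, values, meta)
}
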