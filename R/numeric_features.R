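# Numerical clinical indicators: unit normalisation, plausibility
# validation and assembly into the fixed-length numeric vector that is
# concatenated with the document embedding.
#
# Clinical free text records numbers in inconsistent units ("menopause 8
# weeks" vs "menopause 2 months") and with occasional transcription errors
# (a uterine height of "29 m").  Each feature therefore carries a target
# unit, multiplicative conversion rules from alternative units, and a
# plausibility range [min, max]; values outside the range are treated as
# erroneous and deleted (imputed as missing), never clamped.

#' Define a numeric feature schema
#'
#' @param features A list of feature definitions, each a list with `name`,
#'   `unit` (target unit), `min`, `max` (inclusive plausibility bounds) and
#'   optional `convert`, a named numeric vector of multiplicative factors
#'   from alternative units into the target unit.  The list order defines
#'   the layout of the numeric vector.
#' @return A `feature_schema` object.
#' @export
feature_schema <- function(features) {
  for (f in features) {
    stopifnot(is.character(f$name), is.numeric(f$min), is.numeric(f$max))
    if (f$min >= f$max) stop("feature '", f$name, "': min must be < max")
    if (!is.null(f$convert) && any(f$convert <= 0)) {
      stop("feature '", f$name, "': conversion factors must be positive")
    }
  }
  nm <- vapply(features, function(f) f$name, "")
  if (anyDuplicated(nm)) stop("duplicate feature names in schema")
  structure(list(features = features), class = "feature_schema")
}

#' @export
print.feature_schema <- function(x, ...) {
  cat("Numeric feature schema (", length(x$features), " features):\n", sep = "")
  for (f in x$features) {
    cat("  ", f$name, " [", f$unit, "], valid ", f$min, "..", f$max, "\n",
        sep = "")
  }
  invisible(x)
}

#' @rdname feature_schema
#' @param path Path to a YAML file with a top-level `features` list.
#' @export
read_feature_schema <- function(path) {
  obj <- yaml::read_yaml(path)
  feats <- lapply(obj$features, function(f) {
    f$convert <- if (!is.null(f$convert)) unlist(f$convert) else NULL
    f
  })
  feature_schema(feats)
}

#' @rdname feature_schema
#' @param schema A `feature_schema` to serialize.
#' @export
write_feature_schema <- function(schema, path) {
  obj <- list(features = lapply(schema$features, function(f) {
    out <- list(name = f$name, unit = f$unit, min = f$min, max = f$max)
    if (!is.null(f$convert)) out$convert <- as.list(f$convert)
    out
  }))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Example obstetric feature schema
#'
#' A three-feature schema (maternal age in years, months since last
#' menstruation with a weeks-to-months rule of 4 weeks per month, and
#' uterine height in cm with a metres conversion) used by the synthetic
#' corpus generator and the documentation.  Real deployments supply their
#' own schema file; the plausibility thresholds here are illustrative.
#'
#' @return A `feature_schema`.
#' @export
example_feature_schema <- function() {
  feature_schema(list(
    list(name = "age", unit = "years", min = 10, max = 60),
    list(name = "menopause", unit = "months", min = 0, max = 11,
         convert = c(weeks = 1 / 4)),
    list(name = "uterine_height", unit = "cm", min = 10, max = 45,
         convert = c(m = 100, mm = 1 / 10))
  ))
}

#' Convert a raw value into a feature's target unit
#'
#' @param value Numeric value in `source_unit`.
#' @param source_unit Unit string; the feature's own unit is the identity.
#' @param entry One feature definition from a [feature_schema()].
#' @return Value in the feature's target unit.
#' @export
normalize_unit <- function(value, source_unit, entry) {
  if (identical(source_unit, entry$unit)) return(value)
  f <- if (!is.null(entry$convert) && source_unit %in% names(entry$convert))
    entry$convert[[source_unit]] else NA_real_
  if (is.na(f)) {
    stop("feature '", entry$name, "': unknown unit '", source_unit, "'")
  }
  value * f
}

#' Validate a value against a feature's plausibility range
#'
#' Bounds are inclusive; out-of-range values are erroneous records of the
#' measurement and are deleted (treated as missing), never clamped.
#'
#' @inheritParams normalize_unit
#' @return Logical: is the value plausible?
#' @export
validate_value <- function(value, entry) {
  is.finite(value) & value >= entry$min & value <= entry$max
}

# Parse a raw field like "8", "8 weeks" or "29 m" into value + unit.
parse_numeric_raw <- function(x) {
  x <- trimws(as.character(x))
  m <- regmatches(x, regexec("^([-+]?[0-9]*\\.?[0-9]+)\\s*([^0-9[:space:]]\\S*)?$", x))[[1]]
  if (length(m) == 0L || !nzchar(m[2])) return(list(value = NA_real_, unit = NA_character_))
  list(value = as.numeric(m[2]),
       unit = if (length(m) >= 3L && nzchar(m[3])) m[3] else NA_character_)
}

# Parse + unit-normalise + validate one record's raw numeric fields.
# Returns list(values, valid): parsed values (NA where missing/invalid)
# and the validity flags.
numeric_parse_record <- function(record, schema) {
  p <- length(schema$features)
  values <- rep(NA_real_, p)
  valid <- rep(FALSE, p)
  for (j in seq_len(p)) {
    entry <- schema$features[[j]]
    raw <- if (entry$name %in% names(record$numeric_raw))
      record$numeric_raw[[entry$name]] else NA_character_
    if (is.na(raw)) next
    pv <- parse_numeric_raw(raw)
    if (is.na(pv$value)) next
    val <- if (is.na(pv$unit)) pv$value else
      tryCatch(normalize_unit(pv$value, pv$unit, entry),
               error = function(e) NA_real_)
    if (is.na(val)) next
    if (validate_value(val, entry)) {
      values[j] <- val
      valid[j] <- TRUE
    }
  }
  list(values = values, valid = valid)
}

#' Fit imputation and standardisation statistics on training records
#'
#' Computes, per feature, the mean and standard deviation of the valid
#' training values.  Missing and out-of-range values are imputed with the
#' training mean and the whole vector is z-scored with these statistics
#' before entering the model, so that physiological magnitudes do not
#' dominate the unit-scale document embedding.
#'
#' @param records Training records.
#' @param schema A `feature_schema`.
#' @return A `numeric_stats` object with `mean` and `sd` vectors.
#' @export
fit_numeric_stats <- function(records, schema) {
  p <- length(schema$features)
  vals <- matrix(NA_real_, length(records), p)
  for (i in seq_along(records)) {
    vals[i, ] <- numeric_parse_record(records[[i]], schema)$values
  }
  mu <- colMeans(vals, na.rm = TRUE)
  sdv <- apply(vals, 2L, stats::sd, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  sdv[is.na(sdv) | sdv < 1e-12] <- 1
  structure(list(mean = mu, sd = sdv,
                 names = vapply(schema$features, function(f) f$name, "")),
            class = "numeric_stats")
}

#' Extract the numeric feature vector of a record
#'
#' One slot per schema feature: raw fields are parsed, converted to the
#' target unit, range-validated ("deleted" if implausible), mean-imputed
#' where missing/invalid, and z-scored with the training statistics.
#'
#' @param record One record.
#' @param schema A `feature_schema`.
#' @param stats A `numeric_stats` from [fit_numeric_stats()]; `NULL` skips
#'   standardisation (raw values, zero-imputed).
#' @return List with `values` (length `|schema|`) and `valid` (logical mask,
#'   `FALSE` on imputed slots).
#' @export
extract_vector <- function(record, schema, stats = NULL) {
  pr <- numeric_parse_record(record, schema)
  if (is.null(stats)) {
    vals <- ifelse(pr$valid, pr$values, 0)
    return(list(values = vals, valid = pr$valid))
  }
  vals <- ifelse(pr$valid, pr$values, stats$mean)
  list(values = (vals - stats$mean) / stats$sd, valid = pr$valid)
}

#' Numeric feature matrix for a set of records
#'
#' @param records List of records.
#' @inheritParams extract_vector
#' @return List with `values` (n x p matrix, z-scored and imputed) and
#'   `valid` (n x p logical matrix).
#' @export
extract_matrix <- function(records, schema, stats) {
  p <- length(schema$features)
  values <- matrix(0, length(records), p)
  valid <- matrix(FALSE, length(records), p)
  for (i in seq_along(records)) {
    ev <- extract_vector(records[[i]], schema, stats)
    values[i, ] <- ev$values
    valid[i, ] <- ev$valid
  }
  colnames(values) <- vapply(schema$features, function(f) f$name, "")
  list(values = values, valid = valid)
}
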