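# Experiment metadata records and minimum-information completeness
# scoring. A record maps content-bearing field ids to values; scores
# report the fraction of applicable fields (by requirement floor and in
# vitro / in vivo model context) that the record actually fills.

#' Construct a metadata record
#'
#' @param values Data frame with columns `field_id`, `value` and
#'   optionally `unit`, or a named list mapping field ids to values.
#' @param record_id Record identifier.
#' @param schema_version Version string of the schema the record was
#'   written against.
#' @param model_context One of `"in_vitro"`, `"in_vivo"`, `"both"`; the
#'   biological-model branch the experiment used.
#' @return An object of class `mit_record`.
#' @export
mit_record <- function(values, record_id = "record",
                       schema_version = "1.0",
                       model_context = c("in_vitro", "in_vivo", "both")) {
  model_context <- match.arg(model_context)
  if (is.list(values) && !is.data.frame(values)) {
    values <- data.frame(field_id = names(values),
                         value = unname(vapply(values, as.character,
                                               character(1))),
                         stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(values))
  if (nrow(values) > 0) stopifnot(all(c("field_id", "value") %in%
                                      names(values)))
  for (col in c("field_id", "value", "unit")) {
    if (!col %in% names(values)) values[[col]] <- rep("", nrow(values))
    values[[col]] <- as.character(values[[col]])
    values[[col]][is.na(values[[col]])] <- ""
  }
  values <- values[, c("field_id", "value", "unit"), drop = FALSE]
  rownames(values) <- NULL
  structure(list(record_id = record_id, schema_version = schema_version,
                 model_context = model_context, values = values),
            class = "mit_record")
}

#' @export
print.mit_record <- function(x, ...) {
  cat("Metadata record <", x$record_id, "> (", x$model_context, "): ",
      nrow(x$values), " values against schema version ",
      x$schema_version, "\n", sep = "")
  invisible(x)
}

#' Read / write a metadata record
#'
#' CSV layout: leading comment lines `#record_id`, `#schema_version`,
#' `#model_context`, then a header row `field_id,value,unit`. JSON
#' layout: one document with the same content.
#'
#' @param path File path.
#' @param format `"csv"` or `"json"`; inferred from the extension when
#'   missing.
#' @return `read_record` returns a `mit_record`.
#' @export
read_record <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path)) "json" else "csv"
  }
  if (format == "json") {
    doc <- jsonlite::read_json(path)
    vals <- if (length(doc$values) == 0) {
      data.frame(field_id = character(), value = character(),
                 stringsAsFactors = FALSE)
    } else {
      do.call(rbind, lapply(doc$values, function(v) {
        data.frame(field_id = v$field_id, value = as.character(v$value),
                   unit = v$unit %||% "", stringsAsFactors = FALSE)
      }))
    }
    return(mit_record(vals, record_id = doc$record_id %||% "record",
                      schema_version = doc$schema_version %||% "1.0",
                      model_context = doc$model_context %||% "both"))
  }
  lines <- readLines(path, encoding = "UTF-8")
  meta <- grep("^#", lines, value = TRUE)
  get_meta <- function(key, default) {
    hit <- grep(paste0("^#", key, ": ?"), meta, value = TRUE)
    if (length(hit) == 0) default else
      sub(paste0("^#", key, ": ?"), "", hit[1])
  }
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE,
                        colClasses = "character")
  mit_record(df, record_id = get_meta("record_id", "record"),
             schema_version = get_meta("schema_version", "1.0"),
             model_context = get_meta("model_context", "both"))
}

#' @rdname read_record
#' @param record A `mit_record`.
#' @export
write_record <- function(record, path, format = NULL) {
  stopifnot(inherits(record, "mit_record"))
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path)) "json" else "csv"
  }
  if (format == "json") {
    doc <- list(record_id = record$record_id,
                schema_version = record$schema_version,
                model_context = record$model_context,
                values = lapply(seq_len(nrow(record$values)), function(i) {
                  as.list(record$values[i, ])
                }))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
    return(invisible(path))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste0("#record_id: ", record$record_id),
               paste0("#schema_version: ", record$schema_version),
               paste0("#model_context: ", record$model_context)),
             con, sep = "\n")
  utils::write.table(record$values, con, sep = ",", qmethod = "double",
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

# "not applicable" is an explicit sentinel: the experimenter addressed
# the field, so it counts as present and passes value-kind checks.
.is_na_sentinel <- function(value) {
  normalize_join(value) %in% c("not applicable", "na", "n a")
}

.value_kind_ok <- function(value, kind) {
  if (.is_na_sentinel(value)) return(TRUE)
  switch(kind,
         quantity_with_unit = grepl("[0-9]", value),
         boolean = normalize_join(value) %in%
           c("yes", "no", "true", "false"),
         identifier = !grepl("\\s", trimws(value)) && nzchar(trimws(value)),
         TRUE)
}

#' Validate a metadata record against a schema
#'
#' Returns a data frame of findings, one row per problem: unknown keys
#' (not a content-bearing field of the schema), value-kind violations
#' (e.g. no numeric content where a quantity is required), and
#' applicability violations (a field of the other in vitro / in vivo
#' branch present given the record's model context). An empty record is
#' valid -- emptiness is a completeness matter, not a validity one. A
#' schema-version mismatch is an error, not a finding.
#'
#' @param record A `mit_record`.
#' @param schema A `mit_schema`.
#' @return Data frame with columns `field_id`, `finding`, `detail`;
#'   zero rows when clean.
#' @export
validate_record <- function(record, schema) {
  stopifnot(inherits(record, "mit_record"), inherits(schema, "mit_schema"))
  if (record$schema_version != schema$version) {
    stop("version error: record written against schema version ",
         record$schema_version, ", schema is ", schema$version)
  }
  f <- content_fields(schema)
  findings <- list()
  add <- function(fid, what, detail) {
    findings[[length(findings) + 1L]] <<- data.frame(
      field_id = fid, finding = what, detail = detail,
      stringsAsFactors = FALSE)
  }
  v <- record$values
  for (i in seq_len(nrow(v))) {
    fid <- v$field_id[i]
    row <- f[f$field_id == fid, , drop = FALSE]
    if (nrow(row) == 0) {
      add(fid, "unknown_field", "not a content-bearing schema field")
      next
    }
    if (!.value_kind_ok(v$value[i], row$value_kind)) {
      add(fid, "value_kind",
          paste0("value '", v$value[i], "' does not satisfy kind '",
                 row$value_kind, "'"))
    }
    app <- row$applicability
    ctx <- record$model_context
    if ((app == "in_vivo_only" && ctx == "in_vitro") ||
        (app == "in_vitro_only" && ctx == "in_vivo")) {
      add(fid, "applicability",
          paste0("field is ", app, " but record context is ", ctx))
    }
  }
  if (length(findings) == 0) {
    return(data.frame(field_id = character(), finding = character(),
                      detail = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, findings)
}

.applicable_fields <- function(schema, model_context, requirement_floor) {
  f <- content_fields(schema)
  req_rank <- c(minimum = 3L, recommended = 2L, optional = 1L)
  floor_rank <- req_rank[[requirement_floor]]
  app_ok <- switch(model_context,
                   both = rep(TRUE, nrow(f)),
                   in_vitro = f$applicability %in% c("always",
                                                     "in_vitro_only"),
                   in_vivo = f$applicability %in% c("always",
                                                    "in_vivo_only"))
  f[app_ok & req_rank[f$requirement] >= floor_rank, , drop = FALSE]
}

#' Minimum-information completeness score of a record
#'
#' For every module counts the applicable content-bearing fields (those
#' whose requirement level is at or above `requirement_floor` and whose
#' applicability matches the record's model context) and how many of them
#' the record fills with at least one non-empty value ("not applicable"
#' counts as addressed). Unknown keys never contribute. The overall
#' fraction is total present over total applicable (0 when nothing is
#' applicable).
#'
#' @param record A `mit_record`.
#' @param schema A `mit_schema`.
#' @param requirement_floor `"minimum"`, `"recommended"` or `"optional"`;
#'   fields with requirement below the floor are excluded from the
#'   denominator. `"optional"` admits every field.
#' @return An object of class `mit_completeness`: `per_module` data frame
#'   (`module_id`, `n_applicable`, `n_present`, `fraction`),
#'   `overall_fraction`, `missing_minimum` (absent minimum-requirement
#'   applicable field ids) and `unknown_fields`.
#' @export
#' @examples
#' sch <- build_reference_mit()
#' rec <- mit_record(list(zeta_potential = "-30 mV"))
#' completeness_score(rec, sch)$overall_fraction
completeness_score <- function(record, schema,
                               requirement_floor = c("minimum",
                                                     "recommended",
                                                     "optional")) {
  requirement_floor <- match.arg(requirement_floor)
  stopifnot(inherits(record, "mit_record"), inherits(schema, "mit_schema"))
  f_all <- content_fields(schema)
  appl <- .applicable_fields(schema, record$model_context,
                             requirement_floor)
  present_ids <- unique(record$values$field_id[
    nzchar(trimws(record$values$value))])
  unknown <- setdiff(unique(record$values$field_id), f_all$field_id)
  present_ids <- setdiff(present_ids, unknown)
  mods <- unique(schema$fields$module_id)
  mods <- c(intersect(mit_modules(), mods), setdiff(mods, mit_modules()))
  per_module <- do.call(rbind, lapply(mods, function(m) {
    am <- appl$field_id[appl$module_id == m]
    np <- sum(am %in% present_ids)
    data.frame(module_id = m, n_applicable = length(am), n_present = np,
               fraction = if (length(am) == 0) 0 else np / length(am),
               stringsAsFactors = FALSE)
  }))
  n_app <- sum(per_module$n_applicable)
  n_pres <- sum(per_module$n_present)
  min_ids <- appl$field_id[appl$requirement == "minimum"]
  structure(list(
    per_module = per_module,
    overall_fraction = if (n_app == 0) 0 else n_pres / n_app,
    n_applicable = n_app,
    n_present = n_pres,
    missing_minimum = setdiff(min_ids, present_ids),
    unknown_fields = unknown
  ), class = "mit_completeness")
}

#' @export
print.mit_completeness <- function(x, ...) {
  cat(sprintf("Completeness: %.1f%% (%d of %d applicable fields)\n",
              100 * x$overall_fraction, x$n_present, x$n_applicable))
  pm <- x$per_module
  for (i in seq_len(nrow(pm))) {
    cat(sprintf("  %-30s %3d / %3d\n", pm$module_id[i], pm$n_present[i],
                pm$n_applicable[i]))
  }
  if (length(x$unknown_fields) > 0) {
    cat("  unknown keys ignored:", length(x$unknown_fields), "\n")
  }
  invisible(x)
}
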