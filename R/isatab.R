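# Export of metadata records into an ISA-TAB-like four-table layout
# (Investigation / Study / Assay / Material), following the rough
# module correspondence between the minimum-information table and
# ISA-TAB-Nano: general information -> investigation; biological model
# and exposure information -> study; material information -> material;
# endpoint read out and analysis/statistics -> assay. Values of fields
# without a dedicated ISA-TAB column are emitted in the generic
# "Parameter Value[...]" convention.

.isatab_routing <- c(
  general_information          = "investigation",
  biological_model_information = "study",
  exposure_information         = "study",
  material_information         = "material",
  endpoint_readout_information = "assay",
  analysis_statistics          = "assay"
)

#' Module-to-table routing used for ISA-TAB export
#'
#' @return Named character vector mapping module ids to one of
#'   `"investigation"`, `"study"`, `"assay"`, `"material"`.
#' @export
isatab_routing <- function() .isatab_routing

#' Export a metadata record to an ISA-TAB-like bundle
#'
#' Validates the record against the schema (delegating; validation
#' findings raise an error), then routes every value to exactly one of
#' the four tables according to the module correspondence. Each table is
#' a two-column data frame of `column` (a `Parameter Value[<field name>]`
#' header) and `value`; every record value appears in exactly one table.
#'
#' @param record A `mit_record`.
#' @param schema A `mit_schema`.
#' @return An object of class `mit_isatab`: a list of data frames
#'   `investigation`, `study`, `assay`, `material` plus the record id.
#' @export
#' @examples
#' sch <- build_reference_mit()
#' rec <- mit_record(list(statistic = "ANOVA"))
#' record_to_isatab(rec, sch)$assay
record_to_isatab <- function(record, schema) {
  findings <- validate_record(record, schema)
  findings <- findings[findings$finding != "applicability", ,
                       drop = FALSE]
  if (nrow(findings) > 0) {
    stop("validation error: record does not validate: ",
         paste(unique(findings$finding), collapse = ", "))
  }
  f <- content_fields(schema)
  tables <- list(
    investigation = list(), study = list(), assay = list(),
    material = list())
  v <- record$values
  for (i in seq_len(nrow(v))) {
    row <- f[f$field_id == v$field_id[i], , drop = FALSE]
    tab <- .isatab_routing[[row$module_id]]
    tables[[tab]][[length(tables[[tab]]) + 1L]] <- data.frame(
      column = paste0("Parameter Value[", row$name, "]"),
      value = v$value[i], unit = v$unit[i], field_id = row$field_id,
      stringsAsFactors = FALSE)
  }
  empty <- data.frame(column = character(), value = character(),
                      unit = character(), field_id = character(),
                      stringsAsFactors = FALSE)
  out <- lapply(tables, function(rows) {
    if (length(rows) == 0) empty else do.call(rbind, rows)
  })
  structure(c(out, list(record_id = record$record_id,
                        schema_version = record$schema_version,
                        model_context = record$model_context)),
            class = "mit_isatab")
}

#' @export
print.mit_isatab <- function(x, ...) {
  cat("ISA-TAB-like bundle for record <", x$record_id, ">\n", sep = "")
  for (t in c("investigation", "study", "assay", "material")) {
    cat(sprintf("  %-14s %d values\n", t, nrow(x[[t]])))
  }
  invisible(x)
}

#' Write / read an ISA-TAB-like bundle as four TSV files
#'
#' Files follow the ISA-TAB-Nano naming convention: `i_<id>.txt`
#' (investigation), `s_<id>.txt` (study), `a_<id>.txt` (assay),
#' `m_<id>.txt` (material), each a header row plus one row per value.
#'
#' @param bundle A `mit_isatab`.
#' @param dir Output directory (created if missing).
#' @return `write_isatab` returns the four file paths invisibly;
#'   `read_isatab` returns a `mit_isatab`.
#' @export
write_isatab <- function(bundle, dir) {
  stopifnot(inherits(bundle, "mit_isatab"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  prefix <- c(investigation = "i", study = "s", assay = "a",
              material = "m")
  id <- gsub("[^A-Za-z0-9_-]", "_", bundle$record_id)
  paths <- character()
  meta <- c(paste0("#record_id: ", bundle$record_id),
            paste0("#schema_version: ", bundle$schema_version),
            paste0("#model_context: ", bundle$model_context))
  for (t in names(prefix)) {
    path <- file.path(dir, paste0(prefix[[t]], "_", id, ".txt"))
    con <- file(path, open = "wb")
    writeLines(meta, con, sep = "\n")
    utils::write.table(bundle[[t]], con, sep = "\t", row.names = FALSE,
                       quote = FALSE, eol = "\n")
    close(con)
    paths[t] <- path
  }
  invisible(paths)
}

#' @rdname write_isatab
#' @param record_id Record id naming the bundle files to read.
#' @export
read_isatab <- function(dir, record_id) {
  prefix <- c(investigation = "i", study = "s", assay = "a",
              material = "m")
  id <- gsub("[^A-Za-z0-9_-]", "_", record_id)
  out <- list()
  meta <- c(record_id = record_id, schema_version = "1.0",
            model_context = "both")
  for (t in names(prefix)) {
    path <- file.path(dir, paste0(prefix[[t]], "_", id, ".txt"))
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path, encoding = "UTF-8")
    hdr <- grep("^#", lines, value = TRUE)
    for (key in c("record_id", "schema_version", "model_context")) {
      hit <- grep(paste0("^#", key, ": ?"), hdr, value = TRUE)
      if (length(hit) > 0) meta[key] <- sub(paste0("^#", key, ": ?"), "",
                                            hit[1])
    }
    body <- lines[!grepl("^#", lines)]
    df <- utils::read.delim(text = paste(body, collapse = "\n"),
                            stringsAsFactors = FALSE,
                            colClasses = "character")
    if (nrow(df) == 0) {
      df <- data.frame(column = character(), value = character(),
                       unit = character(), field_id = character(),
                       stringsAsFactors = FALSE)
    }
    out[[t]] <- df
  }
  structure(c(out, list(record_id = meta[["record_id"]],
                        schema_version = meta[["schema_version"]],
                        model_context = meta[["model_context"]])),
            class = "mit_isatab")
}

#' Recover a metadata record from an ISA-TAB-like bundle
#'
#' Inverse of [record_to_isatab()]: concatenates the four tables back
#' into a field-id to value mapping.
#'
#' @param bundle A `mit_isatab`.
#' @return A `mit_record`.
#' @export
isatab_to_record <- function(bundle) {
  stopifnot(inherits(bundle, "mit_isatab"))
  vals <- do.call(rbind, lapply(
    c("investigation", "study", "assay", "material"), function(t) {
      bundle[[t]][, c("field_id", "value", "unit"), drop = FALSE]
    }))
  mit_record(vals, record_id = bundle$record_id,
             schema_version = bundle$schema_version,
             model_context = bundle$model_context)
}
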