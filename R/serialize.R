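# Schema serialization. The canonical dialect is a flat CSV mirroring the
# spreadsheet shape the minimum-information table originated as: one row
# per labeled field. JSON and XML are lossless projections of the same
# content; load(save(x)) is identical to x in every dialect.

.csv_columns <- c("Module", "Subdivision", "Category", "Name", "Synonyms",
                  "Applicability", "Requirement", "ValueKind", "Unit",
                  "Description", "Provenance", "Profile")

#' Write a schema to disk
#'
#' @param schema A `mit_schema`.
#' @param path Output file path.
#' @param dialect One of `"csv"` (canonical), `"json"`, `"xml"`.
#' @return `path`, invisibly.
#' @seealso [read_schema()]
#' @export
write_schema <- function(schema, path, dialect = c("csv", "json", "xml")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(schema, "mit_schema"))
  switch(dialect,
         csv  = .write_schema_csv(schema, path),
         json = .write_schema_json(schema, path),
         xml  = .write_schema_xml(schema, path))
  invisible(path)
}

#' Read a schema from disk
#'
#' Parses and validates a schema file in any supported dialect. Structural
#' violations (duplicate field ids, unknown enum values) raise integrity
#' errors; unparseable files raise parse errors naming the offending
#' content.
#'
#' @param path Input file path.
#' @param dialect One of `"csv"`, `"json"`, `"xml"`.
#' @return A validated `mit_schema`.
#' @export
read_schema <- function(path, dialect = c("csv", "json", "xml")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(dialect,
         csv  = .read_schema_csv(path),
         json = .read_schema_json(path),
         xml  = .read_schema_xml(path))
}

.write_schema_csv <- function(schema, path) {
  f <- schema$fields
  out <- data.frame(
    Module = f$module_id, Subdivision = f$subdivision,
    Category = f$category, Name = f$name, Synonyms = f$synonyms,
    Applicability = f$applicability, Requirement = f$requirement,
    ValueKind = f$value_kind, Unit = f$unit, Description = f$description,
    Provenance = f$provenance, Profile = f$profile,
    stringsAsFactors = FALSE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  header <- c(paste0("#schema_id: ", schema$schema_id),
              paste0("#version: ", schema$version),
              paste0("#profiles: ", paste(schema$profile_tags,
                                          collapse = "|")))
  writeLines(header, con, sep = "\n")
  utils::write.table(out, con, sep = ",", qmethod = "double",
                     row.names = FALSE, col.names = TRUE, eol = "\n",
                     na = "")
}

.read_schema_csv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  meta <- grep("^#", lines, value = TRUE)
  get_meta <- function(key) {
    hit <- grep(paste0("^#", key, ": ?"), meta, value = TRUE)
    if (length(hit) == 0) return("")
    sub(paste0("^#", key, ": ?"), "", hit[1])
  }
  body <- lines[!grepl("^#", lines)]
  df <- tryCatch(
    utils::read.csv(text = paste(body, collapse = "\n"),
                    stringsAsFactors = FALSE, colClasses = "character"),
    error = function(e) stop("parse error in ", path, ": ",
                             conditionMessage(e)))
  if (nrow(df) > 0 && !all(.csv_columns %in% names(df))) {
    stop("parse error in ", path, ": missing columns ",
         paste(setdiff(.csv_columns, names(df)), collapse = ", "))
  }
  profiles <- get_meta("profiles")
  profiles <- if (profiles == "") character() else
    strsplit(profiles, "|", fixed = TRUE)[[1]]
  fields <- data.frame(
    name = df$Name, category = df$Category, module_id = df$Module,
    subdivision = df$Subdivision, synonyms = df$Synonyms,
    applicability = df$Applicability, requirement = df$Requirement,
    value_kind = df$ValueKind, unit = df$Unit, description = df$Description,
    provenance = df$Provenance, profile = df$Profile,
    stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    fields <- fields[0, , drop = FALSE]
  }
  mit_schema(fields,
             schema_id = get_meta("schema_id"),
             version = get_meta("version"),
             profile_tags = profiles)
}

.write_schema_json <- function(schema, path) {
  f <- schema$fields
  mods <- unique(f$module_id)
  mods <- c(intersect(mit_modules(), mods), setdiff(mods, mit_modules()))
  module_list <- lapply(mods, function(m) {
    rows <- f[f$module_id == m, , drop = FALSE]
    list(module_id = m,
         fields = lapply(seq_len(nrow(rows)), function(i) {
           as.list(rows[i, setdiff(.field_columns, "module_id")])
         }))
  })
  doc <- list(schema_id = schema$schema_id, version = schema$version,
              profile_tags = as.list(schema$profile_tags),
              modules = module_list)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
}

.read_schema_json <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("parse error in ", path, ": ",
                                           conditionMessage(e)))
  rows <- list()
  for (mod in doc$modules) {
    for (fl in mod$fields) {
      fl$module_id <- mod$module_id
      rows[[length(rows) + 1L]] <- fl
    }
  }
  fields <- if (length(rows) == 0) {
    data.frame(name = character(), category = character(),
               module_id = character(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, lapply(rows, function(r) {
      as.data.frame(r[.field_columns], stringsAsFactors = FALSE)
    }))
  }
  mit_schema(fields, schema_id = doc$schema_id %||% "",
             version = doc$version %||% "",
             profile_tags = unlist(doc$profile_tags) %||% character())
}

.write_schema_xml <- function(schema, path) {
  doc <- xml2::xml_new_root("schema", id = schema$schema_id,
                            version = schema$version,
                            profiles = paste(schema$profile_tags,
                                             collapse = "|"))
  f <- schema$fields
  mods <- unique(f$module_id)
  mods <- c(intersect(mit_modules(), mods), setdiff(mods, mit_modules()))
  for (m in mods) {
    mnode <- xml2::xml_add_child(doc, "module", id = m)
    rows <- f[f$module_id == m, , drop = FALSE]
    for (i in seq_len(nrow(rows))) {
      xml2::xml_add_child(
        mnode, "field",
        field_id = rows$field_id[i], name = rows$name[i],
        category = rows$category[i], subdivision = rows$subdivision[i],
        synonyms = rows$synonyms[i], applicability = rows$applicability[i],
        requirement = rows$requirement[i], value_kind = rows$value_kind[i],
        unit = rows$unit[i], description = rows$description[i],
        provenance = rows$provenance[i], profile = rows$profile[i])
    }
  }
  xml2::write_xml(doc, path)
}

.read_schema_xml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("parse error in ", path, ": ",
                                           conditionMessage(e)))
  root_attr <- function(a) {
    v <- xml2::xml_attr(doc, a)
    if (is.na(v)) "" else v
  }
  rows <- list()
  for (mnode in xml2::xml_find_all(doc, "./module")) {
    m <- xml2::xml_attr(mnode, "id")
    for (fnode in xml2::xml_find_all(mnode, "./field")) {
      attr_of <- function(a) {
        v <- xml2::xml_attr(fnode, a)
        if (is.na(v)) "" else v
      }
      rows[[length(rows) + 1L]] <- data.frame(
        field_id = attr_of("field_id"), name = attr_of("name"),
        category = attr_of("category"), module_id = m,
        subdivision = attr_of("subdivision"),
        synonyms = attr_of("synonyms"),
        applicability = attr_of("applicability"),
        requirement = attr_of("requirement"),
        value_kind = attr_of("value_kind"), unit = attr_of("unit"),
        description = attr_of("description"),
        provenance = attr_of("provenance"), profile = attr_of("profile"),
        stringsAsFactors = FALSE)
    }
  }
  fields <- if (length(rows) == 0) {
    data.frame(name = character(), category = character(),
               module_id = character(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
  profiles <- root_attr("profiles")
  profiles <- if (profiles == "") character() else
    strsplit(profiles, "|", fixed = TRUE)[[1]]
  mit_schema(fields, schema_id = root_attr("id"),
             version = root_attr("version"), profile_tags = profiles)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
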