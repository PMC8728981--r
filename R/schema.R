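# Core schema container: a modular minimum-information table (MIT) of
# labeled fields. A labeled field is either "grouping" (a structural
# header) or "content_bearing" (holds a value in a metadata record).

#' Canonical module identifiers of the reference schema
#'
#' The six modules of the reference minimum-information table, in canonical
#' order: general information, material information, biological model
#' information, exposure information, endpoint read out information, and
#' analysis and statistics.
#'
#' @return Character vector of the six module ids.
#' @export
mit_modules <- function() {
  c("general_information", "material_information",
    "biological_model_information", "exposure_information",
    "endpoint_readout_information", "analysis_statistics")
}

.module_display_names <- c(
  general_information          = "General Information",
  material_information         = "Material Information",
  biological_model_information = "Biological Model Information",
  exposure_information         = "Exposure Information",
  endpoint_readout_information = "Endpoint Read Out Information",
  analysis_statistics          = "Analysis and Statistics"
)

.categories     <- c("grouping", "content_bearing")
.applicability  <- c("always", "in_vitro_only", "in_vivo_only")
.requirements   <- c("minimum", "recommended", "optional")
.value_kinds    <- c("free_text", "quantity_with_unit", "controlled_term",
                     "identifier", "boolean")

.field_columns <- c("field_id", "name", "category", "module_id",
                    "subdivision", "synonyms", "applicability",
                    "requirement", "value_kind", "unit", "description",
                    "provenance", "profile")

#' Turn a label into a stable snake-case slug
#'
#' Lowercases, strips punctuation, and joins tokens with underscores.
#' Used to derive `field_id` values from field names.
#'
#' @param x Character vector of labels.
#' @return Character vector of slugs.
#' @export
#' @examples
#' slugify("Zeta potential")   # "zeta_potential"
slugify <- function(x) {
  x <- tolower(x)
  x <- gsub("[^a-z0-9]+", "_", x)
  gsub("^_+|_+$", "", x)
}

#' Construct a schema object
#'
#' Builds a `mit_schema` from a data frame of labeled fields (one row per
#' field) and checks all structural invariants: unique field ids, known
#' enum values, synonyms distinct from the primary name, and grouping
#' fields carrying no value-kind constraint.
#'
#' @param fields Data frame with columns `name`, `category`, `module_id`,
#'   and optionally `subdivision`, `synonyms` (pipe-separated),
#'   `applicability`, `requirement`, `value_kind`, `unit`, `description`,
#'   `provenance`, `profile`, `field_id`. Missing optional columns are
#'   filled with defaults (`applicability = "always"`,
#'   `requirement = "minimum"`, `value_kind = "free_text"`). `field_id`
#'   defaults to the slug of `name`, module-prefixed on collision.
#' @param schema_id Schema identifier string.
#' @param version Schema version string.
#' @param profile_tags Character vector of applied extension-profile ids.
#' @return An object of class `mit_schema`.
#' @export
mit_schema <- function(fields, schema_id = "schema", version = "1.0",
                       profile_tags = character()) {
  stopifnot(is.data.frame(fields))
  if (nrow(fields) > 0 && !all(c("name", "category", "module_id") %in%
                               names(fields))) {
    stop("fields must have columns name, category, module_id")
  }
  defaults <- list(subdivision = "", synonyms = "", applicability = "always",
                   requirement = "minimum", value_kind = "free_text",
                   unit = "", description = "", provenance = "",
                   profile = "")
  for (col in names(defaults)) {
    if (!col %in% names(fields)) fields[[col]] <- rep(defaults[[col]],
                                                      nrow(fields))
  }
  if (!"field_id" %in% names(fields)) {
    ids <- slugify(fields$name)
    dup <- duplicated(ids) | duplicated(ids, fromLast = TRUE)
    ids[dup] <- paste(slugify(fields$module_id[dup]), ids[dup], sep = "__")
    fields$field_id <- ids
  }
  fields <- fields[, .field_columns, drop = FALSE]
  for (col in .field_columns) {
    fields[[col]] <- as.character(fields[[col]])
    fields[[col]][is.na(fields[[col]])] <- ""
  }
  # canonical row order: stable sort by module so every serialization
  # dialect lists fields identically
  mods <- unique(fields$module_id)
  mods <- c(intersect(mit_modules(), mods), setdiff(mods, mit_modules()))
  fields <- fields[order(match(fields$module_id, mods)), , drop = FALSE]
  rownames(fields) <- NULL
  obj <- structure(
    list(schema_id = as.character(schema_id),
         version = as.character(version),
         profile_tags = as.character(profile_tags),
         fields = fields),
    class = "mit_schema")
  validate_mit_schema(obj)
  obj
}

#' Validate a schema's structural invariants
#'
#' Errors with an informative message if any invariant is violated:
#' duplicate field ids, unknown enum values, a grouping field carrying a
#' unit hint, or a synonym duplicating the primary name after
#' normalization.
#'
#' @param schema A `mit_schema`.
#' @return The schema, invisibly.
#' @export
validate_mit_schema <- function(schema) {
  f <- schema$fields
  if (nrow(f) == 0) return(invisible(schema))
  dup <- f$field_id[duplicated(f$field_id)]
  if (length(dup) > 0) {
    stop("integrity error: duplicate field_id: ",
         paste(unique(dup), collapse = ", "))
  }
  bad <- setdiff(f$category, .categories)
  if (length(bad) > 0) stop("integrity error: unknown category: ",
                            paste(bad, collapse = ", "))
  bad <- setdiff(f$applicability, .applicability)
  if (length(bad) > 0) stop("integrity error: unknown applicability: ",
                            paste(bad, collapse = ", "))
  bad <- setdiff(f$requirement, .requirements)
  if (length(bad) > 0) stop("integrity error: unknown requirement: ",
                            paste(bad, collapse = ", "))
  cb <- f$category == "content_bearing"
  bad <- setdiff(f$value_kind[cb], .value_kinds)
  if (length(bad) > 0) stop("integrity error: unknown value_kind: ",
                            paste(bad, collapse = ", "))
  # grouping fields structure, they do not store: no value constraint
  if (any(f$category == "grouping" & f$unit != "")) {
    stop("integrity error: grouping field with unit hint")
  }
  for (i in which(f$synonyms != "")) {
    syn <- split_synonyms(f$synonyms[i])
    if (normalize_join(f$name[i]) %in% vapply(syn, normalize_join,
                                              character(1))) {
      stop("integrity error: synonym duplicates primary name for field ",
           f$field_id[i])
    }
  }
  invisible(schema)
}

split_synonyms <- function(x) {
  if (is.na(x) || x == "") return(character())
  trimws(strsplit(x, "|", fixed = TRUE)[[1]])
}

#' @export
print.mit_schema <- function(x, ...) {
  st <- schema_stats(x)
  cat("Minimum-information schema <", x$schema_id, "> version ",
      x$version, "\n", sep = "")
  if (length(x$profile_tags) > 0) {
    cat("  profiles applied:", paste(x$profile_tags, collapse = ", "), "\n")
  }
  cat("  modules: ", st$n_modules, "; grouping fields: ", st$grouping,
      "; content-bearing fields: ", st$content_bearing,
      "; total: ", st$total, "\n", sep = "")
  invisible(x)
}

#' Count labeled fields in a schema
#'
#' Tallies grouping and content-bearing labeled fields overall and
#' content-bearing fields per module.
#'
#' @param schema A `mit_schema`.
#' @return An object of class `mit_schema_stats`: a list with `n_modules`,
#'   `grouping`, `content_bearing`, `total`, and `per_module` (named
#'   integer vector of content-bearing counts in module order).
#' @export
#' @examples
#' schema_stats(build_reference_mit())
schema_stats <- function(schema) {
  stopifnot(inherits(schema, "mit_schema"))
  f <- schema$fields
  mods <- unique(f$module_id)
  mods <- c(intersect(mit_modules(), mods), setdiff(mods, mit_modules()))
  cb <- f[f$category == "content_bearing", , drop = FALSE]
  per_module <- vapply(mods, function(m) sum(cb$module_id == m), integer(1))
  structure(list(
    n_modules = length(mods),
    grouping = sum(f$category == "grouping"),
    content_bearing = nrow(cb),
    total = nrow(f),
    per_module = per_module
  ), class = "mit_schema_stats")
}

#' @export
print.mit_schema_stats <- function(x, ...) {
  cat("Labeled fields: ", x$total, " (", x$grouping, " grouping, ",
      x$content_bearing, " content-bearing) in ", x$n_modules,
      " modules\n", sep = "")
  if (length(x$per_module) > 0) {
    cat("Content-bearing per module:\n")
    for (m in names(x$per_module)) {
      cat(sprintf("  %-30s %d\n", m, x$per_module[[m]]))
    }
  }
  invisible(x)
}

#' Define an extension profile
#'
#' An extension profile adds model-specific labeled fields (and optionally
#' tightens or relaxes requirement levels of existing fields) on top of a
#' base schema, as needed by new approach methodologies such as air-liquid
#' interface, advanced intestinal, or 3D skin models.
#'
#' @param profile_id Profile slug.
#' @param added_fields Data frame of new fields in the same layout accepted
#'   by [mit_schema()].
#' @param modified_requirements Optional data frame with columns `field_id`
#'   and `requirement` overriding requirement levels of base-schema fields.
#' @return An object of class `mit_profile`.
#' @export
mit_profile <- function(profile_id, added_fields,
                        modified_requirements = NULL) {
  stopifnot(is.character(profile_id), length(profile_id) == 1L)
  structure(list(profile_id = profile_id,
                 added_fields = added_fields,
                 modified_requirements = modified_requirements),
            class = "mit_profile")
}

#' Merge an extension profile into a schema
#'
#' Appends the profile's fields (tagged with the profile id) to the schema
#' and applies any requirement modifications. Field-id collisions with the
#' base schema are an integrity error, so merging the same profile twice
#' fails.
#'
#' @param schema A `mit_schema`.
#' @param profile A `mit_profile`, or one of the bundled profile ids
#'   `"ali"`, `"intestine_advanced"`, `"skin_3d"` (see [nam_profile()]).
#' @return A new `mit_schema` containing base plus profile fields.
#' @export
#' @examples
#' ali <- merge_profile(build_reference_mit(), "ali")
#' schema_stats(ali)$total > 333
merge_profile <- function(schema, profile) {
  stopifnot(inherits(schema, "mit_schema"))
  if (is.character(profile)) profile <- nam_profile(profile)
  stopifnot(inherits(profile, "mit_profile"))
  added <- profile$added_fields
  tmp <- mit_schema(added, schema_id = profile$profile_id)
  added <- tmp$fields
  added$profile <- rep(profile$profile_id, nrow(added))
  clash <- intersect(added$field_id, schema$fields$field_id)
  if (length(clash) > 0) {
    stop("integrity error: profile field_id collides with schema: ",
         paste(clash, collapse = ", "))
  }
  fields <- rbind(schema$fields, added)
  mods <- profile$modified_requirements
  if (!is.null(mods) && nrow(mods) > 0) {
    unknown <- setdiff(mods$field_id, fields$field_id)
    if (length(unknown) > 0) {
      stop("integrity error: requirement override for unknown field_id: ",
           paste(unknown, collapse = ", "))
    }
    idx <- match(mods$field_id, fields$field_id)
    fields$requirement[idx] <- as.character(mods$requirement)
  }
  mit_schema(fields, schema_id = schema$schema_id, version = schema$version,
             profile_tags = c(schema$profile_tags, profile$profile_id))
}

#' Content-bearing fields of a schema
#'
#' @param schema A `mit_schema`.
#' @return Data frame of the content-bearing field rows.
#' @export
content_fields <- function(schema) {
  schema$fields[schema$fields$category == "content_bearing", , drop = FALSE]
}
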