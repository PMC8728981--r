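# Compatibility statistics over a crosswalk: matched/total counts and
# integer percentages per module (content-bearing fields), per field
# category, and overall, in one-to-one mode (exact matches only) or
# partial mode (exact plus partial). Percent values are rounded half-up,
# the only rule consistent with every printed pair in the compatibility
# analyses this engine reproduces (e.g. 55/333 = 16.52 -> 17 and
# 11/31 = 35.48 -> 35).

#' Round-half-up integer percent
#'
#' @param matched,total Non-negative counts.
#' @return Integer percent; 0 when `total` is 0.
#' @export
#' @examples
#' percent_half_up(55, 333)  # 17
#' percent_half_up(11, 31)   # 35
percent_half_up <- function(matched, total) {
  ifelse(total == 0, 0L, as.integer(floor(100 * matched / total + 0.5)))
}

#' Coverage report over a crosswalk
#'
#' Computes matched/total counts and integer percentages for every
#' stratum: each module's content-bearing fields, the grouping and
#' content-bearing field categories, and the overall field set. In
#' `one_to_one` mode only exact decisions count as matched; in `partial`
#' mode exact and partial both count.
#'
#' @param crosswalk A `mit_crosswalk`.
#' @param mode `"one_to_one"` or `"partial"`.
#' @return An object of class `mit_coverage`: a data frame of rows
#'   (`stratum`, `stratum_type`, `matched`, `total`, `percent`,
#'   `empty_stratum`) with the mode and crosswalk provenance attached.
#' @export
coverage_report <- function(crosswalk, mode = c("one_to_one", "partial")) {
  mode <- match.arg(mode)
  stopifnot(inherits(crosswalk, "mit_crosswalk"))
  d <- crosswalk$decisions
  sf <- crosswalk$schema_fields
  stopifnot(identical(d$field_id, sf$field_id))
  matched_types <- if (mode == "one_to_one") "exact" else
    c("exact", "partial")
  is_matched <- d$match_type %in% matched_types
  cb <- sf$category == "content_bearing"
  mods <- unique(sf$module_id)
  mods <- c(intersect(mit_modules(), mods), setdiff(mods, mit_modules()))
  row_of <- function(stratum, type, sel) {
    data.frame(stratum = stratum, stratum_type = type,
               matched = sum(is_matched & sel), total = sum(sel),
               stringsAsFactors = FALSE)
  }
  rows <- do.call(rbind, c(
    lapply(mods, function(m) row_of(m, "module", cb & sf$module_id == m)),
    list(row_of("grouping", "category", !cb),
         row_of("content_bearing", "category", cb),
         row_of("overall", "overall", rep(TRUE, nrow(sf))))))
  rows$percent <- percent_half_up(rows$matched, rows$total)
  rows$empty_stratum <- rows$total == 0
  structure(list(mode = mode, rows = rows,
                 schema_id = crosswalk$schema_id,
                 vocab_id = crosswalk$vocab_id),
            class = "mit_coverage")
}

#' @export
print.mit_coverage <- function(x, ...) {
  cat("Coverage report (", x$mode, " mode), <", x$schema_id, "> -> <",
      x$vocab_id, ">\n", sep = "")
  r <- x$rows
  for (i in seq_len(nrow(r))) {
    cat(sprintf("  %-30s %3d%% (%d of %d)%s\n", r$stratum[i],
                r$percent[i], r$matched[i], r$total[i],
                if (r$empty_stratum[i]) "  [empty stratum]" else ""))
  }
  invisible(x)
}

#' Build a deterministic crosswalk realizing requested per-stratum counts
#'
#' Test and worked-example harness: constructs a crosswalk over `schema`
#' whose coverage report reproduces the requested exact and partial
#' decision counts per stratum exactly. Fields are filled in schema order
#' (first the exact decisions, then the partial, the rest none) against
#' synthetic term ids.
#'
#' @param schema A `mit_schema`.
#' @param counts Data frame with columns `stratum` (a module id or
#'   `"grouping"`), `exact` and (optionally) `partial` counts. Modules
#'   refer to their content-bearing fields; `"grouping"` to all grouping
#'   fields.
#' @param vocab_id Identifier recorded as the synthetic target.
#' @return A `mit_crosswalk`.
#' @export
#' @examples
#' sch <- build_reference_mit()
#' cw <- crosswalk_from_counts(sch,
#'   data.frame(stratum = "general_information", exact = 14))
#' coverage_report(cw, "one_to_one")
crosswalk_from_counts <- function(schema, counts,
                                  vocab_id = "count-fixture") {
  stopifnot(inherits(schema, "mit_schema"), is.data.frame(counts))
  if (!"partial" %in% names(counts)) counts$partial <- 0L
  counts$exact <- as.integer(counts$exact)
  counts$partial <- as.integer(counts$partial)
  f <- schema$fields
  decisions <- .decision(f$field_id)
  decisions$method <- "auto"
  for (i in seq_len(nrow(counts))) {
    s <- counts$stratum[i]
    sel <- if (s == "grouping") {
      which(f$category == "grouping")
    } else {
      which(f$category == "content_bearing" & f$module_id == s)
    }
    need <- counts$exact[i] + counts$partial[i]
    if (counts$exact[i] < 0 || counts$partial[i] < 0 ||
        need > length(sel)) {
      stop("bounds error: requested ", need, " matches in stratum '", s,
           "' of size ", length(sel))
    }
    ex <- sel[seq_len(counts$exact[i])]
    pa <- sel[counts$exact[i] + seq_len(counts$partial[i])]
    decisions$match_type[ex] <- "exact"
    decisions$score[ex] <- 1
    decisions$term_id[ex] <- paste0("T_", f$field_id[ex])
    decisions$match_type[pa] <- "partial"
    decisions$score[pa] <- 0.5
    decisions$term_id[pa] <- paste0("T_", f$field_id[pa])
  }
  structure(list(schema_id = schema$schema_id, vocab_id = vocab_id,
                 schema_fields = f[, c("field_id", "category",
                                       "module_id")],
                 decisions = decisions),
            class = "mit_crosswalk")
}

#' Compare two coverage reports stratum by stratum
#'
#' @param a,b `mit_coverage` reports over the same schema strata.
#' @return Data frame with `stratum`, the two percent columns and
#'   `delta_percent` = b - a.
#' @export
compare_reports <- function(a, b) {
  stopifnot(inherits(a, "mit_coverage"), inherits(b, "mit_coverage"))
  if (!identical(a$rows$stratum, b$rows$stratum)) {
    stop("comparability error: reports cover different strata")
  }
  data.frame(stratum = a$rows$stratum,
             percent_a = a$rows$percent,
             percent_b = b$rows$percent,
             delta_percent = b$rows$percent - a$rows$percent,
             stringsAsFactors = FALSE)
}

#' Render a coverage report as a plain data frame or write it to disk
#'
#' @param report A `mit_coverage`.
#' @param path Optional output path; `.json` writes JSON, anything else
#'   TSV.
#' @return The report rows as a data frame (invisibly when writing).
#' @export
coverage_table <- function(report, path = NULL) {
  stopifnot(inherits(report, "mit_coverage"))
  out <- report$rows
  if (is.null(path)) return(out)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(mode = report$mode, rows = out), path,
                         auto_unbox = TRUE, pretty = TRUE)
  } else {
    utils::write.table(out, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(out)
}
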