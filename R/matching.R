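# Crosswalk construction against flat target vocabularies, following the
# source-to-target principle: every labeled field of the source schema
# receives exactly one match decision (exact / partial / none) against the
# target vocabulary. Exact matching compares normalized labels and
# synonyms; partial matching fires when one token set is a proper subset
# of the other, scored by Jaccard similarity. Curated decisions loaded
# from annotation files dominate both.

#' Normalize a label into a token sequence
#'
#' Case-folds, strips punctuation, collapses whitespace and splits on
#' spaces. Deterministic and idempotent under re-joining.
#'
#' @param label Character scalar.
#' @return Character vector of tokens (possibly empty).
#' @export
#' @examples
#' normalize_label("Zeta potential")  # c("zeta", "potential")
normalize_label <- function(label) {
  if (length(label) == 0 || is.na(label)) return(character())
  x <- tolower(label)
  x <- gsub("[^a-z0-9]+", " ", x)
  x <- trimws(gsub(" +", " ", x))
  if (x == "") return(character())
  strsplit(x, " ", fixed = TRUE)[[1]]
}

normalize_join <- function(label) {
  paste(normalize_label(label), collapse = " ")
}

# all normalized token sets for a field or term: primary name + synonyms
.label_variants <- function(name, synonyms) {
  labs <- c(name, split_synonyms(synonyms))
  labs <- labs[labs != ""]
  lapply(labs, normalize_label)
}

.jaccard <- function(a, b) {
  u <- union(a, b)
  if (length(u) == 0) return(0)
  length(intersect(a, b)) / length(u)
}

#' Construct a target vocabulary
#'
#' A flat term table standing in for an external standard or ontology:
#' one row per term with `term_id`, `label`, `synonyms` (pipe-separated)
#' and optional `parent_id`. Parent links must resolve within the
#' vocabulary and be acyclic.
#'
#' @param terms Data frame with columns `term_id`, `label` and optionally
#'   `synonyms`, `parent_id`.
#' @param vocab_id Vocabulary identifier.
#' @param name Display name.
#' @return An object of class `mit_vocabulary`.
#' @export
mit_vocabulary <- function(terms, vocab_id = "vocab", name = vocab_id) {
  stopifnot(is.data.frame(terms))
  if (nrow(terms) > 0) stopifnot(all(c("term_id", "label") %in%
                                     names(terms)))
  for (col in c("term_id", "label", "synonyms", "parent_id")) {
    if (!col %in% names(terms)) terms[[col]] <- rep("", nrow(terms))
    terms[[col]] <- as.character(terms[[col]])
    terms[[col]][is.na(terms[[col]])] <- ""
  }
  terms <- terms[, c("term_id", "label", "synonyms", "parent_id"),
                 drop = FALSE]
  rownames(terms) <- NULL
  if (anyDuplicated(terms$term_id)) {
    stop("integrity error: duplicate term_id")
  }
  has_parent <- terms$parent_id != ""
  if (any(has_parent & !(terms$parent_id %in% terms$term_id))) {
    stop("integrity error: parent_id does not resolve")
  }
  # acyclicity: follow parents; a cycle revisits a node
  parent <- stats::setNames(terms$parent_id, terms$term_id)
  for (t in terms$term_id) {
    seen <- character()
    cur <- t
    while (cur != "" && !is.na(parent[cur])) {
      if (cur %in% seen) stop("integrity error: cyclic parent links at ",
                              cur)
      seen <- c(seen, cur)
      cur <- parent[[cur]]
      if (cur == "") break
    }
  }
  structure(list(vocab_id = vocab_id, name = name, terms = terms),
            class = "mit_vocabulary")
}

#' @export
print.mit_vocabulary <- function(x, ...) {
  cat("Target vocabulary <", x$vocab_id, ">: ", nrow(x$terms),
      " terms\n", sep = "")
  invisible(x)
}

#' Read / write a vocabulary as TSV
#'
#' Columns: `term_id`, `label`, `synonyms` (pipe-separated), `parent_id`.
#' Users are expected to flatten richer ontology formats to this table.
#'
#' @param path File path.
#' @param vocab_id,name Passed to [mit_vocabulary()] on read.
#' @return `read_vocabulary` returns a `mit_vocabulary`; `write_vocabulary`
#'   returns `path` invisibly.
#' @export
read_vocabulary <- function(path, vocab_id = "vocab", name = vocab_id) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  mit_vocabulary(df, vocab_id = vocab_id, name = name)
}

#' @rdname read_vocabulary
#' @param vocab A `mit_vocabulary`.
#' @export
write_vocabulary <- function(vocab, path) {
  stopifnot(inherits(vocab, "mit_vocabulary"))
  utils::write.table(vocab$terms, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

.decision <- function(field_id, term_id = "", match_type = "none",
                      method = "auto", score = 0) {
  data.frame(field_id = field_id, term_id = term_id,
             match_type = match_type, method = method, score = score,
             stringsAsFactors = FALSE)
}

#' One-to-one (exact) match of a field against a vocabulary
#'
#' A field matches exactly when its normalized name, or any of its
#' synonyms, equals a term's normalized label or any term synonym. Ties
#' are broken by the lexicographically lowest `term_id`. Exact matches
#' score 1; otherwise the decision is `none` with score 0.
#'
#' @param field One-row data frame of a schema field (a row of
#'   `schema$fields`), or a list with `field_id`, `name`, `synonyms`.
#' @param vocab A `mit_vocabulary`.
#' @return A one-row match-decision data frame with columns `field_id`,
#'   `term_id`, `match_type`, `method`, `score`.
#' @export
match_exact <- function(field, vocab) {
  stopifnot(inherits(vocab, "mit_vocabulary"))
  fvar <- vapply(.label_variants(field$name, field$synonyms),
                 paste, character(1), collapse = " ")
  terms <- vocab$terms
  hits <- character()
  for (i in seq_len(nrow(terms))) {
    tvar <- vapply(.label_variants(terms$label[i], terms$synonyms[i]),
                   paste, character(1), collapse = " ")
    if (any(fvar %in% tvar)) hits <- c(hits, terms$term_id[i])
  }
  if (length(hits) == 0) return(.decision(field$field_id))
  .decision(field$field_id, term_id = sort(hits)[1],
            match_type = "exact", score = 1)
}

#' Partial match of a field against a vocabulary
#'
#' A term is a partial-match candidate when one normalized token set (of
#' the field's name/synonyms vs the term's label/synonyms) is a non-empty
#' proper subset of the other, capturing more generally labeled targets
#' (e.g. source "dispersion protocol" against target "protocol"). The
#' score is the Jaccard similarity of the token sets; the best-scoring
#' term wins, ties broken by lowest `term_id`; decisions below
#' `min_score` become `none`. Identical labels are the province of
#' [match_exact()] and are never returned as partial.
#'
#' @inheritParams match_exact
#' @param min_score Minimum Jaccard score in (0, 1] to accept a partial
#'   match (default 0.25).
#' @return A one-row match-decision data frame.
#' @export
match_partial <- function(field, vocab, min_score = 0.25) {
  stopifnot(inherits(vocab, "mit_vocabulary"),
            min_score > 0, min_score <= 1)
  fsets <- .label_variants(field$name, field$synonyms)
  terms <- vocab$terms
  best_score <- 0
  best_id <- ""
  for (i in seq_len(nrow(terms))) {
    tsets <- .label_variants(terms$label[i], terms$synonyms[i])
    for (fs in fsets) {
      for (ts in tsets) {
        if (length(fs) == 0 || length(ts) == 0) next
        proper_subset <-
          (all(fs %in% ts) || all(ts %in% fs)) &&
          !setequal(fs, ts)
        if (!proper_subset) next
        sc <- .jaccard(fs, ts)
        if (sc > best_score ||
            (sc == best_score && best_id != "" &&
             terms$term_id[i] < best_id)) {
          best_score <- sc
          best_id <- terms$term_id[i]
        }
      }
    }
  }
  if (best_id == "" || best_score < min_score) {
    return(.decision(field$field_id))
  }
  .decision(field$field_id, term_id = best_id, match_type = "partial",
            score = best_score)
}

#' Build a total crosswalk from a schema to a vocabulary
#'
#' Produces exactly one match decision per labeled field (grouping and
#' content-bearing alike), with precedence curated > exact > partial >
#' none. The result is deterministic: tie-breaks are lexicographic and no
#' randomness is involved.
#'
#' @param schema A `mit_schema`.
#' @param vocab A `mit_vocabulary`.
#' @param curated Optional data frame of curated decisions with columns
#'   `field_id`, `term_id`, `match_type` (and optionally `score`); these
#'   override automatic decisions. A curated `match_type` of `"none"`
#'   suppresses any automatic match.
#' @param min_score Passed to [match_partial()].
#' @return An object of class `mit_crosswalk`: the decision table plus
#'   schema/vocabulary references.
#' @export
#' @examples
#' sch <- build_reference_mit()
#' voc <- mit_vocabulary(data.frame(term_id = "T1", label = "protocol"))
#' cw <- auto_crosswalk(sch, voc)
#' nrow(cw$decisions) == schema_stats(sch)$total
auto_crosswalk <- function(schema, vocab, curated = NULL,
                           min_score = 0.25) {
  stopifnot(inherits(schema, "mit_schema"),
            inherits(vocab, "mit_vocabulary"))
  f <- schema$fields
  if (!is.null(curated) && nrow(curated) > 0) {
    unknown <- setdiff(curated$field_id, f$field_id)
    if (length(unknown) > 0) {
      stop("integrity error: curated decision for unknown field_id: ",
           paste(unknown, collapse = ", "))
    }
    if (anyDuplicated(curated$field_id)) {
      stop("integrity error: duplicate curated decisions")
    }
  }
  decisions <- vector("list", nrow(f))
  for (i in seq_len(nrow(f))) {
    fid <- f$field_id[i]
    cur <- if (!is.null(curated)) curated[curated$field_id == fid, ,
                                          drop = FALSE] else NULL
    if (!is.null(cur) && nrow(cur) == 1) {
      mt <- cur$match_type[1]
      sc <- if ("score" %in% names(cur) && !is.na(cur$score[1])) {
        as.numeric(cur$score[1])
      } else if (mt == "exact") 1 else if (mt == "none") 0 else 0.5
      tid <- if (mt == "none") "" else as.character(cur$term_id[1])
      decisions[[i]] <- .decision(fid, term_id = tid, match_type = mt,
                                  method = "curated",
                                  score = if (mt == "none") 0 else sc)
      next
    }
    d <- match_exact(f[i, ], vocab)
    if (d$match_type == "none") {
      d <- match_partial(f[i, ], vocab, min_score = min_score)
    }
    decisions[[i]] <- d
  }
  structure(list(schema_id = schema$schema_id,
                 vocab_id = vocab$vocab_id,
                 schema_fields = f[, c("field_id", "category",
                                       "module_id")],
                 decisions = do.call(rbind, decisions)),
            class = "mit_crosswalk")
}

#' @export
print.mit_crosswalk <- function(x, ...) {
  tab <- table(factor(x$decisions$match_type,
                      levels = c("exact", "partial", "none")))
  cat("Crosswalk <", x$schema_id, "> -> <", x$vocab_id, ">: ",
      nrow(x$decisions), " decisions (", tab[["exact"]], " exact, ",
      tab[["partial"]], " partial, ", tab[["none"]], " none)\n",
      sep = "")
  invisible(x)
}

#' Read / write a crosswalk decision table as TSV
#'
#' Columns: `field_id`, `term_id`, `match_type`, `method`, `score`.
#' `read_curated` reads a curated annotation file (columns `field_id`,
#' `term_id`, `match_type`, optional `note`) for use as the `curated`
#' argument of [auto_crosswalk()].
#'
#' @param crosswalk A `mit_crosswalk`.
#' @param path File path.
#' @export
write_crosswalk <- function(crosswalk, path) {
  stopifnot(inherits(crosswalk, "mit_crosswalk"))
  utils::write.table(crosswalk$decisions, path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_crosswalk
#' @param schema The `mit_schema` the crosswalk was built over (restores
#'   the per-field category/module bookkeeping).
#' @param vocab_id Vocabulary identifier to record.
#' @export
read_crosswalk <- function(path, schema, vocab_id = "vocab") {
  if (!file.exists(path)) stop("file not found: ", path)
  stopifnot(inherits(schema, "mit_schema"))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$field_id <- as.character(df$field_id)
  df$term_id <- as.character(df$term_id)
  df$term_id[is.na(df$term_id)] <- ""
  df$score <- as.numeric(df$score)
  if (!setequal(df$field_id, schema$fields$field_id) ||
      nrow(df) != nrow(schema$fields)) {
    stop("integrity error: crosswalk is not total over the schema")
  }
  df <- df[match(schema$fields$field_id, df$field_id), , drop = FALSE]
  rownames(df) <- NULL
  structure(list(schema_id = schema$schema_id, vocab_id = vocab_id,
                 schema_fields = schema$fields[, c("field_id", "category",
                                                   "module_id")],
                 decisions = df),
            class = "mit_crosswalk")
}

#' @rdname write_crosswalk
#' @export
read_curated <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$field_id <- as.character(df$field_id)
  df$term_id <- as.character(df$term_id)
  df$term_id[is.na(df$term_id)] <- ""
  df
}
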