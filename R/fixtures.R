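# Synthetic fixture generators with planted ground truth. The vocabulary
# generator plants, per schema field, an exact copy of its label, a
# one-token perturbation that fires the token-subset partial rule, or a
# fresh label over a disjoint token alphabet (so "none" plants cannot
# match accidentally); it returns the planted truth alongside, and its
# construction guarantees that auto_crosswalk recovers the plant exactly.

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# proper-subset Jaccard relation between any label variants of two fields;
# conservative interference predicate for the plant repair below
.fields_related <- function(sets_i, sets_j, min_score) {
  for (a in sets_i) {
    for (b in sets_j) {
      if (length(a) == 0 || length(b) == 0) next
      if ((all(a %in% b) || all(b %in% a))) {
        if (.jaccard(a, b) >= min_score || setequal(a, b)) return(TRUE)
      }
    }
  }
  FALSE
}

#' Generate a target vocabulary with planted match ground truth
#'
#' For every labeled field of `schema`, independently with the stated
#' probabilities: an `exact` plant copies the field label into the
#' vocabulary; a `partial` plant perturbs it by one token (adding a
#' qualifier token from a disjoint alphabet, or dropping a token when
#' `perturbation = "drop_qualifier_token"` and dropping is safe) so the
#' token-subset rule fires; a `none` plant emits a random label sharing
#' no tokens with any field. Where nested field names would let a planted
#' `none` field accidentally partial-match another field's term, the
#' plant assignment is repaired deterministically by swapping with an
#' unrelated field, preserving the drawn type frequencies.
#'
#' @param schema A `mit_schema`.
#' @param p_exact,p_partial,p_none Plant probabilities, summing to 1.
#' @param seed Integer seed; same seed, same output.
#' @param perturbation `"add_qualifier_token"` (default) or
#'   `"drop_qualifier_token"`.
#' @param min_score The partial-match threshold the matcher will use.
#' @return A list with `vocabulary` (a `mit_vocabulary`) and `truth`
#'   (data frame `field_id`, `match_type`, `term_id`).
#' @export
#' @examples
#' gv <- generate_vocabulary(build_reference_mit(), 1, 0, 0, seed = 1)
#' nrow(gv$vocabulary$terms)
generate_vocabulary <- function(schema, p_exact, p_partial, p_none,
                                seed = 1L,
                                perturbation = c("add_qualifier_token",
                                                 "drop_qualifier_token"),
                                min_score = 0.25) {
  perturbation <- match.arg(perturbation)
  stopifnot(inherits(schema, "mit_schema"),
            p_exact >= 0, p_partial >= 0, p_none >= 0,
            abs(p_exact + p_partial + p_none - 1) < 1e-9)
  f <- schema$fields
  n <- nrow(f)
  variant_sets <- lapply(seq_len(n), function(i) {
    .label_variants(f$name[i], f$synonyms[i])
  })
  related <- lapply(seq_len(n), function(i) {
    which(vapply(seq_len(n), function(j) {
      j != i && .fields_related(variant_sets[[i]], variant_sets[[j]],
                                min_score)
    }, logical(1)))
  })

  .with_seed(seed, {
    types <- sample(c("exact", "partial", "none"), n, replace = TRUE,
                    prob = c(p_exact, p_partial, p_none))
    # repair: a none plant next to a non-none neighbour could be matched
    # by the neighbour's term; swap with an unrelated (isolated) field
    isolated <- vapply(related, length, integer(1)) == 0
    for (pass in 1:10) {
      bad <- which(vapply(seq_len(n), function(i) {
        types[i] == "none" && any(types[related[[i]]] != "none")
      }, logical(1)))
      if (perturbation == "drop_qualifier_token") {
        bad <- union(bad, which(vapply(seq_len(n), function(i) {
          types[i] == "partial" && any(types[related[[i]]] != "none")
        }, logical(1))))
      }
      if (length(bad) == 0) break
      for (i in bad) {
        donor <- which(isolated & types != "none" &
                       seq_len(n) != i)[1]
        if (is.na(donor)) {
          types[i] <- "exact"  # last resort: exact always dominates
        } else {
          tmp <- types[donor]
          types[donor] <- types[i]
          types[i] <- tmp
        }
      }
    }

    qualifier_pool <- sprintf("qx%04d", seq_len(n))
    noise_pool <- sprintf("zq%04d", seq_len(3L * n))
    terms <- vector("list", n)
    truth <- data.frame(field_id = f$field_id, match_type = types,
                        term_id = "", stringsAsFactors = FALSE)
    for (i in seq_len(n)) {
      tid <- sprintf("V%04d", i)
      name_tokens <- normalize_label(f$name[i])
      label <- switch(types[i],
        exact = f$name[i],
        partial = {
          lab <- NULL
          if (perturbation == "drop_qualifier_token" &&
              length(name_tokens) >= 2) {
            for (k in sample(seq_along(name_tokens))) {
              cand <- name_tokens[-k]
              ok <- .jaccard(cand, name_tokens) >= min_score
              if (ok) {
                for (j in seq_len(n)) {
                  if (j == i) next
                  if (.fields_related(list(cand), variant_sets[[j]],
                                      min_score)) { ok <- FALSE; break }
                }
              }
              if (ok) { lab <- paste(cand, collapse = " "); break }
            }
          }
          if (is.null(lab)) {
            lab <- paste(c(name_tokens, qualifier_pool[i]),
                         collapse = " ")
          }
          lab
        },
        none = paste(sample(noise_pool, 2), collapse = " "))
      terms[[i]] <- data.frame(term_id = tid, label = label,
                               synonyms = "", parent_id = "",
                               stringsAsFactors = FALSE)
      if (types[i] != "none") truth$term_id[i] <- tid
    }
    vocab <- mit_vocabulary(do.call(rbind, terms),
                            vocab_id = paste0("planted-", seed))
    list(vocabulary = vocab, truth = truth)
  })
}

#' Generate a metadata record with controlled completeness
#'
#' Each applicable content-bearing field is present independently with
#' probability `p_present`; present fields receive a value conforming to
#' their value kind (a number with the unit hint for quantities, a
#' boolean literal, a whitespace-free token for identifiers, plain text
#' otherwise). Deterministic under `seed`.
#'
#' @param schema A `mit_schema`.
#' @param p_present Presence probability in \code{[0, 1]}.
#' @param seed Integer seed.
#' @param model_context Record context; `"both"` (default) makes every
#'   applicability branch applicable.
#' @return A `mit_record`.
#' @export
generate_record <- function(schema, p_present, seed = 1L,
                            model_context = c("both", "in_vitro",
                                              "in_vivo")) {
  model_context <- match.arg(model_context)
  stopifnot(inherits(schema, "mit_schema"),
            p_present >= 0, p_present <= 1)
  appl <- .applicable_fields(schema, model_context, "optional")
  .with_seed(seed, {
    keep <- stats::runif(nrow(appl)) < p_present
    rows <- appl[keep, , drop = FALSE]
    value_for <- function(kind, unit, fid) {
      switch(kind,
             quantity_with_unit = paste(round(stats::runif(1, 1, 100), 2),
                                        unit),
             boolean = sample(c("yes", "no"), 1),
             identifier = paste0("id-", fid),
             controlled_term = paste0("term ", fid),
             paste("value for", fid))
    }
    vals <- data.frame(
      field_id = rows$field_id,
      value = vapply(seq_len(nrow(rows)), function(i) {
        value_for(rows$value_kind[i], rows$unit[i], rows$field_id[i])
      }, character(1)),
      unit = rows$unit, stringsAsFactors = FALSE)
    mit_record(vals, record_id = paste0("synthetic-", seed),
               schema_version = schema$version,
               model_context = model_context)
  })
}
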