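# Shared fixtures built in code.

# a small schema with two modules and a mix of grouping/content fields
tiny_schema <- function() {
  mit_schema(data.frame(
    name = c("General Information", "experiment name", "zeta potential",
             "dispersion protocol", "housing conditions",
             "passage number", "serum presence"),
    category = c("grouping", rep("content_bearing", 6)),
    module_id = c("general_information", "general_information",
                  "material_information", "material_information",
                  "biological_model_information",
                  "biological_model_information",
                  "biological_model_information"),
    synonyms = c("", "", "surface charge", "", "", "", ""),
    applicability = c("always", "always", "always", "always",
                      "in_vivo_only", "in_vitro_only", "in_vitro_only"),
    value_kind = c("", "free_text", "quantity_with_unit", "free_text",
                   "free_text", "quantity_with_unit", "boolean"),
    unit = c("", "", "mV", "", "", "count", ""),
    stringsAsFactors = FALSE
  ), schema_id = "tiny", version = "1.0")
}

# independent brute-force one-to-one matcher used as an oracle: plain
# string comparisons, no calls into the package's normalization helpers
oracle_exact_match <- function(field_name, field_synonyms, terms) {
  norm <- function(x) {
    x <- tolower(x)
    x <- gsub("[^a-z0-9]+", " ", x)
    trimws(gsub(" +", " ", x))
  }
  split_pipe <- function(x) {
    if (is.na(x) || x == "") character() else
      trimws(strsplit(x, "|", fixed = TRUE)[[1]])
  }
  fvars <- norm(c(field_name, split_pipe(field_synonyms)))
  hits <- character()
  for (i in seq_len(nrow(terms))) {
    tvars <- norm(c(terms$label[i], split_pipe(terms$synonyms[i])))
    if (any(fvars %in% tvars)) hits <- c(hits, terms$term_id[i])
  }
  if (length(hits) == 0) "" else sort(hits)[1]
}

# per-module one-to-one counts printed for the eNanoMapper comparison
enm_module_exact_counts <- function() {
  data.frame(
    stratum = c("general_information", "material_information",
                "biological_model_information", "exposure_information",
                "endpoint_readout_information", "analysis_statistics"),
    exact = c(14L, 29L, 16L, 13L, 22L, 11L),
    stringsAsFactors = FALSE)
}
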