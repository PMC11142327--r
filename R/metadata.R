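# Model-level metadata: provenance links, creators, timestamps, notes.
#
# Keywords follow BioModels curation practice: `model_source`, `publication`,
# `biological_system` and `taxon` hold identifiers.org-style URIs, `created`
# and `modified` hold W3CDTF (ISO-8601) timestamps, `creatorN.<field>` builds
# a vCard-like creator list and `notes` holds free text.  Using any metadata
# keyword requires the model to be written as an explicit
# `model name() ... end` block.

empty_metadata <- function() {
  list(model_source = NULL, publication = NULL, biological_system = NULL,
       taxon = NULL, created = NULL, modified = NULL,
       creators = list(), notes = NULL)
}

metadata_is_empty <- function(rec) {
  is.null(rec$model_source) && is.null(rec$publication) &&
    is.null(rec$biological_system) && is.null(rec$taxon) &&
    is.null(rec$created) && is.null(rec$modified) &&
    length(rec$creators) == 0L && is.null(rec$notes)
}

is_absolute_uri <- function(x) grepl("^[A-Za-z][A-Za-z0-9+.-]*://", x)

# W3CDTF as used by BioModels: 2007-07-16T09:41:14Z (zone offset allowed)
is_w3cdtf <- function(x) {
  grepl("^\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}:\\d{2}(Z|[+-]\\d{2}:\\d{2})$", x)
}

#' Apply metadata statements to a model
#'
#' @param model An `ant_model`.
#' @param statements Metadata-variant AST statements (`model key "value"`).
#' @return The model with its metadata record populated; diagnostics are
#'   appended to `model$diagnostics`.
#' @export
ant_apply_metadata <- function(model, statements) {
  rec <- model$metadata
  for (s in statements) {
    stopifnot(identical(s$variant, "metadata"))
    if (is.null(model$name)) {
      ant_stop(sprintf(
        "metadata keyword '%s' requires the model to be bracketed by 'model name()' and 'end'",
        s$key), s$loc$line, s$loc$col, "ant_semantic_error")
    }
    if (grepl("^creator[0-9]+\\.", s$key)) {
      idx <- as.integer(sub("^creator([0-9]+)\\..*$", "\\1", s$key))
      field <- sub("^creator[0-9]+\\.", "", s$key)
      if (!field %in% CREATOR_FIELDS) {
        ant_stop(sprintf("unknown creator field '%s'", field),
                 s$loc$line, s$loc$col, "ant_semantic_error")
      }
      if (idx < 1L) {
        ant_stop("creator indices start at 1", s$loc$line, s$loc$col,
                 "ant_semantic_error")
      }
      while (length(rec$creators) < idx) {
        rec$creators[[length(rec$creators) + 1L]] <-
          list(index = length(rec$creators) + 1L, givenName = NULL,
               familyName = NULL, organization = NULL, email = NULL)
      }
      rec$creators[[idx]][[field]] <- s$value
    } else if (s$key %in% METADATA_SCALAR_KEYS) {
      val <- s$value
      if (s$key %in% c("created", "modified") && !is_w3cdtf(val)) {
        ant_stop(sprintf("'%s' timestamp is not ISO-8601/W3CDTF: \"%s\"",
                         s$key, val), s$loc$line, s$loc$col,
                 "ant_semantic_error")
      }
      if (s$key %in% c("model_source", "publication", "biological_system",
                       "taxon") && !is_absolute_uri(val)) {
        ant_stop(sprintf("'%s' must be an absolute URI: \"%s\"", s$key, val),
                 s$loc$line, s$loc$col, "ant_semantic_error")
      }
      rec[[s$key]] <- val
    } else {
      ant_stop(sprintf("unknown metadata keyword '%s'", s$key),
               s$loc$line, s$loc$col, "ant_semantic_error")
    }
  }
  # sparse creator indices (creator2 without creator1) violate the
  # at-least-one-field invariant and are rejected rather than silently held
  for (cr in rec$creators) {
    if (is.null(cr$givenName) && is.null(cr$familyName) &&
        is.null(cr$organization) && is.null(cr$email)) {
      ant_stop(sprintf("creator%d has no fields set (sparse creator indices are not allowed)",
                       cr$index), NA, NA, "ant_semantic_error")
    }
  }
  model$metadata <- rec
  model
}

metadata_unparse_lines <- function(rec) {
  lines <- character(0)
  q <- function(key, val) sprintf("model %s \"%s\"", key, val)
  for (key in c("model_source", "publication", "biological_system", "taxon",
                "created", "modified")) {
    if (!is.null(rec[[key]])) lines <- c(lines, q(key, rec[[key]]))
  }
  for (cr in rec$creators) {
    for (field in CREATOR_FIELDS) {
      if (!is.null(cr[[field]])) {
        lines <- c(lines, q(sprintf("creator%d.%s", cr$index, field),
                            cr[[field]]))
      }
    }
  }
  if (!is.null(rec$notes)) lines <- c(lines, q("notes", rec$notes))
  lines
}
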