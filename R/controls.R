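#' Specify the control probes of a panel
#'
#' Targeted panels carry synthetic spike-in probes ("positive controls", a
#' large read share flags a failed sample) and probes against non-human
#' sequences ("negative controls", whose reads measure background and
#' contamination). A `control_spec` names both sets.
#'
#' @param positive_ids Character vector of positive-control (spike-in) probe ids.
#' @param negative_ids Character vector of negative-control probe ids.
#' @return An object of class `control_spec`.
#' @seealso [detect_controls()] to derive the sets from id prefixes.
#' @export
control_spec <- function(positive_ids, negative_ids) {
  positive_ids <- unique(as.character(positive_ids))
  negative_ids <- unique(as.character(negative_ids))
  overlap <- intersect(positive_ids, negative_ids)
  if (length(overlap) > 0L) {
    abort(sprintf("Probe(s) listed as both positive and negative controls: %s",
                  paste(overlap, collapse = ", ")))
  }
  structure(list(positive_ids = positive_ids, negative_ids = negative_ids),
            class = "control_spec")
}

#' @export
print.control_spec <- function(x, ...) {
  cat(sprintf("<control_spec> %d positive (%s), %d negative (%s)\n",
              length(x$positive_ids), paste(x$positive_ids, collapse = ", "),
              length(x$negative_ids), paste(x$negative_ids, collapse = ", ")))
  invisible(x)
}

#' Detect control probes by identifier prefix
#'
#' HTG-style panels name their four spike-ins `POS1..POS4` and their four
#' non-human probes `ANT1..ANT4`; matching is case-insensitive on the prefix.
#' Explicit id vectors, when given, take precedence over the prefixes.
#'
#' @param counts Counts tibble (see [read_counts()]).
#' @param pos_prefix,neg_prefix Identifier prefixes (case-insensitive).
#' @param pos_ids,neg_ids Optional explicit probe-id vectors overriding the
#'   prefix match.
#' @return A [control_spec()].
#' @export
detect_controls <- function(counts, pos_prefix = "POS", neg_prefix = "ANT",
                            pos_ids = NULL, neg_ids = NULL) {
  probe_ids <- rownames(counts_tbl_to_matrix(counts))
  match_set <- function(ids, prefix, label) {
    if (!is.null(ids)) {
      missing <- setdiff(ids, probe_ids)
      if (length(missing) > 0L) {
        abort(sprintf("%s control id(s) not in matrix: %s",
                      label, paste(missing, collapse = ", ")))
      }
      return(as.character(ids))
    }
    if (!nzchar(prefix)) abort(sprintf("%s control prefix must be non-empty.", label))
    hits <- probe_ids[startsWith(tolower(probe_ids), tolower(prefix))]
    if (length(hits) == 0L) {
      abort(sprintf(
        "No probe id starts with %s prefix '%s'. Available probes: %s",
        tolower(label), prefix,
        paste(head(probe_ids, 20L), collapse = ", ")))
    }
    hits
  }
  control_spec(match_set(pos_ids, pos_prefix, "Positive"),
               match_set(neg_ids, neg_prefix, "Negative"))
}

# Bind a spec to a matrix: every id must exist, both sets non-empty.
validate_controls <- function(controls, probe_ids) {
  if (!inherits(controls, "control_spec")) {
    abort("`controls` must be a control_spec (see control_spec() / detect_controls()).")
  }
  missing <- setdiff(c(controls$positive_ids, controls$negative_ids), probe_ids)
  if (length(missing) > 0L) {
    abort(sprintf("Control id(s) not present in the matrix: %s",
                  paste(missing, collapse = ", ")))
  }
  controls
}
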