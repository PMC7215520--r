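#' Merge predicted binding-site residue sets into a consensus
#'
#' Combines independently predicted residue sets (e.g. a pocket-detection
#' and an interface-prediction program's outputs) into one consensus set.
#' Under the default `"intersection"` rule a residue must appear in every
#' source set; `majority(k)` keeps residues present in at least `k` sets
#' (`k = 1` is the union, `k = n` the intersection). Residue identity for
#' set operations is the residue number; differing residue names at the
#' same number raise a warning, not an error.
#'
#' @param sets List of two or more [residue_set()]s.
#' @param rule `"intersection"` or `"majority"`.
#' @param k Minimum number of supporting sets for `rule = "majority"`.
#' @return A `consensus_result`: list with `consensus` (a
#'   [residue_set()]), `per_source_counts`, `union_size`,
#'   `intersection_size`, `rule` and an (initially empty) `annotations`
#'   list.
#' @export
consensus <- function(sets, rule = c("intersection", "majority"), k = NULL) {
  rule <- match.arg(rule)
  if (length(sets) < 2) stop("need at least 2 residue sets")
  for (s in sets) stopifnot(inherits(s, "residue_set"))
  if (rule == "intersection") k <- length(sets)
  if (is.null(k)) stop("majority rule needs k")
  stopifnot(k >= 1, k <= length(sets))

  all_numbers <- unlist(lapply(sets, `[[`, "numbers"))
  all_members <- unlist(lapply(sets, `[[`, "members"))
  # name consistency at a shared number
  by_num <- split(all_members, all_numbers)
  clash <- vapply(by_num, function(v) length(unique(v)) > 1, TRUE)
  if (any(clash)) {
    warning("conflicting residue names at number(s): ",
            paste(names(by_num)[clash], collapse = ", "))
  }
  # each residue_set is already deduplicated, so occurrences = support
  support <- table(all_numbers)
  keep_numbers <- as.integer(names(support)[support >= k])
  members <- all_members[match(keep_numbers, all_numbers)]
  cons <- if (length(members)) {
    residue_set(members, name = paste0("consensus_", rule,
                                       if (rule == "majority") k else ""))
  } else {
    structure(list(name = "consensus", members = character(0),
                   numbers = integer(0)), class = "residue_set")
  }
  src_names <- vapply(seq_along(sets), function(i) {
    if (nzchar(sets[[i]]$name)) sets[[i]]$name else paste0("set", i)
  }, "")
  structure(list(
    consensus = cons,
    per_source_counts = stats::setNames(vapply(sets, length, 1L), src_names),
    union_size = length(unique(all_numbers)),
    intersection_size = sum(support == length(sets)),
    rule = rule, k = k,
    annotations = list()
  ), class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("<consensus_result> %s: %d residues (union %d, intersection %d)\n",
              x$rule, length(x$consensus), x$union_size, x$intersection_size))
  cat("  sources:", paste(sprintf("%s=%d", names(x$per_source_counts),
                                  x$per_source_counts), collapse = ", "), "\n")
  for (tag in names(x$annotations)) {
    a <- x$annotations[[tag]]
    cat(sprintf("  %s: %d/%d in consensus%s\n", tag, a$n_in_consensus,
                a$n_total,
                if (a$n_in_consensus)
                  paste0(" (", paste(a$members_in_consensus, collapse = ", "), ")")
                else ""))
  }
  invisible(x)
}

#' Annotate a consensus with residue tags
#'
#' Performs membership queries of annotation sets (variant positions,
#' stability residues, terminal groups, ...) against the consensus:
#' which tagged residues fall inside the consensus binding site?
#'
#' @param result A `consensus_result` from [consensus()].
#' @param annotations Named list of [residue_set()]s (names are the tags),
#'   or of plain integer residue-number vectors.
#' @return The `consensus_result` with its `annotations` list extended;
#'   each entry records `n_total`, `n_in_consensus` and
#'   `members_in_consensus`.
#' @export
annotate_consensus <- function(result, annotations) {
  stopifnot(inherits(result, "consensus_result"))
  if (length(annotations) == 0) return(result)
  if (is.null(names(annotations)) || any(!nzchar(names(annotations)))) {
    stop("annotations must be a named list")
  }
  cn <- result$consensus$numbers
  for (tag in names(annotations)) {
    a <- annotations[[tag]]
    nums <- if (inherits(a, "residue_set")) a$numbers else as.integer(a)
    inside <- nums %in% cn
    members <- if (inherits(a, "residue_set")) a$members[inside] else
      result$consensus$members[match(nums[inside], cn)]
    result$annotations[[tag]] <- list(
      n_total = length(nums),
      n_in_consensus = sum(inside),
      numbers_in_consensus = nums[inside],
      members_in_consensus = members
    )
  }
  result
}
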