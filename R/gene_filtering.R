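# Phase-I post-processing: remove genes on named exclusion lists (e.g. the
# cell-viability screen overlap and predicted-only ORFs) with an auditable
# accounting of removals.

#' Filter a hit list against ordered exclusion lists
#'
#' Applies each named exclusion list in turn to the running survivor set and
#' records how many genes each list removed *of those still surviving* — so
#' a gene on two lists is counted against the first only. The surviving set
#' itself is order-invariant (input minus the union of all lists); only the
#' per-list accounting depends on order. Identifier matching is exact string
#' match after whitespace trimming; no synonym resolution is attempted.
#'
#' @param hits Character vector of gene ids (duplicates are collapsed with
#'   a warning).
#' @param exclusion_lists Named list of character vectors, applied in order.
#'   Duplicated entries within a list are dropped with a warning.
#' @return Object of class `exclusion_report`: a list with `input_count`,
#'   `removed` (named integer vector, one entry per list), `surviving`
#'   (gene ids, input order preserved), and `surviving_count`.
#' @export
apply_exclusions <- function(hits, exclusion_lists = list()) {
  hits <- trimws(as.character(hits))
  if (any(!nzchar(hits) | is.na(hits)))
    stop("gene ids must be non-empty strings", call. = FALSE)
  if (anyDuplicated(hits)) {
    warning("duplicate gene ids in input collapsed", call. = FALSE)
    hits <- unique(hits)
  }
  if (length(exclusion_lists) && is.null(names(exclusion_lists)))
    names(exclusion_lists) <- sprintf("list%d", seq_along(exclusion_lists))

  surviving <- hits
  removed <- integer(0)
  for (nm in names(exclusion_lists)) {
    excl <- trimws(as.character(exclusion_lists[[nm]]))
    if (anyDuplicated(excl)) {
      warning("exclusion list '", nm, "' contains duplicates; de-duplicated",
              call. = FALSE)
      excl <- unique(excl)
    }
    drop <- surviving %in% excl
    removed[nm] <- sum(drop)
    surviving <- surviving[!drop]
  }
  structure(list(input_count = length(hits), removed = removed,
                 surviving = surviving, surviving_count = length(surviving)),
            class = "exclusion_report")
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat(sprintf("<exclusion_report> %d genes in\n", x$input_count))
  for (nm in names(x$removed))
    cat(sprintf("  - %-20s removed %d\n", nm, x$removed[[nm]]))
  cat(sprintf("  = %d surviving\n", x$surviving_count))
  invisible(x)
}
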