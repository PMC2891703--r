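# Core data model for plate-based reporter screens: addressed wells, reagent
# annotation, screen datasets, and the delimited-text formats every stage
# consumes.

WELL_ROLES <- c("sample", "negative_control", "positive_control", "empty")
SCREEN_STAGES <- c("primary", "secondary", "tertiary")
SCREEN_CONDITIONS <- c("DFO", "hypoxia", "normoxia")

#' Plate geometry for a supported microplate format
#'
#' @param plate_format 96 or 384.
#' @return List with `rows` (row letters), `n_col`, and `n_wells`.
#' @keywords internal
plate_format_spec <- function(plate_format) {
  switch(as.character(plate_format),
    "96"  = list(rows = LETTERS[1:8],  n_col = 12L, n_wells = 96L),
    "384" = list(rows = LETTERS[1:16], n_col = 24L, n_wells = 384L),
    stop("unsupported plate format: ", plate_format, " (use 96 or 384)",
         call. = FALSE))
}

#' Canonical well label
#'
#' Formats a (row letter, column) address as the zero-padded industry
#' convention, e.g. `"A01"`, `"P24"`, which sorts lexically in plate order.
#'
#' @param row Row letter(s), `"A"`..`"P"`.
#' @param col Column number(s), 1-based.
#' @return Character vector of labels.
#' @export
well_label <- function(row, col) sprintf("%s%02d", row, as.integer(col))

#' Construct a validated screen dataset
#'
#' A screen dataset is one stage of a screen: a set of addressed wells across
#' one or more plates, each well carrying a firefly (and optionally Renilla)
#' luminescence reading, a reagent id, and a role. Replicated plates are
#' linked through `replicate_map`.
#'
#' Hard errors are raised for malformed data that no downstream stage can
#' interpret: duplicated well addresses, negative luminescence, unknown
#' roles, or addresses outside the plate format. Softer contract violations
#' (e.g. a secondary-stage well missing its Renilla reading) are reported by
#' [validate_dataset()].
#'
#' @param wells data.frame with columns `plate_id`, `row`, `col`,
#'   `reagent_id` (NA allowed for controls/empties), `role` (one of sample,
#'   negative_control, positive_control, empty), `firefly`, and optionally
#'   `renilla`.
#' @param stage Screen stage: "primary", "secondary" or "tertiary".
#' @param condition Stimulus: "DFO", "hypoxia" or "normoxia".
#' @param plate_format 96 or 384.
#' @param replicate_map Named integer vector mapping plate_id to replicate
#'   index. Defaults to parsing a `_r<k>` suffix from plate ids, else 1.
#' @return Object of class `screen_dataset`.
#' @export
screen_dataset <- function(wells, stage = "primary", condition = "DFO",
                           plate_format = 384, replicate_map = NULL) {
  stage <- match.arg(stage, SCREEN_STAGES)
  condition <- match.arg(condition, SCREEN_CONDITIONS)
  fmt <- plate_format_spec(plate_format)

  required <- c("plate_id", "row", "col", "reagent_id", "role", "firefly")
  missing_cols <- setdiff(required, names(wells))
  if (length(missing_cols))
    stop("wells table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (!"renilla" %in% names(wells)) wells$renilla <- NA_real_

  wells$plate_id <- as.character(wells$plate_id)
  wells$row <- toupper(trimws(as.character(wells$row)))
  wells$col <- as.integer(wells$col)
  wells$reagent_id <- as.character(wells$reagent_id)
  wells$reagent_id[!is.na(wells$reagent_id) & wells$reagent_id == ""] <- NA
  wells$role <- as.character(wells$role)
  wells$firefly <- as.numeric(wells$firefly)
  wells$renilla <- as.numeric(wells$renilla)

  bad_role <- setdiff(unique(wells$role), WELL_ROLES)
  if (length(bad_role))
    stop("unknown well role(s): ", paste(bad_role, collapse = ", "),
         call. = FALSE)
  bad_addr <- !(wells$row %in% fmt$rows) | is.na(wells$col) |
    wells$col < 1L | wells$col > fmt$n_col
  if (any(bad_addr))
    stop("well address outside ", plate_format, "-well format: ",
         paste(unique(sprintf("%s:%s%d", wells$plate_id[bad_addr],
                              wells$row[bad_addr], wells$col[bad_addr])),
               collapse = ", "), call. = FALSE)
  addr <- sprintf("%s:%s%d", wells$plate_id, wells$row, wells$col)
  if (anyDuplicated(addr))
    stop("duplicate well address: ",
         paste(unique(addr[duplicated(addr)]), collapse = ", "),
         call. = FALSE)
  if (any(wells$firefly < 0, na.rm = TRUE) || any(wells$renilla < 0, na.rm = TRUE))
    stop("negative luminescence at well ",
         paste(addr[which(wells$firefly < 0 | (!is.na(wells$renilla) & wells$renilla < 0))],
               collapse = ", "), call. = FALSE)

  plates <- unique(wells$plate_id)
  if (is.null(replicate_map)) {
    rep_idx <- suppressWarnings(as.integer(sub(".*_r(\\d+)$", "\\1", plates)))
    rep_idx[is.na(rep_idx)] <- 1L
    replicate_map <- stats::setNames(rep_idx, plates)
  } else {
    replicate_map <- stats::setNames(as.integer(replicate_map), names(replicate_map))
    missing_plates <- setdiff(plates, names(replicate_map))
    if (length(missing_plates))
      stop("replicate_map lacks plate(s): ",
           paste(missing_plates, collapse = ", "), call. = FALSE)
  }

  rownames(wells) <- NULL
  structure(
    list(stage = stage, condition = condition,
         plate_format = as.integer(plate_format),
         wells = wells[, c("plate_id", "row", "col", "reagent_id", "role",
                           "firefly", "renilla")],
         replicate_map = replicate_map),
    class = "screen_dataset")
}

#' @export
print.screen_dataset <- function(x, ...) {
  cat(sprintf("<screen_dataset> stage=%s condition=%s format=%d-well\n",
              x$stage, x$condition, x$plate_format))
  cat(sprintf("  %d wells on %d plate(s), %d replicate(s)\n",
              nrow(x$wells), length(unique(x$wells$plate_id)),
              length(unique(x$replicate_map))))
  invisible(x)
}

#' Read a plate measurement table
#'
#' Reads the screen's CSV interchange format, one row per well with columns
#' `plate_id,row,col,reagent_id,role,firefly[,renilla][,replicate]`, and
#' returns a validated [screen_dataset()]. Parsing is loss-less: writing with
#' [write_plate_table()] and reading back yields an identical dataset.
#'
#' @param path Path to the CSV file.
#' @inheritParams screen_dataset
#' @return A `screen_dataset`.
#' @export
read_plate_table <- function(path, plate_format = 384, stage = "primary",
                             condition = "DFO") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  required <- c("plate_id", "row", "col", "reagent_id", "role", "firefly")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("header lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  replicate_map <- NULL
  if ("replicate" %in% names(tab)) {
    per_plate <- unique(tab[, c("plate_id", "replicate")])
    if (anyDuplicated(per_plate$plate_id))
      stop("plate(s) assigned to more than one replicate index", call. = FALSE)
    replicate_map <- stats::setNames(as.integer(per_plate$replicate),
                                     as.character(per_plate$plate_id))
    tab$replicate <- NULL
  }
  screen_dataset(tab, stage = stage, condition = condition,
                 plate_format = plate_format, replicate_map = replicate_map)
}

#' Write a plate measurement table
#'
#' Serialises a dataset to the canonical CSV column order, including a
#' `replicate` column reflecting the dataset's replicate map. The `renilla`
#' column is written only when at least one well carries a Renilla reading.
#'
#' @param ds A `screen_dataset`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_plate_table <- function(ds, path) {
  stopifnot(inherits(ds, "screen_dataset"))
  out <- ds$wells
  out$replicate <- unname(ds$replicate_map[out$plate_id])
  if (all(is.na(out$renilla))) out$renilla <- NULL
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Report contract violations in a screen dataset
#'
#' Checks every dataset invariant and reports each violation as a message
#' naming the offending plate, well, reagent, or field. Unlike the hard
#' errors raised at construction, this is a pure reporting operation: a
#' well-formed dataset returns `character(0)`.
#'
#' Checked: non-negative luminescence; sample wells carry a reagent id;
#' secondary/tertiary stages have a Renilla reading on every non-empty well;
#' every replicate index covers the same set of sample reagents.
#'
#' @param ds A `screen_dataset`.
#' @return Character vector of violation messages (empty if none).
#' @export
validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "screen_dataset"))
  w <- ds$wells
  addr <- sprintf("plate %s well %s", w$plate_id, well_label(w$row, w$col))
  v <- character(0)

  neg <- which(w$firefly < 0 | (!is.na(w$renilla) & w$renilla < 0))
  if (length(neg))
    v <- c(v, sprintf("%s: negative luminescence", addr[neg]))

  orphan <- which(w$role == "sample" & is.na(w$reagent_id))
  if (length(orphan))
    v <- c(v, sprintf("%s: sample well lacks reagent_id", addr[orphan]))

  if (ds$stage %in% c("secondary", "tertiary")) {
    no_ren <- which(w$role != "empty" & is.na(w$renilla))
    if (length(no_ren))
      v <- c(v, sprintf("%s: %s stage requires a renilla reading",
                        addr[no_ren], ds$stage))
  }

  rep_of <- unname(ds$replicate_map[w$plate_id])
  samp <- w$role == "sample" & !is.na(w$reagent_id)
  reagent_sets <- split(w$reagent_id[samp], rep_of[samp])
  if (length(reagent_sets) > 1) {
    all_reagents <- unique(unlist(reagent_sets))
    for (r in names(reagent_sets)) {
      missing <- setdiff(all_reagents, reagent_sets[[r]])
      if (length(missing))
        v <- c(v, sprintf("replicate %s: missing reagent %s", r, missing))
    }
  }
  v
}

#' Read a reagent annotation table
#'
#' CSV with columns `reagent_id,target_gene_id,amplicon_index`, one row per
#' dsRNA amplicon. A gene may own several amplicons; the amplicon index must
#' be unique within each gene.
#'
#' @param path Path to the CSV file.
#' @return data.frame with those three columns.
#' @export
read_reagent_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("reagent_id", "target_gene_id", "amplicon_index")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("header lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  tab$amplicon_index <- as.integer(tab$amplicon_index)
  if (any(tab$amplicon_index < 1L))
    stop("amplicon_index must be >= 1", call. = FALSE)
  dup <- duplicated(tab[, c("target_gene_id", "amplicon_index")])
  if (any(dup))
    stop("duplicated amplicon_index within gene(s): ",
         paste(unique(tab$target_gene_id[dup]), collapse = ", "),
         call. = FALSE)
  tab[, required]
}

#' Read a gene exclusion list
#'
#' Plain text, one gene identifier per line; `#` starts a comment; blank
#' lines are ignored; identifiers are whitespace-trimmed and de-duplicated
#' (case preserved — matching downstream is exact).
#'
#' @param path Path to the text file.
#' @return Character vector of gene ids.
#' @export
read_exclusion_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  unique(lines[nzchar(lines)])
}
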