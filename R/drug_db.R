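# Unified drug-target-toxicity database: per-source target tables merged
# by set union, per-source binary toxicity labels merged by logical OR
# (a drug is toxic if at least one source calls it toxic).

new_drug_db <- function(df, targets) {
  stopifnot(length(targets) == nrow(df))
  df$targets <- I(targets)
  if (anyDuplicated(df$drug_id)) stop("one record per drug_id required")
  if (any(lengths(targets) == 0)) stop("target_genes must be non-empty")
  class(df) <- c("drug_db", "data.frame")
  df
}

#' @export
print.drug_db <- function(x, ...) {
  cat(sprintf("drug_db: %d drugs (%d toxic, %d nontoxic), %d distinct target genes\n",
              nrow(x), sum(x$label == "toxic"), sum(x$label == "nontoxic"),
              length(unique(unlist(x$targets)))))
  ex <- attr(x, "exclusions")
  if (!is.null(ex) && sum(ex) > 0) {
    cat("exclusions:", paste(sprintf("%s=%d", names(ex), ex), collapse = ", "), "\n")
  }
  invisible(x)
}

# lower-case, trim, collapse internal whitespace; no synonym resolution
normalize_drug_id <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

normalize_label <- function(x, source = "?") {
  x <- tolower(trimws(as.character(x)))
  map <- c("toxic" = "toxic", "1" = "toxic", "true" = "toxic",
           "nontoxic" = "nontoxic", "non-toxic" = "nontoxic",
           "0" = "nontoxic", "false" = "nontoxic")
  out <- unname(map[x])
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stop("non-binary toxicity labels in source '", source, "': ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  out
}

#' Merge per-source toxicity labels by logical OR
#'
#' A drug is labeled toxic if at least one source labels it toxic;
#' nontoxic if at least one source labels it nontoxic and none labels it
#' toxic. Drugs absent from all sources are (vacuously) excluded. The OR
#' also applies to conflicting duplicate rows within a single source.
#'
#' @param source_tables Named list of data.frames with columns `drug_id`
#'   and `label` (binary: toxic/nontoxic, 1/0 or TRUE/FALSE); the list
#'   names tag the sources (e.g. `ryan`, `acs_fda`, `diril`).
#' @return data.frame with columns `drug_id` (normalized), `label`,
#'   `label_sources` (semicolon-joined sources that mentioned the drug).
#' @export
merge_toxicity_labels <- function(source_tables) {
  stopifnot(is.list(source_tables), length(source_tables) >= 1)
  src_names <- names(source_tables) %||% paste0("source", seq_along(source_tables))
  if (is.null(names(source_tables))) names(source_tables) <- src_names
  rows <- lapply(src_names, function(s) {
    tab <- source_tables[[s]]
    if (!all(c("drug_id", "label") %in% names(tab))) {
      stop("label table '", s, "' needs columns drug_id and label")
    }
    data.frame(drug_id = normalize_drug_id(tab$drug_id),
               label = normalize_label(tab$label, s),
               source = s, stringsAsFactors = FALSE)
  })
  all_rows <- do.call(rbind, rows)
  merged <- lapply(split(all_rows, all_rows$drug_id), function(d) {
    data.frame(drug_id = d$drug_id[1],
               label = if (any(d$label == "toxic")) "toxic" else "nontoxic",
               label_sources = paste(sort(unique(d$source)), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, merged)
  rownames(out) <- NULL
  out[order(out$drug_id), , drop = FALSE]
}

#' Build the unified drug-target-toxicity database
#'
#' Combines per-source drug-target tables (set union of targets across
#' sources, deduplicated) with OR-merged toxicity labels, keeping only
#' drugs with an allowed approval status. Drugs lacking any target, any
#' label, or the required status are dropped; the exclusion tally is
#' attached as the `"exclusions"` attribute.
#'
#' @param target_tables Named list of data.frames with columns `drug_id`,
#'   `target_gene` and optionally `status` (approval status, default
#'   `"approved"`).
#' @param labels Merged label table from [merge_toxicity_labels()].
#' @param require_status Allowed approval statuses.
#' @return A `drug_db` table: one row per drug with `drug_id`, `label`,
#'   `label_sources`, `target_sources`, `approval_status` and a `targets`
#'   list column; `attr(, "exclusions")` counts drops per reason.
#' @export
build_drug_database <- function(target_tables, labels,
                                require_status = c("approved", "withdrawn")) {
  stopifnot(is.list(target_tables), length(target_tables) >= 1)
  src_names <- names(target_tables) %||% paste0("source", seq_along(target_tables))
  rows <- lapply(seq_along(target_tables), function(i) {
    tab <- target_tables[[i]]
    if (!all(c("drug_id", "target_gene") %in% names(tab))) {
      stop("target table '", src_names[i], "' needs columns drug_id and target_gene")
    }
    if (nrow(tab) == 0) stop("target table '", src_names[i], "' is empty")
    data.frame(drug_id = normalize_drug_id(tab$drug_id),
               target_gene = trimws(as.character(tab$target_gene)),
               status = if ("status" %in% names(tab)) {
                 tolower(trimws(tab$status))
               } else "approved",
               source = src_names[i], stringsAsFactors = FALSE)
  })
  tg <- do.call(rbind, rows)
  labels$drug_id <- normalize_drug_id(labels$drug_id)

  by_drug <- split(tg, tg$drug_id)
  drug_ids <- names(by_drug)
  status <- vapply(by_drug, function(d) d$status[1], character(1))
  has_status <- status %in% tolower(require_status)
  targets <- lapply(by_drug, function(d) sort(unique(d$target_gene[nzchar(d$target_gene)])))
  has_targets <- lengths(targets) > 0
  lab_idx <- match(drug_ids, labels$drug_id)
  has_label <- !is.na(lab_idx)

  unlabeled_drop <- sum(has_targets & has_status & !has_label)
  status_drop <- sum(has_targets & !has_status)
  # targetless covers empty target sets and labeled drugs never seen in a
  # target table
  targetless_drop <- sum(!has_targets) + sum(!(labels$drug_id %in% drug_ids))

  keep <- has_targets & has_status & has_label
  if (!any(keep)) {
    stop("empty database: no drug has both targets and a toxicity label ",
         "under the required status filter")
  }
  kept_ids <- drug_ids[keep]
  li <- lab_idx[keep]
  df <- data.frame(
    drug_id = kept_ids,
    label = labels$label[li],
    label_sources = labels$label_sources[li],
    target_sources = vapply(by_drug[keep], function(d) {
      paste(sort(unique(d$source)), collapse = ";")
    }, character(1)),
    approval_status = status[keep],
    stringsAsFactors = FALSE)
  rownames(df) <- NULL
  db <- new_drug_db(df, unname(targets[keep]))
  attr(db, "exclusions") <- c(no_label = unlabeled_drop,
                              no_targets = targetless_drop,
                              status = status_drop)
  db
}

#' Extract named toxicity labels from a drug database
#'
#' @param db A `drug_db` table.
#' @return Named character vector (`toxic`/`nontoxic`) keyed by drug id.
#' @export
drug_labels <- function(db) {
  stopifnot(inherits(db, "drug_db"))
  stats::setNames(db$label, db$drug_id)
}

#' Write a drug database as TSV (semicolon-joined target lists)
#'
#' @param db A `drug_db` table.
#' @param path Output file path.
#' @export
write_drug_db <- function(db, path) {
  stopifnot(inherits(db, "drug_db"))
  out <- as.data.frame(db[setdiff(names(db), "targets")])
  out$targets <- vapply(db$targets, paste, character(1), collapse = ";")
  write_tsv_file(out, path)
}

#' Read a drug database written by [write_drug_db()]
#'
#' @param path Input TSV path.
#' @return A `drug_db` table.
#' @export
read_drug_db <- function(path) {
  df <- read_tsv_file(path)
  targets <- strsplit(df$targets, ";", fixed = TRUE)
  new_drug_db(df[setdiff(names(df), "targets")], targets)
}
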