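## Annotation data model: drugs, viruses, drug-virus activities and published
## combinations, plus tab-separated readers/writers. Set-valued cells (routes,
## infected_systems, related_families, target_essential_for) are stored as
## semicolon-delimited strings so that commas in drug names never need quoting.

drug_columns <- c(
  "drug_id", "name", "smiles", "moa_class", "target_kind", "target_name",
  "target_essential_for", "replication_stage", "immunomodulatory", "routes"
)
virus_columns <- c(
  "virus_id", "name", "genus", "family", "related_families",
  "infected_systems", "case_fatality_rate"
)
activity_columns <- c("drug_id", "virus_id", "status", "source")
combination_columns <- c("drug_id_1", "drug_id_2", "virus_id", "published", "source")

#' Assemble and validate an annotation bundle
#'
#' The bundle is the single container every scorer consumes: a drug table, a
#' virus table, a drug-by-virus activity table (absent pairs default to
#' `untested`) and an optional table of published combinations. All enum
#' fields are normalized against [bsa_vocabulary()]; out-of-vocabulary values
#' are recorded as `"unknown"` with a warning, and referential integrity is
#' checked at construction time.
#'
#' @param drugs,viruses,activities Data frames with the documented columns
#'   (missing optional columns are added empty).
#' @param combinations Optional data frame of published two-drug combinations.
#' @return An object of class `annotation_bundle`: a list with elements
#'   `drugs`, `viruses`, `activities`, `combinations`.
#' @seealso [load_bundle()], [write_bundle()]
#' @export
annotation_bundle <- function(drugs, viruses, activities, combinations = NULL) {
  voc <- bsa_vocabulary()
  drugs <- complete_columns(as.data.frame(drugs), drug_columns)
  viruses <- complete_columns(as.data.frame(viruses), virus_columns)
  activities <- complete_columns(as.data.frame(activities), activity_columns)

  drugs$drug_id <- normalize_id(drugs$drug_id)
  if (any(!nzchar(drugs$drug_id))) stop("empty drug_id", call. = FALSE)
  if (anyDuplicated(drugs$drug_id)) {
    stop("duplicate drug_id: ",
         paste(unique(drugs$drug_id[duplicated(drugs$drug_id)]), collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_len(nrow(drugs))) {
    id <- drugs$drug_id[i]
    drugs$moa_class[i] <- normalize_moa(drugs$moa_class[i], voc$moa_class, id)
    drugs$target_kind[i] <- normalize_enum(drugs$target_kind[i], voc$target_kind, "target_kind", id)
    drugs$replication_stage[i] <- normalize_enum(
      drugs$replication_stage[i], voc$replication_stage, "replication_stage", id)
    drugs$immunomodulatory[i] <- normalize_enum(
      drugs$immunomodulatory[i], voc$immunomodulatory, "immunomodulatory", id)
    routes <- normalize_id(split_set(drugs$routes[i]))
    bad <- setdiff(routes, voc$routes)
    if (length(bad)) {
      warning(id, ": route(s) ", paste(bad, collapse = ", "),
              " outside vocabulary, recorded as 'other'", call. = FALSE)
      routes <- unique(c(setdiff(routes, bad), "other"))
    }
    drugs$routes[i] <- join_set(routes)
    drugs$target_essential_for[i] <- join_set(normalize_id(split_set(drugs$target_essential_for[i])))
  }

  viruses$virus_id <- normalize_id(viruses$virus_id)
  if (any(!nzchar(viruses$virus_id))) stop("empty virus_id", call. = FALSE)
  if (anyDuplicated(viruses$virus_id)) {
    stop("duplicate virus_id: ",
         paste(unique(viruses$virus_id[duplicated(viruses$virus_id)]), collapse = ", "),
         call. = FALSE)
  }
  viruses$genus <- normalize_id(viruses$genus)
  viruses$family <- normalize_id(viruses$family)
  if (any(!nzchar(viruses$genus)) || any(!nzchar(viruses$family))) {
    stop("virus genus and family must be non-empty", call. = FALSE)
  }
  for (i in seq_len(nrow(viruses))) {
    id <- viruses$virus_id[i]
    rel <- normalize_id(split_set(viruses$related_families[i]))
    if (viruses$family[i] %in% rel) {
      warning(id, ": family listed in its own related_families, dropped", call. = FALSE)
      rel <- setdiff(rel, viruses$family[i])
    }
    viruses$related_families[i] <- join_set(rel)
    sys <- normalize_id(split_set(viruses$infected_systems[i]))
    bad <- setdiff(sys, voc$infected_systems)
    if (length(bad)) {
      warning(id, ": infected_systems value(s) ", paste(bad, collapse = ", "),
              " outside vocabulary, dropped", call. = FALSE)
      sys <- setdiff(sys, bad)
    }
    if (!length(sys)) stop(id, ": infected_systems must be non-empty", call. = FALSE)
    viruses$infected_systems[i] <- join_set(sys)
  }
  viruses$case_fatality_rate <- suppressWarnings(as.numeric(viruses$case_fatality_rate))
  cfr <- viruses$case_fatality_rate
  if (any(!is.na(cfr) & (cfr < 0 | cfr > 1))) {
    stop("case_fatality_rate must lie in [0, 1]", call. = FALSE)
  }

  activities$drug_id <- normalize_id(activities$drug_id)
  activities$virus_id <- normalize_id(activities$virus_id)
  if (nrow(activities)) {
    key <- paste(activities$drug_id, activities$virus_id)
    if (anyDuplicated(key)) {
      stop("duplicate (drug_id, virus_id) activity rows: ",
           paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
    }
    for (i in seq_len(nrow(activities))) {
      activities$status[i] <- normalize_activity_status(
        activities$status[i], voc$activity_status,
        paste(activities$drug_id[i], activities$virus_id[i]))
    }
    check_foreign("activities", activities$drug_id, drugs$drug_id, "drug_id")
    check_foreign("activities", activities$virus_id, viruses$virus_id, "virus_id")
  }

  if (!is.null(combinations)) {
    combinations <- complete_columns(as.data.frame(combinations), combination_columns)
    if (nrow(combinations)) {
      for (i in seq_len(nrow(combinations))) {
        pr <- canonical_pair(combinations$drug_id_1[i], combinations$drug_id_2[i])
        combinations$drug_id_1[i] <- pr[1]
        combinations$drug_id_2[i] <- pr[2]
      }
      combinations$virus_id <- normalize_id(combinations$virus_id)
      combinations$published <- as.logical(combinations$published)
      combinations$published[is.na(combinations$published)] <- TRUE
      key <- paste(combinations$drug_id_1, combinations$drug_id_2, combinations$virus_id)
      combinations <- combinations[!duplicated(key), , drop = FALSE]
      check_foreign("combinations", combinations$drug_id_1, drugs$drug_id, "drug_id_1")
      check_foreign("combinations", combinations$drug_id_2, drugs$drug_id, "drug_id_2")
      check_foreign("combinations", combinations$virus_id, viruses$virus_id, "virus_id")
    }
  }

  structure(
    list(drugs = drugs, viruses = viruses, activities = activities,
         combinations = combinations),
    class = "annotation_bundle"
  )
}

normalize_activity_status <- function(x, vocab, id) {
  x <- trimws(tolower(as.character(x)))
  if (length(x) != 1L || is.na(x) || !nzchar(x)) return("untested")
  if (!x %in% vocab) {
    warning(id, ": unknown activity status '", x, "' recorded as 'untested'",
            call. = FALSE)
    x <- "untested"
  }
  x
}

complete_columns <- function(df, cols) {
  for (cl in setdiff(cols, names(df))) df[[cl]] <- rep("", nrow(df))
  for (cl in cols) {
    if (!is.character(df[[cl]]) && cl != "published") df[[cl]] <- as.character(df[[cl]])
    df[[cl]][is.na(df[[cl]])] <- ""
  }
  rownames(df) <- NULL
  df[, cols, drop = FALSE]
}

check_foreign <- function(table, keys, universe, field) {
  bad <- which(!keys %in% universe)
  if (length(bad)) {
    stop(sprintf("%s: %s value(s) not found in parent table (rows %s): %s",
                 table, field, paste(bad, collapse = ", "),
                 paste(unique(keys[bad]), collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.annotation_bundle <- function(x, ...) {
  cat(sprintf("annotation_bundle: %d drugs, %d viruses, %d activity records%s\n",
              nrow(x$drugs), nrow(x$viruses), nrow(x$activities),
              if (is.null(x$combinations)) ""
              else sprintf(", %d combinations", nrow(x$combinations))))
  invisible(x)
}

#' Load an annotation bundle from delimited files
#'
#' Reads the drug, virus and activity tables (and, when present, the
#' combinations table) and validates them into an [annotation_bundle()].
#' Headers are matched case-insensitively; the field separator defaults to tab
#' and may be set to comma via `sep`.
#'
#' @param drugs,viruses,activities Paths to the three required tables. When
#'   only `drugs` is given and is a directory, the conventional file names
#'   `drugs.tsv`, `viruses.tsv`, `activities.tsv`, `combinations.tsv` under it
#'   are used.
#' @param combinations Optional path to a combinations table.
#' @param sep Field separator, `"\t"` (default) or `","`.
#' @return A validated `annotation_bundle`.
#' @examples
#' dir <- tempfile(); b <- ebov_fixture()
#' write_bundle(b, dir)
#' b2 <- load_bundle(dir)
#' @export
load_bundle <- function(drugs, viruses = NULL, activities = NULL,
                        combinations = NULL, sep = "\t") {
  if (is.null(viruses) && length(drugs) == 1L && dir.exists(drugs)) {
    dir <- drugs
    drugs <- file.path(dir, "drugs.tsv")
    viruses <- file.path(dir, "viruses.tsv")
    activities <- file.path(dir, "activities.tsv")
    cmb <- file.path(dir, "combinations.tsv")
    combinations <- if (file.exists(cmb)) cmb else NULL
  }
  annotation_bundle(
    drugs = read_annotation_table(drugs, drug_columns, sep),
    viruses = read_annotation_table(viruses, virus_columns, sep),
    activities = read_annotation_table(activities, activity_columns, sep),
    combinations = if (!is.null(combinations)) {
      read_annotation_table(combinations, combination_columns, sep)
    }
  )
}

read_annotation_table <- function(path, cols, sep = "\t") {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  df <- utils::read.delim(path, sep = sep, header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          quote = "", na.strings = NULL, fileEncoding = "UTF-8")
  names(df) <- tolower(trimws(names(df)))
  missing <- setdiff(setdiff(cols, c("smiles", "target_name", "source", "case_fatality_rate")),
                     names(df))
  missing <- setdiff(missing, names(df))
  if (length(missing)) {
    stop(basename(path), ": missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

#' Write an annotation bundle to a directory
#'
#' Serializes the bundle as UTF-8 tab-separated files (`drugs.tsv`,
#' `viruses.tsv`, `activities.tsv`, plus `combinations.tsv` when present).
#' Writing then reloading a valid bundle reproduces it field for field.
#'
#' @param bundle An `annotation_bundle`.
#' @param directory Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_bundle <- function(bundle, directory) {
  stopifnot(inherits(bundle, "annotation_bundle"))
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory: ", directory, call. = FALSE)
  }
  paths <- c(
    drugs = file.path(directory, "drugs.tsv"),
    viruses = file.path(directory, "viruses.tsv"),
    activities = file.path(directory, "activities.tsv")
  )
  write_tsv_utf8(bundle$drugs, paths[["drugs"]])
  vir <- bundle$viruses
  vir$case_fatality_rate <- ifelse(is.na(vir$case_fatality_rate), "",
                                   format(vir$case_fatality_rate, trim = TRUE))
  write_tsv_utf8(vir, paths[["viruses"]])
  write_tsv_utf8(bundle$activities, paths[["activities"]])
  if (!is.null(bundle$combinations)) {
    cmb <- bundle$combinations
    cmb$published <- ifelse(cmb$published, "true", "false")
    paths <- c(paths, combinations = file.path(directory, "combinations.tsv"))
    write_tsv_utf8(cmb, paths[["combinations"]])
  }
  invisible(paths)
}

write_tsv_utf8 <- function(df, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

#' Development status of a drug-virus pair
#'
#' Absent pairs default to `"untested"`.
#'
#' @param bundle An `annotation_bundle`.
#' @param drug_id,virus_id Identifiers (normalized internally).
#' @return A status string from `bsa_vocabulary()$activity_status`.
#' @export
activity_status <- function(bundle, drug_id, virus_id) {
  drug_id <- normalize_id(drug_id)
  virus_id <- normalize_id(virus_id)
  a <- bundle$activities
  hit <- which(a$drug_id == drug_id & a$virus_id == virus_id)
  if (!length(hit)) "untested" else a$status[hit[1]]
}

get_drug <- function(bundle, drug_id) {
  drug_id <- normalize_id(drug_id)
  i <- match(drug_id, bundle$drugs$drug_id)
  if (is.na(i)) stop("unknown drug_id: ", drug_id, call. = FALSE)
  bundle$drugs[i, , drop = FALSE]
}

get_virus <- function(bundle, virus_id) {
  virus_id <- normalize_id(virus_id)
  i <- match(virus_id, bundle$viruses$virus_id)
  if (is.na(i)) stop("unknown virus_id: ", virus_id, call. = FALSE)
  bundle$viruses[i, , drop = FALSE]
}
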