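## Taxonomy-based virus relatedness (the C_Phyl ladder) and activity-gap
## prediction: untested drug-virus pairs made plausible by recorded activity
## against a taxonomic relative.

.relation_levels <- c("related_family", "same_family", "same_genus")

#' Taxonomic relation between two viruses
#'
#' `same_genus` when genera match; `same_family` when families match but
#' genera differ; `related_family` when either virus lists the other's family
#' among its `related_families`; `NA` otherwise. The corresponding C_Phyl
#' values are 1, 0.5 and 0.25.
#'
#' @param voi,other One-row virus annotations.
#' @return `"same_genus"`, `"same_family"`, `"related_family"` or `NA`.
#' @export
virus_relation <- function(voi, other) {
  g1 <- normalize_id(voi$genus); g2 <- normalize_id(other$genus)
  f1 <- normalize_id(voi$family); f2 <- normalize_id(other$family)
  if (identical(g1, g2)) return("same_genus")
  if (identical(f1, f2)) return("same_family")
  rel_voi <- normalize_id(split_set(voi$related_families))
  rel_other <- normalize_id(split_set(other$related_families))
  if (f2 %in% rel_voi || f1 %in% rel_other) return("related_family")
  NA_character_
}

#' C_Phyl value implied by a relation
#'
#' @param relation Relation string from [virus_relation()].
#' @return 1, 0.5 or 0.25 (0 for `NA`).
#' @export
relation_cphyl <- function(relation) {
  ifelse(is.na(relation), 0, unname(.phyl_ladder[relation]))
}

#' Predict activity gaps from taxonomic relatedness
#'
#' For every drug and every virus the drug has no (non-untested) record
#' against, reports the pair when the drug has qualifying activity against at
#' least one taxonomic relative at or above `min_relation`. Each prediction
#' carries the strongest available relation, the evidence virus realizing it,
#' and the implied C_Phyl value.
#'
#' @param bundle An `annotation_bundle`.
#' @param min_relation Weakest relation that still counts
#'   (`"related_family"` < `"same_family"` < `"same_genus"`).
#' @param statuses Which evidence statuses qualify (default: every
#'   non-untested status; restrict to e.g. exclude in-vitro-only evidence).
#' @return Data frame with columns `drug_id`, `virus_id`,
#'   `evidence_virus_id`, `relation`, `implied_c_phyl`, ordered by
#'   (`drug_id`, `virus_id`).
#' @export
find_activity_gaps <- function(bundle,
                               min_relation = c("related_family", "same_family", "same_genus"),
                               statuses = setdiff(bsa_vocabulary()$activity_status, "untested")) {
  min_relation <- match.arg(min_relation)
  min_rank <- match(min_relation, .relation_levels)
  a <- bundle$activities
  a <- a[a$status %in% statuses, , drop = FALSE]
  out <- list()
  for (drug_id in sort(unique(a$drug_id), method = "radix")) {
    evidence_ids <- unique(a$virus_id[a$drug_id == drug_id])
    tested_ids <- unique(bundle$activities$virus_id[
      bundle$activities$drug_id == drug_id & bundle$activities$status != "untested"])
    candidates <- setdiff(bundle$viruses$virus_id, tested_ids)
    for (vid in sort(candidates, method = "radix")) {
      voi <- get_virus(bundle, vid)
      best_rank <- 0L
      best_evidence <- NA_character_
      for (eid in sort(evidence_ids, method = "radix")) {
        rel <- virus_relation(voi, get_virus(bundle, eid))
        r <- if (is.na(rel)) 0L else match(rel, .relation_levels)
        if (r > best_rank) {
          best_rank <- r
          best_evidence <- eid
        }
      }
      if (best_rank >= min_rank) {
        relation <- .relation_levels[best_rank]
        out[[length(out) + 1L]] <- data.frame(
          drug_id = drug_id, virus_id = vid, evidence_virus_id = best_evidence,
          relation = relation, implied_c_phyl = relation_cphyl(relation),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(out)) {
    return(data.frame(drug_id = character(0), virus_id = character(0),
                      evidence_virus_id = character(0), relation = character(0),
                      implied_c_phyl = numeric(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Count drugs active against each subset of a family's viruses
#'
#' For Venn-style summaries of activity overlap within a virus family: for
#' every non-empty subset of the family's viruses, the number of drugs whose
#' qualifying activity within the family covers exactly that subset.
#'
#' @param bundle An `annotation_bundle`.
#' @param family Virus family name.
#' @param viruses Optional explicit virus ids (required when the family has
#'   more than 5 viruses; subsets grow combinatorially).
#' @param statuses Which statuses count as activity (default non-untested).
#' @return Data frame with columns `viruses` (semicolon-joined subset),
#'   `n_viruses` and `n_drugs`; subset counts sum to the number of drugs with
#'   at least one qualifying activity among the selected viruses.
#' @export
activity_overlap_counts <- function(bundle, family, viruses = NULL,
                                    statuses = setdiff(bsa_vocabulary()$activity_status, "untested")) {
  family <- normalize_id(family)
  fam_viruses <- bundle$viruses$virus_id[bundle$viruses$family == family]
  if (!length(fam_viruses)) stop("no viruses in family: ", family, call. = FALSE)
  if (is.null(viruses)) {
    if (length(fam_viruses) > 5L) {
      stop("family has ", length(fam_viruses),
           " viruses; pass an explicit `viruses` list of at most 5", call. = FALSE)
    }
    viruses <- fam_viruses
  } else {
    viruses <- normalize_id(viruses)
    bad <- setdiff(viruses, fam_viruses)
    if (length(bad)) stop("not in family ", family, ": ",
                          paste(bad, collapse = ", "), call. = FALSE)
    if (length(viruses) > 5L) stop("at most 5 viruses per overlap diagram", call. = FALSE)
  }
  viruses <- sort(unique(viruses), method = "radix")

  a <- bundle$activities
  a <- a[a$status %in% statuses & a$virus_id %in% viruses, , drop = FALSE]
  profile <- vapply(
    split(a$virus_id, a$drug_id),
    function(v) paste(sort(unique(v), method = "radix"), collapse = ";"),
    character(1)
  )

  k <- length(viruses)
  subsets <- lapply(seq_len(2^k - 1L), function(m) viruses[bitwAnd(m, 2^(seq_len(k) - 1L)) > 0])
  keys <- vapply(subsets, paste, character(1), collapse = ";")
  data.frame(
    viruses = keys,
    n_viruses = lengths(subsets),
    n_drugs = vapply(keys, function(kk) sum(profile == kk), numeric(1), USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
}
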