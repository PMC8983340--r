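## Six-component additive score for a broad-spectrum antiviral (BSA) against a
## virus of interest (Voi):
##
##   BSA score = C_SAR + C_DDS + C_TR + C_IC + C_RoA + C_Phyl
##
## All components are dyadic rationals, so totals are exact in floating point.

#' Structural/developmental identity component (C_SAR)
#'
#' 1 when the drug itself has been developed or tested against the virus of
#' interest (any non-untested activity record); 0.5 when it has no record but
#' is structurally similar (at the configured Tanimoto threshold) to a drug
#' that has one; 0 otherwise. Requesting the similarity tier for a drug whose
#' structure the provider does not know degrades to 0 with a warning rather
#' than an error.
#'
#' @param drug_id Drug id.
#' @param virus_id Virus of interest.
#' @param bundle An `annotation_bundle`.
#' @param similarity Optional similarity provider from
#'   [similarity_provider()]; without one the 0.5 tier is unreachable.
#' @return List with `value` and a `note` describing the rule that fired.
#' @export
score_sar <- function(drug_id, virus_id, bundle, similarity = NULL) {
  drug_id <- normalize_id(drug_id)
  virus_id <- normalize_id(virus_id)
  status <- activity_status(bundle, drug_id, virus_id)
  if (status != "untested") {
    return(list(value = 1,
                note = sprintf("C_SAR=1: drug has a '%s' record against %s", status, virus_id)))
  }
  a <- bundle$activities
  developed <- setdiff(unique(a$drug_id[a$virus_id == virus_id & a$status != "untested"]),
                       drug_id)
  if (!is.null(similarity) && length(developed)) {
    hit <- similarity(drug_id, developed)
    if (isTRUE(hit$similar)) {
      return(list(value = 0.5,
                  note = sprintf("C_SAR=0.5: structurally similar to %s (tanimoto %.3f >= %.2f)",
                                 hit$match, hit$similarity, hit$threshold)))
    }
  }
  list(value = 0, note = sprintf("C_SAR=0: no record and no qualifying structural similarity for %s", virus_id))
}

#' Development-status component (C_DDS)
#'
#' Ladder over the drug-virus development status: approved or phase 4 -> 1,
#' phase 1-3 -> 0.75, in vivo -> 0.5, in vitro -> 0.25, untested -> 0. The
#' component only applies to drugs with C_SAR = 1 and is forced to 0
#' otherwise.
#'
#' @param status Activity status string.
#' @param c_sar The C_SAR value already computed for the same pair.
#' @return Numeric component value.
#' @export
score_dds <- function(status, c_sar) {
  status <- match.arg(status, names(.dds_ladder))
  if (!isTRUE(all.equal(c_sar, 1))) return(0)
  unname(.dds_ladder[status])
}

#' Target-relevance component (C_TR)
#'
#' 1 when the drug's confirmed primary target is annotated as essential for
#' replication of the virus of interest (explicit, per-virus evidence in
#' `target_essential_for`); 0 otherwise.
#'
#' @param drug One-row drug annotation.
#' @param virus_id Virus of interest.
#' @return 0 or 1.
#' @export
score_tr <- function(drug, virus_id) {
  essential <- split_set(drug$target_essential_for)
  if (normalize_id(virus_id) %in% essential) 1 else 0
}

#' Immunomodulation component (C_IC)
#'
#' 1 when the drug does not interfere with the host immune response; 0 when it
#' is immunomodulatory. Unreported status scores 1: not-reported is
#' distinguished from a positive finding.
#'
#' @param drug One-row drug annotation.
#' @return 0 or 1.
#' @export
score_ic <- function(drug) {
  if (identical(drug$immunomodulatory, "yes")) 0 else 1
}

#' Route-of-administration suitability component (C_RoA)
#'
#' 1 when at least one of the drug's routes is suited to at least one organ
#' system the virus infects (union over the virus's infected systems under the
#' configured suitability map); 0 otherwise. A drug with no annotated route
#' scores 0 with a warning.
#'
#' @param drug One-row drug annotation.
#' @param virus One-row virus annotation.
#' @param suitability Organ-system to route map, see
#'   [default_route_suitability()].
#' @return 0 or 1.
#' @export
score_roa <- function(drug, virus, suitability = default_route_suitability()) {
  routes <- split_set(drug$routes)
  if (!length(routes)) {
    warning(drug$drug_id, ": no routes annotated; C_RoA scored 0", call. = FALSE)
    return(0)
  }
  systems <- split_set(virus$infected_systems)
  missing <- setdiff(systems, names(suitability))
  if (length(missing)) {
    stop("route suitability map lacks organ system(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  suitable <- unique(unlist(suitability[systems], use.names = FALSE))
  if (length(intersect(routes, suitable))) 1 else 0
}

#' Phylogenetic proximity component (C_Phyl)
#'
#' Taxonomic relation of the virus of interest to the viruses the drug has
#' been developed or tested against (its non-untested activity records): same
#' genus -> 1, same family -> 0.5, closely related family (explicit
#' `related_families` adjacency, in either direction) -> 0.25, otherwise 0.
#' With several reference viruses the maximum applies.
#'
#' @param voi One-row virus annotation for the virus of interest.
#' @param references Virus annotation table of reference viruses (may have
#'   zero rows, giving 0).
#' @return Component value in `{1, 0.5, 0.25, 0}`.
#' @export
score_phyl <- function(voi, references) {
  if (is.null(references) || nrow(references) == 0L) return(0)
  best <- 0
  for (i in seq_len(nrow(references))) {
    rel <- virus_relation(voi, references[i, , drop = FALSE])
    v <- if (is.na(rel)) 0 else unname(.phyl_ladder[rel])
    if (v > best) best <- v
  }
  best
}

#' Compute the full six-component BSA score
#'
#' Applies the six component rules to one drug against one virus of interest
#' and sums them. Manual per-component overrides supplied in
#' `config$overrides$bsa[[drug_id]][[virus_id]]` replace the computed values
#' and are recorded in the provenance.
#'
#' @param drug_id Drug id.
#' @param virus_id Virus of interest.
#' @param bundle An `annotation_bundle`.
#' @param config A [run_config()].
#' @param similarity Optional similarity provider for the C_SAR = 0.5 tier; by
#'   default the provider attached to the bundle (if any) is used.
#' @return A `bsa_breakdown`: list with `drug_id`, `virus_id`, `components`
#'   (named numeric of the six values), `total`, and `provenance` (one note
#'   per component).
#' @examples
#' b <- ebov_fixture()
#' compute_bsa_score("merimepodib", "ebov", b)
#' @export
compute_bsa_score <- function(drug_id, virus_id, bundle,
                              config = run_config(), similarity = NULL) {
  drug_id <- normalize_id(drug_id)
  virus_id <- normalize_id(virus_id)
  drug <- get_drug(bundle, drug_id)
  voi <- get_virus(bundle, virus_id)
  if (is.null(similarity)) similarity <- attr(bundle, "similarity")

  sar <- score_sar(drug_id, virus_id, bundle, similarity)
  status <- activity_status(bundle, drug_id, virus_id)
  dds <- score_dds(status, sar$value)
  refs <- reference_viruses(bundle, drug_id)

  comp <- c(
    c_sar = sar$value,
    c_dds = dds,
    c_tr = score_tr(drug, virus_id),
    c_ic = score_ic(drug),
    c_roa = score_roa(drug, voi, config$route_suitability),
    c_phyl = score_phyl(voi, refs)
  )
  prov <- c(
    sar$note,
    sprintf("C_DDS=%g: status '%s'%s", comp[["c_dds"]], status,
            if (sar$value != 1) " (gated: C_SAR != 1)" else ""),
    sprintf("C_TR=%g: target %s annotated essential for %s", comp[["c_tr"]],
            if (comp[["c_tr"]] == 1) "is" else "is not", virus_id),
    sprintf("C_IC=%g: immunomodulatory '%s'", comp[["c_ic"]], drug$immunomodulatory),
    sprintf("C_RoA=%g: routes {%s} vs systems {%s}", comp[["c_roa"]],
            drug$routes, voi$infected_systems),
    sprintf("C_Phyl=%g: reference viruses {%s}", comp[["c_phyl"]],
            paste(refs$virus_id, collapse = ","))
  )

  ov <- bsa_override(config, drug_id, virus_id)
  if (!is.null(ov)) {
    ov <- unlist(ov)
    bad <- setdiff(names(ov), names(comp))
    if (length(bad)) stop("unknown BSA component override(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    for (nm in names(ov)) {
      comp[[nm]] <- as.numeric(ov[[nm]])
      prov <- c(prov, sprintf("override: %s=%g (manual)", nm, comp[[nm]]))
    }
  }
  check_components(comp)

  structure(
    list(drug_id = drug_id, virus_id = virus_id, components = comp,
         total = sum(comp), provenance = prov),
    class = "bsa_breakdown"
  )
}

## Viruses against which the drug has any non-untested record.
reference_viruses <- function(bundle, drug_id) {
  a <- bundle$activities
  ids <- unique(a$virus_id[a$drug_id == drug_id & a$status != "untested"])
  bundle$viruses[bundle$viruses$virus_id %in% ids, , drop = FALSE]
}

check_components <- function(comp) {
  allowed <- list(
    c_sar = c(1, 0.5, 0), c_dds = c(1, 0.75, 0.5, 0.25, 0),
    c_tr = c(1, 0), c_ic = c(1, 0), c_roa = c(1, 0),
    c_phyl = c(1, 0.5, 0.25, 0)
  )
  for (nm in names(allowed)) {
    if (!comp[[nm]] %in% allowed[[nm]]) {
      stop(sprintf("component %s=%g outside its enumerated set", nm, comp[[nm]]),
           call. = FALSE)
    }
  }
  if (comp[["c_dds"]] > 0 && comp[["c_sar"]] != 1) {
    stop("C_DDS > 0 requires C_SAR = 1", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.bsa_breakdown <- function(x, ...) {
  cat(sprintf("BSA score: %s vs %s\n", x$drug_id, x$virus_id))
  comp <- x$components
  cat(sprintf("  C_SAR=%g C_DDS=%g C_TR=%g C_IC=%g C_RoA=%g C_Phyl=%g\n",
              comp[["c_sar"]], comp[["c_dds"]], comp[["c_tr"]],
              comp[["c_ic"]], comp[["c_roa"]], comp[["c_phyl"]]))
  cat(sprintf("  total: %s\n", display_score(x$total, 2)))
  invisible(x)
}
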