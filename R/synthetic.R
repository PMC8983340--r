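## Seeded synthetic annotation-bundle generator for property-based testing.
## Generation is a pure function of the spec (seed included); the caller's RNG
## state is left untouched.

#' Specification for a synthetic annotation bundle
#'
#' @param n_drugs,n_viruses Positive table sizes.
#' @param family_count Number of virus families to spread the viruses over.
#' @param activity_density Probability that any given drug-virus pair carries
#'   a (non-untested) activity record. The default 0.15 emulates a sparsely
#'   tested drug-virus matrix, the typical situation for repurposing panels.
#' @param immunomodulatory_rate Probability that a drug is annotated
#'   immunomodulatory (default 0.3).
#' @param seed Integer seed; identical `(spec, seed)` give identical bundles.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_drugs, n_viruses, family_count = 3L,
                           activity_density = 0.15,
                           immunomodulatory_rate = 0.3, seed = 1L) {
  stopifnot(
    n_drugs >= 1, n_viruses >= 1, family_count >= 1,
    activity_density >= 0, activity_density <= 1,
    immunomodulatory_rate >= 0, immunomodulatory_rate <= 1
  )
  structure(
    list(n_drugs = as.integer(n_drugs), n_viruses = as.integer(n_viruses),
         family_count = as.integer(family_count),
         activity_density = activity_density,
         immunomodulatory_rate = immunomodulatory_rate,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

## Simple, guaranteed-parseable structures for synthetic drugs.
.synthetic_smiles <- c(
  "CCO", "CCCO", "CCCCO", "CC(C)O", "CCN", "CCC(=O)O", "c1ccccc1",
  "Cc1ccccc1", "Oc1ccccc1", "Nc1ccccc1", "c1ccncc1", "CC(=O)Nc1ccccc1",
  "C1CCCCC1", "C1CCOC1", "CC(C)CC(=O)O", "COc1ccccc1"
)

#' Generate a reproducible synthetic annotation bundle
#'
#' Viruses are assigned to families and genera (families carry a sparse
#' "closely related" adjacency, mirrored on both sides), drugs draw their
#' mechanism class, target kind, replication stage, immunomodulatory flag,
#' routes and a simple parseable structure from the package vocabularies, and
#' activities are sampled per drug-virus pair at `activity_density`.
#'
#' @param spec A [synthetic_spec()].
#' @return A validated `annotation_bundle`.
#' @examples
#' b <- generate_bundle(synthetic_spec(6, 4, seed = 7))
#' @export
generate_bundle <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  voc <- bsa_vocabulary()
  with_local_seed(spec$seed, {
    families <- paste0("fam", seq_len(spec$family_count))
    related <- stats::setNames(vector("list", length(families)), families)
    if (length(families) >= 2L) {
      for (f in families) {
        others <- setdiff(families, f)
        pick <- others[stats::runif(length(others)) < 0.3]
        related[[f]] <- union(related[[f]], pick)
        for (p in pick) related[[p]] <- union(related[[p]], f)
      }
    }
    vir_family <- sample(families, spec$n_viruses, replace = TRUE)
    ## ~2 genera per family so same-family/different-genus pairs occur
    vir_genus <- paste0(vir_family, "_g", sample(1:2, spec$n_viruses, replace = TRUE))
    viruses <- data.frame(
      virus_id = sprintf("virus%02d", seq_len(spec$n_viruses)),
      name = sprintf("Virus %02d", seq_len(spec$n_viruses)),
      genus = vir_genus,
      family = vir_family,
      related_families = vapply(vir_family, function(f) join_set(related[[f]]), character(1)),
      infected_systems = vapply(seq_len(spec$n_viruses), function(i) {
        join_set(sample(voc$infected_systems, sample(1:2, 1)))
      }, character(1)),
      case_fatality_rate = format(round(stats::runif(spec$n_viruses, 0, 0.9), 3)),
      stringsAsFactors = FALSE
    )

    drug_ids <- sprintf("drug%02d", seq_len(spec$n_drugs))
    drugs <- data.frame(
      drug_id = drug_ids,
      name = sprintf("Drug %02d", seq_len(spec$n_drugs)),
      smiles = sample(.synthetic_smiles, spec$n_drugs, replace = TRUE),
      moa_class = sample(voc$moa_class, spec$n_drugs, replace = TRUE),
      target_kind = sample(voc$target_kind, spec$n_drugs, replace = TRUE,
                           prob = c(0.45, 0.35, 0.1, 0.1)),
      target_name = "synthetic target",
      target_essential_for = vapply(seq_len(spec$n_drugs), function(i) {
        n <- stats::rbinom(1, min(2L, spec$n_viruses), 0.4)
        join_set(sample(viruses$virus_id, n))
      }, character(1)),
      replication_stage = sample(voc$replication_stage, spec$n_drugs,
                                 replace = TRUE, prob = c(0.2, 0.5, 0.1, 0.2)),
      immunomodulatory = ifelse(
        stats::runif(spec$n_drugs) < spec$immunomodulatory_rate, "yes",
        sample(c("no", "unknown"), spec$n_drugs, replace = TRUE)),
      routes = vapply(seq_len(spec$n_drugs), function(i) {
        join_set(sample(setdiff(voc$routes, "other"), sample(1:2, 1)))
      }, character(1)),
      stringsAsFactors = FALSE
    )

    grid <- expand.grid(drug_id = drug_ids, virus_id = viruses$virus_id,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    keep <- stats::runif(nrow(grid)) < spec$activity_density
    activities <- grid[keep, , drop = FALSE]
    statuses <- setdiff(voc$activity_status, "untested")
    activities$status <- if (nrow(activities)) {
      sample(statuses, nrow(activities), replace = TRUE)
    } else character(0)
    activities$source <- if (nrow(activities)) "synthetic" else character(0)

    annotation_bundle(drugs, viruses, activities)
  })
}

## Evaluate `expr` under a fixed seed without disturbing the caller's RNG.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
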