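# Small hand-built bundles and fingerprint constructors used across tests.

toy_bundle <- function(combinations = NULL) {
  drugs <- data.frame(
    drug_id = c("alpha", "beta", "gamma"),
    name = c("Alpha", "Beta", "Gamma"),
    smiles = "",
    moa_class = c("nucleoside_analog", "nucleoside_analog", "protease_inhibitor"),
    target_kind = c("virus", "virus", "host"),
    target_name = "",
    target_essential_for = c("v1", "", ""),
    replication_stage = c("replication", "replication", "entry"),
    immunomodulatory = c("no", "unknown", "yes"),
    routes = c("oral", "oral;intravenous", "topical"),
    stringsAsFactors = FALSE
  )
  viruses <- data.frame(
    virus_id = c("v1", "v2", "v3"),
    name = c("V1", "V2", "V3"),
    genus = c("g1", "g2", "g3"),
    family = c("famA", "famA", "famB"),
    related_families = c("", "", "famc"),
    infected_systems = c("multiple", "respiratory", "digestive"),
    case_fatality_rate = "",
    stringsAsFactors = FALSE
  )
  activities <- data.frame(
    drug_id = c("alpha", "alpha", "beta"),
    virus_id = c("v1", "v2", "v1"),
    status = c("approved_or_phase4", "in_vitro", "phase1_3"),
    source = "",
    stringsAsFactors = FALSE
  )
  annotation_bundle(drugs, viruses, activities, combinations)
}

get_drug_row <- function(bundle, id) {
  bundle$drugs[bundle$drugs$drug_id == id, , drop = FALSE]
}

# Fingerprint with an explicit bit set (bypasses chemistry for set-algebra and
# clustering tests).
raw_fp <- function(id, bits, n_bits = 2048L) {
  structure(list(drug_id = id, bits = sort(unique(as.integer(bits))),
                 n_bits = as.integer(n_bits), radius = 2L),
            class = "fingerprint")
}

random_fp_set <- function(n, seed, n_bits = 256L) {
  set.seed(seed)
  fps <- lapply(seq_len(n), function(i) {
    raw_fp(sprintf("cpd%02d", i), sample(0:(n_bits - 1L), sample(8:40, 1)), n_bits)
  })
  names(fps) <- vapply(fps, function(f) f$drug_id, character(1))
  fps
}
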