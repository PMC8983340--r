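# Independent brute-force re-derivation of the scoring rules, written straight
# from the rule text against the raw annotation tables. Deliberately shares no
# code with the package internals beyond the public table layout.

o_split <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  trimws(strsplit(x, ";", fixed = TRUE)[[1]])
}

o_status <- function(bundle, drug, virus) {
  a <- bundle$activities
  i <- which(a$drug_id == drug & a$virus_id == virus)
  if (length(i)) a$status[i[1]] else "untested"
}

o_relation_value <- function(v1, v2) {
  if (v1$genus == v2$genus) return(1)
  if (v1$family == v2$family) return(0.5)
  if (v2$family %in% o_split(v1$related_families) ||
      v1$family %in% o_split(v2$related_families)) return(0.25)
  0
}

o_suitable_routes <- function(systems, suitability) {
  unique(unlist(suitability[systems], use.names = FALSE))
}

# similar_pairs: list of length-2 id vectors declared structurally similar.
oracle_bsa <- function(drug_id, virus_id, bundle, suitability,
                       similar_pairs = NULL) {
  drow <- bundle$drugs[bundle$drugs$drug_id == drug_id, ]
  vrow <- bundle$viruses[bundle$viruses$virus_id == virus_id, ]
  status <- o_status(bundle, drug_id, virus_id)

  c_sar <- 0
  if (status != "untested") {
    c_sar <- 1
  } else if (!is.null(similar_pairs)) {
    a <- bundle$activities
    developed <- unique(a$drug_id[a$virus_id == virus_id & a$status != "untested"])
    for (p in similar_pairs) {
      partner <- setdiff(p, drug_id)
      if (drug_id %in% p && length(partner) && any(partner %in% developed)) {
        c_sar <- 0.5
        break
      }
    }
  }

  ladder <- c(approved_or_phase4 = 1, phase1_3 = 0.75, in_vivo = 0.5,
              in_vitro = 0.25, untested = 0)
  c_dds <- if (c_sar == 1) ladder[[status]] else 0
  c_tr <- as.numeric(virus_id %in% o_split(drow$target_essential_for))
  c_ic <- if (drow$immunomodulatory == "yes") 0 else 1
  routes <- o_split(drow$routes)
  suitable <- o_suitable_routes(o_split(vrow$infected_systems), suitability)
  c_roa <- as.numeric(length(intersect(routes, suitable)) > 0)

  a <- bundle$activities
  refs <- unique(a$virus_id[a$drug_id == drug_id & a$status != "untested"])
  c_phyl <- 0
  for (r in refs) {
    rv <- bundle$viruses[bundle$viruses$virus_id == r, ]
    c_phyl <- max(c_phyl, o_relation_value(vrow, rv))
  }

  comp <- c(c_sar = c_sar, c_dds = c_dds, c_tr = c_tr, c_ic = c_ic,
            c_roa = c_roa, c_phyl = c_phyl)
  list(components = comp, total = sum(comp))
}

oracle_bcc <- function(drug_a, drug_b, virus_id, bundle, suitability,
                       similar_pairs = NULL, margin = 5) {
  ids <- sort(c(drug_a, drug_b))
  d1 <- bundle$drugs[bundle$drugs$drug_id == ids[1], ]
  d2 <- bundle$drugs[bundle$drugs$drug_id == ids[2], ]
  vrow <- bundle$viruses[bundle$viruses$virus_id == virus_id, ]

  k_di <- if (d1$moa_class == d2$moa_class) 0.5 else 1
  kinds <- c(d1$target_kind, d2$target_kind)
  if (any(kinds == "unknown")) {
    k_dti <- 1.0
  } else {
    kinds[kinds == "both"] <- "host"
    nv <- sum(kinds == "virus")
    k_dti <- if (nv == 2) 1.2 else if (nv == 1) 1.1 else 1.0
  }
  k_drs <- if (d1$replication_stage == d2$replication_stage &&
               d1$replication_stage != "unknown") 1.2 else 1.0
  r1 <- o_split(d1$routes); r2 <- o_split(d2$routes)
  shared <- intersect(r1, r2)
  if (!length(r1) || !length(r2) || !length(shared)) {
    k_roa <- 0.8
  } else {
    suitable <- o_suitable_routes(o_split(vrow$infected_systems), suitability)
    k_roa <- if (length(intersect(shared, suitable))) 1.2 else 1.0
  }

  s1 <- oracle_bsa(ids[1], virus_id, bundle, suitability, similar_pairs)$total
  s2 <- oracle_bsa(ids[2], virus_id, bundle, suitability, similar_pairs)$total
  bsa_sum <- s1 + s2
  bcc <- k_di * k_dti * k_drs * k_roa * bsa_sum
  list(k = c(k_di = k_di, k_dti = k_dti, k_drs = k_drs, k_roa = k_roa),
       bsa_sum = bsa_sum, bcc_score = bcc, delta = bcc - bsa_sum,
       effective = (bcc - bsa_sum) > margin)
}
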