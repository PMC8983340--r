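test_that("taxonomic relations follow the genus/family/related-family ladder", {
  b <- toy_bundle()
  v1 <- b$viruses[1, ]; v2 <- b$viruses[2, ]; v3 <- b$viruses[3, ]
  expect_identical(virus_relation(v1, v1), "same_genus")
  expect_identical(virus_relation(v1, v2), "same_family")
  expect_true(is.na(virus_relation(v1, v3)))
  v4 <- v3; v4$virus_id <- "v4"; v4$related_families <- "famA"
  expect_identical(virus_relation(v1, v4), "related_family")  # either direction
  expect_identical(virus_relation(v4, v1), "related_family")
  expect_equal(relation_cphyl(c("same_genus", "same_family", "related_family", NA)),
               c(1, 0.5, 0.25, 0))
})

test_that("activity gaps report untested relatives with the strongest relation", {
  # a drug active against one virus, untested against a same-family relative
  drugs <- data.frame(
    drug_id = "remdesivir_like", name = "RDV", smiles = "",
    moa_class = "nucleoside_analog", target_kind = "virus", target_name = "",
    target_essential_for = "", replication_stage = "replication",
    immunomodulatory = "no", routes = "intravenous", stringsAsFactors = FALSE
  )
  viruses <- data.frame(
    virus_id = c("sars_cov_2", "mers_cov", "flu"),
    name = c("SARS-CoV-2", "MERS-CoV", "Influenza"),
    genus = c("betacoronavirus", "merbecovirus", "alphainfluenzavirus"),
    family = c("coronaviridae", "coronaviridae", "orthomyxoviridae"),
    related_families = "", infected_systems = "respiratory",
    case_fatality_rate = "", stringsAsFactors = FALSE
  )
  activities <- data.frame(drug_id = "remdesivir_like", virus_id = "sars_cov_2",
                           status = "approved_or_phase4", source = "",
                           stringsAsFactors = FALSE)
  b <- annotation_bundle(drugs, viruses, activities)
  g <- find_activity_gaps(b, min_relation = "same_family")
  expect_equal(nrow(g), 1L)
  expect_identical(g$virus_id, "mers_cov")
  expect_identical(g$evidence_virus_id, "sars_cov_2")
  expect_identical(g$relation, "same_family")
  expect_equal(g$implied_c_phyl, 0.5)
  # the unrelated virus only appears if no relation is required at all
  expect_equal(nrow(find_activity_gaps(b, min_relation = "related_family")), 1L)

  # a drug active against everything yields no predictions
  all_act <- data.frame(drug_id = "remdesivir_like",
                        virus_id = viruses$virus_id,
                        status = "in_vitro", source = "", stringsAsFactors = FALSE)
  b2 <- annotation_bundle(drugs, viruses, all_act)
  expect_equal(nrow(find_activity_gaps(b2)), 0L)
})

test_that("gap predictions never duplicate existing activity and tighten monotonically", {
  for (seed in 1:10) {
    b <- generate_bundle(synthetic_spec(8, 6, seed = seed, activity_density = 0.3))
    g_rel <- find_activity_gaps(b, "related_family")
    g_fam <- find_activity_gaps(b, "same_family")
    g_gen <- find_activity_gaps(b, "same_genus")
    expect_gte(nrow(g_rel), nrow(g_fam))
    expect_gte(nrow(g_fam), nrow(g_gen))
    if (nrow(g_rel)) {
      st <- mapply(function(d, v) activity_status(b, d, v),
                   g_rel$drug_id, g_rel$virus_id)
      expect_true(all(st == "untested"))
      ev <- mapply(function(d, v) activity_status(b, d, v),
                   g_rel$drug_id, g_rel$evidence_virus_id)
      expect_false(any(ev == "untested"))
    }
  }
})

test_that("overlap counts enumerate exact activity subsets within a family", {
  drugs <- data.frame(
    drug_id = c("a", "b"), name = c("A", "B"), smiles = "",
    moa_class = "nucleoside_analog", target_kind = "virus", target_name = "",
    target_essential_for = "", replication_stage = "replication",
    immunomodulatory = "no", routes = "oral", stringsAsFactors = FALSE
  )
  viruses <- data.frame(
    virus_id = c("v1", "v2"), name = c("V1", "V2"),
    genus = c("g1", "g2"), family = "famx", related_families = "",
    infected_systems = "multiple", case_fatality_rate = "",
    stringsAsFactors = FALSE
  )
  activities <- data.frame(
    drug_id = c("a", "a", "b"), virus_id = c("v1", "v2", "v1"),
    status = "in_vitro", source = "", stringsAsFactors = FALSE
  )
  b <- annotation_bundle(drugs, viruses, activities)
  counts <- activity_overlap_counts(b, "famx")
  got <- stats::setNames(counts$n_drugs, counts$viruses)
  expect_equal(got[["v1;v2"]], 1)  # drug a on both
  expect_equal(got[["v1"]], 1)     # drug b on v1 only
  expect_equal(got[["v2"]], 0)
  # counts sum to the number of drugs with any activity in the family
  expect_equal(sum(counts$n_drugs), 2)
  # single-virus family: one count equal to its active-drug total
  single <- activity_overlap_counts(b, "famx", viruses = "v1")
  expect_equal(single$n_drugs, 2)
  expect_error(activity_overlap_counts(b, "nosuchfam"), "no viruses")
})
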