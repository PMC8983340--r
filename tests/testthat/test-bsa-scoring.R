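test_that("C_SAR distinguishes direct records, similarity, and absence", {
  b <- ebov_fixture()
  # direct phase-3 record
  expect_equal(score_sar("favipiravir", "ebov", b)$value, 1)
  # no record, declared similarity to a drug with one
  sim <- attr(b, "similarity")
  expect_equal(score_sar("ribavirin", "ebov", b, sim)$value, 0.5)
  # no record, no provider
  expect_equal(score_sar("ribavirin", "ebov", b)$value, 0)
  # provider present but query structure unknown: degrade with warning, not error
  fps <- list(favipiravir = raw_fp("favipiravir", 1:10))
  prov <- similarity_provider(fingerprints = fps, threshold = 0.4)
  expect_warning(v <- score_sar("ribavirin", "ebov", b, prov)$value, "no structure")
  expect_equal(v, 0)
})

test_that("C_DDS follows the development ladder and is gated on C_SAR = 1", {
  expect_equal(score_dds("approved_or_phase4", 1), 1)
  expect_equal(score_dds("phase1_3", 1), 0.75)
  expect_equal(score_dds("in_vivo", 1), 0.5)
  expect_equal(score_dds("in_vitro", 1), 0.25)
  expect_equal(score_dds("untested", 1), 0)
  expect_equal(score_dds("approved_or_phase4", 0.5), 0)
  expect_equal(score_dds("phase1_3", 0), 0)
})

test_that("C_TR, C_IC and C_RoA follow their annotation rules", {
  b <- toy_bundle()
  alpha <- b$drugs[1, ]; beta <- b$drugs[2, ]; gamma <- b$drugs[3, ]
  # target essentiality is per-virus evidence
  expect_equal(score_tr(alpha, "v1"), 1)
  expect_equal(score_tr(alpha, "v2"), 0)
  expect_equal(score_tr(beta, "v1"), 0)
  # immunomodulatory: yes -> 0; no and unknown -> 1
  expect_equal(score_ic(gamma), 0)
  expect_equal(score_ic(alpha), 1)
  expect_equal(score_ic(beta), 1)
  # route suitability: oral suits a multi-organ virus, topical does not
  v1 <- b$viruses[1, ]; v2 <- b$viruses[2, ]
  expect_equal(score_roa(alpha, v1), 1)
  expect_equal(score_roa(gamma, v1), 0)
  # inhalation-only drug against a respiratory virus
  inh <- alpha; inh$routes <- "inhalation"
  expect_equal(score_roa(inh, v2), 1)
  # no routes: scored 0 with a warning
  none <- alpha; none$routes <- ""
  expect_warning(v <- score_roa(none, v1), "no routes")
  expect_equal(v, 0)
})

test_that("C_Phyl takes the taxonomy ladder, maximized over reference viruses", {
  b <- toy_bundle()
  v1 <- b$viruses[1, ]; v2 <- b$viruses[2, ]; v3 <- b$viruses[3, ]
  expect_equal(score_phyl(v1, v1), 1)                      # same virus/genus
  expect_equal(score_phyl(v1, v2), 0.5)                    # same family only
  expect_equal(score_phyl(v1, v3), 0)                      # unrelated
  expect_equal(score_phyl(v1, rbind(v2, v3)), 0.5)         # maximum over refs
  expect_equal(score_phyl(v1, b$viruses[0, ]), 0)          # no references
  # related-family adjacency works in either direction
  v4 <- v3; v4$virus_id <- "v4"; v4$related_families <- "famA"
  expect_equal(score_phyl(v1, v4), 0.25)
  v5 <- v1; v5$related_families <- "famB"
  expect_equal(score_phyl(v5, v3), 0.25)
})

test_that("worked-example breakdowns reproduce from annotations alone", {
  b <- ebov_fixture()
  mer <- compute_bsa_score("merimepodib", "ebov", b)
  expect_equal(unname(mer$components), c(1, 0.25, 1, 0, 1, 1))
  expect_identical(mer$total, 4.25)
  fav <- compute_bsa_score("favipiravir", "ebov", b)
  expect_equal(unname(fav$components), c(1, 0.75, 1, 1, 1, 1))
  expect_identical(fav$total, 5.75)
  rib <- compute_bsa_score("ribavirin", "ebov", b)
  expect_identical(rib$total, 2.75)
  expect_error(compute_bsa_score("nosuchdrug", "ebov", b), "unknown drug_id")
  expect_error(compute_bsa_score("ribavirin", "nosuchvirus", b), "unknown virus_id")
})

test_that("losing the direct record gates C_DDS and drops the total accordingly", {
  b <- ebov_fixture()
  before <- compute_bsa_score("favipiravir", "ebov", b)
  # remove favipiravir's EBOV record: C_SAR falls below 1 (its declared
  # similarity partner ribavirin has no EBOV record), so C_DDS is forced to 0
  act <- b$activities[b$activities$drug_id != "favipiravir", ]
  b2 <- annotation_bundle(b$drugs, b$viruses, act)
  attr(b2, "similarity") <- attr(b, "similarity")
  after <- compute_bsa_score("favipiravir", "ebov", b2)
  expect_equal(after$components[["c_dds"]], 0)
  expect_lte(after$total, before$total - before$components[["c_dds"]])
})

test_that("manual component overrides replace computed values and are logged", {
  b <- ebov_fixture()
  cfg <- run_config(overrides = list(bsa = list(
    merimepodib = list(ebov = c(c_ic = 1))
  )))
  s <- compute_bsa_score("merimepodib", "ebov", b, cfg)
  expect_identical(s$total, 5.25)
  expect_true(any(grepl("override: c_ic=1", s$provenance)))
  bad <- run_config(overrides = list(bsa = list(
    merimepodib = list(ebov = c(c_xx = 1))
  )))
  expect_error(compute_bsa_score("merimepodib", "ebov", b, bad), "override")
})
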