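test_that("the four coefficients follow the published interaction rules", {
  b <- ebov_fixture()
  fav <- get_drug_row(b, "favipiravir")
  mer <- get_drug_row(b, "merimepodib")
  rib <- get_drug_row(b, "ribavirin")
  ebov <- b$viruses[b$viruses$virus_id == "ebov", ]

  # k_DI: same MoA class halves the combination
  expect_equal(coeff_di(fav, rib), 0.5)
  expect_equal(coeff_di(fav, mer), 1.0)
  expect_equal(coeff_di(mer, mer), 0.5)

  # k_DTI and target class
  expect_equal(coeff_dti(fav, rib), list(k = 1.2, target_class = "virus_virus"))
  expect_equal(coeff_dti(fav, mer), list(k = 1.1, target_class = "virus_host"))
  expect_equal(coeff_dti(mer, mer), list(k = 1.0, target_class = "host_host"))
  unk <- fav; unk$target_kind <- "unknown"
  expect_equal(coeff_dti(unk, fav)$target_class, "unknown")
  expect_equal(coeff_dti(unk, fav)$k, 1.0)
  both <- fav; both$target_kind <- "both"
  expect_equal(coeff_dti(both, fav)$k, 1.1)
  expect_equal(coeff_dti(both, mer)$k, 1.0)

  # k_DRS: same named stage only
  expect_equal(coeff_drs(fav, mer), 1.2)
  entry <- fav; entry$replication_stage <- "entry"
  expect_equal(coeff_drs(entry, fav), 1.0)
  unk2 <- fav; unk2$replication_stage <- "unknown"
  expect_equal(coeff_drs(unk2, unk2), 1.0)

  # k_RoA: shared-and-suited 1.2, shared-unsuited 1.0, disjoint 0.8
  expect_equal(coeff_roa(fav, mer, ebov), 1.2)
  iv <- fav; iv$routes <- "intravenous"
  expect_equal(coeff_roa(fav, iv, ebov), 0.8)
  resp <- ebov; resp$infected_systems <- "respiratory"
  sub1 <- fav; sub1$routes <- "subcutaneous"
  sub2 <- mer; sub2$routes <- "subcutaneous;oral"
  expect_equal(coeff_roa(sub1, sub2, resp), 1.0)
  none <- fav; none$routes <- ""
  expect_warning(k <- coeff_roa(none, mer, ebov), "missing route")
  expect_equal(k, 0.8)
})

test_that("worked-example combination scores and verdicts reproduce", {
  b <- ebov_fixture()
  fm <- compute_bcc_score("favipiravir", "merimepodib", "ebov", b)
  expect_equal(c(fm$k_di, fm$k_dti, fm$k_drs, fm$k_roa), c(1.0, 1.1, 1.2, 1.2))
  expect_equal(fm$bsa_sum, 10)
  expect_equal(fm$bcc_score, 15.84, tolerance = 1e-9)
  expect_identical(display_score(fm$bcc_score), "15.8")
  expect_true(fm$effective)

  fr <- compute_bcc_score("favipiravir", "ribavirin", "ebov", b)
  expect_equal(c(fr$k_di, fr$k_dti, fr$k_drs, fr$k_roa), c(0.5, 1.2, 1.2, 1.2))
  expect_equal(fr$bsa_sum, 8.5)
  expect_equal(fr$bcc_score, 7.344, tolerance = 1e-9)
  expect_identical(display_score(fr$bcc_score), "7.3")
  expect_false(fr$effective)

  # symmetry in the argument order
  fm2 <- compute_bcc_score("merimepodib", "favipiravir", "ebov", b)
  expect_equal(fm2[setdiff(names(fm2), "provenance")],
               fm[setdiff(names(fm), "provenance")])

  # degenerate pair and zero-sum multiplicativity
  expect_error(compute_bcc_score("ribavirin", "ribavirin", "ebov", b), "degenerate")
  z <- compute_bcc_score("favipiravir", "merimepodib", "ebov", b,
                         bsa = list(favipiravir = 0, merimepodib = 0))
  expect_equal(z$bcc_score, 0)
  expect_false(z$effective)
})

test_that("ranking orders pairs by score then delta with deterministic ties", {
  b <- ebov_fixture()
  r <- rank_combinations("ebov", b)
  expect_equal(nrow(r), 3L)  # 3 drugs -> 3 unordered pairs
  expect_equal(r$drug_1[1], "favipiravir")
  expect_equal(r$drug_2[1], "merimepodib")
  expect_true(all(diff(r$bcc_score) <= 0))
  expect_true(r$published[1])   # joined from the combinations table
  expect_false(any(r$published[-1]))

  eff <- rank_combinations("ebov", b, effective_only = TRUE)
  expect_equal(nrow(eff), 1L)
  expect_equal(eff$drug_1, "favipiravir")

  two <- rank_combinations("ebov", b, drug_ids = c("favipiravir", "ribavirin"))
  expect_equal(nrow(two), 1L)
  expect_error(rank_combinations("ebov", b, drug_ids = "favipiravir"), "at least 2")

  expect_equal(nrow(rank_combinations("ebov", b, top = 2)), 2L)
})

test_that("published reference rows reproduce at printed precision by rule", {
  fx <- table1_fixture()
  exp <- fx$expected[!fx$expected$override_required, ]
  for (i in seq_len(nrow(exp))) {
    s <- compute_bcc_score(exp$drug_1[i], exp$drug_2[i], exp$virus[i], fx$bundle)
    expect_equal(s$bsa_sum, exp$bsa_sum[i],
                 info = paste(exp$drug_1[i], exp$drug_2[i]))
    expect_identical(display_score(s$bcc_score), exp$expected_display[i])
  }
  # override-required rows are flagged, not silently reproduced
  flagged <- fx$expected[fx$expected$override_required, ]
  expect_true(all(is.na(flagged$expected_display)))
  expect_true(nrow(flagged) >= 2L)
})

test_that("coefficient overrides reproduce otherwise-unreachable rows and are logged", {
  fx <- table1_fixture()
  # a published row implying a coefficient contradicting the rules (both drugs
  # virus-directed but multiplier 1.584) is reachable only under override
  cfg <- run_config(overrides = list(coeff = list(
    "baloxavir|favipiravir|sftsv" = c(k_dti = 1.1)
  )))
  s <- compute_bcc_score("baloxavir", "favipiravir", "sftsv", fx$bundle, cfg,
                         bsa = list(baloxavir = 5.5, favipiravir = 5.5))
  expect_equal(s$k_dti, 1.1)
  expect_identical(display_score(s$bcc_score), "17.4")
  expect_true(any(grepl("override: k_dti", s$provenance)))
})

test_that("display formatting rounds half away from zero at printed precision", {
  expect_identical(display_score(15.84, 1), "15.8")
  expect_identical(display_score(15.84, 2), "15.84")
  expect_identical(display_score(15.05, 2), "15.05")
  expect_identical(display_score(14.256, 1), "14.3")
  expect_identical(display_score(0, 1), "0.0")
  expect_identical(display_score(2.25, 1), "2.3")     # half away from zero
  expect_identical(display_score(-2.25, 1), "-2.3")
  expect_identical(display_score(10, 1), "10.0")      # trailing zero kept
})

test_that("coefficient products stay within bounds and sub-unit products are never effective", {
  for (seed in 1:30) {
    b <- generate_bundle(synthetic_spec(5, 4, seed = seed))
    voi <- b$viruses$virus_id[1]
    r <- suppressWarnings(rank_combinations(voi, b))
    prod <- r$k_di * r$k_dti * r$k_drs * r$k_roa
    expect_true(all(prod >= 0.4 - 1e-12 & prod <= 1.728 + 1e-12))
    expect_equal(r$bcc_score, prod * r$bsa_sum, tolerance = 1e-9)
    # if the multiplier does not exceed 1 the delta cannot exceed 0, let alone 5
    expect_false(any(r$effective[prod <= 1]))
    expect_true(all(r$delta[r$effective] > 5))
  }
})
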