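test_that("fingerprints are canonical over spelling, kekulization and salts", {
  fps <- fingerprint_set(c(
    a = "CCO", b = "OCC", salt = "CCO.Cl",
    benzene1 = "c1ccccc1", benzene2 = "C1=CC=CC=C1",
    methane = "C", ethane = "CC", toluene = "Cc1ccccc1"
  ))
  expect_identical(fps$a$bits, fps$b$bits)                 # equivalent spellings
  expect_identical(fps$salt$bits, fps$a$bits)              # largest-fragment desalt
  expect_identical(fps$benzene1$bits, fps$benzene2$bits)   # aromatic vs kekulized
  expect_false(identical(fps$methane$bits, fps$ethane$bits))
  expect_true(all(fps$a$bits >= 0 & fps$a$bits < fps$a$n_bits))
  expect_gt(length(fps$toluene$bits), 0L)
  expect_error(fingerprint("xq(((", "junk"), "unparseable SMILES for junk")
})

test_that("tanimoto is intersection over union, symmetric and bounded", {
  a <- raw_fp("a", c(1, 2, 3))
  b <- raw_fp("b", c(2, 3, 4))
  c_ <- raw_fp("c", c(10, 11))
  expect_equal(tanimoto(a, b), 0.5)        # 2 shared / 4 total
  expect_equal(tanimoto(a, b), tanimoto(b, a))
  expect_equal(tanimoto(a, a), 1)
  expect_equal(tanimoto(a, c_), 0)
  expect_error(tanimoto(a, raw_fp("d", 1:3, n_bits = 1024L)), "different widths")
  for (seed in 1:20) {
    fps <- random_fp_set(2, seed)
    s <- tanimoto(fps[[1]], fps[[2]])
    expect_true(s >= 0 && s <= 1)
    expect_identical(s == 1, identical(fps[[1]]$bits, fps[[2]]$bits))
  }
})

test_that("clustering partitions compounds and respects the distance cutoff", {
  # two identical molecules and one unrelated: flat cut at 0.6 separates them
  fps <- list(a = raw_fp("a", 1:20), b = raw_fp("b", 1:20),
              c = raw_fp("c", 100:119))
  cl <- cluster_compounds(fps, cutoff = 0.6)
  m <- cl$members
  expect_identical(m$cluster_id[m$drug_id == "a"], m$cluster_id[m$drug_id == "b"])
  expect_false(m$cluster_id[m$drug_id == "c"] == m$cluster_id[m$drug_id == "a"])

  # single compound: one singleton
  one <- cluster_compounds(fps["a"], cutoff = 0.6)
  expect_equal(nrow(one$members), 1L)

  # cutoff 0: all singletons except exact duplicates
  cl0 <- cluster_compounds(fps, cutoff = 0)
  m0 <- cl0$members
  expect_identical(m0$cluster_id[m0$drug_id == "a"], m0$cluster_id[m0$drug_id == "b"])
  expect_equal(length(unique(m0$cluster_id)), 2L)
})

test_that("raising the cutoff never increases the number of clusters", {
  for (seed in 1:15) {
    fps <- random_fp_set(10, seed)
    counts <- vapply(c(0, 0.2, 0.4, 0.6, 0.8, 1), function(h) {
      length(unique(cluster_compounds(fps, h)$members$cluster_id))
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
    # partition property at every cutoff
    m <- cluster_compounds(fps, 0.5)$members
    expect_setequal(m$drug_id, names(fps))
    expect_false(anyDuplicated(m$drug_id) > 0)
  }
})

test_that("candidate nomination requires two anchoring BSAs in the sub-cluster", {
  fps <- list(
    tam = raw_fp("tam", 1:30), tor = raw_fp("tor", c(1:28, 40, 41)),
    osp = raw_fp("osp", c(1:25, 50:54)),          # non-BSA near the two BSAs
    lone_bsa = raw_fp("lone_bsa", 200:230),
    lone_cand = raw_fp("lone_cand", 201:231),     # cluster with a single BSA
    far = raw_fp("far", 500:520)
  )
  cl <- cluster_compounds(fps, cutoff = 0.6)
  noms <- nominate_candidates(cl, c("tam", "tor", "lone_bsa"), fps)
  expect_identical(noms$candidate_id, "osp")
  expect_identical(noms$anchors, "tam;tor")
  expect_equal(noms$max_tanimoto, tanimoto(fps$osp, fps$tam))
  # a BSA is never nominated; anchors always >= 2
  expect_false(any(noms$candidate_id %in% c("tam", "tor", "lone_bsa")))
  expect_true(all(lengths(strsplit(noms$anchors, ";")) >= 2L))
  # no qualifying cluster -> empty, well-formed result
  none <- nominate_candidates(cl, "lone_bsa", fps)
  expect_equal(nrow(none), 0L)
})

test_that("the similarity provider applies a strict >= threshold", {
  near <- list(q = raw_fp("q", 1:49), r = raw_fp("r", 1:50))  # 49/50 = 0.98
  p98 <- similarity_provider(near, threshold = 1.0)
  expect_false(p98("q", "r")$similar)
  p40 <- similarity_provider(near, threshold = 0.4)
  hit <- p40("q", "r")
  expect_true(hit$similar)
  expect_equal(hit$similarity, 0.98)
  pex <- similarity_provider(near, threshold = 0.98)
  expect_true(pex("q", "r")$similar)         # >= is inclusive
  expect_false(p40("q", character(0))$similar)  # empty reference set
  # declared pairs answer without structures
  pd <- similarity_provider(pairs = list(c("x", "y")))
  expect_true(pd("x", "y")$similar)
  expect_false(pd("x", "z")$similar)
})
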