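test_that("encoder dimensions match their scheme definitions", {
  s <- "MKVLYACDGHIKLMNPQRSTVWY"
  expect_length(compute_aac(s), 20)
  expect_length(compute_dpc(s), 400)
  expect_length(compute_gpc(s, gap = 1), 400)
  expect_length(compute_gpc(s, gap = 2), 400)
  expect_length(compute_ctd(s), 310)
  expect_length(compute_pseaac(s, lambda = 1), 21)
  expect_length(compute_pseaac(s, lambda = 5), 25)
  expect_length(compute_acf(s, order = 1), 531)
})

test_that("AAC is count over length, in canonical order, summing to 1", {
  v <- compute_aac("AAAA")
  expect_equal(as.vector(v["A"]), 1)
  expect_equal(sum(v), 1)
  v <- compute_aac("ACDG")
  expect_equal(as.vector(v[c("A", "C", "D", "G")]), rep(0.25, 4))
  expect_equal(sum(v == 0), 16)
  expect_equal(names(v), AA_ALPHABET)
})

test_that("DPC counts adjacent ordered pairs over N - 1", {
  expect_equal(as.vector(compute_dpc("AAA")["AA"]), 1)
  v <- compute_dpc("ACAC")
  expect_equal(as.vector(v["AC"]), 2 / 3)
  expect_equal(as.vector(v["CA"]), 1 / 3)
  expect_equal(sum(v), 1)
  expect_error(compute_dpc("A"), "too short")
})

test_that("GPC counts pairs at offset G + 1 over N - G - 1", {
  v <- compute_gpc("ACACA", gap = 1)
  expect_equal(as.vector(v["AA"]), 2 / 3)
  expect_equal(as.vector(v["CC"]), 1 / 3)
  expect_equal(sum(v), 1)
  expect_equal(as.vector(compute_gpc("AAAA", gap = 2)["AA"]), 1)
  expect_error(compute_gpc("ACA", gap = 2), "too short")
})

test_that("AAC/DPC/GPC equal brute-force counting on random sequences", {
  set.seed(101)
  for (i in 1:200) {
    s <- random_residue_string(sample(10:500, 1))
    expect_equal(as.vector(compute_aac(s)), as.vector(oracle_aac(s)))
    expect_equal(as.vector(compute_dpc(s)), as.vector(oracle_dpc(s)))
    g <- sample(1:3, 1)
    expect_equal(as.vector(compute_gpc(s, g)), as.vector(oracle_pair_comp(s, g)))
  }
})

test_that("PseAAC normalizes to 1 and its tiers vanish on homopolymers", {
  v <- compute_pseaac("AAAAA", lambda = 1, w = 0.5)
  expect_equal(as.vector(v["A"]), 1)
  expect_equal(as.vector(v["lambda1"]), 0)
  set.seed(7)
  for (i in 1:20) {
    s <- random_residue_string(sample(10:100, 1))
    lam <- sample(1:4, 1)
    v <- compute_pseaac(s, lambda = lam, w = 0.1)
    expect_equal(sum(v), 1, tolerance = 1e-12)
  }
  expect_error(compute_pseaac("ACD", lambda = 3), "lambda")
})

test_that("PseAAC converges to AAC as the tier weight vanishes", {
  set.seed(8)
  for (i in 1:10) {
    s <- random_residue_string(80)
    v <- compute_pseaac(s, lambda = 2, w = 1e-9)
    expect_lt(max(abs(v[1:20] - compute_aac(s))), 1e-6)
  }
})

test_that("CTD blocks: composition = AAC, transitions are symmetric hetero pairs", {
  v <- compute_ctd("ACACA")
  expect_equal(as.vector(v["T.AC"]), 1)
  expect_equal(sum(v[21:210] != 0), 1)
  v2 <- compute_ctd("AAAAA")
  expect_true(all(v2[21:210] == 0))
  expect_equal(as.vector(v2[paste0("D.A.", c("first", "q25", "q50", "q75",
                                          "q100"))]),
               c(20, 40, 60, 80, 100))
  set.seed(9)
  for (i in 1:100) {
    s <- random_residue_string(sample(10:300, 1))
    v <- compute_ctd(s)
    expect_equal(as.vector(v[1:20]), as.vector(compute_aac(s)))
    expect_equal(as.vector(v[21:210]), as.vector(oracle_ctd_transition(s)))
    # transition block sums to hetero-adjacency fraction <= 1
    expect_lte(sum(v[21:210]), 1 + 1e-12)
    # distribution anchors in [0, 100], non-decreasing for present residues
    d <- matrix(v[211:310], nrow = 5)
    expect_true(all(d >= 0 & d <= 100))
    present <- colSums(d) > 0
    expect_true(all(apply(d[, present, drop = FALSE], 2,
                          function(col) all(diff(col) >= 0))))
  }
})

test_that("ACF matches closed forms and is reversal-invariant", {
  tab <- aaindex_table()
  vA <- tab$normalized[, "A"]
  vC <- tab$normalized[, "C"]
  # homopolymer: every lag-1 product is v^2
  r <- compute_acf(strrep("A", 30), tab, order = 1)
  expect_equal(as.vector(r), as.vector(vA^2))
  # alternating sequence: every adjacent product is vA * vC
  r <- compute_acf(strrep("AC", 15), tab, order = 1)
  expect_equal(as.vector(r), as.vector(vA * vC))
  # reversal symmetry for each lag
  set.seed(11)
  for (i in 1:10) {
    s <- random_residue_string(60)
    rev_s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
    expect_equal(compute_acf(s, tab, order = 3),
                 compute_acf(rev_s, tab, order = 3))
  }
  expect_error(compute_acf("ACD", tab, order = 3), "too short")
})

test_that("permuting residues preserves AAC but changes order-sensitive encoders", {
  s <- "AAACCCDDDGGG"
  p <- "ACDGACDGACDG"  # same composition, different order
  expect_equal(compute_aac(s), compute_aac(p))
  expect_false(isTRUE(all.equal(compute_dpc(s), compute_dpc(p))))
  expect_false(isTRUE(all.equal(compute_gpc(s, 1), compute_gpc(p, 1))))
  expect_false(isTRUE(all.equal(compute_ctd(s)[21:210],
                                compute_ctd(p)[21:210])))
  tab <- aaindex_table()
  expect_false(isTRUE(all.equal(compute_acf(s, tab), compute_acf(p, tab))))
})

test_that("encode_dataset builds deterministic matrices and rejects bad input", {
  ps <- random_sequences(3, c(50, 60), seed = 3)
  m <- encode_dataset(ps, "ctd")
  expect_equal(dim(m), c(3L, 310L))
  expect_equal(rownames(m), ps$id)
  expect_identical(m, encode_dataset(ps, "ctd"))
  expect_equal(attr(m, "scheme"), "ctd")
  expect_error(encode_dataset(ps[0, ], "aac"), "empty dataset")
  short <- protein_set(c("s1", "s2"), c("MK", "ACDGACDG"))
  expect_error(encode_dataset(short, "gpc", gap = 2), "s1")
})

test_that("encoders reject sequences with non-standard residues", {
  expect_error(compute_aac("MXV"), "non-standard")
  expect_error(compute_ctd("MKB"), "non-standard")
})
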