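test_that("pairwise identity counts jointly ungapped, unambiguous columns", {
  s <- paste(rep("ACGT", 75), collapse = "")
  expect_equal(pairwise_identity(s, s), 1.0)
  expect_equal(pairwise_identity("ACGT", "ACGA"), 0.75)
  expect_equal(pairwise_identity("AC-T", "ACGT"), 1.0) # gap column excluded
  expect_equal(pairwise_identity("ACNT", "ACGT"), 1.0) # N column excluded
  expect_error(pairwise_identity("---", "AAA"), "no overlap")
  expect_error(pairwise_identity("AC", "ACGT"), "equal length")
})

test_that("single-site substitutions classify by amino-acid identity", {
  expect_equal(classify_site_substitution("GAA", "GAG", 2), "synonymous")
  expect_equal(classify_site_substitution("TTT", "TTA", 2), "nonsynonymous")
  expect_equal(classify_site_substitution("ATG", "AGG", 1), "nonsynonymous")
  # substitutions creating a stop are nonsynonymous
  expect_equal(classify_site_substitution("TAC", "TAA", 2), "nonsynonymous")
  expect_warning(out <- classify_site_substitution("GA-", "GAG", 2), "gap")
  expect_true(is.na(out))
})

test_that("ng_sites matches the neighbour-enumeration oracle on all sense codons", {
  for (codon in oracle_sense_codons()) {
    got <- ng_sites(codon)
    want <- oracle_ng_sites(codon)
    expect_equal(got[["s_sites"]], want[["s_sites"]], tolerance = 1e-12,
                 info = codon)
    expect_equal(sum(got), 3, tolerance = 1e-12, info = codon)
  }
  # frozen spot checks derived from the oracle
  expect_equal(unname(ng_sites("TTT")), c(1 / 3, 8 / 3))
  expect_equal(unname(ng_sites("GGG")), c(1, 2))
  expect_equal(unname(ng_sites("ATG")), c(0, 3))
  expect_error(ng_sites("TAA"), "stop")
  expect_error(ng_sites("AT-"), "A/C/G/T")
})

test_that("identical sequences give zero distances and undefined omega", {
  s <- paste(rep(c("ATG", "CTT", "GGA", "TCC"), 25), collapse = "")
  est <- ng_pairwise(s, s)
  expect_equal(est$s_diffs, 0)
  expect_equal(est$n_diffs, 0)
  expect_equal(est$d_n, 0)
  expect_equal(est$d_s, 0)
  expect_true(is.na(est$omega))
  expect_true("omega_undefined_zero_dS" %in% est$flags)
  expect_equal(est$s_sites + est$n_sites, 3 * est$n_codons)
})

test_that("ng_pairwise is symmetric and matches the pathway oracle on random pairs", {
  set.seed(101)
  sense <- oracle_sense_codons()
  n_pairs <- 120
  ca <- sample(sense, n_pairs, replace = TRUE)
  cb <- sample(sense, n_pairs, replace = TRUE)
  a <- paste(ca, collapse = "")
  b <- paste(cb, collapse = "")
  est <- ng_pairwise(a, b)
  rev <- ng_pairwise(b, a)
  expect_identical(est$s_diffs, rev$s_diffs)
  expect_identical(est$n_diffs, rev$n_diffs)
  expect_identical(est$s_sites, rev$s_sites)

  want <- oracle_ng_pair(ca, cb)
  expect_equal(est$s_diffs, want$s_diffs, tolerance = 1e-9)
  expect_equal(est$n_diffs, want$n_diffs, tolerance = 1e-9)
  expect_equal(est$s_sites, want$s_sites, tolerance = 1e-9)
  expect_equal(est$n_sites, want$n_sites, tolerance = 1e-9)
})

test_that("gapped and stop codons are excluded pairwise", {
  a <- "ATGCTTGGA"
  b <- "ATGC-TGGG"
  est <- ng_pairwise(a, b) # middle codon dropped in both
  expect_equal(est$n_codons, 2L)
  # stop codon in one sequence drops the codon pair
  est2 <- ng_pairwise("ATGTAACTT", "ATGTACCTT")
  expect_equal(est2$n_codons, 2L)
  expect_error(ng_pairwise("---", "---"), "zero comparable")
})

test_that("a synonymous-only extra difference never increases d_n", {
  set.seed(202)
  sense <- oracle_sense_codons()
  for (rep_i in 1:20) {
    ca <- sample(sense, 40, replace = TRUE)
    cb <- ca
    cb[sample.int(40, 5)] <- sample(sense, 5, replace = TRUE) # mild divergence
    base_n <- ng_pairwise(paste(ca, collapse = ""), paste(cb, collapse = ""))$d_n
    # append a fourfold-degenerate codon differing only at a silent site
    with_syn <- ng_pairwise(paste(c(ca, "GGA"), collapse = ""),
                            paste(c(cb, "GGC"), collapse = ""))$d_n
    expect_lte(with_syn, base_n + 1e-12)
  }
})

test_that("saturation flags suppress omega", {
  # maximally divergent synonymous-rich comparison saturates p_s
  a <- paste(rep("CTA", 60), collapse = "")
  b <- paste(rep("TTG", 60), collapse = "")
  est <- ng_pairwise(a, b)
  if (est$p_s >= 0.75) {
    expect_true("saturated_dS" %in% est$flags)
    expect_true(is.na(est$omega))
  } else {
    succeed()
  }
})

test_that("ds_filter retains OGs at or below the cutoff", {
  mk <- function(ds) structure(list(d_s = ds), class = "rate_estimate")
  ests <- list(a = mk(0.1), b = mk(0.5), c = mk(2.5), d = mk(NA), e = mk(1.9))
  expect_message(keep <- ds_filter(ests, cutoff = 2), "removed 2 of 5")
  expect_setequal(keep, c("a", "b", "e"))
  expect_message(keep_all <- ds_filter(ests[1:2], cutoff = 2), "removed 0")
  expect_setequal(keep_all, c("a", "b"))
  expect_error(ds_filter(ests, cutoff = 0))
})

test_that("log2 omega ratio behaves on equal, doubled and degenerate rates", {
  expect_equal(log2_omega_ratio(0.2, 0.2), 0)
  expect_equal(log2_omega_ratio(0.4, 0.2), 1)
  expect_equal(log2_omega_ratio(0.05, 0.2), -2)
  bad <- log2_omega_ratio(0, 0.2)
  expect_true(is.na(bad))
  expect_match(attr(bad, "reason"), "zero or undefined")
  expect_true(is.na(log2_omega_ratio(NA, 0.2)))
})
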