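# Fixture: 30-codon Leu backbone; parents differ at 10 sites (6 synonymous
# third-position changes, 4 nonsynonymous first-position changes); the
# allopolyploid inherits the maternal (A) sequence plus 2 private
# mutations (1 synonymous, 1 nonsynonymous).
typing_fixture <- function() {
  a <- backbone()
  b <- a
  for (i in 1:6) b <- set_codon(b, i, "CTC")   # Leu -> Leu, synonymous
  for (i in 7:10) b <- set_codon(b, i, "ATT")  # Leu -> Ile, nonsynonymous
  allo <- set_codon(set_codon(a, 20, "CTG"),   # Leu -> Leu, synonymous
                    21, "CAT")                 # Leu -> His, nonsynonymous
  make_aln(c("allo|AB|allopolyploid" = allo,
             "pA|A|diploid_parent" = a,
             "pB|B|diploid_parent" = b))
}

ab_design <- cross_design("AB", "A", "B")

test_that("maternal inheritance with private mutations types correctly", {
  rec <- type_variants(typing_fixture(), ab_design)
  expect_equal(unname(rec$genome_like$A), c(6, 4))
  expect_equal(unname(rec$genome_like$B), c(0, 0))
  expect_equal(rec$private_count, 2)
  expect_equal(rec$private_syn, 1)
  expect_equal(rec$private_nonsyn, 1)
  expect_equal(rec$total, 12)
})

test_that("fully identical sequences yield an all-zero record", {
  s <- backbone()
  aln <- make_aln(c("allo|AB|allopolyploid" = s,
                    "pA|A|diploid_parent" = s,
                    "pB|B|diploid_parent" = s))
  rec <- type_variants(aln, ab_design)
  expect_equal(rec$total, 0)
  expect_equal(sum(unlist(rec$genome_like)), 0)
})

test_that("columns shared by two candidates are non-diagnostic and skipped", {
  a <- backbone()
  b <- a
  for (i in 1:5) b <- set_codon(b, i, "CTC")
  # C sides with A at every B-variant column -> allopolyploid matches two
  # candidates there
  aln <- make_aln(c("allo|AB|allopolyploid" = a,
                    "pA|A|diploid_parent" = a,
                    "pB|B|diploid_parent" = b,
                    "pC|C|diploid_parent" = a))
  design3 <- cross_design("AB", "A", "B", other_genomes = "C")
  rec <- type_variants(aln, design3)
  expect_equal(rec$total, 0)
  expect_equal(attr(rec, "non_diagnostic"), 5L)

  # a column where A is the odd genome out stays diagnostic (A-like)
  a2 <- set_codon(a, 12, "CTA") # Leu, synonymous vs CTT
  aln2 <- make_aln(c("allo|AB|allopolyploid" = a2,
                     "pA|A|diploid_parent" = a2,
                     "pB|B|diploid_parent" = b,
                     "pC|C|diploid_parent" = a))
  rec2 <- type_variants(aln2, design3)
  expect_equal(unname(rec2$genome_like$A), c(1, 0))
})

test_that("discordant varieties of a genome exclude the column", {
  a <- backbone()
  b1 <- set_codon(a, 3, "CTC")
  b2 <- set_codon(a, 3, "CTG") # B varieties disagree at codon 3
  aln <- make_aln(c("allo|AB|allopolyploid" = a,
                    "pA|A|diploid_parent" = a,
                    "pB1|B|diploid_parent" = b1,
                    "pB2|B|diploid_parent" = b2))
  rec <- type_variants(aln, ab_design)
  expect_equal(rec$total, 0)
  expect_equal(attr(rec, "skipped"), 1L)
})

test_that("count closure holds and parent relabeling leaves counts keyed by genome", {
  rec <- type_variants(typing_fixture(), ab_design)
  expect_equal(rec$total,
               sum(unlist(rec$genome_like)) + rec$private_count)
  rec_swapped <- type_variants(typing_fixture(), swap_parents(ab_design))
  expect_equal(rec_swapped$genome_like[names(rec$genome_like)],
               rec$genome_like)
  expect_equal(rec_swapped$private_count, rec$private_count)
})

test_that("aggregation sums records and reproduces the published plastid total", {
  rec <- type_variants(typing_fixture(), ab_design)
  single <- aggregate_typing(list(rec), "plastid")
  expect_equal(single$sum, rec$total)
  expect_equal(unname(single$genome_like["A", ]), c(6, 4))

  empty <- aggregate_typing(list(), "plastid")
  expect_equal(empty$sum, 0)

  records <- read_typing_counts(extdata("table1_organelle_variants.tsv"))
  pt <- aggregate_typing(list(records$AABB_tumida$plastid), "plastid")
  expect_equal(pt$sum, 844)
  expect_equal(unname(pt$genome_like["A", "synonymous"]), 486)
  expect_equal(unname(pt$genome_like["A", "nonsynonymous"]), 358)
})

test_that("donor inference is confident for one-sided counts and wary otherwise", {
  records <- read_typing_counts(extdata("table1_organelle_variants.tsv"))
  # one-sided maternal signal: support 1, confident
  pt <- aggregate_typing(list(records$AABB_tumida$plastid), "plastid")
  mt <- aggregate_typing(list(records$AABB_tumida$mitochondrion), "mitochondrion")
  donor <- infer_maternal_donor(list(pt, mt))
  expect_equal(donor$genome_id, "A")
  expect_equal(donor$support, 1)
  expect_equal(donor$status, "confident")

  # tie between candidates
  tie <- variant_typing_record("g", list(A = c(synonymous = 5, nonsynonymous = 5),
                                         B = c(synonymous = 4, nonsynonymous = 6)))
  expect_equal(infer_maternal_donor(aggregate_typing(list(tie), "plastid"))$status,
               "ambiguous")

  # private-heavy pattern stays ambiguous despite a clear best candidate
  pt_napus <- aggregate_typing(list(records$AACC_No2127$plastid), "plastid")
  donor_napus <- infer_maternal_donor(list(pt_napus))
  expect_equal(donor_napus$status, "ambiguous")
  expect_match(donor_napus$reason, "private-heavy")

  # zero diagnostic variants
  zero <- variant_typing_record("g", list(A = c(synonymous = 0, nonsynonymous = 0)))
  nd <- infer_maternal_donor(aggregate_typing(list(zero), "plastid"))
  expect_equal(nd$status, "ambiguous")
  expect_match(nd$reason, "no signal")
})

test_that("a missing allopolyploid sequence is an error", {
  s <- backbone()
  aln <- make_aln(c("pA|A|diploid_parent" = s, "pB|B|diploid_parent" = s))
  expect_error(type_variants(aln, ab_design), "allopolyploid")
})
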