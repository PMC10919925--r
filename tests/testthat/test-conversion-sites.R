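# Clade fixture: 30-codon backbone, two varieties per parental genome.
# Parents differ at chosen codons; diagnostic-site and event arithmetic is
# hand-countable.
ab <- cross_design("AB", "A", "B")

build_clade <- function(b_syn_codons = c(2, 5, 9), b_nonsyn_codons = c(12, 15),
                        discordant_codon = NULL, gap_codon = NULL) {
  a <- backbone()
  b <- a
  for (i in b_syn_codons) b <- set_codon(b, i, "CTC")    # silent third position
  for (i in b_nonsyn_codons) b <- set_codon(b, i, "ATT") # Leu -> Ile
  a2 <- a
  b2 <- b
  if (!is.null(discordant_codon)) {
    b2 <- set_codon(b2, discordant_codon, "CTG") # varieties disagree
  }
  if (!is.null(gap_codon)) {
    a <- set_codon(a, gap_codon, "-TT") # gap on the diagnostic first position
  }
  list(a1 = a, a2 = a2, b1 = b, b2 = b2)
}

clade_aln <- function(p, hom_m, hom_p) {
  make_aln(c("a1|A|diploid_parent" = p$a1, "a2|A|diploid_parent" = p$a2,
             "b1|B|diploid_parent" = p$b1, "b2|B|diploid_parent" = p$b2,
             "hm|AB|subgenome|maternal" = hom_m,
             "hp|AB|subgenome|paternal" = hom_p))
}

test_that("diagnostic sites require concordant, ungapped, differing parents", {
  p <- build_clade()
  aln <- clade_aln(p, p$a1, p$b1)
  sites <- find_diagnostic_sites(aln, c("A", "B"), clade_id = "cl1")
  expect_equal(nrow(sites), 5L)
  expect_equal(sites$column, c(5L, 14L, 26L, 33L, 42L))
  expect_equal(sites$pos_in_codon, c(2L, 2L, 2L, 0L, 0L))
  expect_equal(sites$codon_index, c(1L, 4L, 8L, 11L, 14L))
  expect_equal(sites$state_A, c("T", "T", "T", "C", "C"))
  expect_equal(sites$state_B, c("C", "C", "C", "A", "A"))

  # identical parents: nothing is diagnostic
  q <- build_clade(b_syn_codons = integer(0), b_nonsyn_codons = integer(0))
  expect_equal(nrow(find_diagnostic_sites(clade_aln(q, q$a1, q$b1),
                                          c("A", "B"))), 0L)

  # a discordant variety and a parental gap both disqualify their columns
  r <- build_clade(discordant_codon = 2, gap_codon = 12)
  expect_equal(nrow(find_diagnostic_sites(clade_aln(r, r$a1, r$b1),
                                          c("A", "B"))), 3L)
  expect_error(find_diagnostic_sites(clade_aln(p, p$a1, p$b1), c("A", "Z")),
               "no parental sequences")
})

test_that("a homoeolog identical to its own parent yields no events", {
  p <- build_clade()
  aln <- clade_aln(p, p$a1, p$b1)
  sites <- find_diagnostic_sites(aln, c("A", "B"), "cl1")
  ev <- detect_site_conversions(p$a1, "maternal", sites, ab, gene_id = "hm")
  expect_equal(nrow(ev), 0L)
  expect_equal(attr(ev, "other_state"), 0L)
})

test_that("converted sites are detected with direction and effect", {
  p <- build_clade()
  # maternal homoeolog takes the paternal state at codons 2, 5 (synonymous
  # columns) and 12 (nonsynonymous column)
  hm <- p$a1
  hm <- set_codon(hm, 2, "CTC")
  hm <- set_codon(hm, 5, "CTC")
  hm <- set_codon(hm, 12, "ATT")
  aln <- clade_aln(p, hm, p$b1)
  sites <- find_diagnostic_sites(aln, c("A", "B"), "cl1")
  ev <- detect_site_conversions(hm, "maternal", sites, ab, gene_id = "hm")
  expect_equal(nrow(ev), 3L)
  expect_true(all(ev$direction == "P_to_M"))
  expect_equal(sum(ev$effect == "synonymous"), 2L)
  expect_equal(sum(ev$effect == "nonsynonymous"), 1L)
  expect_equal(ev$column_1based, ev$column + 1L)
  # every event column is a diagnostic column (subset property)
  expect_true(all(ev$column %in% sites$column))
})

test_that("third states and gaps at diagnostic sites are tallied, not called", {
  p <- build_clade()
  hm <- set_codon(p$a1, 2, "CTG") # matches neither parent
  hm_gap <- set_codon(p$a1, 5, "CT-") # gap at the diagnostic third position
  aln <- clade_aln(p, hm, p$b1)
  sites <- find_diagnostic_sites(aln, c("A", "B"), "cl1")
  ev <- detect_site_conversions(hm, "maternal", sites, ab)
  expect_equal(nrow(ev), 0L)
  expect_equal(attr(ev, "other_state"), 1L)
  ev2 <- detect_site_conversions(hm_gap, "maternal", sites, ab)
  expect_equal(attr(ev2, "skipped"), 1L)
})

test_that("scanning both homoeologs flags reciprocal columns and swaps labels", {
  p <- build_clade()
  hm <- set_codon(p$a1, 2, "CTC")  # maternal copy carries the paternal state
  hp <- set_codon(p$b1, 2, "CTT")  # paternal copy carries the maternal state
  hp <- set_codon(hp, 15, "CTT")   # and again at a nonsynonymous column
  aln <- clade_aln(p, hm, hp)
  ev <- scan_clade_conversions(aln, ab, clade_id = "cl1")
  expect_equal(nrow(ev), 3L)
  expect_setequal(ev$direction[ev$gene_id == "hm"], "P_to_M")
  expect_setequal(ev$direction[ev$gene_id == "hp"], "M_to_P")
  expect_true(all(ev$reciprocal[ev$column == 5L]))
  expect_false(any(ev$reciprocal[ev$column != 5L]))

  # relabeling the cross swaps direction labels but not the event columns
  r <- aln$records
  sw <- r$origin
  sw[r$origin == "maternal"] <- "paternal"
  sw[r$origin == "paternal"] <- "maternal"
  aln_sw <- codon_alignment(r$gene_id, r$genome, r$role, sw, r$sequence)
  ev_sw <- scan_clade_conversions(aln_sw, swap_parents(ab), clade_id = "cl1")
  expect_setequal(ev_sw$column, ev$column)
  expect_setequal(ev_sw$direction[ev_sw$gene_id == "hm"], "M_to_P")
})

test_that("family tabulation reproduces the published maternally biased totals", {
  tab <- read_tsv_table(extdata("table4_site_conversions.tsv"))
  for (expected in list(c("AABB_tumida", 47, 11), c("AABB_varuna", 58, 14),
                        c("BBCC", 55, 42))) {
    fam <- tab[tab$allopolyploid == expected[1],
               c("family", "snps", "m_to_p_syn", "m_to_p_nonsyn",
                 "p_to_m_syn", "p_to_m_nonsyn")]
    out <- tabulate_families(fam)
    expect_equal(attr(out, "maternally_biased"), as.numeric(expected[2]),
                 info = expected[1])
    total <- out[out$family == "Total", ]
    # the Total row is the exact column-wise sum of the family rows
    expect_equal(total$snps, sum(fam$snps))
    expect_equal(total$m_to_p_syn + total$m_to_p_nonsyn,
                 as.numeric(expected[2]))
  }
  # AABB_tumida Total synonymous/nonsynonymous split: 40 + 7
  tum <- tabulate_families(tab[tab$allopolyploid == "AABB_tumida", -1])
  expect_equal(tum[tum$family == "Total", "m_to_p_syn"], 40)
  expect_equal(tum[tum$family == "Total", "m_to_p_nonsyn"], 7)

  # single family: Total equals that family's row
  one <- tabulate_families(tab[tab$allopolyploid == "BBCC" &
                                 tab$family == "UCR1", -1])
  expect_equal(one[one$family == "Total", "m_to_p_syn"], 27)
  # empty input: all-zero table
  empty <- tabulate_families(tab[0, -1])
  expect_equal(attr(empty, "maternally_biased"), 0)
  expect_equal(empty[empty$family == "Total", "snps"], 0)
})

test_that("events_to_family_counts aggregates direction by effect", {
  ev <- data.frame(
    family = c("f1", "f1", "f1", "f2"),
    direction = c("M_to_P", "M_to_P", "P_to_M", "P_to_M"),
    effect = c("synonymous", "nonsynonymous", "synonymous", "synonymous"),
    stringsAsFactors = FALSE)
  counts <- events_to_family_counts(ev, c(f1 = 10, f2 = 4))
  expect_equal(counts$m_to_p_syn, c(1, 0))
  expect_equal(counts$m_to_p_nonsyn, c(1, 0))
  expect_equal(counts$p_to_m_syn, c(1, 1))
  expect_equal(counts$snps, c(10, 4))
})
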