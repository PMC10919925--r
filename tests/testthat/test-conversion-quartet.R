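# Quartet fixtures on a 60-codon backbone: parents differ at 20 silent
# third positions (codons 1-20); each subgenome copy carries 2 private
# post-hybridization substitutions. Conversion overwrites the recipient
# copy with the donor copy over a codon tract.
build_quartet <- function(conversion = c("none", "P_to_M", "M_to_P"),
                          tract_codons = 60) {
  conversion <- match.arg(conversion)
  par_m <- backbone(60)
  par_p <- par_m
  for (i in 1:20) par_p <- set_codon(par_p, i, "CTC")
  sub_m <- par_m
  for (i in 55:56) sub_m <- set_codon(sub_m, i, "CTA")
  sub_p <- par_p
  for (i in 50:51) sub_p <- set_codon(sub_p, i, "CTG")
  if (conversion != "none") {
    donor <- if (conversion == "P_to_M") sub_p else sub_m
    for (i in seq_len(tract_codons)) {
      if (conversion == "P_to_M") {
        sub_m <- set_codon(sub_m, i, codon_at(donor, i))
      } else {
        sub_p <- set_codon(sub_p, i, codon_at(donor, i))
      }
    }
  }
  make_aln(c("pm|A|diploid_parent" = par_m,
             "pp|B|diploid_parent" = par_p,
             "sm|AB|subgenome|maternal" = sub_m,
             "sp|AB|subgenome|paternal" = sub_p))
}

ab <- cross_design("AB", "A", "B")

test_that("identical quartets are unknown for lack of parental divergence", {
  s <- backbone(60)
  aln <- make_aln(c("pm|A|diploid_parent" = s, "pp|B|diploid_parent" = s,
                    "sm|AB|subgenome|maternal" = s,
                    "sp|AB|subgenome|paternal" = s))
  call <- classify_quartet(aln, ab)
  expect_equal(call$call, "reciprocal_or_unknown")
  expect_match(call$flag, "insufficient divergence")
})

test_that("orthologous similarity dominating homoeologous means no conversion", {
  call <- classify_quartet(build_quartet("none"), ab, og_id = "og1")
  expect_equal(call$call, "no_conversion")
  # direct identity arithmetic oracle on the construction
  expect_equal(call$o1, 1 - 2 / 180)
  expect_equal(call$o2, 1 - 2 / 180)
  expect_equal(call$h1, 1 - 24 / 180)
  expect_equal(call$h2, 1 - 22 / 180)
  expect_equal(call$n_parent_diffs, 20L)
})

test_that("whole-gene overwrites are called with the correct direction", {
  p2m <- classify_quartet(build_quartet("P_to_M"), ab)
  expect_equal(p2m$call, "P_to_M")
  expect_equal(p2m$h1, 1)             # homoeologs identical after overwrite
  expect_equal(p2m$o1, 1 - 22 / 180)  # converted copy lost its own parent
  expect_equal(p2m$o2, 1 - 2 / 180)

  m2p <- classify_quartet(build_quartet("M_to_P"), ab)
  expect_equal(m2p$call, "M_to_P")
  expect_equal(m2p$o2, 1 - 22 / 180)
  expect_equal(m2p$o1, 1 - 2 / 180)
})

test_that("partial tracts below half the diagnostic sites are not detected", {
  # the similarity rule's documented insensitivity to small events: the
  # unconverted majority of the gene keeps orthologous similarity on top
  call <- classify_quartet(build_quartet("P_to_M", tract_codons = 10), ab)
  expect_equal(call$call, "no_conversion")
})

test_that("detection is non-decreasing in tract length", {
  detected <- vapply(c(5, 20, 40, 60), function(k) {
    classify_quartet(build_quartet("P_to_M", tract_codons = k), ab)$call == "P_to_M"
  }, logical(1))
  expect_true(all(diff(as.integer(detected)) >= 0))
  expect_true(detected[length(detected)]) # full-gene exchange is caught
})

test_that("relabeling the parents maps P_to_M onto M_to_P and fixes other calls", {
  relabel <- function(aln) {
    r <- aln$records
    sw <- r$origin
    sw[r$origin == "maternal"] <- "paternal"
    sw[r$origin == "paternal"] <- "maternal"
    codon_alignment(r$gene_id, r$genome, r$role, sw, r$sequence)
  }
  ba <- swap_parents(ab)
  for (kind in c("none", "P_to_M", "M_to_P")) {
    fwd <- classify_quartet(build_quartet(kind), ab)
    rev <- classify_quartet(relabel(build_quartet(kind)), ba)
    expected <- switch(fwd$call,
                       P_to_M = "M_to_P",
                       M_to_P = "P_to_M",
                       fwd$call)
    expect_equal(rev$call, expected, info = kind)
  }
})

test_that("exact ties at epsilon = 0 fall through to reciprocal/unknown", {
  # converted copy with no post-hybrid drift on the donor: h1 == o2 exactly
  par_m <- backbone(60)
  par_p <- par_m
  for (i in 1:20) par_p <- set_codon(par_p, i, "CTC")
  aln <- make_aln(c("pm|A|diploid_parent" = par_m,
                    "pp|B|diploid_parent" = par_p,
                    "sm|AB|subgenome|maternal" = par_p, # fully converted, no drift
                    "sp|AB|subgenome|paternal" = par_p))
  call <- classify_quartet(aln, ab)
  expect_equal(call$call, "no_conversion")
  expect_equal(call$flag, "weak-signal")
})

test_that("published per-category counts reproduce the directional ratios", {
  tab <- read_tsv_table(extdata("table2_quartet_conversions.tsv"))
  s_tum <- summarize_conversions(tab[tab$allopolyploid == "AABB_tumida",
                                     c("category", "m_to_p", "p_to_m")])
  expect_equal(s_tum$ratio_pct[s_tum$category == "Other"], 58)
  expect_equal(s_tum$ratio_pct[s_tum$category == "pt_tar"], 80)
  expect_equal(s_tum$ratio_pct[s_tum$category == "pt_com"], 100)
  expect_equal(s_tum$n_events[s_tum$category == "Total"], 66)
  expect_equal(s_tum$m_to_p[s_tum$category == "Plastid-targeted genes"], 5)
  expect_equal(s_tum$p_to_m[s_tum$category == "Plastid-targeted genes"], 6)

  s_bbcc <- summarize_conversions(tab[tab$allopolyploid == "BBCC",
                                      c("category", "m_to_p", "p_to_m")])
  expect_equal(s_bbcc$ratio_pct[s_bbcc$category == "Other"], 84)
  expect_equal(s_bbcc$ratio_pct[s_bbcc$category == "mt_tar"], 600)
  expect_equal(s_bbcc$ratio_pct[s_bbcc$category == "Dual"], 0)
  expect_equal(
    s_bbcc$ratio_pct[s_bbcc$category == "Organelle-targeted excluding Dual"],
    175)
  expect_equal(s_bbcc$n_events[s_bbcc$category == "Total"], 84)
})

test_that("summaries built from call objects match count-table summaries", {
  calls <- list(
    classify_quartet(build_quartet("P_to_M"), ab, og_id = "og1",
                     category = "Other"),
    classify_quartet(build_quartet("M_to_P"), ab, og_id = "og2",
                     category = "Other"),
    classify_quartet(build_quartet("P_to_M"), ab, og_id = "og3",
                     category = "pt_tar"),
    classify_quartet(build_quartet("none"), ab, og_id = "og4",
                     category = "pt_tar"))
  s <- summarize_conversions(calls)
  expect_equal(s$m_to_p[s$category == "Other"], 1)
  expect_equal(s$p_to_m[s$category == "Other"], 1)
  expect_equal(s$ratio_pct[s$category == "Other"], 100)
  expect_equal(s$p_to_m[s$category == "pt_tar"], 1)
  expect_true(is.na(s$ratio_pct[s$category == "Dual"]))
  expect_equal(s$ratio_pct[s$category == "pt_tar"], 0)
  expect_equal(s$n_events[s$category == "Total"], 3)
})
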