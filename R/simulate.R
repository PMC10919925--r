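# Synthetic triangle-of-U generator.
#
# Emulates three diploid genomes A, B, C with A and C sister to each other
# and B outside (plus an outgroup), and two allotetraploids with opposite
# maternal donors for the shared B genome: AB (maternal A x paternal B) and
# BC (maternal B x paternal C). Codon sequences evolve by per-site
# Jukes-Cantor substitution with a configurable fraction of nonsynonymous
# proposals rejected (so synonymous/nonsynonymous truth is trackable);
# stop codons are never created. Homoeologous conversions, category-biased
# gene loss, maternally inherited organelle genes with rare private
# mutations, and subgenome-biased expression are all injected with
# machine-readable truth tables.

#' Build a simulation configuration
#'
#' All probabilities must lie in `[0, 1]`; the seed fully determines the
#' emitted dataset.
#'
#' @param seed integer RNG seed.
#' @param n_genes named integer vector: ortholog groups per functional
#'   category (names must be [FUNCTIONAL_CATEGORIES]).
#' @param codons_per_gene codons per nuclear gene.
#' @param branch_lengths expected substitutions/site per branch of the tree
#'   `((A,C),B,OUT)`: components `outgroup`, `b`, `ac`, `a`, `c`.
#' @param nonsyn_acceptance named per-category probability that a proposed
#'   nonsynonymous substitution is retained (purifying-selection knob; the
#'   realized dN/dS of a category is approximately this value).
#' @param variety_divergence substitutions/site between a diploid genome
#'   and each of its two emitted varieties.
#' @param post_hybrid_divergence substitutions/site accumulated by each
#'   subgenome copy after hybridization.
#' @param quartet_conversion_rate per-OG probability of a homoeologous
#'   conversion (applied after post-hybridization divergence, i.e. recent
#'   events, to OGs retaining both copies).
#' @param direction_bias fraction of conversions that are paternal-to-
#'   maternal.
#' @param tract_fraction fraction of the gene overwritten (codon-aligned
#'   contiguous tract; 1 = whole-gene homoeologous exchange, the regime the
#'   quartet similarity rule detects).
#' @param n_clade_families,clade_codons gene-family clades per cross used
#'   for site-level conversion detection, and their length.
#' @param clade_post_hybrid_divergence substitutions/site layered onto
#'   clade homoeologs (default 0: site conversions are the most recent
#'   events, so the site scanner sees noise-free signal).
#' @param site_conversion_rate per diagnostic site per homoeolog
#'   probability of a single-site conversion.
#' @param loss_prob either `c(maternal =, paternal =)` recycled over
#'   categories, or an 8 x 2 matrix (rows = categories, columns =
#'   maternal/paternal) of per-copy loss probabilities.
#' @param n_organelle_genes named vector `c(plastid =, mitochondrion =)`.
#' @param organelle_codons codons per organelle gene.
#' @param organelle_rate_scale organelle branch lengths relative to
#'   nuclear (organelle genomes evolve more slowly).
#' @param organelle_nonsyn_acceptance nonsynonymous acceptance for
#'   organelle genes.
#' @param organelle_private_rate per-site probability of a private
#'   mutation in the allopolyploid's organelle copy.
#' @param expression list: `meanlog`, `sdlog` of the lognormal FPKM
#'   baseline, `n_reps`, `rep_sd` (lognormal replicate noise),
#'   `biased_fraction` (share of pairs with a true expression shift),
#'   `paternal_share` (share of shifted pairs shifted toward the paternal
#'   copy) and `shift_log2` (true shift in log2 units).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(
    seed = 1L,
    n_genes = c(Other = 120, Dual = 20, pt_tar = 30, pt_int = 20, pt_com = 15,
                mt_tar = 30, mt_int = 20, mt_com = 15),
    codons_per_gene = 120,
    branch_lengths = c(outgroup = 0.12, b = 0.03, ac = 0.015, a = 0.015, c = 0.015),
    nonsyn_acceptance = c(Other = 0.5, Dual = 0.4, pt_tar = 0.35, pt_int = 0.3,
                          pt_com = 0.2, mt_tar = 0.35, mt_int = 0.3, mt_com = 0.2),
    variety_divergence = 0.002,
    post_hybrid_divergence = 0.005,
    quartet_conversion_rate = 0.15,
    direction_bias = 0.6,
    tract_fraction = 1.0,
    n_clade_families = 6,
    clade_codons = 150,
    clade_post_hybrid_divergence = 0,
    site_conversion_rate = 0.05,
    loss_prob = c(maternal = 0.08, paternal = 0.12),
    n_organelle_genes = c(plastid = 20, mitochondrion = 10),
    organelle_codons = 120,
    organelle_rate_scale = 0.5,
    organelle_nonsyn_acceptance = 0.4,
    organelle_private_rate = 0.002,
    expression = list(meanlog = 3, sdlog = 1.2, n_reps = 3, rep_sd = 0.05,
                      biased_fraction = 0.2, paternal_share = 0.5,
                      shift_log2 = 2)) {
  stopifnot(all(sort(names(n_genes)) == sort(FUNCTIONAL_CATEGORIES)),
            all(n_genes >= 0),
            all(c("outgroup", "b", "ac", "a", "c") %in% names(branch_lengths)),
            all(branch_lengths >= 0))
  check01 <- function(x, what) {
    if (any(x < 0 | x > 1)) stop(what, " must lie in [0, 1]")
  }
  check01(nonsyn_acceptance, "nonsyn_acceptance")
  check01(quartet_conversion_rate, "quartet_conversion_rate")
  check01(direction_bias, "direction_bias")
  check01(tract_fraction, "tract_fraction")
  check01(site_conversion_rate, "site_conversion_rate")
  check01(organelle_private_rate, "organelle_private_rate")
  check01(expression$biased_fraction, "expression$biased_fraction")
  check01(expression$paternal_share, "expression$paternal_share")
  if (is.matrix(loss_prob)) {
    stopifnot(all(rownames(loss_prob) %in% FUNCTIONAL_CATEGORIES),
              ncol(loss_prob) == 2L)
    colnames(loss_prob) <- c("maternal", "paternal")
  } else {
    stopifnot(all(c("maternal", "paternal") %in% names(loss_prob)))
    loss_prob <- matrix(rep(loss_prob[c("maternal", "paternal")],
                            each = length(FUNCTIONAL_CATEGORIES)),
                        ncol = 2,
                        dimnames = list(FUNCTIONAL_CATEGORIES,
                                        c("maternal", "paternal")))
  }
  check01(loss_prob, "loss_prob")
  structure(
    list(seed = as.integer(seed), n_genes = n_genes,
         codons_per_gene = codons_per_gene, branch_lengths = branch_lengths,
         nonsyn_acceptance = nonsyn_acceptance,
         variety_divergence = variety_divergence,
         post_hybrid_divergence = post_hybrid_divergence,
         quartet_conversion_rate = quartet_conversion_rate,
         direction_bias = direction_bias, tract_fraction = tract_fraction,
         n_clade_families = n_clade_families, clade_codons = clade_codons,
         clade_post_hybrid_divergence = clade_post_hybrid_divergence,
         site_conversion_rate = site_conversion_rate,
         loss_prob = loss_prob, n_organelle_genes = n_organelle_genes,
         organelle_codons = organelle_codons,
         organelle_rate_scale = organelle_rate_scale,
         organelle_nonsyn_acceptance = organelle_nonsyn_acceptance,
         organelle_private_rate = organelle_private_rate,
         expression = expression),
    class = "simulation_config")
}

# Jukes-Cantor evolution of a codon character vector: each site changes to
# a uniformly chosen different base with probability 3/4 (1 - exp(-4t/3));
# nonsynonymous proposals are kept with probability `acc`; proposals that
# create stop codons are always rejected.
.evolve_jc <- function(chars, t, acc) {
  if (t <= 0) return(chars)
  L <- length(chars)
  p <- 3 / 4 * (1 - exp(-4 * t / 3))
  hit <- which(stats::runif(L) < p)
  for (j in hit) {
    new_base <- sample(setdiff(.BASES, chars[j]), 1L)
    ci <- (j - 1L) %/% 3L
    cols <- (ci * 3L + 1L):(ci * 3L + 3L)
    ref <- paste(chars[cols], collapse = "")
    alt_chars <- chars[cols]
    alt_chars[j - ci * 3L] <- new_base
    alt <- paste(alt_chars, collapse = "")
    if (.is_stop(alt)) next
    if (.step_is_synonymous(ref, alt) || stats::runif(1) < acc) {
      chars[j] <- new_base
    }
  }
  chars
}

.random_coding <- function(n_codons) {
  unlist(strsplit(sample(.sense_codons(), n_codons, replace = TRUE), ""))
}

.collapse <- function(chars) paste(chars, collapse = "")

#' Simulate a labelled triangle-of-U dataset
#'
#' See [simulation_config()] for the generative model. The same seed
#' yields byte-identical output.
#'
#' @param config a [simulation_config].
#' @return An object of class `triangle_sim`: list with `config`, the two
#'   [cross_design]s (`designs`), per-OG alignments (`ogs`), the long
#'   `og_table`, `categories` (named og -> category), `ortholog_map` and
#'   `reference_annotation` (category transfer via outgroup orthologs),
#'   clade alignments (`clades`), organelle alignments per cross and
#'   compartment (`organelle`), an `expression` table, and `truth`
#'   (quartet conversions, losses, site conversions, organelle private
#'   mutations, expression classes, donor per cross).
#' @export
simulate_triangle <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  bl <- config$branch_lengths
  designs <- list(
    AB = cross_design("AB", maternal_genome = "A", paternal_genome = "B",
                      other_genomes = "C", outgroup = "OUT"),
    BC = cross_design("BC", maternal_genome = "B", paternal_genome = "C",
                      other_genomes = "A", outgroup = "OUT"))

  categories <- rep(names(config$n_genes), config$n_genes)
  n_og <- length(categories)
  og_ids <- sprintf("OG%04d", seq_len(n_og))
  names(categories) <- og_ids

  ogs <- vector("list", n_og)
  names(ogs) <- og_ids
  og_rows <- list()
  truth_quartet <- list()
  truth_loss <- list()

  for (i in seq_len(n_og)) {
    og <- og_ids[i]
    cat_i <- categories[[i]]
    acc <- config$nonsyn_acceptance[[cat_i]]
    L <- config$codons_per_gene
    anc <- .random_coding(L)
    seqs <- list(
      OUT = .evolve_jc(anc, bl[["outgroup"]], acc),
      B = .evolve_jc(anc, bl[["b"]], acc))
    ac_anc <- .evolve_jc(anc, bl[["ac"]], acc)
    seqs$A <- .evolve_jc(ac_anc, bl[["a"]], acc)
    seqs$C <- .evolve_jc(ac_anc, bl[["c"]], acc)

    # subgenome copies: parent state at hybridization + post-hybrid drift
    copies <- list(
      AB = list(maternal = .evolve_jc(seqs$A, config$post_hybrid_divergence, acc),
                paternal = .evolve_jc(seqs$B, config$post_hybrid_divergence, acc)),
      BC = list(maternal = .evolve_jc(seqs$B, config$post_hybrid_divergence, acc),
                paternal = .evolve_jc(seqs$C, config$post_hybrid_divergence, acc)))

    retained <- list()
    for (cross in names(copies)) {
      lost_m <- stats::runif(1) < config$loss_prob[cat_i, "maternal"]
      lost_p <- stats::runif(1) < config$loss_prob[cat_i, "paternal"]
      truth_loss[[length(truth_loss) + 1L]] <- data.frame(
        og_id = og, cross = cross, lost_maternal = lost_m,
        lost_paternal = lost_p, stringsAsFactors = FALSE)
      conv_dir <- NA_character_
      tract <- c(NA_integer_, NA_integer_)
      if (!lost_m && !lost_p &&
          stats::runif(1) < config$quartet_conversion_rate) {
        conv_dir <- if (stats::runif(1) < config$direction_bias) "P_to_M" else "M_to_P"
        tract_codons <- max(1L, round(config$tract_fraction * L))
        start <- if (tract_codons >= L) 0L else sample.int(L - tract_codons + 1L, 1L) - 1L
        tract <- c(start, start + tract_codons) # codons, half-open
        cols <- (start * 3L + 1L):(tract[2] * 3L)
        if (conv_dir == "P_to_M") {
          copies[[cross]]$maternal[cols] <- copies[[cross]]$paternal[cols]
        } else {
          copies[[cross]]$paternal[cols] <- copies[[cross]]$maternal[cols]
        }
      }
      truth_quartet[[length(truth_quartet) + 1L]] <- data.frame(
        og_id = og, cross = cross,
        converted = !is.na(conv_dir),
        direction = conv_dir,
        tract_start = tract[1], tract_end = tract[2],
        both_retained = !lost_m && !lost_p,
        stringsAsFactors = FALSE)
      retained[[cross]] <- c(maternal = !lost_m, paternal = !lost_p)
    }

    rec <- data.frame(
      gene_id = c(paste0(og, "_A"), paste0(og, "_B"), paste0(og, "_C"),
                  paste0(og, "_OUT")),
      genome = c("A", "B", "C", "OUT"),
      role = c("diploid_parent", "diploid_parent", "diploid_parent", "outgroup"),
      origin = "not_applicable",
      sequence = c(.collapse(seqs$A), .collapse(seqs$B), .collapse(seqs$C),
                   .collapse(seqs$OUT)),
      stringsAsFactors = FALSE)
    for (cross in names(copies)) {
      for (side in c("maternal", "paternal")) {
        if (!retained[[cross]][[side]]) next
        rec <- rbind(rec, data.frame(
          gene_id = paste0(og, "_", cross, "_", side),
          genome = cross, role = "subgenome", origin = side,
          sequence = .collapse(copies[[cross]][[side]]),
          stringsAsFactors = FALSE))
      }
    }
    ogs[[og]] <- codon_alignment(rec$gene_id, rec$genome, rec$role,
                                 rec$origin, rec$sequence)
    rec$og_id <- og
    rec$category <- cat_i
    og_rows[[i]] <- rec[, c("og_id", "gene_id", "genome", "role", "origin",
                            "category")]
  }
  og_table <- do.call(rbind, og_rows)
  og_table$tier <- "primary"
  # high-quality: one gene per parent, one per subgenome of both crosses, outgroup
  hq <- vapply(split(og_table, og_table$og_id), function(x) {
    sum(x$role == "subgenome") == 4L
  }, logical(1))
  og_table$tier[og_table$og_id %in% names(hq)[hq]] <- "high_quality"

  ortholog_map <- data.frame(
    gene_id = og_table$gene_id[og_table$role != "outgroup"],
    reference_gene_id = paste0(og_table$og_id[og_table$role != "outgroup"], "_OUT"),
    stringsAsFactors = FALSE)
  reference_annotation <- data.frame(
    reference_gene_id = paste0(og_ids, "_OUT"),
    category = unname(categories),
    stringsAsFactors = FALSE)

  # ---- gene-family clades for site-level conversion detection ----
  clades <- list(AB = list(), BC = list())
  truth_sites <- list()
  for (cross in names(designs)) {
    design <- designs[[cross]]
    for (k in seq_len(config$n_clade_families)) {
      fam <- sprintf("%s_fam%02d", cross, k)
      L <- config$clade_codons
      acc <- 0.4
      anc <- .random_coding(L)
      par_seqs <- list(
        B = .evolve_jc(anc, bl[["b"]], acc))
      ac_anc <- .evolve_jc(anc, bl[["ac"]], acc)
      par_seqs$A <- .evolve_jc(ac_anc, bl[["a"]], acc)
      par_seqs$C <- .evolve_jc(ac_anc, bl[["c"]], acc)
      pm <- par_seqs[[design$maternal_genome]]
      pp <- par_seqs[[design$paternal_genome]]
      varieties <- list(
        m1 = .evolve_jc(pm, config$variety_divergence, acc),
        m2 = .evolve_jc(pm, config$variety_divergence, acc),
        p1 = .evolve_jc(pp, config$variety_divergence, acc),
        p2 = .evolve_jc(pp, config$variety_divergence, acc))
      # two varieties never concordantly disagree with their genome's
      # canonical state: intra-genome polymorphism is discordant only, so
      # diagnostic states always represent the genome
      fix_concordant <- function(v1, v2, canonical) {
        bad <- which(v1 == v2 & v1 != canonical)
        v1[bad] <- canonical[bad]
        v2[bad] <- canonical[bad]
        list(v1, v2)
      }
      fm <- fix_concordant(varieties$m1, varieties$m2, pm)
      varieties$m1 <- fm[[1]]
      varieties$m2 <- fm[[2]]
      fp <- fix_concordant(varieties$p1, varieties$p2, pp)
      varieties$p1 <- fp[[1]]
      varieties$p2 <- fp[[2]]
      hom <- list(
        maternal = .evolve_jc(pm, config$clade_post_hybrid_divergence, acc),
        paternal = .evolve_jc(pp, config$clade_post_hybrid_divergence, acc))

      # diagnostic columns: varieties concordant per genome, states differ
      diag_cols <- integer(0)
      for (j in seq_len(3L * L)) {
        sm <- unique(c(varieties$m1[j], varieties$m2[j]))
        sp <- unique(c(varieties$p1[j], varieties$p2[j]))
        if (length(sm) == 1L && length(sp) == 1L && sm != sp &&
            sm %in% .BASES && sp %in% .BASES) {
          diag_cols <- c(diag_cols, j)
        }
      }
      states <- list()
      states[[design$maternal_genome]] <- vapply(diag_cols, function(j) varieties$m1[j], character(1))
      states[[design$paternal_genome]] <- vapply(diag_cols, function(j) varieties$p1[j], character(1))
      for (side in c("maternal", "paternal")) {
        other <- if (side == "maternal") design$paternal_genome else design$maternal_genome
        direction <- if (side == "maternal") "P_to_M" else "M_to_P"
        for (idx in seq_along(diag_cols)) {
          if (stats::runif(1) >= config$site_conversion_rate) next
          j <- diag_cols[idx]
          new_state <- states[[other]][idx]
          ci <- (j - 1L) %/% 3L
          cols <- (ci * 3L + 1L):(ci * 3L + 3L)
          alt <- hom[[side]][cols]
          alt[j - ci * 3L] <- new_state
          if (.is_stop(paste(alt, collapse = ""))) next # keep sequences stop-free
          ref_codon <- paste(hom[[side]][cols], collapse = "")
          hom[[side]][j] <- new_state
          eff <- .classify_codon_change(ref_codon, paste(alt, collapse = ""))
          truth_sites[[length(truth_sites) + 1L]] <- data.frame(
            cross = cross, clade_id = fam,
            gene_id = paste0(fam, "_", cross, "_", side),
            column = j - 1L, direction = direction,
            effect = if (eff[["synonymous"]] >= eff[["nonsynonymous"]]) "synonymous" else "nonsynonymous",
            stringsAsFactors = FALSE)
        }
      }
      rec <- data.frame(
        gene_id = c(paste0(fam, "_", design$maternal_genome, "_v1"),
                    paste0(fam, "_", design$maternal_genome, "_v2"),
                    paste0(fam, "_", design$paternal_genome, "_v1"),
                    paste0(fam, "_", design$paternal_genome, "_v2"),
                    paste0(fam, "_", cross, "_maternal"),
                    paste0(fam, "_", cross, "_paternal")),
        genome = c(design$maternal_genome, design$maternal_genome,
                   design$paternal_genome, design$paternal_genome,
                   cross, cross),
        role = c(rep("diploid_parent", 4), "subgenome", "subgenome"),
        origin = c(rep("not_applicable", 4), "maternal", "paternal"),
        sequence = c(.collapse(varieties$m1), .collapse(varieties$m2),
                     .collapse(varieties$p1), .collapse(varieties$p2),
                     .collapse(hom$maternal), .collapse(hom$paternal)),
        stringsAsFactors = FALSE)
      clades[[cross]][[fam]] <- codon_alignment(rec$gene_id, rec$genome,
                                                rec$role, rec$origin,
                                                rec$sequence)
    }
  }

  # ---- organelle genes: maternal inheritance + rare private mutations ----
  organelle <- list(AB = list(), BC = list())
  truth_private <- list()
  for (compartment in c("plastid", "mitochondrion")) {
    n_genes_c <- config$n_organelle_genes[[compartment]]
    for (g in seq_len(n_genes_c)) {
      gene <- sprintf("%s%02d", if (compartment == "plastid") "pt" else "mt", g)
      L <- config$organelle_codons
      acc <- config$organelle_nonsyn_acceptance
      sc <- config$organelle_rate_scale
      anc <- .random_coding(L)
      seqs <- list(B = .evolve_jc(anc, sc * bl[["b"]], acc))
      ac_anc <- .evolve_jc(anc, sc * bl[["ac"]], acc)
      seqs$A <- .evolve_jc(ac_anc, sc * bl[["a"]], acc)
      seqs$C <- .evolve_jc(ac_anc, sc * bl[["c"]], acc)
      for (cross in names(designs)) {
        design <- designs[[cross]]
        allo <- seqs[[design$maternal_genome]]
        hit <- which(stats::runif(length(allo)) < config$organelle_private_rate)
        for (j in hit) {
          new_base <- sample(setdiff(.BASES, allo[j]), 1L)
          ci <- (j - 1L) %/% 3L
          cols <- (ci * 3L + 1L):(ci * 3L + 3L)
          alt <- allo[cols]
          alt[j - ci * 3L] <- new_base
          if (.is_stop(paste(alt, collapse = ""))) next
          ref_codon <- paste(allo[cols], collapse = "")
          allo[j] <- new_base
          eff <- .classify_codon_change(ref_codon, paste(alt, collapse = ""))
          truth_private[[length(truth_private) + 1L]] <- data.frame(
            cross = cross, compartment = compartment, gene_id = gene,
            column = j - 1L,
            effect = if (eff[["synonymous"]] >= eff[["nonsynonymous"]]) "synonymous" else "nonsynonymous",
            stringsAsFactors = FALSE)
        }
        rec <- data.frame(
          gene_id = c(paste0(gene, "_A"), paste0(gene, "_B"), paste0(gene, "_C"),
                      paste0(gene, "_", cross)),
          genome = c("A", "B", "C", cross),
          role = c(rep("diploid_parent", 3), "allopolyploid"),
          origin = "not_applicable",
          sequence = c(.collapse(seqs$A), .collapse(seqs$B), .collapse(seqs$C),
                       .collapse(allo)),
          stringsAsFactors = FALSE)
        organelle[[cross]][[compartment]][[gene]] <-
          codon_alignment(rec$gene_id, rec$genome, rec$role, rec$origin,
                          rec$sequence)
      }
    }
  }

  # ---- expression with configured subgenome bias ----
  ex <- config$expression
  expr_rows <- list()
  truth_expr <- list()
  loss_df <- do.call(rbind, truth_loss)
  for (cross in names(designs)) {
    for (og in og_ids) {
      lost <- loss_df[loss_df$og_id == og & loss_df$cross == cross, ]
      if (lost$lost_maternal || lost$lost_paternal) next
      base <- stats::rlnorm(1, ex$meanlog, ex$sdlog)
      class <- "unbiased"
      mean_m <- base
      mean_p <- base
      if (stats::runif(1) < ex$biased_fraction) {
        if (stats::runif(1) < ex$paternal_share) {
          class <- "paternal_biased"
          mean_p <- base * 2^ex$shift_log2
        } else {
          class <- "maternal_biased"
          mean_m <- base * 2^ex$shift_log2
        }
      }
      reps_m <- mean_m * exp(stats::rnorm(ex$n_reps, 0, ex$rep_sd))
      reps_p <- mean_p * exp(stats::rnorm(ex$n_reps, 0, ex$rep_sd))
      row <- data.frame(og_id = og, cross = cross,
                        category = categories[[og]],
                        stringsAsFactors = FALSE)
      for (r in seq_len(ex$n_reps)) row[[paste0("m_rep", r)]] <- reps_m[r]
      for (r in seq_len(ex$n_reps)) row[[paste0("p_rep", r)]] <- reps_p[r]
      expr_rows[[length(expr_rows) + 1L]] <- row
      truth_expr[[length(truth_expr) + 1L]] <- data.frame(
        og_id = og, cross = cross, class = class, stringsAsFactors = FALSE)
    }
  }

  bind_or_empty <- function(lst, proto) {
    if (length(lst)) do.call(rbind, lst) else proto
  }
  structure(
    list(config = config, designs = designs, ogs = ogs, og_table = og_table,
         categories = categories, ortholog_map = ortholog_map,
         reference_annotation = reference_annotation, clades = clades,
         organelle = organelle,
         expression = bind_or_empty(expr_rows, NULL),
         truth = list(
           quartet = do.call(rbind, truth_quartet),
           losses = loss_df,
           sites = bind_or_empty(
             truth_sites,
             data.frame(cross = character(0), clade_id = character(0),
                        gene_id = character(0), column = integer(0),
                        direction = character(0), effect = character(0))),
           organelle_private = bind_or_empty(
             truth_private,
             data.frame(cross = character(0), compartment = character(0),
                        gene_id = character(0), column = integer(0),
                        effect = character(0))),
           expression = bind_or_empty(truth_expr, NULL),
           donor = list(AB = "A", BC = "B"))),
    class = "triangle_sim")
}

#' @export
print.triangle_sim <- function(x, ...) {
  cat(sprintf(
    "triangle_sim (seed %d): %d OGs, %d clade families/cross, %d+%d organelle genes\n",
    x$config$seed, length(x$ogs), x$config$n_clade_families,
    x$config$n_organelle_genes[["plastid"]],
    x$config$n_organelle_genes[["mitochondrion"]]))
  invisible(x)
}

#' Write a simulated dataset to a directory
#'
#' Emits aligned FASTA per ortholog group, clade and organelle gene,
#' TSV tables (ortholog groups, category annotation, expression) and the
#' truth tables as JSON. Output is byte-stable for a fixed seed.
#'
#' @param sim a [simulate_triangle()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sub in c("ogs", "clades", "organelle")) {
    dir.create(file.path(dir, sub), showWarnings = FALSE)
  }
  for (og in names(sim$ogs)) {
    write_codon_fasta(sim$ogs[[og]], file.path(dir, "ogs", paste0(og, ".fasta")))
  }
  for (cross in names(sim$clades)) {
    for (fam in names(sim$clades[[cross]])) {
      write_codon_fasta(sim$clades[[cross]][[fam]],
                        file.path(dir, "clades", paste0(fam, ".fasta")))
    }
  }
  for (cross in names(sim$organelle)) {
    for (compartment in names(sim$organelle[[cross]])) {
      for (gene in names(sim$organelle[[cross]][[compartment]])) {
        write_codon_fasta(
          sim$organelle[[cross]][[compartment]][[gene]],
          file.path(dir, "organelle",
                    paste0(cross, "_", compartment, "_", gene, ".fasta")))
      }
    }
  }
  write_tsv_table(sim$og_table, file.path(dir, "og_table.tsv"))
  write_tsv_table(sim$reference_annotation, file.path(dir, "annotation.tsv"))
  write_tsv_table(sim$ortholog_map, file.path(dir, "ortholog_map.tsv"))
  write_tsv_table(sim$expression, file.path(dir, "expression.tsv"))
  for (d in names(sim$designs)) {
    write_cross_design(sim$designs[[d]], file.path(dir, paste0("design_", d, ".json")))
  }
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  jsonlite::write_json(
    lapply(unclass(sim$config), function(x) if (is.matrix(x)) as.data.frame(x) else x),
    file.path(dir, "config.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
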