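# Maternal/paternal variant typing of allopolyploid organelle genes and
# cytoplasmic-donor inference.
#
# Plastid and mitochondrial genomes are uniparentally (maternally)
# inherited, so at columns where the candidate parental genomes differ, the
# allopolyploid's organelle gene should carry the maternal state. Counting
# which genome each variant matches, split synonymous/nonsynonymous,
# recovers the cytoplasmic donor; variants matching no candidate are
# private mutations accumulated since hybridization.

#' Construct a variant typing record
#'
#' One record per organelle gene: how many variant sites match each
#' candidate genome (split synonymous/nonsynonymous) and how many are
#' private to the allopolyploid.
#'
#' @param gene_id gene identifier.
#' @param genome_like named list mapping genome id to a numeric vector
#'   `c(synonymous =, nonsynonymous =)`.
#' @param private_syn,private_nonsyn synonymous/nonsynonymous private
#'   variant counts (when the split is known).
#' @param private_count total private variants; defaults to
#'   `private_syn + private_nonsyn`.
#' @return An object of class `variant_typing_record`.
#' @export
variant_typing_record <- function(gene_id, genome_like,
                                  private_syn = 0, private_nonsyn = 0,
                                  private_count = private_syn + private_nonsyn) {
  stopifnot(is.list(genome_like), !is.null(names(genome_like)))
  genome_like <- lapply(genome_like, function(v) {
    stopifnot(all(c("synonymous", "nonsynonymous") %in% names(v)),
              all(v >= 0))
    v[c("synonymous", "nonsynonymous")]
  })
  stopifnot(private_count >= 0, private_syn >= 0, private_nonsyn >= 0)
  total <- sum(unlist(genome_like)) + private_count
  structure(
    list(gene_id = gene_id, genome_like = genome_like,
         private_syn = private_syn, private_nonsyn = private_nonsyn,
         private_count = private_count, total = total),
    class = "variant_typing_record")
}

#' Type variant sites of an allopolyploid organelle gene by parental origin
#'
#' Scans every alignment column of one organelle gene. At a column, the
#' allopolyploid state is compared with the states of the candidate genomes
#' (parents plus `other_genomes` of the cross design; a genome represented
#' by several varieties must be internally concordant, otherwise the column
#' is skipped). A column is counted as
#' \itemize{
#'   \item *genome-like* when the allopolyploid matches exactly one
#'     candidate genome and differs from all others;
#'   \item *private* when the allopolyploid differs from every candidate;
#'   \item *non-diagnostic* (skipped) when two or more candidates share the
#'     allopolyploid's state at a column where candidates differ.
#' }
#' Synonymous/nonsynonymous effects are computed by substituting the
#' alternative state into the allopolyploid's codon context; codons hit by
#' several variant columns fall back to mutational-pathway averaging, so
#' effect counts can be fractional.
#'
#' @param aln a [codon_alignment] holding one allopolyploid sequence
#'   (genome equal to `design$allopolyploid_id`) and at least two candidate
#'   genome sequences.
#' @param design a [cross_design].
#' @return A [variant_typing_record] with attributes `non_diagnostic` and
#'   `skipped` (column counts).
#' @export
type_variants <- function(aln, design) {
  recs <- aln$records
  allo_idx <- which(recs$genome == design$allopolyploid_id)
  if (length(allo_idx) != 1L) {
    stop("expected exactly one allopolyploid sequence (genome ",
         design$allopolyploid_id, "), found ", length(allo_idx))
  }
  candidates <- c(design$maternal_genome, design$paternal_genome,
                  design$other_genomes)
  cand_rows <- lapply(candidates, function(g) which(recs$genome == g))
  names(cand_rows) <- candidates
  present <- candidates[lengths(cand_rows) > 0L]
  if (length(present) < 2L) stop("need sequences for at least 2 candidate genomes")
  cand_rows <- cand_rows[present]

  m <- .aln_matrix(aln)
  allo <- m[allo_idx, ]
  ncol_aln <- aln$length

  assign_genome <- character(ncol_aln)   # "" none, genome id, or "private"
  alt_state <- character(ncol_aln)       # alternative state used for effect
  non_diag <- 0L
  skipped <- 0L

  for (j in seq_len(ncol_aln)) {
    states <- vapply(cand_rows, function(rows) {
      s <- unique(m[rows, j])
      if (length(s) == 1L) s else NA_character_
    }, character(1))
    if (anyNA(states)) { # intra-genome discordance at this column
      raw <- c(m[unlist(cand_rows), j], allo[j])
      if (length(unique(raw)) > 1L) skipped <- skipped + 1L
      next
    }
    if (any(!states %in% .BASES) || !allo[j] %in% .BASES) {
      # gap/N at a column that is not trivially invariant
      if (length(unique(c(states, allo[j]))) > 1L) skipped <- skipped + 1L
      next
    }
    if (all(states == allo[j])) next # invariant column
    hits <- names(states)[states == allo[j]]
    if (length(hits) == 0L) {
      assign_genome[j] <- "private"
      tab <- table(states)
      alt_state[j] <- names(tab)[order(-tab, names(tab))][1] # modal, ties alphabetic
    } else if (length(hits) == 1L) {
      assign_genome[j] <- hits
      others <- states[names(states) != hits]
      tab <- table(others)
      alt_state[j] <- names(tab)[order(-tab, names(tab))][1]
    } else {
      non_diag <- non_diag + 1L
    }
  }

  counts <- lapply(c(present, private = "private"), function(g) {
    c(synonymous = 0, nonsynonymous = 0)
  })
  names(counts) <- c(present, "private")
  private_unclassified <- 0

  variant_cols <- which(assign_genome != "")
  if (length(variant_cols)) {
    codon_of <- (variant_cols - 1L) %/% 3L
    for (grp in split(variant_cols, list(codon_of, assign_genome[variant_cols]),
                      drop = TRUE)) {
      target <- assign_genome[grp[1]]
      ci <- (grp[1] - 1L) %/% 3L
      cols <- (ci * 3L + 1L):(ci * 3L + 3L)
      ref_codon <- paste(allo[cols], collapse = "")
      alt <- allo[cols]
      alt[match(grp, cols)] <- alt_state[grp]
      alt_codon <- paste(alt, collapse = "")
      eff <- .classify_codon_change(ref_codon, alt_codon)
      if (anyNA(eff)) {
        warning("gap/N in codon context at columns ",
                paste(grp, collapse = ","), "; effect not classified")
        if (target == "private") {
          private_unclassified <- private_unclassified + length(grp)
        } else {
          skipped <- skipped + length(grp)
          next
        }
      } else {
        counts[[target]] <- counts[[target]] + eff
      }
    }
  }

  rec <- variant_typing_record(
    gene_id = recs$gene_id[allo_idx],
    genome_like = counts[present],
    private_syn = counts[["private"]][["synonymous"]],
    private_nonsyn = counts[["private"]][["nonsynonymous"]],
    private_count = sum(counts[["private"]]) + private_unclassified)
  attr(rec, "non_diagnostic") <- non_diag
  attr(rec, "skipped") <- skipped
  rec
}

#' Aggregate variant typing records for one organelle compartment
#'
#' Sums genome-like synonymous/nonsynonymous counts, private counts, and
#' the grand total over the protein-coding genes of one compartment.
#'
#' @param records list of [variant_typing_record]s sharing one
#'   allopolyploid.
#' @param compartment `"plastid"` or `"mitochondrion"` (annotation only).
#' @return An object of class `typing_summary`: per-genome synonymous and
#'   nonsynonymous totals, `private`, `total_synonymous`,
#'   `total_nonsynonymous` (both including classified private variants) and
#'   the grand `sum`.
#' @export
aggregate_typing <- function(records, compartment = c("plastid", "mitochondrion")) {
  compartment <- match.arg(compartment)
  genomes <- unique(unlist(lapply(records, function(r) names(r$genome_like))))
  gl <- matrix(0, nrow = length(genomes), ncol = 2,
               dimnames = list(genomes, c("synonymous", "nonsynonymous")))
  private <- 0
  private_syn <- 0
  private_nonsyn <- 0
  for (r in records) {
    for (g in names(r$genome_like)) gl[g, ] <- gl[g, ] + r$genome_like[[g]]
    private <- private + r$private_count
    private_syn <- private_syn + r$private_syn
    private_nonsyn <- private_nonsyn + r$private_nonsyn
  }
  structure(
    list(compartment = compartment,
         genome_like = gl,
         private = private,
         total_synonymous = sum(gl[, "synonymous"]) + private_syn,
         total_nonsynonymous = sum(gl[, "nonsynonymous"]) + private_nonsyn,
         sum = sum(gl) + private),
    class = "typing_summary")
}

#' @export
print.typing_summary <- function(x, ...) {
  cat(sprintf("typing_summary (%s)\n", x$compartment))
  for (g in rownames(x$genome_like)) {
    cat(sprintf("  %s-like: S %.6g, N %.6g\n", g,
                x$genome_like[g, "synonymous"], x$genome_like[g, "nonsynonymous"]))
  }
  cat(sprintf("  private: %.6g\n  Sum: %.6g\n", x$private, x$sum))
  invisible(x)
}

#' Read per-type variant counts in the published table layout
#'
#' Parses a TSV with columns `allopolyploid`, `compartment`, `type`
#' (a genome label such as `A-like`, or `Private`), `synonymous`,
#' `nonsynonymous` and `count`, and builds one [variant_typing_record]
#' per allopolyploid and compartment (genome ids are the type labels with
#' the `-like` suffix stripped).
#'
#' @param path TSV path.
#' @return Nested list: `records[[allopolyploid]][[compartment]]` is a
#'   [variant_typing_record].
#' @export
read_typing_counts <- function(path) {
  x <- read_tsv_table(path)
  need <- c("allopolyploid", "compartment", "type", "synonymous",
            "nonsynonymous", "count")
  stopifnot(all(need %in% names(x)))
  out <- list()
  for (allo in unique(x$allopolyploid)) {
    for (compartment in unique(x$compartment[x$allopolyploid == allo])) {
      rows <- x[x$allopolyploid == allo & x$compartment == compartment, ]
      like <- rows[rows$type != "Private", ]
      gl <- lapply(seq_len(nrow(like)), function(i) {
        c(synonymous = like$synonymous[i], nonsynonymous = like$nonsynonymous[i])
      })
      names(gl) <- sub("-like$", "", like$type)
      priv <- rows[rows$type == "Private", ]
      priv_n <- if (nrow(priv)) sum(priv$count) else 0
      out[[allo]][[compartment]] <- variant_typing_record(
        gene_id = paste(allo, compartment, sep = ":"),
        genome_like = gl, private_count = priv_n)
    }
  }
  out
}

#' Infer the cytoplasmic (maternal) donor from typing summaries
#'
#' The candidate genome with the largest genome-like variant count is the
#' putative donor; support is its share of all genome-like (diagnostic)
#' variants. The call is declared ambiguous when support falls below the
#' threshold, when private variants make up too large a fraction of all
#' variants (the signature of an unresolved or complex origin), or on ties.
#'
#' @param summaries one [aggregate_typing()] result or a list of them
#'   (e.g. plastid and mitochondrial) for the same allopolyploid.
#' @param support_threshold minimum support for a confident call
#'   (default 0.8).
#' @param private_threshold maximum tolerated private fraction of all
#'   variants (default 0.4).
#' @return List with `genome_id`, `support`, `private_fraction`, `status`
#'   (`"confident"` or `"ambiguous"`) and `reason`.
#' @export
infer_maternal_donor <- function(summaries, support_threshold = 0.8,
                                 private_threshold = 0.4) {
  if (inherits(summaries, "typing_summary")) summaries <- list(summaries)
  genomes <- unique(unlist(lapply(summaries, function(s) rownames(s$genome_like))))
  counts <- stats::setNames(numeric(length(genomes)), genomes)
  private <- 0
  for (s in summaries) {
    counts[rownames(s$genome_like)] <- counts[rownames(s$genome_like)] +
      rowSums(s$genome_like)
    private <- private + s$private
  }
  total_diag <- sum(counts)
  if (total_diag == 0) {
    return(list(genome_id = NA_character_, support = NA_real_,
                private_fraction = if (private > 0) 1 else NA_real_,
                status = "ambiguous", reason = "no signal"))
  }
  best <- max(counts)
  winners <- names(counts)[counts == best]
  support <- best / total_diag
  private_fraction <- private / (total_diag + private)
  if (length(winners) > 1L) {
    return(list(genome_id = NA_character_, support = support,
                private_fraction = private_fraction,
                status = "ambiguous", reason = "tie between candidate genomes"))
  }
  reason <- NULL
  if (support < support_threshold) reason <- c(reason, "support below threshold")
  if (private_fraction >= private_threshold) reason <- c(reason, "private-heavy")
  list(genome_id = winners,
       support = support,
       private_fraction = private_fraction,
       status = if (is.null(reason)) "confident" else "ambiguous",
       reason = if (is.null(reason)) "" else paste(reason, collapse = "; "))
}
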