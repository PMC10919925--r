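# Functional-category assignment (organelle-interaction scheme) and
# maternal-vs-paternal retention bias.
#
# Nuclear genes are binned into 8 categories by organelle targeting and
# interaction strength: Other (non-targeted), Dual (dual-targeted), and per
# compartment targeted-only (pt_tar/mt_tar), interacting-without-complex
# (pt_int/mt_int) and chimeric enzyme complex members (pt_com/mt_com).

#' The 8 functional category labels, in canonical order
#' @export
FUNCTIONAL_CATEGORIES <- c("Other", "Dual", "pt_tar", "pt_int", "pt_com",
                           "mt_tar", "mt_int", "mt_com")

# interaction-strength rank used for conflict resolution
.category_rank <- c(Other = 0, Dual = 1,
                    pt_tar = 2, mt_tar = 2,
                    pt_int = 3, mt_int = 3,
                    pt_com = 4, mt_com = 4)

#' Assign a nuclear gene to a functional category via reference orthology
#'
#' A gene inherits the category of its reference-genome ortholog(s). With
#' several reference orthologs of different categories, the strongest
#' interaction wins (`com > int > tar > Dual > Other`); a tie between a
#' plastid and a mitochondrial category of equal strength resolves to
#' `Dual`. A gene without any reference ortholog is `Other`.
#'
#' @param gene_id gene to classify.
#' @param ortholog_map data frame with columns `gene_id`,
#'   `reference_gene_id`.
#' @param reference_annotation data frame with columns `reference_gene_id`,
#'   `category` (one of [FUNCTIONAL_CATEGORIES]).
#' @return A single category label.
#' @export
assign_category <- function(gene_id, ortholog_map, reference_annotation) {
  refs <- ortholog_map$reference_gene_id[ortholog_map$gene_id == gene_id]
  if (length(refs) == 0L) return("Other")
  missing <- setdiff(refs, reference_annotation$reference_gene_id)
  if (length(missing)) {
    stop("reference annotation lacks gene(s): ", paste(missing, collapse = ", "))
  }
  cats <- unique(reference_annotation$category[
    match(refs, reference_annotation$reference_gene_id)])
  if (!all(cats %in% FUNCTIONAL_CATEGORIES)) {
    stop("unknown category label: ",
         paste(setdiff(cats, FUNCTIONAL_CATEGORIES), collapse = ", "))
  }
  if (length(cats) == 1L) return(cats)
  r <- .category_rank[cats]
  top <- cats[r == max(r)]
  if (length(top) == 1L) return(top)
  if (max(r) <= 1) return(top[1])
  comp <- substr(top, 1, 2)
  if (all(c("pt", "mt") %in% comp)) "Dual" else top[1]
}

#' Per-category subgenome retention counts and bias
#'
#' For every functional category, computes the fraction of ortholog groups
#' with a maternal-parent gene that retain a maternal-subgenome copy
#' (`r_m`), the paternal analogue (`r_p`), and the retention bias
#' `r_m - r_p`. Ortholog groups that lost both subgenome copies are
#' excluded from the denominators (retention is measured relative to
#' parental presence). Each category is tested against `Other` with
#' [retention_bias_test()].
#'
#' @param og_table data frame with one row per gene: columns `og_id`,
#'   `gene_id`, `genome`, `role` (`diploid_parent` / `subgenome` /
#'   `outgroup`), `origin` (`maternal` / `paternal` / `not_applicable`).
#' @param categories named character vector mapping `og_id` to a category;
#'   alternatively `og_table` may carry a `category` column.
#' @param design a [cross_design].
#' @return Data frame of per-category retention summaries with columns
#'   `category`, `n_parent_genes`, `retained_maternal`, `retained_paternal`,
#'   `r_m`, `r_p`, `bias`, `lost_m_only`, `lost_p_only`, `p_value_vs_other`.
#' @export
retention_counts <- function(og_table, categories = NULL, design) {
  if (is.null(categories)) {
    if (!"category" %in% names(og_table)) {
      stop("provide `categories` or a category column in og_table")
    }
    categories <- tapply(og_table$category, og_table$og_id, function(x) x[1])
  }
  ogs <- unique(og_table$og_id)
  has <- function(og_rows, genome, role, origin = NULL) {
    ok <- og_rows$genome == genome & og_rows$role == role
    if (!is.null(origin)) ok <- ok & og_rows$origin == origin
    any(ok)
  }
  per_og <- do.call(rbind, lapply(ogs, function(og) {
    r <- og_table[og_table$og_id == og, , drop = FALSE]
    data.frame(
      og_id = og,
      category = unname(categories[og]),
      parent_m = has(r, design$maternal_genome, "diploid_parent"),
      parent_p = has(r, design$paternal_genome, "diploid_parent"),
      sub_m = has(r, design$allopolyploid_id, "subgenome", "maternal"),
      sub_p = has(r, design$allopolyploid_id, "subgenome", "paternal"),
      stringsAsFactors = FALSE)
  }))
  per_og$both_lost <- !per_og$sub_m & !per_og$sub_p

  summarize_cat <- function(cat) {
    x <- per_og[per_og$category == cat, , drop = FALSE]
    den_m <- sum(x$parent_m & !x$both_lost)
    den_p <- sum(x$parent_p & !x$both_lost)
    ret_m <- sum(x$parent_m & !x$both_lost & x$sub_m)
    ret_p <- sum(x$parent_p & !x$both_lost & x$sub_p)
    data.frame(
      category = cat,
      n_parent_genes = sum(x$parent_m | x$parent_p),
      retained_maternal = ret_m,
      retained_paternal = ret_p,
      r_m = if (den_m > 0) ret_m / den_m else NA_real_,
      r_p = if (den_p > 0) ret_p / den_p else NA_real_,
      lost_m_only = sum(x$parent_m & !x$sub_m & x$sub_p),
      lost_p_only = sum(x$parent_p & !x$sub_p & x$sub_m),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(FUNCTIONAL_CATEGORIES, summarize_cat))
  out$bias <- out$r_m - out$r_p
  other <- out[out$category == "Other", ]
  out$p_value_vs_other <- vapply(seq_len(nrow(out)), function(i) {
    if (out$category[i] == "Other") return(NA_real_)
    retention_bias_test(out[i, ], other)
  }, numeric(1))
  out[, c("category", "n_parent_genes", "retained_maternal",
          "retained_paternal", "r_m", "r_p", "bias",
          "lost_m_only", "lost_p_only", "p_value_vs_other")]
}

#' Fisher exact test of retention bias against the non-targeted control
#'
#' Two-sided Fisher exact test on the 2x2 table of
#' (maternal-only-lost, paternal-only-lost) counts for a focal category
#' versus `Other`. Asymmetric loss that differs between a category and the
#' control is the signal of category-specific retention bias.
#'
#' @param category_summary,other_summary one-row data frames (or lists)
#'   carrying `lost_m_only` and `lost_p_only` counts, as produced by
#'   [retention_counts()].
#' @return The p-value; `1` with attribute `flag = "empty margin"` when a
#'   margin of the table is empty.
#' @export
retention_bias_test <- function(category_summary, other_summary) {
  tab <- matrix(c(category_summary$lost_m_only, category_summary$lost_p_only,
                  other_summary$lost_m_only, other_summary$lost_p_only),
                nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(structure(1, flag = "empty margin"))
  }
  stats::fisher.test(tab)$p.value
}
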