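# Homoeolog expression-bias classification.
#
# A deterministic mean-ratio classifier: replicate FPKM values are averaged
# per homoeolog, a pseudocount stabilises the ratio, and pairs are called
# maternally/paternally biased at |log2 fold change| >= 1 (values exactly
# at the threshold are biased). Pairs with both means below the expression
# floor are not_expressed.

#' Classify one homoeolog pair by expression log2 fold change
#'
#' @param expr_m,expr_p non-negative replicate FPKM vectors for the
#'   maternal and paternal homoeolog.
#' @param pseudocount added to both means before the ratio (default 0.1).
#' @param floor minimum mean FPKM for a pair to count as expressed
#'   (default 1).
#' @param threshold |log2FC| at or above which a pair is biased (default 1).
#' @param og_id,category identifiers carried into the record.
#' @return One-row data frame (`expression_bias_record`) with columns
#'   `og_id`, `expr_maternal`, `expr_paternal`, `log2fc`
#'   (log2 of paternal over maternal), `bias_class` (`maternal_biased`,
#'   `paternal_biased`, `unbiased`, `not_expressed`) and `category`.
#' @examples
#' homoeolog_log2fc(c(200, 200), c(50, 50), pseudocount = 0) # maternal_biased
#' @export
homoeolog_log2fc <- function(expr_m, expr_p, pseudocount = 0.1, floor = 1,
                             threshold = 1, og_id = NA_character_,
                             category = NA_character_) {
  if (any(expr_m < 0) || any(expr_p < 0)) stop("negative FPKM")
  if (length(expr_m) < 1L || length(expr_p) < 1L) stop("need >= 1 replicate")
  mean_m <- mean(expr_m)
  mean_p <- mean(expr_p)
  log2fc <- log2((mean_p + pseudocount) / (mean_m + pseudocount))
  bias_class <- if (mean_m < floor && mean_p < floor) {
    "not_expressed"
  } else if (log2fc >= threshold) {
    "paternal_biased"
  } else if (log2fc <= -threshold) {
    "maternal_biased"
  } else {
    "unbiased"
  }
  data.frame(og_id = og_id, expr_maternal = mean_m, expr_paternal = mean_p,
             log2fc = log2fc, bias_class = bias_class, category = category,
             stringsAsFactors = FALSE)
}

#' Per-category counts of expression-biased homoeologs
#'
#' Counts maternally and paternally biased pairs per functional category
#' (`not_expressed` pairs are excluded from all denominators), computes
#' the maternal:paternal biased ratio, and a two-sided Fisher exact
#' p-value of each category's biased counts against `Other`.
#'
#' @param records data frame of rows from [homoeolog_log2fc()].
#' @return Data frame with columns `category`, `n_expressed`,
#'   `maternal_biased`, `paternal_biased`, `unbiased`, `mp_ratio`,
#'   `p_value_vs_other`.
#' @export
bias_summary <- function(records) {
  per_cat <- do.call(rbind, lapply(FUNCTIONAL_CATEGORIES, function(cat) {
    x <- records[records$category == cat &
                   records$bias_class != "not_expressed", , drop = FALSE]
    data.frame(category = cat,
               n_expressed = nrow(x),
               maternal_biased = sum(x$bias_class == "maternal_biased"),
               paternal_biased = sum(x$bias_class == "paternal_biased"),
               unbiased = sum(x$bias_class == "unbiased"),
               stringsAsFactors = FALSE)
  }))
  per_cat$mp_ratio <- ifelse(per_cat$paternal_biased > 0,
                             per_cat$maternal_biased / per_cat$paternal_biased,
                             NA_real_)
  other <- per_cat[per_cat$category == "Other", ]
  per_cat$p_value_vs_other <- vapply(seq_len(nrow(per_cat)), function(i) {
    if (per_cat$category[i] == "Other") return(NA_real_)
    tab <- matrix(c(per_cat$maternal_biased[i], per_cat$paternal_biased[i],
                    other$maternal_biased, other$paternal_biased),
                  nrow = 2, byrow = TRUE)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
    stats::fisher.test(tab)$p.value
  }, numeric(1))
  per_cat
}
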