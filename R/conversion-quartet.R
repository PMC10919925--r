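# Quartet similarity rule for homoeologous gene conversion.
#
# Each high-quality ortholog group contributes four focal sequences:
# maternal parent, paternal parent, and the allopolyploid's maternal and
# paternal subgenome copies. Without conversion each subgenome copy is most
# similar to its own parent (orthologous similarity beats homoeologous
# similarity); a large conversion makes the homoeolog pair more similar
# than the ortholog pairs, and which ortholog similarity dropped tells the
# direction.

#' Classify one ortholog group with the quartet similarity rule
#'
#' Computes four identities on jointly ungapped columns:
#' `o1` maternal-subgenome copy vs maternal parent, `o2` paternal-subgenome
#' copy vs paternal parent, `h1` the homoeolog pair, and `h2` the
#' paternal-subgenome copy vs the maternal parent. The decision tree:
#' \enumerate{
#'   \item both ortholog similarities exceed both homoeolog similarities
#'     (by more than `epsilon`): no conversion;
#'   \item `h1` exceeds both ortholog similarities: directional -- the copy
#'     whose own-parent similarity dropped is the converted one
#'     (`o1 < o2`: paternal overwrote maternal, `P_to_M`; `o1 > o2`:
#'     `M_to_P`; tie: reciprocal/unknown);
#'   \item both homoeolog similarities exceed both ortholog similarities:
#'     reciprocal or unknown;
#'   \item anything else: no conversion, flagged `weak-signal`.
#' }
#' Parents must differ at `min_diag` comparable sites or the call is
#' `reciprocal_or_unknown` with flag `insufficient divergence`.
#'
#' @param og_alignment [codon_alignment] with exactly the four focal
#'   sequences: two `diploid_parent` records whose genomes match the cross
#'   design, and two `subgenome` records with maternal/paternal origin.
#' @param design a [cross_design].
#' @param epsilon tie tolerance on similarity comparisons (default 0:
#'   strict inequalities, exact ties fall through to reciprocal/unknown).
#' @param min_diag minimum number of comparable sites at which the parents
#'   must differ (default 3).
#' @param og_id ortholog-group identifier carried into the call.
#' @param category functional category carried into the call.
#' @return Object of class `quartet_call` with fields `og_id`, `call`
#'   (`no_conversion`, `P_to_M`, `M_to_P`, `reciprocal_or_unknown`), the
#'   four similarities `o1`, `o2`, `h1`, `h2`, `flag` and `category`.
#' @export
classify_quartet <- function(og_alignment, design, epsilon = 0, min_diag = 3,
                             og_id = NA_character_, category = NA_character_) {
  r <- og_alignment$records
  pick <- function(genome, role, origin = NULL) {
    ok <- r$genome == genome & r$role == role
    if (!is.null(origin)) ok <- ok & r$origin == origin
    i <- which(ok)
    if (length(i) != 1L) {
      stop("expected exactly one sequence for ", genome, "/", role,
           if (!is.null(origin)) paste0("/", origin) else "", ", found ", length(i))
    }
    r$sequence[i]
  }
  par_m <- pick(design$maternal_genome, "diploid_parent")
  par_p <- pick(design$paternal_genome, "diploid_parent")
  sub_m <- pick(design$allopolyploid_id, "subgenome", "maternal")
  sub_p <- pick(design$allopolyploid_id, "subgenome", "paternal")

  ca <- strsplit(par_m, "")[[1]]
  cb <- strsplit(par_p, "")[[1]]
  comparable <- ca %in% .BASES & cb %in% .BASES
  n_diag <- sum(ca[comparable] != cb[comparable])

  o1 <- pairwise_identity(sub_m, par_m)
  o2 <- pairwise_identity(sub_p, par_p)
  h1 <- pairwise_identity(sub_m, sub_p)
  h2 <- pairwise_identity(sub_p, par_m)

  make <- function(call, flag = "") {
    structure(list(og_id = og_id, call = call,
                   o1 = o1, o2 = o2, h1 = h1, h2 = h2,
                   n_parent_diffs = n_diag, flag = flag, category = category),
              class = "quartet_call")
  }

  if (n_diag < min_diag) {
    return(make("reciprocal_or_unknown", "insufficient divergence"))
  }
  gt <- function(x, y) x > y + epsilon
  if (gt(o1, h1) && gt(o2, h1) && gt(o1, h2) && gt(o2, h2)) {
    return(make("no_conversion"))
  }
  if (gt(h1, o1) && gt(h1, o2)) {
    if (gt(o2, o1)) return(make("P_to_M"))
    if (gt(o1, o2)) return(make("M_to_P"))
    return(make("reciprocal_or_unknown", "direction tie"))
  }
  if (gt(h1, o1) && gt(h1, o2) && gt(h2, o1) && gt(h2, o2)) {
    return(make("reciprocal_or_unknown"))
  }
  make("no_conversion", "weak-signal")
}

#' @export
print.quartet_call <- function(x, ...) {
  cat(sprintf("quartet_call %s: %s (o1=%.4f o2=%.4f h1=%.4f h2=%.4f)%s\n",
              x$og_id, x$call, x$o1, x$o2, x$h1, x$h2,
              if (nzchar(x$flag)) paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

#' Summarize directional conversion calls per functional category
#'
#' Builds the genome-wide conversion table: per-category counts of
#' maternal-to-paternal and paternal-to-maternal calls, the directional
#' percentage `ratio_pct = round(100 * M_to_P / P_to_M)`, and aggregate
#' rows for plastid-targeted genes (pt_tar + pt_int + pt_com),
#' mitochondria-targeted genes (mt_tar + mt_int + mt_com), organelle-targeted
#' genes excluding Dual, and the overall total.
#'
#' @param calls either a list of `quartet_call` objects, or a data frame of
#'   pre-tabulated per-category counts with columns `category`, `m_to_p`,
#'   `p_to_m` (one row per leaf category).
#' @return Data frame with columns `category`, `m_to_p`, `p_to_m`,
#'   `n_events`, `ratio_pct`. `ratio_pct` is `Inf` when only
#'   maternal-to-paternal events exist and `NA` when a category has no
#'   directional events.
#' @export
summarize_conversions <- function(calls) {
  if (is.data.frame(calls)) {
    stopifnot(all(c("category", "m_to_p", "p_to_m") %in% names(calls)))
    counts <- calls
  } else {
    df <- data.frame(
      category = vapply(calls, function(x) x$category, character(1)),
      call = vapply(calls, function(x) x$call, character(1)),
      stringsAsFactors = FALSE)
    counts <- do.call(rbind, lapply(FUNCTIONAL_CATEGORIES, function(cat) {
      x <- df[df$category == cat, , drop = FALSE]
      data.frame(category = cat,
                 m_to_p = sum(x$call == "M_to_P"),
                 p_to_m = sum(x$call == "P_to_M"),
                 stringsAsFactors = FALSE)
    }))
  }
  counts <- counts[match(intersect(FUNCTIONAL_CATEGORIES, counts$category),
                         counts$category), , drop = FALSE]
  agg <- function(label, cats) {
    x <- counts[counts$category %in% cats, , drop = FALSE]
    data.frame(category = label, m_to_p = sum(x$m_to_p), p_to_m = sum(x$p_to_m),
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    counts[, c("category", "m_to_p", "p_to_m")],
    agg("Plastid-targeted genes", c("pt_tar", "pt_int", "pt_com")),
    agg("Mitochondria-targeted genes", c("mt_tar", "mt_int", "mt_com")),
    agg("Organelle-targeted excluding Dual",
        c("pt_tar", "pt_int", "pt_com", "mt_tar", "mt_int", "mt_com")),
    agg("Total", FUNCTIONAL_CATEGORIES))
  out$n_events <- out$m_to_p + out$p_to_m
  out$ratio_pct <- ifelse(
    out$p_to_m > 0, round(100 * out$m_to_p / out$p_to_m),
    ifelse(out$m_to_p > 0, Inf, NA_real_))
  rownames(out) <- NULL
  out
}
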