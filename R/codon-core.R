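#' Pairwise sequence identity over comparable columns
#'
#' Fraction of identical columns among columns where both sequences are
#' ungapped and unambiguous (`A/C/G/T` in both). The quartet conversion rule
#' is built entirely on this statistic.
#'
#' @param a,b aligned sequences of equal length (character scalars).
#' @return Identity fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("sequences must have equal length")
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  ok <- ca %in% .BASES & cb %in% .BASES
  if (!any(ok)) stop("no overlap: no jointly ungapped, unambiguous columns")
  sum(ca[ok] == cb[ok]) / sum(ok)
}

#' Classify a single-site substitution as synonymous or nonsynonymous
#'
#' Compares two codons differing at one position under the standard genetic
#' code: synonymous iff both encode the same amino acid. A substitution that
#' creates or removes a stop codon is nonsynonymous.
#'
#' @param ref_codon,alt_codon codons over `A/C/G/T` differing at
#'   `pos_in_codon`.
#' @param pos_in_codon 0-based position within the codon (0, 1 or 2).
#' @return `"synonymous"` or `"nonsynonymous"`; `NA_character_` (with a
#'   warning) when either codon contains a gap or `N`.
#' @examples
#' classify_site_substitution("GAA", "GAG", 2) # synonymous (Glu/Glu)
#' classify_site_substitution("TTT", "TTA", 2) # nonsynonymous (Phe/Leu)
#' @export
classify_site_substitution <- function(ref_codon, alt_codon, pos_in_codon) {
  stopifnot(pos_in_codon %in% 0:2)
  if (grepl("[^ACGT]", ref_codon) || grepl("[^ACGT]", alt_codon)) {
    warning("codon with gap/N at site; skipped")
    return(NA_character_)
  }
  p <- pos_in_codon + 1L
  same_elsewhere <- all(strsplit(ref_codon, "")[[1]][-p] ==
                          strsplit(alt_codon, "")[[1]][-p])
  if (!same_elsewhere) {
    stop("codons differ outside pos_in_codon; use pathway averaging instead")
  }
  if (.step_is_synonymous(ref_codon, alt_codon)) "synonymous" else "nonsynonymous"
}

# Fractional (synonymous, nonsynonymous) effect of the differences between
# two codons; single-position differences give a 0/1 split, multi-position
# differences average over minimal mutational pathways.
.classify_codon_change <- function(ref_codon, alt_codon) {
  if (grepl("[^ACGT]", ref_codon) || grepl("[^ACGT]", alt_codon)) {
    return(c(synonymous = NA_real_, nonsynonymous = NA_real_))
  }
  d <- .ng_pair_diff(ref_codon, alt_codon)
  c(synonymous = d[["s"]], nonsynonymous = d[["n"]])
}

#' Synonymous and nonsynonymous site counts of one codon
#'
#' For each of the 9 single-nucleotide mutations of the codon, accumulates
#' the synonymous fraction per position; `s_sites + n_sites = 3` always.
#' Mutations that create stop codons count as nonsynonymous.
#'
#' @param codon a sense codon over `A/C/G/T`.
#' @return Named numeric vector `c(s_sites =, n_sites =)`.
#' @examples
#' ng_sites("GGG") # third position fourfold degenerate: s_sites = 1
#' @export
ng_sites <- function(codon) {
  codon <- toupper(codon)
  if (grepl("[^ACGT]", codon) || nchar(codon) != 3L) {
    stop("ng_sites expects a codon over A/C/G/T")
  }
  if (.is_stop(codon)) stop("stop codon excluded from site counting: ", codon)
  s <- .ng_site_table()[[codon]]
  c(s_sites = s, n_sites = 3 - s)
}

#' Counting-based dN/dS for a codon-aligned sequence pair
#'
#' Nei-Gojobori-style counting estimator: site totals are averaged over the
#' two sequences; differences between unequal codons are averaged over all
#' minimal mutational pathways (pathways through stop codons are dropped
#' when any stop-free pathway exists). Proportions are corrected with the
#' Jukes-Cantor formula `d = -3/4 * log(1 - 4/3 * p)`. Codons containing a
#' gap or `N` in either sequence, and stop codons, are excluded pairwise.
#'
#' @param a,b codon-aligned sequences of equal length.
#' @return An object of class `rate_estimate`: list with `n_sites`,
#'   `s_sites`, `n_diffs`, `s_diffs`, `p_n`, `p_s`, `d_n`, `d_s`, `omega`,
#'   `n_codons` (compared complete codons) and `flags`. `omega` is `NA` when
#'   `d_s` is zero or saturated.
#' @export
ng_pairwise <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b)) stop("sequences must have equal length")
  if (nchar(a) %% 3L != 0L) stop("sequence length must be divisible by 3")
  ca <- substring(a, seq(1, nchar(a), 3), seq(3, nchar(a), 3))
  cb <- substring(b, seq(1, nchar(b), 3), seq(3, nchar(b), 3))
  clean <- !grepl("[^ACGT]", ca) & !grepl("[^ACGT]", cb)
  keep <- clean
  keep[clean] <- !(.is_stop(ca[clean]) | .is_stop(cb[clean]))
  ca <- ca[keep]; cb <- cb[keep]
  if (length(ca) == 0L) stop("zero comparable codons")

  site_tab <- .ng_site_table()
  s_sites <- (sum(site_tab[ca]) + sum(site_tab[cb])) / 2
  n_sites <- 3 * length(ca) - s_sites

  tabs <- .ng_diff_tables()
  idx <- cbind(match(ca, rownames(tabs$s)), match(cb, colnames(tabs$s)))
  s_diffs <- sum(tabs$s[idx])
  n_diffs <- sum(tabs$n[idx])

  p_s <- if (s_sites > 0) s_diffs / s_sites else 0
  p_n <- if (n_sites > 0) n_diffs / n_sites else 0
  flags <- character(0)
  jc <- function(p) {
    if (p >= 3 / 4) return(NA_real_)
    -3 / 4 * log(1 - 4 / 3 * p)
  }
  d_s <- jc(p_s)
  d_n <- jc(p_n)
  if (is.na(d_s)) flags <- c(flags, "saturated_dS")
  if (is.na(d_n)) flags <- c(flags, "saturated_dN")
  omega <- NA_real_
  if (!is.na(d_s) && !is.na(d_n) && d_s > 0) {
    omega <- d_n / d_s
  } else if (!is.na(d_s) && d_s == 0) {
    flags <- c(flags, "omega_undefined_zero_dS")
  }
  structure(
    list(n_sites = n_sites, s_sites = s_sites,
         n_diffs = n_diffs, s_diffs = s_diffs,
         p_n = p_n, p_s = p_s, d_n = d_n, d_s = d_s,
         omega = omega, n_codons = length(ca), flags = flags),
    class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf(
    "rate_estimate: %d codons | S sites %.2f, N sites %.2f | Sd %.3f, Nd %.3f\n",
    x$n_codons, x$s_sites, x$n_sites, x$s_diffs, x$n_diffs))
  cat(sprintf("  dS = %s, dN = %s, omega = %s%s\n",
              format(x$d_s, digits = 4), format(x$d_n, digits = 4),
              format(x$omega, digits = 4),
              if (length(x$flags)) paste0("  [", paste(x$flags, collapse = ","), "]") else ""))
  invisible(x)
}

#' @export
as.data.frame.rate_estimate <- function(x, ...) {
  data.frame(n_sites = x$n_sites, s_sites = x$s_sites,
             n_diffs = x$n_diffs, s_diffs = x$s_diffs,
             p_n = x$p_n, p_s = x$p_s, d_n = x$d_n, d_s = x$d_s,
             omega = x$omega, n_codons = x$n_codons,
             flags = paste(x$flags, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Filter ortholog groups on synonymous divergence
#'
#' Drops poorly aligned ortholog groups whose `d_s` exceeds the cutoff; the
#' number removed is reported via `message()`.
#'
#' @param estimates named list of [ng_pairwise()] results keyed by OG id.
#' @param cutoff positive dS cutoff (default 2).
#' @return Character vector of retained OG ids.
#' @export
ds_filter <- function(estimates, cutoff = 2) {
  stopifnot(cutoff > 0)
  ds <- vapply(estimates, function(e) {
    if (is.na(e$d_s)) Inf else e$d_s
  }, numeric(1))
  keep <- names(estimates)[ds <= cutoff]
  message(sprintf("ds_filter: cutoff %.3g removed %d of %d OGs",
                  cutoff, length(estimates) - length(keep), length(estimates)))
  keep
}

#' log2 ratio of paternal to maternal evolutionary rate
#'
#' @param omega_paternal,omega_maternal finite, positive dN/dS estimates for
#'   the paternal and maternal copy of the same gene set.
#' @return `log2(omega_paternal / omega_maternal)`; `NA` (with attribute
#'   `reason`) when either rate is missing, zero or non-finite.
#' @export
log2_omega_ratio <- function(omega_paternal, omega_maternal) {
  bad <- function(x) is.na(x) || !is.finite(x) || x <= 0
  if (bad(omega_paternal) || bad(omega_maternal)) {
    return(structure(NA_real_, reason = "omega zero or undefined"))
  }
  log2(omega_paternal / omega_maternal)
}
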