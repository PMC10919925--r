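# Site-level gene conversion detection inside gene-family clades.
#
# A diagnostic (genome-specific) SNP is an alignment column at which every
# variety of one parental genome shares a state, every variety of the
# other shares a different state, and no parental sequence carries a gap
# or N. An allopolyploid homoeolog carrying the *other* parent's state at
# such a column is a site-level conversion event; its direction follows
# from the homoeolog's subgenome of origin and its synonymous/nonsynonymous
# effect from swapping the two parental states in the homoeolog's codon
# context.

#' Find genome-diagnostic SNP columns between two parental genomes
#'
#' @param clade_aln [codon_alignment] of one gene-family clade containing
#'   the parental sequences (possibly several varieties per genome).
#' @param parent_genomes character vector of the two parental genome ids;
#'   rows with `role == "diploid_parent"` and these genomes are used.
#' @param clade_id clade identifier carried into the output.
#' @return Data frame of diagnostic sites with columns `clade_id`, `column`
#'   (0-based), one state column per parental genome (named `state_<id>`),
#'   `codon_index` (0-based) and `pos_in_codon` (0-2).
#' @export
find_diagnostic_sites <- function(clade_aln, parent_genomes,
                                  clade_id = NA_character_) {
  stopifnot(length(parent_genomes) == 2L)
  r <- clade_aln$records
  groups <- lapply(parent_genomes, function(g) {
    which(r$genome == g & r$role == "diploid_parent")
  })
  names(groups) <- parent_genomes
  if (any(lengths(groups) == 0L)) {
    stop("no parental sequences for genome: ",
         paste(parent_genomes[lengths(groups) == 0L], collapse = ", "))
  }
  m <- .aln_matrix(clade_aln)
  state_of <- function(rows, j) {
    s <- unique(m[rows, j])
    if (length(s) == 1L && s %in% .BASES) s else NA_character_
  }
  cols <- seq_len(clade_aln$length)
  s1 <- vapply(cols, function(j) state_of(groups[[1]], j), character(1))
  s2 <- vapply(cols, function(j) state_of(groups[[2]], j), character(1))
  keep <- !is.na(s1) & !is.na(s2) & s1 != s2
  out <- data.frame(
    clade_id = rep(clade_id, sum(keep)),
    column = cols[keep] - 1L,
    state1 = s1[keep],
    state2 = s2[keep],
    codon_index = (cols[keep] - 1L) %/% 3L,
    pos_in_codon = (cols[keep] - 1L) %% 3L,
    stringsAsFactors = FALSE)
  names(out)[names(out) == "state1"] <- paste0("state_", parent_genomes[1])
  names(out)[names(out) == "state2"] <- paste0("state_", parent_genomes[2])
  out
}

#' Scan a homoeolog for the opposite parent's state at diagnostic sites
#'
#' @param homoeolog_seq the aligned homoeolog sequence (character scalar).
#' @param origin subgenome of origin of the homoeolog, `"maternal"` or
#'   `"paternal"`.
#' @param sites diagnostic sites from [find_diagnostic_sites()].
#' @param design a [cross_design]; its maternal/paternal genomes must match
#'   the state columns of `sites`.
#' @param gene_id identifier carried into the events.
#' @return Data frame of events with columns `clade_id`, `gene_id`,
#'   `column` (0-based), `column_1based`, `direction` (`M_to_P` when a
#'   paternal homoeolog carries the maternal state, `P_to_M` for the
#'   reverse), `effect` (`synonymous`/`nonsynonymous`, fractional effects
#'   from multi-variant codons resolved to the larger share), and
#'   attributes `other_state` (count of third-state columns, i.e. new
#'   mutations matching neither parent) and `skipped` (gapped columns).
#' @export
detect_site_conversions <- function(homoeolog_seq, origin, sites, design,
                                    gene_id = NA_character_) {
  stopifnot(origin %in% c("maternal", "paternal"))
  mcol <- paste0("state_", design$maternal_genome)
  pcol <- paste0("state_", design$paternal_genome)
  if (!all(c(mcol, pcol) %in% names(sites))) {
    stop("diagnostic sites lack state columns for the cross's parents")
  }
  chars <- strsplit(homoeolog_seq, "")[[1]]
  own_col <- if (origin == "maternal") mcol else pcol
  other_col <- if (origin == "maternal") pcol else mcol
  direction <- if (origin == "maternal") "P_to_M" else "M_to_P"

  events <- list()
  other_state <- 0L
  skipped <- 0L
  for (i in seq_len(nrow(sites))) {
    j <- sites$column[i] + 1L
    h <- chars[j]
    if (!h %in% .BASES) { skipped <- skipped + 1L; next }
    if (h == sites[[own_col]][i]) next
    if (h != sites[[other_col]][i]) { other_state <- other_state + 1L; next }
    ci <- sites$codon_index[i]
    cols <- (ci * 3L + 1L):(ci * 3L + 3L)
    ref <- chars[cols]
    alt <- ref
    alt[sites$pos_in_codon[i] + 1L] <- sites[[own_col]][i]
    eff <- .classify_codon_change(paste(ref, collapse = ""),
                                  paste(alt, collapse = ""))
    effect <- if (anyNA(eff)) {
      NA_character_
    } else if (eff[["synonymous"]] >= eff[["nonsynonymous"]]) {
      "synonymous"
    } else {
      "nonsynonymous"
    }
    events[[length(events) + 1L]] <- data.frame(
      clade_id = sites$clade_id[i], gene_id = gene_id,
      column = sites$column[i], column_1based = j,
      direction = direction, effect = effect,
      stringsAsFactors = FALSE)
  }
  out <- if (length(events)) {
    do.call(rbind, events)
  } else {
    data.frame(clade_id = character(0), gene_id = character(0),
               column = integer(0), column_1based = integer(0),
               direction = character(0), effect = character(0),
               stringsAsFactors = FALSE)
  }
  attr(out, "other_state") <- other_state
  attr(out, "skipped") <- skipped
  out
}

#' Scan both homoeologs of a clade and collect events
#'
#' Convenience wrapper: finds diagnostic sites between the cross's parents
#' and scans every `subgenome` record of the clade alignment. A column
#' converted in both homoeologs (both directions) is emitted as two events
#' and flagged `reciprocal`.
#'
#' @param clade_aln [codon_alignment] with parental (`diploid_parent`) and
#'   homoeolog (`subgenome`) records.
#' @param design a [cross_design].
#' @param clade_id clade identifier.
#' @return Events data frame (see [detect_site_conversions()]) with an
#'   extra logical column `reciprocal`.
#' @export
scan_clade_conversions <- function(clade_aln, design, clade_id = NA_character_) {
  sites <- find_diagnostic_sites(
    clade_aln, c(design$maternal_genome, design$paternal_genome), clade_id)
  r <- clade_aln$records
  homs <- which(r$role == "subgenome")
  ev <- lapply(homs, function(i) {
    detect_site_conversions(r$sequence[i], r$origin[i], sites, design,
                            gene_id = r$gene_id[i])
  })
  out <- do.call(rbind, ev)
  attr(out, "n_diagnostic") <- nrow(sites)
  if (nrow(out)) {
    both <- table(out$column)
    out$reciprocal <- out$column %in% as.integer(names(both)[both > 1])
  } else {
    out$reciprocal <- logical(0)
  }
  out
}

#' Tabulate site-conversion events per gene family
#'
#' Builds the per-family summary table: diagnostic-SNP count and direction
#' x effect event counts per family, a `Total` row summing every column,
#' and the derived maternally/paternally biased totals (synonymous +
#' nonsynonymous events per direction).
#'
#' @param family_counts data frame with one row per gene family: columns
#'   `family`, `snps` (genome-specific SNP count), `m_to_p_syn`,
#'   `m_to_p_nonsyn`, `p_to_m_syn`, `p_to_m_nonsyn`. Use
#'   [events_to_family_counts()] to build it from raw events.
#' @return Data frame of the family rows plus a `Total` row, with
#'   attributes `maternally_biased` (total M-to-P events: maternal states
#'   fixed into the paternal homoeolog) and `paternally_biased`.
#' @export
tabulate_families <- function(family_counts) {
  need <- c("family", "snps", "m_to_p_syn", "m_to_p_nonsyn",
            "p_to_m_syn", "p_to_m_nonsyn")
  if (nrow(family_counts) == 0L) {
    family_counts <- data.frame(family = character(0), snps = numeric(0),
                                m_to_p_syn = numeric(0), m_to_p_nonsyn = numeric(0),
                                p_to_m_syn = numeric(0), p_to_m_nonsyn = numeric(0),
                                stringsAsFactors = FALSE)
  }
  stopifnot(all(need %in% names(family_counts)))
  fc <- family_counts[, need]
  total <- data.frame(family = "Total",
                      snps = sum(fc$snps),
                      m_to_p_syn = sum(fc$m_to_p_syn),
                      m_to_p_nonsyn = sum(fc$m_to_p_nonsyn),
                      p_to_m_syn = sum(fc$p_to_m_syn),
                      p_to_m_nonsyn = sum(fc$p_to_m_nonsyn),
                      stringsAsFactors = FALSE)
  out <- rbind(fc, total)
  rownames(out) <- NULL
  attr(out, "maternally_biased") <- total$m_to_p_syn + total$m_to_p_nonsyn
  attr(out, "paternally_biased") <- total$p_to_m_syn + total$p_to_m_nonsyn
  out
}

#' Count events per family for [tabulate_families()]
#'
#' @param events events data frame (rows from [detect_site_conversions()])
#'   with a `family` column.
#' @param snps named numeric vector: diagnostic-SNP count per family.
#' @return Per-family counts data frame.
#' @export
events_to_family_counts <- function(events, snps) {
  fams <- names(snps)
  do.call(rbind, lapply(fams, function(f) {
    x <- events[events$family == f, , drop = FALSE]
    data.frame(
      family = f, snps = unname(snps[f]),
      m_to_p_syn = sum(x$direction == "M_to_P" & x$effect == "synonymous", na.rm = TRUE),
      m_to_p_nonsyn = sum(x$direction == "M_to_P" & x$effect == "nonsynonymous", na.rm = TRUE),
      p_to_m_syn = sum(x$direction == "P_to_M" & x$effect == "synonymous", na.rm = TRUE),
      p_to_m_nonsyn = sum(x$direction == "P_to_M" & x$effect == "nonsynonymous", na.rm = TRUE),
      stringsAsFactors = FALSE)
  }))
}
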