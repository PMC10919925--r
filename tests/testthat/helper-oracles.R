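# Independent oracles and fixture builders.
#
# The oracles deliberately avoid the package's internal lookup tables:
# translation goes through seqinr and pathway enumeration is a plain
# recursive walk over position orderings.

BASES <- c("A", "C", "G", "T")

oracle_translate <- function(codon) {
  seqinr::translate(strsplit(codon, "")[[1]])
}

oracle_is_stop <- function(codon) oracle_translate(codon) == "*"

oracle_sense_codons <- function() {
  g <- expand.grid(BASES, BASES, BASES, stringsAsFactors = FALSE)
  codons <- paste0(g[[1]], g[[2]], g[[3]])
  codons[!vapply(codons, oracle_is_stop, logical(1))]
}

# per-position synonymous fraction over the 9 single-base neighbours;
# mutations to stop codons are nonsynonymous
oracle_ng_sites <- function(codon) {
  aa <- oracle_translate(codon)
  syn <- 0
  for (pos in 1:3) {
    for (base in setdiff(BASES, substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- base
      if (!oracle_is_stop(mut) && oracle_translate(mut) == aa) syn <- syn + 1 / 3
    }
  }
  c(s_sites = syn, n_sites = 3 - syn)
}

# average synonymous/nonsynonymous differences over all orderings of the
# differing positions; orderings that pass through a stop codon are
# dropped unless every ordering does
oracle_pair_diffs <- function(a, b) {
  pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  if (length(pos) == 0L) return(c(s = 0, n = 0))
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  bb <- strsplit(b, "")[[1]]
  syn_counts <- numeric(0)
  stop_flags <- logical(0)
  for (ord in perms(pos)) {
    cur <- a
    syn <- 0
    hit <- FALSE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- bb[p]
      if (!oracle_is_stop(cur) && !oracle_is_stop(nxt) &&
          oracle_translate(cur) == oracle_translate(nxt)) {
        syn <- syn + 1
      }
      if (oracle_is_stop(nxt)) hit <- TRUE
      cur <- nxt
    }
    syn_counts <- c(syn_counts, syn)
    stop_flags <- c(stop_flags, hit)
  }
  use <- if (all(stop_flags)) syn_counts else syn_counts[!stop_flags]
  s <- mean(use)
  c(s = s, n = length(pos) - s)
}

# NG-style totals for a pair of codon vectors, all via the oracle
oracle_ng_pair <- function(codons_a, codons_b) {
  s_sites <- 0
  s_diffs <- 0
  n_diffs <- 0
  for (i in seq_along(codons_a)) {
    s_sites <- s_sites +
      (oracle_ng_sites(codons_a[i])[["s_sites"]] +
         oracle_ng_sites(codons_b[i])[["s_sites"]]) / 2
    d <- oracle_pair_diffs(codons_a[i], codons_b[i])
    s_diffs <- s_diffs + d[["s"]]
    n_diffs <- n_diffs + d[["n"]]
  }
  list(s_sites = s_sites, n_sites = 3 * length(codons_a) - s_sites,
       s_diffs = s_diffs, n_diffs = n_diffs)
}

# ---- fixture builders ----

# alignment from a named character vector; metadata parsed from names
# "geneID|genome|role|origin"
make_aln <- function(seqs) {
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  codon_alignment(
    gene_id = vapply(parts, `[[`, character(1), 1),
    genome = vapply(parts, `[[`, character(1), 2),
    role = vapply(parts, `[[`, character(1), 3),
    origin = vapply(parts, function(p) {
      if (length(p) >= 4) p[[4]] else "not_applicable"
    }, character(1)),
    sequence = unname(seqs))
}

# replace the codon at 1-based codon index i
set_codon <- function(seq, i, codon) {
  substr(seq, 3 * i - 2, 3 * i) <- codon
  seq
}

codon_at <- function(seq, i) substr(seq, 3 * i - 2, 3 * i)

# a fixed 30-codon Leu-rich coding backbone used by hand-built fixtures
backbone <- function(n_codons = 30) {
  paste(rep("CTT", n_codons), collapse = "")
}

extdata <- function(file) {
  path <- system.file("extdata", file, package = "cytonuclear")
  if (!nzchar(path)) stop("missing extdata fixture: ", file)
  path
}
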