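# Internal genetic-code machinery shared by the codon-level primitives.
#
# All lookups are precomputed once per session and cached: per-codon
# synonymous/nonsynonymous site fractions, and per codon-pair averaged
# synonymous/nonsynonymous difference counts over minimal mutational
# pathways. Mutations that create a stop codon count as nonsynonymous;
# pathways through stop codons are dropped unless every pathway crosses a
# stop, in which case all pathways are weighted equally.

.cyto_cache <- new.env(parent = emptyenv())

.BASES <- c("A", "C", "G", "T")

.all_codons <- function() {
  g <- expand.grid(p3 = .BASES, p2 = .BASES, p1 = .BASES,
                   stringsAsFactors = FALSE)
  paste0(g$p1, g$p2, g$p3)
}

# codon -> one-letter amino acid, "*" for stop
.translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

.is_stop <- function(codon) {
  .translate_codon(codon) == "*"
}

# synonymous iff both are sense codons encoding the same amino acid
.step_is_synonymous <- function(from, to) {
  aa_from <- .translate_codon(from)
  aa_to <- .translate_codon(to)
  aa_from != "*" && aa_to != "*" && aa_from == aa_to
}

.mutate_codon <- function(codon, pos, base) {
  substr(codon, pos, pos) <- base
  codon
}

# per-codon (s_sites, n_sites); s + n = 3 for every sense codon
.ng_site_table <- function() {
  if (!is.null(.cyto_cache$site_table)) return(.cyto_cache$site_table)
  codons <- .all_codons()
  s <- rep(NA_real_, length(codons))
  names(s) <- codons
  for (codon in codons) {
    if (.is_stop(codon)) next
    syn <- 0
    for (pos in 1:3) {
      ref <- substr(codon, pos, pos)
      for (base in setdiff(.BASES, ref)) {
        if (.step_is_synonymous(codon, .mutate_codon(codon, pos, base))) {
          syn <- syn + 1 / 3
        }
      }
    }
    s[codon] <- syn
  }
  .cyto_cache$site_table <- s
  s
}

# All orderings of the differing positions between two codons; each ordering
# is a stepwise path a -> ... -> b. Returns per-path synonymous step counts
# and whether the path crosses a stop codon.
.codon_paths <- function(a, b) {
  pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  k <- length(pos)
  if (k == 0L) return(data.frame(syn = numeric(0), stop = logical(0)))
  orderings <- switch(as.character(k),
    "1" = list(pos),
    "2" = list(pos, rev(pos)),
    "3" = {
      p <- list()
      for (i in 1:3) for (j in 1:3) for (l in 1:3) {
        if (length(unique(c(i, j, l))) == 3L) p[[length(p) + 1L]] <- pos[c(i, j, l)]
      }
      p
    })
  syn <- numeric(length(orderings))
  crosses_stop <- logical(length(orderings))
  bb <- strsplit(b, "")[[1]]
  for (i in seq_along(orderings)) {
    cur <- a
    s <- 0
    hit_stop <- FALSE
    for (p in orderings[[i]]) {
      nxt <- .mutate_codon(cur, p, bb[p])
      if (.step_is_synonymous(cur, nxt)) s <- s + 1
      if (.is_stop(nxt)) hit_stop <- TRUE
      cur <- nxt
    }
    syn[i] <- s
    crosses_stop[i] <- hit_stop
  }
  data.frame(syn = syn, stop = crosses_stop)
}

# Averaged (s_diff, n_diff) for one codon pair under the pathway rule.
.ng_pair_diff <- function(a, b) {
  paths <- .codon_paths(a, b)
  k <- nchar(a) - sum(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
  if (nrow(paths) == 0L) return(c(s = 0, n = 0))
  usable <- paths[!paths$stop, , drop = FALSE]
  if (nrow(usable) == 0L) usable <- paths
  s <- mean(usable$syn)
  c(s = s, n = k - s)
}

# 64 x 64 lookup of averaged synonymous/nonsynonymous differences.
# NA rows/cols for stop codons (excluded pairwise upstream).
.ng_diff_tables <- function() {
  if (!is.null(.cyto_cache$diff_tables)) return(.cyto_cache$diff_tables)
  codons <- .all_codons()
  n <- length(codons)
  sd <- matrix(NA_real_, n, n, dimnames = list(codons, codons))
  nd <- matrix(NA_real_, n, n, dimnames = list(codons, codons))
  sense <- codons[!vapply(codons, .is_stop, logical(1))]
  for (a in sense) {
    for (b in sense) {
      if (a == b) {
        sd[a, b] <- 0
        nd[a, b] <- 0
      } else if (is.na(sd[a, b])) {
        d <- .ng_pair_diff(a, b)
        sd[a, b] <- d[["s"]]
        nd[a, b] <- d[["n"]]
        sd[b, a] <- d[["s"]]
        nd[b, a] <- d[["n"]]
      }
    }
  }
  .cyto_cache$diff_tables <- list(s = sd, n = nd)
  .cyto_cache$diff_tables
}

.sense_codons <- function() {
  codons <- .all_codons()
  codons[!vapply(codons, .is_stop, logical(1))]
}
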