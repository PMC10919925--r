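#' Codon-framed multiple sequence alignment
#'
#' The substrate of every detector in the package: a gapped, codon-framed
#' alignment whose rows carry taxon metadata (genome, role, parent of
#' origin). Sequences must be equal length, the length divisible by three,
#' and use only `A`, `C`, `G`, `T`, `-` (gap) and `N`.
#'
#' @param gene_id character vector of gene identifiers.
#' @param genome character vector of genome identifiers (e.g. `"A"`, `"B"`,
#'   `"C"`, `"OUT"`, or an allopolyploid id for organelle sequences).
#' @param role one of `"diploid_parent"`, `"subgenome"`, `"outgroup"`,
#'   `"allopolyploid"` per sequence.
#' @param origin `"maternal"`, `"paternal"`, or `"not_applicable"`;
#'   must be maternal/paternal exactly when `role == "subgenome"`.
#' @param sequence character vector of aligned sequences.
#' @return An object of class `codon_alignment`: a list with a `records`
#'   data frame and the alignment `length` in columns.
#' @examples
#' aln <- codon_alignment(
#'   gene_id = c("g1", "g2"),
#'   genome = c("A", "B"),
#'   role = c("diploid_parent", "diploid_parent"),
#'   origin = c("not_applicable", "not_applicable"),
#'   sequence = c("ATGAAA", "ATGAAG"))
#' aln
#' @export
codon_alignment <- function(gene_id, genome, role, origin, sequence) {
  n <- length(sequence)
  stopifnot(length(gene_id) == n, length(genome) == n,
            length(role) == n, length(origin) == n)
  if (n < 2L) stop("a codon alignment needs at least 2 records")
  lens <- nchar(sequence)
  if (length(unique(lens)) != 1L) stop("sequences must have equal length")
  if (lens[1] %% 3L != 0L) stop("alignment length must be divisible by 3")
  sequence <- toupper(sequence)
  if (any(grepl("[^ACGTN-]", sequence))) {
    stop("sequences may contain only A, C, G, T, N and '-'")
  }
  roles <- c("diploid_parent", "subgenome", "outgroup", "allopolyploid")
  if (!all(role %in% roles)) {
    stop("unknown role; expected one of: ", paste(roles, collapse = ", "))
  }
  origins <- c("maternal", "paternal", "not_applicable")
  if (!all(origin %in% origins)) {
    stop("unknown origin; expected one of: ", paste(origins, collapse = ", "))
  }
  bad <- xor(role == "subgenome", origin != "not_applicable")
  if (any(bad)) {
    stop("parent_of_origin must be maternal/paternal exactly for subgenome records")
  }
  records <- data.frame(gene_id = unname(gene_id), genome = unname(genome),
                        role = unname(role), origin = unname(origin),
                        sequence = unname(sequence),
                        stringsAsFactors = FALSE)
  rownames(records) <- NULL
  structure(list(records = records, length = unname(lens[1])),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("codon_alignment: %d sequences x %d columns (%d codons)\n",
              nrow(x$records), x$length, x$length %/% 3L))
  for (i in seq_len(min(nrow(x$records), 10L))) {
    r <- x$records[i, ]
    cat(sprintf("  %s  [%s/%s/%s]\n", r$gene_id, r$genome, r$role, r$origin))
  }
  if (nrow(x$records) > 10L) cat(sprintf("  ... %d more\n", nrow(x$records) - 10L))
  invisible(x)
}

# character matrix view: rows = sequences, cols = alignment columns
.aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$records$sequence, ""))
  rownames(m) <- aln$records$gene_id
  m
}

# subset by record index, preserving metadata
.aln_subset <- function(aln, idx) {
  r <- aln$records[idx, , drop = FALSE]
  codon_alignment(r$gene_id, r$genome, r$role, r$origin, r$sequence)
}

.seq_of <- function(aln, which) aln$records$sequence[which]

#' Read a codon alignment from gapped FASTA
#'
#' Sequence headers carry taxon metadata as pipe-delimited tokens
#' `geneID|genome|role|origin` (the package-wide ID convention); a missing
#' origin token defaults to `not_applicable`.
#'
#' @param path path to an aligned FASTA file.
#' @return A [codon_alignment].
#' @export
read_codon_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  ids <- names(set)
  parts <- strsplit(ids, "|", fixed = TRUE)
  n_tok <- lengths(parts)
  if (any(n_tok < 3L)) {
    stop("FASTA ", path, ": headers must be 'geneID|genome|role|origin' (",
         ids[which(n_tok < 3L)[1]], ")")
  }
  get <- function(k, default = NULL) {
    vapply(parts, function(p) if (length(p) >= k) p[[k]] else default,
           character(1))
  }
  codon_alignment(
    gene_id = get(1),
    genome = get(2),
    role = get(3),
    origin = vapply(parts, function(p) if (length(p) >= 4L) p[[4]] else "not_applicable",
                    character(1)),
    sequence = as.character(set))
}

#' Write a codon alignment to gapped FASTA
#'
#' @param aln a [codon_alignment].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_codon_fasta <- function(aln, path) {
  r <- aln$records
  headers <- paste(r$gene_id, r$genome, r$role, r$origin, sep = "|")
  lines <- character(2L * nrow(r))
  lines[c(TRUE, FALSE)] <- paste0(">", headers)
  lines[c(FALSE, TRUE)] <- r$sequence
  writeLines(lines, path)
  invisible(path)
}
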