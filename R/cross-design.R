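#' Describe an allopolyploid cross
#'
#' Names the allopolyploid, its maternal and paternal diploid parents, any
#' further candidate genomes included in variant typing (e.g. the third
#' diploid of a triangle-of-U scheme), and an optional outgroup. Every
#' direction label in the package (maternal-to-paternal conversion and the
#' reverse) is oriented by this object.
#'
#' @param allopolyploid_id identifier of the allopolyploid (e.g. `"AB"`).
#' @param maternal_genome,paternal_genome the two parental genome ids;
#'   must differ.
#' @param other_genomes further candidate genome ids for organelle variant
#'   typing (default none).
#' @param outgroup outgroup genome id or `NA`.
#' @return An object of class `cross_design`.
#' @examples
#' cross_design("AB", maternal_genome = "A", paternal_genome = "B",
#'              other_genomes = "C", outgroup = "OUT")
#' @export
cross_design <- function(allopolyploid_id, maternal_genome, paternal_genome,
                         other_genomes = character(0), outgroup = NA_character_) {
  if (maternal_genome == paternal_genome) {
    stop("maternal and paternal genome must differ")
  }
  ids <- c(maternal_genome, paternal_genome, other_genomes)
  if (anyDuplicated(ids)) stop("a genome appears twice in the cross design")
  structure(
    list(allopolyploid_id = allopolyploid_id,
         maternal_genome = maternal_genome,
         paternal_genome = paternal_genome,
         other_genomes = other_genomes,
         outgroup = outgroup),
    class = "cross_design")
}

#' @export
print.cross_design <- function(x, ...) {
  cat(sprintf("cross_design %s: maternal %s x paternal %s",
              x$allopolyploid_id, x$maternal_genome, x$paternal_genome))
  if (length(x$other_genomes)) {
    cat(" | other:", paste(x$other_genomes, collapse = ","))
  }
  if (!is.na(x$outgroup)) cat(" | outgroup:", x$outgroup)
  cat("\n")
  invisible(x)
}

#' Swap the maternal/paternal designation of a cross
#'
#' Utility used by the label-swap invariance checks: exchanging the parents
#' must swap maternal/paternal-oriented outputs and change nothing else.
#'
#' @param design a [cross_design].
#' @return A [cross_design] with the parents exchanged.
#' @export
swap_parents <- function(design) {
  cross_design(design$allopolyploid_id,
               maternal_genome = design$paternal_genome,
               paternal_genome = design$maternal_genome,
               other_genomes = design$other_genomes,
               outgroup = design$outgroup)
}

#' Read or write a cross design as JSON
#'
#' @param path JSON file path.
#' @return `read_cross_design()` returns a [cross_design];
#'   `write_cross_design()` returns `path` invisibly.
#' @export
read_cross_design <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cross_design(x$allopolyploid_id, x$maternal_genome, x$paternal_genome,
               other_genomes = if (is.null(x$other_genomes)) character(0) else x$other_genomes,
               outgroup = if (is.null(x$outgroup)) NA_character_ else x$outgroup)
}

#' @rdname read_cross_design
#' @param design a [cross_design].
#' @export
write_cross_design <- function(design, path) {
  jsonlite::write_json(unclass(design), path, auto_unbox = TRUE, null = "null")
  invisible(path)
}
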