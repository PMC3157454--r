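#' Worked-example count tables
#'
#' Small published per-gene allelic read counts shipped with the package and
#' used as desk-scale worked examples: reciprocal endosperm counts for
#' previously known imprinted genes (with a flag for the genes that pass all
#' calling criteria), maternal/paternal read totals for the paternally
#' expressed epigenetic-regulator genes, and the cloned RT-PCR allele counts
#' for the SDG20 embryo locus whose Col bias is a strain (cis) effect rather
#' than imprinting.
#'
#' @return A data frame.
#' @name worked_examples
NULL

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "imprintcall")
  if (path == "") stop("fixture not found: ", file)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname worked_examples
#' @export
known_imprinted_counts <- function() {
  .extdata("known_imprinted_endosperm_counts.tsv")
}

#' @rdname worked_examples
#' @export
epigenetic_peg_reads <- function() {
  .extdata("epigenetic_peg_reads.tsv")
}

#' @rdname worked_examples
#' @export
sdg20_clone_counts <- function() {
  .extdata("sdg20_clones.tsv")
}
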