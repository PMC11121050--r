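#' @importFrom stats rbinom runif setNames sd phyper
#' @importFrom utils read.delim write.table
NULL

BASES <- c("A", "C", "G", "T")

# ordered directional substitution labels used throughout the package
SUB_TYPES <- c("A>C", "A>G", "A>T",
               "C>A", "C>G", "C>T",
               "G>A", "G>C", "G>T",
               "T>A", "T>C", "T>G")

TRANSITION_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")

#' Span of the IRGSP-1.0 rice reference assembly, in bp
#'
#' Used as the default denominator when converting back-projected M1 mutation
#' counts into per-bp mutation rates for rice resequencing panels.
#' @export
RICE_GENOME_LENGTH <- 373245519

stop_badarg <- function(...) stop(..., call. = FALSE)

check_bases <- function(x, arg = deparse(substitute(x))) {
  bad <- !grepl("^[ACGT]+$", x)
  if (any(bad)) {
    stop_badarg(sprintf("%s contains non-ACGT alleles: %s",
                        arg, paste(utils::head(x[bad], 3), collapse = ", ")))
  }
  invisible(x)
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

translate_dna <- function(x) {
  # standard nuclear codon table; no.init.codon so internal ATG is plain Met
  as.character(Biostrings::translate(Biostrings::DNAStringSet(x),
                                     if.fuzzy.codon = "error",
                                     no.init.codon = TRUE))
}

variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}
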