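## Small RNA strand utilities. Strands are plain character scalars over
## {A,C,G,U}, written 5'->3'; genomic sequence is DNA over {A,C,G,T}.

RNA_BASES <- c("A", "C", "G", "U")

#' Validate an RNA strand
#'
#' Checks that `x` is a single 5'->3' string over the RNA alphabet
#' \{A, C, G, U\}.
#'
#' @param x Character scalar.
#' @param what Label used in error messages.
#' @return `x`, invisibly, after validation.
#' @keywords internal
check_rna <- function(x, what = "strand") {
  if (!is.character(x) || length(x) != 1L || is.na(x) || nchar(x) < 1L) {
    abort(sprintf("`%s` must be a non-empty character scalar", what))
  }
  bad <- setdiff(unique(strsplit(x, "")[[1]]), RNA_BASES)
  if (length(bad) > 0) {
    abort(sprintf("`%s` contains non-RNA characters: %s",
                  what, paste(bad, collapse = ", ")))
  }
  invisible(x)
}

#' RNA complement and reverse complement
#'
#' `rna_complement()` complements base-by-base without reversing;
#' `rna_revcomp()` returns the reverse complement (5'->3' of the opposite
#' strand). `dna_to_rna()`/`rna_from_genome()` convert genomic DNA to the
#' RNA reading of the + or - strand.
#'
#' @param x RNA string(s), 5'->3'.
#' @return Character vector of the same length.
#' @examples
#' rna_revcomp("AUGC")
#' @export
rna_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGU", "UGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' @rdname rna_revcomp
#' @export
rna_complement <- function(x) chartr("ACGU", "UGCA", x)

#' @rdname rna_revcomp
#' @export
dna_to_rna <- function(x) chartr("T", "U", toupper(x))

## RNA reading of the genomic minus strand over [start, end), 0-based
## half-open: reverse complement of the plus-strand slice, then T->U.
rna_from_genome <- function(chrom_seq, start, end, strand = "+") {
  s <- substr(chrom_seq, start + 1L, end)
  if (strand == "+") return(dna_to_rna(s))
  dna_to_rna(paste(rev(strsplit(chartr("ACGT", "TGCA", toupper(s)), "")[[1]]),
                   collapse = ""))
}

## Watson-Crick pair test for single bases (strict; G:U wobble is a mismatch).
wc_pair <- function(a, b) {
  (a == "A" & b == "U") | (a == "U" & b == "A") |
    (a == "G" & b == "C") | (a == "C" & b == "G")
}

strand_chars <- function(x) strsplit(x, "")[[1]]

## sample() without the scalar-x surprise: draws from the vector `x` itself.
sample_from <- function(x, size = 1, replace = FALSE, prob = NULL) {
  if (length(x) == 1L) return(rep(x, size))
  sample(x, size, replace = replace, prob = prob)
}
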