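# IUPAC nucleotide conventions, codon translation, shared sequence helpers.
#
# Sanger consensus sequences encode heterozygous positions as IUPAC ambiguity
# symbols (a double peak A/T is written W).  Everything downstream -- exon
# location, variant calling, zygosity -- relies on the base-set semantics of
# those symbols, so they are centralised here.

# 15 symbols (gap excluded); values are the constituent base strings.
.iupac_sets <- local({
  m <- Biostrings::IUPAC_CODE_MAP
  sets <- strsplit(unname(m), "")
  names(sets) <- names(m)
  sets
})

IUPAC_SYMBOLS <- names(.iupac_sets)

# symbol x symbol compatibility: TRUE iff the base sets intersect.
.compat_matrix <- local({
  syms <- names(.iupac_sets)
  m <- matrix(FALSE, length(syms), length(syms), dimnames = list(syms, syms))
  for (a in syms) {
    for (b in syms) {
      m[a, b] <- length(intersect(.iupac_sets[[a]], .iupac_sets[[b]])) > 0L
    }
  }
  m
})

# Alignment scoring used for exon location: +1 any compatible pair, -1 else.
.iupac_score_matrix <- local({
  m <- ifelse(.compat_matrix, 1, -1)
  storage.mode(m) <- "double"
  m
})

# reverse lookup: sorted base-set string -> symbol ("AT" -> "W")
.code_for_set <- local({
  key <- vapply(.iupac_sets, function(b) paste(sort(b), collapse = ""), "")
  setNames(names(.iupac_sets), key)
})

#' Expand an IUPAC nucleotide symbol to its base set
#'
#' @param code A single IUPAC nucleotide symbol (one of the 15 non-gap
#'   symbols; case-insensitive).
#'
#' @return Character vector of constituent bases, e.g. `"W"` gives
#'   `c("A", "T")`; an unambiguous base returns itself.
#' @export
#'
#' @examples
#' expand_iupac("W")
#' expand_iupac("N")
expand_iupac <- function(code) {
  if (!is.character(code) || length(code) != 1L || is.na(code)) {
    abort("`code` must be a single nucleotide symbol.")
  }
  code <- toupper(code)
  if (!code %in% IUPAC_SYMBOLS) {
    abort(sprintf("unknown IUPAC nucleotide symbol: '%s'", code))
  }
  .iupac_sets[[code]]
}

# vectorised internal variant: list of base sets
.expand_many <- function(codes) {
  bad <- !codes %in% IUPAC_SYMBOLS
  if (any(bad)) {
    abort(sprintf("unknown IUPAC nucleotide symbol: '%s'", codes[which(bad)[1]]))
  }
  .iupac_sets[codes]
}

# IUPAC symbol for a base set (used to encode heterozygotes)
iupac_code <- function(bases) {
  key <- paste(sort(unique(toupper(bases))), collapse = "")
  out <- .code_for_set[key]
  if (is.na(out)) abort(sprintf("no IUPAC symbol for base set {%s}", key))
  unname(out)
}

# vectorised compatibility of two equal-length symbol vectors
iupac_compatible <- function(a, b) {
  .compat_matrix[cbind(a, b)]
}

#' Translate an unambiguous codon with the standard genetic code
#'
#' Display labels such as "Y139F" are always derived by translation of the
#' reference and alternate codons, never copied from input tables.
#'
#' @param codon Character vector of triplets over A/C/G/T.
#'
#' @return One-letter amino-acid symbols; stop codons return `"*"`.
#' @export
#'
#' @examples
#' translate_codon(c("TAT", "TTT", "TAA"))
translate_codon <- function(codon) {
  if (length(codon) == 0L) return(character())
  codon <- toupper(codon)
  bad <- !grepl("^[ACGT]{3}$", codon)
  if (any(bad)) {
    abort(sprintf(
      "codon '%s' is not an unambiguous A/C/G/T triplet", codon[which(bad)[1]]
    ))
  }
  unname(Biostrings::GENETIC_CODE[codon])
}

# reverse complement preserving IUPAC ambiguity symbols
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# split a sequence string into single characters
seq_chars <- function(x) strsplit(toupper(x), "", fixed = TRUE)[[1]]

codon_at <- function(cds, codon_index) {
  substr(cds, 3L * codon_index - 2L, 3L * codon_index)
}

# half-up decimal rounding at the table's printed precision
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}
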