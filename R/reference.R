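# Reference coding sequences and their exon partition.
#
# All coordinates in the package are CDS coordinates: 1-based, inclusive,
# counted from the first base of the start codon.  Codon i occupies CDS
# positions 3i-2 .. 3i and amino-acid index equals codon index ("codon 139"
# means residue 139).

#' Load reference coding sequences and exon partitions
#'
#' Reads a species-keyed reference set: one FASTA record per species (record
#' id = species label, first whitespace-delimited token) plus a tab-delimited
#' exon table with columns `species_id`, `exon_index`, `start`, `end` giving
#' the 1-based inclusive CDS interval of each exon.  Exons must tile the CDS
#' exactly, the CDS length must be divisible by 3, and the reference may not
#' contain ambiguity codes.
#'
#' @param fasta_path Path to the reference FASTA.
#' @param exon_table_path Path to the exon partition TSV.
#'
#' @return A `vkor_reference` tibble with one row per species and columns
#'   `species_id`, `cds`, `codon_count` and a nested `exons` list-column.
#' @export
#'
#' @examples
#' ref <- load_reference(
#'   vkor_example("synthetic_vkorc1_cds.fasta"),
#'   vkor_example("synthetic_vkorc1_exons.tsv")
#' )
#' ref$codon_count
load_reference <- function(fasta_path, exon_table_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) == 0L) abort("reference FASTA contains no records")
  ids <- sub("\\s.*$", "", names(seqs))
  exons <- readr::read_tsv(
    exon_table_path,
    col_types = readr::cols(
      species_id = readr::col_character(),
      exon_index = readr::col_integer(),
      start = readr::col_integer(),
      end = readr::col_integer()
    )
  )
  new_reference_set(
    tibble(species_id = ids, cds = unname(toupper(as.character(seqs)))),
    exons
  )
}

# construct + validate a vkor_reference from plain tibbles
new_reference_set <- function(seq_tbl, exon_tbl) {
  if (anyDuplicated(seq_tbl$species_id)) {
    abort("reference FASTA must contain exactly one record per species")
  }
  missing_sp <- setdiff(exon_tbl$species_id, seq_tbl$species_id)
  if (length(missing_sp) > 0L) {
    abort(sprintf(
      "exon table references species '%s' absent from the FASTA", missing_sp[1]
    ))
  }
  ref <- seq_tbl |>
    mutate(
      exons = purrr::map(.data$species_id, function(sp) {
        exon_tbl |>
          filter(.data$species_id == sp) |>
          select("exon_index", "start", "end") |>
          arrange(.data$exon_index)
      })
    )
  purrr::pwalk(ref, function(species_id, cds, exons) {
    validate_reference_entry(species_id, cds, exons)
  })
  ref <- ref |> mutate(codon_count = nchar(.data$cds) %/% 3L, .after = "cds")
  class(ref) <- c("vkor_reference", class(ref))
  ref
}

validate_reference_entry <- function(species_id, cds, exons) {
  len <- nchar(cds)
  bad <- regexpr("[^ACGT]", cds)
  if (bad > 0L) {
    abort(sprintf(
      "reference '%s' contains ambiguity code '%s' at position %d",
      species_id, substr(cds, bad, bad), bad
    ))
  }
  if (len %% 3L != 0L) {
    abort(sprintf(
      "reference '%s' length %d is not divisible by 3", species_id, len
    ))
  }
  if (nrow(exons) == 0L) {
    abort(sprintf("no exon rows for reference '%s'", species_id))
  }
  if (!identical(exons$exon_index, seq_len(nrow(exons)))) {
    abort(sprintf(
      "exon indices for '%s' must be 1..%d in order", species_id, nrow(exons)
    ))
  }
  if (any(exons$start > exons$end)) {
    abort(sprintf("empty exon interval in reference '%s'", species_id))
  }
  bounds <- c(1L, exons$end + 1L)
  for (i in seq_len(nrow(exons))) {
    if (exons$start[i] < bounds[i]) {
      abort(sprintf(
        "exon overlap in reference '%s' at position %d", species_id,
        exons$start[i]
      ))
    }
    if (exons$start[i] > bounds[i]) {
      abort(sprintf(
        "exon gap in reference '%s' at position %d", species_id, bounds[i]
      ))
    }
  }
  if (exons$end[nrow(exons)] != len) {
    abort(sprintf(
      "exons of reference '%s' end at %d but the CDS has %d bases",
      species_id, exons$end[nrow(exons)], len
    ))
  }
  invisible(TRUE)
}

# fetch the single row for a species (hard error when absent)
ref_entry <- function(ref, species_id) {
  i <- match(species_id, ref$species_id)
  if (is.na(i)) {
    abort(sprintf("species '%s' is not in the reference set", species_id))
  }
  ref[i, ]
}

ref_exon_seq <- function(ref, species_id, exon_index) {
  e <- ref_entry(ref, species_id)
  ex <- e$exons[[1]]
  j <- match(exon_index, ex$exon_index)
  if (is.na(j)) {
    abort(sprintf(
      "species '%s' has no exon %d", species_id, exon_index
    ))
  }
  substr(e$cds, ex$start[j], ex$end[j])
}

#' Path to a file shipped with the package
#'
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return Absolute path (or a vector of file names).
#' @export
vkor_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "vkorcall")))
  }
  system.file("extdata", file, package = "vkorcall", mustWork = TRUE)
}
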