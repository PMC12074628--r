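# End-to-end genotyping: amplicons in, annotated per-animal variants out.

#' Genotype a cohort of exon amplicons
#'
#' Runs the full sequence pipeline: locate each exon inside its amplicon on
#' either strand, quarantine samples with indel-bearing or unlocatable exons,
#' assemble the complete CDS of every clean sample, call codon-level variants
#' with IUPAC zygosity and annotate them against the catalogue.
#'
#' @param amplicons Tibble with columns `sample_id`, `species_id`,
#'   `exon_index`, `sequence` (see [read_amplicons()] for the FASTA dialect).
#' @param ref A `vkor_reference`.
#' @param catalogue Catalogue tibble from [load_catalogue()].
#' @param min_identity Exon acceptance threshold (see [align_exon()]).
#'
#' @return List: `annotated` (variant calls), `cds` (assembled sequences),
#'   `assembly_report` (per-amplicon alignment diagnostics), `quarantined`
#'   (samples excluded from codon calling, with reasons).
#' @export
#'
#' @examples
#' ref <- synthetic_reference_set()
#' cat <- default_catalogue(ref)
#' sim <- simulate_cohort(build_fixture_spec(), ref, seed = 7)
#' res <- genotype_cohort(sim$amplicons, ref, cat)
#' dplyr::count(res$annotated, status)
genotype_cohort <- function(amplicons, ref, catalogue, min_identity = 0.90) {
  alignments <- extract_exons(amplicons, ref, min_identity)
  bad <- alignments |> filter(!.data$accepted)
  quarantined <- bad |>
    select("sample_id", "species_id", "exon_index", "identity", "flag")
  clean <- alignments |>
    filter(!.data$sample_id %in% bad$sample_id)
  if (nrow(clean) == 0L) {
    abort("no sample passed exon extraction")
  }
  cds <- assemble_cds(clean, ref)
  annotated <- call_variants(cds, ref, catalogue)
  list(
    annotated = annotated,
    cds = cds,
    assembly_report = alignments |> select(-"extracted_exon"),
    quarantined = quarantined
  )
}
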