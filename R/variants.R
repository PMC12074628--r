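# Nucleotide- and codon-level variant calling with IUPAC zygosity.
#
# Zygosity is inferred purely from the IUPAC symbol observed in the Sanger
# consensus: an unambiguous non-reference base is a homozygous alternate, a
# two-base code containing the reference base is a ref/alt heterozygote, and
# any other ambiguity (a two-base code excluding the reference, or a 3-4 base
# code) is reported as complex and excluded from table-style counts.  There is
# no read-depth or peak-height model, and none is pretended.

#' Call nucleotide variants against the species reference
#'
#' One call per CDS position where the observed symbol differs from the
#' reference base.  Positions observed as `N` are no-calls: skipped with a
#' warning.
#'
#' @param cds_tbl Tibble from [assemble_cds()]: `sample_id`, `species_id`,
#'   `cds`.
#' @param ref A `vkor_reference`.
#'
#' @return Tibble: `sample_id`, `species_id`, `cds_pos`, `ref_base`,
#'   `observed_code`, `zygosity` (`hom_alt`/`het`/`complex_het`).
#' @export
call_nucleotide_variants <- function(cds_tbl, ref) {
  out <- purrr::pmap(cds_tbl, function(sample_id, species_id, cds, ...) {
    ref_cds <- ref_entry(ref, species_id)$cds
    if (nchar(cds) != nchar(ref_cds)) {
      abort(sprintf(
        "sample '%s': CDS length %d does not match reference length %d",
        sample_id, nchar(cds), nchar(ref_cds)
      ))
    }
    obs <- seq_chars(cds)
    refc <- seq_chars(ref_cds)
    pos <- which(obs != refc)
    if (length(pos) == 0L) return(NULL)
    is_n <- obs[pos] == "N"
    if (any(is_n)) {
      warn(sprintf(
        "sample '%s': %d position(s) observed as N skipped (no-call)",
        sample_id, sum(is_n)
      ))
      pos <- pos[!is_n]
      if (length(pos) == 0L) return(NULL)
    }
    sets <- unname(.expand_many(obs[pos]))
    zyg <- purrr::map2_chr(sets, refc[pos], function(s, r) {
      if (length(s) == 1L) "hom_alt"
      else if (length(s) == 2L && r %in% s) "het"
      else "complex_het"
    })
    tibble(
      sample_id = sample_id, species_id = species_id,
      cds_pos = as.integer(pos), ref_base = refc[pos],
      observed_code = obs[pos], zygosity = zyg
    )
  })
  out <- bind_rows(out)
  if (nrow(out) == 0L) {
    out <- tibble(
      sample_id = character(), species_id = character(),
      cds_pos = integer(), ref_base = character(),
      observed_code = character(), zygosity = character()
    )
  }
  out
}

# allele expansion of one observed codon: all unambiguous codons compatible
# with the three observed symbols
.expand_codon <- function(obs3) {
  sets <- .expand_many(obs3)
  grid <- expand.grid(sets[[1]], sets[[2]], sets[[3]],
                      stringsAsFactors = FALSE)
  apply(grid, 1L, paste, collapse = "")
}

#' Group nucleotide variants into codon-level calls
#'
#' Variants are grouped by the codon containing them; the observed codon's
#' IUPAC symbols are expanded into candidate alleles.  A codon with a single
#' heterozygous position yields the usual ref/alt allele pair; a codon with
#' two or more heterozygous positions cannot be phased from a Sanger
#' consensus, so all candidate alleles are listed, `phase_ambiguous` is set
#' and the codon is excluded from single-mutation frequency counts.  Calls
#' whose ambiguity excludes the reference base (or spans more than two bases)
#' are likewise excluded (`excluded_from_counts`).
#'
#' @param nuc_variants Output of [call_nucleotide_variants()].
#' @param cds_tbl The assembled CDS table the variants were called from.
#' @param ref A `vkor_reference`.
#'
#' @return Tibble with one row per (sample, codon, alternate allele):
#'   `sample_id`, `species_id`, `codon_index`, `ref_codon`, `obs_codon`,
#'   `alt_codon`, `alleles` ("/"-joined candidate alleles), `zygosity`,
#'   `phase_ambiguous`, `excluded_from_counts`, `effect`
#'   (`silent`/`missense`/`nonsense`), `label`.
#' @export
call_codon_variants <- function(nuc_variants, cds_tbl, ref) {
  empty <- tibble(
    sample_id = character(), species_id = character(),
    codon_index = integer(), ref_codon = character(),
    obs_codon = character(), alt_codon = character(), alleles = character(),
    zygosity = character(), phase_ambiguous = logical(),
    excluded_from_counts = logical(), effect = character(),
    label = character()
  )
  if (nrow(nuc_variants) == 0L) return(empty)

  cds_by_sample <- setNames(cds_tbl$cds, cds_tbl$sample_id)
  groups <- nuc_variants |>
    mutate(codon_index = (as.integer(.data$cds_pos) + 2L) %/% 3L) |>
    group_by(.data$sample_id, .data$species_id, .data$codon_index)

  dplyr::group_map(groups, function(g, key) {
    ref_cds <- ref_entry(ref, key$species_id)$cds
    ref_codon <- codon_at(ref_cds, key$codon_index)
    obs_codon <- codon_at(cds_by_sample[[key$sample_id]], key$codon_index)
    obs3 <- seq_chars(obs_codon)
    sizes <- vapply(.expand_many(obs3), length, 1L)
    amb_pos <- which(sizes > 1L)
    alleles <- .expand_codon(obs3)
    any_complex <- any(g$zygosity == "complex_het")
    phase_ambiguous <- length(amb_pos) >= 2L
    alts <- setdiff(alleles, ref_codon)

    zygosity <- if (any_complex) {
      "complex_het"
    } else if (length(amb_pos) == 0L) {
      "hom_alt"
    } else {
      "het"
    }
    excluded <- any_complex || phase_ambiguous
    aa_ref <- translate_codon(ref_codon)
    aa_alt <- translate_codon(alts)
    effect <- dplyr::case_when(
      aa_alt == "*" ~ "nonsense",
      aa_alt == aa_ref ~ "silent",
      TRUE ~ "missense"
    )
    tibble(
      sample_id = key$sample_id, species_id = key$species_id,
      codon_index = key$codon_index, ref_codon = ref_codon,
      obs_codon = obs_codon, alt_codon = alts,
      alleles = paste(sort(alleles), collapse = "/"),
      zygosity = zygosity, phase_ambiguous = phase_ambiguous,
      excluded_from_counts = excluded,
      effect = effect,
      label = paste0(aa_ref, key$codon_index, aa_alt)
    )
  }) |>
    bind_rows() |>
    arrange(.data$sample_id, .data$codon_index, .data$alt_codon)
}

#' Annotate codon variants against a resistance catalogue
#'
#' Looks each call up by (species, codon, ref codon, alt codon).  Matches
#' inherit the catalogue `status` and `evidence`; unmatched calls get status
#' `unlisted`.  Species-fixed sites (the black-rat codon-90 Leu) are flagged
#' via `species_fixed = TRUE`: they are the species wild type, retained for
#' table rendering but never counted as polymorphism or resistance.
#'
#' @param codon_variants Output of [call_codon_variants()].
#' @param catalogue Output of [load_catalogue()] / [default_catalogue()].
#'
#' @return The input with `status`, `evidence` and `species_fixed` columns.
#' @export
classify_variants <- function(codon_variants, catalogue) {
  out <- codon_variants |>
    left_join(
      catalogue |>
        select("species_id", "codon_index", "ref_codon", "alt_codon",
               "status", "evidence"),
      by = c("species_id", "codon_index", "ref_codon", "alt_codon")
    ) |>
    mutate(
      status = dplyr::coalesce(.data$status, "unlisted"),
      species_fixed = .data$status == "species_fixed"
    )
  out
}

#' Call and annotate all variants of assembled coding sequences
#'
#' Convenience chain of [call_nucleotide_variants()],
#' [call_codon_variants()] and [classify_variants()].
#'
#' @inheritParams call_nucleotide_variants
#' @inheritParams classify_variants
#' @return Annotated codon-variant tibble (see [classify_variants()]).
#' @export
call_variants <- function(cds_tbl, ref, catalogue) {
  nuc <- call_nucleotide_variants(cds_tbl, ref)
  call_codon_variants(nuc, cds_tbl, ref) |>
    classify_variants(catalogue)
}
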