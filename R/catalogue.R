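# Resistance-mutation catalogue.
#
# The catalogue is data, not code: a versioned TSV shipped under extdata so
# newly published mutations are additions, not releases.  Mutation identity is
# keyed by (species, codon_index, ref_codon, alt_codon); the display label is
# always re-derived by translation and compared to the printed label, which
# guards against label/codon inconsistencies in source tables.

.catalogue_statuses <- c(
  "resistance_associated", "novel", "known_other", "species_fixed"
)

#' Load a resistance-mutation catalogue
#'
#' Reads a tab-delimited catalogue with columns `species_scope`
#' (comma-separated species labels), `codon_index`, `ref_codon`, `alt_codon`,
#' `label` (the label as printed in the source literature), `status` (one of
#' `resistance_associated`, `novel`, `known_other`, `species_fixed`) and
#' `evidence`.  Labels are re-derived by translating the two codons; rows
#' whose printed label disagrees with the derived one are kept but flagged
#' (`label_consistent = FALSE`) with a warning.
#'
#' @param tsv_path Path to the catalogue TSV.
#' @param reference Optional `vkor_reference`; when given, each entry's
#'   `ref_codon` is checked against the reference codon at that position for
#'   every species in scope.
#'
#' @return A tibble with one row per (species, mutation): columns
#'   `species_id`, `codon_index`, `ref_codon`, `alt_codon`, `label` (derived),
#'   `label_printed`, `label_consistent`, `status`, `evidence`.
#' @export
#'
#' @examples
#' cat <- load_catalogue(vkor_example("vkorc1_mutation_catalogue.tsv"))
#' dplyr::filter(cat, status == "resistance_associated")
load_catalogue <- function(tsv_path, reference = NULL) {
  raw <- readr::read_tsv(
    tsv_path,
    col_types = readr::cols(
      species_scope = readr::col_character(),
      codon_index = readr::col_integer(),
      ref_codon = readr::col_character(),
      alt_codon = readr::col_character(),
      label = readr::col_character(),
      status = readr::col_character(),
      evidence = readr::col_character()
    )
  )
  raw <- raw |> mutate(
    ref_codon = toupper(.data$ref_codon),
    alt_codon = toupper(.data$alt_codon)
  )
  bad_codon <- !grepl("^[ACGT]{3}$", raw$ref_codon) |
    !grepl("^[ACGT]{3}$", raw$alt_codon)
  if (any(bad_codon)) {
    abort(sprintf(
      "catalogue row %d: codons must be unambiguous triplets",
      which(bad_codon)[1]
    ))
  }
  if (any(raw$ref_codon == raw$alt_codon)) {
    abort(sprintf(
      "catalogue row %d: ref_codon equals alt_codon",
      which(raw$ref_codon == raw$alt_codon)[1]
    ))
  }
  bad_status <- !raw$status %in% .catalogue_statuses
  if (any(bad_status)) {
    abort(sprintf(
      "catalogue row %d: unknown status '%s'",
      which(bad_status)[1], raw$status[which(bad_status)[1]]
    ))
  }
  fixed_multi <- raw$status == "species_fixed" &
    vapply(strsplit(raw$species_scope, ","), length, 1L) != 1L
  if (any(fixed_multi)) {
    abort(sprintf(
      "catalogue row %d: species_fixed entries must name exactly one species",
      which(fixed_multi)[1]
    ))
  }

  cat <- raw |>
    mutate(row = row_number(),
           species_id = strsplit(.data$species_scope, ",")) |>
    tidyr::unnest("species_id") |>
    mutate(
      species_id = trimws(.data$species_id),
      label_printed = .data$label,
      label = paste0(
        translate_codon(.data$ref_codon), .data$codon_index,
        translate_codon(.data$alt_codon)
      ),
      label_consistent = .data$label == .data$label_printed
    ) |>
    select(
      "species_id", "codon_index", "ref_codon", "alt_codon", "label",
      "label_printed", "label_consistent", "status", "evidence"
    )

  dup <- duplicated(cat[, c("species_id", "codon_index", "alt_codon")])
  if (any(dup)) {
    d <- cat[which(dup)[1], ]
    abort(sprintf(
      "duplicate catalogue entry: %s codon %d alt %s",
      d$species_id, d$codon_index, d$alt_codon
    ))
  }
  if (any(!cat$label_consistent)) {
    bad <- cat[!cat$label_consistent, ]
    warn(sprintf(
      "%d catalogue entr%s with printed label disagreeing with translation (e.g. codon %d printed '%s', derived '%s'); derived labels are used",
      nrow(bad), if (nrow(bad) == 1L) "y" else "ies",
      bad$codon_index[1], bad$label_printed[1], bad$label[1]
    ))
  }

  if (!is.null(reference)) {
    purrr::pwalk(cat, function(species_id, codon_index, ref_codon, ...) {
      have <- codon_at(ref_entry(reference, species_id)$cds, codon_index)
      if (have != ref_codon) {
        abort(sprintf(
          "catalogue ref_codon %s at codon %d of '%s' disagrees with the reference codon %s",
          ref_codon, codon_index, species_id, have
        ))
      }
    })
  }
  cat
}

#' Load the catalogue shipped with the package
#'
#' Convenience wrapper around [load_catalogue()] for the default catalogue
#' (`vkorc1_mutation_catalogue.tsv` under `extdata`), which lists every
#' published mutation of the three-species survey with its literature status,
#' including the black-rat codon-90 species-fixed site.
#'
#' @inheritParams load_catalogue
#' @return See [load_catalogue()].
#' @export
default_catalogue <- function(reference = NULL) {
  suppressWarnings(
    load_catalogue(vkor_example("vkorc1_mutation_catalogue.tsv"), reference)
  )
}
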