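# Cohort aggregation: per-species mutation frequency tables and the
# resistance-prevalence headline.
#
# Frequency of a mutation is the number of animals carrying it -- whether in
# homozygosis or heterozygosis -- out of the species census; prevalence is
# the fraction of all animals carrying at least one resistance-associated
# variant, each animal counted once no matter how many it carries.  Printed
# values use half-up rounding at a per-species precision; full-precision
# values are retained alongside.

default_digits <- c(.default = 1, Mus_musculus = 2)

.species_digits <- function(species, digits) {
  d <- unname(digits[species])
  ifelse(is.na(d), unname(digits[".default"]) %||% 1, d)
}

#' Summarise annotated variants into per-species frequency tables
#'
#' @param annotated Annotated variant tibble from [call_variants()] /
#'   [classify_variants()].  Calls flagged `excluded_from_counts` (complex or
#'   phase-ambiguous heterozygotes) are dropped from the tables; species-fixed
#'   sites are retained as flagged rows (they belong in the published table
#'   layout) but never contribute to prevalence.
#' @param animals Census tibble with columns `sample_id` and `species_id`;
#'   must list every animal, including those with no variants (they count in
#'   the denominators).
#' @param digits Named vector of printed decimal places per species; the
#'   `.default` element covers unnamed species.  Default: 1 decimal, 2 for
#'   the house mouse (the published table convention).
#'
#' @return A `vkor_cohort` object; see [tidy.vkor_cohort()],
#'   [glance.vkor_cohort()], [autoplot.vkor_cohort()], [render_tables()].
#' @export
#'
#' @examples
#' ref <- synthetic_reference_set()
#' cat <- default_catalogue(ref)
#' spec <- build_fixture_spec()
#' sim <- simulate_cohort(spec, ref, seed = 1)
#' cds <- extract_exons(sim$amplicons, ref) |> assemble_cds(ref)
#' ann <- call_variants(cds, ref, cat)
#' summarize_cohort(ann, spec$animals)
summarize_cohort <- function(annotated, animals, digits = default_digits) {
  unknown <- setdiff(annotated$species_id, animals$species_id)
  if (length(unknown) > 0L) {
    abort(sprintf("variant table names species '%s' absent from the census",
                  unknown[1]))
  }
  orphan <- setdiff(annotated$sample_id, animals$sample_id)
  if (length(orphan) > 0L) {
    abort(sprintf("animal '%s' has variants but is not in the census",
                  orphan[1]))
  }
  census <- animals |>
    distinct(.data$sample_id, .data$species_id) |>
    count(.data$species_id, name = "n_animals")

  counted <- annotated |> filter(!.data$excluded_from_counts)
  mutations <- counted |>
    group_by(.data$species_id, .data$codon_index, .data$ref_codon,
             .data$alt_codon, .data$label, .data$effect, .data$status) |>
    summarise(
      homo_count = sum(.data$zygosity == "hom_alt"),
      het_count = sum(.data$zygosity == "het"),
      carrier_count = n_distinct(.data$sample_id),
      .groups = "drop"
    ) |>
    left_join(census, by = "species_id") |>
    mutate(
      frequency_pct = 100 * .data$carrier_count / .data$n_animals,
      frequency_printed = round_half_up(
        .data$frequency_pct, .species_digits(.data$species_id, digits)
      )
    ) |>
    arrange(.data$species_id, .data$codon_index, .data$alt_codon)
  stopifnot(all(mutations$homo_count + mutations$het_count ==
                  mutations$carrier_count))

  prev <- compute_prevalence(annotated, animals)
  structure(
    list(
      mutations = mutations,
      census = census,
      prevalence = prev,
      digits = digits
    ),
    class = "vkor_cohort"
  )
}

#' Cohort resistance prevalence
#'
#' Counts animals carrying at least one resistance-associated variant, each
#' animal once (a compound carrier of two resistance mutations still counts
#' once).  Novel, known-other, unlisted and species-fixed calls never count.
#'
#' @inheritParams summarize_cohort
#' @return One-row tibble: `resistant_animal_count`, `total_animals`,
#'   `prevalence_pct` (half-up, 2 decimals), plus a `by_species` attribute
#'   tibble with per-species resistant counts.
#' @export
compute_prevalence <- function(annotated, animals) {
  animals <- animals |> distinct(.data$sample_id, .data$species_id)
  resistant <- annotated |>
    filter(.data$status == "resistance_associated",
           !.data$excluded_from_counts) |>
    distinct(.data$sample_id)
  by_species <- animals |>
    mutate(resistant = .data$sample_id %in% resistant$sample_id) |>
    group_by(.data$species_id) |>
    summarise(
      resistant_animal_count = sum(.data$resistant),
      n_animals = n(), .groups = "drop"
    )
  out <- tibble(
    resistant_animal_count = nrow(resistant),
    total_animals = nrow(animals),
    prevalence_pct = round_half_up(100 * nrow(resistant) / nrow(animals), 2)
  )
  attr(out, "by_species") <- by_species
  out
}

#' @export
print.vkor_cohort <- function(x, ...) {
  p <- x$prevalence
  cat(sprintf(
    "Vkorc1 cohort summary: %d animals, %d species\n",
    p$total_animals, nrow(x$census)
  ))
  cat(sprintf(
    "Resistance prevalence: %d/%d animals (%.2f%%) carry >=1 resistance-associated SNP\n\n",
    p$resistant_animal_count, p$total_animals, p$prevalence_pct
  ))
  print(x$mutations, n = Inf)
  invisible(x)
}

#' Tidy a cohort summary into its per-mutation table
#'
#' @param x A `vkor_cohort`.
#' @param ... Unused.
#' @return The per-mutation tibble (one row per species x mutation).
#' @export
tidy.vkor_cohort <- function(x, ...) x$mutations

#' One-row cohort headline
#'
#' @param x A `vkor_cohort`.
#' @param ... Unused.
#' @return One-row tibble: species count, census, resistant animals,
#'   prevalence.
#' @export
glance.vkor_cohort <- function(x, ...) {
  tibble(
    n_species = nrow(x$census),
    total_animals = x$prevalence$total_animals,
    resistant_animal_count = x$prevalence$resistant_animal_count,
    prevalence_pct = x$prevalence$prevalence_pct
  )
}

#' Plot per-species mutation frequencies
#'
#' Bar chart of carrier frequency per mutation, faceted by species and
#' coloured by catalogue status.
#'
#' @param object A `vkor_cohort`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vkor_cohort <- function(object, ...) {
  d <- object$mutations |>
    mutate(label = stats::reorder(.data$label, .data$codon_index))
  ggplot2::ggplot(
    d,
    ggplot2::aes(x = .data$label, y = .data$frequency_pct,
                 fill = .data$status)
  ) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~species_id, scales = "free_x") +
    ggplot2::labs(
      x = "mutation (derived label)", y = "carrier frequency (% of species)",
      fill = "catalogue status"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

.fmt_freq <- function(x, digits) {
  formatC(x, format = "f", digits = digits)
}

#' Write cohort report files
#'
#' Emits, per species, a machine-readable TSV and an aligned plain-text table
#' (rows in ascending codon order), plus a cohort headline text block and a
#' JSON file of machine-readable counts.  Output is byte-stable: identical
#' inputs give identical files.
#'
#' @param x A `vkor_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
render_tables <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (sp in sort(x$census$species_id)) {
    d <- .species_digits(sp, x$digits)
    tbl <- x$mutations |>
      filter(.data$species_id == sp) |>
      arrange(.data$codon_index, .data$alt_codon) |>
      mutate(frequency_printed = .fmt_freq(.data$frequency_printed, d))
    tsv <- file.path(dir, sprintf("summary_%s.tsv", sp))
    readr::write_tsv(tbl, tsv)
    txt <- file.path(dir, sprintf("summary_%s.txt", sp))
    header <- sprintf("%-6s %-8s %-4s %-4s %-9s %-9s %5s %5s",
                      "codon", "label", "ref", "alt", "effect",
                      "frequency", "homo", "het")
    lines <- sprintf(
      "%-6d %-8s %-4s %-4s %-9s %9s %5d %5d",
      tbl$codon_index, tbl$label, tbl$ref_codon, tbl$alt_codon, tbl$effect,
      .fmt_freq(as.numeric(tbl$frequency_printed), d),
      tbl$homo_count, tbl$het_count
    )
    n <- x$census$n_animals[x$census$species_id == sp]
    writeLines(c(sprintf("%s (n = %d)", sp, n), header, lines), txt)
    paths <- c(paths, tsv, txt)
  }
  p <- x$prevalence
  by_sp <- attr(p, "by_species")
  headline <- file.path(dir, "cohort_headline.txt")
  writeLines(c(
    sprintf("animals analysed: %d", p$total_animals),
    sprintf("animals with >=1 resistance-associated SNP: %d",
            p$resistant_animal_count),
    sprintf("resistance prevalence: %.2f%%", p$prevalence_pct),
    sprintf("  %s: %d/%d", by_sp$species_id, by_sp$resistant_animal_count,
            by_sp$n_animals)
  ), headline)
  json <- file.path(dir, "cohort_counts.json")
  jsonlite::write_json(
    list(
      census = x$census,
      prevalence = list(
        resistant_animal_count = p$resistant_animal_count,
        total_animals = p$total_animals,
        prevalence_pct = p$prevalence_pct
      ),
      by_species = by_sp,
      mutations = x$mutations
    ),
    json, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  paths <- c(paths, headline, json)
  invisible(paths)
}
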