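# Synthetic cohorts: per-animal genotype truth, exon amplicons, COI barcodes
# and toy structures, with the statistical shape of a three-species rodent
# resistance survey.

new_cohort_spec <- function(animals, genotypes, species_fixed,
                            pad_range = c(20L, 60L), revcomp_prob = 0.5) {
  stopifnot(all(genotypes$sample_id %in% animals$sample_id))
  stopifnot(all(genotypes$zygosity %in% c("hom", "het")))
  dup <- duplicated(genotypes[, c("sample_id", "codon_index")])
  if (any(dup)) {
    d <- genotypes[which(dup)[1], ]
    abort(sprintf("animal '%s' assigned two genotypes at codon %d",
                  d$sample_id, d$codon_index))
  }
  structure(
    list(animals = animals, genotypes = genotypes,
         species_fixed = species_fixed, pad_range = pad_range,
         revcomp_prob = revcomp_prob),
    class = "vkor_cohort_spec"
  )
}

#' @export
print.vkor_cohort_spec <- function(x, ...) {
  cat("synthetic cohort spec\n")
  print(count(x$animals, .data$species_id))
  cat(sprintf("%d planted genotypes, %d species-fixed sites\n",
              nrow(x$genotypes), nrow(x$species_fixed)))
  invisible(x)
}

# assignment helper: one mutation over a set of animals
.assign <- function(species, ids, codon, ref, alt, zyg) {
  tibble(
    sample_id = ids, species_id = species,
    codon_index = as.integer(codon), ref_codon = ref, alt_codon = alt,
    zygosity = zyg
  )
}

#' Deterministic fixture cohort matching the published survey
#'
#' Builds the per-animal genotype assignment of a 67-animal cohort (24 brown
#' rats, 35 black rats, 8 house mice) whose aggregates reproduce every
#' homozygote/heterozygote count of the published per-species tables and
#' honour the stated co-occurrence constraints: no brown rat carries both
#' R61W and Y139F, and exactly three mice are heterozygous for both L128S and
#' Y139C (so six of eight mice carry at least one resistance mutation).  The
#' assignment of the silent background to individual animals is not published
#' beyond its aggregate counts; it is fixed here deterministically.
#'
#' @return A `vkor_cohort_spec`: `animals` (census), `genotypes` (one row per
#'   animal x codon with `zygosity` `hom`/`het`), `species_fixed` sites and
#'   amplicon generation settings.  Aggregates are re-counted on construction
#'   and an infeasible assignment is an error.
#' @export
build_fixture_spec <- function() {
  rn <- sprintf("Rn%02d", 1:24)
  rr <- sprintf("Rr%02d", 1:35)
  mm <- sprintf("Mm%02d", 1:8)
  animals <- tibble(
    sample_id = c(rn, rr, mm),
    species_id = rep(c("Rattus_norvegicus", "Rattus_rattus", "Mus_musculus"),
                     c(24L, 35L, 8L))
  )

  g <- bind_rows(
    # brown rats: Y139F (9 hom) and R61W (2 hom + 2 het) are disjoint
    .assign("Rattus_norvegicus", rn[1:9], 139, "TAT", "TTT", "hom"),
    .assign("Rattus_norvegicus", rn[10:11], 61, "CGG", "TGG", "hom"),
    .assign("Rattus_norvegicus", rn[12:13], 61, "CGG", "TGG", "het"),
    .assign("Rattus_norvegicus", rn[14], 28, "CAC", "CAG", "hom"),
    .assign("Rattus_norvegicus",
            rn[c(1:5, 10, 12, 14, 15, 16)], 82, "ATA", "ATT", "hom"),
    .assign("Rattus_norvegicus", rn[17], 96, "TGC", "GGC", "het"),
    .assign("Rattus_norvegicus", rn[18], 123, "ATC", "AGC", "hom"),
    # black rats: W59R carriers are animals 1..10
    .assign("Rattus_rattus", rr[1:6], 59, "TGG", "AGG", "hom"),
    .assign("Rattus_rattus", rr[7:10], 59, "TGG", "AGG", "het"),
    .assign("Rattus_rattus", rr[11], 7, "AGC", "GGC", "het"),
    .assign("Rattus_rattus", rr[1:34], 12, "CGG", "CGA", "hom"),
    .assign("Rattus_rattus", rr[35], 12, "CGG", "CGA", "het"),
    .assign("Rattus_rattus", rr[11], 28, "CAC", "CAG", "hom"),
    .assign("Rattus_rattus", rr[12:13], 28, "CAC", "CAG", "het"),
    .assign("Rattus_rattus", rr[14], 35, "CGC", "CGT", "het"),
    .assign("Rattus_rattus", rr[15], 36, "AAT", "CAT", "hom"),
    .assign("Rattus_rattus", rr[1:8], 41, "GCG", "GCA", "hom"),
    .assign("Rattus_rattus", rr[9:14], 41, "GCG", "GCA", "het"),
    .assign("Rattus_rattus", rr[16:20], 42, "CTC", "CCC", "hom"),
    .assign("Rattus_rattus", rr[21:23], 42, "CTC", "CCC", "het"),
    .assign("Rattus_rattus", rr[5:22], 94, "TTA", "CTA", "hom"),
    .assign("Rattus_rattus", rr[23:24], 94, "TTA", "CTA", "het"),
    .assign("Rattus_rattus", rr[24], 96, "TGC", "GGC", "het"),
    .assign("Rattus_rattus", rr[1:34], 107, "ATC", "ATA", "hom"),
    .assign("Rattus_rattus", rr[25:27], 123, "ATC", "TTC", "het"),
    .assign("Rattus_rattus", rr[2:35], 137, "ACC", "ACT", "hom"),
    .assign("Rattus_rattus", rr[1:17], 143, "GCG", "GCA", "hom"),
    .assign("Rattus_rattus", rr[18:30], 143, "GCG", "GCA", "het"),
    # mice: three double heterozygotes; the two homozygotes are distinct
    # animals; mice 7-8 carry nothing
    .assign("Mus_musculus", mm[1], 128, "TTA", "TCA", "hom"),
    .assign("Mus_musculus", mm[3:5], 128, "TTA", "TCA", "het"),
    .assign("Mus_musculus", mm[2], 139, "TAT", "TGT", "hom"),
    .assign("Mus_musculus", mm[3:6], 139, "TAT", "TGT", "het"),
    .assign("Mus_musculus", mm[6], 87, "TTC", "TTA", "het"),
    .assign("Mus_musculus", mm[7], 78, "CAA", "CAC", "het"),
    .assign("Mus_musculus", mm[8], 85, "TGC", "CGC", "het")
  )

  species_fixed <- tibble(
    species_id = "Rattus_rattus", codon_index = 90L,
    ref_codon = "ATA", alt_codon = "TTA"
  )

  spec <- new_cohort_spec(animals, g, species_fixed)

  # self-check: recount against the declared published aggregates
  declared <- .fixture_declared_counts()
  counted <- g |>
    group_by(.data$species_id, .data$codon_index, .data$alt_codon) |>
    summarise(homo = sum(.data$zygosity == "hom"),
              het = sum(.data$zygosity == "het"), .groups = "drop")
  chk <- dplyr::full_join(
    declared, counted,
    by = c("species_id", "codon_index", "alt_codon"),
    suffix = c("_want", "_have")
  )
  ok <- !is.na(chk$homo_want) & !is.na(chk$homo_have) &
    chk$homo_want == chk$homo_have & chk$het_want == chk$het_have
  if (!all(ok)) {
    bad <- chk[!ok, ][1, ]
    abort(sprintf(
      "fixture self-check failed at %s codon %d", bad$species_id,
      bad$codon_index
    ))
  }
  both_rats <- intersect(
    g$sample_id[g$species_id == "Rattus_norvegicus" & g$codon_index == 139],
    g$sample_id[g$species_id == "Rattus_norvegicus" & g$codon_index == 61]
  )
  both_mice <- intersect(
    g$sample_id[g$species_id == "Mus_musculus" & g$codon_index == 128 &
                  g$zygosity == "het"],
    g$sample_id[g$species_id == "Mus_musculus" & g$codon_index == 139 &
                  g$zygosity == "het"]
  )
  if (length(both_rats) != 0L || length(both_mice) != 3L) {
    abort("fixture self-check failed: co-occurrence constraints violated")
  }
  spec
}

# declared (published) homo/het aggregates of the fixture
.fixture_declared_counts <- function() {
  rn <- "Rattus_norvegicus"; rr <- "Rattus_rattus"; mm <- "Mus_musculus"
  tribble_cols <- function(...) {
    m <- matrix(list(...), ncol = 5L, byrow = TRUE)
    tibble(
      species_id = unlist(m[, 1]), codon_index = as.integer(unlist(m[, 2])),
      alt_codon = unlist(m[, 3]), homo = as.integer(unlist(m[, 4])),
      het = as.integer(unlist(m[, 5]))
    )
  }
  tribble_cols(
    rn, 28, "CAG", 1, 0,
    rn, 61, "TGG", 2, 2,
    rn, 82, "ATT", 10, 0,
    rn, 96, "GGC", 0, 1,
    rn, 123, "AGC", 1, 0,
    rn, 139, "TTT", 9, 0,
    rr, 7, "GGC", 0, 1,
    rr, 12, "CGA", 34, 1,
    rr, 28, "CAG", 1, 2,
    rr, 35, "CGT", 0, 1,
    rr, 36, "CAT", 1, 0,
    rr, 41, "GCA", 8, 6,
    rr, 42, "CCC", 5, 3,
    rr, 59, "AGG", 6, 4,
    rr, 94, "CTA", 18, 2,
    rr, 96, "GGC", 0, 1,
    rr, 107, "ATA", 34, 0,
    rr, 123, "TTC", 0, 3,
    rr, 137, "ACT", 34, 0,
    rr, 143, "GCA", 17, 13,
    mm, 78, "CAC", 0, 1,
    mm, 85, "CGC", 0, 1,
    mm, 87, "TTA", 0, 1,
    mm, 128, "TCA", 1, 3,
    mm, 139, "TGT", 1, 4
  )
}

#' Random cohort spec for property testing
#'
#' Samples a small cohort with random planted substitutions: per animal a
#' Poisson number of variant codons, a random single-base substitution per
#' codon and random zygosity.  Codons carrying species-fixed sites and the
#' terminal start/stop codons are never mutated.
#'
#' @param ref A `vkor_reference`.
#' @param n_by_species Named integer vector of animals per species.
#' @param seed Integer seed; same seed, same spec.
#' @param mean_variants Mean planted variants per animal.
#' @param het_prob Probability a planted variant is heterozygous.
#' @param pad_range Length-2 range of flanking pad lengths for generation.
#'
#' @return A `vkor_cohort_spec`.
#' @export
random_cohort_spec <- function(ref,
                               n_by_species = c(Rattus_norvegicus = 4L,
                                                Rattus_rattus = 4L,
                                                Mus_musculus = 4L),
                               seed = 1L, mean_variants = 1.5,
                               het_prob = 0.5, pad_range = c(20L, 200L)) {
  species_fixed <- tibble(
    species_id = "Rattus_rattus", codon_index = 90L,
    ref_codon = "ATA", alt_codon = "TTA"
  )
  withr::with_seed(seed, {
    animals <- purrr::imap(n_by_species, function(n, sp) {
      tibble(sample_id = sprintf("%s_%02d", sp, seq_len(n)),
             species_id = sp)
    }) |> bind_rows()
    bases <- c("A", "C", "G", "T")
    genotypes <- purrr::pmap(animals, function(sample_id, species_id) {
      entry <- ref_entry(ref, species_id)
      banned <- c(1L, entry$codon_count,
                  species_fixed$codon_index[
                    species_fixed$species_id == species_id])
      k <- stats::rpois(1L, mean_variants)
      if (k == 0L) return(NULL)
      codons <- sample(setdiff(seq_len(entry$codon_count), banned),
                       min(k, entry$codon_count - length(banned)))
      purrr::map(codons, function(ci) {
        ref_codon <- codon_at(entry$cds, ci)
        p <- sample(1:3, 1L)
        old <- substr(ref_codon, p, p)
        alt_codon <- ref_codon
        substr(alt_codon, p, p) <- sample(setdiff(bases, old), 1L)
        tibble(
          sample_id = sample_id, species_id = species_id,
          codon_index = ci, ref_codon = ref_codon, alt_codon = alt_codon,
          zygosity = if (runif(1L) < het_prob) "het" else "hom"
        )
      }) |> bind_rows()
    }) |> bind_rows()
    new_cohort_spec(animals, genotypes, species_fixed,
                    pad_range = pad_range)
  })
}

# apply one codon genotype to a character vector of CDS bases
.apply_genotype <- function(chars, codon_index, ref_codon, alt_codon,
                            zygosity) {
  at <- 3L * codon_index - 2L
  stopifnot(paste(chars[at:(at + 2L)], collapse = "") == ref_codon)
  refc <- seq_chars(ref_codon)
  altc <- seq_chars(alt_codon)
  for (p in which(refc != altc)) {
    chars[at + p - 1L] <- if (zygosity == "hom") altc[p]
                          else iupac_code(c(refc[p], altc[p]))
  }
  chars
}

#' Generate a synthetic cohort from a spec
#'
#' For each animal: applies the species-fixed substitutions and the planted
#' genotypes to the species reference CDS (heterozygotes become IUPAC
#' ambiguity codes, mirroring a Sanger consensus), splits the CDS at the exon
#' boundaries, wraps every exon in random non-exonic padding, and
#' reverse-complements a random half of the amplicons.  A COI barcode per
#' animal is drawn from the species panel with under 2% random divergence.
#' Identical seeds give byte-identical outputs.
#'
#' @param spec A `vkor_cohort_spec`.
#' @param ref A `vkor_reference`.
#' @param seed Integer seed for padding, strand flips and barcode noise.
#' @param out_dir Optional directory; when given, writes one FASTA per exon
#'   (record ids `sampleID|species|exonN`), a COI FASTA, a truth TSV and a
#'   spec echo JSON.
#' @param coi_panel Barcode panel (defaults to the packaged synthetic panel).
#'
#' @return List with tibbles `amplicons` (`sample_id`, `species_id`,
#'   `exon_index`, `sequence`, `strand`), `coi`, `truth`, and `files` (paths,
#'   when written).
#' @export
simulate_cohort <- function(spec, ref, seed = 1L, out_dir = NULL,
                            coi_panel = synthetic_coi_panel()) {
  bases <- c("A", "C", "G", "T")
  withr::with_seed(seed, {
    per_animal <- purrr::pmap(spec$animals, function(sample_id, species_id) {
      entry <- ref_entry(ref, species_id)
      chars <- seq_chars(entry$cds)
      sf <- spec$species_fixed |> filter(.data$species_id == !!species_id)
      for (i in seq_len(nrow(sf))) {
        chars <- .apply_genotype(chars, sf$codon_index[i], sf$ref_codon[i],
                                 sf$alt_codon[i], "hom")
      }
      gt <- spec$genotypes |> filter(.data$sample_id == !!sample_id)
      for (i in seq_len(nrow(gt))) {
        chars <- .apply_genotype(chars, gt$codon_index[i], gt$ref_codon[i],
                                 gt$alt_codon[i], gt$zygosity[i])
      }
      cds <- paste(chars, collapse = "")
      ex <- entry$exons[[1]]
      amps <- purrr::pmap(ex, function(exon_index, start, end) {
        pad <- function() {
          paste(sample(bases, sample(spec$pad_range[1]:spec$pad_range[2], 1L),
                       replace = TRUE), collapse = "")
        }
        amp <- paste0(pad(), substr(cds, start, end), pad())
        flip <- runif(1L) < spec$revcomp_prob
        tibble(
          sample_id = sample_id, species_id = species_id,
          exon_index = exon_index,
          sequence = if (flip) revcomp(amp) else amp,
          strand = if (flip) "-" else "+"
        )
      }) |> bind_rows()
      panel_seq <- coi_panel$sequence[coi_panel$species_id == species_id]
      cc <- seq_chars(panel_seq)
      k <- sample(0:4, 1L)
      if (k > 0L) {
        at <- sample(length(cc), k)
        cc[at] <- vapply(cc[at],
                         function(b) sample(setdiff(bases, b), 1L), "")
      }
      list(amps = amps,
           coi = tibble(sample_id = sample_id, species_id = species_id,
                        sequence = paste(cc, collapse = "")))
    })
    amplicons <- bind_rows(purrr::map(per_animal, "amps"))
    coi <- bind_rows(purrr::map(per_animal, "coi"))
  })
  truth <- spec$genotypes |>
    arrange(.data$sample_id, .data$codon_index)
  files <- character()
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (e in sort(unique(amplicons$exon_index))) {
      a <- amplicons |> filter(.data$exon_index == e)
      path <- file.path(out_dir, sprintf("exon%d.fasta", e))
      writeLines(as.vector(rbind(
        sprintf(">%s|%s|exon%d", a$sample_id, a$species_id, e), a$sequence
      )), path)
      files <- c(files, path)
    }
    coi_path <- file.path(out_dir, "coi.fasta")
    writeLines(as.vector(rbind(paste0(">", coi$sample_id), coi$sequence)),
               coi_path)
    truth_path <- file.path(out_dir, "truth.tsv")
    readr::write_tsv(truth, truth_path)
    spec_path <- file.path(out_dir, "spec.json")
    jsonlite::write_json(
      list(animals = spec$animals, genotypes = spec$genotypes,
           species_fixed = spec$species_fixed, pad_range = spec$pad_range,
           revcomp_prob = spec$revcomp_prob, seed = seed),
      spec_path, auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    files <- c(files, coi_path, truth_path, spec_path)
  }
  list(amplicons = amplicons, coi = coi, truth = truth, files = files)
}

#' Compare recovered genotypes against the generator truth
#'
#' Exact comparison of every (animal, codon, alternate codon, zygosity)
#' record between the truth table and the pipeline calls.  Species-fixed and
#' count-excluded calls are ignored on the call side; truth zygosity `hom`
#' matches call zygosity `hom_alt`.
#'
#' @param truth Truth tibble from [simulate_cohort()].
#' @param annotated Annotated calls from [call_variants()].
#'
#' @return Tibble of mismatches (`direction` is `missing_call` for truth rows
#'   the pipeline missed and `unexpected_call` for calls not in the truth);
#'   zero rows means exact recovery.
#' @export
verify_roundtrip <- function(truth, annotated) {
  key <- c("sample_id", "codon_index", "alt_codon", "zygosity")
  t_norm <- truth |>
    mutate(zygosity = ifelse(.data$zygosity == "hom", "hom_alt",
                             .data$zygosity)) |>
    select(dplyr::all_of(key))
  c_norm <- annotated |>
    filter(!.data$species_fixed, !.data$excluded_from_counts) |>
    select(dplyr::all_of(key))
  bind_rows(
    anti_join(t_norm, c_norm, by = key) |>
      mutate(direction = "missing_call"),
    anti_join(c_norm, t_norm, by = key) |>
      mutate(direction = "unexpected_call")
  )
}

#' Write a toy PDB file from an atom table
#'
#' Fixture plumbing for the structural tests: emits fixed-width ATOM/HETATM
#' coordinate records (one model, `END` terminated) that any PDB parser
#' reads back.
#'
#' @param atoms Tibble with columns `resno`, `x`, `y`, `z` and optionally
#'   `type` (default ATOM), `eleno`, `elety`, `altloc`, `resid`, `chain`,
#'   `occupancy`, `bfactor`, `element`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_toy_pdb <- function(atoms, path) {
  n <- nrow(atoms)
  get <- function(col, default) {
    if (col %in% names(atoms)) atoms[[col]] else rep(default, length.out = n)
  }
  elety <- get("elety", "CA")
  name4 <- ifelse(nchar(elety) < 4L, paste0(" ", elety), elety)
  lines <- sprintf(
    "%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    get("type", "ATOM"), get("eleno", seq_len(n)), name4,
    get("altloc", ""), get("resid", "ALA"), get("chain", "A"),
    atoms$resno, atoms$x, atoms$y, atoms$z,
    get("occupancy", 1), get("bfactor", 0),
    get("element", toupper(substr(elety, 1L, 1L)))
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}
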