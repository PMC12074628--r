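# Synthetic stand-in references.
#
# The genotyping logic only needs a coordinate frame: a stop-free CDS whose
# wild-type codon is known at every catalogued position.  The generator below
# builds such a frame deterministically -- random non-stop codons with every
# catalogued wild-type codon planted at its published position -- so the whole
# pipeline is testable without any sequence download.  Both *Rattus* species
# share one reference record (the survey convention: a single brown-rat
# reference for both rats, with the codon-90 Ile/Leu difference handled as a
# species-fixed site), while the mouse gets its own record and exon partition.

# wild-type codons at catalogued positions (codon index -> triplet)
.rat_wt_codons <- c(
  `7` = "AGC", `12` = "CGG", `28` = "CAC", `35` = "CGC", `36` = "AAT",
  `41` = "GCG", `42` = "CTC", `59` = "TGG", `61` = "CGG", `82` = "ATA",
  `90` = "ATA", `94` = "TTA", `96` = "TGC", `107` = "ATC", `123` = "ATC",
  `137` = "ACC", `139` = "TAT", `143` = "GCG"
)

.mouse_wt_codons <- c(
  `78` = "CAA", `85` = "TGC", `87` = "TTC", `128` = "TTA", `139` = "TAT"
)

.stop_codons <- c("TAA", "TAG", "TGA")

# deterministic stop-free CDS with planted codons; 1 = ATG, last = TGA
.synthetic_cds <- function(codon_count, plant, seed) {
  all_codons <- apply(
    expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                c("A", "C", "G", "T"), stringsAsFactors = FALSE),
    1L, paste, collapse = ""
  )
  sense <- setdiff(all_codons, .stop_codons)
  codons <- withr::with_seed(
    seed,
    sample(sense, codon_count, replace = TRUE)
  )
  codons[1L] <- "ATG"
  codons[codon_count] <- "TGA"
  idx <- as.integer(names(plant))
  stopifnot(all(idx > 1L & idx < codon_count))
  codons[idx] <- unname(plant)
  paste(codons, collapse = "")
}

#' Build the synthetic three-species reference set in memory
#'
#' Deterministic; identical to the files shipped under `extdata`
#' (`synthetic_vkorc1_cds.fasta` / `synthetic_vkorc1_exons.tsv`).
#' 161 codons per species; three exons whose sizes mimic the published
#' amplicon proportions.
#'
#' @return A `vkor_reference` tibble (see [load_reference()]).
#' @export
synthetic_reference_set <- function() {
  rat_cds <- .synthetic_cds(161L, .rat_wt_codons, seed = 961L)
  mouse_cds <- .synthetic_cds(161L, .mouse_wt_codons, seed = 962L)
  seq_tbl <- tibble(
    species_id = c("Rattus_norvegicus", "Rattus_rattus", "Mus_musculus"),
    cds = c(rat_cds, rat_cds, mouse_cds)
  )
  exon_tbl <- tibble(
    species_id = rep(seq_tbl$species_id, each = 3L),
    exon_index = rep(1:3, times = 3L),
    start = as.integer(c(1, 161, 327, 1, 161, 327, 1, 158, 331)),
    end = as.integer(c(160, 326, 483, 160, 326, 483, 157, 330, 483))
  )
  new_reference_set(seq_tbl, exon_tbl)
}

# deterministic synthetic COI barcode panel: one well-separated 420-nt
# barcode per species (identity between species far below any sensible
# assignment threshold)
synthetic_coi_panel <- function() {
  bases <- c("A", "C", "G", "T")
  make <- function(seed) {
    paste(withr::with_seed(seed, sample(bases, 420L, replace = TRUE)),
          collapse = "")
  }
  tibble(
    species_id = c("Rattus_norvegicus", "Rattus_rattus", "Mus_musculus"),
    sequence = c(make(9711L), make(9712L), make(9713L))
  )
}

#' Write the synthetic reference fixtures to a directory
#'
#' Emits `synthetic_vkorc1_cds.fasta`, `synthetic_vkorc1_exons.tsv` and
#' `synthetic_coi_panel.fasta` (the files shipped under `extdata`).
#'
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_synthetic_references <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- synthetic_reference_set()
  fasta <- file.path(dir, "synthetic_vkorc1_cds.fasta")
  writeLines(
    as.vector(rbind(paste0(">", ref$species_id), ref$cds)),
    fasta
  )
  exon_tbl <- tidyr::unnest(
    select(ref, "species_id", "exons"), "exons"
  )
  tsv <- file.path(dir, "synthetic_vkorc1_exons.tsv")
  readr::write_tsv(exon_tbl, tsv)
  panel <- synthetic_coi_panel()
  coi <- file.path(dir, "synthetic_coi_panel.fasta")
  writeLines(
    as.vector(rbind(paste0(">", panel$species_id), panel$sequence)),
    coi
  )
  invisible(c(fasta, tsv, coi))
}
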