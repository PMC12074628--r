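# Exon location inside amplicons, strand resolution and CDS assembly.
#
# Each Sanger amplicon contains one exon plus non-exonic flanking sequence on
# an unknown strand.  The reference exon is aligned semi-globally against the
# amplicon (free end gaps on the amplicon side) on both strands with a scoring
# scheme in which any IUPAC-compatible pair counts as a match, so heterozygous
# double-peak positions do not penalise the alignment: match +1, mismatch -1,
# gap opening -5, gap extension -1.  Indel-bearing alignments are quarantined
# rather than called: every variant handled downstream is a substitution.

#' Identify the species of a COI barcode by percent identity
#'
#' Global pairwise alignment of each query barcode against every record of a
#' species-labelled panel; the species of the best-identity record is assigned
#' when its identity reaches `min_identity`, otherwise the call is
#' `unresolved`.  Exact identity ties are broken by panel order and flagged.
#'
#' @param coi A tibble with columns `sample_id` and `sequence`, or a single
#'   sequence string.
#' @param panel Species barcode panel: a tibble with columns `species_id` and
#'   `sequence`, or a path to a FASTA whose record ids are species labels.
#' @param min_identity Assignment threshold in percent (default 98).
#'
#' @return Tibble with one row per query: `sample_id`, `best_species`,
#'   `identity_pct`, `decision` (`assigned`/`unresolved`), `tie`.
#' @export
identify_species <- function(coi, panel, min_identity = 98) {
  if (is.character(coi)) {
    coi <- tibble(sample_id = names(coi) %||% paste0("query", seq_along(coi)),
                  sequence = unname(coi))
  }
  if (is.character(panel) && length(panel) == 1L && file.exists(panel)) {
    seqs <- Biostrings::readDNAStringSet(panel)
    panel <- tibble(species_id = sub("\\s.*$", "", names(seqs)),
                    sequence = as.character(seqs))
  }
  if (nrow(panel) == 0L) abort("the barcode panel is empty")
  check_alphabet <- function(x, what) {
    bad <- regexpr(sprintf("[^%s]", paste(IUPAC_SYMBOLS, collapse = "")),
                   toupper(x))
    if (any(bad > 0L)) {
      i <- which(bad > 0L)[1]
      abort(sprintf("%s contains a non-nucleotide symbol '%s'",
                    what, substr(toupper(x[i]), bad[i], bad[i])))
    }
  }
  check_alphabet(panel$sequence, "barcode panel")
  check_alphabet(coi$sequence, "COI query")

  purrr::pmap(coi, function(sample_id, sequence, ...) {
    ids <- vapply(panel$sequence, function(p) {
      aln <- Biostrings::pairwiseAlignment(
        pattern = Biostrings::DNAString(toupper(sequence)),
        subject = Biostrings::DNAString(toupper(p)),
        type = "global"
      )
      Biostrings::pid(aln, type = "PID1")
    }, numeric(1), USE.NAMES = FALSE)
    best <- which.max(ids)
    tie <- sum(abs(ids - ids[best]) < 1e-9) > 1L
    tibble(
      sample_id = sample_id,
      best_species = panel$species_id[best],
      identity_pct = ids[best],
      decision = if (ids[best] >= min_identity) "assigned" else "unresolved",
      tie = tie
    )
  }) |> bind_rows()
}

#' Locate a reference exon inside one amplicon
#'
#' Aligns the reference exon of `species_id`/`exon_index` against the amplicon
#' on both strands and returns the better-scoring placement.  The extracted
#' exon has exactly the reference exon length and retains IUPAC heterozygote
#' codes.  Acceptance requires gap-free alignment and identity (fraction of
#' IUPAC-compatible positions over the exon length) of at least
#' `min_identity`; rejected amplicons carry an explanatory `flag`.
#'
#' @param sequence Amplicon sequence (IUPAC alphabet).
#' @param exon_index Which exon the amplicon covers.
#' @param species_id Species whose reference frames the exon.
#' @param ref A `vkor_reference`.
#' @param min_identity Acceptance threshold, fraction 0..1 (default 0.90).
#'
#' @return One-row tibble: `exon_index`, `strand` (`+`/`-`), `window_start`,
#'   `window_end` (1-based inclusive on the reported strand), `identity`,
#'   `gap_count`, `extracted_exon`, `accepted`, `flag`.
#' @export
align_exon <- function(sequence, exon_index, species_id, ref,
                       min_identity = 0.90) {
  exon <- ref_exon_seq(ref, species_id, exon_index)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) abort("empty amplicon sequence")

  score_one <- function(amp) {
    aln <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAString(exon),
      subject = Biostrings::DNAString(amp),
      type = "global-local",
      substitutionMatrix = .iupac_score_matrix,
      gapOpening = 5, gapExtension = 1
    )
    pat <- as.character(Biostrings::alignedPattern(aln))
    sub <- as.character(Biostrings::alignedSubject(aln))
    gaps <- sum(seq_chars(pat) == "-") + sum(seq_chars(sub) == "-")
    pc <- seq_chars(pat)
    sc <- seq_chars(sub)
    keep <- pc != "-" & sc != "-"
    matches <- sum(iupac_compatible(pc[keep], sc[keep]))
    list(
      score = BiocGenerics::score(aln),
      gaps = gaps,
      identity = matches / nchar(exon),
      start = BiocGenerics::start(Biostrings::subject(aln)),
      end = BiocGenerics::end(Biostrings::subject(aln)),
      seq = amp
    )
  }

  fwd <- score_one(sequence)
  rev <- score_one(revcomp(sequence))
  if (isTRUE(all.equal(fwd$score, rev$score))) {
    warn(sprintf(
      "exon %d: identical alignment score on both strands; keeping '+'",
      exon_index
    ))
    best <- fwd
    strand <- "+"
  } else if (fwd$score >= rev$score) {
    best <- fwd
    strand <- "+"
  } else {
    best <- rev
    strand <- "-"
  }

  flag <- NA_character_
  extracted <- NA_character_
  accepted <- FALSE
  if (best$identity < min_identity) {
    flag <- "exon not found"
  } else if (best$gaps > 0L) {
    flag <- "indel-containing amplicon"
  } else {
    accepted <- TRUE
    extracted <- substr(best$seq, best$start, best$end)
    stopifnot(nchar(extracted) == nchar(exon))
  }
  tibble(
    exon_index = as.integer(exon_index),
    strand = strand,
    window_start = best$start,
    window_end = best$end,
    score = best$score,
    identity = best$identity,
    gap_count = as.integer(best$gaps),
    extracted_exon = extracted,
    accepted = accepted,
    flag = flag
  )
}

#' Locate exons for a whole table of amplicons
#'
#' @param amplicons Tibble with columns `sample_id`, `species_id`,
#'   `exon_index`, `sequence`.
#' @inheritParams align_exon
#' @return Tibble: one row per amplicon with the [align_exon()] columns
#'   prefixed by `sample_id` and `species_id`.
#' @export
extract_exons <- function(amplicons, ref, min_identity = 0.90) {
  need <- c("sample_id", "species_id", "exon_index", "sequence")
  miss <- setdiff(need, names(amplicons))
  if (length(miss) > 0L) {
    abort(sprintf("amplicon table lacks column '%s'", miss[1]))
  }
  purrr::pmap(amplicons, function(sample_id, species_id, exon_index,
                                  sequence, ...) {
    dplyr::bind_cols(
      tibble(sample_id = sample_id, species_id = species_id),
      align_exon(sequence, exon_index, species_id, ref, min_identity)
    )
  }) |> bind_rows()
}

#' Assemble complete coding sequences from accepted exon alignments
#'
#' Joins the extracted exons of each sample in exon order into the complete
#' CDS.  Samples are keyed by `sample_id`; input row order never matters.
#' Every sample must contribute exactly one accepted alignment per exon.
#'
#' @param alignments Output of [extract_exons()] (accepted rows are used;
#'   rejected rows cause an error naming the exon, so quarantine first).
#' @param ref A `vkor_reference`.
#'
#' @return Tibble with columns `sample_id`, `species_id`, `cds`.
#' @export
assemble_cds <- function(alignments, ref) {
  if (any(!alignments$accepted)) {
    bad <- alignments[!alignments$accepted, ]
    abort(sprintf(
      "sample '%s' exon %d was not accepted (%s); quarantine before assembly",
      bad$sample_id[1], bad$exon_index[1], bad$flag[1]
    ))
  }
  alignments |>
    group_by(.data$sample_id, .data$species_id) |>
    dplyr::group_modify(function(g, key) {
      entry <- ref_entry(ref, key$species_id)
      want <- entry$exons[[1]]$exon_index
      if (!identical(sort(g$exon_index), want)) {
        missing <- setdiff(want, g$exon_index)
        dup <- g$exon_index[duplicated(g$exon_index)]
        abort(sprintf(
          "sample '%s': %s",
          key$sample_id,
          if (length(missing) > 0L) {
            sprintf("missing exon %s", paste(missing, collapse = ", "))
          } else {
            sprintf("duplicate exon %s", paste(unique(dup), collapse = ", "))
          }
        ))
      }
      cds <- paste(g$extracted_exon[order(g$exon_index)], collapse = "")
      if (nchar(cds) != nchar(entry$cds)) {
        abort(sprintf(
          "internal error: assembled CDS of '%s' has %d bases, reference %d",
          key$sample_id, nchar(cds), nchar(entry$cds)
        ))
      }
      tibble(cds = cds)
    }) |>
    ungroup() |>
    arrange(.data$sample_id)
}

#' Read exon amplicons from FASTA files
#'
#' Record ids must follow the dialect `sampleID|species|exonN`, e.g.
#' `Rn01|Rattus_norvegicus|exon2`.
#'
#' @param paths FASTA file paths (each may hold any mix of samples/exons).
#' @return Amplicon tibble for [extract_exons()], plus a `source_file` column.
#' @export
read_amplicons <- function(paths) {
  purrr::map(paths, function(p) {
    seqs <- Biostrings::readDNAStringSet(p)
    ids <- sub("\\s.*$", "", names(seqs))
    parts <- strsplit(ids, "|", fixed = TRUE)
    bad <- vapply(parts, length, 1L) != 3L |
      !grepl("^exon[0-9]+$", vapply(parts, function(x) x[3], ""))
    if (any(bad)) {
      abort(sprintf(
        "record id '%s' in %s does not follow 'sampleID|species|exonN'",
        ids[which(bad)[1]], p
      ))
    }
    tibble(
      sample_id = vapply(parts, function(x) x[1], ""),
      species_id = vapply(parts, function(x) x[2], ""),
      exon_index = as.integer(sub("^exon", "",
                                  vapply(parts, function(x) x[3], ""))),
      sequence = as.character(seqs),
      source_file = p
    )
  }) |> bind_rows()
}
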