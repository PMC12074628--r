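pad_seq <- function(n, seed) {
  paste(withr::with_seed(seed, sample(c("A", "C", "G", "T"), n, TRUE)),
        collapse = "")
}

test_that("species identification by percent identity with threshold and ties", {
  panel <- tibble(
    species_id = c("SpA", "SpB"),
    sequence = c(pad_seq(120, 1), pad_seq(120, 2))
  )
  # exact match
  hit <- identify_species(panel$sequence[2], panel)
  expect_equal(hit$best_species, "SpB")
  expect_equal(hit$identity_pct, 100)
  expect_equal(hit$decision, "assigned")
  expect_false(hit$tie)
  # ~90% identity: unresolved under the default 98% threshold
  q <- panel$sequence[1]
  ch <- strsplit(q, "")[[1]]
  at <- seq(1, 111, by = 10)  # 12 substitutions over 120 nt
  ch[at] <- vapply(ch[at],
                   function(b) setdiff(c("A", "C", "G", "T"), b)[1], "")
  far <- identify_species(paste(ch, collapse = ""), panel)
  expect_equal(far$best_species, "SpA")
  expect_lt(far$identity_pct, 98)
  expect_equal(far$decision, "unresolved")
  # equidistant query: one substitution from each of two panel records that
  # differ at exactly two positions (brute-force construction)
  base <- pad_seq(60, 3)
  a <- b <- q2 <- strsplit(base, "")[[1]]
  a[10] <- setdiff(c("A", "C", "G", "T"), a[10])[1]
  b[40] <- setdiff(c("A", "C", "G", "T"), b[40])[1]
  q2[10] <- a[10]; q2[40] <- b[40]  # one mismatch to each
  tie_panel <- tibble(species_id = c("First", "Second"),
                      sequence = c(paste(a, collapse = ""),
                                   paste(b, collapse = "")))
  tie <- identify_species(paste(q2, collapse = ""), tie_panel)
  expect_equal(tie$best_species, "First")  # panel order breaks the tie
  expect_true(tie$tie)
  # errors
  expect_error(identify_species("ACGT", panel[0, ]), "empty")
  expect_error(identify_species("ACXT", panel), "non-nucleotide")
})

test_that("exon extraction finds padded exons on either strand, keeping IUPAC codes", {
  ref <- toy_ref()
  exon2 <- "TGGCGG"  # reference exon 2
  amp <- paste0(pad_seq(20, 11), exon2, pad_seq(20, 12))
  fwd <- align_exon(amp, 2, "SpA", ref)
  expect_true(fwd$accepted)
  expect_equal(fwd$strand, "+")
  expect_equal(fwd$identity, 1)
  expect_equal(fwd$gap_count, 0L)
  expect_equal(fwd$extracted_exon, exon2)
  # reverse complement of the same amplicon: identical extraction, strand -
  rev <- align_exon(revcomp_oracle(amp), 2, "SpA", ref)
  expect_true(rev$accepted)
  expect_equal(rev$strand, "-")
  expect_equal(rev$extracted_exon, exon2)
  # heterozygote W at a reference-T position is compatible: identity stays 1
  het_amp <- sub("TGGCGG", "WGGCGG", amp)
  het <- align_exon(het_amp, 2, "SpA", ref)
  expect_equal(het$identity, 1)
  expect_equal(het$extracted_exon, "WGGCGG")
})

test_that("degraded amplicons are flagged rather than called", {
  # a single-base deletion in the middle of a full-length exon is cheaper to
  # explain with a gap than with half an exon of mismatches: indel flag
  ref <- synthetic_reference_set()
  entry <- ref[ref$species_id == "Mus_musculus", ]
  exon1 <- substr(entry$cds, 1, 157)
  broken <- paste0(substr(exon1, 1, 80), substr(exon1, 82, 157))
  out <- align_exon(paste0(pad_seq(25, 21), broken, pad_seq(25, 22)),
                    1, "Mus_musculus", ref)
  expect_false(out$accepted)
  expect_equal(out$flag, "indel-containing amplicon")
  # unrelated sequence: exon not found on either strand
  junk <- align_exon(pad_seq(200, 23), 1, "Mus_musculus", ref)
  expect_false(junk$accepted)
  expect_equal(junk$flag, "exon not found")
})

test_that("extraction matches the exhaustive window-scoring oracle", {
  ref <- synthetic_reference_set()
  entry <- ref[ref$species_id == "Mus_musculus", ]
  for (seed in 1:6) {
    spec <- random_cohort_spec(
      ref, n_by_species = c(Mus_musculus = 1L), seed = seed,
      mean_variants = 3, pad_range = c(10L, 120L)
    )
    sim <- simulate_cohort(spec, ref, seed = seed + 100)
    amp <- sim$amplicons[sample(nrow(sim$amplicons), 1), ]
    exon_seq <- substr(entry$cds,
                       entry$exons[[1]]$start[amp$exon_index],
                       entry$exons[[1]]$end[amp$exon_index])
    got <- align_exon(amp$sequence, amp$exon_index, "Mus_musculus", ref)
    want <- oracle_best_window(exon_seq, amp$sequence)
    expect_equal(got$strand, want$strand)
    expect_equal(got$extracted_exon, want$window)
    expect_equal(got$identity, want$identity)
  }
})

test_that("padding of any length up to 200 nt leaves extraction unchanged", {
  ref <- toy_ref()
  exon3 <- "TCCTTA"
  for (seed in 1:5) {
    n_left <- withr::with_seed(seed, sample(0:200, 2))
    amp <- paste0(pad_seq(n_left[1], seed + 30), exon3,
                  pad_seq(n_left[2], seed + 60))
    out <- align_exon(amp, 3, "SpA", ref)
    expect_true(out$accepted)
    expect_equal(out$extracted_exon, exon3)
  }
})

test_that("assembly is keyed by sample id, not input order", {
  ref <- toy_ref()
  amps <- tibble(
    sample_id = rep(c("s1", "s2"), each = 3),
    species_id = "SpA",
    exon_index = rep(1:3, 2),
    sequence = c("ATGTAT", "TGGCGG", "TCCTTA",   # s1 = reference
                 "ATGTAT", "TGGAGG", "TCCTTA")   # s2 carries one substitution
  )
  # toy exons are 6 nt, so one substitution is 5/6 identity; relax the
  # acceptance threshold accordingly
  shuffled <- amps[c(5, 1, 6, 3, 2, 4), ]
  cds_a <- extract_exons(amps, ref, min_identity = 0.8) |> assemble_cds(ref)
  cds_b <- extract_exons(shuffled, ref, min_identity = 0.8) |>
    assemble_cds(ref)
  expect_identical(cds_a, cds_b)
  expect_equal(cds_a$cds[cds_a$sample_id == "s1"], "ATGTATTGGCGGTCCTTA")
  diffs <- which(strsplit(cds_a$cds[1], "")[[1]] !=
                   strsplit(cds_a$cds[2], "")[[1]])
  expect_length(diffs, 1)
  # missing exon errors name the exon
  expect_error(
    extract_exons(amps[-2, ], ref, min_identity = 0.8) |> assemble_cds(ref),
    "missing exon 2"
  )
  # duplicate exon
  expect_error(
    extract_exons(amps[c(1, 2, 2, 3), ], ref) |> assemble_cds(ref),
    "duplicate exon 2"
  )
})

test_that("amplicon FASTA dialect round-trips through read_amplicons", {
  dir <- tempfile(); dir.create(dir)
  path <- file.path(dir, "exon1.fasta")
  writeLines(c(">s1|SpA|exon1", "ATGTAT", ">s2|SpA|exon1", "ATGTWT"), path)
  amps <- read_amplicons(path)
  expect_equal(amps$sample_id, c("s1", "s2"))
  expect_equal(amps$exon_index, c(1L, 1L))
  writeLines(c(">oops", "ACGT"), path)
  expect_error(read_amplicons(path), "dialect|sampleID")
})
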