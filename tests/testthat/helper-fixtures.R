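# Shared fixtures and independent oracles for the test suite.
# Oracles deliberately avoid the code paths they check: plain loops over
# expansions, windows, rotations and atom pairs.

suppressMessages({
  library(dplyr)
  library(tibble)
})

# ---- toy references ------------------------------------------------------

write_ref_files <- function(seq_tbl, exon_tbl, dir = tempfile("ref")) {
  dir.create(dir)
  fasta <- file.path(dir, "ref.fasta")
  writeLines(as.vector(rbind(paste0(">", seq_tbl$species_id), seq_tbl$cds)),
             fasta)
  tsv <- file.path(dir, "exons.tsv")
  readr::write_tsv(exon_tbl, tsv)
  list(fasta = fasta, tsv = tsv)
}

# 18-nt single-species toy: codons ATG TAT TGG CGG TCC TTA
toy_ref_files <- function(cds = "ATGTATTGGCGGTCCTTA",
                          exons = tibble(species_id = "SpA",
                                         exon_index = 1:3,
                                         start = c(1L, 7L, 13L),
                                         end = c(6L, 12L, 18L))) {
  write_ref_files(tibble(species_id = "SpA", cds = cds), exons)
}

toy_ref <- function(...) {
  f <- toy_ref_files(...)
  load_reference(f$fasta, f$tsv)
}

# ---- IUPAC / alignment oracles ------------------------------------------

iupac_sets_oracle <- local({
  m <- Biostrings::IUPAC_CODE_MAP
  s <- strsplit(unname(m), "")
  names(s) <- names(m)
  s
})

compat_oracle <- function(a, b) {
  length(intersect(iupac_sets_oracle[[a]], iupac_sets_oracle[[b]])) > 0
}

revcomp_oracle <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# exhaustive gap-free window scorer: every start, both strands,
# +1 per IUPAC-compatible position, -1 otherwise
oracle_best_window <- function(exon, amplicon) {
  ex <- strsplit(exon, "")[[1]]
  best <- list(score = -Inf)
  for (strand in c("+", "-")) {
    amp <- if (strand == "+") amplicon else revcomp_oracle(amplicon)
    ac <- strsplit(amp, "")[[1]]
    n_win <- length(ac) - length(ex) + 1L
    if (n_win < 1L) next
    for (s in seq_len(n_win)) {
      win <- ac[s:(s + length(ex) - 1L)]
      comp <- mapply(compat_oracle, ex, win)
      score <- sum(ifelse(comp, 1, -1))
      if (score > best$score) {
        best <- list(score = score, strand = strand, start = s,
                     window = paste(win, collapse = ""),
                     identity = mean(comp))
      }
    }
  }
  best
}

# ---- structural oracles --------------------------------------------------

dist3 <- function(a, b) sqrt(sum((a - b)^2))

# O(n^2) contact scan over heavy atoms
oracle_contacts <- function(atoms, cutoff) {
  heavy <- atoms[atoms$element != "H", ]
  lig <- heavy[heavy$is_ligand, ]
  prot <- heavy[!heavy$is_ligand & !heavy$resid %in% c("HOH", "WAT"), ]
  out <- list()
  for (key in unique(paste(prot$chain, prot$resno))) {
    sub <- prot[paste(prot$chain, prot$resno) == key, ]
    dmin <- Inf
    for (i in seq_len(nrow(sub))) {
      for (j in seq_len(nrow(lig))) {
        dmin <- min(dmin, dist3(c(sub$x[i], sub$y[i], sub$z[i]),
                                c(lig$x[j], lig$y[j], lig$z[j])))
      }
    }
    if (dmin <= cutoff) out[[key]] <- tibble(resno = sub$resno[1],
                                             min_dist = dmin)
  }
  bind_rows(out) |> arrange(min_dist)
}

oracle_hbonds <- function(atoms, cutoff, polar = c("N", "O", "S")) {
  heavy <- atoms[atoms$element %in% polar, ]
  lig <- heavy[heavy$is_ligand, ]
  prot <- heavy[!heavy$is_ligand, ]
  out <- list()
  for (i in seq_len(nrow(prot))) {
    for (j in seq_len(nrow(lig))) {
      d <- dist3(c(prot$x[i], prot$y[i], prot$z[i]),
                 c(lig$x[j], lig$y[j], lig$z[j]))
      if (d <= cutoff) {
        out[[length(out) + 1L]] <- tibble(
          resno = prot$resno[i], atom = prot$elety[i],
          ligand_atom = lig$elety[j], dist = d
        )
      }
    }
  }
  bind_rows(out) |> arrange(dist)
}

euler_rot <- function(a, b, c) {
  rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1),
                           3, byrow = TRUE)
  ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0, -sin(t), 0, cos(t)),
                           3, byrow = TRUE)
  rz(a) %*% ry(b) %*% rz(c)
}

# independent minimiser: coarse Euler-angle grid, then Nelder-Mead refinement
oracle_min_rmsd <- function(fixed, mobile, step_deg = 20) {
  f0 <- sweep(fixed, 2, colMeans(fixed))
  m0 <- sweep(mobile, 2, colMeans(mobile))
  rmsd_of <- function(ang) {
    r <- euler_rot(ang[1], ang[2], ang[3])
    sqrt(mean(rowSums((f0 - m0 %*% t(r))^2)))
  }
  grid <- seq(0, 2 * pi, by = step_deg * pi / 180)
  grid_b <- seq(0, pi, by = step_deg * pi / 180)
  best <- c(0, 0, 0); best_v <- rmsd_of(best)
  for (a in grid) for (b in grid_b) for (c in grid) {
    v <- rmsd_of(c(a, b, c))
    if (v < best_v) { best <- c(a, b, c); best_v <- v }
  }
  opt <- stats::optim(best, rmsd_of, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  opt$value
}

# random toy protein-ligand structure as an atom tibble ready for
# write_toy_pdb(); residues at increasing distance from a compact ligand
random_toy_structure <- function(n_res = 12, lig_atoms = 4, seed = 1) {
  withr::with_seed(seed, {
    lig <- tibble(
      type = "HETATM", resid = "LIG", chain = "L",
      resno = 900L, elety = paste0(c("C", "O", "N", "C", "O")[
        seq_len(lig_atoms)], seq_len(lig_atoms)),
      x = runif(lig_atoms, -1, 1), y = runif(lig_atoms, -1, 1),
      z = runif(lig_atoms, -1, 1),
      element = substr(c("C", "O", "N", "C", "O")[seq_len(lig_atoms)], 1, 1)
    )
    res <- purrr::map(seq_len(n_res), function(i) {
      centre <- stats::rnorm(3) * runif(1, 1, 10)
      k <- sample(2:4, 1)
      el <- sample(c("C", "N", "O", "S", "H"), k, replace = TRUE)
      tibble(
        type = "ATOM", resid = "ALA", chain = "A", resno = i,
        elety = paste0(el, seq_len(k)),
        x = centre[1] + stats::rnorm(k, sd = 0.5),
        y = centre[2] + stats::rnorm(k, sd = 0.5),
        z = centre[3] + stats::rnorm(k, sd = 0.5),
        element = el
      )
    }) |> bind_rows()
    bind_rows(res, lig) |> mutate(eleno = dplyr::row_number())
  })
}

load_toy_structure <- function(atoms, ligand = "LIG") {
  path <- tempfile(fileext = ".pdb")
  write_toy_pdb(atoms, path)
  read_structure(path, ligand = ligand)
}

# ---- frozen published table ---------------------------------------------
# Per-species expected cells of the survey's frequency tables: printed
# frequency (half-up at the printed precision), homozygote and heterozygote
# counts, keyed by codon and nucleotide change.

expected_survey_cells <- function() {
  rn <- "Rattus_norvegicus"; rr <- "Rattus_rattus"; mm <- "Mus_musculus"
  tibble::tribble(
    ~species_id, ~codon_index, ~ref_codon, ~alt_codon, ~freq, ~homo, ~het,
    rn, 28L, "CAC", "CAG", 4.2, 1L, 0L,
    rn, 61L, "CGG", "TGG", 16.7, 2L, 2L,
    rn, 82L, "ATA", "ATT", 41.7, 10L, 0L,
    rn, 96L, "TGC", "GGC", 4.2, 0L, 1L,
    rn, 123L, "ATC", "AGC", 4.2, 1L, 0L,
    rn, 139L, "TAT", "TTT", 37.5, 9L, 0L,
    rr, 7L, "AGC", "GGC", 2.9, 0L, 1L,
    rr, 12L, "CGG", "CGA", 100.0, 34L, 1L,
    rr, 28L, "CAC", "CAG", 8.6, 1L, 2L,
    rr, 35L, "CGC", "CGT", 2.9, 0L, 1L,
    rr, 36L, "AAT", "CAT", 2.9, 1L, 0L,
    rr, 41L, "GCG", "GCA", 40.0, 8L, 6L,
    rr, 42L, "CTC", "CCC", 22.9, 5L, 3L,
    rr, 59L, "TGG", "AGG", 28.6, 6L, 4L,
    rr, 90L, "ATA", "TTA", 100.0, 35L, 0L,
    rr, 94L, "TTA", "CTA", 57.1, 18L, 2L,
    rr, 96L, "TGC", "GGC", 2.9, 0L, 1L,
    rr, 107L, "ATC", "ATA", 97.1, 34L, 0L,
    rr, 123L, "ATC", "TTC", 8.6, 0L, 3L,
    rr, 137L, "ACC", "ACT", 97.1, 34L, 0L,
    rr, 143L, "GCG", "GCA", 85.7, 17L, 13L,
    mm, 78L, "CAA", "CAC", 12.50, 0L, 1L,
    mm, 85L, "TGC", "CGC", 12.50, 0L, 1L,
    mm, 87L, "TTC", "TTA", 12.50, 0L, 1L,
    mm, 128L, "TTA", "TCA", 50.00, 1L, 3L,
    mm, 139L, "TAT", "TGT", 62.50, 1L, 4L
  )
}

# run the whole fixture pipeline once per session and cache the result
fixture_run <- local({
  cache <- NULL
  function(seed = 97L) {
    if (!is.null(cache)) return(cache)
    ref <- synthetic_reference_set()
    catalogue <- default_catalogue(ref)
    spec <- build_fixture_spec()
    sim <- simulate_cohort(spec, ref, seed = seed)
    res <- genotype_cohort(sim$amplicons, ref, catalogue)
    cache <<- list(ref = ref, catalogue = catalogue, spec = spec, sim = sim,
                   res = res,
                   summary = summarize_cohort(res$annotated, spec$animals))
    cache
  }
})
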