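test_that("toy PDB files parse with altloc resolution and ligand tagging", {
  atoms <- tibble(
    type = c("ATOM", "ATOM", "ATOM", "HETATM"),
    elety = c("CA", "CA", "CB", "C1"),
    altloc = c("A", "B", "", ""),
    resid = c("ALA", "ALA", "ALA", "LIG"),
    chain = c("A", "A", "A", "L"),
    resno = c(1L, 1L, 1L, 900L),
    x = c(0, 5, 1, 10), y = 0, z = 0,
    occupancy = c(0.6, 0.4, 1, 1),
    element = c("C", "C", "C", "C")
  )
  path <- tempfile(fileext = ".pdb")
  write_toy_pdb(atoms, path)
  s <- read_structure(path, ligand = "LIG")
  expect_equal(nrow(s), 3)  # altloc B dropped
  ca <- s[s$elety == "CA", ]
  expect_equal(ca$x, 0)     # the 0.6-occupancy copy won
  expect_equal(sum(s$is_ligand), 1)
  expect_error(read_structure(path, ligand = "XYZ"), "matches no atom")
})

test_that("contact sets obey the cutoff and are monotone", {
  atoms <- tibble(
    type = c("ATOM", "ATOM", "HETATM"),
    elety = c("CA", "CA", "C1"),
    resid = c("ALA", "ALA", "LIG"),
    chain = c("A", "A", "L"),
    resno = c(1L, 2L, 900L),
    x = c(4.9, 5.1, 0), y = 0, z = 0,
    element = "C"
  )
  s <- load_toy_structure(atoms)
  inside <- ligand_neighborhood(s, 5)
  expect_equal(inside$resno, 1L)
  expect_equal(inside$min_dist, 4.9, tolerance = 1e-6)
  expect_equal(nrow(ligand_neighborhood(s, 0.1)), 0)
  expect_equal(sort(ligand_neighborhood(s, 6)$resno), c(1L, 2L))
})

test_that("contact and hydrogen-bond scans match the all-pairs oracles", {
  for (seed in 1:4) {
    atoms <- random_toy_structure(n_res = 15, seed = seed)
    s <- load_toy_structure(atoms)
    for (cutoff in c(3.5, 5, 8)) {
      got <- ligand_neighborhood(s, cutoff)
      want <- oracle_contacts(s, cutoff)
      expect_equal(sort(got$resno), sort(want$resno))
      expect_equal(got$min_dist[order(got$resno)],
                   want$min_dist[order(want$resno)], tolerance = 1e-9)
    }
    hb <- detect_hbonds(s, 4.5)
    hb_want <- oracle_hbonds(s, 4.5)
    expect_equal(nrow(hb), nrow(hb_want))
    if (nrow(hb) > 0) {
      expect_equal(hb$dist, hb_want$dist, tolerance = 1e-9)
      expect_equal(hb$atom, hb_want$atom)
    }
    # hydrogens and apolar atoms never appear in H-bond lists
    expect_false(any(!hb$atom %in%
                       s$elety[s$element %in% c("N", "O", "S")]))
    # monotonicity in the cutoff
    expect_true(all(ligand_neighborhood(s, 4)$resno %in%
                      ligand_neighborhood(s, 6)$resno))
  }
})

test_that("hydrogen bonds require polar elements on both sides", {
  atoms <- tibble(
    type = c("ATOM", "ATOM", "HETATM", "HETATM"),
    elety = c("OG", "CB", "O1", "C1"),
    resid = c("SER", "SER", "LIG", "LIG"),
    chain = "A", resno = c(1L, 1L, 900L, 900L),
    x = c(0, 0, 2.8, 2.8), y = c(0, 3, 0, 3), z = 0,
    element = c("O", "C", "O", "C")
  )
  s <- load_toy_structure(atoms)
  hb <- detect_hbonds(s, 3.5)
  expect_equal(nrow(hb), 1)       # only the O...O pair at 2.8
  expect_equal(hb$atom, "OG")
  expect_equal(hb$dist, 2.8, tolerance = 1e-9)
})

test_that("superposition recovers rigid motions exactly", {
  pts <- withr::with_seed(5, matrix(stats::rnorm(30), ncol = 3))
  # identical sets: zero RMSD, identity rotation
  sup0 <- kabsch_superpose(pts, pts)
  expect_equal(sup0$rmsd, 0, tolerance = 1e-10)
  expect_equal(sup0$rotation, diag(3), tolerance = 1e-10)
  # rotated 37 degrees about z and translated: still zero RMSD
  th <- 37 * pi / 180
  rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
               3, byrow = TRUE)
  moved <- sweep(pts %*% t(rz), 2, c(1, 2, 3), "+")
  sup <- kabsch_superpose(pts, moved)
  expect_equal(sup$rmsd, 0, tolerance = 1e-9)
  expect_equal(det(sup$rotation), 1, tolerance = 1e-9)
  # the reported transform reproduces the reported RMSD
  back <- apply_superposition(moved, sup)
  expect_equal(sqrt(mean(rowSums((pts - back)^2))), sup$rmsd,
               tolerance = 1e-9)
  # degenerate input
  line <- cbind(1:5, 1:5, 1:5) + 0
  expect_error(kabsch_superpose(line, line), "degenerate")
  expect_error(kabsch_superpose(pts[1:2, ], pts[1:2, ]), "3 atom pairs")
})

test_that("superposition RMSD matches a rotation-search oracle within 1e-3", {
  for (seed in 1:4) {
    coords <- withr::with_seed(seed, {
      f <- matrix(stats::rnorm(15, sd = 3), ncol = 3)
      m <- f + matrix(stats::rnorm(15, sd = 0.4), ncol = 3)
      list(f = f, m = m)
    })
    got <- kabsch_superpose(coords$f, coords$m)$rmsd
    want <- oracle_min_rmsd(coords$f, coords$m)
    expect_equal(got, want, tolerance = 1e-3)
    expect_lte(got, want + 1e-9)  # never worse than any explicit rotation
  }
})

test_that("superposition RMSD is invariant under pre-applied rigid motions", {
  coords <- withr::with_seed(11, {
    f <- matrix(stats::rnorm(24, sd = 3), ncol = 3)
    m <- f + matrix(stats::rnorm(24, sd = 0.3), ncol = 3)
    list(f = f, m = m)
  })
  base <- kabsch_superpose(coords$f, coords$m)$rmsd
  th <- 1.1
  r <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)),
              3, byrow = TRUE)
  spun <- sweep(coords$m %*% t(r), 2, c(-4, 2, 9), "+")
  expect_equal(kabsch_superpose(coords$f, spun)$rmsd, base,
               tolerance = 1e-9)
})

test_that("structure-level superposition pairs by residue and selection", {
  backbone <- c("N", "CA", "C", "O")
  mk <- function(shift = 0, resno_shift = 0L) {
    withr::with_seed(21, {
      purrr::map(1:5, function(i) {
        centre <- stats::rnorm(3, sd = 4)
        tibble(
          type = "ATOM", resid = "ALA", chain = "A",
          resno = i + resno_shift,
          elety = c(backbone, "CB"),
          x = centre[1] + stats::rnorm(5, sd = 0.6) + shift,
          y = centre[2] + stats::rnorm(5, sd = 0.6),
          z = centre[3] + stats::rnorm(5, sd = 0.6),
          element = c("N", "C", "C", "O", "C")
        )
      }) |> bind_rows()
    })
  }
  fixed <- load_toy_structure(mk(), ligand = NULL)
  mobile <- load_toy_structure(mk(shift = 3), ligand = NULL)
  sup <- kabsch_superpose(fixed, mobile, selection = "backbone")
  expect_equal(sup$atom_pair_count, 20)  # 5 residues x 4 backbone atoms
  expect_equal(sup$rmsd, 0, tolerance = 1e-6)  # pure translation
  side <- kabsch_superpose(fixed, mobile, selection = "sidechain")
  expect_equal(side$atom_pair_count, 5)
  # a residue-numbering offset is honoured
  shifted <- load_toy_structure(mk(shift = 3, resno_shift = 10L),
                                ligand = NULL)
  sup_off <- kabsch_superpose(fixed, shifted, selection = "backbone",
                              resno_offset = -10L)
  expect_equal(sup_off$rmsd, sup$rmsd, tolerance = 1e-9)
})

test_that("triage is contact-driven with region-annotated rejections", {
  atoms <- bind_rows(
    tibble(type = "ATOM", elety = "CA", resid = "ALA", chain = "A",
           resno = c(59L, 139L), x = c(30, 3), y = 0, z = 0, element = "C"),
    tibble(type = "HETATM", elety = "C1", resid = "LIG", chain = "L",
           resno = 900L, x = 0, y = 0, z = 0, element = "C")
  )
  s <- load_toy_structure(atoms)
  regions <- tibble(start = c(50L, 120L), end = c(75L, 161L),
                    region = c("cap domain", "binding pocket wall"))
  muts <- tibble(label = c("W59R", "Y139F"), residue_number = c(59L, 139L))
  out <- triage_mutations(muts, s, regions = regions, cutoff = 5)
  expect_equal(out$decision, c("not_suitable", "suitable"))
  expect_equal(out$reason[1], "cap domain")
  expect_equal(out$reason[2], "in ligand contact set")
  expect_error(
    triage_mutations(tibble(label = "X1Y", residue_number = 7L), s,
                     regions = regions),
    "absent from the structure"
  )
})
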