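test_that("PDB reader recovers atoms, gaps and the altloc rule", {
  lines <- c(
    pdb_atom_line(1, "N",  "ALA", "A", 1, 1.5, 2.25, 3.125),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 4.0, 5.0, 6.0),
    pdb_atom_line(3, "CA", "GLY", "A", 2, 7.0, 8.0, 9.0))
  m <- read_structure(write_fixture_pdb(lines))
  expect_equal(nrow(m$atoms), 3)
  expect_equal(m$atoms$x, c(1.5, 4.0, 7.0))
  expect_equal(m$atoms$z[1], 3.125)
  expect_equal(m$atoms$element, c("N", "C", "C"))
  expect_equal(nrow(m$unresolved), 0)

  # residues 1-5 and 10-12: unresolved gap 6-9
  lines2 <- sapply(c(1:5, 10:12), function(i)
    pdb_atom_line(i, "CA", "ALA", "A", i, i * 4, 0, 0))
  m2 <- read_structure(write_fixture_pdb(lines2))
  expect_equal(m2$unresolved,
               data.frame(chain = "A", start = 6L, end = 9L,
                          stringsAsFactors = FALSE))

  # altloc: keep highest occupancy; ties go to altloc A
  lines3 <- c(
    pdb_atom_line(1, "CA", "SER", "A", 1, 0, 0, 0, occ = 0.4, alt = "A"),
    pdb_atom_line(2, "CA", "SER", "A", 1, 9, 9, 9, occ = 0.6, alt = "B"),
    pdb_atom_line(3, "CA", "SER", "A", 2, 1, 1, 1, occ = 0.5, alt = "A"),
    pdb_atom_line(4, "CA", "SER", "A", 2, 8, 8, 8, occ = 0.5, alt = "B"))
  m3 <- read_structure(write_fixture_pdb(lines3))
  expect_equal(nrow(m3$atoms), 2)
  expect_equal(m3$atoms$x, c(9, 1))  # occupancy winner, then altloc-A tie

  # HETATM and waters dropped; no ATOM records is an error
  het <- "HETATM    1  O   HOH A 101      0.000   0.000   0.000  1.00  0.00           O"
  expect_error(read_structure(write_fixture_pdb(het)), "no ATOM records")
})

test_that("sequence positions map to residues or explicit gaps", {
  lines <- sapply(c(1:5, 10:12), function(i)
    pdb_atom_line(i, "CA", "ALA", "A", i, i * 4, 0, 0))
  m <- read_structure(write_fixture_pdb(lines))
  hit <- map_position(m, "A", 3)
  expect_true(hit$resolved)
  expect_equal(hit$resno, 3)
  gap <- map_position(m, "A", 7)
  expect_false(gap$resolved)
  expect_equal(gap$resno, 7)
  expect_error(map_position(m, "A", 40), "outside")
  expect_error(map_position(m, "B", 3), "unknown chain")
  # negative offset shifts the lookup
  shifted <- map_position(m, "A", 8, offset = -5)
  expect_true(shifted$resolved)
  expect_equal(shifted$resno, 3)
})

test_that("residue distances follow the chosen atom convention", {
  atoms <- data.frame(
    chain = "A", resno = c(1, 1, 2, 2), insert = "",
    resid = c("ALA", "ALA", "GLY", "GLY"),
    elety = c("CA", "CB", "CA", "CB"), element = "C",
    x = c(0, 1, 3, 2), y = c(0, 0, 4, 0), z = 0, o = 1,
    stringsAsFactors = FALSE)
  m <- structure_model(atoms)
  expect_equal(residue_distance(m, "A:1", "A:2", mode = "ca"), 5)
  expect_equal(residue_distance(m, "A:1", "A:2", mode = "min_heavy"), 1)
  expect_equal(residue_distance(m, "A:1", "A:1", mode = "min_heavy"), 0)
  expect_equal(residue_distance(m, "A:1", "A:2"),
               residue_distance(m, "A:2", "A:1"))
  expect_error(residue_distance(m, "A:1", "A:9"), "not resolved")
})

test_that("distance is a metric on random resolved residues", {
  set.seed(13)
  xyz <- matrix(runif(30, 0, 50), ncol = 3)
  atoms <- data.frame(chain = "A", resno = 1:10, insert = "", resid = "ALA",
                      elety = "CA", element = "C", x = xyz[, 1],
                      y = xyz[, 2], z = xyz[, 3], o = 1,
                      stringsAsFactors = FALSE)
  m <- structure_model(atoms)
  for (rep in 1:20) {
    ijk <- sample(10, 3)
    dij <- residue_distance(m, list(chain = "A", resno = ijk[1]),
                            list(chain = "A", resno = ijk[2]))
    djk <- residue_distance(m, list(chain = "A", resno = ijk[2]),
                            list(chain = "A", resno = ijk[3]))
    dik <- residue_distance(m, list(chain = "A", resno = ijk[1]),
                            list(chain = "A", resno = ijk[3]))
    expect_lte(dik, dij + djk + 1e-9)
  }
})

test_that("single-linkage clusters equal the brute-force components", {
  set.seed(17)
  for (rep in 1:30) {
    n <- sample(1:12, 1)
    xyz <- matrix(runif(3 * n, 0, 40), ncol = 3)
    atoms <- data.frame(chain = "A", resno = seq_len(n), insert = "",
                        resid = "ALA", elety = "CA", element = "C",
                        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], o = 1,
                        stringsAsFactors = FALSE)
    m <- structure_model(atoms)
    cutoff <- runif(1, 5, 30)
    got <- cluster_residues(m, sprintf("A:%d", seq_len(n)), cutoff)
    want <- oracle_threshold_components(xyz, cutoff)
    expect_true(same_partition(got$cluster, want))
  }
  # degenerate inputs
  expect_equal(nrow(cluster_residues(structure_model(
    data.frame(chain = "A", resno = 1, insert = "", resid = "ALA",
               elety = "CA", element = "C", x = 0, y = 0, z = 0, o = 1)),
    list(), 10)), 0)
})

test_that("domain annotation returns the innermost interval", {
  dmap <- domain_map(data.frame(
    name = c("spiral", "FAT", "TRD3", "kinase"),
    start = c(1, 1900, 2195, 2657),
    end = c(1166, 2656, 2475, 3056)))
  expect_equal(annotate_domain(dmap, 2300), "TRD3")   # nested inside FAT
  expect_equal(annotate_domain(dmap, 1), "spiral")
  expect_equal(annotate_domain(dmap, 2000), "FAT")
  expect_equal(annotate_domain(dmap, 3200), "unannotated")
  expect_equal(annotate_domain(dmap, c(2300, 1)), c("TRD3", "spiral"))
  expect_error(domain_map(data.frame(name = "x", start = 5, end = 2)),
               "start")
})

test_that("shipped domain annotation files load and cover the kinase domain", {
  atm <- read_domain_map(system.file("extdata", "domains_atm.tsv",
                                     package = "pikkmap"))
  expect_equal(annotate_domain(atm, 2300), "TRD3")
  expect_equal(annotate_domain(atm, 2900), "kinase")
})
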