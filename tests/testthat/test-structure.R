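# compact synthetic residue builders (heavy atoms only)
res_atoms <- function(chain, resno, resid, names, elements, xyz) {
  data.frame(chain = chain, resno = resno, resid = resid, elety = names,
             element = elements, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}

test_that("PDB and mmCIF files with the same content read to identical models", {
  atoms <- helix_atoms(5, chain = "A")
  atoms <- rbind(atoms, helix_atoms(3, chain = "B", origin = c(10, 0, 0)))
  pdb <- tempfile(fileext = ".pdb"); cif <- tempfile(fileext = ".cif")
  write_pdb_text(atoms, pdb)
  write_cif_text(atoms, cif)
  m1 <- read_structure(pdb)
  m2 <- read_structure(cif)
  expect_equal(model_chains(m1), c("A", "B"))
  expect_equal(nrow(m1$atoms), 8L)
  cols <- c("chain", "resno", "resid", "elety", "x", "y", "z")
  expect_equal(m1$atoms[, cols], m2$atoms[, cols], tolerance = 1e-6)

  # two-residue synthetic file: 1 chain, 2 residues
  m3 <- read_structure(write_pdb_text(helix_atoms(2), tempfile(fileext = ".pdb")))
  expect_equal(length(model_chains(m3)), 1L)
  expect_equal(length(unique(m3$atoms$resno)), 2L)
})

test_that("altloc atoms resolve to the highest occupancy and hydrogens are dropped", {
  atoms <- data.frame(
    chain = "A", resno = c(1, 1, 1, 1), resid = "SER",
    elety = c("CA", "CA", "OG", "HB2"),
    element = c("C", "C", "O", "H"),
    alt = c("A", "B", "", ""),
    x = c(1.0, 9.0, 2.0, 3.0), y = 0, z = 0,
    occ = c(0.6, 0.4, 1, 1))
  path <- write_pdb_text(atoms, tempfile(fileext = ".pdb"))
  m <- read_structure(path)
  ca <- m$atoms[m$atoms$elety == "CA", ]
  expect_equal(nrow(ca), 1L)
  expect_equal(ca$x, 1.0)          # occupancy 0.6 conformer kept
  expect_false(any(m$atoms$element == "H"))
})

test_that("inter-chain contacts classify vdw, hbond and salt bridges and are symmetric", {
  # two 'glycines' reduced to lone CA atoms, 3.5 A apart: vdw
  ga <- res_atoms("A", 1, "GLY", "CA", "C", matrix(c(0, 0, 0), 1))
  gb <- res_atoms("B", 1, "GLY", "CA", "C", matrix(c(3.5, 0, 0), 1))
  m <- structure_model(rbind(ga, gb))
  ct <- inter_chain_contacts(m, "A", "B")
  expect_equal(nrow(ct), 1L)
  expect_equal(ct$category, "vdw")
  expect_equal(ct$min_dist, 3.5)

  # same pair at 10 A: no contact
  gb10 <- res_atoms("B", 1, "GLY", "CA", "C", matrix(c(10, 0, 0), 1))
  expect_equal(nrow(inter_chain_contacts(structure_model(rbind(ga, gb10)),
                                         "A", "B")), 0L)

  # Glu side-chain O vs Arg side-chain N at 3.0 A: salt bridge
  glu <- res_atoms("A", 10, "GLU", c("CA", "CD", "OE1"), c("C", "C", "O"),
                   rbind(c(0, 0, 0), c(1.5, 0, 0), c(2.5, 0, 0)))
  arg <- res_atoms("B", 20, "ARG", c("CA", "CZ", "NH1"), c("C", "C", "N"),
                   rbind(c(8, 0, 0), c(6.5, 0, 0), c(5.5, 0, 0)))
  msalt <- structure_model(rbind(glu, arg))
  cts <- inter_chain_contacts(msalt, "A", "B")
  expect_equal(cts$category, "salt_bridge")

  # backbone-style O...N at 3.2 A without an acid/base side-chain pair: hbond
  s1 <- res_atoms("A", 1, "SER", c("CA", "OG"), c("C", "O"),
                  rbind(c(0, 0, 0), c(1.5, 0, 0)))
  s2 <- res_atoms("B", 1, "SER", c("CA", "OG"), c("C", "O"),
                  rbind(c(6.2, 0, 0), c(4.7, 0, 0)))
  expect_equal(inter_chain_contacts(structure_model(rbind(s1, s2)),
                                    "A", "B")$category, "hbond")

  # symmetry: swapping the chain arguments yields the same pairs
  fwd <- inter_chain_contacts(msalt, "A", "B")
  rev <- inter_chain_contacts(msalt, "B", "A")
  expect_equal(fwd$resno_a, rev$resno_b)
  expect_equal(fwd$resno_b, rev$resno_a)
  expect_equal(fwd$category, rev$category)
  expect_equal(fwd$min_dist, rev$min_dist)

  expect_error(inter_chain_contacts(m, "A", "C"), "available chains")
})

test_that("burial proxy equals the O(n^2) brute-force oracle and flags packed hydrophobics", {
  # 6 leucines whose side-chain atoms pack within a 5 A ball
  set.seed(3)
  cluster <- do.call(rbind, lapply(1:6, function(i) {
    centre <- 2.5 * c(cos(i), sin(i), cos(2 * i))
    res_atoms("A", i, "LEU",
              c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2"),
              c("N", "C", "C", "O", "C", "C", "C", "C"),
              sweep(matrix(stats::rnorm(24, sd = 0.8), 8), 2, centre, "+"))
  }))
  # plus one serine far away on the surface
  ser <- res_atoms("A", 7, "SER", c("N", "CA", "C", "O", "OG"),
                   c("N", "C", "C", "O", "O"),
                   sweep(matrix(stats::rnorm(15, sd = 0.5), 5), 2,
                         c(30, 0, 0), "+"))
  m <- structure_model(rbind(cluster, ser))
  core <- hydrophobic_core_residues(m, "A")
  expect_true(all(core$in_core[core$resno <= 6]))
  expect_false(core$in_core[core$resno == 7])
  expect_false(core$is_hydrophobic[core$resno == 7])

  # random coordinates: burial equals the brute-force all-pairs oracle
  rand <- do.call(rbind, lapply(1:40, function(i) {
    res_atoms(sample(c("A", "B"), 1), i, sample(c("LEU", "SER", "VAL"), 1),
              c("N", "CA", "C", "O", "CB"), c("N", "C", "C", "O", "C"),
              matrix(stats::runif(15, 0, 18), 5))
  }))
  mr <- structure_model(rand)
  got <- hydrophobic_core_residues(mr, "A")
  want <- oracle_burial(mr$atoms, "A")
  expect_equal(got$burial, unname(want))

  expect_error(hydrophobic_core_residues(structure_model(helix_atoms(2)), "A"),
               "fewer than 3")
})

test_that("site annotation labels interface/core/other/unresolved and summarises fractions", {
  region <- region_spec("toy", 1, 10, "LVIAMWYFST")
  recs <- data.frame(position = 1:10, wt_aa = region_residues(region),
                     mut_aa = "R")
  recs$mut_aa[8] <- "K"  # F8K, avoid no constraint issues
  contacts <- data.frame(chain_a = "A", resno_a = c(1L, 2L), resid_a = "LEU",
                         chain_b = "B", resno_b = c(5L, 6L), resid_b = "ALA",
                         min_dist = 3.5, category = "vdw")
  ann <- annotate_sites(recs, region, contacts = contacts,
                        core_positions = c(3L, 4L, 5L, 6L), chain = "A",
                        resolved_positions = 1:9)
  expect_equal(ann$category[1], "interface")
  expect_equal(ann$category[3], "hydrophobic_core")
  expect_equal(ann$category[7], "other")
  expect_equal(ann$category[10], "unresolved")
  expect_true(all(ann$n_contacts[ann$interface] >= 1))

  s <- site_summary(ann)
  expect_equal(s$n_total, 9L)           # unresolved excluded
  expect_equal(s$n_unresolved, 1L)
  expect_equal(s$fraction_core, 4 / 9)

  # toy count check: 10 records, 4 in core
  ann2 <- annotate_sites(recs, region, core_positions = c(2L, 4L, 6L, 8L))
  expect_equal(site_summary(ann2)$fraction_core, 0.4)
})
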