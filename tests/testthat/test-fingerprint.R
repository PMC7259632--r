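split_ab <- interface_split("A", "B")

two_residue_fixture <- function(rows_a, rows_b) {
  structure_from_rows(do.call(rbind, rows_a), do.call(rbind, rows_b))
}

test_that("hydrogen bonds obey the distance cutoff", {
  near <- two_residue_fixture(
    list(atom_row("N", 0, 0, 0, "GLY", "A", 1),
         atom_row("CA", -1.4, 0, 0, "GLY", "A", 1)),
    list(atom_row("O", 3.0, 0, 0, "GLY", "B", 1),
         atom_row("C", 4.2, 0, 0, "GLY", "B", 1)))
  rec <- detect_hbonds(near, split_ab)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$distance, 3.0)
  expect_equal(rec$group_a, "donor")
  expect_equal(rec$side_a, "main")

  far <- two_residue_fixture(
    list(atom_row("N", 0, 0, 0, "GLY", "A", 1)),
    list(atom_row("O", 3.6, 0, 0, "GLY", "B", 1)))
  expect_equal(nrow(detect_hbonds(far, split_ab)), 0)
})

test_that("explicit hydrogens impose the 120-degree angle test", {
  base <- list(atom_row("N", 0, 0, 0, "GLY", "A", 1))
  acceptor <- list(atom_row("O", 3.0, 0, 0, "GLY", "B", 1))
  # H pointing at the acceptor: angle 180, kept
  good <- two_residue_fixture(c(base, list(
    atom_row("H", 1.0, 0, 0, "GLY", "A", 1, element = "H"))), acceptor)
  expect_equal(nrow(detect_hbonds(good, split_ab)), 1)
  # H pointing away: angle 0, rejected
  bad <- two_residue_fixture(c(base, list(
    atom_row("H", -1.0, 0, 0, "GLY", "A", 1, element = "H"))), acceptor)
  expect_equal(nrow(detect_hbonds(bad, split_ab)), 0)
})

test_that("hydrophobic contacts need both residues in the apolar set", {
  leu_val <- two_residue_fixture(
    list(atom_row("CD1", 0, 0, 0, "LEU", "A", 1)),
    list(atom_row("CG1", 4.2, 0, 0, "VAL", "B", 1)))
  rec <- detect_hydrophobic(leu_val, split_ab)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$distance, 4.2)
  leu_ser <- two_residue_fixture(
    list(atom_row("CD1", 0, 0, 0, "LEU", "A", 1)),
    list(atom_row("CB", 4.2, 0, 0, "SER", "B", 1)))
  expect_equal(nrow(detect_hydrophobic(leu_ser, split_ab)), 0)
})

test_that("ionic interactions pair charged groups within 6 A", {
  mk <- function(d) two_residue_fixture(
    list(atom_row("NZ", 0, 0, 0, "LYS", "A", 1)),
    list(atom_row("OE1", d, 0, 0, "GLU", "B", 1)))
  expect_equal(nrow(detect_ionic(mk(4.0), split_ab)), 1)
  expect_equal(nrow(detect_ionic(mk(6.5), split_ab)), 0)
})

test_that("the chain C-terminal carboxylate counts as anionic", {
  st <- two_residue_fixture(
    list(atom_row("NZ", 0, 0, 0, "LYS", "A", 1)),
    list(atom_row("N", 3.5, 4, 0, "ALA", "B", 42),
         atom_row("O", 3.5, 0, 0, "ALA", "B", 42),
         atom_row("OXT", 4.5, 0.5, 0, "ALA", "B", 42)))
  rec <- detect_ionic(st, split_ab)
  expect_equal(nrow(rec), 1)  # side-chain NZ vs the B-chain C-terminus
  ct <- rec[rec$group_a == "cation:sidechain", ]
  expect_equal(ct$group_b, "anion:c-terminus")
  expect_equal(ct$distance, 3.5)
})

test_that("aromatic-aromatic interactions respect the centroid band", {
  mk <- function(d) {
    ring <- function(chain, res, resname, x0) {
      ang <- (0:5) * pi / 3
      do.call(rbind, lapply(1:6, function(k)
        atom_row(c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")[k],
                 x0 + 1.39 * cos(ang[k]), 1.39 * sin(ang[k]), 0,
                 resname, chain, res)))
    }
    structure_from_rows(ring("A", 1, "PHE", 0), ring("B", 1, "PHE", d))
  }
  expect_equal(nrow(detect_aromatic_aromatic(mk(5.5), split_ab)), 1)
  expect_equal(nrow(detect_aromatic_aromatic(mk(4.0), split_ab)), 0)
  expect_equal(nrow(detect_aromatic_aromatic(mk(7.5), split_ab)), 0)
})

test_that("incomplete rings are skipped with a warning", {
  st <- two_residue_fixture(
    list(atom_row("CG", 0, 0, 0, "PHE", "A", 1),
         atom_row("CD1", 1.4, 0, 0, "PHE", "A", 1)),
    list(atom_row("NZ", 5, 0, 0, "LYS", "B", 1)))
  expect_warning(rec <- detect_cation_pi(st, split_ab), "incomplete")
  expect_equal(nrow(rec), 0)
})

test_that("aromatic-sulphur and cation-pi detectors hit their cutoffs", {
  ci1 <- make_contact_interface(list(list(kind = "aromatic_sulphur",
                                          distance = 4.0)))
  expect_equal(nrow(detect_aromatic_sulphur(ci1, split_ab)), 1)
  ci2 <- make_contact_interface(list(list(kind = "aromatic_sulphur",
                                          distance = 4.3)))
  rec2 <- detect_aromatic_sulphur(ci2, split_ab)
  expect_equal(rec2$distance, 4.3, tolerance = 1e-9)
  ci3 <- make_contact_interface(list(list(kind = "cation_pi", distance = 5.0)))
  rec3 <- detect_cation_pi(ci3, split_ab)
  expect_equal(nrow(rec3), 1)
  expect_equal(rec3$distance, 5.0, tolerance = 1e-9)
})

test_that("salt bridges are the residue-pair intersection of hbond and ionic", {
  close_pair <- make_contact_interface(list(list(kind = "salt_bridge",
                                                 distance = 2.9)))
  hb <- detect_hbonds(close_pair, split_ab)
  io <- detect_ionic(close_pair, split_ab)
  sb <- label_salt_bridges(hb, io)
  expect_equal(nrow(sb), 1)
  expect_equal(sb$kind, "salt_bridge")
  expect_equal(sb$distance, io$distance)

  ionic_only <- make_contact_interface(list(list(kind = "ionic",
                                                 distance = 5.5)))
  expect_equal(nrow(label_salt_bridges(
    detect_hbonds(ionic_only, split_ab),
    detect_ionic(ionic_only, split_ab))), 0)
})

test_that("fingerprint of a far-separated interface is empty", {
  st <- two_residue_fixture(
    list(atom_row("NZ", 0, 0, 0, "LYS", "A", 1)),
    list(atom_row("OE1", 25, 0, 0, "GLU", "B", 1)))
  expect_equal(nrow(fingerprint(st, split_ab)), 0)
})

test_that("a mimotope-like complex yields the constructed record set", {
  # one lysine-glutamate salt bridge plus two backbone hydrogen bonds
  st <- make_contact_interface(list(
    list(kind = "salt_bridge", distance = 2.9),
    list(kind = "hbond", distance = 3.0),
    list(kind = "hbond", distance = 3.2)))
  fp <- fingerprint(st, split_ab)
  expect_equal(sum(fp$kind == "salt_bridge"), 1)
  expect_equal(sum(fp$kind == "hbond"), 3)
  expect_equal(sum(fp$kind == "ionic"), 1)
})

test_that("detectors are symmetric under swapping the two selections", {
  st <- make_random_interface(12, 12, seed = 31, box = 10, depth = 6)
  fwd <- fingerprint(st, interface_split("A", "B"))
  rev <- fingerprint(st, interface_split("B", "A"))
  fwd_keys <- sort(paste(fwd$kind, fwd$chain_a, fwd$res_a, fwd$chain_b,
                         fwd$res_b))
  rev_keys <- sort(paste(rev$kind, rev$chain_b, rev$res_b, rev$chain_a,
                         rev$res_a))
  expect_identical(fwd_keys, rev_keys)
})

test_that("record sets survive rigid-body transformation", {
  st <- make_random_interface(10, 10, seed = 17, box = 10, depth = 6)
  fp1 <- fingerprint(st, split_ab)
  set.seed(99)
  st2 <- transform_structure(st, random_rotation(), rnorm(3, sd = 15))
  fp2 <- fingerprint(st2, split_ab)
  expect_identical(pair_keys(fp1), pair_keys(fp2))
  expect_equal(fp1$distance, fp2$distance, tolerance = 1e-9)
})

test_that("raising a cutoff never removes records of that kind", {
  st <- make_random_interface(15, 15, seed = 23, box = 10, depth = 6)
  base <- detect_hbonds(st, split_ab, interaction_cutoffs(hbond = 3.0))
  wide <- detect_hbonds(st, split_ab, interaction_cutoffs(hbond = 3.5))
  expect_true(all(pair_keys(base) %in% pair_keys(wide)))
  base_i <- detect_ionic(st, split_ab, interaction_cutoffs(ionic = 4.5))
  wide_i <- detect_ionic(st, split_ab, interaction_cutoffs(ionic = 6.0))
  expect_true(all(pair_keys(base_i) %in% pair_keys(wide_i)))
})

test_that("salt-bridge pairs are a subset of both ionic and hbond pairs", {
  for (seed in c(41, 42, 43)) {
    st <- make_random_interface(20, 20, seed = seed, box = 12, depth = 6)
    fp <- fingerprint(st, split_ab)
    sb <- fp[fp$kind == "salt_bridge", ]
    if (nrow(sb) == 0) next
    pk <- function(r) paste(r$chain_a, r$res_a, r$chain_b, r$res_b)
    expect_true(all(pk(sb) %in% pk(fp[fp$kind == "ionic", ])))
    expect_true(all(pk(sb) %in% pk(fp[fp$kind == "hbond", ])))
  }
})

test_that("every detector matches its brute-force oracle", {
  for (seed in c(101, 102)) {
    st <- make_random_interface(20, 20, seed = seed, box = 12, depth = 6)
    expect_identical(record_pair_set(detect_hbonds(st, split_ab)),
                     oracle_hbond_pairs(st, "A", "B"))
    expect_identical(record_pair_set(detect_hydrophobic(st, split_ab)),
                     oracle_hydrophobic_pairs(st, "A", "B"))
    expect_identical(record_pair_set(detect_ionic(st, split_ab)),
                     oracle_ionic_pairs(st, "A", "B"))
    expect_identical(record_pair_set(detect_aromatic_aromatic(st, split_ab)),
                     oracle_aromatic_pairs(st, "A", "B"))
    expect_identical(record_pair_set(detect_aromatic_sulphur(st, split_ab)),
                     oracle_aromatic_sulphur_pairs(st, "A", "B"))
    expect_identical(record_pair_set(detect_cation_pi(st, split_ab)),
                     oracle_cation_pi_pairs(st, "A", "B"))
  }
})
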