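make_pdb_text <- function(rows) paste(c(rows, "END", ""), collapse = "\n")

atom_line <- function(serial, name, res, chain, resno, x, y, z,
                      occ = 1, alt = " ", record = "ATOM  ") {
  sprintf("%s%5d  %-3s%s%3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          record, serial, name, alt, res, chain, resno, x, y, z, occ, 0)
}

ala_residue <- function(serial0, chain, resno, x0) {
  c(atom_line(serial0, "N", "ALA", chain, resno, x0, 0, 0),
    atom_line(serial0 + 1, "CA", "ALA", chain, resno, x0 + 1.4, 0, 0),
    atom_line(serial0 + 2, "C", "ALA", chain, resno, x0 + 2.0, 1.2, 0))
}

test_that("parse_structure reads single-model files and filters non-protein records", {
  rows <- unlist(lapply(1:5, function(i)
    ala_residue(3 * i - 2, "A", i, 4 * i)))
  rows <- c(rows,
            atom_line(90, "O", "HOH", "A", 99, 0, 0, 0, record = "HETATM"),
            atom_line(91, "ZN", "ZN", "A", 100, 5, 5, 5, record = "HETATM"))
  s <- parse_structure(make_pdb_text(rows))
  expect_s3_class(s, "DomainStructure")
  expect_equal(unname(structure_chains(s)), 5)
  expect_equal(chain_sequence(s), "AAAAA")
  expect_false(any(s$atoms$residue_name == "HOH"))
})

test_that("multi-model files keep only the requested model (default: first)", {
  m1 <- ala_residue(1, "A", 1, 0)
  m2 <- ala_residue(1, "A", 1, 50)
  rows <- c("MODEL        1", m1, ala_residue(4, "A", 2, 4),
            ala_residue(7, "A", 3, 8), "ENDMDL",
            "MODEL        2", m2, ala_residue(4, "A", 2, 54),
            ala_residue(7, "A", 3, 58), "ENDMDL")
  s <- parse_structure(make_pdb_text(rows))
  expect_equal(max(s$atoms$x), 10)       # model 1 coordinates only
  s2 <- parse_structure(make_pdb_text(rows), model_index = 2)
  expect_equal(min(s2$atoms$x), 50)
  expect_error(parse_structure(make_pdb_text(rows), model_index = 3),
               "only 2 model")
})

test_that("a bound peptide chain parses with its own sequence", {
  fx <- small_fixture()
  d <- fx$domains[[1]]
  s <- parse_structure(write_pdb(d$structure))
  expect_equal(length(structure_chains(s)), 2)
  expect_equal(chain_sequence(s, "B"), "GRETQV")
})

test_that("altlocs resolve by occupancy then alphabetical code", {
  rows <- c(ala_residue(1, "A", 1, 0), ala_residue(4, "A", 2, 4),
            atom_line(7, "N", "ALA", "A", 3, 8, 0, 0),
            atom_line(8, "CA", "ALA", "A", 3, 9.4, 0, 0, occ = 0.4,
                      alt = "A"),
            atom_line(9, "CA", "ALA", "A", 3, 19.4, 0, 0, occ = 0.6,
                      alt = "B"),
            atom_line(10, "C", "ALA", "A", 3, 10, 1.2, 0))
  s <- parse_structure(make_pdb_text(rows))
  ca3 <- s$atoms[s$atoms$residue_index == 2 & s$atoms$name == "CA", ]
  expect_equal(nrow(ca3), 1)
  expect_equal(ca3$x, 19.4)              # higher occupancy wins
  # equal occupancy: alphabetical altloc
  rows[8] <- atom_line(8, "CA", "ALA", "A", 3, 9.4, 0, 0, occ = 0.5,
                       alt = "A")
  rows[9] <- atom_line(9, "CA", "ALA", "A", 3, 19.4, 0, 0, occ = 0.5,
                       alt = "B")
  s <- parse_structure(make_pdb_text(rows))
  expect_equal(s$atoms[s$atoms$residue_index == 2 &
                         s$atoms$name == "CA", "x"], 9.4)
})

test_that("malformed and empty inputs fail with informative errors", {
  rows <- c(ala_residue(1, "A", 1, 0), "ATOM     99  CA ALA A   2    garbage")
  expect_error(parse_structure(make_pdb_text(rows)),
               "malformed ATOM record at line 4")
  expect_error(
    parse_structure(make_pdb_text(
      atom_line(1, "O", "HOH", "A", 1, 0, 0, 0, record = "HETATM"))),
    "no ATOM records|no standard")
})

test_that("phi angles follow the dihedral convention and flag undefined residues", {
  # planar-trans four points -> 180 exactly
  expect_equal(dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                              c(1, -1, 0)), 180)
  # chirality: mirroring negates any non-planar dihedral
  p <- list(c(0, 1, 0.3), c(0, 0, 0), c(1, 0, 0), c(1.3, -1, 0.8))
  mirrored <- lapply(p, function(v) c(v[1], v[2], -v[3]))
  expect_equal(do.call(dihedral_angle, mirrored),
               -do.call(dihedral_angle, p))
  # idealized helix: all defined phi near -57
  hx <- make_toy_domain(fixture_spec(seed = 2, jitter = 0), 1,
                        with_peptide = FALSE)
  phi <- compute_phi(hx$structure, "A")
  expect_true(is.na(phi[1]))
  expect_true(all(phi[-1] > -80 & phi[-1] < -40))
})

test_that("dihedral agrees with an independent implementation on random quadruples", {
  skip_if_not_installed("bio3d")
  withr::with_seed(11, {
    for (i in 1:1000) {
      q <- matrix(stats::rnorm(12, sd = 3), nrow = 4)
      mine <- dihedral_angle(q[1, ], q[2, ], q[3, ], q[4, ])
      ref <- bio3d::torsion.xyz(as.numeric(t(q)))
      ref <- ref[!is.na(ref)][1]
      delta <- (mine - ref) %% 360
      delta <- min(delta, 360 - delta)
      expect_lt(delta, 1e-9)
    }
  })
})

test_that("hydrogen bonds obey the distance/angle criteria and classify by kind", {
  hb <- detect_hbonds(gly_ser_hbond_structure())
  expect_equal(nrow(hb), 1)
  expect_equal(hb$kind, "sc_mc_carbonyl")
  expect_equal(hb$donor_atom, "OG")
  expect_equal(hb$acceptor_atom, "O")
  # same pair pushed to 5 A: no bond
  far <- gly_ser_hbond_structure(og_xyz = c(5.0, 1.9, 4.0))
  expect_equal(nrow(detect_hbonds(far)), 0)
})

test_that("side-chain / side-chain bonds are detected (Asp-Arg pair)", {
  at <- data.frame(
    name = c("N", "CA", "CB", "OD1", "N", "CA", "N", "CA", "CB", "NH1"),
    element = c("N", "C", "C", "O", "N", "C", "N", "C", "C", "N"),
    residue_index = c(0L, 0L, 0L, 0L, 1L, 1L, 2L, 2L, 2L, 2L),
    residue_name = c(rep("ASP", 4), rep("GLY", 2), rep("ARG", 4)),
    chain = "A",
    x = c(0, 1.4, 2.2, 3.0, 5, 6.4, 9, 8.2, 7.2, 5.8),
    y = c(0, 0, 1.2, 0.4, 3, 3, 0, 0.6, 0.3, 0.4),
    z = 0, stringsAsFactors = FALSE)
  s <- pdzpred:::new_domain_structure(at)
  hb <- detect_hbonds(s)
  expect_true("sc_sc" %in% hb$kind)
  sc <- hb[hb$kind == "sc_sc", ]
  expect_setequal(c(sc$donor_atom, sc$acceptor_atom), c("NH1", "OD1"))
})

test_that("hydrogen-bond detection is invariant under rigid motion", {
  s <- gly_ser_hbond_structure()
  hb1 <- detect_hbonds(s)
  hb2 <- detect_hbonds(transform_structure(s, random_rotation(5),
                                           c(12, -7, 3)))
  expect_equal(hb1[, setdiff(names(hb1), "distance")],
               hb2[, setdiff(names(hb2), "distance")])
  expect_equal(hb1$distance, hb2$distance, tolerance = 1e-9)
})

test_that("SASA matches the closed form for an isolated atom and decreases on overlap", {
  a1 <- data.frame(name = "CA", element = "C", residue_index = 0L,
                   residue_name = "ALA", chain = "A", x = 0, y = 0, z = 0)
  sr <- shrake_rupley(a1, probe_radius = 1.4, n_points = 960)
  expect_equal(sr$atom_area, 4 * pi * 3.1^2, tolerance = 0.005)

  two <- function(d) rbind(a1, within(a1, x <- d))
  far <- sum(shrake_rupley(two(20), 1.4, 960)$atom_area)
  near <- sum(shrake_rupley(two(3), 1.4, 960)$atom_area)
  closer <- sum(shrake_rupley(two(1.5), 1.4, 960)$atom_area)
  expect_equal(far, 2 * 4 * pi * 3.1^2, tolerance = 1e-9)
  expect_lt(near, far)
  expect_lt(closer, near)
})

test_that("per-residue SASA agrees with a 10x point-density oracle within 5%", {
  ch <- pdzpred:::build_chain("ASTNQ", "A", -57, -47)
  s <- pdzpred:::new_domain_structure(ch)
  lo <- compute_sasa(s, n_points = 960)
  hi <- compute_sasa(s, n_points = 9600)
  expect_true(all(abs(lo$area - hi$area) / hi$area < 0.05))
  expect_equal(attr(lo, "total"), sum(lo$area))
  expect_true(all(lo$rel_acc >= 0))
})

test_that("unknown elements are rejected by name", {
  a <- data.frame(name = "XX", element = "XX", residue_index = 0L,
                  residue_name = "ALA", chain = "A", x = 0, y = 0, z = 0)
  expect_error(shrake_rupley(a), "unknown element.*XX")
})

test_that("core positions come from strict sub-cutoff heavy-atom contacts", {
  # one domain residue at 4.0 A from the peptide, another at exactly 4.5,
  # rest far away
  dom <- data.frame(
    name = "CA", element = "C", residue_index = 0:2,
    residue_name = "ALA", chain = "A",
    x = c(0, 10, 20), y = 0, z = 0, stringsAsFactors = FALSE)
  pep <- data.frame(
    name = "CA", element = "C", residue_index = 0:2, residue_name = "GLY",
    chain = "B", x = c(4.0, 14.5, 40), y = 0, z = 0,
    stringsAsFactors = FALSE)
  s <- pdzpred:::new_domain_structure(rbind(dom, pep))
  cx <- list(structure = s, domain_chain = "A", peptide_chain = "B")
  site <- derive_core_positions(list(cx))
  expect_equal(site$positions, 0L)        # 4.5 A excluded: strict less-than
  expect_equal(site$provenance, "derived")
  # widen the cutoff just past 4.5 and the boundary residue enters
  expect_equal(derive_core_positions(list(cx),
                                     contact_cutoff = 4.5001)$positions,
               c(0L, 1L))
  expect_error(derive_core_positions(list(cx), contact_cutoff = 1),
               "no contacting columns")
})

test_that("multi-complex consensus respects min_structures and input order", {
  base <- function(shift_contact) {
    dom <- data.frame(name = "CA", element = "C", residue_index = 0:2,
                      residue_name = "ALA", chain = "A",
                      x = c(0, 10, 20), y = 0, z = 0)
    pep <- data.frame(name = "CA", element = "C", residue_index = 0L,
                      residue_name = "GLY", chain = "B",
                      x = shift_contact, y = 0, z = 0)
    list(structure = pdzpred:::new_domain_structure(rbind(dom, pep)),
         domain_chain = "A", peptide_chain = "B")
  }
  # residue 0 contacts in all three complexes; residue 1 in only one
  cxs <- list(base(3), base(3), {
    cx <- base(3)
    cx$structure$atoms[4, "x"] <- 13    # peptide near residue 1 instead
    cx
  })
  site <- derive_core_positions(cxs, min_structures = 2)
  expect_equal(site$positions, 0L)
  for (perm in list(c(2, 1, 3), c(3, 2, 1))) {
    expect_equal(derive_core_positions(cxs[perm], min_structures = 2),
                 site)
  }
})

test_that("binding-site definitions round-trip through TSV", {
  site <- binding_site(c(4L, 9L, 17L), "derived")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_binding_site(site, path)
  expect_equal(read_binding_site(path), site)
})
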