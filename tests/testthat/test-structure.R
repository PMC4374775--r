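test_that("PDB reading handles minimal records, altlocs and malformed input", {
  one <- "ATOM      1  CA  ALA A   1      11.000  22.000  33.000  1.00  0.00           C"
  s <- read_structure(one)
  expect_equal(nrow(s$atoms), 1)
  expect_equal(s$atoms$x, 11)
  expect_equal(s$atoms$resno, 1)

  # altloc: keep the higher occupancy; on a tie keep 'A'
  alt <- c(
    "ATOM      1  CA AALA A   1      10.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1      20.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CB AALA A   1      30.000   0.000   0.000  0.50  0.00           C",
    "ATOM      4  CB BALA A   1      40.000   0.000   0.000  0.50  0.00           C")
  sa <- read_structure(paste(alt, collapse = "\n"))
  expect_equal(nrow(sa$atoms), 2)
  expect_equal(sa$atoms$x[sa$atoms$elety == "CA"], 20) # occupancy 0.6 wins
  expect_equal(sa$atoms$x[sa$atoms$elety == "CB"], 30) # tie -> altloc A

  bad <- "ATOM      1  CA  ALA A   1      xx.000"
  expect_error(read_structure(bad), "line 1")
})

test_that("fixture structures round-trip through PDB write/read", {
  s <- make_fixture_structure(list(
    phe_ring(c(0, 0, 0)), phe_ring(c(0, 0, 4.0)),
    lys_glu_pair(at = c(30, 0, 0), distance = 3.0)))
  s2 <- read_structure(paste(write_structure(s), collapse = "\n"))
  expect_equal(nrow(s2$atoms), nrow(s$atoms))
  expect_lt(max(abs(as.matrix(s2$atoms[, c("x", "y", "z")]) -
                    as.matrix(s$atoms[, c("x", "y", "z")]))), 1e-3)
  expect_equal(s2$atoms$resid, s$atoms$resid)
  # measured geometry survives the round trip
  expect_equal(pi_pi_pairs(s2)$distance, 4.0, tolerance = 1e-3)
  expect_equal(salt_bridges(s2)$distance, 3.0, tolerance = 1e-3)
})

test_that("pi-pi geometry matches the analytic fixture construction", {
  s <- make_fixture_structure(list(
    phe_ring(c(0, 0, 0), normal = c(0, 0, 1)),
    phe_ring(c(0, 0, 4.0), normal = c(0, 0, 1)),       # stacked
    phe_ring(c(40, 0, 0), normal = c(0, 0, 1)),
    phe_ring(c(45, 0, 0), normal = c(1, 0, 0))))       # perpendicular, 5 A
  pp <- pi_pi_pairs(s)
  expect_equal(nrow(pp), 2)
  expect_equal(pp$distance, c(4.0, 5.0), tolerance = 1e-9)
  expect_equal(pp$angle, c(0, 90), tolerance = 1e-6)
  # oblique normals give the acute interplane angle
  s2 <- make_fixture_structure(list(
    phe_ring(c(0, 0, 0), normal = c(0, 0, 1)),
    phe_ring(c(0, 0, 5), normal = c(sin(pi / 3), 0, cos(pi / 3)))))
  expect_equal(pi_pi_pairs(s2)$angle, 60, tolerance = 1e-6)
  # beyond the centroid cutoff: nothing
  s3 <- make_fixture_structure(list(
    phe_ring(c(0, 0, 0)), phe_ring(c(0, 0, 8))))
  expect_equal(nrow(pi_pi_pairs(s3)), 0)
  # incomplete ring is skipped with a warning
  s4 <- s
  s4$atoms <- s4$atoms[-1, ]
  expect_warning(pi_pi_pairs(s4), "incomplete")
})

test_that("salt bridges and hydrogen bonds obey their cutoffs", {
  s_in <- make_fixture_structure(list(lys_glu_pair(distance = 3.0)))
  expect_equal(nrow(salt_bridges(s_in)), 1)
  s_out <- make_fixture_structure(list(lys_glu_pair(distance = 4.5)))
  expect_equal(nrow(salt_bridges(s_out)), 0)

  # planted pairs + decoys: brute-force count is exact
  s5 <- make_fixture_structure(list(
    lys_glu_pair(at = c(0, 0, 0), distance = 2.8),
    lys_glu_pair(at = c(40, 0, 0), distance = 3.5),
    lys_glu_pair(at = c(80, 0, 0), distance = 3.9),
    lys_glu_pair(at = c(120, 0, 0), distance = 4.2),  # decoy: beyond 4.0
    lys_glu_pair(at = c(160, 0, 0), distance = 6.0))) # decoy
  sb <- salt_bridges(s5)
  expect_equal(nrow(sb), 3)
  expect_equal(sort(sb$distance), c(2.8, 3.5, 3.9), tolerance = 1e-9)

  sh <- make_fixture_structure(list(backbone_hbond(distance = 2.9)))
  hb <- hbonds(sh)
  expect_equal(nrow(hb), 1)
  expect_equal(hb$distance, 2.9, tolerance = 1e-9)
  sh2 <- make_fixture_structure(list(backbone_hbond(distance = 3.8)))
  expect_equal(nrow(hbonds(sh2)), 0)
  # k planted donor-acceptor pairs are all found
  k <- 4
  shk <- make_fixture_structure(lapply(seq_len(k) - 1, function(j)
    backbone_hbond(at = c(j * 30, 0, 0), distance = 2.7 + 0.1 * j)))
  expect_equal(nrow(hbonds(shk)), k)
})

test_that("interface contacts classify polar and hydrophobic pairs as Dimplot does", {
  # two residues facing each other across a domain boundary
  lines <- c(
    "ATOM      1  OG1 THR A  10       0.000   0.000   0.000  1.00  0.00           O",
    "ATOM      2  CB  THR A  10       0.000   1.400   0.000  1.00  0.00           C",
    "ATOM      3  OD1 ASP A  50       2.600   0.000   0.000  1.00  0.00           O",
    "ATOM      4  CG  ASP A  50       3.500   1.400   0.000  1.00  0.00           C")
  s <- read_structure(paste(lines, collapse = "\n"))
  dom_a <- domain_definition("A", "1-20")
  dom_b <- domain_definition("B", "40-60")
  ic <- interface_contacts(s, dom_a, dom_b)
  # OG1-OD1 2.60 Polar; CB-CG 3.50 Hydrophobic; OG1-CG & CB-OD1 mixed pairs
  polar <- dplyr::filter(ic, contact_class == "Polar")
  expect_equal(nrow(polar), 1)
  expect_equal(polar$atom1, "OG1"); expect_equal(polar$atom2, "OD1")
  expect_equal(polar$distance, 2.6, tolerance = 1e-9)
  expect_true(all(dplyr::filter(ic, atom1 == "CB", atom2 == "CG")$contact_class ==
                    "Hydrophobic"))
  # N/O pair beyond 3.35 but inside 3.90 is not polar (and not hydrophobic)
  expect_false(any(ic$contact_class == "Polar" & ic$distance > 3.35))

  # symmetric in the domain order, up to partner order
  ic_ba <- interface_contacts(s, dom_b, dom_a)
  expect_equal(nrow(ic_ba), nrow(ic))
  expect_setequal(paste(ic$atom1, ic$atom2), paste(ic_ba$atom2, ic_ba$atom1))

  # exclusions and degenerate cases
  expect_equal(nrow(interface_contacts(s, dom_a, dom_b, exclude = c(10))), 0)
  expect_error(interface_contacts(s, dom_a, domain_definition("B", "15-60")),
               "overlap")
  far <- make_fixture_structure(list(ca_chain(2, start = c(0, 0, 0)),
                                     ca_chain(2, start = c(50, 0, 0))))
  expect_equal(nrow(interface_contacts(far, domain_definition("A", "1-5"),
                                       domain_definition("B", "6-20"))), 0)
})

test_that("all interaction geometry is invariant under rigid motions", {
  s <- make_fixture_structure(list(
    phe_ring(c(0, 0, 0)), phe_ring(c(2, 1, 4), normal = c(1, 1, 1)),
    lys_glu_pair(at = c(30, 0, 0), distance = 3.2),
    backbone_hbond(at = c(60, 0, 0), distance = 3.0)))
  base_pp <- pi_pi_pairs(s)
  base_sb <- salt_bridges(s)
  base_hb <- hbonds(s)
  for (seed in 1:5) {
    rot <- random_rotation(seed)
    sr <- transform_structure(s, rot, shift = c(7.1, -3.3, 12.9) * seed)
    expect_equal(pi_pi_pairs(sr)$distance, base_pp$distance, tolerance = 1e-8)
    expect_equal(pi_pi_pairs(sr)$angle, base_pp$angle, tolerance = 1e-6)
    expect_equal(salt_bridges(sr)$distance, base_sb$distance, tolerance = 1e-8)
    expect_equal(hbonds(sr)$distance, base_hb$distance, tolerance = 1e-8)
  }
})

test_that("published domain definitions are exposed and validated", {
  d <- pk_domains("TpPK")
  expect_equal(pkmech:::domain_resnos(d$B), 66:164)
  expect_equal(range(pkmech:::domain_resnos(d$A)), c(1, 334))
  expect_equal(pkmech:::domain_resnos(pk_domains("PaPK")$B), 81:177)
  expect_equal(pkmech:::domain_resnos(pk_domains("RMPK")$B), 116:223)
  expect_error(domain_definition("X", list(c(5, 2))), "end >= start")
  expect_error(domain_definition("X", "1-10,8-20"), "overlap")
})
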