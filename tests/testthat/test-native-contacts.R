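test_that("contact map matches brute-force enumeration on small fixtures", {
  # 4 collinear CAs at 3.8 A spacing: only (1,4) survives min_seq_sep 3,
  # and only with a cutoff that admits 11.4 A
  ref <- make_fixture_structure(list(ca_chain(4, spacing = 3.8)))
  cm <- native_contact_map(ref, cutoff = 12, min_seq_sep = 3)
  expect_equal(nrow(cm$pairs), 1)
  expect_equal(cm$pairs$i, 1)
  expect_equal(cm$pairs$j, 4)
  expect_equal(cm$pairs$native_distance, 3 * 3.8, tolerance = 1e-9)
  # the default 8 A cutoff excludes it
  expect_equal(nrow(native_contact_map(ref, cutoff = 8)$pairs), 0)
  # degenerate cases
  expect_equal(nrow(native_contact_map(ref, cutoff = 0)$pairs), 0)
  sel <- domain_definition("none", "900-950")
  expect_equal(nrow(native_contact_map(ref, selection = sel)$pairs), 0)

  # brute force over a random CA cloud
  set.seed(9)
  n <- 30
  cloud <- tibble::tibble(
    chain = "A", resno = 1:n, insert = "", resid = "GLY", elety = "CA",
    elesy = "C", x = runif(n, 0, 25), y = runif(n, 0, 25),
    z = runif(n, 0, 25), o = 1, type = "ATOM")
  s <- structure(list(atoms = cloud, source = "cloud"), class = "pk_structure")
  cm2 <- native_contact_map(s, cutoff = 8, min_seq_sep = 3)
  brute <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- sqrt(sum((cloud[i, c("x", "y", "z")] - cloud[j, c("x", "y", "z")])^2))
    if (d <= 8 && j - i >= 3) brute <- brute + 1
  }
  expect_equal(nrow(cm2$pairs), brute)
})

test_that("Q recovers the scheduled contact loss exactly on paired fixtures", {
  ref <- paired_reference(10)
  cm <- native_contact_map(ref)
  expect_equal(nrow(cm$pairs), 10)
  tr <- make_trajectory(ref, schedule = c(0, 0.5, 1), contacts = cm)
  q <- q_trajectory(tr, cm)
  expect_equal(q$q, c(1, 0.5, 0))

  # identity frame and fully-expanded frame
  tr0 <- make_trajectory(ref, schedule = numeric(), contacts = cm)
  expect_equal(q_trajectory(tr0, cm)$q, 1)
  trx <- tr0
  trx$coords <- list(tr0$coords[[1]] * 10)
  expect_equal(q_trajectory(trx, cm)$q, 0)

  # monotone schedule gives monotone non-increasing Q (irreversible breaking)
  sched <- c(0, 0.15, 0.35, 0.35, 0.6, 0.8, 1)
  qm <- q_trajectory(make_trajectory(ref, sched, contacts = cm), cm)
  expect_true(all(diff(qm$q) <= 1e-12))
  expect_lt(max(abs(qm$q - (1 - sched))), 0.1 + 1e-9) # one-contact resolution

  # same seed, same trajectory
  t1 <- make_trajectory(ref, c(0.3, 0.7), seed = 5, contacts = cm)
  t2 <- make_trajectory(ref, c(0.3, 0.7), seed = 5, contacts = cm)
  expect_identical(t1$coords, t2$coords)
})

test_that("Q is invariant under rigid-body motion of a frame", {
  ref <- paired_reference(8)
  cm <- native_contact_map(ref)
  tr <- make_trajectory(ref, schedule = c(0.25, 0.75), contacts = cm)
  q0 <- q_trajectory(tr, cm)$q
  for (seed in 1:3) {
    rot <- random_rotation(seed + 100)
    trr <- tr
    trr$coords <- lapply(tr$coords, function(m)
      m %*% t(rot) + matrix(c(3, -8, 15), nrow(m), 3, byrow = TRUE))
    expect_equal(q_trajectory(trr, cm)$q, q0)
  }
})

test_that("domain-restricted Q equals whole-monomer Q on the isolated domain", {
  ref <- paired_reference(12)
  dom <- domain_definition("half", "1-40")   # first ~6 pairs fall in 1-40
  cm_dom <- native_contact_map(ref, selection = dom)
  iso <- ref
  iso$atoms <- dplyr::filter(iso$atoms, resno <= 40)
  cm_iso <- native_contact_map(iso)
  expect_equal(cm_dom$pairs[, c("i", "j", "native_distance")],
               cm_iso$pairs[, c("i", "j", "native_distance")])
  tr <- make_trajectory(ref, schedule = c(0.5), contacts = cm_dom)
  tr_iso <- make_trajectory(iso, schedule = c(0.5), contacts = cm_iso)
  expect_equal(q_trajectory(tr, cm_dom)$q, q_trajectory(tr_iso, cm_iso)$q)
})

test_that("trajectories round-trip through multi-MODEL PDB and xyz text", {
  ref <- paired_reference(6)
  cm <- native_contact_map(ref)
  tr <- make_trajectory(ref, schedule = c(0, 1 / 3, 1), contacts = cm)
  q0 <- q_trajectory(tr, cm)$q

  pdb_file <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(tr, pdb_file, ca = cm$ca)
  tr_pdb <- read_trajectory(pdb_file, format = "pdb")
  expect_equal(length(tr_pdb$coords), 3)
  expect_equal(q_trajectory(tr_pdb, cm)$q, q0, tolerance = 1e-6)

  xyz_file <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(nrow(cm$ca), unlist(lapply(tr$coords, function(m)
    apply(m, 1, paste, collapse = " ")))), xyz_file)
  tr_xyz <- read_trajectory(xyz_file, format = "xyz")
  expect_equal(q_trajectory(tr_xyz, cm)$q, q0)

  # frame/reference size mismatch is an error
  small <- native_contact_map(paired_reference(4))
  expect_error(q_trajectory(tr, small), "does not match")
})
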