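# minimal PDB writers for hand-built fixtures
pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          occ = 1, alt = " ", type = "ATOM") {
  sprintf("%-6s%5d %-4s%s%3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          type, serial, name, alt, resname, chain, resno, x, y, z, occ, 0)
}

write_mini_pdb <- function(lines, path) {
  writeLines(c(lines, "END"), path)
  path
}

test_that("PDB reading returns exact coordinates for a hand-written file", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_mini_pdb(c(
    pdb_atom_line(1, "N", "ALA", "A", 1, 1.234, 2.345, 3.456),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 4.000, 5.000, 6.000),
    pdb_atom_line(3, "CA", "GLY", "A", 2, 7.500, 8.500, 9.500)), tf)
  s <- read_structure(tf)
  expect_equal(nrow(s$atoms), 3L)
  expect_equal(s$atoms$x[1], 1.234)
  expect_equal(s$atoms$z[3], 9.5)
  expect_equal(s$chains$A$sequence, "AG")
})

test_that("altloc resolution keeps the highest occupancy, ties prefer A", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_mini_pdb(c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 1, 1, 1, occ = 0.6, alt = "A"),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 2, 2, 2, occ = 0.4, alt = "B"),
    pdb_atom_line(3, "CA", "GLY", "A", 2, 3, 3, 3, occ = 0.5, alt = "A"),
    pdb_atom_line(4, "CA", "GLY", "A", 2, 4, 4, 4, occ = 0.5, alt = "B"),
    pdb_atom_line(5, "CA", "SER", "A", 3, 5, 5, 5, occ = 0.3, alt = "A"),
    pdb_atom_line(6, "CA", "SER", "A", 3, 6, 6, 6, occ = 0.7, alt = "B")),
    tf)
  s <- read_structure(tf)
  expect_equal(nrow(s$atoms), 3L)
  expect_equal(s$atoms$x[s$atoms$resno == 1], 1)  # higher occupancy
  expect_equal(s$atoms$x[s$atoms$resno == 2], 3)  # tie -> altloc A
  expect_equal(s$atoms$x[s$atoms$resno == 3], 6)  # higher occupancy B
})

test_that("files without ATOM records or with bad coordinates are rejected", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("HEADER    NOTHING", "END"), tf)
  expect_error(read_structure(tf), "ATOM")
})

test_that("a synthetic helix survives a PDB round trip at format precision", {
  set.seed(61)
  s <- make_toy_structure(40, sequence = random_protein(40))
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, tf)
  back <- read_structure(tf)
  expect_equal(nrow(back$atoms), 40L)
  expect_equal(back$atoms$x, s$atoms$x, tolerance = 1e-3)
  expect_equal(back$atoms$y, s$atoms$y, tolerance = 1e-3)
  expect_equal(back$atoms$z, s$atoms$z, tolerance = 1e-3)
  expect_equal(back$chains$A$sequence, s$chains$A$sequence)
})

test_that("Kabsch: identity on self, zero RMSD on rigid copies", {
  set.seed(62)
  P <- matrix(rnorm(30), ncol = 3)
  sp <- kabsch_superpose(P, P)
  expect_equal(sp$rmsd, 0, tolerance = 1e-10)
  expect_equal(sp$rotation, diag(3), tolerance = 1e-8)

  for (k in 1:5) {
    q <- rnorm(4); q <- q / sqrt(sum(q^2))
    R <- matrix(c(
      1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
      2 * (q[2] * q[4] + q[1] * q[3]),
      2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
      2 * (q[3] * q[4] - q[1] * q[2]),
      2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]),
      1 - 2 * (q[2]^2 + q[3]^2)), 3, 3, byrow = TRUE)
    Q <- sweep(P %*% t(R), 2, runif(3, -10, 10), `+`)
    sp <- kabsch_superpose(P, Q)
    expect_lt(sp$rmsd, 1e-6)
    expect_equal(det(sp$rotation), 1, tolerance = 1e-6)
  }
})

test_that("Kabsch RMSD matches the numerical-optimizer oracle on noisy pairs", {
  set.seed(63)
  for (k in 1:5) {
    P <- matrix(rnorm(30, sd = 3), ncol = 3)
    Q <- P + matrix(rnorm(30, sd = 0.5), ncol = 3)
    sp <- kabsch_superpose(P, Q)
    expect_equal(sp$rmsd, oracle_min_rmsd(P, Q), tolerance = 1e-4)
    # cross-check against the field-standard fitting routine
    ref <- bio3d::rmsd(as.numeric(t(Q)), as.numeric(t(P)), fit = TRUE)
    expect_equal(sp$rmsd, ref, tolerance = 1e-3)
    # never worse than not superposing at all
    expect_lte(sp$rmsd, sqrt(mean(rowSums((P - Q)^2))) + 1e-12)
  }
})

test_that("Kabsch rejects degenerate and mismatched input", {
  P <- cbind(1:10, 2 * (1:10), 3 * (1:10))  # collinear
  expect_error(kabsch_superpose(P, P), "degenerate")
  expect_error(kabsch_superpose(matrix(rnorm(9), 3), matrix(rnorm(12), 4)),
               "size")
})

test_that("CA-RMSD by alignment: self is zero, rigid invariance holds", {
  set.seed(64)
  s1 <- make_toy_structure(60, sequence = random_protein(60))
  sp <- ca_rmsd_by_alignment(s1, s1)
  expect_equal(sp$rmsd, 0, tolerance = 1e-10)
  expect_equal(sp$n_pairs, 60L)
  expect_equal(unname(sp$coverage), c(1, 1))

  # rigidly moved copy of the same trace
  s2 <- s1
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  R <- diag(3)  # then a genuine rotation
  R <- matrix(c(cos(1), -sin(1), 0, sin(1), cos(1), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  xyz <- as.matrix(s1$atoms[, c("x", "y", "z")]) %*% t(R)
  s2$atoms[, c("x", "y", "z")] <- sweep(xyz, 2, c(5, -3, 8), `+`)
  s2$protein <- s2$atoms
  sp2 <- ca_rmsd_by_alignment(s1, s2)
  expect_lt(sp2$rmsd, 1e-6)

  # moving one input rigidly leaves the alignment RMSD unchanged
  set.seed(65)
  s3 <- make_toy_structure(60, sigma = 0.4,
                           sequence = s1$chains$A$sequence)
  base <- ca_rmsd_by_alignment(s1, s3)$rmsd
  s3m <- s3
  xyz <- as.matrix(s3$atoms[, c("x", "y", "z")]) %*% t(R)
  s3m$atoms[, c("x", "y", "z")] <- sweep(xyz, 2, c(-4, 2, 11), `+`)
  s3m$protein <- s3m$atoms
  expect_equal(ca_rmsd_by_alignment(s1, s3m)$rmsd, base,
               tolerance = 1e-6)
})

test_that("ligand-anchored pocket extraction respects the contact radius", {
  # three CA residues at controlled distances from a planted ligand atom
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_mini_pdb(c(
    pdb_atom_line(1, "CA", "ASP", "A", 1, 0, 0, 3),     # 3 A from ligand
    pdb_atom_line(2, "CA", "LYS", "A", 2, 0, 3, 0),     # 3 A
    pdb_atom_line(3, "CA", "GLY", "A", 3, 0, 0, 10),    # 10 A
    pdb_atom_line(4, "O", "HOH", "A", 101, 0, 2, 0),    # water, 2 A
    pdb_atom_line(5, "N1", "SPD", "B", 201, 0, 0, 0, type = "HETATM")),
    tf)
  s <- read_structure(tf)
  pocket <- extract_pocket(s, ligand = "SPD", radius = 4.5)
  expect_equal(sort(pocket$positions$resno), c(1L, 2L))
  expect_setequal(pocket$positions$resname, c("D", "K"))
  expect_equal(pocket$n_water_contacts, 1L)

  expect_equal(nrow(extract_pocket(s, ligand = "SPD",
                                   radius = 0)$positions), 0L)
  # monotone in radius
  r1 <- extract_pocket(s, ligand = "SPD", radius = 3.5)$positions$resno
  r2 <- extract_pocket(s, ligand = "SPD", radius = 12)$positions$resno
  expect_true(all(r1 %in% r2))

  expect_error(extract_pocket(s, ligand = "COA"), "SPD")
})

test_that("bundled pocket lists classify acidic with the expected net charge", {
  sht <- bahd_pocket("AtSHT")
  expect_equal(nrow(sht$positions), 9L)
  expect_equal(sht$net_charge, -1.9)
  expect_equal(sht$electro_class, "acidic")

  sdt <- bahd_pocket("AtSDT")
  expect_equal(nrow(sdt$positions), 13L)
  expect_equal(sdt$net_charge, -3)
  expect_equal(sdt$electro_class, "acidic")

  basic <- pocket_profile(data.frame(resno = 1:5,
                                     resname = c("R", "R", "K", "S", "T")))
  expect_equal(basic$net_charge, 3)
  expect_equal(basic$electro_class, "basic")
})

test_that("pocket charge is permutation-invariant and additive", {
  pos <- bahd_pocket("AtSDT")$positions
  set.seed(66)
  shuffled <- pocket_charge(pos[sample(nrow(pos)), ])
  expect_equal(shuffled$net_charge, pocket_charge(pos)$net_charge)
  a <- pos[1:6, ]; b <- pos[7:13, ]
  expect_equal(pocket_charge(a)$net_charge + pocket_charge(b)$net_charge,
               pocket_charge(pos)$net_charge)
})

test_that("unknown residue names contribute zero charge with a warning", {
  expect_warning(p <- pocket_profile(
    data.frame(resno = 1:2, resname = c("D", "ZZZ"))), "unknown")
  expect_equal(p$net_charge, -1)
})

test_that("pocket mapping: self-identity, single-substitution arithmetic, floor", {
  sdt <- synthetic_scaffold("AtSDT")
  prof <- bahd_pocket("AtSDT")
  self <- map_pocket_to_query(sdt, prof, sdt)
  expect_equal(self$profile$net_charge, prof$net_charge)
  expect_equal(self$profile$positions$resno, prof$positions$resno)
  expect_equal(nrow(self$unresolved), 0L)

  # mutate one pocket Asp to Ala: net charge rises by exactly 1
  chars <- strsplit(sdt$sequence, "")[[1]]
  chars[316] <- "A"
  mut <- sdt; mut$sequence <- paste(chars, collapse = ""); mut$id <- "mut"
  m <- map_pocket_to_query(sdt, prof, mut)
  expect_equal(m$profile$net_charge, prof$net_charge + 1)

  set.seed(67)
  expect_error(map_pocket_to_query(sdt, prof, random_protein(451)),
               class = "bahdscope_low_identity")
})
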