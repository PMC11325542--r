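test_that("residue templates are planar with canonical bond lengths", {
  canon <- list(HIS = 1.37, PHE = 1.39, TYR = 1.39, TRP = 1.39)
  cycles <- list(
    HIS = c("CG", "ND1", "CE1", "NE2", "CD2", "CG"),
    PHE = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2", "CG"),
    TYR = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2", "CG"),
    TRP = c("CG", "CD1", "NE1", "CE2", "CD2", "CG"))
  for (nm in names(cycles)) {
    t <- make_residue_template(nm)
    r <- build_ring(t)
    expect_lt(r$planarity_rmsd, 1e-6)
    cyc <- cycles[[nm]]
    for (i in seq_len(length(cyc) - 1)) {
      a <- as.numeric(t[t$name == cyc[i], c("x", "y", "z")])
      b <- as.numeric(t[t$name == cyc[i + 1], c("x", "y", "z")])
      expect_lt(abs(onorm(a - b) - canon[[nm]]), 0.05)
    }
  }
  # scenario hydrogens
  hie <- make_residue_template("HIS", "HIE")
  expect_equal(hie$name[hie$name %in% c("HD1", "HE2")], "HE2")
  hid <- make_residue_template("HIS", "HID")
  expect_equal(hid$name[hid$name %in% c("HD1", "HE2")], "HD1")
  phe <- make_residue_template("PHE")
  expect_equal(sum(phe$element == "H"), 5)
  expect_error(make_residue_template("HIS", "lys_NZ3"), "invalid scenario")
  expect_error(make_residue_template("GLY"), "unsupported")
  expect_equal(attr(make_residue_template("HIS", "HIP"), "charge"), 1L)
  expect_equal(attr(make_residue_template("LYS"), "charge"), 1L)
})

test_that("aromatic placement: forced P=0 case and feasibility errors", {
  his <- make_residue_template("HIS", "HIE")
  phe <- make_residue_template("PHE")
  st <- place_aromatic_pair(his, phe, D = 4, P = 0, T_theta2 = 90)
  g <- pair_geom_of(st)
  expect_equal(g$T_theta1, g$T_theta2, tolerance = 1e-9)  # P=0 forces equality
  expect_equal(unlist(g), c(D = 4, P = 0, T_theta1 = 90, T_theta2 = 90),
               tolerance = 1e-6)
  # P=0 with incompatible constrained elevations is infeasible
  expect_error(place_aromatic_pair(his, phe, D = 4, P = 0, T_theta2 = 80,
                                   T_theta1 = 20), "infeasible")
  expect_error(place_aromatic_pair(his, phe, D = 4, P = 5, T_theta2 = 90,
                                   T_theta1 = 0), "infeasible")
  expect_error(place_aromatic_pair(his, phe, D = 1, P = 0, T_theta2 = 0))
})

test_that("aromatic placement round-trips random feasible targets", {
  his <- make_residue_template("HIS", "HIE")
  trp <- make_residue_template("TRP")
  set.seed(47)
  for (i in 1:150) {
    tg <- feasible_aromatic_target()
    st <- place_aromatic_pair(his, trp, D = tg$D, P = tg$P,
                              T_theta2 = tg$t2, T_theta1 = tg$t1)
    g <- pair_geom_of(st)
    expect_equal(c(g$D, g$P, g$T_theta1, g$T_theta2),
                 c(tg$D, tg$P, tg$t1, tg$t2), tolerance = 1e-3)
  }
  # free T_theta1 round-trips too
  for (i in 1:100) {
    D <- runif(1, 2.5, 8); P <- runif(1, 0, 90); t2 <- runif(1, 0, 90)
    g <- pair_geom_of(place_aromatic_pair(his, trp, D, P, t2))
    expect_equal(c(g$D, g$P, g$T_theta2), c(D, P, t2), tolerance = 1e-3)
  }
})

test_that("cation placement round-trips and the His+ nitrogen is by design", {
  phe <- make_residue_template("PHE")
  lys <- make_residue_template("LYS")
  arg <- make_residue_template("ARG")
  hip <- make_residue_template("HIS", "HIP")
  g <- cation_geom_of(place_cation_pair(phe, lys, D = 4, theta1 = 0))
  expect_equal(c(g$D, g$theta1), c(4, 0), tolerance = 1e-6)
  expect_error(place_cation_pair(phe, lys, D = 4, theta1 = 0, theta2 = 30),
               "theta2")
  set.seed(53)
  for (i in 1:60) {
    D <- runif(1, 2.5, 7); t1 <- runif(1, 0, 90); t2 <- runif(1, 0, 90)
    g <- cation_geom_of(place_cation_pair(phe, arg, D, t1, t2))
    expect_equal(c(g$D, g$theta1, g$theta2), c(D, t1, t2), tolerance = 1e-3)
    g2 <- cation_geom_of(place_cation_pair(phe, hip, D, t1, t2))
    expect_equal(c(g2$D, g2$theta1, g2$theta2), c(D, t1, t2), tolerance = 1e-3)
    expect_equal(g2$chosen_nitrogen, "NE2")
  }
})

test_that("fixture structures honour separation and designed outcomes", {
  fx <- make_fixture_structure(list(
    list(type = "aromatic_pair", a = "HIS", b = "PHE", D = 3.8, P = 10,
         T_theta2 = 70),
    list(type = "his_tag", n = 6),
    list(type = "metal_his", distance = 4.0),
    list(type = "water")))
  expect_equal(nrow(fx$units), 4)
  expect_equal(nrow(mine(fx$structure)), 1)
  # unit chains are distinct
  expect_equal(length(unique(fx$units$chain)), 4)
  # deuterium is written for neutron-like His and survives PDB round-trip
  path <- withr::local_tempfile(fileext = ".pdb")
  fx2 <- make_fixture_structure(
    list(list(type = "deuterated_his", tautomer = "positive")),
    method = "neutron")
  write_pdb(fx2$structure, path)
  back <- read_structure(path)
  expect_equal(sum(back$is_deuterium), 2)
  expect_equal(tautomer_census(list(back))$positive, 1L)
})

test_that("fragments match their chemical formulas and keep heavy atoms fixed", {
  cases <- list(
    list(res = "HIS", sc = "HIE", compound = "4-methylimidazole", n = 12, q = 0),
    list(res = "HIS", sc = "HID", compound = "4-methylimidazole", n = 12, q = 0),
    list(res = "HIS", sc = "HIP", compound = "4-methylimidazolium", n = 13, q = 1),
    list(res = "PHE", sc = NULL, compound = "toluene", n = 15, q = 0),
    list(res = "TYR", sc = NULL, compound = "4-methylphenol", n = 16, q = 0),
    list(res = "TRP", sc = NULL, compound = "3-methylindole", n = 19, q = 0),
    list(res = "LYS", sc = NULL, compound = "methylammonium", n = 8, q = 1),
    list(res = "ARG", sc = NULL, compound = "methylguanidinium", n = 13, q = 1))
  set.seed(67)
  for (cs in cases) {
    src <- rigid_pose(make_residue_template(cs$res, cs$sc))
    frag <- extract_qm_fragment(src, cs$sc)
    expect_equal(frag$compound, cs$compound)
    expect_equal(nrow(frag$atoms), cs$n)
    expect_equal(frag$charge, cs$q)
    # retained heavy atoms keep source coordinates exactly
    heavy <- frag$atoms[!frag$atoms$element %in% c("H", "D"), ]
    for (i in seq_len(nrow(heavy))) {
      sa <- src[src$name == heavy$name[i], c("x", "y", "z")]
      expect_lt(onorm(as.numeric(sa) - as.numeric(heavy[i, c("x", "y", "z")])),
                1e-9)
    }
    # every cap hydrogen at 1.09 A from the cap carbon
    capname <- if (cs$res == "LYS") "CE" else if (cs$res == "ARG") "CD" else "CB"
    capC <- as.numeric(frag$atoms[frag$atoms$name == capname, c("x", "y", "z")])
    caph <- frag$atoms[startsWith(frag$atoms$name, paste0("H", capname)), ]
    expect_equal(nrow(caph), 3)
    for (i in 1:3)
      expect_equal(onorm(as.numeric(caph[i, c("x", "y", "z")]) - capC), 1.09,
                   tolerance = 1e-9)
  }
  expect_error(extract_qm_fragment(make_atoms("C", "C", c(0, 0, 0),
                                              resname = "GLY")), "unsupported")
})

test_that("XYZ export: counts, charge comment, concatenation, round-trip", {
  phe <- extract_qm_fragment(make_residue_template("PHE"))
  path <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(phe, path)
  lines <- readLines(path)
  expect_equal(lines[1], "15")
  expect_match(lines[2], "charge=0")
  back <- read_xyz(path)
  expect_equal(nrow(back$atoms), 15)
  expect_equal(as.matrix(back$atoms[, c("x", "y", "z")]),
               as.matrix(phe$atoms[, c("x", "y", "z")]),
               tolerance = 1e-6, ignore_attr = TRUE)

  hip <- extract_qm_fragment(make_residue_template("HIS", "HIP"), "HIP")
  path2 <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(list(phe, hip), path2)
  lines2 <- readLines(path2)
  expect_equal(lines2[1], "28")
  expect_match(lines2[2], "charge=1")
})

test_that("micro-environment fixtures drive the designed protonation calls", {
  for (cs in list(c("acceptor_at_ND1", "neutral", "epsilon0"),
                  c("acceptor_at_NE2", "neutral", "delta0"),
                  c("double_donor", "positive", NA),
                  c("isolated", "undetermined", NA))) {
    s <- make_fixture_structure(list(list(type = "microenv", kind = cs[1])))$structure
    key <- structure_residues(s)$key[1]
    call <- infer_protonation_hbond(s, key)
    expect_equal(call$state, cs[2])
    if (!is.na(cs[3])) expect_equal(call$tautomer, cs[3])
  }
})
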