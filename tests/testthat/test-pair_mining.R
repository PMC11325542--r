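test_that("carbon-carbon cutoff is inclusive and monotone", {
  phe <- make_residue_template("PHE")
  # two coplanar Phe translated along x; tune the offset until the minimum
  # ring C-C distance is exactly the cutoff
  min_cc <- function(off) {
    b <- rigid_pose(phe, R = diag(3), t = c(off, 0, 0))
    d <- as.matrix(stats::dist(rbind(ring_xyz_of(phe), ring_xyz_of(b))))
    min(d[1:6, -(1:6)])
  }
  off <- 7
  for (i in 1:60) off <- off + (5.0 - min_cc(off))
  expect_equal(min_cc(off), 5.0, tolerance = 1e-9)

  at_cut <- scatter_structure(list(
    list(name = "PHE", offset = c(0, 0, 0), resseq = 1),
    list(name = "PHE", offset = c(off, 0, 0), resseq = 2)))
  expect_equal(nrow(find_aromatic_pairs(at_cut)), 1)

  beyond <- scatter_structure(list(
    list(name = "PHE", offset = c(0, 0, 0), resseq = 1),
    list(name = "PHE", offset = c(off + 1e-4, 0, 0), resseq = 2)))
  expect_equal(nrow(find_aromatic_pairs(beyond)), 0)
  # monotone in the cutoff
  expect_equal(nrow(find_aromatic_pairs(beyond, mining_config(cc_cutoff = 5.2))), 1)

  far <- scatter_structure(list(
    list(name = "PHE", offset = c(0, 0, 0), resseq = 1),
    list(name = "PHE", offset = c(20, 0, 0), resseq = 2)))
  expect_equal(nrow(find_aromatic_pairs(far)), 0)
})

test_that("aromatic and cation-pi mining match a brute-force scan", {
  set.seed(41)
  for (rep in 1:3) {
    names <- c("HIS", "PHE", "TYR", "TRP", "HIS", "LYS", "ARG")
    specs <- lapply(seq_along(names), function(i)
      list(name = names[i], scenario = NULL, R = random_rotation(),
           offset = runif(3, 0, 14), resseq = i))
    s <- scatter_structure(specs)
    cfg <- mining_config()

    got <- find_aromatic_pairs(s, cfg)
    res <- structure_residues(s)
    arom <- res[res$resname %in% c("HIS", "PHE", "TYR", "TRP"), ]
    expected <- 0
    for (i in seq_len(nrow(arom) - 1)) for (j in (i + 1):nrow(arom)) {
      xi <- ring_xyz_of(residue_atoms(s, arom$key[i]))
      xj <- ring_xyz_of(residue_atoms(s, arom$key[j]))
      xi <- xi[startsWith(rownames(xi), "C"), , drop = FALSE]
      xj <- xj[startsWith(rownames(xj), "C"), , drop = FALSE]
      d <- as.matrix(stats::dist(rbind(xi, xj)))
      if (min(d[seq_len(nrow(xi)), -seq_len(nrow(xi))]) <= cfg$cc_cutoff)
        expected <- expected + 1
    }
    expect_equal(nrow(got), expected)

    got_c <- find_cation_pi_pairs(s, cfg)
    cats <- res[res$resname %in% c("LYS", "ARG", "HIS"), ]
    expected_c <- 0
    for (i in seq_len(nrow(arom))) for (j in seq_len(nrow(cats))) {
      if (arom$key[i] == cats$key[j]) next
      ring <- oracle_ring(ring_xyz_of(residue_atoms(s, arom$key[i])))
      ca <- residue_atoms(s, cats$key[j])
      center <- switch(ca$resname[1],
        LYS = as.numeric(ca[ca$name == "NZ", c("x", "y", "z")]),
        ARG = as.numeric(ca[ca$name == "CZ", c("x", "y", "z")]),
        HIS = {
          ne2 <- as.numeric(ca[ca$name == "NE2", c("x", "y", "z")])
          nd1 <- as.numeric(ca[ca$name == "ND1", c("x", "y", "z")])
          if (onorm(ne2 - ring$centroid) <= onorm(nd1 - ring$centroid)) ne2 else nd1
        })
      if (onorm(center - ring$centroid) <= cfg$cation_centroid_cutoff)
        expected_c <- expected_c + 1
    }
    expect_equal(nrow(got_c), expected_c)
  }
})

test_that("His-His cation candidates appear in both role assignments", {
  his1 <- make_residue_template("HIS", "HIE")
  his2 <- make_residue_template("HIS", "HIP")
  st <- place_cation_pair(his1, his2, D = 4, theta1 = 10, theta2 = 20)
  got <- find_cation_pi_pairs(as_structure(as.data.frame(st)))
  hh <- got[got$resname1 == "HIS" & got$resname2 == "HIS", ]
  expect_equal(nrow(hh), 2)
  expect_setequal(paste(hh$res1, hh$res2), c("A|1| A|2|", "A|2| A|1|"))
  expect_true(all(!is.na(hh$chosen_nitrogen)))
})

test_that("His-tag runs: >=5 excluded, 4 kept, runs do not cross chains", {
  tag6 <- make_fixture_structure(list(list(type = "his_tag", n = 6)))$structure
  expect_equal(length(his_tag_exclusions(tag6)), 6)

  tag4 <- make_fixture_structure(list(list(type = "his_tag", n = 4)))$structure
  expect_equal(length(his_tag_exclusions(tag4)), 0)

  # 3 + 2 split across chains with consecutive numbers: no exclusion
  rows <- list()
  for (i in 1:5) {
    h <- make_residue_template("HIS", "aromatic_CH_only")
    h <- rigid_pose(h, R = diag(3), t = c(10 * i, 0, 0))
    h$chain <- if (i <= 3) "A" else "B"
    h$resseq <- as.integer(i)
    rows[[i]] <- h
  }
  split_chain <- as_structure(do.call(rbind, rows))
  expect_equal(length(his_tag_exclusions(split_chain)), 0)
  # same numbering on one chain is a 5-run
  one_chain <- do.call(rbind, rows)
  one_chain$chain <- "A"
  expect_equal(length(his_tag_exclusions(as_structure(one_chain))), 5)
})

test_that("metal exclusions use any His atom within the radius", {
  near <- make_fixture_structure(list(list(type = "metal_his", distance = 4.0)))$structure
  expect_equal(length(metal_exclusions(near)), 1)
  far <- make_fixture_structure(list(list(type = "metal_his", distance = 6.0)))$structure
  # NE2 is 6 A away but ring C-H hydrogens do not count; CE1/CD2 are further
  expect_equal(length(metal_exclusions(far)), 0)

  set.seed(57)
  specs <- lapply(1:3, function(i)
    list(name = "HIS", R = random_rotation(), offset = runif(3, 0, 12), resseq = i))
  s0 <- scatter_structure(specs)
  metals <- rbind(
    make_atoms("ZN", "ZN", runif(3, 0, 12), "ZN", resseq = 90, record = "HETATM"),
    make_atoms("MG", "MG", runif(3, 0, 12), "MG", resseq = 91, record = "HETATM"))
  s <- as_structure(rbind(as.data.frame(s0), metals))
  got <- metal_exclusions(s)
  res <- structure_residues(s)
  expected <- character(0)
  for (k in res$key[res$resname == "HIS"]) {
    a <- residue_atoms(s, k)
    dmin <- Inf
    for (i in seq_len(nrow(a))) for (j in 1:2)
      dmin <- min(dmin, onorm(as.numeric(a[i, c("x", "y", "z")]) -
                              as.numeric(metals[j, c("x", "y", "z")])))
    if (dmin <= 5.0) expected <- c(expected, k)
  }
  expect_setequal(got, expected)
})

test_that("mine() applies exclusions and yields the designed pair list", {
  fx <- make_fixture_structure(list(
    list(type = "aromatic_pair", a = "HIS", b = "PHE", D = 3.8, P = 10, T_theta2 = 70),
    list(type = "his_tag", n = 6),
    list(type = "metal_his", distance = 4.0)))
  got <- mine(fx$structure)
  expect_equal(nrow(got), 1)
  expect_equal(got$resname1, "HIS")
  expect_equal(got$resname2, "PHE")
  expect_equal(got$families, "aromatic+cation_pi")

  only_metal <- make_fixture_structure(list(
    list(type = "aromatic_pair", a = "HIS", b = "PHE", D = 3.8, P = 10, T_theta2 = 70,
         scenario_a = "HIE")))
  s <- only_metal$structure
  # drop a metal right next to the His of the only pair
  his_atoms <- residue_atoms(s, "A|1|")
  zn <- make_atoms("ZN", "ZN",
                   as.numeric(his_atoms[his_atoms$name == "NE2", c("x", "y", "z")]) + c(0, 0, 4),
                   "ZN", chain = "A", resseq = 95, record = "HETATM")
  s2 <- as_structure(rbind(as.data.frame(s), zn))
  expect_equal(nrow(mine(s2)), 0)
})

test_that("mining is invariant to residue input order", {
  set.seed(77)
  specs <- lapply(1:5, function(i)
    list(name = c("HIS", "PHE", "TYR", "LYS", "HIS")[i], R = random_rotation(),
         offset = runif(3, 0, 12), resseq = i))
  s <- scatter_structure(specs)
  m1 <- mine(s)
  # permute residue blocks
  df <- as.data.frame(s)
  blocks <- split(seq_len(nrow(df)), residue_key(df$chain, df$resseq, df$icode))
  df2 <- df[unlist(blocks[sample(length(blocks))]), ]
  m2 <- mine(as_structure(df2, id = attr(s, "id")))
  rownames(m2) <- NULL
  expect_equal(m1, m2)
})
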