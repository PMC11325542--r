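thr0 <- geometry_thresholds()

test_that("stacked and cation-pi rules match direct threshold evaluation", {
  g <- list(D = 3.8, P = 10, T_theta1 = 70, T_theta2 = 70)
  expect_true(classify_stacked(g, thr0))
  expect_false(classify_stacked(list(D = 12, P = 0, T_theta1 = 0, T_theta2 = 0), thr0))
  expect_true(classify_cation_pi(list(D = 3.5, theta1 = 15, theta2 = NA), thr0))
  expect_false(classify_cation_pi(list(D = 4, theta1 = 89, theta2 = NA), thr0))

  # grid sweep equals the rule evaluated inline
  for (D in seq(0.5, 12, by = 0.5)) for (P in seq(0, 90, by = 7.5)) {
    g <- list(D = D, P = P, T_theta1 = 45, T_theta2 = 45)
    expect_identical(classify_stacked(g, thr0),
                     D <= thr0$stack_max_D && P <= thr0$stack_max_P)
  }
  set.seed(12)
  for (i in 1:500) {
    g <- list(D = runif(1, 0.5, 10), theta1 = runif(1, 0, 90), theta2 = NA)
    expect_identical(classify_cation_pi(g, thr0),
                     g$D <= thr0$catpi_max_D && g$theta1 <= thr0$catpi_max_theta1)
  }
  # optional T_theta2 knob
  thr_knob <- geometry_thresholds(stack_min_T_theta2 = 45)
  expect_false(classify_stacked(list(D = 3.8, P = 5, T_theta2 = 30), thr_knob))
  expect_true(classify_stacked(list(D = 3.8, P = 5, T_theta2 = 60), thr_knob))
})

test_that("CH-pi contacts: ideal T-shape, distance rejection, oracle", {
  phe <- make_residue_template("PHE")
  ring <- build_ring(phe)
  # donor C on the ring axis at 3.6 A, H pointing at the centroid
  u <- ring$normal
  C <- ring$centroid + 3.6 * u
  H <- C - 1.08 * u
  donor <- make_atoms(c("CX", "HX"), c("C", "H"), rbind(C, H),
                      resname = "LIG", resseq = 9)
  got <- classify_ch_pi(donor, ring, thr0)
  expect_equal(nrow(got), 1)
  expect_equal(got$C_centroid, 3.6, tolerance = 1e-9)
  expect_equal(got$H_projection, 0, tolerance = 1e-9)
  expect_equal(got$CH_centroid_angle, 180, tolerance = 1e-6)

  far <- make_atoms(c("CX", "HX"), c("C", "H"),
                    rbind(ring$centroid + 6 * u, ring$centroid + 4.92 * u),
                    resname = "LIG", resseq = 9)
  expect_equal(nrow(classify_ch_pi(far, ring, thr0)), 0)
  expect_error(classify_ch_pi(phe[phe$element != "H", ], ring, thr0),
               "no C-H hydrogens")

  # tilted constructed poses vs an explicit trigonometric oracle
  set.seed(19)
  for (i in 1:100) {
    C <- ring$centroid + runif(1, 2.5, 5.5) *
      c(sin(a <- runif(1, 0, pi / 3)) * cos(b <- runif(1, 0, 2 * pi)),
        sin(a) * sin(b), cos(a))
    hd <- rnorm(3); hd <- hd / onorm(hd)
    H <- C + 1.08 * hd
    donor <- make_atoms(c("CX", "HX"), c("C", "H"), rbind(C, H), resseq = 9)
    got <- nrow(classify_ch_pi(donor, ring, thr0)) == 1
    proj <- H - sum((H - ring$centroid) * ring$normal) * ring$normal
    want <- onorm(C - ring$centroid) <= thr0$chpi_max_C_centroid &&
      onorm(proj - ring$centroid) <= thr0$chpi_max_H_projection &&
      oracle_angle(C - H, ring$centroid - H) >= thr0$chpi_min_CH_centroid_angle
    expect_identical(got, want)
  }
})

test_that("H-bond rule: distance, linearity and His-plane elevation", {
  his <- make_residue_template("HIS", "HIE")
  ring <- build_ring(his)
  ne2 <- as.numeric(his[his$name == "NE2", c("x", "y", "z")])
  h <- as.numeric(his[his$name == "HE2", c("x", "y", "z")])
  d_inplane <- (h - ne2) / onorm(h - ne2)      # N-H direction, in-plane

  acc <- ne2 + 2.9 * d_inplane
  r <- classify_h_bond(ne2, h, acc, ring, thr0)
  expect_true(r$is_hbond)
  expect_equal(r$DA, 2.9, tolerance = 1e-9)
  expect_equal(r$DHA, 180, tolerance = 1e-6)
  expect_lt(r$plane_elevation, 1e-6)

  expect_false(classify_h_bond(ne2, h, ne2 + 5 * d_inplane, ring, thr0)$is_hbond)

  # acceptor 60 deg out of the ring plane: within distance but rejected by
  # the in-plane lone-pair constraint
  d60 <- cos(pi / 3) * d_inplane + sin(pi / 3) * ring$normal
  out_of_plane <- ne2 + 2.9 * d60
  r60 <- classify_h_bond(ne2, h, out_of_plane, ring, thr0)
  expect_false(r60$is_hbond)
  expect_equal(r60$plane_elevation, 60, tolerance = 1e-6)
  # without a His ring the same geometry passes on distance + angle alone
  h2 <- ne2 + 1.01 * d60
  expect_true(classify_h_bond(ne2, h2, out_of_plane, NULL, thr0)$is_hbond)
  # donor_H = NULL skips the angle test (orientation-free water donor)
  expect_true(classify_h_bond(ne2, NULL, acc, ring, thr0)$is_hbond)
})

test_that("label_pair: stack, mixed stacked/CH-pi, distant pair, cation pair", {
  his <- make_residue_template("HIS", "HIE")
  phe <- make_residue_template("PHE")
  pr <- data.frame(family = "aromatic", res1 = "A|1|", res2 = "A|2|",
                   resname1 = "HIS", resname2 = "PHE", stringsAsFactors = FALSE)

  stack <- place_aromatic_pair(his, phe, D = 3.6, P = 0, T_theta2 = 90)
  lab <- label_pair(pr, stack, "HIE", thr0)
  expect_true("stacked" %in% lab$labels)
  expect_false("other" %in% lab$labels)

  # strongly slipped stack: an edge C-H of the partner reaches into the
  # reference ring face, so both criteria fire
  mixed <- place_aromatic_pair(his, phe, D = 5.0, P = 5, T_theta2 = 34)
  labm <- label_pair(pr, mixed, "HIE", thr0)
  expect_true(all(c("stacked", "ch_pi") %in% labm$labels))

  farpair <- place_aromatic_pair(his, phe, D = 9, P = 0, T_theta2 = 90)
  expect_equal(label_pair(pr, farpair, "HIE", thr0)$labels, "other")

  lys <- make_residue_template("LYS")
  prc <- data.frame(family = "cation_pi", res1 = "A|1|", res2 = "A|2|",
                    resname1 = "PHE", resname2 = "LYS", stringsAsFactors = FALSE)
  onaxis <- place_cation_pair(phe, lys, D = 3.5, theta1 = 15)
  expect_true("cation_pi" %in% label_pair(prc, onaxis, "HIE", thr0)$labels)
})

test_that("label monotonicity: loosening thresholds never removes a label", {
  set.seed(71)
  for (i in 1:200) {
    g <- list(D = runif(1, 2, 8), P = runif(1, 0, 90),
              T_theta1 = runif(1, 0, 90), T_theta2 = runif(1, 0, 90))
    c1 <- classify_stacked(g, thr0)
    loose <- geometry_thresholds(stack_max_D = thr0$stack_max_D + runif(1, 0, 2),
                                 stack_max_P = thr0$stack_max_P + runif(1, 0, 30))
    if (c1) expect_true(classify_stacked(g, loose))
    gc <- list(D = runif(1, 2, 8), theta1 = runif(1, 0, 90), theta2 = NA)
    if (classify_cation_pi(gc, thr0)) {
      loose_c <- geometry_thresholds(catpi_max_D = thr0$catpi_max_D + runif(1, 0, 2),
                                     catpi_max_theta1 = thr0$catpi_max_theta1 + runif(1, 0, 20))
      expect_true(classify_cation_pi(gc, loose_c))
    }
  }
})

test_that("poses placed 10% inside/outside each stacked boundary classify as designed", {
  his <- make_residue_template("HIS", "HIE")
  phe <- make_residue_template("PHE")
  pr <- data.frame(family = "aromatic", res1 = "A|1|", res2 = "A|2|",
                   resname1 = "HIS", resname2 = "PHE", stringsAsFactors = FALSE)
  inside <- place_aromatic_pair(his, phe, D = 0.9 * thr0$stack_max_D,
                                P = 0.9 * thr0$stack_max_P, T_theta2 = 80)
  expect_true("stacked" %in% label_pair(pr, inside, "HIE", thr0)$labels)
  out_D <- place_aromatic_pair(his, phe, D = 1.1 * thr0$stack_max_D,
                               P = 0.9 * thr0$stack_max_P, T_theta2 = 80)
  expect_false("stacked" %in% label_pair(pr, out_D, "HIE", thr0)$labels)
  out_P <- place_aromatic_pair(his, phe, D = 0.9 * thr0$stack_max_D,
                               P = 1.1 * thr0$stack_max_P, T_theta2 = 80)
  expect_false("stacked" %in% label_pair(pr, out_P, "HIE", thr0)$labels)

  lys <- make_residue_template("LYS")
  prc <- data.frame(family = "cation_pi", res1 = "A|1|", res2 = "A|2|",
                    resname1 = "PHE", resname2 = "LYS", stringsAsFactors = FALSE)
  in_c <- place_cation_pair(phe, lys, D = 0.9 * thr0$catpi_max_D,
                            theta1 = 0.9 * thr0$catpi_max_theta1)
  expect_true("cation_pi" %in% label_pair(prc, in_c, "HIE", thr0)$labels)
  out_c <- place_cation_pair(phe, lys, D = 1.1 * thr0$catpi_max_D,
                             theta1 = 0.9 * thr0$catpi_max_theta1)
  expect_false("cation_pi" %in% label_pair(prc, out_c, "HIE", thr0)$labels)
})

test_that("energy filter keeps strictly below the cutoff and drops missing", {
  lp <- data.frame(pair_id = c("p1", "p2", "p3", "p4"),
                   family = "aromatic", stringsAsFactors = FALSE)
  et <- data.frame(pair_id = c("p1", "p2", "p3"),
                   energy = c(-3.1, -0.5, -1.0), stringsAsFactors = FALSE)
  expect_message(got <- filter_by_energy(lp, et, cutoff = -1), "1 pair")
  expect_equal(got$pair_id, "p1")        # -0.5 and -1.0 fail strict <; p4 missing
  expect_equal(got$energy, -3.1)
  expect_error(filter_by_energy(lp, data.frame(x = 1)), "pair_id")

  set.seed(8)
  lp2 <- data.frame(pair_id = sprintf("q%d", 1:50), stringsAsFactors = FALSE)
  et2 <- data.frame(pair_id = lp2$pair_id, energy = runif(50, -5, 1))
  got2 <- filter_by_energy(lp2, et2)
  expect_setequal(got2$pair_id, et2$pair_id[et2$energy < -1])
})

test_that("energy summary: mean, sample SD, single-entry cells", {
  df <- data.frame(family = c("His0-Phe", "His0-Phe", "His0-Tyr"),
                   label = c("stacked", "stacked", "h_bond"),
                   phase = "solvent",
                   energy = c(-2, -4, -3.0), stringsAsFactors = FALSE)
  got <- summarize_energies(df)
  st <- got[got$family == "His0-Phe", ]
  expect_equal(st$mean, -3.0)
  expect_equal(st$sd, 1.4142, tolerance = 1e-4)
  expect_equal(st$n, 2)
  single <- got[got$family == "His0-Tyr", ]
  expect_equal(single$mean, -3.0)
  expect_equal(single$sd, 0)
  expect_equal(single$n, 1)
  expect_equal(nrow(got), 2)             # empty cells omitted
})
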