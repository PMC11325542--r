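# Ground-truth fixture generation: idealized residue templates, pair
# placement at exact target descriptors, full fixture structures (His-tags,
# metals, waters, deuterated His, designed H-bond micro-environments) and
# methyl-capped model-compound fragments for QM input.
#
# Placement follows a zero-twist convention: every rotational degree of
# freedom the descriptors do not constrain is fixed deterministically, so
# identical targets always give identical coordinates.

RING_EDGE <- c(HIS = 1.37, PHE = 1.39, TYR = 1.39, TRP = 1.39)

atom_df <- function(name, element, xyz, resname, chain = "A", resseq = 1L,
                    record = "ATOM") {
  data.frame(record = record, name = name, altloc = "", resname = resname,
             chain = chain, resseq = as.integer(resseq), icode = "",
             x = xyz[1], y = xyz[2], z = xyz[3], occupancy = 1,
             element = element, is_deuterium = element == "D",
             stringsAsFactors = FALSE)
}

regular_polygon_xy <- function(n, edge, start_angle_deg = 90) {
  r <- edge / (2 * sin(pi / n))
  ang <- deg2rad(start_angle_deg + (0:(n - 1)) * 360 / n)
  cbind(r * cos(ang), r * sin(ang), 0)
}

res_transform <- function(atoms, R = diag(3), t = c(0, 0, 0), center = c(0, 0, 0)) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  xyz <- sweep(xyz, 2, center) %*% t(R)
  xyz <- sweep(xyz, 2, t, "+")
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  atoms
}

# external (away from ring centroid) in-plane direction at a ring atom
external_dir <- function(xyz_ring, atom_name) {
  ctr <- colMeans(xyz_ring)
  unitv(xyz_ring[atom_name, ] - ctr)
}

default_scenario <- function(name) {
  switch(name, HIS = "HIE", LYS = "lys_NZ3", ARG = "arg_guanidinium",
         "aromatic_CH_only")
}

#' Build an idealized residue template
#'
#' Planar rings (His imidazole edge 1.37 A, benzene rings 1.39 A, Trp
#' indole as a fused regular hexagon + pentagon sharing the CD2-CE2 edge),
#' a CB stub for the aromatics (the future methyl cap), Lys NZ-CE-CD and
#' the Arg guanidinium with CD. Hydrogens are placed per scenario with
#' [add_ideal_hydrogens()]. Ring planarity of the template is exact.
#'
#' @param name one of `"HIS"`, `"PHE"`, `"TYR"`, `"TRP"`, `"LYS"`, `"ARG"`.
#' @param scenario protonation scenario (default: `"HIE"` for His,
#'   `"lys_NZ3"` for Lys, `"arg_guanidinium"` for Arg, `"aromatic_CH_only"`
#'   otherwise).
#' @param chain,resseq identifiers stamped on the atoms.
#' @return residue atom table with attributes `scenario` and `charge`.
#' @export
make_residue_template <- function(name, scenario = NULL, chain = "A", resseq = 1L) {
  if (is.null(scenario)) scenario <- default_scenario(name)
  valid <- switch(name,
    HIS = c("HID", "HIE", "HIP", "aromatic_CH_only"),
    PHE = , TYR = , TRP = "aromatic_CH_only",
    LYS = "lys_NZ3", ARG = "arg_guanidinium",
    stop("unsupported residue: ", name))
  if (!scenario %in% valid)
    stop("invalid scenario ", scenario, " for residue ", name)

  rows <- list()
  add <- function(nm, el, p) rows[[length(rows) + 1]] <<-
    atom_df(nm, el, p, name, chain, resseq)

  if (name == "HIS") {
    ring_names <- c("CG", "ND1", "CE1", "NE2", "CD2")
    xy <- regular_polygon_xy(5, RING_EDGE["HIS"])
    rownames(xy) <- ring_names
    for (nm in ring_names) add(nm, substr(nm, 1, 1), xy[nm, ])
    add("CB", "C", xy["CG", ] + 1.50 * external_dir(xy, "CG"))
  } else if (name %in% c("PHE", "TYR")) {
    ring_names <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
    xy <- regular_polygon_xy(6, RING_EDGE[name])
    rownames(xy) <- ring_names
    for (nm in ring_names) add(nm, "C", xy[nm, ])
    add("CB", "C", xy["CG", ] + 1.50 * external_dir(xy, "CG"))
    if (name == "TYR") add("OH", "O", xy["CZ", ] + 1.36 * external_dir(xy, "CZ"))
  } else if (name == "TRP") {
    hex_names <- c("CD2", "CE3", "CZ3", "CH2", "CZ2", "CE2")
    hx <- regular_polygon_xy(6, RING_EDGE["TRP"])
    rownames(hx) <- hex_names
    # fused pentagon sharing the CD2-CE2 edge, on the far side of the hexagon
    A <- hx["CD2", ]; B <- hx["CE2", ]
    mid <- (A + B) / 2
    edge <- vnorm(B - A)
    apo <- edge / (2 * tan(pi / 5))
    p0 <- mid + apo * unitv(mid)                    # pentagon center
    aA <- atan2(A[2] - p0[2], A[1] - p0[1])
    aB <- atan2(B[2] - p0[2], B[1] - p0[1])
    step <- 2 * pi / 5
    # walk from CD2 away from CE2: CD2 -> CG -> CD1 -> NE1 -> CE2
    sgn <- if (sin(aB - aA) > 0) -1 else 1
    rp <- vnorm(A - p0)
    pent <- lapply(1:3, function(i) {
      a <- aA + sgn * i * step
      c(p0[1] + rp * cos(a), p0[2] + rp * sin(a), 0)
    })
    for (nm in hex_names) add(nm, "C", hx[nm, ])
    add("CG", "C", pent[[1]])
    add("CD1", "C", pent[[2]])
    add("NE1", "N", pent[[3]])
    heavy <- do.call(rbind, rows)
    xyz9 <- atom_xyz(heavy, ring_spec()[["TRP"]])
    add("CB", "C", as.vector(atom_xyz(heavy, "CG")) +
          1.50 * external_dir(xyz9, "CG"))
  } else if (name == "LYS") {
    add("CE", "C", c(0, 0, 0))
    add("NZ", "N", c(1.49, 0, 0))
    add("CD", "C", 1.52 * c(cos(deg2rad(111)), sin(deg2rad(111)), 0))
  } else if (name == "ARG") {
    add("CZ", "C", c(0, 0, 0))
    for (p in list(c("NE", 90), c("NH1", 210), c("NH2", 330)))
      add(p[1], "N", 1.33 * c(cos(deg2rad(as.numeric(p[2]))),
                              sin(deg2rad(as.numeric(p[2]))), 0))
    heavy <- do.call(rbind, rows)
    ne <- as.vector(atom_xyz(heavy, "NE"))
    v <- unitv(as.vector(atom_xyz(heavy, "CZ")) - ne)
    d <- rotation_about(c(0, 0, 1), deg2rad(124)) %*% v
    add("CD", "C", ne + 1.46 * as.vector(d))
  }
  out <- do.call(rbind, rows)
  out <- add_ideal_hydrogens(out, scenario)
  rownames(out) <- NULL
  attr(out, "scenario") <- scenario
  attr(out, "charge") <- if (scenario == "HIP" || name %in% c("LYS", "ARG")) 1L else 0L
  out
}

# rigid-move a residue so its ring centroid sits at the origin, its plane
# normal along +z, and the first ring atom along +x (zero twist)
canonicalize_on_ring <- function(atoms) {
  ring <- build_ring(atoms[!atoms$element %in% c("H", "D"), , drop = FALSE])
  R0 <- rotation_align(ring$normal, c(0, 0, 1))
  a <- res_transform(atoms, R0, center = ring$centroid)
  v <- as.vector(atom_xyz(a, rownames(ring$xyz)[1]))
  phi <- atan2(v[2], v[1])
  res_transform(a, rotation_about(c(0, 0, 1), -phi))
}

#' Place two aromatic residues at exact target descriptors
#'
#' Builds a two-residue structure whose recomputed
#' [aromatic_pair_geometry()] reproduces the targets (D, P, T_theta2 and,
#' when constrained, T_theta1) to numerical precision. The reference
#' residue's ring sits in the z = 0 plane with centroid at the origin; the
#' partner centroid lies in the xz half-plane; the free in-plane twist is
#' fixed by the zero-twist convention. When `T_theta1` is `NULL` it is
#' chosen as close to `T_theta2` as the geometry allows (for `P = 0` the
#' two elevations are forced equal). An infeasible (D, P, T_theta1,
#' T_theta2) combination is an error; feasibility is approximately
#' `|T_theta1 - T_theta2| <= P`.
#'
#' @param template_ref,template_partner residue templates
#'   ([make_residue_template()]).
#' @param D target centroid distance, Angstrom (> 2).
#' @param P target inter-plane angle, degrees in \[0, 90\].
#' @param T_theta2 target elevation of the reference centroid over the
#'   partner plane, degrees in \[0, 90\].
#' @param T_theta1 target elevation of the partner centroid over the
#'   reference plane, or `NULL` (free).
#' @return a two-residue `hispi_structure` (chain A, resseq 1 and 2).
#' @export
place_aromatic_pair <- function(template_ref, template_partner, D, P,
                                T_theta2, T_theta1 = NULL) {
  stopifnot(D > 2, P >= 0, P <= 90, T_theta2 >= 0, T_theta2 <= 90)
  ref <- canonicalize_on_ring(template_ref)
  ref$chain <- "A"; ref$resseq <- 1L
  t2 <- deg2rad(T_theta2); Pr <- deg2rad(P)

  solve_psi <- function(t1) {
    # need |u . n2| = sin t2 with u = (cos t1, 0, sin t1),
    # n2 = (sinP cos psi, sinP sin psi, cosP)
    for (sgn in c(1, -1)) {
      num <- sgn * sin(t2) - sin(t1) * cos(Pr)
      den <- cos(t1) * sin(Pr)
      if (abs(den) < 1e-12) {
        if (abs(num) < 1e-9) return(0)
        next
      }
      cpsi <- num / den
      if (abs(cpsi) <= 1 + 1e-9) return(acos(clamp1(cpsi)))
    }
    NULL
  }

  if (is.null(T_theta1)) {
    t1 <- t2
    psi <- solve_psi(t1)
    if (is.null(psi)) { t1 <- pi / 2 - Pr; psi <- solve_psi(t1) }
    if (is.null(psi)) stop("infeasible target combination")
  } else {
    stopifnot(T_theta1 >= 0, T_theta1 <= 90)
    t1 <- deg2rad(T_theta1)
    psi <- solve_psi(t1)
    if (is.null(psi))
      stop(sprintf("infeasible target combination (D=%g, P=%g, Ttheta1=%g, Ttheta2=%g)",
                   D, P, T_theta1, T_theta2))
  }
  u <- c(cos(t1), 0, sin(t1))
  n2 <- c(sin(Pr) * cos(psi), sin(Pr) * sin(psi), cos(Pr))

  partner <- canonicalize_on_ring(template_partner)
  partner <- res_transform(partner, rotation_align(c(0, 0, 1), n2), t = D * u)
  partner$chain <- "A"; partner$resseq <- 2L
  new_structure(rbind(ref, partner), id = "placed_pair")
}

#' Place a cation over an aromatic ring at exact target descriptors
#'
#' The pi ring sits in the z = 0 plane; the cation center atom is placed at
#' distance `D` with off-axis angle `theta1`; for planar cations (Arg,
#' His+) the plane normal is tilted to `theta2` from the centroid-to-cation
#' vector (`theta2 = NULL` places the plane perpendicular to it, i.e.
#' theta2 = 0). A His+ cation is oriented so the designed center nitrogen
#' is strictly the nearer ring nitrogen to the partner centroid.
#'
#' @param ring_template aromatic residue template (the pi system).
#' @param cation_template Lys, Arg or His (HIP) template.
#' @param D target center-to-centroid distance, Angstrom (> 2).
#' @param theta1 target off-axis angle, degrees in \[0, 90\].
#' @param theta2 target cation-plane angle, degrees in \[0, 90\], or `NULL`;
#'   must be `NULL` for Lys (no plane).
#' @return a two-residue `hispi_structure`.
#' @export
place_cation_pair <- function(ring_template, cation_template, D, theta1,
                              theta2 = NULL) {
  stopifnot(D > 2, theta1 >= 0, theta1 <= 90)
  ring <- canonicalize_on_ring(ring_template)
  ring$chain <- "A"; ring$resseq <- 1L
  t1 <- deg2rad(theta1)
  u <- c(sin(t1), 0, cos(t1))              # angle t1 to the ring normal z
  p <- D * u
  resname <- cation_template$resname[1]

  if (resname == "LYS") {
    if (!is.null(theta2)) stop("theta2 undefined for a Lys cation (no plane)")
    nz <- as.vector(atom_xyz(cation_template, "NZ"))
    ce <- as.vector(atom_xyz(cation_template, "CE"))
    R <- rotation_align(unitv(nz - ce), u)  # CE points back toward the ring axis
    cat_atoms <- res_transform(cation_template, R, t = p, center = nz)
  } else {
    t2 <- deg2rad(if (is.null(theta2)) 0 else theta2)
    if (!is.null(theta2)) stopifnot(theta2 >= 0, theta2 <= 90)
    axis <- if (abs(t1) < 1e-12) c(0, 1, 0) else unitv(pracma_cross(u, c(0, 0, 1)))
    m <- as.vector(rotation_about(axis, t2) %*% u)   # cation plane normal
    if (resname == "ARG") {
      cz <- as.vector(atom_xyz(cation_template, "CZ"))
      cat_atoms <- res_transform(cation_template, rotation_align(c(0, 0, 1), m),
                                 t = p, center = cz)
    } else if (resname == "HIS") {
      if (!identical(attr(cation_template, "scenario"), "HIP"))
        warning("His cation template is not HIP; treating it as the cation anyway")
      ctpl <- canonicalize_on_ring(cation_template)
      ne2 <- as.vector(atom_xyz(ctpl, "NE2"))
      cat_atoms <- res_transform(ctpl, rotation_align(c(0, 0, 1), m),
                                 t = p, center = ne2)
      # in-plane spin: put the ring centroid on the far side of NE2 from the
      # pi centroid so NE2 is strictly the closest nitrogen
      w <- u - sum(u * m) * m
      w <- if (vnorm(w) < 1e-9) {
        cand <- c(1, 0, 0) - m[1] * m
        if (vnorm(cand) < 1e-9) cand <- c(0, 1, 0) - m[2] * m
        unitv(cand)
      } else unitv(w)
      ring2 <- build_ring(cat_atoms[!cat_atoms$element %in% c("H", "D"), , drop = FALSE])
      cur <- ring2$centroid - p
      tgt <- vnorm(cur) * w
      ang <- atan2(sum(pracma_cross(cur, tgt) * m), sum(cur * tgt))
      cat_atoms <- res_transform(cat_atoms, rotation_about(m, ang), t = p, center = p)
    } else stop("unsupported cation residue: ", resname)
  }
  cat_atoms$chain <- "A"; cat_atoms$resseq <- 2L
  new_structure(rbind(ring, cat_atoms), id = "placed_cation_pair")
}

microenv_neighbors <- function(his, kind, chain, seq0) {
  heavy <- his[!his$element %in% c("H", "D"), , drop = FALSE]
  xyz <- atom_xyz(heavy, ring_spec()[["HIS"]])
  nb <- ring_neighbor_map[["HIS"]]
  lp_dir <- function(n) {   # in-plane lone-pair / N-H direction
    A <- xyz[n, ]
    -unitv(unitv(xyz[nb[[n]][1], ] - A) + unitv(xyz[nb[[n]][2], ] - A))
  }
  carbonyl <- function(n, seq) {
    A <- xyz[n, ]; d <- lp_dir(n)
    o <- A + 2.9 * d
    rbind(atom_df("O", "O", o, "ACE", chain, seq),
          atom_df("C", "C", o + 1.23 * d, "ACE", chain, seq))
  }
  hydroxyl_donor <- function(n, seq) {
    A <- xyz[n, ]; d <- lp_dir(n)
    o <- A + 2.8 * d
    rbind(atom_df("OG", "O", o, "SER", chain, seq),
          atom_df("HG", "H", o - 0.96 * d, "SER", chain, seq))
  }
  switch(kind,
    acceptor_at_ND1 = rbind(hydroxyl_donor("ND1", seq0), carbonyl("NE2", seq0 + 1L)),
    acceptor_at_NE2 = rbind(hydroxyl_donor("NE2", seq0), carbonyl("ND1", seq0 + 1L)),
    double_donor = rbind(carbonyl("ND1", seq0), carbonyl("NE2", seq0 + 1L)),
    isolated = NULL,
    stop("unknown micro-environment kind: ", kind))
}

deuterate_ring_N <- function(his) {
  sel <- his$name %in% c("HD1", "HE2")
  his$name[sel] <- sub("^H", "D", his$name[sel])
  his$element[sel] <- "D"
  his$is_deuterium[sel] <- TRUE
  his
}

#' Build a fixture structure from a manifest
#'
#' Assembles designed units into one PDB-writable structure, spacing them
#' on a 3-D grid so that no two units come within `min_separation`
#' (default 15 A) and designed pairs are the only minable pairs. Each unit
#' is a list with a `type` field:
#'
#' * `aromatic_pair`: fields a, b (residue names), scenario_a, scenario_b,
#'   D, P, T_theta2, optional T_theta1.
#' * `cation_pair`: fields ring, cation (residue names), scenario_ring,
#'   scenario_cation, D, theta1, optional theta2.
#' * `his_tag`: field n (run length).
#' * `metal_his`: fields metal (element, default ZN), distance (metal to
#'   NE2, default 2.1).
#' * `deuterated_his`: field tautomer (`"epsilon0"`, `"delta0"`,
#'   `"positive"`, or `"none"` for an undeuterated His).
#' * `microenv`: field kind (`"acceptor_at_ND1"`, `"acceptor_at_NE2"`,
#'   `"double_donor"`, `"isolated"`).
#' * `water`: a lone water oxygen.
#'
#' Each unit gets its own chain (A, B, C, ...). The returned manifest echo
#' records each unit's chain and residue keys so tests can derive every
#' expected pipeline output from the design.
#'
#' @param manifest list of unit lists.
#' @param id structure id.
#' @param method recorded experimental method (`"xray"`, `"neutron"`, ...).
#' @param resolution,r_factor recorded metadata.
#' @param min_separation minimum inter-unit atom distance, Angstrom.
#' @return list(structure = `hispi_structure`, units = data.frame echo).
#' @export
make_fixture_structure <- function(manifest, id = "fixture", method = "xray",
                                   resolution = 1.5, r_factor = 0.15,
                                   min_separation = 15) {
  chains <- c(LETTERS, letters)
  if (length(manifest) > length(chains)) stop("too many units")
  all_atoms <- list()
  unit_rows <- list()
  for (i in seq_along(manifest)) {
    u <- manifest[[i]]
    ch <- chains[i]
    atoms <- NULL
    note <- ""
    if (u$type == "aromatic_pair") {
      sa <- if (!is.null(u$scenario_a)) u$scenario_a else default_scenario(u$a)
      sb <- if (!is.null(u$scenario_b)) u$scenario_b else default_scenario(u$b)
      st <- place_aromatic_pair(make_residue_template(u$a, sa),
                                make_residue_template(u$b, sb),
                                D = u$D, P = u$P, T_theta2 = u$T_theta2,
                                T_theta1 = u$T_theta1)
      atoms <- as.data.frame(st)
    } else if (u$type == "cation_pair") {
      sr <- if (!is.null(u$scenario_ring)) u$scenario_ring else default_scenario(u$ring)
      sc <- if (!is.null(u$scenario_cation)) u$scenario_cation else
        if (u$cation == "HIS") "HIP" else default_scenario(u$cation)
      st <- place_cation_pair(make_residue_template(u$ring, sr),
                              make_residue_template(u$cation, sc),
                              D = u$D, theta1 = u$theta1, theta2 = u$theta2)
      atoms <- as.data.frame(st)
    } else if (u$type == "his_tag") {
      n <- u$n
      rows <- list()
      for (k in seq_len(n)) {
        h <- make_residue_template("HIS", "aromatic_CH_only", resseq = k)
        h <- res_transform(h, t = c(8 * (k - 1), 0, 0))
        rows[[k]] <- h
      }
      atoms <- do.call(rbind, rows)
    } else if (u$type == "metal_his") {
      metal <- if (!is.null(u$metal)) u$metal else "ZN"
      dist <- if (!is.null(u$distance)) u$distance else 2.1
      h <- make_residue_template("HIS", "aromatic_CH_only")
      heavy <- h[!h$element %in% c("H", "D"), , drop = FALSE]
      xyz <- atom_xyz(heavy, ring_spec()[["HIS"]])
      nb <- ring_neighbor_map[["HIS"]][["NE2"]]
      d <- -unitv(unitv(xyz[nb[1], ] - xyz["NE2", ]) + unitv(xyz[nb[2], ] - xyz["NE2", ]))
      zn <- atom_df(metal, metal, xyz["NE2", ] + dist * d, metal,
                    chain = "A", resseq = 90L, record = "HETATM")
      atoms <- rbind(h, zn)
    } else if (u$type == "deuterated_his") {
      taut <- u$tautomer
      sc <- switch(taut, epsilon0 = "HIE", delta0 = "HID", positive = "HIP",
                   none = "aromatic_CH_only", stop("unknown tautomer ", taut))
      h <- make_residue_template("HIS", sc)
      if (taut != "none") h <- deuterate_ring_N(h)
      atoms <- h
      note <- taut
    } else if (u$type == "microenv") {
      h <- make_residue_template("HIS", "aromatic_CH_only")
      h <- h[!h$element %in% c("H", "D") | !h$name %in% c("HD1", "HE2"), , drop = FALSE]
      nbs <- microenv_neighbors(h, u$kind, chain = "A", seq0 = 50L)
      atoms <- rbind(h, nbs)
      note <- u$kind
    } else if (u$type == "water") {
      atoms <- atom_df("O", "O", c(0, 0, 0), "HOH", chain = "A", resseq = 900L,
                       record = "HETATM")
    } else stop("unknown unit type: ", u$type)
    atoms$chain <- ch
    # recenter the unit at its own centroid; offsets are applied below
    ctr <- colMeans(as.matrix(atoms[, c("x", "y", "z")]))
    atoms <- res_transform(atoms, t = -ctr)
    all_atoms[[i]] <- atoms
    unit_rows[[i]] <- data.frame(
      unit = i, type = u$type, chain = ch, note = note,
      keys = paste(unique(residue_key(atoms$chain, atoms$resseq, atoms$icode)),
                   collapse = ","),
      stringsAsFactors = FALSE)
  }
  # grid pitch adapted to the largest unit so gaps stay >= min_separation
  radii <- vapply(all_atoms, function(a)
    max(sqrt(rowSums(as.matrix(a[, c("x", "y", "z")])^2))), 0)
  pitch <- 2 * max(radii) + min_separation
  for (i in seq_along(all_atoms)) {
    g <- i - 1
    offset <- pitch * c(g %% 4, (g %/% 4) %% 4, g %/% 16)
    all_atoms[[i]] <- res_transform(all_atoms[[i]], t = offset)
  }
  atoms <- do.call(rbind, all_atoms)
  s <- new_structure(atoms, id = id, resolution = resolution,
                     r_factor = r_factor, method = method)
  # collision check: minimum inter-unit atom distance
  if (length(all_atoms) > 1) {
    for (i in seq_len(length(all_atoms) - 1)) for (j in (i + 1):length(all_atoms)) {
      xi <- as.matrix(all_atoms[[i]][, c("x", "y", "z")])
      xj <- as.matrix(all_atoms[[j]][, c("x", "y", "z")])
      dd <- as.matrix(stats::dist(rbind(xi, xj)))
      if (min(dd[seq_len(nrow(xi)), -seq_len(nrow(xi))]) < min_separation)
        stop("manifest collision: units too close")
    }
  }
  list(structure = s, units = do.call(rbind, unit_rows))
}

FRAGMENT_MAP <- list(
  HIS = list(keep = c("CG", "ND1", "CE1", "NE2", "CD2"), cap = "CB", anchor = "CG"),
  PHE = list(keep = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"), cap = "CB", anchor = "CG"),
  TYR = list(keep = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2", "OH"), cap = "CB", anchor = "CG"),
  TRP = list(keep = c("CG", "CD1", "NE1", "CE2", "CD2", "CE3", "CZ3", "CH2", "CZ2"),
             cap = "CB", anchor = "CG"),
  LYS = list(keep = "NZ", cap = "CE", anchor = "NZ"),
  ARG = list(keep = c("NE", "CZ", "NH1", "NH2"), cap = "CD", anchor = "NE"))

fragment_compound <- function(resname, scenario) {
  switch(resname,
    HIS = if (scenario == "HIP") "4-methylimidazolium" else "4-methylimidazole",
    PHE = "toluene", TYR = "4-methylphenol", TRP = "3-methylindole",
    LYS = "methylammonium", ARG = "methylguanidinium")
}

methyl_hydrogens <- function(capC, anchor) {
  a <- unitv(capC - anchor)          # anchor -> cap axis; H fan out beyond cap
  ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  r0 <- unitv(ref - sum(ref * a) * a)
  q <- unitv(pracma_cross(a, r0))
  t(sapply(0:2, function(k) {
    phi <- deg2rad(120 * k)
    capC + 1.09 * (cos(deg2rad(70.53)) * a +
                   sin(deg2rad(70.53)) * (cos(phi) * r0 + sin(phi) * q))
  }))
}

#' Extract a methyl-capped model-compound fragment
#'
#' Reduces a side chain to its functional group plus exactly one extra
#' carbon converted into a methyl cap: His -> 4-methylimidazole (neutral)
#' or 4-methylimidazolium (HIP, +1); Phe -> toluene; Tyr -> 4-methylphenol;
#' Trp -> 3-methylindole; Lys -> methylammonium (+1); Arg ->
#' methylguanidinium (+1). Retained heavy atoms keep their source
#' coordinates exactly; ring/N hydrogens are placed ideally in the source
#' pose and cap hydrogens at ideal tetrahedral geometry (C-H 1.09 A).
#'
#' @param res_atoms residue atom table (heavy atoms required; hydrogens are
#'   rebuilt).
#' @param scenario protonation scenario (His: `"HID"`, `"HIE"`, `"HIP"`).
#' @return a `hispi_qm_fragment`: list(compound, source_resname, scenario,
#'   charge, atoms = data.frame(element, name, x, y, z)).
#' @export
extract_qm_fragment <- function(res_atoms, scenario = NULL) {
  resname <- res_atoms$resname[1]
  map <- FRAGMENT_MAP[[resname]]
  if (is.null(map)) stop("unsupported residue for fragment extraction: ", resname)
  if (is.null(scenario)) scenario <- default_scenario(resname)
  heavy <- res_atoms[!res_atoms$element %in% c("H", "D"), , drop = FALSE]
  # ideal hydrogens in the source pose (full residue, so every anchor exists)
  with_h <- add_ideal_hydrogens(heavy, scenario)
  keep_heavy <- heavy[heavy$name %in% c(map$keep, map$cap), , drop = FALSE]
  if (!all(c(map$keep, map$cap) %in% keep_heavy$name))
    stop("missing heavy atoms for fragment extraction")
  # hydrogens attached to retained functional-group atoms
  hyd <- with_h[with_h$element %in% c("H", "D"), , drop = FALSE]
  keep_h <- list()
  for (i in seq_len(nrow(hyd))) {
    hx <- as.numeric(hyd[i, c("x", "y", "z")])
    for (nm in map$keep) {
      ax <- as.vector(atom_xyz(keep_heavy, nm))
      if (vnorm(hx - ax) <= 1.3) { keep_h[[length(keep_h) + 1]] <- hyd[i, ]; break }
    }
  }
  capC <- as.vector(atom_xyz(keep_heavy, map$cap))
  anchor <- as.vector(atom_xyz(keep_heavy, map$anchor))
  mh <- methyl_hydrogens(capC, anchor)
  cap_rows <- do.call(rbind, lapply(1:3, function(k)
    atom_df(paste0("H", map$cap, k), "H", mh[k, ], resname)))
  atoms <- rbind(keep_heavy, do.call(rbind, c(keep_h, list(cap_rows))))
  charge <- if (resname %in% c("LYS", "ARG") ||
                (resname == "HIS" && scenario == "HIP")) 1L else 0L
  structure(list(compound = fragment_compound(resname, scenario),
                 source_resname = resname, scenario = scenario,
                 charge = charge,
                 atoms = data.frame(element = atoms$element, name = atoms$name,
                                    x = atoms$x, y = atoms$y, z = atoms$z,
                                    stringsAsFactors = FALSE)),
            class = "hispi_qm_fragment")
}

#' Write fragments to an XYZ file
#'
#' Standard XYZ: atom-count line, comment line carrying the total charge
#' and provenance, then one `element x y z` line per atom at 6-decimal
#' precision. A list of fragments is concatenated into one block with the
#' summed charge.
#'
#' @param fragment a `hispi_qm_fragment` or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(fragment, path) {
  frags <- if (inherits(fragment, "hispi_qm_fragment")) list(fragment) else fragment
  atoms <- do.call(rbind, lapply(frags, `[[`, "atoms"))
  charge <- sum(vapply(frags, `[[`, 0L, "charge"))
  compounds <- paste(vapply(frags, `[[`, "", "compound"), collapse = "+")
  lines <- c(sprintf("%d", nrow(atoms)),
             sprintf("charge=%d compound=%s", charge, compounds),
             sprintf("%-2s %12.6f %12.6f %12.6f", atoms$element,
                     atoms$x, atoms$y, atoms$z))
  writeLines(lines, path)
  invisible(path)
}

#' Read an XYZ file
#'
#' @param path file path.
#' @return list(atoms = data.frame(element, x, y, z), comment).
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- as.integer(lines[1])
  body <- lines[3:(2 + n)]
  parts <- strsplit(trimws(body), "\\s+")
  data <- do.call(rbind, lapply(parts, function(p)
    data.frame(element = p[1], x = as.numeric(p[2]), y = as.numeric(p[3]),
               z = as.numeric(p[4]), stringsAsFactors = FALSE)))
  list(atoms = data, comment = lines[2])
}
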