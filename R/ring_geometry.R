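# Ring geometry: aromatic ring objects, the D/P/T-theta descriptors for
# ring-ring pairs, the D/theta1/theta2 descriptors for cation-pi pairs, and
# idealized hydrogen placement.
#
# Conventions: all reported angles are folded into [0, 90] degrees because
# ring normals carry no physical sign; elevation angles are unsigned.
# arcsin arguments are clamped to [-1, 1] before evaluation.

#' Ring atom names per aromatic residue
#'
#' His: 5-membered imidazole; Phe/Tyr: benzene ring; Trp: full 9-atom indole
#' by default, or the 6-membered benzene sub-ring when
#' `trp_ring = "six"`.
#'
#' @param trp_ring `"indole"` (default) or `"six"`.
#' @return named list residue name -> ordered ring atom names.
#' @export
ring_spec <- function(trp_ring = c("indole", "six")) {
  trp_ring <- match.arg(trp_ring)
  list(
    HIS = c("CG", "ND1", "CE1", "NE2", "CD2"),
    PHE = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
    TYR = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
    TRP = if (trp_ring == "indole")
      c("CG", "CD1", "NE1", "CE2", "CD2", "CE3", "CZ3", "CH2", "CZ2")
    else c("CD2", "CE3", "CZ3", "CH2", "CZ2", "CE2"))
}

atom_xyz <- function(res_atoms, names) {
  idx <- match(names, res_atoms$name)
  if (anyNA(idx)) stop("missing atom(s): ", paste(names[is.na(idx)], collapse = ", "))
  m <- as.matrix(res_atoms[idx, c("x", "y", "z")])
  dimnames(m) <- list(names, NULL)
  m
}

#' Build an aromatic ring object
#'
#' Centroid is the arithmetic mean of the ring atoms; the normal is the unit
#' minimizer of squared out-of-plane deviations (least-squares plane, SVD).
#' The sign of the normal is unspecified: every downstream angle is folded.
#'
#' @param res_atoms atom table of one residue ([residue_atoms()]).
#' @param planarity_tol maximum allowed out-of-plane RMSD, Angstrom.
#' @param trp_ring Trp ring convention, see [ring_spec()].
#' @return a `hispi_ring`: list(residue, resname, xyz, centroid, normal,
#'   planarity_rmsd).
#' @export
build_ring <- function(res_atoms, planarity_tol = 0.1, trp_ring = "indole") {
  resname <- res_atoms$resname[1]
  spec <- ring_spec(trp_ring)[[resname]]
  if (is.null(spec)) stop("no ring defined for residue ", resname)
  xyz <- atom_xyz(res_atoms, spec)
  pl <- fit_plane(xyz)
  if (pl$rmsd > planarity_tol)
    stop(sprintf("ring planarity RMSD %.3f A exceeds tolerance %.3f A (%s %s)",
                 pl$rmsd, planarity_tol, resname,
                 residue_key(res_atoms$chain[1], res_atoms$resseq[1], res_atoms$icode[1])))
  structure(list(
    residue = residue_key(res_atoms$chain[1], res_atoms$resseq[1], res_atoms$icode[1]),
    resname = resname, xyz = xyz,
    centroid = pl$centroid, normal = pl$normal, planarity_rmsd = pl$rmsd),
    class = "hispi_ring")
}

#' Aromatic pair descriptors D, P, T-theta-1, T-theta-2
#'
#' `D` is the centroid-centroid distance; `P` the folded angle between the
#' ring normals; `T_theta1` the elevation of the partner centroid above the
#' reference ring plane (`asin(|d . n_ref| / D)`), `T_theta2` the elevation
#' of the reference centroid above the partner plane. 90 deg = directly over
#' the face, 0 deg = in-plane.
#'
#' @param ring_ref reference ring (His, when exactly one member is His).
#' @param ring_partner partner ring.
#' @return list(D, P, T_theta1, T_theta2), Angstrom / degrees.
#' @export
aromatic_pair_geometry <- function(ring_ref, ring_partner) {
  d <- ring_partner$centroid - ring_ref$centroid
  D <- vnorm(d)
  if (D < 0.1) stop("coincident ring centroids")
  list(
    D = D,
    P = fold90(angle_deg(ring_ref$normal, ring_partner$normal)),
    T_theta1 = rad2deg(asin(clamp1(abs(sum(d * ring_ref$normal)) / D))),
    T_theta2 = rad2deg(asin(clamp1(abs(sum(-d * ring_partner$normal)) / D))))
}

#' Build a cation site for Lys, Arg or protonated His
#'
#' Lys: charge center NZ, no plane. Arg: center CZ with the guanidinium
#' plane (NE, CZ, NH1, NH2). His used as a cation: the ring nitrogen (NE2 or
#' ND1) closest to the partner centroid, ties to NE2, with the imidazole
#' plane; the choice is recorded in `chosen_nitrogen`.
#'
#' @param res_atoms atom table of the cation residue.
#' @param partner_centroid 3-vector; required for His.
#' @return a `hispi_cation_site`: list(residue, resname, center_name, center,
#'   plane_normal (or NULL), chosen_nitrogen (or NA)).
#' @export
cation_site <- function(res_atoms, partner_centroid = NULL) {
  resname <- res_atoms$resname[1]
  key <- residue_key(res_atoms$chain[1], res_atoms$resseq[1], res_atoms$icode[1])
  if (resname == "LYS") {
    site <- list(residue = key, resname = resname, center_name = "NZ",
                 center = as.vector(atom_xyz(res_atoms, "NZ")),
                 plane_normal = NULL, chosen_nitrogen = NA_character_)
  } else if (resname == "ARG") {
    pl <- fit_plane(atom_xyz(res_atoms, c("NE", "CZ", "NH1", "NH2")))
    site <- list(residue = key, resname = resname, center_name = "CZ",
                 center = as.vector(atom_xyz(res_atoms, "CZ")),
                 plane_normal = pl$normal, chosen_nitrogen = NA_character_)
  } else if (resname == "HIS") {
    if (is.null(partner_centroid))
      stop("partner_centroid required to choose the His cation nitrogen")
    site <- his_plus_cation_site(res_atoms, partner_centroid)
  } else stop("no cation site defined for residue ", resname)
  structure(site, class = "hispi_cation_site")
}

#' Choose the His+ cation nitrogen
#'
#' For doubly protonated His acting as a cation, the charge center is
#' whichever ring nitrogen (NE2 or ND1) is closer to the partner ring
#' centroid; exact ties go to NE2.
#'
#' @param res_atoms His atom table (must contain NE2 and ND1).
#' @param partner_centroid 3-vector.
#' @return a `hispi_cation_site` with `chosen_nitrogen` set.
#' @export
his_plus_cation_site <- function(res_atoms, partner_centroid) {
  xyz <- atom_xyz(res_atoms, c("NE2", "ND1"))
  d_ne2 <- vnorm(xyz["NE2", ] - partner_centroid)
  d_nd1 <- vnorm(xyz["ND1", ] - partner_centroid)
  chosen <- if (d_ne2 <= d_nd1) "NE2" else "ND1"
  pl <- fit_plane(atom_xyz(res_atoms, ring_spec()[["HIS"]]))
  structure(list(
    residue = residue_key(res_atoms$chain[1], res_atoms$resseq[1], res_atoms$icode[1]),
    resname = "HIS", center_name = chosen, center = xyz[chosen, ],
    plane_normal = pl$normal, chosen_nitrogen = chosen),
    class = "hispi_cation_site")
}

#' Cation-pi descriptors D, theta1, theta2
#'
#' `D` is the distance from the cation center atom to the ring centroid;
#' `theta1` the folded angle between the pi-ring normal and the
#' centroid-to-cation vector (0 deg = on-axis over the face); `theta2` the
#' folded angle between the cation-plane normal and the D vector, defined
#' only when the cation has a plane (Arg, His+).
#'
#' @param pi_ring a `hispi_ring`.
#' @param cation a `hispi_cation_site`.
#' @return list(D, theta1, theta2 (NA for Lys), chosen_nitrogen).
#' @export
cation_pi_geometry <- function(pi_ring, cation) {
  d <- cation$center - pi_ring$centroid
  D <- vnorm(d)
  if (D < 0.1) stop("cation atom coincident with ring centroid")
  theta2 <- if (is.null(cation$plane_normal)) NA_real_
    else fold90(angle_deg(cation$plane_normal, d))
  list(D = D,
       theta1 = fold90(angle_deg(pi_ring$normal, d)),
       theta2 = theta2,
       chosen_nitrogen = cation$chosen_nitrogen)
}

# ---- idealized hydrogen placement ---------------------------------------

BOND_NH <- 1.01
BOND_CH <- 1.08
BOND_OH <- 0.96

# which hydrogens exist on which heavy atom, per residue and scenario.
# value: list(parent = heavy atom, hname, kind = bisector|amine3|oh|guanidinium)
his_ring_CH <- list(c("CE1", "HE1"), c("CD2", "HD2"))

ring_h_sites <- function(resname, scenario) {
  pair <- function(p, h) list(parent = p, hname = h, kind = "bisector")
  sites <- switch(resname,
    HIS = {
      s <- lapply(his_ring_CH, function(x) pair(x[1], x[2]))
      if (scenario %in% c("HID", "HIP")) s <- c(s, list(pair("ND1", "HD1")))
      if (scenario %in% c("HIE", "HIP")) s <- c(s, list(pair("NE2", "HE2")))
      s
    },
    PHE = list(pair("CD1", "HD1"), pair("CE1", "HE1"), pair("CZ", "HZ"),
               pair("CE2", "HE2"), pair("CD2", "HD2")),
    TYR = c(list(pair("CD1", "HD1"), pair("CE1", "HE1"), pair("CE2", "HE2"),
                 pair("CD2", "HD2")),
            list(list(parent = "OH", hname = "HH", kind = "oh"))),
    TRP = list(pair("CD1", "HD1"), pair("NE1", "HE1"), pair("CE3", "HE3"),
               pair("CZ3", "HZ3"), pair("CH2", "HH2"), pair("CZ2", "HZ2")),
    LYS = list(list(parent = "NZ", hname = "HZ", kind = "amine3")),
    ARG = list(pair("NE", "HE"),
               list(parent = "NH1", hname = "HH1", kind = "guanidinium"),
               list(parent = "NH2", hname = "HH2", kind = "guanidinium")),
    stop("no hydrogen template for residue ", resname))
  sites
}

# two covalent ring neighbours of each H-bearing ring atom
ring_neighbor_map <- list(
  HIS = list(CE1 = c("ND1", "NE2"), CD2 = c("CG", "NE2"),
             ND1 = c("CG", "CE1"), NE2 = c("CE1", "CD2")),
  PHE = list(CD1 = c("CG", "CE1"), CE1 = c("CD1", "CZ"), CZ = c("CE1", "CE2"),
             CE2 = c("CZ", "CD2"), CD2 = c("CE2", "CG")),
  TYR = list(CD1 = c("CG", "CE1"), CE1 = c("CD1", "CZ"),
             CE2 = c("CZ", "CD2"), CD2 = c("CE2", "CG")),
  TRP = list(CD1 = c("CG", "NE1"), NE1 = c("CD1", "CE2"),
             CE3 = c("CD2", "CZ3"), CZ3 = c("CE3", "CH2"),
             CH2 = c("CZ3", "CZ2"), CZ2 = c("CH2", "CE2")),
  ARG = list(NE = c("CD", "CZ")))

h_row <- function(template_row, name, xyz, element = "H") {
  r <- template_row
  r$name <- name
  r$x <- xyz[1]; r$y <- xyz[2]; r$z <- xyz[3]
  r$element <- element
  r$is_deuterium <- element == "D"
  r$occupancy <- 1
  r$altloc <- ""
  r
}

#' Place idealized hydrogens on a residue
#'
#' Standard idealized geometry: aromatic C-H and ring N-H in the ring plane
#' along the external bisector (C-H 1.08 A, N-H 1.01 A); Lys NZ three
#' tetrahedral hydrogens staggered relative to CE-CD; Arg guanidinium
#' hydrogens in-plane; Tyr hydroxyl in-plane at 109.5 deg. Existing
#' hydrogens or deuteriums bonded to rebuilt sites are replaced.
#'
#' Scenarios for His: `HID` (ND1 protonated), `HIE` (NE2 protonated), `HIP`
#' (both, the imidazolium cation), `aromatic_CH_only` (ring C-H only). For
#' Phe/Tyr/Trp use `aromatic_CH_only` (places all standard side-chain H,
#' including Trp NE1-H and the Tyr hydroxyl); for Lys `lys_NZ3`; for Arg
#' `arg_guanidinium`.
#'
#' @param res_atoms atom table of one residue.
#' @param scenario one of `"HID"`, `"HIE"`, `"HIP"`, `"aromatic_CH_only"`,
#'   `"lys_NZ3"`, `"arg_guanidinium"`.
#' @return the residue atom table with hydrogens added.
#' @export
add_ideal_hydrogens <- function(res_atoms,
                                scenario = c("aromatic_CH_only", "HID", "HIE",
                                             "HIP", "lys_NZ3", "arg_guanidinium")) {
  scenario <- match.arg(scenario)
  resname <- res_atoms$resname[1]
  if (resname == "HIS" && scenario %in% c("lys_NZ3", "arg_guanidinium"))
    stop("invalid scenario for His")
  if (resname %in% c("LYS") && !scenario %in% "lys_NZ3")
    scenario <- "lys_NZ3"
  if (resname %in% c("ARG") && !scenario %in% "arg_guanidinium")
    scenario <- "arg_guanidinium"
  sites <- ring_h_sites(resname, scenario)
  heavy <- res_atoms[!res_atoms$element %in% c("H", "D"), , drop = FALSE]
  coords <- function(nm) as.vector(atom_xyz(heavy, nm))
  # drop old hydrogens attached (<= 1.3 A) to any rebuilt parent
  parents <- vapply(sites, `[[`, "", "parent")
  keep <- rep(TRUE, nrow(res_atoms))
  hyd <- which(res_atoms$element %in% c("H", "D"))
  for (i in hyd) {
    p <- as.numeric(res_atoms[i, c("x", "y", "z")])
    dmin <- min(vapply(parents, function(nm) vnorm(p - coords(nm)), 0))
    if (dmin <= 1.3) keep[i] <- FALSE
  }
  out <- res_atoms[keep, , drop = FALSE]
  template <- heavy[1, , drop = FALSE]

  ring_normal <- NULL
  if (resname %in% names(ring_spec()))
    ring_normal <- fit_plane(atom_xyz(heavy, ring_spec()[[resname]]))$normal

  new_rows <- list()
  for (s in sites) {
    A <- coords(s$parent)
    blen <- if (startsWith(s$parent, "C")) BOND_CH
            else if (startsWith(s$parent, "O")) BOND_OH else BOND_NH
    if (s$kind == "bisector") {
      nb <- ring_neighbor_map[[resname]][[s$parent]]
      d <- -unitv(unitv(coords(nb[1]) - A) + unitv(coords(nb[2]) - A))
      new_rows[[length(new_rows) + 1]] <- h_row(template, s$hname, A + blen * d)
    } else if (s$kind == "oh") {
      cz <- coords("CZ")
      v <- unitv(cz - A)
      p <- unitv(pracma_cross(ring_normal, v))
      d <- cos(deg2rad(109.5)) * v + sin(deg2rad(109.5)) * p
      new_rows[[length(new_rows) + 1]] <- h_row(template, s$hname, A + blen * d)
    } else if (s$kind == "amine3") {
      a <- unitv(A - coords("CE"))                       # CE -> NZ axis
      r0 <- coords("CD") - coords("CE")
      r0 <- r0 - sum(r0 * a) * a                          # CD azimuth reference
      r0 <- unitv(r0)
      q <- unitv(pracma_cross(a, r0))
      for (k in 1:3) {
        phi <- deg2rad(60 + 120 * (k - 1))                # staggered vs CD at 0
        d <- cos(deg2rad(70.53)) * a +
          sin(deg2rad(70.53)) * (cos(phi) * r0 + sin(phi) * q)
        new_rows[[length(new_rows) + 1]] <-
          h_row(template, paste0(s$hname, k), A + blen * d)
      }
    } else if (s$kind == "guanidinium") {
      pl <- fit_plane(atom_xyz(heavy, c("NE", "CZ", "NH1", "NH2")))
      v <- unitv(coords("CZ") - A)
      p <- unitv(pracma_cross(pl$normal, v))
      for (k in 1:2) {
        sgn <- if (k == 1) 1 else -1
        d <- -0.5 * v + sgn * (sqrt(3) / 2) * p           # H-N-CZ = 120 deg
        new_rows[[length(new_rows) + 1]] <-
          h_row(template, paste0(s$hname, k), A + blen * d)
      }
    }
  }
  rbind(out, do.call(rbind, new_rows))
}
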