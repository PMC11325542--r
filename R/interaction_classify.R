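# Geometric interaction classification: pi-stacked, cation-pi, CH-pi and
# hydrogen bonds, plus the binding-energy threshold filter and the
# per-class energy summary. Labels are a set: a geometry may satisfy
# several criteria at once (stacked and CH-pi frequently co-occur).

#' Geometric classification thresholds
#'
#' Defaults are standard literature criteria for each interaction class;
#' every value is configurable and should be recorded alongside any output.
#' `stack_min_T_theta2` is an optional extra bound on the stacked class
#' (off, `NULL`, by default).
#'
#' @param stack_max_D,stack_max_P stacked: max centroid distance (A), max
#'   inter-plane angle (deg).
#' @param catpi_max_D,catpi_max_theta1 cation-pi: max center-centroid
#'   distance (A), max off-axis angle (deg).
#' @param chpi_max_C_centroid,chpi_max_H_projection,chpi_min_CH_centroid_angle
#'   CH-pi: max donor-C to centroid distance (A), max in-plane distance of
#'   the H projection from the centroid (A), min C-H...centroid angle (deg).
#' @param hb_max_DA,hb_min_DHA_angle,hb_max_plane_elevation H-bond: max
#'   donor-acceptor distance (A), min donor-H-acceptor angle (deg), max
#'   elevation of the bond vector above the His ring plane (deg) when a His
#'   ring nitrogen is involved (in-plane lone-pair constraint).
#' @param energy_cutoff kcal/mol; pairs with binding energy strictly below
#'   this are retained by [filter_by_energy()].
#' @param stack_min_T_theta2 optional min T-theta-2 for stacked, or `NULL`.
#' @return a `hispi_thresholds` list.
#' @export
geometry_thresholds <- function(stack_max_D = 5.5, stack_max_P = 30,
                                catpi_max_D = 6.0, catpi_max_theta1 = 60,
                                chpi_max_C_centroid = 4.5,
                                chpi_max_H_projection = 1.8,
                                chpi_min_CH_centroid_angle = 120,
                                hb_max_DA = 3.5, hb_min_DHA_angle = 120,
                                hb_max_plane_elevation = 45,
                                energy_cutoff = -1,
                                stack_min_T_theta2 = NULL) {
  thr <- list(stack_max_D = stack_max_D, stack_max_P = stack_max_P,
              catpi_max_D = catpi_max_D, catpi_max_theta1 = catpi_max_theta1,
              chpi_max_C_centroid = chpi_max_C_centroid,
              chpi_max_H_projection = chpi_max_H_projection,
              chpi_min_CH_centroid_angle = chpi_min_CH_centroid_angle,
              hb_max_DA = hb_max_DA, hb_min_DHA_angle = hb_min_DHA_angle,
              hb_max_plane_elevation = hb_max_plane_elevation,
              energy_cutoff = energy_cutoff,
              stack_min_T_theta2 = stack_min_T_theta2)
  stopifnot(all(unlist(thr[c(1, 3, 5, 6, 8)]) > 0))
  structure(thr, class = "hispi_thresholds")
}

#' Classify a ring-ring geometry as pi-stacked
#'
#' TRUE iff `D <= stack_max_D` and `P <= stack_max_P` (and, when the
#' optional knob is set, `T_theta2 >= stack_min_T_theta2`).
#'
#' @param geom an [aromatic_pair_geometry()] result.
#' @param thr a [geometry_thresholds()].
#' @export
classify_stacked <- function(geom, thr = geometry_thresholds()) {
  ok <- geom$D <= thr$stack_max_D && geom$P <= thr$stack_max_P
  if (ok && !is.null(thr$stack_min_T_theta2))
    ok <- geom$T_theta2 >= thr$stack_min_T_theta2
  ok
}

#' Classify a cation-ring geometry as cation-pi
#'
#' TRUE iff `D <= catpi_max_D` and `theta1 <= catpi_max_theta1`.
#'
#' @param geom a [cation_pi_geometry()] result.
#' @param thr a [geometry_thresholds()].
#' @export
classify_cation_pi <- function(geom, thr = geometry_thresholds()) {
  geom$D <= thr$catpi_max_D && geom$theta1 <= thr$catpi_max_theta1
}

# (heavy, H) covalent pairs in a residue, by <=1.3 A distance
attached_hydrogens <- function(res_atoms, heavy_prefix = NULL) {
  hyd <- res_atoms[res_atoms$element %in% c("H", "D"), , drop = FALSE]
  heavy <- res_atoms[!res_atoms$element %in% c("H", "D"), , drop = FALSE]
  if (!is.null(heavy_prefix))
    heavy <- heavy[startsWith(heavy$element, heavy_prefix), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(hyd))) {
    hx <- as.numeric(hyd[i, c("x", "y", "z")])
    for (j in seq_len(nrow(heavy))) {
      ax <- as.numeric(heavy[j, c("x", "y", "z")])
      if (vnorm(hx - ax) <= 1.3)
        out[[length(out) + 1]] <- list(heavy = heavy$name[j], heavy_xyz = ax,
                                       h = hyd$name[i], h_xyz = hx)
    }
  }
  out
}

#' Find CH-pi contacts from a donor residue to an acceptor ring
#'
#' One contact per C-H bond satisfying all three criteria: donor carbon
#' within `chpi_max_C_centroid` of the acceptor centroid; the hydrogen's
#' projection onto the acceptor plane within `chpi_max_H_projection` of the
#' centroid; C-H...centroid angle at least `chpi_min_CH_centroid_angle`.
#' The donor must carry explicit hydrogens (from the file or from
#' [add_ideal_hydrogens()]).
#'
#' @param donor_res_atoms donor residue atom table with hydrogens.
#' @param acceptor_ring a `hispi_ring`.
#' @param thr a [geometry_thresholds()].
#' @return data.frame of contacts: donor_C, donor_H, C_centroid, H_projection,
#'   CH_centroid_angle. Zero rows when none qualify.
#' @export
classify_ch_pi <- function(donor_res_atoms, acceptor_ring,
                           thr = geometry_thresholds()) {
  ch <- attached_hydrogens(donor_res_atoms, heavy_prefix = "C")
  if (!length(ch)) stop("donor residue has no C-H hydrogens")
  ctr <- acceptor_ring$centroid
  n <- acceptor_ring$normal
  rows <- list()
  for (b in ch) {
    dC <- vnorm(b$heavy_xyz - ctr)
    if (dC > thr$chpi_max_C_centroid) next
    hp <- b$h_xyz - sum((b$h_xyz - ctr) * n) * n       # H projected onto plane
    dproj <- vnorm(hp - ctr)
    if (dproj > thr$chpi_max_H_projection) next
    ang <- angle_deg(b$h_xyz - b$heavy_xyz, ctr - b$heavy_xyz)
    # C-H...centroid angle: angle at H between H->C and H->centroid
    ang_at_H <- angle_deg(b$heavy_xyz - b$h_xyz, ctr - b$h_xyz)
    if (ang_at_H < thr$chpi_min_CH_centroid_angle) next
    rows[[length(rows) + 1]] <- data.frame(
      donor_C = b$heavy, donor_H = b$h, C_centroid = dC, H_projection = dproj,
      CH_centroid_angle = ang_at_H, CH_to_centroid_tilt = ang,
      stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(donor_C = character(0), donor_H = character(0),
               C_centroid = numeric(0), H_projection = numeric(0),
               CH_centroid_angle = numeric(0), CH_to_centroid_tilt = numeric(0),
               stringsAsFactors = FALSE)
}

#' Evaluate a candidate hydrogen bond
#'
#' TRUE iff donor-acceptor distance `<= hb_max_DA`, donor-H-acceptor angle
#' `>= hb_min_DHA_angle`, and -- when a His ring nitrogen is the donor or
#' acceptor -- the elevation of the bond vector above that His ring plane is
#' `<= hb_max_plane_elevation` (the imidazole lone pair / N-H lies in the
#' ring plane). With `donor_H = NULL` (e.g. a water whose hydrogens are not
#' modelled) the angle test is skipped and the call is distance-based only.
#'
#' @param donor_xyz,acceptor_xyz 3-vectors, donor and acceptor heavy atoms.
#' @param donor_H_xyz 3-vector or NULL.
#' @param his_ring a `hispi_ring` when a His ring N participates, else NULL.
#' @param thr a [geometry_thresholds()].
#' @return list(is_hbond, DA, DHA (NA when skipped), plane_elevation (NA
#'   when no His ring)).
#' @export
classify_h_bond <- function(donor_xyz, donor_H_xyz, acceptor_xyz,
                            his_ring = NULL, thr = geometry_thresholds()) {
  DA <- vnorm(acceptor_xyz - donor_xyz)
  DHA <- if (is.null(donor_H_xyz)) NA_real_
    else angle_deg(donor_xyz - donor_H_xyz, acceptor_xyz - donor_H_xyz)
  elev <- NA_real_
  if (!is.null(his_ring)) {
    v <- unitv(acceptor_xyz - donor_xyz)
    elev <- rad2deg(asin(clamp1(abs(sum(v * his_ring$normal)))))
  }
  ok <- DA <= thr$hb_max_DA &&
    (is.na(DHA) || DHA >= thr$hb_min_DHA_angle) &&
    (is.na(elev) || elev <= thr$hb_max_plane_elevation)
  list(is_hbond = ok, DA = DA, DHA = DHA, plane_elevation = elev)
}

# donor (heavy,H) pairs and acceptor atoms of a residue with explicit H.
# Donors: N or O heavy atoms with an attached hydrogen. Acceptors: any O,
# plus ring N without an attached hydrogen. Water O without H is both
# donor-eligible (orientation-free) and acceptor-capable.
hbond_candidates <- function(res_atoms) {
  heavy <- res_atoms[!res_atoms$element %in% c("H", "D"), , drop = FALSE]
  no <- heavy[heavy$element %in% c("N", "O"), , drop = FALSE]
  bonds <- attached_hydrogens(res_atoms)
  donors <- Filter(function(b) b$heavy %in% no$name, bonds)
  has_h <- vapply(bonds, `[[`, "", "heavy")
  acceptors <- list()
  for (i in seq_len(nrow(no))) {
    nm <- no$name[i]
    is_water <- no$resname[i] %in% c("HOH", "WAT", "DOD")
    is_O <- no$element[i] == "O"
    is_free_ringN <- no$element[i] == "N" && !(nm %in% has_h)
    if (is_O || is_free_ringN || is_water)
      acceptors[[length(acceptors) + 1]] <-
        list(name = nm, xyz = as.numeric(no[i, c("x", "y", "z")]),
             element = no$element[i])
    if (is_water && !(nm %in% has_h))   # H-less water: orientation-free donor
      donors[[length(donors) + 1]] <-
        list(heavy = nm, heavy_xyz = as.numeric(no[i, c("x", "y", "z")]),
             h = NA_character_, h_xyz = NULL)
  }
  list(donors = donors, acceptors = acceptors)
}

#' Label one mined pair with its interaction types
#'
#' Runs every classifier applicable to the pair family: stacked for
#' ring-ring pairs; cation-pi when a cation role exists; CH-pi in both
#' donor directions; hydrogen bonds between side-chain donor/acceptor atoms
#' of the two residues. When a residue lacks explicit hydrogens they are
#' placed with [add_ideal_hydrogens()] under `scenario` (His) or the
#' residue's standard scenario; the scenario used is recorded. Returns
#' `{other}` when no criterion fires.
#'
#' @param pair one row of a [mine()] result.
#' @param s the altloc-resolved `hispi_structure`.
#' @param scenario His protonation scenario: `"HIE"`, `"HID"` or `"HIP"`.
#' @param thr a [geometry_thresholds()].
#' @return list(labels, measurements, scenario).
#' @export
label_pair <- function(pair, s, scenario = "HIE", thr = geometry_thresholds()) {
  prep <- function(key) {
    a <- residue_atoms(s, key)
    if (!any(a$element %in% c("H", "D"))) {
      sc <- switch(a$resname[1], HIS = scenario, LYS = "lys_NZ3",
                   ARG = "arg_guanidinium", "aromatic_CH_only")
      a <- tryCatch(add_ideal_hydrogens(a, sc), error = function(e) a)
    }
    a
  }
  a1 <- prep(pair$res1); a2 <- prep(pair$res2)
  labels <- character(0)
  meas <- list(scenario = scenario)

  ring1 <- tryCatch(build_ring(a1), error = function(e) NULL)
  ring2 <- tryCatch(build_ring(a2), error = function(e) NULL)

  if (pair$family == "aromatic" && !is.null(ring1) && !is.null(ring2)) {
    g <- aromatic_pair_geometry(ring1, ring2)
    meas$aromatic <- g
    if (classify_stacked(g, thr)) labels <- c(labels, "stacked")
  }
  if (pair$family == "cation_pi" && !is.null(ring1)) {
    site <- cation_site(a2, partner_centroid = ring1$centroid)
    g <- cation_pi_geometry(ring1, site)
    meas$cation_pi <- g
    if (classify_cation_pi(g, thr)) labels <- c(labels, "cation_pi")
  }
  # CH-pi, both directions where an acceptor ring exists
  chpi <- list()
  for (dir in list(list(d = a1, r = ring2, tag = "res1_donates"),
                   list(d = a2, r = ring1, tag = "res2_donates"))) {
    if (is.null(dir$r)) next
    cc <- tryCatch(classify_ch_pi(dir$d, dir$r, thr), error = function(e) NULL)
    if (!is.null(cc) && nrow(cc)) chpi[[dir$tag]] <- cc
  }
  if (length(chpi)) { labels <- c(labels, "ch_pi"); meas$ch_pi <- chpi }

  # hydrogen bonds across the pair
  c1 <- hbond_candidates(a1); c2 <- hbond_candidates(a2)
  his_ring_for <- function(atoms, ring, atom_name) {
    if (!is.null(ring) && atoms$resname[1] == "HIS" &&
        atom_name %in% c("ND1", "NE2")) ring else NULL
  }
  hb <- list()
  test_hb <- function(don, don_atoms, don_ring, acc, acc_atoms, acc_ring) {
    hr <- his_ring_for(don_atoms, don_ring, don$heavy)
    if (is.null(hr)) hr <- his_ring_for(acc_atoms, acc_ring, acc$name)
    r <- classify_h_bond(don$heavy_xyz, don$h_xyz, acc$xyz, hr, thr)
    if (r$is_hbond)
      hb[[length(hb) + 1]] <<- c(list(donor = don$heavy, acceptor = acc$name), r)
  }
  for (don in c1$donors) for (acc in c2$acceptors)
    test_hb(don, a1, ring1, acc, a2, ring2)
  for (don in c2$donors) for (acc in c1$acceptors)
    test_hb(don, a2, ring2, acc, a1, ring1)
  if (length(hb)) { labels <- c(labels, "h_bond"); meas$h_bond <- hb }

  labels <- unique(labels)
  if (!length(labels)) labels <- "other"
  list(labels = labels, measurements = meas, scenario = scenario)
}

#' Apply the binding-energy threshold filter
#'
#' Retains pairs whose binding energy is strictly below `cutoff`
#' (default -1 kcal/mol). Pairs without an energy entry are dropped and the
#' dropped count reported via `message()`.
#'
#' @param labeled_pairs data.frame with a `pair_id` column.
#' @param energy_table data.frame with `pair_id` and `energy` (kcal/mol).
#' @param cutoff kcal/mol.
#' @return the retained subset, with an `energy` column attached.
#' @export
filter_by_energy <- function(labeled_pairs, energy_table, cutoff = -1) {
  if (!all(c("pair_id", "energy") %in% names(energy_table)))
    stop("energy table must have columns pair_id, energy")
  e <- energy_table$energy[match(labeled_pairs$pair_id, energy_table$pair_id)]
  missing <- sum(is.na(e))
  if (missing) message(missing, " pair(s) without an energy entry dropped")
  keep <- !is.na(e) & e < cutoff
  out <- labeled_pairs[keep, , drop = FALSE]
  out$energy <- e[keep]
  rownames(out) <- NULL
  out
}

#' Summarize binding energies per pair family, label and phase
#'
#' Arithmetic mean and sample standard deviation per
#' (family, label, phase) cell; a single-entry cell reports SD 0 with
#' `n = 1`. Empty cells are omitted.
#'
#' @param df data.frame with columns family, label, phase, energy.
#' @return data.frame: family, label, phase, n, mean, sd.
#' @export
summarize_energies <- function(df) {
  stopifnot(all(c("family", "label", "phase", "energy") %in% names(df)))
  key <- interaction(df$family, df$label, df$phase, drop = TRUE)
  rows <- lapply(split(df, key), function(g) {
    data.frame(family = g$family[1], label = g$label[1], phase = g$phase[1],
               n = nrow(g), mean = mean(g$energy),
               sd = if (nrow(g) > 1) stats::sd(g$energy) else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$family, out$label, out$phase), , drop = FALSE]
}
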