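# Histidine protonation-state assignment: directly from deuterium positions
# in neutron structures, or indirectly from hydrogen-bond patterns under the
# three protonation scenarios, plus pKa categorization.

#' His tautomer from deuterium positions
#'
#' Inspects hydrogen-isotope (deuterium) atoms bonded to the ring nitrogens
#' (bond inferred by a 1.3 A distance cutoff; neutron files may lack CONECT
#' records). D on NE2 only: the epsilon tautomer (His_e0); D on ND1 only:
#' the delta tautomer (His_d0); D on both: the imidazolium cation (His+);
#' no ring N-D: not determinable.
#'
#' @param res_atoms His residue atom table.
#' @return list(state = one of `"epsilon0"`, `"delta0"`, `"positive"`,
#'   `"not_determinable"`; evidence = character vector of protonated N).
#' @export
tautomer_from_deuterium <- function(res_atoms) {
  stopifnot(res_atoms$resname[1] == "HIS")
  d <- res_atoms[res_atoms$is_deuterium, , drop = FALSE]
  prot <- character(0)
  for (n in c("ND1", "NE2")) {
    nx <- tryCatch(as.vector(atom_xyz(res_atoms, n)), error = function(e) NULL)
    if (is.null(nx) || !nrow(d)) next
    dd <- apply(as.matrix(d[, c("x", "y", "z")]), 1, function(p) vnorm(p - nx))
    if (any(dd <= 1.3)) prot <- c(prot, n)
  }
  state <- if (setequal(prot, c("ND1", "NE2"))) "positive"
    else if (identical(prot, "NE2")) "epsilon0"
    else if (identical(prot, "ND1")) "delta0"
    else "not_determinable"
  list(state = state, evidence = prot)
}

#' Is a His neutral by metal coordination?
#'
#' TRUE iff a ring nitrogen lies within `coordination_cutoff` of a
#' configured metal site (typical first-shell His-metal coordination is
#' ~2.0-2.3 A). A coordinating nitrogen must be deprotonated, so such His
#' are called neutral without H-bond inference.
#'
#' @param s a `hispi_structure`.
#' @param his_key residue key of the His.
#' @param coordination_cutoff Angstrom, default 3.0 (distinct from the 5 A
#'   pair-mining exclusion radius).
#' @param metal_names element symbols counted as metals.
#' @export
metal_bound_neutral <- function(s, his_key, coordination_cutoff = 3.0,
                                metal_names = default_metals()) {
  metals <- find_metals(s, metal_names)
  if (!nrow(metals)) return(FALSE)
  a <- residue_atoms(s, his_key)
  for (n in c("ND1", "NE2")) {
    nx <- tryCatch(as.vector(atom_xyz(a, n)), error = function(e) NULL)
    if (is.null(nx)) next
    dd <- apply(as.matrix(metals[, c("x", "y", "z")]), 1,
                function(p) vnorm(p - nx))
    if (any(dd <= coordination_cutoff)) return(TRUE)
  }
  FALSE
}

# statuses compatible with one piece of evidence: a ring N observed
# accepting must be deprotonated; a ring N observed donating must be
# protonated. Status encoding: which ring N carry H.
status_set <- function(n_atom, role) {
  protonated <- list(epsilon0 = "NE2", delta0 = "ND1", positive = c("ND1", "NE2"))
  keep <- vapply(protonated, function(p)
    if (role == "donate") n_atom %in% p else !(n_atom %in% p), TRUE)
  names(protonated)[keep]
}

#' Infer His protonation state from H-bond patterns
#'
#' The three-scenario procedure for structures without experimental
#' hydrogen positions. Ideal hydrogens are placed under each scenario (ND1
#' protonated, NE2 protonated, both protonated) and hydrogen bonds between
#' the His ring nitrogens and all neighboring atoms (side chains, backbone,
#' waters) are censused with [classify_h_bond()]. A ring N accepting an
#' H-bond implies it is deprotonated (neutral His with a fixed tautomer);
#' both ring N donating implies the protonated cation. A state is returned
#' only when the evidence of every scenario is consistent with a single
#' status; His with at most one supporting H-bond in every scenario are
#' undetermined. Metal-coordinated His are called `neutral_metal` up front
#' and H-bond inference is skipped.
#'
#' A scenario hydrogen that would clash (< 1.2 A) with an explicit hydrogen
#' of the would-be acceptor moiety invalidates that candidate bond: a
#' neighbor hydroxyl pointing its own H at ND1 is evidence that ND1
#' accepts, not that a hypothetical ND1-H donates.
#'
#' @param s a `hispi_structure`.
#' @param his_key residue key of the His.
#' @param thr a [geometry_thresholds()] (H-bond criteria).
#' @param neighbor_radius heavy-atom prefilter radius around the ring N, A.
#' @param coordination_cutoff metal coordination cutoff, A.
#' @param metal_names element symbols counted as metals.
#' @return list(state = `"neutral"`, `"neutral_metal"`, `"positive"` or
#'   `"undetermined"`; tautomer = `"epsilon0"`/`"delta0"`/NA; evidence =
#'   data.frame(scenario, n_atom, role, partner); n_hbonds_max).
#' @export
infer_protonation_hbond <- function(s, his_key, thr = geometry_thresholds(),
                                    neighbor_radius = 4.0,
                                    coordination_cutoff = 3.0,
                                    metal_names = default_metals()) {
  if (metal_bound_neutral(s, his_key, coordination_cutoff, metal_names))
    return(list(state = "neutral_metal", tautomer = NA_character_,
                evidence = NULL, n_hbonds_max = NA_integer_))
  his0 <- residue_atoms(s, his_key)
  stopifnot(his0$resname[1] == "HIS")
  ring <- build_ring(his0)
  nxyz <- atom_xyz(his0, c("ND1", "NE2"))

  # neighbor residues with any heavy atom near a ring N
  all_res <- structure_residues(s)
  near_keys <- character(0)
  sx <- as.data.frame(s)
  heavy_idx <- !sx$element %in% c("H", "D")
  keys_all <- residue_key(sx$chain, sx$resseq, sx$icode)
  for (i in which(heavy_idx)) {
    if (keys_all[i] == his_key) next
    p <- as.numeric(sx[i, c("x", "y", "z")])
    if (vnorm(p - nxyz["ND1", ]) <= neighbor_radius ||
        vnorm(p - nxyz["NE2", ]) <= neighbor_radius)
      near_keys <- c(near_keys, keys_all[i])
  }
  near_keys <- unique(near_keys)

  neighbors <- lapply(near_keys, function(k) {
    a <- residue_atoms(s, k)
    c(hbond_candidates(a), list(atoms = a))
  })

  evid <- list()
  n_per_scenario <- c(HID = 0L, HIE = 0L, HIP = 0L)
  for (sc in c("HID", "HIE", "HIP")) {
    his <- add_ideal_hydrogens(his0[!his0$element %in% c("H", "D"), , drop = FALSE], sc)
    hb <- attached_hydrogens(his)
    h_on <- vapply(hb, `[[`, "", "heavy")
    for (n in c("ND1", "NE2")) {
      has_h <- n %in% h_on
      if (has_h) {
        hx <- hb[[which(h_on == n)[1]]]$h_xyz
        for (nb in neighbors) for (acc in nb$acceptors) {
          # steric clash of the placed H with the acceptor's own hydrogens
          acc_h <- nb$atoms[nb$atoms$element %in% c("H", "D"), , drop = FALSE]
          clash <- FALSE
          if (nrow(acc_h)) {
            dh <- apply(as.matrix(acc_h[, c("x", "y", "z")]), 1,
                        function(p) vnorm(p - hx))
            near_acc <- vnorm(acc$xyz - nxyz[n, ]) <= thr$hb_max_DA + 0.5
            clash <- near_acc && any(dh < 1.2)
          }
          if (clash) next
          r <- classify_h_bond(nxyz[n, ], hx, acc$xyz, ring, thr)
          if (r$is_hbond) {
            evid[[length(evid) + 1]] <- data.frame(
              scenario = sc, n_atom = n, role = "donate",
              partner = acc$name, stringsAsFactors = FALSE)
            n_per_scenario[sc] <- n_per_scenario[sc] + 1L
          }
        }
      } else {
        for (nb in neighbors) for (don in nb$donors) {
          r <- classify_h_bond(don$heavy_xyz, don$h_xyz, nxyz[n, ], ring, thr)
          if (r$is_hbond) {
            evid[[length(evid) + 1]] <- data.frame(
              scenario = sc, n_atom = n, role = "accept",
              partner = don$heavy, stringsAsFactors = FALSE)
            n_per_scenario[sc] <- n_per_scenario[sc] + 1L
          }
        }
      }
    }
  }
  evidence <- if (length(evid)) do.call(rbind, evid) else
    data.frame(scenario = character(0), n_atom = character(0),
               role = character(0), partner = character(0))

  undetermined <- list(state = "undetermined", tautomer = NA_character_,
                       evidence = evidence,
                       n_hbonds_max = max(n_per_scenario))
  if (max(n_per_scenario) <= 1L) return(undetermined)

  compatible <- c("epsilon0", "delta0", "positive")
  for (sc in unique(evidence$scenario)) {
    ev <- evidence[evidence$scenario == sc, , drop = FALSE]
    sets <- mapply(status_set, ev$n_atom, ev$role, SIMPLIFY = FALSE)
    compatible <- Reduce(intersect, sets, compatible)
  }
  if (length(compatible) != 1) return(undetermined)
  if (compatible == "positive")
    list(state = "positive", tautomer = NA_character_, evidence = evidence,
         n_hbonds_max = max(n_per_scenario))
  else
    list(state = "neutral", tautomer = compatible, evidence = evidence,
         n_hbonds_max = max(n_per_scenario))
}

#' Categorize a His pKa value
#'
#' Low: pKa < 5.3; high: pKa > 7.3; medium: 5.3 <= pKa <= 7.3 (boundaries
#' inclusive in the medium group). Vectorized.
#'
#' @param pka numeric vector of pKa values; must be finite.
#' @return character vector in `c("low", "medium", "high")`.
#' @export
categorize_pka <- function(pka) {
  if (any(!is.finite(pka))) stop("non-finite pKa value")
  ifelse(pka < 5.3, "low", ifelse(pka > 7.3, "high", "medium"))
}

#' Interaction-type fractions per pKa group
#'
#' For each (pair family, interaction type) cell, counts are split by the
#' His pKa category of the pair and normalized within the cell, so the
#' fractions over categories sum to 1 for every non-empty cell. Empty cells
#' are omitted.
#'
#' @param categories named character vector: His residue key -> category
#'   (`"low"`, `"medium"`, `"high"`).
#' @param labeled_pairs data.frame with columns family, label, his_res.
#' @return data.frame: family, label, category, count, fraction.
#' @export
pka_group_fractions <- function(categories, labeled_pairs) {
  cat <- categories[labeled_pairs$his_res]
  if (anyNA(cat)) stop("every labeled pair's His needs a pKa category")
  df <- data.frame(family = labeled_pairs$family, label = labeled_pairs$label,
                   category = as.vector(cat), stringsAsFactors = FALSE)
  key <- interaction(df$family, df$label, drop = TRUE)
  rows <- lapply(split(df, key), function(g) {
    tab <- table(factor(g$category, levels = c("low", "medium", "high")))
    tab <- tab[tab > 0]
    data.frame(family = g$family[1], label = g$label[1],
               category = names(tab), count = as.integer(tab),
               fraction = as.numeric(tab) / nrow(g), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a per-residue pKa table
#'
#' Whitespace-separated columns: structure_id chain resnum pka.
#'
#' @param path file path.
#' @return data.frame with a `key` column (`chain|resnum|`) joined on the
#'   residue keys used elsewhere.
#' @export
read_pka_table <- function(path) {
  df <- utils::read.table(path, header = FALSE,
                          col.names = c("structure_id", "chain", "resnum", "pka"),
                          stringsAsFactors = FALSE)
  df$key <- residue_key(df$chain, df$resnum, "")
  df
}
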