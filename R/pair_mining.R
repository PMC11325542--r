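# Candidate-pair enumeration and the exclusion filters: ring-carbon contact
# mining for aromatic-aromatic pairs, center-to-centroid mining for
# cation-aromatic pairs, His-tag runs and metal proximity.

AROMATIC_RESNAMES <- c("HIS", "PHE", "TYR", "TRP")
CATION_RESNAMES <- c("LYS", "ARG", "HIS")

#' Pair-mining configuration
#'
#' `cc_cutoff`: maximum minimum ring-carbon to ring-carbon distance for an
#' aromatic pair (inclusive). `cation_centroid_cutoff`: maximum cation
#' center to ring centroid distance. `his_tag_min_run`: minimum length of a
#' consecutive same-chain His run treated as an engineered His-tag.
#' `metal_exclusion_radius`: His within this distance of any configured
#' metal is excluded from mining.
#'
#' @param cc_cutoff Angstrom, default 5.0.
#' @param cation_centroid_cutoff Angstrom, default 7.0.
#' @param his_tag_min_run count, default 5.
#' @param metal_exclusion_radius Angstrom, default 5.0.
#' @param metal_names element symbols counted as metals.
#' @return a `hispi_mining_config` list.
#' @export
mining_config <- function(cc_cutoff = 5.0, cation_centroid_cutoff = 7.0,
                          his_tag_min_run = 5, metal_exclusion_radius = 5.0,
                          metal_names = default_metals()) {
  stopifnot(cc_cutoff > 0, cation_centroid_cutoff > 0,
            metal_exclusion_radius > 0, his_tag_min_run >= 1)
  structure(list(cc_cutoff = cc_cutoff,
                 cation_centroid_cutoff = cation_centroid_cutoff,
                 his_tag_min_run = his_tag_min_run,
                 metal_exclusion_radius = metal_exclusion_radius,
                 metal_names = metal_names),
            class = "hispi_mining_config")
}

# polymer residues of the given residue names whose ring atoms are all
# present; returns list of (key, resname, atoms, ring) with unparseable
# rings skipped (warning)
collect_rings <- function(s, resnames = AROMATIC_RESNAMES) {
  res <- structure_residues(s)
  res <- res[!res$is_hetero & res$resname %in% resnames, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(res))) {
    atoms <- residue_atoms(s, res$key[i])
    ring <- tryCatch(build_ring(atoms), error = function(e) {
      warning(sprintf("skipping %s %s: %s", res$resname[i], res$key[i],
                      conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (!is.null(ring))
      out[[length(out) + 1]] <- list(key = res$key[i], resname = res$resname[i],
                                     atoms = atoms, ring = ring)
  }
  out
}

residue_sort_index <- function(s, keys) {
  res <- structure_residues(s)
  match(keys, res$key)
}

#' Find aromatic-aromatic candidate pairs
#'
#' Every unordered pair of aromatic residues (His/Phe/Tyr/Trp) whose minimum
#' ring-carbon to ring-carbon distance is `<= cc_cutoff` (inclusive). Only
#' ring carbons are considered (not CB, not ring nitrogens). When exactly
#' one member is His it is reported first (reference role).
#'
#' @param s altloc-resolved `hispi_structure`.
#' @param config a [mining_config()].
#' @return data.frame: family, res1, res2, resname1, resname2, distance
#'   (min ring C-C, Angstrom).
#' @export
find_aromatic_pairs <- function(s, config = mining_config()) {
  rings <- collect_rings(s)
  rows <- list()
  if (length(rings) >= 2) {
    carb <- lapply(rings, function(r) r$ring$xyz[startsWith(rownames(r$ring$xyz), "C"), , drop = FALSE])
    for (i in seq_len(length(rings) - 1)) for (j in (i + 1):length(rings)) {
      dmat <- as.matrix(stats::dist(rbind(carb[[i]], carb[[j]])))
      ni <- nrow(carb[[i]])
      dmin <- min(dmat[seq_len(ni), -seq_len(ni)])
      if (dmin <= config$cc_cutoff) {
        a <- rings[[i]]; b <- rings[[j]]
        if (b$resname == "HIS" && a$resname != "HIS") { tmp <- a; a <- b; b <- tmp }
        rows[[length(rows) + 1]] <- data.frame(
          family = "aromatic", res1 = a$key, res2 = b$key,
          resname1 = a$resname, resname2 = b$resname, distance = dmin,
          chosen_nitrogen = NA_character_, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(family = character(0), res1 = character(0), res2 = character(0),
               resname1 = character(0), resname2 = character(0),
               distance = numeric(0), chosen_nitrogen = character(0),
               stringsAsFactors = FALSE)
  out[order(residue_sort_index(s, out$res1), residue_sort_index(s, out$res2)), ,
      drop = FALSE]
}

#' Find cation-aromatic candidate pairs
#'
#' All (pi ring, cation) pairs with cation-center-to-centroid distance
#' `<= cation_centroid_cutoff`. Cation centers: Lys NZ, Arg CZ, His the ring
#' nitrogen closest to the partner centroid. A His-His pair within the
#' cutoff is emitted in both role assignments (either member may be the
#' cation). `res1` is the pi ring, `res2` the cation.
#'
#' @inheritParams find_aromatic_pairs
#' @return data.frame: family, res1 (pi), res2 (cation), resname1, resname2,
#'   distance, chosen_nitrogen (His cations only).
#' @export
find_cation_pi_pairs <- function(s, config = mining_config()) {
  rings <- collect_rings(s)
  res <- structure_residues(s)
  cats <- res[!res$is_hetero & res$resname %in% CATION_RESNAMES, , drop = FALSE]
  rows <- list()
  for (r in rings) for (i in seq_len(nrow(cats))) {
    if (cats$key[i] == r$key) next
    catoms <- residue_atoms(s, cats$key[i])
    site <- tryCatch(cation_site(catoms, partner_centroid = r$ring$centroid),
                     error = function(e) NULL)
    if (is.null(site)) next
    d <- vnorm(site$center - r$ring$centroid)
    if (d <= config$cation_centroid_cutoff)
      rows[[length(rows) + 1]] <- data.frame(
        family = "cation_pi", res1 = r$key, res2 = cats$key[i],
        resname1 = r$resname, resname2 = cats$resname[i], distance = d,
        chosen_nitrogen = if (is.na(site$chosen_nitrogen)) NA_character_ else site$chosen_nitrogen,
        stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(family = character(0), res1 = character(0), res2 = character(0),
               resname1 = character(0), resname2 = character(0),
               distance = numeric(0), chosen_nitrogen = character(0),
               stringsAsFactors = FALSE)
  out[order(residue_sort_index(s, out$res1), residue_sort_index(s, out$res2)), ,
      drop = FALSE]
}

#' His-tag exclusions
#'
#' Every His in any same-chain run of `min_run` or more His residues at
#' consecutive sequence numbers is excluded as an engineered tag. Runs do
#' not cross chains; an intervening residue number breaks the run.
#'
#' @param s a `hispi_structure`.
#' @param min_run minimum run length, default 5.
#' @return character vector of excluded residue keys.
#' @export
his_tag_exclusions <- function(s, min_run = 5) {
  res <- structure_residues(s)
  his <- res[!res$is_hetero & res$resname == "HIS", , drop = FALSE]
  out <- character(0)
  for (ch in unique(his$chain)) {
    h <- his[his$chain == ch, , drop = FALSE]
    h <- h[order(h$resseq), , drop = FALSE]
    if (!nrow(h)) next
    run_id <- cumsum(c(1, diff(h$resseq) != 1))
    for (g in split(seq_len(nrow(h)), run_id))
      if (length(g) >= min_run) out <- c(out, h$key[g])
  }
  out
}

#' Metal-proximity exclusions
#'
#' A His is excluded when any of its atoms (conservative: not only the ring
#' nitrogens) lies within `metal_exclusion_radius` of any configured metal
#' site.
#'
#' @inheritParams find_aromatic_pairs
#' @return character vector of excluded His residue keys.
#' @export
metal_exclusions <- function(s, config = mining_config()) {
  metals <- find_metals(s, config$metal_names)
  if (!nrow(metals)) return(character(0))
  res <- structure_residues(s)
  his <- res[!res$is_hetero & res$resname == "HIS", , drop = FALSE]
  mxyz <- as.matrix(metals[, c("x", "y", "z")])
  out <- character(0)
  for (k in his$key) {
    a <- residue_atoms(s, k)
    axyz <- as.matrix(a[, c("x", "y", "z")])
    dd <- as.matrix(stats::dist(rbind(axyz, mxyz)))
    if (min(dd[seq_len(nrow(axyz)), -seq_len(nrow(axyz))]) <= config$metal_exclusion_radius)
      out <- c(out, k)
  }
  out
}

#' Mine all candidate pairs with exclusions applied
#'
#' Union of aromatic-aromatic and cation-aromatic candidates, with every
#' pair touching a His-tag His or a metal-proximal His removed. With
#' `collapse = TRUE` (default) one row is returned per unordered residue
#' pair, with a `families` column recording which channels fired
#' (`"aromatic"`, `"cation_pi"` or `"aromatic+cation_pi"`): a close
#' His-aromatic contact is one mined pair even though it is both a
#' ring-ring candidate and a potential cation-pi candidate. Use
#' `collapse = FALSE` (or the per-family finders) for one row per family
#' and role assignment. Output ordering is deterministic (chain, sequence
#' number).
#'
#' @inheritParams find_aromatic_pairs
#' @param collapse collapse to unique residue pairs (default TRUE).
#' @return data.frame; collapsed: res1, res2, resname1, resname2, families,
#'   cc_distance, cation_distance; otherwise as the per-family finders.
#' @export
mine <- function(s, config = mining_config(), collapse = TRUE) {
  s <- resolve_altlocs(s)
  pairs <- rbind(find_aromatic_pairs(s, config), find_cation_pi_pairs(s, config))
  excl <- union(his_tag_exclusions(s, config$his_tag_min_run),
                metal_exclusions(s, config))
  if (length(excl)) {
    res <- structure_residues(s)
    his_keys <- res$key[res$resname == "HIS"]
    excl <- intersect(excl, his_keys)
    drop <- (pairs$res1 %in% excl & pairs$resname1 == "HIS") |
            (pairs$res2 %in% excl & pairs$resname2 == "HIS")
    pairs <- pairs[!drop, , drop = FALSE]
  }
  pairs <- pairs[order(pairs$family, residue_sort_index(s, pairs$res1),
                       residue_sort_index(s, pairs$res2)), , drop = FALSE]
  rownames(pairs) <- NULL
  if (!collapse) return(pairs)
  if (!nrow(pairs))
    return(data.frame(res1 = character(0), res2 = character(0),
                      resname1 = character(0), resname2 = character(0),
                      families = character(0), cc_distance = numeric(0),
                      cation_distance = numeric(0), stringsAsFactors = FALSE))

  ukey <- apply(cbind(pairs$res1, pairs$res2), 1,
                function(r) paste(sort(r), collapse = "~"))
  rows <- lapply(split(seq_len(nrow(pairs)), factor(ukey, levels = unique(ukey))),
                 function(ix) {
    g <- pairs[ix, , drop = FALSE]
    # canonical orientation: His first when exactly one member is His,
    # otherwise structure order
    r1 <- g$res1[1]; n1 <- g$resname1[1]; r2 <- g$res2[1]; n2 <- g$resname2[1]
    if (n2 == "HIS" && n1 != "HIS") {
      tmp <- r1; r1 <- r2; r2 <- tmp; tmp <- n1; n1 <- n2; n2 <- tmp
    }
    cc <- g$distance[g$family == "aromatic"]
    cd <- g$distance[g$family == "cation_pi"]
    data.frame(res1 = r1, res2 = r2, resname1 = n1, resname2 = n2,
               families = paste(sort(unique(g$family)), collapse = "+"),
               cc_distance = if (length(cc)) min(cc) else NA_real_,
               cation_distance = if (length(cd)) min(cd) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(residue_sort_index(s, out$res1),
                   residue_sort_index(s, out$res2)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
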