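# Structure model and file I/O.
#
# A structure is a flat atom table (one row per atom) with file-level
# metadata in attributes -- the same shape bio3d-style tools use, which keeps
# every downstream operation vectorizable. Only the first model of
# multi-model files is read; crystal structures are single-model.

#' Default metal element list
#'
#' Superset of the biologically common His-coordinating cations
#' (Zn, Ca, Mg, Fe, ...). Configurable wherever it is consumed.
#' @export
default_metals <- function() {
  c("ZN", "CA", "MG", "MN", "FE", "CO", "NI", "CU", "NA", "K")
}

new_structure <- function(atoms, id = "struct", resolution = NA_real_,
                          r_factor = NA_real_, method = "other") {
  required <- c("record", "name", "altloc", "resname", "chain", "resseq",
                "icode", "x", "y", "z", "occupancy", "element", "is_deuterium")
  missing <- setdiff(required, names(atoms))
  if (length(missing)) stop("atom table lacks columns: ", paste(missing, collapse = ", "))
  rownames(atoms) <- NULL
  structure(atoms,
            id = id, resolution = resolution, r_factor = r_factor,
            method = method,
            class = c("hispi_structure", "data.frame"))
}

#' Assemble a structure from an atom table
#'
#' Low-level constructor for programmatic structures (fixtures, subsets).
#' The atom table needs the columns record, name, altloc, resname, chain,
#' resseq, icode, x, y, z, occupancy, element, is_deuterium.
#'
#' @param atoms atom data.frame.
#' @param id structure identifier.
#' @param resolution,r_factor metadata (NA when unknown).
#' @param method `"xray"`, `"neutron"` or `"other"`.
#' @return a `hispi_structure`.
#' @export
as_structure <- function(atoms, id = "struct", resolution = NA_real_,
                         r_factor = NA_real_, method = "other") {
  new_structure(as.data.frame(atoms), id = id, resolution = resolution,
                r_factor = r_factor, method = method)
}

#' @export
print.hispi_structure <- function(x, ...) {
  cat(sprintf("<hispi_structure> %s: %d atoms, %d residues, method=%s",
              attr(x, "id"), nrow(x), nrow(structure_residues(x)),
              attr(x, "method")))
  if (!is.na(attr(x, "resolution")))
    cat(sprintf(", res=%.2f A", attr(x, "resolution")))
  if (!is.na(attr(x, "r_factor")))
    cat(sprintf(", R=%.3f", attr(x, "r_factor")))
  cat("\n")
  invisible(x)
}

# Stable per-residue key used throughout: chain|resseq|icode.
residue_key <- function(chain, resseq, icode) paste(chain, resseq, icode, sep = "|")

#' Residue table of a structure
#'
#' One row per residue in file order, with a stable `key` column
#' (`chain|resseq|icode`) used as the residue identifier everywhere else.
#'
#' @param s a `hispi_structure`.
#' @return data.frame with columns key, chain, resseq, icode, resname, is_hetero.
#' @export
structure_residues <- function(s) {
  key <- residue_key(s$chain, s$resseq, s$icode)
  idx <- !duplicated(key)
  data.frame(key = key[idx], chain = s$chain[idx], resseq = s$resseq[idx],
             icode = s$icode[idx], resname = s$resname[idx],
             is_hetero = s$record[idx] == "HETATM",
             stringsAsFactors = FALSE)
}

#' Atoms of one residue
#' @param s a `hispi_structure`.
#' @param key residue key as in [structure_residues()].
#' @return atom table subset (plain data.frame).
#' @export
residue_atoms <- function(s, key) {
  as.data.frame(s)[residue_key(s$chain, s$resseq, s$icode) == key, , drop = FALSE]
}

infer_element <- function(name) {
  # strip leading digits (e.g. "1HB2"), take the leading alpha run
  core <- sub("^[0-9 ]*", "", name)
  first <- substr(core, 1, 1)
  # deuterium naming (DD1, DE2 ...) is handled by the caller via the element
  # column when present; fall back to the first letter here
  toupper(first)
}

parse_pdb_lines <- function(lines, id) {
  # keep only the first model
  mstart <- grep("^MODEL ", lines)
  if (length(mstart) > 1) {
    mend <- grep("^ENDMDL", lines)
    drop <- seq(mend[1] + 1, length(lines))
    lines <- lines[-drop[drop %in% seq_along(lines)]]
  }
  at <- grep("^(ATOM  |HETATM)", lines, value = TRUE)
  if (!length(at)) stop("no coordinates in PDB input")
  f <- function(from, to) trimws(substr(at, from, to))
  elem <- f(77, 78)
  name <- f(13, 16)
  no_elem <- elem == ""
  elem[no_elem] <- infer_element(name[no_elem])
  occ <- suppressWarnings(as.numeric(f(55, 60)))
  occ[is.na(occ)] <- 1
  atoms <- data.frame(
    record = trimws(substr(at, 1, 6)),
    name = name,
    altloc = f(17, 17),
    resname = f(18, 20),
    chain = f(22, 22),
    resseq = as.integer(f(23, 26)),
    icode = f(27, 27),
    x = as.numeric(f(31, 38)), y = as.numeric(f(39, 46)), z = as.numeric(f(47, 54)),
    occupancy = occ,
    element = elem,
    stringsAsFactors = FALSE)
  atoms$is_deuterium <- atoms$element == "D"
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("non-finite coordinates in PDB input")

  res <- NA_real_
  m <- regmatches(lines, regexpr("^REMARK   2 RESOLUTION\\. +[0-9.]+", lines))
  if (length(m)) res <- as.numeric(sub(".*RESOLUTION\\. +", "", m[1]))
  rfac <- NA_real_
  rl <- grep("^REMARK   3   R VALUE", lines, value = TRUE)
  if (length(rl)) {
    v <- suppressWarnings(as.numeric(sub(".*: *", "", rl[1])))
    if (is.finite(v)) rfac <- v
  }
  method <- "other"
  ex <- grep("^EXPDTA", lines, value = TRUE)
  if (length(ex)) {
    if (grepl("X-RAY", ex[1])) method <- "xray"
    else if (grepl("NEUTRON", ex[1])) method <- "neutron"
  }
  new_structure(atoms, id = id, resolution = res, r_factor = rfac, method = method)
}

# minimal whitespace tokenizer honouring single/double quotes (mmCIF values
# in _atom_site loops are simple; multiline ; blocks are not supported)
cif_tokens <- function(line) {
  out <- character(0)
  rest <- line
  while (nchar(rest <- sub("^\\s+", "", rest)) > 0) {
    q <- substr(rest, 1, 1)
    if (q == "'" || q == "\"") {
      end <- regexpr(paste0(q, "(\\s|$)"), substr(rest, 2, nchar(rest)))
      tok <- substr(rest, 2, end)
      rest <- substr(rest, end + 2, nchar(rest))
    } else {
      end <- regexpr("\\s|$", rest)
      tok <- substr(rest, 1, end - 1)
      rest <- substr(rest, end, nchar(rest))
    }
    out <- c(out, tok)
  }
  out
}

parse_mmcif_lines <- function(lines, id) {
  lines <- lines[!grepl("^#", lines)]
  # locate the _atom_site loop
  tagged <- grep("^_atom_site\\.", lines)
  if (!length(tagged)) stop("no _atom_site loop in mmCIF input")
  tags <- sub("^_atom_site\\.", "", trimws(lines[tagged]))
  body_start <- max(tagged) + 1
  rows <- list()
  for (i in body_start:length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || grepl("^(loop_|_|#)", ln)) break
    rows[[length(rows) + 1]] <- cif_tokens(ln)
  }
  if (!length(rows)) stop("empty _atom_site loop")
  mat <- do.call(rbind, rows)
  colnames(mat) <- tags
  pick <- function(...) {
    for (nm in c(...)) if (nm %in% tags) return(mat[, nm])
    rep("", nrow(mat))
  }
  blank_to <- function(x, repl = "") { x[x %in% c(".", "?")] <- repl; x }
  model <- pick("pdbx_PDB_model_num")
  if (any(model != "")) mat <- mat[model == model[1], , drop = FALSE]
  name <- blank_to(pick("auth_atom_id", "label_atom_id"))
  elem <- toupper(blank_to(pick("type_symbol")))
  no_elem <- elem == ""
  elem[no_elem] <- infer_element(name[no_elem])
  occ <- suppressWarnings(as.numeric(blank_to(pick("occupancy"), "1")))
  occ[is.na(occ)] <- 1
  atoms <- data.frame(
    record = pick("group_PDB"),
    name = name,
    altloc = blank_to(pick("label_alt_id")),
    resname = blank_to(pick("auth_comp_id", "label_comp_id")),
    chain = blank_to(pick("auth_asym_id", "label_asym_id")),
    resseq = as.integer(blank_to(pick("auth_seq_id", "label_seq_id"), "0")),
    icode = blank_to(pick("pdbx_PDB_ins_code")),
    x = as.numeric(pick("Cartn_x")),
    y = as.numeric(pick("Cartn_y")),
    z = as.numeric(pick("Cartn_z")),
    occupancy = occ,
    element = elem,
    stringsAsFactors = FALSE)
  atoms$is_deuterium <- atoms$element == "D"

  scalar <- function(tag) {
    ln <- grep(paste0("^", tag, "\\b"), lines, value = TRUE)
    if (!length(ln)) return(NA_character_)
    tok <- cif_tokens(ln[1])
    if (length(tok) >= 2) tok[2] else NA_character_
  }
  res <- suppressWarnings(as.numeric(scalar("_refine\\.ls_d_res_high")))
  if (is.na(res)) res <- suppressWarnings(as.numeric(scalar("_reflns\\.d_resolution_high")))
  rfac <- suppressWarnings(as.numeric(scalar("_refine\\.ls_R_factor_R_work")))
  if (is.na(rfac)) rfac <- suppressWarnings(as.numeric(scalar("_refine\\.ls_R_factor_obs")))
  meth <- scalar("_exptl\\.method")
  method <- if (is.na(meth)) "other"
    else if (grepl("X-RAY", toupper(meth))) "xray"
    else if (grepl("NEUTRON", toupper(meth))) "neutron"
    else "other"
  new_structure(atoms, id = id, resolution = res, r_factor = rfac, method = method)
}

#' Read a protein structure
#'
#' Parses a PDB or mmCIF file into the flat atom-table structure model.
#' Deuterium atoms (element D) are flagged; resolution, R-factor and
#' experimental method are captured when present. Only the first model of a
#' multi-model file is kept.
#'
#' @param path file path.
#' @param format `"pdb"`, `"mmcif"`, or `"auto"` (by extension, default).
#' @param id structure identifier; defaults to the file base name.
#' @return a `hispi_structure`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"), id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (is.null(id)) id <- sub("\\.(pdb|ent|cif|mmcif)$", "", basename(path))
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  lines <- readLines(path, warn = FALSE)
  if (format == "pdb") parse_pdb_lines(lines, id) else parse_mmcif_lines(lines, id)
}

#' Resolve alternate locations
#'
#' Keeps at most one atom per (residue, atom name): the highest-occupancy
#' altloc, ties broken by lexicographically first altloc id. Idempotent.
#'
#' @param s a `hispi_structure`.
#' @param policy only `"highest_occupancy"` is defined.
#' @return the structure with altlocs resolved (altloc column cleared).
#' @export
resolve_altlocs <- function(s, policy = "highest_occupancy") {
  stopifnot(policy == "highest_occupancy")
  key <- paste(residue_key(s$chain, s$resseq, s$icode), s$name)
  ord <- order(match(key, unique(key)), -s$occupancy, s$altloc)
  out <- as.data.frame(s)[ord, , drop = FALSE]
  out <- out[!duplicated(paste(residue_key(out$chain, out$resseq, out$icode), out$name)), , drop = FALSE]
  # restore original file order among survivors
  out <- out[order(match(rownames(out), rownames(as.data.frame(s)))), , drop = FALSE]
  out$altloc <- ""
  new_structure(out, id = attr(s, "id"), resolution = attr(s, "resolution"),
                r_factor = attr(s, "r_factor"), method = attr(s, "method"))
}

#' Structure quality filter
#'
#' Defaults reflect a curated high-resolution X-ray workflow: resolution
#' <= 1.8 A, R-factor <= 0.18, 40-10,000 residues. A neutron profile would
#' use `max_resolution = 2.5`, `check_r_factor = FALSE`,
#' `allowed_methods = "neutron"`. Missing metadata fails the corresponding
#' check unless that check is disabled.
#'
#' @param max_resolution maximum resolution, Angstrom.
#' @param max_r_factor maximum crystallographic R-factor (fraction).
#' @param min_length,max_length residue-count bounds (polymer residues).
#' @param allowed_methods subset of `c("xray", "neutron", "other")`.
#' @param check_resolution,check_r_factor,check_length,check_method set FALSE
#'   to disable the corresponding check.
#' @return a `hispi_filter` list.
#' @export
structure_filter <- function(max_resolution = 1.8, max_r_factor = 0.18,
                             min_length = 40, max_length = 10000,
                             allowed_methods = "xray",
                             check_resolution = TRUE, check_r_factor = TRUE,
                             check_length = TRUE, check_method = TRUE) {
  stopifnot(min_length < max_length)
  structure(list(max_resolution = max_resolution, max_r_factor = max_r_factor,
                 min_length = min_length, max_length = max_length,
                 allowed_methods = allowed_methods,
                 check_resolution = check_resolution,
                 check_r_factor = check_r_factor,
                 check_length = check_length, check_method = check_method),
            class = "hispi_filter")
}

#' Apply a structure quality filter
#'
#' @param s a `hispi_structure`.
#' @param filter a [structure_filter()].
#' @return TRUE iff every enabled check passes; missing metadata fails its
#'   check.
#' @export
passes_filters <- function(s, filter = structure_filter()) {
  if (filter$check_resolution) {
    r <- attr(s, "resolution")
    if (is.na(r) || r > filter$max_resolution) return(FALSE)
  }
  if (filter$check_r_factor) {
    rf <- attr(s, "r_factor")
    if (is.na(rf) || rf > filter$max_r_factor) return(FALSE)
  }
  if (filter$check_length) {
    n <- sum(!structure_residues(s)$is_hetero)
    if (n < filter$min_length || n > filter$max_length) return(FALSE)
  }
  if (filter$check_method) {
    if (!(attr(s, "method") %in% filter$allowed_methods)) return(FALSE)
  }
  TRUE
}

#' Locate metal ion sites
#'
#' @param s a `hispi_structure`.
#' @param metal_names element symbols counted as metals.
#' @return data.frame of HETATM metal sites (name, element, x, y, z).
#' @export
find_metals <- function(s, metal_names = default_metals()) {
  idx <- s$record == "HETATM" & s$element %in% metal_names
  as.data.frame(s)[idx, c("name", "element", "resname", "chain", "resseq", "x", "y", "z"),
                   drop = FALSE]
}

format_pdb_atom_name <- function(name, element) {
  if (nchar(name) >= 4) return(substr(name, 1, 4))
  if (nchar(element) >= 2) sprintf("%-4s", name) else sprintf(" %-3s", name)
}

#' Write a structure as PDB text
#'
#' Fixed-column PDB writer (coordinates to 0.001 A, the field precision).
#' Emits EXPDTA / REMARK 2 / REMARK 3 headers when metadata is present so
#' [read_structure()] round-trips them.
#'
#' @param s a `hispi_structure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path) {
  lines <- character(0)
  meth <- switch(attr(s, "method"),
                 xray = "X-RAY DIFFRACTION",
                 neutron = "NEUTRON DIFFRACTION", NA_character_)
  if (!is.na(meth)) lines <- c(lines, sprintf("EXPDTA    %s", meth))
  if (!is.na(attr(s, "resolution")))
    lines <- c(lines, sprintf("REMARK   2 RESOLUTION. %7.2f ANGSTROMS.", attr(s, "resolution")))
  if (!is.na(attr(s, "r_factor")))
    lines <- c(lines, sprintf("REMARK   3   R VALUE            (WORKING SET) : %.3f", attr(s, "r_factor")))
  a <- as.data.frame(s)
  rec <- sprintf("%-6s", a$record)
  nm <- mapply(format_pdb_atom_name, a$name, a$element, USE.NAMES = FALSE)
  lines <- c(lines, sprintf(
    "%s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    rec, seq_len(nrow(a)) %% 100000, nm, a$altloc, a$resname, a$chain,
    a$resseq, a$icode, a$x, a$y, a$z, a$occupancy, 0, sprintf("%2s", a$element)))
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}
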