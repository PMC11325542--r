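# Independent oracle implementations and fixture builders. The oracles
# deliberately avoid the package's code paths: Newell's method for ring
# normals (vs SVD plane fit in the package) and explicit dot/cross
# arithmetic for every angle.

ocross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])
onorm <- function(v) sqrt(sum(v * v))

oracle_ring <- function(xyz) {
  ctr <- colMeans(xyz)
  n <- nrow(xyz)
  normal <- c(0, 0, 0)
  for (i in seq_len(n)) {
    a <- xyz[i, ] - ctr
    b <- xyz[i %% n + 1, ] - ctr
    normal <- normal + ocross(a, b)
  }
  list(centroid = ctr, normal = normal / onorm(normal))
}

oracle_angle <- function(u, v) {
  acos(min(1, max(-1, sum(u * v) / (onorm(u) * onorm(v))))) * 180 / pi
}

oracle_pair <- function(xyz1, xyz2) {
  r1 <- oracle_ring(xyz1); r2 <- oracle_ring(xyz2)
  d <- r2$centroid - r1$centroid
  D <- onorm(d)
  P <- oracle_angle(r1$normal, r2$normal)
  list(D = D, P = min(P, 180 - P),
       T_theta1 = asin(min(1, abs(sum(d * r1$normal)) / D)) * 180 / pi,
       T_theta2 = asin(min(1, abs(sum(-d * r2$normal)) / D)) * 180 / pi)
}

oracle_cation <- function(ring_xyz, cat_xyz, plane_xyz = NULL) {
  r <- oracle_ring(ring_xyz)
  d <- cat_xyz - r$centroid
  t1 <- oracle_angle(r$normal, d)
  t2 <- NA_real_
  if (!is.null(plane_xyz)) {
    p <- oracle_ring(plane_xyz[1:3, , drop = FALSE])  # any 3 plane points
    a <- oracle_angle(p$normal, d)
    t2 <- min(a, 180 - a)
  }
  list(D = onorm(d), theta1 = min(t1, 180 - t1), theta2 = t2)
}

random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# apply a random rigid pose to a residue atom table
rigid_pose <- function(atoms, R = random_rotation(),
                       t = stats::runif(3, -20, 20)) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, t, "+")
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  atoms
}

ring_xyz_of <- function(res_atoms) {
  spec <- ring_spec()[[res_atoms$resname[1]]]
  m <- as.matrix(res_atoms[match(spec, res_atoms$name), c("x", "y", "z")])
  rownames(m) <- spec
  m
}

make_atoms <- function(names, elements, xyz, resname = "LIG", chain = "A",
                       resseq = 1, record = "ATOM") {
  xyz <- matrix(xyz, ncol = 3)
  data.frame(record = record, name = names, altloc = "", resname = resname,
             chain = chain, resseq = as.integer(resseq), icode = "",
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occupancy = 1,
             element = elements, is_deuterium = elements == "D",
             stringsAsFactors = FALSE)
}

# residues placed at given offsets (list of (name, offset, chain, resseq))
scatter_structure <- function(spec_list, id = "scatter") {
  rows <- lapply(spec_list, function(sp) {
    a <- make_residue_template(sp$name, sp$scenario %||% NULL)
    a <- rigid_pose(a, R = sp$R %||% diag(3), t = sp$offset)
    a$chain <- sp$chain %||% "A"
    a$resseq <- as.integer(sp$resseq)
    a
  })
  as_structure(do.call(rbind, rows), id = id, resolution = 1.5,
               r_factor = 0.15, method = "xray")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a feasible (D, P, T_theta1, T_theta2) target drawn by construction:
# sample the geometry first, then read off the implied descriptors
feasible_aromatic_target <- function() {
  t1 <- stats::runif(1, 0, 90) * pi / 180
  P <- stats::runif(1, 0, 90) * pi / 180
  psi <- stats::runif(1, 0, 2 * pi)
  u <- c(cos(t1), 0, sin(t1))
  n2 <- c(sin(P) * cos(psi), sin(P) * sin(psi), cos(P))
  list(D = stats::runif(1, 2.5, 8), P = P * 180 / pi, t1 = t1 * 180 / pi,
       t2 = asin(min(1, abs(sum(u * n2)))) * 180 / pi)
}

pair_geom_of <- function(st, key1 = "A|1|", key2 = "A|2|") {
  aromatic_pair_geometry(build_ring(residue_atoms(st, key1)),
                         build_ring(residue_atoms(st, key2)))
}

cation_geom_of <- function(st, key_ring = "A|1|", key_cat = "A|2|") {
  ring <- build_ring(residue_atoms(st, key_ring))
  cation_pi_geometry(ring, cation_site(residue_atoms(st, key_cat),
                                       ring$centroid))
}
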