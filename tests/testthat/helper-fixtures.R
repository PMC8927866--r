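# Shared fixtures and independent oracles. Oracles deliberately use different
# algorithms from the package implementation so the two routes stay
# independent.

# --- independent torsion oracle: acos magnitude + determinant sign ----------
oracle_torsion <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cr <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                         u[3] * v[1] - u[1] * v[3],
                         u[1] * v[2] - u[2] * v[1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  cosang <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  cosang <- max(-1, min(1, cosang))
  ang <- acos(cosang) * 180 / pi
  s <- sign(sum(cr(n1, n2) * b2))
  out <- if (s < 0) -ang else ang
  if (out <= -180) out + 360 else out
}

# --- independent RMSD oracle: Horn quaternion method ------------------------
oracle_quaternion_rmsd <- function(a, b) {
  n <- nrow(a)
  a0 <- sweep(a, 2, colMeans(a)); b0 <- sweep(b, 2, colMeans(b))
  M <- crossprod(a0, b0)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy, Szx - Sxz, Sxy - Syx,
    Syz - Szy, Sxx - Syy - Szz, Sxy + Syx, Szx + Sxz,
    Szx - Sxz, Sxy + Syx, -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx, Szx + Sxz, Syz + Szy, -Sxx - Syy + Szz), 4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(a0^2) + sum(b0^2) - 2 * lam) / n
  sqrt(max(msd, 0))
}

# --- synthetic linear structure with complete backbones ---------------------
# a straight strand-like chain: good enough wherever only completeness,
# indexing and separation logic matter
make_linear_structure <- function(n, chain = "A", id = "lin", aa = NULL,
                                  offset = c(0, 0, 0)) {
  if (is.null(aa)) aa <- rep(aa_alphabet(), length.out = n)
  step <- 3.8
  ca <- cbind(seq_len(n) * step, 0, 0)
  ca <- sweep(ca, 2, offset, "+")
  res <- tibble::tibble(
    chain = chain, resno = seq_len(n), aa = aa,
    n_x = ca[, 1] - 1.2, n_y = ca[, 2] + 0.6, n_z = ca[, 3],
    ca_x = ca[, 1], ca_y = ca[, 2], ca_z = ca[, 3],
    c_x = ca[, 1] + 1.2, c_y = ca[, 2] + 0.7, c_z = ca[, 3],
    o_x = ca[, 1] + 1.3, o_y = ca[, 2] + 1.9, o_z = ca[, 3])
  new_structure(res, id = id)
}

# small deterministic synthetic database shared across tests
fixture_db <- function(n = 6, seed = 42, sigma = 3) {
  generate_synthetic_database(generator_spec(n_structures = n, seed = seed,
                                             sigma = sigma))
}

# one-residue PDB text building block
pdb_atom <- function(serial, elety, resid, chain, resno, x, y, z, occ = 1,
                     alt = " ", record = "ATOM  ") {
  sprintf("%-6s%5d %-4s%s%3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          record, serial, elety, alt, resid, chain, resno, x, y, z, occ, 0)
}

pdb_residue_lines <- function(resid = "ALA", chain = "A", resno = 1,
                              origin = c(0, 0, 0), serial0 = 0, occ = 1,
                              alt = " ", record = "ATOM  ", drop = character()) {
  atoms <- list(N = c(0, 0, 0), CA = c(1.46, 0, 0), C = c(2.0, 1.4, 0),
                O = c(1.4, 2.4, 0))
  atoms <- atoms[setdiff(names(atoms), drop)]
  out <- character()
  for (k in seq_along(atoms)) {
    xyz <- atoms[[k]] + origin
    out <- c(out, pdb_atom(serial0 + k, names(atoms)[k], resid, chain, resno,
                           xyz[1], xyz[2], xyz[3], occ = occ, alt = alt,
                           record = record))
  }
  out
}

# contact records drawn with independent amino acids at both positions
null_contact_records <- function(n, freq = NULL, seed = 1) {
  set.seed(seed)
  aa <- aa_alphabet()
  if (is.null(freq)) freq <- rep(1 / 20, 20)
  tibble::tibble(aa_i = sample(aa, n, replace = TRUE, prob = freq),
                 aa_j = sample(aa, n, replace = TRUE, prob = freq),
                 cd = stats::runif(n))
}

# --- independent counting oracle for the contact potential ------------------
oracle_cp <- function(records, eps_fun = function(o, e) 0) {
  aa <- aa_alphabet()
  e <- matrix(NA_real_, 20, 20, dimnames = list(aa, aa))
  n_c <- nrow(records)
  count_a <- stats::setNames(numeric(20), aa)
  for (k in seq_len(n_c)) {
    count_a[records$aa_i[k]] <- count_a[records$aa_i[k]] + 1
    count_a[records$aa_j[k]] <- count_a[records$aa_j[k]] + 1
  }
  f <- count_a / (2 * n_c)
  for (a in aa) for (b in aa) {
    n_obs <- sum((records$aa_i == a & records$aa_j == b) |
                   (a != b & records$aa_i == b & records$aa_j == a))
    h <- if (a == b) 1 else 2
    n_exp <- n_c * f[[a]] * f[[b]] * h
    eps <- eps_fun(n_obs, n_exp)
    e[a, b] <- -log((n_obs + eps) / (n_exp + eps))
  }
  e
}

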