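# Synthetic fixtures: backbone databases with controlled geometric spread,
# match ensembles with planted first-order + pairwise-coupling sequence
# statistics, and noise-graded decoy sets. Everything is deterministic given
# the seed, so all experiments are reproducible without any external data.

.ideal_bb <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7, a_ca_c_o = 120.8
)

.ss_templates <- list(
  helix = c(phi = -57, psi = -47),
  strand = c(phi = -139, psi = 135)
)

#' Specification for the synthetic backbone generator
#'
#' Describes a family of two-segment structures: each structure has two
#' backbone segments (chains A and B) built from ideal internal coordinates
#' with per-residue dihedral noise, with segment B rigidly placed relative to
#' segment A so that the two central residues form an inter-chain contact.
#'
#' @param template `"helix"` or `"strand"`, or a numeric `c(phi=, psi=)` pair.
#' @param sigma Per-residue dihedral noise, degrees (sd of a normal).
#' @param seg_len Residues per segment (must be odd and >= 2*flank+1 for the
#'   motifs you intend to extract; default 7 supports 5x5 motifs).
#' @param n_structures Number of structures in the family.
#' @param distance Central CA-CA placement distance in Angstrom. Default 5.5,
#'   a typical side-chain-mediated contact distance.
#' @param angle Rotation (degrees) of segment B's chain direction about the
#'   contact axis; 180 gives an antiparallel packing.
#' @param placement_noise List with `distance` (Angstrom sd) and `angles`
#'   (degrees sd of a random rigid wobble of segment B).
#' @param seed Integer seed.
#' @return A `scp_generator_spec` list.
#' @export
generator_spec <- function(template = "helix", sigma = 3, seg_len = 7L,
                           n_structures = 10L, distance = 5.5, angle = 180,
                           placement_noise = list(distance = 0.2, angles = 5),
                           seed = 1L) {
  if (is.character(template)) {
    template <- match.arg(template, names(.ss_templates))
    template <- .ss_templates[[template]]
  }
  stopifnot(sigma >= 0, seg_len >= 1)
  structure(list(template = template, sigma = sigma, seg_len = as.integer(seg_len),
                 n_structures = as.integer(n_structures), distance = distance,
                 angle = angle, placement_noise = placement_noise,
                 seed = as.integer(seed)),
            class = "scp_generator_spec")
}

# build one backbone segment from phi/psi/omega vectors; returns residue tibble
.build_segment <- function(phi, psi, omega, chain = "A", aa = NULL) {
  g <- .ideal_bb
  n <- length(phi)
  if (is.null(aa)) aa <- rep("A", n)
  N <- matrix(NA_real_, n, 3); CA <- N; C <- N; O <- N
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_n_ca, 0, 0)
  # first C placed in the xy-plane at the ideal N-CA-C angle
  ang <- g$a_n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + g$b_ca_c * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n - 1)) {
    Nn <- place_atom(N[i, ], CA[i, ], C[i, ], g$b_c_n, g$a_ca_c_n, psi[i])
    CAn <- place_atom(CA[i, ], C[i, ], Nn, g$b_n_ca, g$a_c_n_ca, omega[i + 1])
    Cn <- place_atom(C[i, ], Nn, CAn, g$b_ca_c, g$a_n_ca_c, phi[i + 1])
    N[i + 1, ] <- Nn; CA[i + 1, ] <- CAn; C[i + 1, ] <- Cn
  }
  for (i in seq_len(n)) {
    # carbonyl O anti to the following N (psi + 180 torsion about CA-C)
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], g$b_c_o, g$a_ca_c_o,
                         psi[i] + 180)
  }
  tibble::tibble(chain = chain, resno = seq_len(n), aa = aa,
                 n_x = N[, 1], n_y = N[, 2], n_z = N[, 3],
                 ca_x = CA[, 1], ca_y = CA[, 2], ca_z = CA[, 3],
                 c_x = C[, 1], c_y = C[, 2], c_z = C[, 3],
                 o_x = O[, 1], o_y = O[, 2], o_z = O[, 3])
}

# local frame at a residue: u points along the (pseudo) side-chain direction,
# v along the chain, w completes a right-handed basis
.residue_frame <- function(N, CA, C) {
  b1 <- (N - CA) / sqrt(sum((N - CA)^2))
  b2 <- (C - CA) / sqrt(sum((C - CA)^2))
  u <- -(b1 + b2)
  u <- u / sqrt(sum(u^2))
  v <- C - N
  v <- v - sum(v * u) * u
  v <- v / sqrt(sum(v^2))
  w <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  cbind(u, v, w)
}

.rot_about <- function(axis, theta_deg) {
  th <- theta_deg * pi / 180
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

.random_rotation <- function(sd_deg) {
  if (sd_deg <= 0) return(diag(3))
  ax <- stats::rnorm(3)
  .rot_about(ax, stats::rnorm(1, 0, sd_deg))
}

# build one two-segment structure from a generator spec (rng state consumed)
.build_structure <- function(spec, id, aa_fun = NULL) {
  L <- spec$seg_len
  cen <- (L + 1L) %/% 2L
  mk_angles <- function() {
    list(phi = spec$template[["phi"]] + stats::rnorm(L, 0, spec$sigma),
         psi = spec$template[["psi"]] + stats::rnorm(L, 0, spec$sigma),
         omega = rep(180, L))
  }
  aa_a <- sample(aa_alphabet(), L, replace = TRUE)
  aa_b <- sample(aa_alphabet(), L, replace = TRUE)
  angA <- mk_angles(); angB <- mk_angles()
  segA <- .build_segment(angA$phi, angA$psi, angA$omega, chain = "A", aa = aa_a)
  segB <- .build_segment(angB$phi, angB$psi, angB$omega, chain = "B", aa = aa_b)
  getv <- function(seg, i, at) as.numeric(seg[i, paste0(at, c("_x", "_y", "_z"))])
  fa <- .residue_frame(getv(segA, cen, "n"), getv(segA, cen, "ca"), getv(segA, cen, "c"))
  fb <- .residue_frame(getv(segB, cen, "n"), getv(segB, cen, "ca"), getv(segB, cen, "c"))
  d <- spec$distance + stats::rnorm(1, 0, spec$placement_noise$distance %||% 0)
  u <- fa[, 1]
  # target frame for B: side chain facing A, chain direction rotated by `angle`
  uT <- -u
  vT <- as.numeric(.rot_about(u, spec$angle) %*% fa[, 2])
  vT <- vT - sum(vT * uT) * uT
  vT <- vT / sqrt(sum(vT^2))
  wT <- c(uT[2] * vT[3] - uT[3] * vT[2], uT[3] * vT[1] - uT[1] * vT[3],
          uT[1] * vT[2] - uT[2] * vT[1])
  R <- cbind(uT, vT, wT) %*% t(fb)
  R <- .random_rotation(spec$placement_noise$angles %||% 0) %*% R
  target_ca <- getv(segA, cen, "ca") + d * u
  ca_b <- getv(segB, cen, "ca")
  move <- function(seg) {
    for (at in c("n", "ca", "c", "o")) {
      cols <- paste0(at, c("_x", "_y", "_z"))
      m <- t(R %*% (t(as.matrix(seg[, cols])) - ca_b)) +
        matrix(target_ca, nrow(seg), 3, byrow = TRUE)
      seg[, cols] <- as.data.frame(m)
    }
    seg
  }
  segB <- move(segB)
  s <- new_structure(dplyr::bind_rows(segA, segB), id = id)
  compute_dihedrals(s)
}

#' Generate a synthetic two-segment structure database
#'
#' Builds `n_structures` structures according to a [generator_spec()]: two
#' backbone segments (chains A and B) with template dihedrals plus noise,
#' segment B rigidly placed so the central residues contact each other.
#' Residue types are uniform random unless re-planted afterwards (see
#' [plant_central_pair()]). Deterministic given `spec$seed`.
#'
#' @param spec A [generator_spec()].
#' @return Named list of structures (`scp_structure`), ids `synth_001` ...
#' @export
generate_synthetic_database <- function(spec) {
  stopifnot(inherits(spec, "scp_generator_spec"))
  set.seed(spec$seed)
  ids <- sprintf("synth_%03d", seq_len(spec$n_structures))
  out <- lapply(ids, function(id) .build_structure(spec, id))
  names(out) <- ids
  out
}

#' Planted pairwise-coupling sequence model
#'
#' A Potts-like model over the central residue pair: the probability of the
#' pair (a, b) is proportional to `exp(-h_i(a) - h_j(b) - J(a, b))`. Used to
#' generate match ensembles with known second-order structure so that the
#' structure-conditioned energy machinery can be tested by parameter recovery.
#'
#' @param h_i,h_j First-order fields: numeric length-20 vectors (canonical
#'   order) or a single number recycled.
#' @param J 20x20 coupling matrix (canonical order).
#' @return A `scp_planted_model`.
#' @export
planted_model <- function(h_i = 0, h_j = 0, J = matrix(0, 20, 20)) {
  h_i <- rep_len(h_i, 20); h_j <- rep_len(h_j, 20)
  stopifnot(is.matrix(J), all(dim(J) == c(20, 20)), all(is.finite(J)))
  aa <- aa_alphabet()
  dimnames(J) <- list(aa, aa)
  structure(list(h_i = stats::setNames(h_i, aa),
                 h_j = stats::setNames(h_j, aa), J = J),
            class = "scp_planted_model")
}

#' Random planted model
#'
#' @param seed Integer seed.
#' @param h_sd,j_sd Standard deviations of the normal fields/couplings.
#' @return A [planted_model()].
#' @export
random_planted_model <- function(seed = 1L, h_sd = 0.3, j_sd = 1) {
  set.seed(seed)
  planted_model(h_i = stats::rnorm(20, 0, h_sd),
                h_j = stats::rnorm(20, 0, h_sd),
                J = matrix(stats::rnorm(400, 0, j_sd), 20, 20))
}

#' Exact pair distribution of a planted model
#'
#' @param pm A [planted_model()].
#' @return 20x20 matrix of probabilities summing to 1 (rows: position i).
#' @export
pair_distribution <- function(pm) {
  logw <- -outer(pm$h_i, pm$h_j, "+") - pm$J
  w <- exp(logw - max(logw))
  w / sum(w)
}

#' Generate a match ensemble with planted sequence statistics
#'
#' Samples `n_matches` central-pair sequences exactly from the planted model's
#' normalised 400-outcome distribution and attaches per-match backbone
#' descriptors drawn from the geometry spec (template dihedrals plus noise,
#' omega = 180, uniform burial levels) and increasing pseudo-RMSDs below the
#' flank-appropriate cutoff.
#'
#' @param pm A [planted_model()].
#' @param geometry A [generator_spec()] providing the dihedral template/noise.
#' @param n_matches Ensemble size.
#' @param seed Integer seed.
#' @param flank Flank width k (0, 1 or 2) used only for the nominal cutoff.
#' @return A `scp_ensemble` (see [search_matches()]).
#' @export
generate_planted_ensemble <- function(pm, geometry = generator_spec(),
                                      n_matches = 1000L, seed = 1L, flank = 1L) {
  stopifnot(inherits(pm, "scp_planted_model"), n_matches >= 1)
  set.seed(seed)
  p <- pair_distribution(pm)
  draw <- sample.int(400L, n_matches, replace = TRUE, prob = as.numeric(p))
  ai <- ((draw - 1L) %% 20L) + 1L     # row index (position i)
  aj <- ((draw - 1L) %/% 20L) + 1L    # column index (position j)
  aa <- aa_alphabet()
  cutoff <- default_rmsd_cutoff(flank)
  ang <- function(which) geometry$template[[which]] +
    stats::rnorm(n_matches, 0, geometry$sigma)
  matches <- tibble::tibble(
    structure_id = sprintf("synthmatch_%05d", seq_len(n_matches)),
    chain_i = "A", pos_i = (geometry$seg_len - 1L) %/% 2L,
    chain_j = "B", pos_j = (geometry$seg_len - 1L) %/% 2L,
    rmsd = sort(stats::runif(n_matches, 0, cutoff)),
    swapped = FALSE,
    aa_i = aa[ai], aa_j = aa[aj],
    phi_i = ang("phi"), psi_i = ang("psi"),
    omega_i = rep(180, n_matches),
    burial_i = sample(0:4, n_matches, replace = TRUE),
    phi_j = ang("phi"), psi_j = ang("psi"),
    omega_j = rep(180, n_matches),
    burial_j = sample(0:4, n_matches, replace = TRUE))
  new_ensemble(matches, query = NULL, cutoff = cutoff, max_count = n_matches,
               flank = flank)
}

#' Plant central-pair residue types from a coupling model
#'
#' Re-assigns the amino acids of the two central residues (chains A and B) of
#' every structure in a synthetic database by sampling from a planted model.
#' `pm` may also be a function of the structure returning a model, which lets
#' the couplings vary with geometry.
#'
#' @param db List of two-segment synthetic structures.
#' @param pm A [planted_model()] or `function(structure) -> planted_model`.
#' @param seed Integer seed.
#' @return The database with central residue types replanted.
#' @export
plant_central_pair <- function(db, pm, seed = 1L) {
  set.seed(seed)
  aa <- aa_alphabet()
  lapply(db, function(s) {
    m <- if (is.function(pm)) pm(s) else pm
    p <- pair_distribution(m)
    draw <- sample.int(400L, 1L, prob = as.numeric(p))
    ai <- ((draw - 1L) %% 20L) + 1L
    aj <- ((draw - 1L) %/% 20L) + 1L
    for (ch in c("A", "B")) {
      ii <- which(s$chain == ch)
      cen <- ii[(length(ii) + 1L) %/% 2L]
      s$aa[cen] <- if (ch == "A") aa[ai] else aa[aj]
    }
    s
  })
}

#' Generate a noise-graded decoy set
#'
#' Adds isotropic Gaussian coordinate noise to every backbone atom of the
#' native structure, `per_level` decoys per noise level, and labels each decoy
#' with its best-fit backbone RMSD to the native.
#'
#' @param native A complete structure.
#' @param noise_levels Numeric vector of noise standard deviations (Angstrom).
#' @param per_level Decoys per level.
#' @param seed Integer seed.
#' @return List with `decoys` (named list of structures) and `labels` (tibble
#'   with `model_id`, `noise`, `rmsd`).
#' @export
generate_model_set <- function(native, noise_levels, per_level = 5L, seed = 1L) {
  stopifnot(all(native$complete))
  set.seed(seed)
  nat_xyz <- .bb_coords(native)
  decoys <- list(); labels <- NULL
  for (lev in noise_levels) {
    for (r in seq_len(per_level)) {
      id <- sprintf("decoy_n%.2f_r%02d", lev, r)
      s <- native
      for (col in .coord_cols) s[[col]] <- s[[col]] + stats::rnorm(nrow(s), 0, lev)
      attr(s, "id") <- id
      s <- compute_dihedrals(s)
      decoys[[id]] <- s
      labels <- dplyr::bind_rows(labels, tibble::tibble(
        model_id = id, noise = lev,
        rmsd = kabsch_rmsd(nat_xyz, .bb_coords(s))))
    }
  }
  list(decoys = decoys, labels = labels)
}

#' Remove additive row/column offsets from a 20x20 matrix
#'
#' Double-centering: subtracts row means and column means and adds back the
#' grand mean. Log-odds energies identify a planted coupling matrix only up to
#' additive row/column gauge terms, so recovery comparisons are made in the
#' double-centered gauge.
#'
#' @param m A numeric matrix.
#' @return Matrix with zero row and column means.
#' @export
double_center <- function(m) {
  m <- unclass(as.matrix(m))
  sweep(sweep(m, 1, rowMeans(m)), 2, colMeans(m)) + mean(m)
}
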