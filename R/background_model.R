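# Hierarchical first-order pseudo-energy E1 over phi/psi, omega and burial
# bins. The three tiers are trained in sequence: the phi/psi potential against
# database amino-acid frequencies, the omega potential against expectations
# implied by the phi/psi tier, and the burial potential against expectations
# implied by both.

#' Burial neighbour count
#'
#' Number of CA atoms within `radius` of each residue's CA, excluding the
#' residue itself and its two same-chain sequence neighbours. A standard
#' coordination-number proxy for burial.
#'
#' @param s A structure.
#' @param radius Neighbour radius in Angstrom (default 12).
#' @return Integer vector, one count per residue (NA where CA is missing).
#' @export
burial_count <- function(s, radius = 12) {
  ca <- as.matrix(tibble::as_tibble(s)[, c("ca_x", "ca_y", "ca_z")])
  n <- nrow(ca)
  out <- rep(NA_integer_, n)
  fin <- which(rowSums(is.finite(ca)) == 3L)
  if (length(fin) < 1L) return(out)
  cam <- ca[fin, , drop = FALSE]
  d2 <- outer(rowSums(cam^2), rowSums(cam^2), "+") - 2 * cam %*% t(cam)
  within <- d2 <= radius^2
  diag(within) <- FALSE
  # exclude +-1 same-chain neighbours
  ch <- s$chain[fin]; ps <- s$pos[fin]
  nb <- outer(ch, ch, "==") & abs(outer(ps, ps, "-")) <= 1L
  within[nb] <- FALSE
  out[fin] <- as.integer(rowSums(within))
  out
}

#' Burial level of one residue
#'
#' Bins the burial neighbour count into discrete levels `0..L-1`.
#'
#' @param s A structure.
#' @param chain,pos Residue address.
#' @param radius Neighbour radius (default 12).
#' @param edges Count bin edges (default quintile-like fixed edges
#'   `c(3, 8, 13, 18)`: counts below 3 are level 0, etc.).
#' @return Integer level.
#' @export
burial_level <- function(s, chain, pos, radius = 12, edges = c(3, 8, 13, 18)) {
  row <- which(s$chain == chain & s$pos == pos)
  if (length(row) != 1L) stop("no residue at ", chain, ":", pos)
  cnt <- burial_count(s, radius = radius)[row]
  findInterval(cnt, edges)
}

.phi_psi_bin <- function(ang, width = 10) {
  # half-open (lo, hi] bins over (-180, 180]; -180 folds into the first bin
  b <- ceiling((ang + 180) / width)
  b[b < 1L] <- 1L
  nb <- as.integer(360 / width)
  b[b > nb] <- nb
  as.integer(b)
}

.omega_bin <- function(omega, cis_halfwidth = 30) {
  # 1 = trans (the remainder), 2 = cis [-30, 30]
  ifelse(abs(omega) <= cis_halfwidth, 2L, 1L)
}

#' Train the hierarchical background model
#'
#' Estimates, from a structure database, how much each amino acid prefers
#' regions of backbone dihedral space and burial:
#' \itemize{
#'   \item phi/psi tier: 10 x 10 degree bins; energy
#'     `-log((N_obs(a, bin) + pc) / (freq(a) * N(bin) + pc))`.
#'   \item omega tier: cis/trans bins, conditioned on the phi/psi tier (the
#'     expectation for each bin is the sum of smoothed phi/psi-conditional
#'     amino-acid probabilities of the residues observed in that bin). The cis
#'     bin is merged into trans when it holds fewer than `min_omega_obs`
#'     observations.
#'   \item burial tier: quintile levels of the burial neighbour count,
#'     conditioned on both previous tiers.
#' }
#'
#' @param db A structure or list of structures with dihedrals computed.
#' @param pseudocount Training pseudocount per cell (default 1).
#' @param burial_radius Radius for [burial_count()] (default 12).
#' @param n_burial Number of burial levels (default 5).
#' @param min_omega_obs Minimum observations to keep the cis bin separate.
#' @return A `scp_background` model.
#' @export
train_background <- function(db, pseudocount = 1, burial_radius = 12,
                             n_burial = 5L, min_omega_obs = 50L) {
  if (inherits(db, "scp_structure")) db <- list(db)
  res <- purrr::map_dfr(db, function(s) {
    r <- tibble::as_tibble(s)
    r$burial <- burial_count(s, radius = burial_radius)
    r
  })
  res <- res[!is.na(res$aa) & is.finite(res$phi) & is.finite(res$psi) &
               is.finite(res$omega) & !is.na(res$burial), , drop = FALSE]
  if (nrow(res) == 0L) stop("no trainable residues in database")
  aa <- aa_alphabet()
  pc <- pseudocount
  ai <- aa_index(res$aa)
  freq <- as.numeric(table(factor(res$aa, levels = aa))) / nrow(res)
  # --- phi/psi tier ---
  bp <- .phi_psi_bin(res$phi); bq <- .phi_psi_bin(res$psi)
  cell <- (bp - 1L) * 36L + bq            # 1..1296
  n_cell <- tabulate(cell, 1296L)
  n_obs <- matrix(0, 1296L, 20L)
  for (k in seq_along(cell)) n_obs[cell[k], ai[k]] <- n_obs[cell[k], ai[k]] + 1
  n_exp <- outer(n_cell, freq)
  e_pp <- -log((n_obs + pc) / (n_exp + pc))
  # smoothed conditional P(a | phi/psi cell), used by the higher tiers
  p_cond1 <- (n_obs + pc) / (n_cell + 20 * pc)
  # --- omega tier ---
  ob <- .omega_bin(res$omega)
  omega_merged <- sum(ob == 2L) < min_omega_obs
  if (omega_merged) ob[] <- 1L
  n_om <- max(ob)
  obs_om <- matrix(0, n_om, 20L)
  exp_om <- matrix(0, n_om, 20L)
  for (k in seq_along(ob)) {
    obs_om[ob[k], ai[k]] <- obs_om[ob[k], ai[k]] + 1
    exp_om[ob[k], ] <- exp_om[ob[k], ] + p_cond1[cell[k], ]
  }
  e_om <- -log((obs_om + pc) / (exp_om + pc))
  # conditional over both tiers, per residue, for the burial expectations
  w2 <- p_cond1[cell, , drop = FALSE] * exp(-e_om[ob, , drop = FALSE])
  w2 <- w2 / rowSums(w2)
  # --- burial tier ---
  qs <- stats::quantile(res$burial, probs = seq_len(n_burial - 1L) / n_burial,
                        type = 1)
  edges <- sort(unique(as.numeric(qs)))
  lev <- findInterval(res$burial, edges + 0.5) + 1L   # 1..L
  n_lev <- max(lev)
  obs_b <- matrix(0, n_lev, 20L)
  exp_b <- matrix(0, n_lev, 20L)
  for (k in seq_along(lev)) {
    obs_b[lev[k], ai[k]] <- obs_b[lev[k], ai[k]] + 1
    exp_b[lev[k], ] <- exp_b[lev[k], ] + w2[k, ]
  }
  e_b <- -log((obs_b + pc) / (exp_b + pc))
  structure(list(phi_psi_energy = e_pp, omega_energy = e_om,
                 burial_energy = e_b, burial_edges = edges,
                 omega_merged = omega_merged, aa_freq = stats::setNames(freq, aa),
                 pseudocount = pc, n_residues = nrow(res), flat = FALSE),
            class = "scp_background")
}

#' Flat (uniform) background model
#'
#' A background under which every amino acid is equally preferred everywhere:
#' `e1()` is identically zero. Used for closed-form limits and null
#' experiments.
#'
#' @return A `scp_background` with all energies zero.
#' @export
flat_background <- function() {
  structure(list(phi_psi_energy = matrix(0, 1296L, 20L),
                 omega_energy = matrix(0, 1L, 20L),
                 burial_energy = matrix(0, 1L, 20L),
                 burial_edges = numeric(0), omega_merged = TRUE,
                 aa_freq = uniform_aa_freq(), pseudocount = 0,
                 n_residues = 0L, flat = TRUE),
            class = "scp_background")
}

#' @export
print.scp_background <- function(x, ...) {
  cat(sprintf("<scp_background> %s (%d training residues, %d burial levels)\n",
              if (x$flat) "flat" else "trained", x$n_residues,
              nrow(x$burial_energy)))
  invisible(x)
}

# E1 for all 20 amino acids at a set of descriptor rows; returns n x 20 matrix
e1_profile <- function(bg, phi, psi, omega, burial) {
  n <- length(phi)
  out <- matrix(0, n, 20L)
  if (bg$flat) return(out)
  ok_pp <- is.finite(phi) & is.finite(psi)
  if (any(ok_pp)) {
    cell <- (.phi_psi_bin(phi[ok_pp]) - 1L) * 36L + .phi_psi_bin(psi[ok_pp])
    out[ok_pp, ] <- out[ok_pp, , drop = FALSE] + bg$phi_psi_energy[cell, , drop = FALSE]
  }
  ok_om <- is.finite(omega)
  if (any(ok_om)) {
    ob <- .omega_bin(omega[ok_om])
    if (nrow(bg$omega_energy) == 1L) ob[] <- 1L
    out[ok_om, ] <- out[ok_om, , drop = FALSE] + bg$omega_energy[ob, , drop = FALSE]
  }
  ok_b <- is.finite(burial)
  if (any(ok_b) && nrow(bg$burial_energy) > 0L) {
    lev <- findInterval(burial[ok_b], bg$burial_edges + 0.5) + 1L
    lev[lev > nrow(bg$burial_energy)] <- nrow(bg$burial_energy)
    out[ok_b, ] <- out[ok_b, , drop = FALSE] + bg$burial_energy[lev, , drop = FALSE]
  }
  out
}

#' First-order pseudo-energy of an amino acid in a backbone context
#'
#' Sum of the three hierarchical terms (phi/psi, omega, burial) at the mapped
#' bins. Undefined dihedrals drop the corresponding term (falling back to the
#' remaining tiers).
#'
#' @param bg A `scp_background`.
#' @param aa One-letter amino acid (vectorised).
#' @param phi,psi,omega Dihedrals in degrees (NA allowed).
#' @param burial Burial neighbour count (NA allowed).
#' @return Numeric pseudo-energy vector.
#' @export
e1 <- function(bg, aa, phi, psi, omega = NA_real_, burial = NA_real_) {
  n <- max(length(aa), length(phi), length(psi), length(omega), length(burial))
  aa <- rep_len(aa, n); phi <- rep_len(phi, n); psi <- rep_len(psi, n)
  omega <- rep_len(omega, n); burial <- rep_len(burial, n)
  prof <- e1_profile(bg, phi, psi, omega, burial)
  prof[cbind(seq_len(n), aa_index(aa))]
}

#' Write / read a background model as JSON
#'
#' @param bg A `scp_background`.
#' @param path File path.
#' @return `path` invisibly; for the reader, a `scp_background`.
#' @export
write_background <- function(bg, path) {
  jsonlite::write_json(list(
    phi_psi_energy = bg$phi_psi_energy, omega_energy = bg$omega_energy,
    burial_energy = bg$burial_energy, burial_edges = bg$burial_edges,
    omega_merged = bg$omega_merged, aa_freq = as.list(bg$aa_freq),
    pseudocount = bg$pseudocount, n_residues = bg$n_residues, flat = bg$flat),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_background
#' @export
read_background <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(phi_psi_energy = as.matrix(x$phi_psi_energy),
                 omega_energy = matrix(as.matrix(x$omega_energy),
                                       ncol = 20L),
                 burial_energy = matrix(as.matrix(x$burial_energy),
                                        ncol = 20L),
                 burial_edges = as.numeric(x$burial_edges),
                 omega_merged = isTRUE(x$omega_merged),
                 aa_freq = unlist(x$aa_freq),
                 pseudocount = x$pseudocount,
                 n_residues = x$n_residues, flat = isTRUE(x$flat)),
            class = "scp_background")
}
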