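# Contact degree (CD): the probability-weighted fraction of mutually
# interfering rotamer pairs between two positions, and CD-stratified contact
# databases.

#' Contact-degree bin scheme
#'
#' The 11 geometric CD intervals used for stratified sampling and the binned
#' contact potentials: `[0, 2^-10), [2^-10, 2^-9), ..., [2^-1, 1]`.
#'
#' @return Numeric vector of 12 bin edges.
#' @export
cd_bin_edges <- function() c(0, 2^(-(10:1)), 1)

#' Map CD values to bins
#'
#' Half-open bins `[lo, hi)` except the last, which is closed at 1.
#'
#' @param cd Numeric vector in `[0, 1]`.
#' @return Integer bin index in 1..11.
#' @export
cd_bin <- function(cd) {
  stopifnot(all(cd >= 0 & cd <= 1))
  findInterval(cd, cd_bin_edges(), rightmost.closed = TRUE)
}

#' Contact degree between two positions
#'
#' Places all allowed rotamers of all 20 amino acids at both positions and
#' returns the probability-weighted fraction of mutually interfering rotamer
#' pairs: `CD = sum_{a,b} sum_{ri, rj} C(ri, rj) P(a) P(b) P(ri) P(rj)`, where
#' `C(ri, rj)` is 1 when any pair of heavy atoms between the two rotamers is
#' within `interfere_radius` (3 Angstrom). CD is 0 when no placeable rotamer
#' pair clashes and 1 when all pairs do.
#'
#' @param s A structure.
#' @param chain_i,pos_i,chain_j,pos_j Residue addresses.
#' @param lib A `scp_rotlib`.
#' @param p_aa Amino-acid background probabilities: a named numeric vector
#'   over the canonical alphabet, or NULL for uniform.
#' @param interfere_radius Heavy-atom interference distance (default 3).
#' @param clash_radius Main-chain clash threshold for rotamer placement.
#' @return CD value in `[0, 1]`.
#' @export
contact_degree <- function(s, chain_i, pos_i, chain_j, pos_j, lib,
                           p_aa = NULL, interfere_radius = 3,
                           clash_radius = 2.5) {
  if (is.null(p_aa)) p_aa <- uniform_aa_freq()
  p_aa <- p_aa[aa_alphabet()]
  # cheap reach-based prefilter on the CA-CA distance
  ca_i <- residue_backbone(s, chain_i, pos_i)["CA", ]
  ca_j <- residue_backbone(s, chain_j, pos_j)["CA", ]
  d_ca <- sqrt(sum((ca_i - ca_j)^2))
  max_reach <- .sc_geom$b_ca_cb + (max(.sc_topology$n_atoms) - 1L) * .sc_geom$b_cc
  if (d_ca > 2 * max_reach + interfere_radius) return(0)
  ri <- allowed_rotamers(s, chain_i, pos_i, lib, clash_radius = clash_radius)
  rj <- allowed_rotamers(s, chain_j, pos_j, lib, clash_radius = clash_radius)
  if (nrow(ri) == 0L || nrow(rj) == 0L) {
    warning("no placeable rotamer at one of the positions; CD = 0")
    return(0)
  }
  .cd_from_rotamers(ri, rj, p_aa, interfere_radius)
}

# probability-weighted interfering fraction from two allowed-rotamer tables
.cd_from_rotamers <- function(ri, rj, p_aa, interfere_radius = 3) {
  cd <- 0
  for (ki in seq_len(nrow(ri))) {
    ai <- ri$atoms[[ki]]
    if (nrow(ai) == 0L) next
    wi <- p_aa[[ri$aa[ki]]] * ri$prob[ki]
    if (wi == 0) next
    for (kj in seq_len(nrow(rj))) {
      aj <- rj$atoms[[kj]]
      if (nrow(aj) == 0L) next
      d2 <- outer(rowSums(ai^2), rowSums(aj^2), "+") - 2 * ai %*% t(aj)
      if (min(d2) <= interfere_radius^2) {
        cd <- cd + wi * p_aa[[rj$aa[kj]]] * rj$prob[kj]
      }
    }
  }
  cd
}

#' Enumerate contacts of a structure
#'
#' Computes the contact degree for every eligible residue pair: same-chain
#' pairs with at least `min_seq_sep` residues between the two positions, and
#' all cross-chain pairs. A pair is eligible only if the full
#' `(2*flank+1)`-residue windows around both positions are present,
#' backbone-complete, contiguous in residue numbering, and the central
#' residues are canonical.
#'
#' @param s A structure with dihedrals computed.
#' @param lib A `scp_rotlib`.
#' @param min_seq_sep Minimum number of residues between same-chain contacts
#'   (default 5).
#' @param flank Flank width whose windows must be complete (default 2, the
#'   5x5 requirement used at database construction).
#' @param p_aa Amino-acid background probabilities (default: frequencies of
#'   the structure itself).
#' @param cd_min Keep only contacts with CD at or above this value (default 0,
#'   i.e. keep all pairs including CD = 0).
#' @return Tibble of contact records: `structure_id`, addresses, `aa_i`,
#'   `aa_j`, `cd`, `seq_sep` (NA for cross-chain contacts).
#' @export
enumerate_contacts <- function(s, lib, min_seq_sep = 5L, flank = 2L,
                               p_aa = NULL, cd_min = 0) {
  if (is.null(p_aa)) p_aa <- db_aa_freq(s)
  ok_window <- function(chain, pos) {
    rows <- which(s$chain == chain & s$pos >= pos - flank & s$pos <= pos + flank)
    length(rows) == 2L * flank + 1L && all(s$complete[rows]) &&
      (length(rows) == 1L || all(diff(s$resno[rows]) == 1L))
  }
  cand <- NULL
  res <- tibble::as_tibble(s)
  eligible <- which(res$complete & !is.na(res$aa))
  eligible <- eligible[vapply(eligible, function(r) ok_window(res$chain[r], res$pos[r]),
                              logical(1))]
  if (length(eligible) >= 2L) {
    idx <- t(utils::combn(eligible, 2L))
    same <- res$chain[idx[, 1]] == res$chain[idx[, 2]]
    sep <- abs(res$pos[idx[, 2]] - res$pos[idx[, 1]]) - 1L
    keep <- !same | sep >= min_seq_sep
    idx <- idx[keep, , drop = FALSE]
    cand <- tibble::tibble(ri = idx[, 1], rj = idx[, 2],
                           seq_sep = ifelse(same[keep], sep[keep], NA_integer_))
  }
  if (is.null(cand) || nrow(cand) == 0L) {
    return(tibble::tibble(structure_id = character(), chain_i = character(),
                          pos_i = integer(), chain_j = character(),
                          pos_j = integer(), aa_i = character(),
                          aa_j = character(), cd = numeric(),
                          seq_sep = integer()))
  }
  # prefilter on CA distance, then compute rotamers once per position
  p_aa <- p_aa[aa_alphabet()]
  max_reach <- .sc_geom$b_ca_cb + (max(.sc_topology$n_atoms) - 1L) * .sc_geom$b_cc
  ca <- as.matrix(res[, c("ca_x", "ca_y", "ca_z")])
  d_ca <- sqrt(rowSums((ca[cand$ri, , drop = FALSE] -
                          ca[cand$rj, , drop = FALSE])^2))
  near <- d_ca <= 2 * max_reach + 3
  rot_cache <- new.env(parent = emptyenv())
  get_rot <- function(r) {
    key <- as.character(r)
    if (is.null(rot_cache[[key]])) {
      rot_cache[[key]] <- allowed_rotamers(s, res$chain[r], res$pos[r], lib)
    }
    rot_cache[[key]]
  }
  cd <- numeric(nrow(cand))
  for (k in which(near)) {
    ri <- get_rot(cand$ri[k]); rj <- get_rot(cand$rj[k])
    if (nrow(ri) == 0L || nrow(rj) == 0L) next
    cd[k] <- .cd_from_rotamers(ri, rj, p_aa)
  }
  out <- tibble::tibble(
    structure_id = structure_id(s),
    chain_i = res$chain[cand$ri], pos_i = res$pos[cand$ri],
    chain_j = res$chain[cand$rj], pos_j = res$pos[cand$rj],
    aa_i = res$aa[cand$ri], aa_j = res$aa[cand$rj],
    cd = cd, seq_sep = cand$seq_sep)
  out[out$cd >= cd_min, , drop = FALSE]
}

#' Sample a CD-stratified contact database
#'
#' Draws up to `per_bin` contacts uniformly at random without replacement
#' from each of the 11 contact-degree bins. Bins holding fewer records
#' contribute what they have (with a message). Deterministic given `seed`.
#'
#' @param records Tibble of contact records (see [enumerate_contacts()]).
#' @param per_bin Target number of contacts per bin.
#' @param seed Integer seed.
#' @return A `scp_contact_db` tibble: the sampled records with a `bin` column.
#' @export
sample_contact_database <- function(records, per_bin, seed = 1L) {
  stopifnot(per_bin >= 1L)
  if (is.null(records) || nrow(records) == 0L) stop("no contact records to sample from")
  set.seed(seed)
  records$bin <- cd_bin(records$cd)
  out <- records |>
    dplyr::group_by(.data$bin) |>
    dplyr::slice_sample(n = per_bin) |>
    dplyr::ungroup()
  short <- out |>
    dplyr::count(.data$bin) |>
    dplyr::filter(.data$n < per_bin)
  if (nrow(short) > 0L) {
    message("bins with fewer than ", per_bin, " records: ",
            paste(short$bin, collapse = ", "))
  }
  structure(out, class = c("scp_contact_db", class(out)), per_bin = per_bin)
}

#' Write / read contact records as TSV
#'
#' @param records Contact record tibble.
#' @param path File path.
#' @return `path` invisibly; for the reader, a tibble of records.
#' @export
write_contacts <- function(records, path) {
  readr::write_tsv(tibble::as_tibble(records), path)
  invisible(path)
}

#' @rdname write_contacts
#' @export
read_contacts <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
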