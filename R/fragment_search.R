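# Interaction motifs and structural fragment search.
#
# An interaction motif is two backbone segments centered on a contacting
# residue pair, with flank width k in {0, 1, 2} (1x1, 3x3, 5x5). Matches are
# collected by exhaustive scan over all same-length window pairs in a
# structure database, ranked by best-fit backbone RMSD over all four backbone
# atoms (N, CA, C, O).

#' Default RMSD cutoff for a motif flank width
#'
#' The size-dependent ensemble cutoffs: 1.0 Angstrom for 1x1 motifs (k = 0),
#' 0.79 for 3x3 (k = 1) and 0.77 for 5x5 (k = 2).
#'
#' @param flank Flank width k, one of 0, 1, 2.
#' @return Cutoff in Angstrom.
#' @export
default_rmsd_cutoff <- function(flank) {
  if (!length(flank) == 1L || !flank %in% 0:2) {
    stop("flank must be 0, 1 or 2 (1x1, 3x3 or 5x5 motifs)")
  }
  c(`0` = 1.0, `1` = 0.79, `2` = 0.77)[[as.character(flank)]]
}

#' Extract an interaction motif from a structure
#'
#' Builds the (2k+1)+(2k+1)-residue motif centered on the contacting pair.
#' Both windows must be backbone-complete and contiguous in residue numbering.
#' The segment whose address sorts lower (chain, then position) is stored
#' first.
#'
#' @param s A structure.
#' @param chain_i,pos_i,chain_j,pos_j Addresses of the contacting residues
#'   (`pos` is the 0-based internal index).
#' @param flank Flank width k in {0, 1, 2}.
#' @return A `scp_motif`: source addresses, flank, the ordered
#'   `2*(2k+1)*4 x 3` backbone coordinate matrix and central residue types.
#' @export
extract_motif <- function(s, chain_i, pos_i, chain_j, pos_j, flank = 1L) {
  default_rmsd_cutoff(flank) # validates flank
  if (chain_j < chain_i || (chain_i == chain_j && pos_j < pos_i)) {
    tmp <- list(chain_i, pos_i); chain_i <- chain_j; pos_i <- pos_j
    chain_j <- tmp[[1]]; pos_j <- tmp[[2]]
  }
  win <- function(chain, pos) {
    rows <- which(s$chain == chain & s$pos >= pos - flank & s$pos <= pos + flank)
    sub <- s[rows, , drop = FALSE]
    if (nrow(sub) != 2L * flank + 1L) stop("window incomplete at ", chain, ":", pos)
    if (!all(sub$complete)) stop("incomplete backbone in window at ", chain, ":", pos)
    if (nrow(sub) > 1L && any(diff(sub$resno) != 1L)) {
      stop("chain break in window at ", chain, ":", pos)
    }
    sub
  }
  wi <- win(chain_i, pos_i); wj <- win(chain_j, pos_j)
  if (chain_i == chain_j && pos_j - pos_i < 2L * flank + 2L) {
    stop("motif segments overlap or touch")
  }
  structure(list(structure_id = structure_id(s),
                 chain_i = chain_i, pos_i = pos_i,
                 chain_j = chain_j, pos_j = pos_j, flank = as.integer(flank),
                 coords = rbind(.bb_coords(wi), .bb_coords(wj)),
                 aa_i = wi$aa[flank + 1L], aa_j = wj$aa[flank + 1L]),
            class = "scp_motif")
}

#' @export
print.scp_motif <- function(x, ...) {
  cat(sprintf("<scp_motif> %s %s:%d -- %s:%d (flank %d, %d atoms)\n",
              x$structure_id, x$chain_i, x$pos_i, x$chain_j, x$pos_j,
              x$flank, nrow(x$coords)))
  invisible(x)
}

# constructor shared by search_matches and the synthetic ensemble generator
new_ensemble <- function(matches, query = NULL, cutoff = NA_real_,
                         max_count = NA_integer_, flank = NA_integer_) {
  matches <- tibble::as_tibble(matches)
  o <- order(matches$rmsd, matches$structure_id, matches$chain_i,
             matches$pos_i, matches$chain_j, matches$pos_j)
  structure(list(query = query, matches = matches[o, , drop = FALSE],
                 cutoff = cutoff, max_count = max_count,
                 flank = as.integer(flank)),
            class = "scp_ensemble")
}

#' @export
print.scp_ensemble <- function(x, ...) {
  cat(sprintf("<scp_ensemble> %d matches (flank %s, cutoff %.3g A)\n",
              nrow(x$matches), x$flank, x$cutoff))
  invisible(x)
}

#' Number of matches in an ensemble
#' @param ens A `scp_ensemble`.
#' @return Integer count.
#' @export
n_matches <- function(ens) nrow(ens$matches)

# enumerate complete, numbering-contiguous windows of length L in a structure;
# returns a list of row-index vectors plus bookkeeping tibble
.windows <- function(s, L) {
  out_rows <- list(); meta <- NULL
  for (ch in unique(s$chain)) {
    ii <- which(s$chain == ch)
    if (length(ii) < L) next
    ok <- s$complete[ii]
    contig <- c(diff(s$resno[ii]) == 1L, FALSE)
    for (start in seq_len(length(ii) - L + 1L)) {
      idx <- start:(start + L - 1L)
      if (!all(ok[idx])) next
      if (L > 1L && !all(contig[idx[-L]])) next
      out_rows[[length(out_rows) + 1L]] <- ii[idx]
      meta <- rbind(meta, data.frame(chain = ch, pos = s$pos[ii[start + (L - 1L) %/% 2L]],
                                     start_pos = s$pos[ii[start]],
                                     stringsAsFactors = FALSE))
    }
  }
  list(rows = out_rows, meta = meta)
}

#' Precompute the window decomposition of a structure database
#'
#' Extracts, once per structure, everything [search_matches()] needs per
#' query: the complete backbone windows of length `2*flank+1`, their
#' coordinate blocks, central CA positions and central-residue descriptors.
#' Searching many motifs of the same flank against the same database is much
#' faster with a prepared database.
#'
#' @param db A structure or list of structures (dihedrals computed).
#' @param flank Flank width k in {0, 1, 2}.
#' @param burial_radius Radius for the burial neighbour count descriptor.
#' @return A `scp_search_db` usable as the `db` argument of
#'   [search_matches()].
#' @export
prepare_search_db <- function(db, flank = 1L, burial_radius = 12) {
  if (inherits(db, "scp_structure")) db <- list(db)
  L <- 2L * as.integer(flank) + 1L
  cen <- as.integer(flank) + 1L
  prepared <- lapply(db, function(s) {
    w <- .windows(s, L)
    bur <- burial_count(s, radius = burial_radius)
    blocks <- lapply(w$rows, function(r) .bb_coords(s[r, , drop = FALSE]))
    cas <- if (length(blocks)) {
      t(vapply(blocks, function(b) b[4L * (cen - 1L) + 2L, ], numeric(3)))
    } else matrix(numeric(0), 0, 3)
    crows <- vapply(w$rows, function(r) r[cen], integer(1))
    list(id = structure_id(s), meta = w$meta, blocks = blocks, cas = cas,
         desc = tibble::tibble(aa = s$aa[crows], phi = s$phi[crows],
                               psi = s$psi[crows], omega = s$omega[crows],
                               burial = bur[crows]))
  })
  structure(list(structures = prepared, flank = as.integer(flank)),
            class = "scp_search_db")
}

#' Search a structure database for motif matches
#'
#' Exhaustive scan over all placements of two disjoint same-length backbone
#' windows within each database structure (both same-chain, separated by at
#' least one residue, and cross-chain placements). Both segment-assignment
#' orders are scored by [kabsch_rmsd()] and the better one kept, with the
#' `swapped` flag recording when the query's first segment aligned to the
#' target's second window; central residue types and descriptors are
#' order-corrected accordingly. Results are sorted by ascending RMSD (ties by
#' structure id and addresses) and truncated to `max_count`.
#'
#' A conservative central-CA distance prefilter (bound derived from the
#' triangle inequality: RMSD >= |d_query - d_target| / (2 sqrt(n))) is applied
#' before superposition; it cannot change the result set.
#'
#' @param q A `scp_motif` query.
#' @param db A structure or list of structures (dihedrals computed).
#' @param cutoff Maximum RMSD in Angstrom (default: flank-based cutoff).
#' @param max_count Maximum number of matches kept (default 50,000).
#' @param include_self Keep the query's own occurrence (default TRUE).
#' @param burial_radius Radius for the burial neighbour count descriptor.
#' @return A `scp_ensemble` whose `matches` tibble has one row per match:
#'   addresses, `rmsd`, `swapped`, central residue types `aa_i`/`aa_j` and
#'   central backbone descriptors (`phi`, `psi`, `omega`, `burial` counts).
#' @export
search_matches <- function(q, db, cutoff = NULL, max_count = 50000L,
                           include_self = TRUE, burial_radius = 12) {
  stopifnot(inherits(q, "scp_motif"))
  if (!inherits(db, "scp_search_db")) {
    db <- prepare_search_db(db, flank = q$flank, burial_radius = burial_radius)
  }
  if (db$flank != q$flank) stop("prepared database flank differs from the query")
  if (length(db$structures) == 0L) stop("empty structure database")
  if (is.null(cutoff)) cutoff <- default_rmsd_cutoff(q$flank)
  stopifnot(cutoff > 0)
  L <- 2L * q$flank + 1L
  qc <- q$coords
  if (!all(is.finite(qc))) stop("query motif has incomplete coordinates")
  npts <- nrow(qc)
  cen <- q$flank + 1L                      # central residue within a window
  ca_off <- 4L * (cen - 1L) + 2L
  d_q <- sqrt(sum((qc[ca_off, ] - qc[npts / 2 + ca_off, ])^2))
  pre_tol <- 2 * sqrt(npts) * cutoff
  # center the query once: the cross-covariance with a centered query is
  # invariant to the target's translation, so targets need no re-centering
  q0 <- sweep(qc, 2, colMeans(qc))
  gq <- sum(q0 * q0)
  half <- npts / 2
  q0_top <- q0[1:half, , drop = FALSE]
  q0_bot <- q0[(half + 1):npts, , drop = FALSE]
  rmsd_from_h <- function(h, gb) {
    sv <- svd(h)
    tr <- sv$d[1] + sv$d[2] + sign(det(sv$v %*% t(sv$u))) * sv$d[3]
    sqrt(max((gq + gb - 2 * tr) / npts, 0))
  }
  res <- list()
  for (p in db$structures) {
    nw <- length(p$blocks)
    if (nw < 2L) next
    blocks <- p$blocks; cas <- p$cas; meta <- p$meta; desc <- p$desc
    bsum <- lapply(blocks, colSums)
    bsq <- vapply(blocks, function(b) sum(b * b), numeric(1))
    hits <- NULL
    for (i in seq_len(nw - 1L)) {
      for (j in (i + 1L):nw) {
        if (meta$chain[i] == meta$chain[j]) {
          gap <- meta$start_pos[j] - (meta$start_pos[i] + L - 1L) - 1L
          if (gap < 1L) next
        }
        d_t <- sqrt(sum((cas[i, ] - cas[j, ])^2))
        if (abs(d_t - d_q) > pre_tol) next
        tm <- (bsum[[i]] + bsum[[j]]) / npts
        gb <- bsq[i] + bsq[j] - npts * sum(tm * tm)
        h_ti <- crossprod(q0_top, blocks[[i]])
        h_bj <- crossprod(q0_bot, blocks[[j]])
        h_tj <- crossprod(q0_top, blocks[[j]])
        h_bi <- crossprod(q0_bot, blocks[[i]])
        r12 <- rmsd_from_h(h_ti + h_bj, gb)
        r21 <- rmsd_from_h(h_tj + h_bi, gb)
        swapped <- r21 < r12
        r <- min(r12, r21)
        if (r > cutoff) next
        a <- if (swapped) j else i
        b <- if (swapped) i else j
        hits <- rbind(hits, c(a, b, r, swapped))
      }
    }
    if (!is.null(hits)) {
      a <- hits[, 1]; b <- hits[, 2]
      res[[length(res) + 1L]] <- tibble::tibble(
        structure_id = p$id,
        chain_i = meta$chain[a], pos_i = meta$pos[a],
        chain_j = meta$chain[b], pos_j = meta$pos[b],
        rmsd = hits[, 3], swapped = hits[, 4] > 0,
        aa_i = desc$aa[a], aa_j = desc$aa[b],
        phi_i = desc$phi[a], psi_i = desc$psi[a],
        omega_i = desc$omega[a], burial_i = desc$burial[a],
        phi_j = desc$phi[b], psi_j = desc$psi[b],
        omega_j = desc$omega[b], burial_j = desc$burial[b])
    }
  }
  matches <- if (length(res)) dplyr::bind_rows(res) else tibble::tibble(
    structure_id = character(), chain_i = character(), pos_i = integer(),
    chain_j = character(), pos_j = integer(), rmsd = numeric(),
    swapped = logical(), aa_i = character(), aa_j = character(),
    phi_i = numeric(), psi_i = numeric(), omega_i = numeric(),
    burial_i = numeric(), phi_j = numeric(), psi_j = numeric(),
    omega_j = numeric(), burial_j = numeric())
  if (!include_self && nrow(matches)) {
    self <- matches$structure_id == q$structure_id &
      ((matches$chain_i == q$chain_i & matches$pos_i == q$pos_i &
          matches$chain_j == q$chain_j & matches$pos_j == q$pos_j) |
         (matches$chain_i == q$chain_j & matches$pos_i == q$pos_j &
            matches$chain_j == q$chain_i & matches$pos_j == q$pos_i))
    matches <- matches[!self, , drop = FALSE]
  }
  ens <- new_ensemble(matches, query = q, cutoff = cutoff,
                      max_count = max_count, flank = q$flank)
  if (n_matches(ens) > max_count) {
    ens$matches <- ens$matches[seq_len(max_count), , drop = FALSE]
  }
  ens
}

#' Truncate a match ensemble
#'
#' Restrict an ensemble to its best matches, either by count or by an RMSD
#' cap. Used for ensemble-size sweeps.
#'
#' @param ens A `scp_ensemble`.
#' @param max_matches Keep at most this many lowest-RMSD matches.
#' @param rmsd_max Keep only matches with RMSD at or below this value.
#' @return The truncated ensemble.
#' @export
truncate_ensemble <- function(ens, max_matches = NULL, rmsd_max = NULL) {
  m <- ens$matches
  if (!is.null(rmsd_max)) m <- m[m$rmsd <= rmsd_max, , drop = FALSE]
  if (!is.null(max_matches)) m <- m[seq_len(min(nrow(m), max_matches)), , drop = FALSE]
  ens$matches <- m
  if (!is.null(rmsd_max)) ens$cutoff <- rmsd_max
  ens
}

#' Write / read a match ensemble as TSV
#'
#' @param ens A `scp_ensemble`.
#' @param path File path.
#' @return `path` invisibly; for the reader, a `scp_ensemble`.
#' @export
write_ensemble <- function(ens, path) {
  readr::write_tsv(ens$matches, path)
  invisible(path)
}

#' @rdname write_ensemble
#' @param flank,cutoff,max_count Metadata to attach on read.
#' @export
read_ensemble <- function(path, flank = 1L, cutoff = NA_real_,
                          max_count = NA_integer_) {
  m <- readr::read_tsv(path, show_col_types = FALSE)
  new_ensemble(m, cutoff = cutoff, max_count = max_count, flank = flank)
}
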