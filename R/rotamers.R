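# Rotamer libraries and side-chain template construction.
#
# Side-chain heavy atoms are modelled as a coarse linear chain grown from the
# backbone by ideal internal coordinates, with the library's chi angles as the
# successive torsions. This deliberately simple heavy-atom model is sufficient
# for clash counting, which is all the contact-degree metric needs.

# number of side-chain heavy atoms along the coarse chain and number of chi
# torsions consumed (first atom, CB, uses a fixed improper)
.sc_topology <- tibble::tribble(
  ~aa, ~n_atoms, ~n_chi,
  "A", 1L, 0L, "R", 6L, 4L, "N", 3L, 2L, "D", 3L, 2L, "C", 2L, 1L,
  "Q", 4L, 3L, "E", 4L, 3L, "G", 0L, 0L, "H", 4L, 2L, "I", 3L, 2L,
  "L", 3L, 2L, "K", 5L, 4L, "M", 4L, 3L, "F", 4L, 2L, "P", 2L, 1L,
  "S", 2L, 1L, "T", 2L, 1L, "W", 5L, 2L, "Y", 5L, 2L, "V", 2L, 1L
)

.sc_geom <- list(b_ca_cb = 1.53, a_n_ca_cb = 110.5, t_c_n_ca_cb = -122.6,
                 b_cc = 1.52, a_cc = 113)

#' Build side-chain template atoms onto a backbone frame
#'
#' Grows the coarse heavy-atom chain for amino acid `aa` from the residue's
#' backbone N/CA/C atoms: CB from a fixed improper, then one atom per chi
#' torsion (remaining atoms extended at 180 degrees).
#'
#' @param aa One-letter amino-acid code.
#' @param chis Numeric vector of chi angles in degrees (recycled/truncated to
#'   the residue's chi count).
#' @param N,CA,C Backbone atom coordinates (length-3 vectors).
#' @return k x 3 matrix of side-chain heavy-atom coordinates (0 rows for Gly).
#' @export
build_rotamer_atoms <- function(aa, chis, N, CA, C) {
  top <- .sc_topology[.sc_topology$aa == aa, ]
  if (nrow(top) == 0L) stop("unknown amino acid: ", aa)
  n_at <- top$n_atoms
  if (n_at == 0L) return(matrix(numeric(0), 0, 3))
  g <- .sc_geom
  atoms <- matrix(NA_real_, n_at, 3)
  atoms[1, ] <- place_atom(C, N, CA, g$b_ca_cb, g$a_n_ca_cb, g$t_c_n_ca_cb)
  if (n_at >= 2L) {
    prev2 <- N; prev1 <- CA; cur <- atoms[1, ]
    for (t in 2:n_at) {
      tor <- if (t - 1L <= length(chis) && is.finite(chis[t - 1L])) chis[t - 1L] else 180
      nxt <- place_atom(prev2, prev1, cur, g$b_cc, g$a_cc, tor)
      atoms[t, ] <- nxt
      prev2 <- prev1; prev1 <- cur; cur <- nxt
    }
  }
  atoms
}

new_rotamer_library <- function(rotamers, backbone_dependent = FALSE) {
  rotamers <- tibble::as_tibble(rotamers)
  stopifnot(all(c("aa", "rot_id", "prob", "chi") %in% names(rotamers)))
  sums <- rotamers |>
    dplyr::group_by(.data$aa, .data$phi, .data$psi) |>
    dplyr::summarise(p = sum(.data$prob), .groups = "drop")
  if (any(abs(sums$p - 1) > 1e-6)) {
    stop("rotamer probabilities must sum to 1 per amino acid (per backbone bin)")
  }
  structure(list(rotamers = rotamers, backbone_dependent = backbone_dependent),
            class = "scp_rotlib")
}

#' @export
print.scp_rotlib <- function(x, ...) {
  cat(sprintf("<scp_rotlib> %d rotamers, %d amino acids%s\n",
              nrow(x$rotamers), dplyr::n_distinct(x$rotamers$aa),
              if (x$backbone_dependent) ", backbone-dependent" else ""))
  invisible(x)
}

#' Deterministic toy rotamer library
#'
#' A small backbone-independent library for tests and synthetic experiments:
#' up to `n_rot` rotamers per amino acid at canonical chi-1 values (-60, 180,
#' 60 degrees; further chis extended) with probabilities proportional to
#' (0.5, 0.3, 0.2).
#'
#' @param n_rot Rotamers per amino acid (1 to 3).
#' @param aas Amino acids to include (default all 20).
#' @return A `scp_rotlib`.
#' @export
toy_rotamer_library <- function(n_rot = 3L, aas = aa_alphabet()) {
  stopifnot(n_rot >= 1L, n_rot <= 3L)
  chi1 <- c(-60, 180, 60)[seq_len(n_rot)]
  p <- c(0.5, 0.3, 0.2)[seq_len(n_rot)]
  p <- p / sum(p)
  rot <- purrr::map_dfr(aas, function(a) {
    nchi <- .sc_topology$n_chi[.sc_topology$aa == a]
    tibble::tibble(aa = a, rot_id = seq_len(n_rot), prob = p,
                   phi = NA_real_, psi = NA_real_,
                   chi = purrr::map(chi1, function(x) {
                     if (nchi == 0L) numeric(0) else c(x, rep(180, max(0L, nchi - 1L)))
                   }))
  })
  new_rotamer_library(rot, backbone_dependent = FALSE)
}

#' Read a rotamer library from disk
#'
#' Two dialects are supported. `"tsv"` is the native fixture dialect with
#' columns `aa` (one-letter), `rot_id`, `prob`, `chi1..chi4` and optional
#' `phi`/`psi` columns for backbone-dependent tables. `"dunbrack"` parses the
#' whitespace-delimited backbone-dependent format (`aa3 phi psi count r1-r4
#' prob chi1-chi4 ...`), keeping the chi means and probabilities.
#'
#' @param path File path.
#' @param format `"tsv"` or `"dunbrack"`.
#' @return A `scp_rotlib`.
#' @export
read_rotamer_library <- function(path, format = c("tsv", "dunbrack")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- readr::read_tsv(path, show_col_types = FALSE)
    if (!"phi" %in% names(tab)) tab$phi <- NA_real_
    if (!"psi" %in% names(tab)) tab$psi <- NA_real_
    chi_cols <- intersect(paste0("chi", 1:4), names(tab))
    tab$chi <- purrr::pmap(tab[chi_cols], function(...) {
      v <- c(...)
      v[is.finite(v)]
    })
    bbd <- any(is.finite(tab$phi))
    new_rotamer_library(tab[, c("aa", "rot_id", "prob", "phi", "psi", "chi")],
                        backbone_dependent = bbd)
  } else {
    lines <- readLines(path)
    lines <- lines[!grepl("^\\s*(#|$)", lines)]
    f <- do.call(rbind, strsplit(trimws(lines), "\\s+"))
    aa1 <- unname(.aa3to1[toupper(f[, 1])])
    keep <- !is.na(aa1)
    f <- f[keep, , drop = FALSE]; aa1 <- aa1[keep]
    tab <- tibble::tibble(
      aa = aa1,
      phi = as.numeric(f[, 2]), psi = as.numeric(f[, 3]),
      prob = as.numeric(f[, 9]),
      chi = purrr::map(seq_len(nrow(f)), function(i) {
        v <- as.numeric(f[i, 10:13])
        nchi <- .sc_topology$n_chi[.sc_topology$aa == aa1[i]]
        v[seq_len(min(nchi, 4L))]
      }))
    tab <- tab |>
      dplyr::group_by(.data$aa, .data$phi, .data$psi) |>
      dplyr::mutate(rot_id = dplyr::row_number(),
                    prob = .data$prob / sum(.data$prob)) |>
      dplyr::ungroup()
    new_rotamer_library(tab, backbone_dependent = TRUE)
  }
}

# rotamer rows applicable at a residue: nearest phi/psi bin if bb-dependent
.rot_rows_for <- function(lib, phi, psi) {
  rot <- lib$rotamers
  if (!lib$backbone_dependent) return(rot)
  if (!is.finite(phi) || !is.finite(psi)) {
    # fall back to the bin nearest the helical region centre
    phi <- -60; psi <- -45
  }
  angdist <- function(a, b) {
    d <- abs(a - b) %% 360
    pmin(d, 360 - d)
  }
  rot |>
    dplyr::group_by(.data$aa) |>
    dplyr::mutate(.d = angdist(.data$phi, !!phi) + angdist(.data$psi, !!psi)) |>
    dplyr::filter(.data$.d == min(.data$.d)) |>
    dplyr::mutate(prob = .data$prob / sum(.data$prob)) |>
    dplyr::ungroup() |>
    dplyr::select(-".d")
}

#' Placeable ("allowed") rotamers at a position
#'
#' Builds every library rotamer of every amino acid onto the residue's
#' backbone frame and removes those clashing with the main chain: a rotamer is
#' disallowed if any of its side-chain heavy atoms lies within `clash_radius`
#' of any backbone heavy atom of a residue other than itself and its two
#' sequence neighbours. Probabilities are left unrenormalised by default, so
#' heavily occluded positions carry less total probability mass.
#'
#' @param s A structure.
#' @param chain,pos Residue address.
#' @param lib A `scp_rotlib`.
#' @param clash_radius Main-chain clash threshold in Angstrom (default 2.5).
#' @param renormalize Renormalise probabilities over surviving rotamers per
#'   amino acid (default FALSE).
#' @return Tibble with columns `aa`, `rot_id`, `prob` and a list-column
#'   `atoms` of global side-chain coordinates.
#' @export
allowed_rotamers <- function(s, chain, pos, lib, clash_radius = 2.5,
                             renormalize = FALSE) {
  row <- which(s$chain == chain & s$pos == pos)
  if (length(row) != 1L) stop("no residue at ", chain, ":", pos)
  if (!s$complete[row]) stop("residue backbone incomplete at ", chain, ":", pos)
  bb <- residue_backbone(s, chain, pos)
  rot <- .rot_rows_for(lib, s$phi[row], s$psi[row])
  # backbone atoms of all residues except self and sequence neighbours
  excl <- s$chain == chain & abs(s$pos - pos) <= 1L
  other <- s[!excl & s$complete, , drop = FALSE]
  obb <- if (nrow(other)) .bb_coords(other) else matrix(numeric(0), 0, 3)
  atoms <- purrr::pmap(list(rot$aa, rot$chi), function(a, ch) {
    build_rotamer_atoms(a, ch, bb["N", ], bb["CA", ], bb["C", ])
  })
  ok <- vapply(atoms, function(at) {
    if (nrow(at) == 0L || nrow(obb) == 0L) return(TRUE)
    d2 <- outer(rowSums(at^2), rowSums(obb^2), "+") - 2 * at %*% t(obb)
    min(d2) >= clash_radius^2
  }, logical(1))
  out <- rot[ok, c("aa", "rot_id", "prob")]
  out$atoms <- atoms[ok]
  if (renormalize && nrow(out)) {
    out <- out |>
      dplyr::group_by(.data$aa) |>
      dplyr::mutate(prob = .data$prob / sum(.data$prob)) |>
      dplyr::ungroup()
  }
  out
}
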