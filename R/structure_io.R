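# Structure input/output and per-residue backbone descriptors.
#
# A structure is represented as a tibble with one row per residue and
# coordinate columns for the four backbone atoms (N, CA, C, O), carrying the
# structure id and experimental metadata as attributes. This keeps all
# downstream operations vectorised and pipe-friendly.

.bb_atoms <- c("n", "ca", "c", "o")
.coord_cols <- as.vector(t(outer(.bb_atoms, c("x", "y", "z"), paste, sep = "_")))

#' Construct a structure object from a residue table
#'
#' Low-level constructor used by [read_structure()] and the synthetic
#' generators. Most users will not call this directly.
#'
#' @param residues Tibble with columns `chain`, `resno`, `aa` (one-letter code
#'   or NA for non-canonical residues) and the twelve backbone coordinate
#'   columns `n_x ... o_z`.
#' @param id Structure identifier.
#' @param resolution Optional resolution in Angstrom.
#' @param method Optional experimental method string.
#' @return A `scp_structure` tibble with 0-based per-chain `pos` indices and a
#'   backbone-completeness flag.
#' @export
new_structure <- function(residues, id = "struct", resolution = NA_real_,
                          method = NA_character_) {
  res <- tibble::as_tibble(residues)
  stopifnot(all(c("chain", "resno", "aa", .coord_cols) %in% names(res)))
  res <- res |>
    dplyr::group_by(.data$chain) |>
    dplyr::mutate(pos = dplyr::row_number() - 1L) |>
    dplyr::ungroup()
  bad <- res |>
    dplyr::group_by(.data$chain) |>
    dplyr::summarise(ok = !is.unsorted(.data$resno, strictly = TRUE)) |>
    dplyr::filter(!.data$ok)
  if (nrow(bad) > 0L) {
    stop("residue numbers not strictly increasing in chain(s): ",
         paste(bad$chain, collapse = ", "))
  }
  coord <- as.matrix(res[, .coord_cols])
  res$complete <- rowSums(is.finite(coord)) == 12L
  for (col in c("phi", "psi", "omega")) {
    if (!col %in% names(res)) res[[col]] <- NA_real_
  }
  res <- res[, c("chain", "pos", "resno", "aa", "complete",
                 .coord_cols, "phi", "psi", "omega",
                 setdiff(names(res), c("chain", "pos", "resno", "aa", "complete",
                                       .coord_cols, "phi", "psi", "omega")))]
  structure(res,
            class = c("scp_structure", class(tibble::tibble())),
            id = id, resolution = resolution, method = method)
}

#' @export
print.scp_structure <- function(x, ...) {
  cat(sprintf("<scp_structure> %s: %d residues in %d chain(s)\n",
              structure_id(x), nrow(x), dplyr::n_distinct(x$chain)))
  NextMethod()
}

#' Structure identifier
#' @param s A structure.
#' @return The id string.
#' @export
structure_id <- function(s) attr(s, "id", exact = TRUE) %||% "struct"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a protein structure from a PDB file or text
#'
#' Parses ATOM/HETATM records (first MODEL only) through \pkg{bio3d} and
#' reduces them to one row per residue holding the four backbone atoms.
#' Selenomethionine (MSE) is mapped to MET; other non-canonical amino acids
#' are retained with `aa = NA` so that chain continuity is preserved, and are
#' removed by [filter_chains()]. Alternate locations are resolved to the
#' highest-occupancy conformer (ties broken by file order). Residues missing
#' any of N, CA, C, O are flagged incomplete. Gzipped files are handled
#' transparently.
#'
#' @param x Path to a PDB file (optionally `.gz`) or a character scalar of PDB
#'   text.
#' @param id Structure id; defaults to the file base name.
#' @return A `scp_structure` tibble (see [new_structure()]).
#' @export
read_structure <- function(x, id = NULL) {
  if (length(x) != 1L || !is.character(x)) stop("x must be a single path or PDB text")
  path <- x
  cleanup <- character()
  if (grepl("\n", x) || !file.exists(x)) {
    if (!grepl("^(ATOM|HETATM|HEADER|MODEL|REMARK|CRYST|TITLE|EXPDTA)", x)) {
      stop("input is neither an existing file nor PDB-format text")
    }
    path <- tempfile(fileext = ".pdb")
    writeLines(x, path)
    cleanup <- path
    if (is.null(id)) id <- "struct"
  }
  if (grepl("\\.gz$", path)) {
    raw <- readLines(gzfile(path))
    path2 <- tempfile(fileext = ".pdb")
    writeLines(raw, path2)
    cleanup <- c(cleanup, path2)
    path <- path2
  }
  if (is.null(id)) id <- sub("\\.(pdb|ent)(\\.gz)?$", "", basename(x))
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("failed to parse PDB input: ", conditionMessage(e)))
  if (length(cleanup)) unlink(cleanup)
  at <- tibble::as_tibble(pdb$atom)
  at$chain[is.na(at$chain)] <- " "
  at <- at |>
    dplyr::filter(toupper(.data$elety) %in% c("N", "CA", "C", "O")) |>
    dplyr::mutate(elety = toupper(.data$elety),
                  o = ifelse(is.na(.data$o), 1, .data$o),
                  ord = dplyr::row_number())
  # resolve alternate locations: highest occupancy, ties -> first encountered
  at <- at |>
    dplyr::group_by(.data$chain, .data$resno, .data$insert, .data$elety) |>
    dplyr::arrange(dplyr::desc(.data$o), .data$ord, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$ord)
  # a residue must carry both N and CA records to count as protein
  keep <- at |>
    dplyr::group_by(.data$chain, .data$resno, .data$insert) |>
    dplyr::filter(any(.data$elety == "N") && any(.data$elety == "CA")) |>
    dplyr::ungroup()
  if (nrow(keep) == 0L) stop("no protein residues found in input")
  res <- keep |>
    dplyr::group_by(.data$chain, .data$resno, .data$insert) |>
    dplyr::summarise(
      aa = unname(.aa3to1[.data$resid[1]]),
      n_x = .data$x[match("N", .data$elety)],
      n_y = .data$y[match("N", .data$elety)],
      n_z = .data$z[match("N", .data$elety)],
      ca_x = .data$x[match("CA", .data$elety)],
      ca_y = .data$y[match("CA", .data$elety)],
      ca_z = .data$z[match("CA", .data$elety)],
      c_x = .data$x[match("C", .data$elety)],
      c_y = .data$y[match("C", .data$elety)],
      c_z = .data$z[match("C", .data$elety)],
      o_x = .data$x[match("O", .data$elety)],
      o_y = .data$y[match("O", .data$elety)],
      o_z = .data$z[match("O", .data$elety)],
      ord = min(.data$ord),
      .groups = "drop") |>
    dplyr::arrange(.data$ord) |>
    dplyr::select(-"ord", -"insert")
  new_structure(res, id = id,
                resolution = .pdb_resolution(pdb),
                method = .pdb_method(pdb))
}

.pdb_resolution <- function(pdb) {
  # bio3d does not expose resolution for all files; best effort
  r <- tryCatch(as.numeric(pdb$resolution), error = function(e) NA_real_)
  if (length(r) == 0L || all(is.na(r))) NA_real_ else r[1]
}

.pdb_method <- function(pdb) {
  m <- tryCatch(pdb$method, error = function(e) NULL)
  if (is.null(m) || length(m) == 0L) NA_character_ else as.character(m)[1]
}

#' Write a structure to a PDB file
#'
#' Backbone atoms only (N, CA, C, O), written through [bio3d::write.pdb()].
#' Residues with incomplete backbones are skipped.
#'
#' @param s A structure.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  res <- s[s$complete, , drop = FALSE]
  if (nrow(res) == 0L) stop("no complete residues to write")
  aa3 <- names(.aa3to1)[match(res$aa, .aa3to1)]
  aa3[is.na(aa3)] <- "UNK"
  n <- nrow(res)
  xyz <- matrix(NA_real_, 4L * n, 3L)
  for (k in seq_along(.bb_atoms)) {
    cols <- paste0(.bb_atoms[k], c("_x", "_y", "_z"))
    xyz[seq(k, by = 4L, length.out = n), ] <- as.matrix(res[, cols])
  }
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(xyz)),
                   resno = rep(res$resno, each = 4L),
                   chain = rep(res$chain, each = 4L),
                   resid = rep(aa3, each = 4L),
                   elety = rep(c("N", "CA", "C", "O"), n),
                   o = rep(1, 4L * n), b = rep(0, 4L * n))
  invisible(path)
}

#' Filter chains by length and drop non-canonical residues
#'
#' Non-canonical residues (anything that did not map to the 20 canonical amino
#' acids) are removed first; chains whose remaining length falls outside
#' `[min_len, max_len]` are then dropped entirely. Idempotent.
#'
#' @param s A structure.
#' @param min_len,max_len Inclusive chain-length bounds (defaults 40 and
#'   10,000, the bounds used for database construction).
#' @return Filtered structure (possibly with zero rows).
#' @export
filter_chains <- function(s, min_len = 40L, max_len = 10000L) {
  stopifnot(min_len <= max_len)
  res <- s |>
    dplyr::filter(!is.na(.data$aa)) |>
    dplyr::group_by(.data$chain) |>
    dplyr::filter(dplyr::n() >= min_len, dplyr::n() <= max_len) |>
    dplyr::ungroup()
  new_structure(res[, c("chain", "resno", "aa", .coord_cols, "phi", "psi", "omega")],
                id = structure_id(s),
                resolution = attr(s, "resolution", exact = TRUE),
                method = attr(s, "method", exact = TRUE))
}

#' Compute backbone dihedral angles
#'
#' Populates `phi`, `psi` and `omega` (degrees, range `(-180, 180]`) for every
#' residue whose own backbone and the required neighbour atoms are present.
#' `omega` of residue i is the torsion of the peptide bond between residues
#' i-1 and i (CA, C of i-1; N, CA of i). Residues at chain termini or next to
#' a numbering gap keep `NA` for the affected angles.
#'
#' @param s A structure.
#' @return The structure with dihedral columns filled.
#' @export
compute_dihedrals <- function(s) {
  res <- s
  for (ch in unique(res$chain)) {
    ii <- which(res$chain == ch)
    sub <- res[ii, ]
    n <- nrow(sub)
    get <- function(at) as.matrix(sub[, paste0(at, c("_x", "_y", "_z"))])
    N <- get("n"); CA <- get("ca"); C <- get("c")
    prev_ok <- c(FALSE, diff(sub$resno) == 1L) & c(FALSE, sub$complete[-n]) & sub$complete
    next_ok <- c(diff(sub$resno) == 1L, FALSE) & c(sub$complete[-1], FALSE) & sub$complete
    phi <- psi <- omega <- rep(NA_real_, n)
    if (any(prev_ok)) {
      j <- which(prev_ok)
      phi[j] <- torsion_angle(C[j - 1L, , drop = FALSE], N[j, , drop = FALSE],
                              CA[j, , drop = FALSE], C[j, , drop = FALSE])
      omega[j] <- torsion_angle(CA[j - 1L, , drop = FALSE], C[j - 1L, , drop = FALSE],
                                N[j, , drop = FALSE], CA[j, , drop = FALSE])
    }
    if (any(next_ok)) {
      j <- which(next_ok)
      psi[j] <- torsion_angle(N[j, , drop = FALSE], CA[j, , drop = FALSE],
                              C[j, , drop = FALSE], N[j + 1L, , drop = FALSE])
    }
    res$phi[ii] <- phi; res$psi[ii] <- psi; res$omega[ii] <- omega
  }
  res
}

#' Combine structures into one residue table
#'
#' @param db A structure or (possibly named) list of structures.
#' @return Tibble of residues with a `structure_id` column prepended.
#' @export
bind_structures <- function(db) {
  if (inherits(db, "scp_structure")) db <- list(db)
  purrr::map_dfr(db, function(s) {
    tibble::as_tibble(s) |>
      dplyr::mutate(structure_id = structure_id(s), .before = 1L)
  })
}

# 4x3 backbone coordinate matrix (N, CA, C, O) for one residue
residue_backbone <- function(s, chain, pos) {
  row <- which(s$chain == chain & s$pos == pos)
  if (length(row) != 1L) stop("no residue at ", chain, ":", pos)
  matrix(as.numeric(s[row, .coord_cols]), nrow = 4L, byrow = TRUE,
         dimnames = list(c("N", "CA", "C", "O"), c("x", "y", "z")))
}

# all-backbone coordinate matrix for a run of residues (rows of s)
.bb_coords <- function(res_rows) {
  n <- nrow(res_rows)
  out <- matrix(NA_real_, 4L * n, 3L)
  m <- as.matrix(res_rows[, .coord_cols])
  for (k in 1:4) out[seq(k, by = 4L, length.out = n), ] <- m[, (3 * k - 2):(3 * k), drop = FALSE]
  out
}
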