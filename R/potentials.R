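# Contact potentials, CD-binned potentials and structure-conditioned energies.
#
# All energies are dimensionless -log ratios of observed over expected pair
# counts; they differ only in the set of contacts the counts come from (a
# generic database, a CD bin, or the match ensemble of one interaction motif)
# and in the reference state used for the expectation.

#' Construct an energy matrix
#'
#' @param values 20x20 numeric matrix in canonical amino-acid order.
#' @param symmetric Whether the matrix is symmetric by construction.
#' @param provenance List describing how the matrix was computed
#'   (`type` one of "CP", "CDP", "SCE"; free-form extras).
#' @param n Number of contacts or matches behind the statistics.
#' @param check_finite Reject non-finite entries (TRUE except for
#'   pseudocount-free energies, where unobserved pairs are infinite).
#' @return A `scp_energy` matrix.
#' @export
new_energy_matrix <- function(values, symmetric = FALSE,
                              provenance = list(type = "CP"), n = NA_integer_,
                              check_finite = TRUE) {
  stopifnot(is.matrix(values), all(dim(values) == c(20, 20)))
  if (check_finite) stopifnot(all(is.finite(values)))
  # without a pseudocount, unobserved/unexpected pairs are +/-Inf; 0/0 pairs
  # carry no signal and are set to 0
  values[is.nan(values)] <- 0
  aa <- aa_alphabet()
  dimnames(values) <- list(aa, aa)
  structure(values, class = c("scp_energy", "matrix", "array"),
            symmetric = symmetric, provenance = provenance, n = n)
}

#' @export
print.scp_energy <- function(x, ...) {
  p <- attr(x, "provenance", exact = TRUE)
  cat(sprintf("<scp_energy> %s (n = %s%s)\n", p$type %||% "?",
              attr(x, "n", exact = TRUE),
              if (isTRUE(attr(x, "symmetric", exact = TRUE))) ", symmetric" else ""))
  print(round(unclass(x), 3))
  invisible(x)
}

#' Tidy an energy matrix into a long tibble
#'
#' @param x A `scp_energy`.
#' @param ... Unused.
#' @return Tibble with columns `aa_i`, `aa_j`, `energy`.
#' @exportS3Method generics::tidy
tidy.scp_energy <- function(x, ...) {
  aa <- aa_alphabet()
  tibble::tibble(aa_i = rep(aa, times = 20),
                 aa_j = rep(aa, each = 20),
                 energy = as.numeric(unclass(x)))
}

#' One-row summary of an energy matrix
#'
#' @param x A `scp_energy`.
#' @param ... Unused.
#' @return One-row tibble with provenance type, n, symmetry flag and the
#'   energy range.
#' @exportS3Method generics::glance
glance.scp_energy <- function(x, ...) {
  p <- attr(x, "provenance", exact = TRUE)
  tibble::tibble(type = p$type %||% NA_character_,
                 n = attr(x, "n", exact = TRUE),
                 symmetric = isTRUE(attr(x, "symmetric", exact = TRUE)),
                 min_energy = min(x), max_energy = max(x))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

.epsilon <- function(n_obs, n_exp, mode = c("max", "fixed", "laplace", "none")) {
  mode <- match.arg(mode)
  switch(mode,
         max = pmax(n_obs, n_exp, 1) / 20,
         fixed = 0.05,
         laplace = 1,
         none = 0)
}

# ordered 20x20 pair count matrix from character vectors
.pair_count_matrix <- function(aa_i, aa_j) {
  m <- matrix(0, 20, 20, dimnames = list(aa_alphabet(), aa_alphabet()))
  t <- table(factor(aa_i, levels = aa_alphabet()),
             factor(aa_j, levels = aa_alphabet()))
  m[] <- as.numeric(t)
  m
}

#' Traditional contact potential
#'
#' Log-odds pair pseudo-energies over a set of contacts:
#' `E(a,b) = -log((N_obs(a,b) + eps) / (N_exp(a,b) + eps))` with the
#' quasichemical reference `N_exp(a,b) = n_c f(a) f(b) H(a,b)`, where
#' `N_obs(a,b)` sums the two orders of heterotypic pairs, `n_c` is the number
#' of contacts, `f(a)` the fraction of amino acid `a` among all contact
#' residues and `H(a,b) = 2 - I(a=b)` doubles the heterotypic expectation (the
#' potential is directionless). With this normalisation the expectations sum
#' to the number of observed contacts, so a database with no pair preferences
#' gives energies that are zero up to counting noise. Symmetric by
#' construction.
#'
#' @param records Contact records (tibble with `aa_i`, `aa_j`).
#' @param epsilon_mode Pseudocount mode: `"max"` (default,
#'   `max(N_obs, N_exp, 1)/20`), `"fixed"` (0.05), `"laplace"` (1) or
#'   `"none"`.
#' @return A symmetric `scp_energy` with provenance type "CP".
#' @export
contact_potential <- function(records, epsilon_mode = "max") {
  records <- tibble::as_tibble(records)
  if (nrow(records) < 1L) stop("need at least one contact record")
  ordered <- .pair_count_matrix(records$aa_i, records$aa_j)
  eye <- diag(20)
  n_obs_pair <- ordered + (1 - eye) * t(ordered)
  marg <- rowSums(ordered) + colSums(ordered)   # homotypic residues counted twice
  f <- marg / (2 * nrow(records))
  h <- 2 - eye
  n_exp <- nrow(records) * outer(f, f) * h
  eps <- .epsilon(n_obs_pair, n_exp, epsilon_mode)
  e <- -log((n_obs_pair + eps) / (n_exp + eps))
  new_energy_matrix(e, symmetric = TRUE,
                    provenance = list(type = "CP", epsilon_mode = epsilon_mode),
                    n = nrow(records), check_finite = epsilon_mode != "none")
}

#' Contact-degree-binned contact potentials
#'
#' One contact potential per CD bin of a stratified contact database. Empty
#' bins yield a zero matrix flagged with `n = 0`.
#'
#' @param dbase Contact records carrying a `cd` column (e.g. a
#'   [sample_contact_database()] result).
#' @param epsilon_mode Passed to [contact_potential()].
#' @return Named list of 11 `scp_energy` matrices (provenance type "CDP" with
#'   the bin index and CD interval).
#' @export
cd_binned_potentials <- function(dbase, epsilon_mode = "max") {
  dbase <- tibble::as_tibble(dbase)
  dbase$bin <- cd_bin(dbase$cd)
  edges <- cd_bin_edges()
  out <- lapply(1:11, function(b) {
    sub <- dbase[dbase$bin == b, , drop = FALSE]
    if (nrow(sub) == 0L) {
      return(new_energy_matrix(matrix(0, 20, 20), symmetric = TRUE,
                               provenance = list(type = "CDP", bin = b,
                                                 cd_lo = edges[b], cd_hi = edges[b + 1],
                                                 zero_count = TRUE),
                               n = 0L))
    }
    e <- contact_potential(sub, epsilon_mode = epsilon_mode)
    attr(e, "provenance") <- list(type = "CDP", bin = b, cd_lo = edges[b],
                                  cd_hi = edges[b + 1],
                                  epsilon_mode = epsilon_mode)
    e
  })
  names(out) <- sprintf("bin%02d", 1:11)
  out
}

#' Look up the CD-binned potential for a contact degree
#'
#' @param cdps Result of [cd_binned_potentials()].
#' @param cd A CD value.
#' @return The `scp_energy` of the corresponding bin.
#' @export
cdp_lookup <- function(cdps, cd) cdps[[cd_bin(cd)]]

#' Expected pair counts of a match ensemble under the background model
#'
#' The reference state of the structure-conditioned energy. For each match m
#' and position p, the probability of amino acid a is the double-softmax
#' `p_m(a) = exp(-E1(a|m_p) - Delta_p(a)) / sum_a' exp(-E1(a'|m_p) -
#' Delta_p(a'))`, where the residual `Delta_p(a) = -ln(N_o(a) / N_e(a))`
#' pushes the expected marginals onto the observed ones and
#' `N_e(a) = sum_m softmax_a(-E1(a|m_p))` is the first-order expectation.
#' The expected pair count is `N_exp(a,b) = sum_m p_m(a at i) p_m(b at j)`.
#'
#' Amino acids never observed at a position receive zero weight (the
#' `delta = 0` default applies the residual as a multiplicative marginal ratio,
#' so no infinite energies are ever formed); a positive `delta` smooths the
#' ratio to `(N_o + delta) / (N_e + delta)`.
#'
#' Matches flagged as swapped were already order-corrected by
#' [search_matches()], so every row contributes its `i` descriptors to
#' position i.
#'
#' @param ens A `scp_ensemble`.
#' @param bg A `scp_background`.
#' @param delta Residual smoothing count (default 0).
#' @return A `scp_expectation`: `n_exp` (20x20), per-position observed and
#'   expected marginals, residuals `delta_i`/`delta_j` and the per-match
#'   probability matrices `p_i`, `p_j`.
#' @export
expected_pair_counts <- function(ens, bg, delta = 0) {
  m <- ens$matches
  if (nrow(m) < 1L) stop("empty match ensemble")
  aa <- aa_alphabet()
  one_side <- function(suffix) {
    prof <- e1_profile(bg, m[[paste0("phi_", suffix)]], m[[paste0("psi_", suffix)]],
                       m[[paste0("omega_", suffix)]], m[[paste0("burial_", suffix)]])
    w0 <- exp(-prof)
    p0 <- w0 / rowSums(w0)
    n_e <- colSums(p0)
    n_o <- as.numeric(table(factor(m[[paste0("aa_", suffix)]], levels = aa)))
    ratio <- (n_o + delta) / (n_e + delta)
    w <- sweep(p0, 2, ratio, "*")
    p <- w / rowSums(w)
    list(p = p, n_e = stats::setNames(n_e, aa), n_o = stats::setNames(n_o, aa),
         delta = stats::setNames(-log(ratio), aa))
  }
  si <- one_side("i"); sj <- one_side("j")
  n_exp <- crossprod(si$p, sj$p)
  dimnames(n_exp) <- list(aa, aa)
  structure(list(n_exp = n_exp, n_matches = nrow(m),
                 n_obs_i = si$n_o, n_obs_j = sj$n_o,
                 n_e_i = si$n_e, n_e_j = sj$n_e,
                 delta_i = si$delta, delta_j = sj$delta,
                 p_i = si$p, p_j = sj$p, delta_smoothing = delta),
            class = "scp_expectation")
}

#' @export
print.scp_expectation <- function(x, ...) {
  cat(sprintf("<scp_expectation> %d matches, sum(N_exp) = %.6f\n",
              x$n_matches, sum(x$n_exp)))
  invisible(x)
}

#' Structure-conditioned energy matrix
#'
#' The 20x20 SCE matrix of an interaction motif:
#' `SCE(a_i, a_j) = -log((N_obs(a_i, a_j) + eps) / (N_exp(a_i, a_j) + eps))`
#' over the central-pair counts of the motif's match ensemble, with the
#' expectation from [expected_pair_counts()]. The matrix is ordered (position
#' i indexes rows); use [symmetrize()] for comparisons against symmetric
#' contact potentials.
#'
#' @param ens A `scp_ensemble`.
#' @param bg A `scp_background`.
#' @param epsilon_mode Pseudocount mode (see [contact_potential()]).
#' @param delta Residual smoothing passed to [expected_pair_counts()].
#' @param min_matches Ensemble size below which a warning is issued
#'   (default 1,000, the size below which sparse statistics dominate).
#' @return A `scp_energy` with provenance type "SCE".
#' @export
sce_matrix <- function(ens, bg, epsilon_mode = "max", delta = 0,
                       min_matches = 1000L) {
  m <- ens$matches
  if (nrow(m) < 1L) stop("empty match ensemble")
  if (nrow(m) < min_matches) {
    warning("ensemble has only ", nrow(m), " matches (< ", min_matches,
            "); SCEs may be dominated by sparse statistics")
  }
  n_obs <- .pair_count_matrix(m$aa_i, m$aa_j)
  exp_model <- expected_pair_counts(ens, bg, delta = delta)
  n_exp <- exp_model$n_exp
  eps <- .epsilon(n_obs, n_exp, epsilon_mode)
  e <- -log((n_obs + eps) / (n_exp + eps))
  new_energy_matrix(e, symmetric = FALSE,
                    provenance = list(type = "SCE", epsilon_mode = epsilon_mode,
                                      cutoff = ens$cutoff, flank = ens$flank),
                    n = nrow(m), check_finite = epsilon_mode != "none")
}

#' Symmetrize an energy matrix
#'
#' `(E + t(E)) / 2`, with the symmetric flag set.
#'
#' @param e A `scp_energy`.
#' @return Symmetric `scp_energy`.
#' @export
symmetrize <- function(e) {
  v <- (unclass(e) + t(unclass(e))) / 2
  new_energy_matrix(v, symmetric = TRUE,
                    provenance = attr(e, "provenance", exact = TRUE),
                    n = attr(e, "n", exact = TRUE))
}

#' Write / read an energy matrix
#'
#' TSV: a header row plus 20 rows in canonical order, first column the row
#' amino acid. JSON adds the provenance block.
#'
#' @param e A `scp_energy`.
#' @param path File path; format chosen by extension (`.json` or TSV
#'   otherwise).
#' @return `path` invisibly; for the reader, a `scp_energy`.
#' @export
write_energy_matrix <- function(e, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(values = unclass(e),
                              symmetric = isTRUE(attr(e, "symmetric", exact = TRUE)),
                              provenance = attr(e, "provenance", exact = TRUE),
                              n = attr(e, "n", exact = TRUE)),
                         path, digits = NA, auto_unbox = TRUE)
  } else {
    df <- data.frame(aa = aa_alphabet(), unclass(e), check.names = FALSE)
    readr::write_tsv(df, path)
  }
  invisible(path)
}

#' @rdname write_energy_matrix
#' @export
read_energy_matrix <- function(path) {
  if (grepl("\\.json$", path)) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    new_energy_matrix(as.matrix(x$values), symmetric = isTRUE(x$symmetric),
                      provenance = as.list(x$provenance), n = x$n)
  } else {
    df <- readr::read_tsv(path, show_col_types = FALSE)
    m <- as.matrix(df[, -1])
    dimnames(m) <- list(df[[1]], colnames(df)[-1])
    new_energy_matrix(m[aa_alphabet(), aa_alphabet()])
  }
}
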