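test_that("contact potential matches brute-force counting on a hand-built set", {
  # 10 Ala-Ala contacts plus 20 contacts with a single Ala: Ala appears 40
  # times among the 200 residues of 100 contacts
  rec <- tibble::tibble(
    aa_i = c(rep("A", 10), rep("A", 20), rep(c("L", "K", "F", "S", "E", "T", "W"), 10)),
    aa_j = c(rep("A", 10), rep("V", 20), rep(c("K", "L", "S", "F", "T", "E", "Y"), 10)))
  expect_equal(nrow(rec), 100L)
  expect_equal(sum(rec$aa_i == "A") + sum(rec$aa_j == "A"), 40L)
  cp <- contact_potential(rec, epsilon_mode = "none")
  want <- oracle_cp(rec)
  expect_equal(unclass(cp)[is.finite(want)], want[is.finite(want)],
               tolerance = 1e-12)
  # the quasichemical expectation for Ala-Ala: n_c * (40/200)^2 = 4
  expect_equal(unclass(cp)["A", "A"], -log(10 / 4), tolerance = 1e-12)
  # the max-based pseudocount route agrees with the oracle under the same rule
  cp2 <- contact_potential(rec, epsilon_mode = "max")
  want2 <- oracle_cp(rec, eps_fun = function(o, e) max(o, e, 1) / 20)
  expect_equal(unclass(cp2), want2, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("contact potential is symmetric and zero under the exact reference premise", {
  rec <- null_contact_records(500, seed = 31)
  cp <- contact_potential(rec)
  expect_identical(unclass(cp), t(unclass(cp)))
  # product-distributed records, large n: energies are counting noise only
  recN <- null_contact_records(50000, seed = 7)
  cpN <- contact_potential(recN)
  expect_lt(max(abs(unclass(cpN))), 0.3)
  expect_lt(mean(abs(unclass(cpN))), 0.08)
})

test_that("CD-binned potentials equal per-bin counting and flag empty bins", {
  set.seed(5)
  rec <- null_contact_records(600, seed = 11)
  rec$cd <- stats::runif(600) # dense top bins only
  cdps <- cd_binned_potentials(rec, epsilon_mode = "max")
  expect_length(cdps, 11L)
  for (b in c(10, 11)) {
    sub <- rec[cd_bin(rec$cd) == b, ]
    expect_equal(unclass(cdps[[b]]), unclass(contact_potential(sub, "max")),
                 ignore_attr = TRUE)
    expect_equal(attr(cdps[[b]], "n", exact = TRUE), nrow(sub))
  }
  empty <- cdps[[1]]
  expect_equal(attr(empty, "n", exact = TRUE), 0L)
  expect_true(all(unclass(empty) == 0))
  # lookup maps a CD value to its bin's matrix
  expect_identical(cdp_lookup(cdps, 0.6), cdps[[11]])
  # a bin where a third of the contacts are Cys-Cys favors that pair strongly
  rec2 <- rec
  hi <- which(cd_bin(rec2$cd) == 11)
  cys <- hi[seq_len(ceiling(length(hi) / 3))]
  rec2$aa_i[cys] <- "C"; rec2$aa_j[cys] <- "C"
  cdps2 <- cd_binned_potentials(rec2)
  expect_lt(unclass(cdps2[[11]])["C", "C"], -0.5)
})

test_that("expected counts reduce to observed-marginal products under flat E1", {
  # 100 matches: position i half Ala half Gly, position j all Val
  m <- tibble::tibble(
    structure_id = sprintf("m%03d", 1:100), chain_i = "A", pos_i = 3L,
    chain_j = "B", pos_j = 3L, rmsd = seq(0, 0.5, length.out = 100),
    swapped = FALSE,
    aa_i = rep(c("A", "G"), 50), aa_j = "V",
    phi_i = -57, psi_i = -47, omega_i = 180, burial_i = 3,
    phi_j = -60, psi_j = -45, omega_j = 180, burial_j = 4)
  ens <- scpot:::new_ensemble(m, cutoff = 0.79, max_count = 100L, flank = 1L)
  em <- expected_pair_counts(ens, flat_background())
  expect_equal(em$n_exp["A", "V"], 50, tolerance = 1e-12)
  expect_equal(em$n_exp["G", "V"], 50, tolerance = 1e-12)
  expect_equal(sum(em$n_exp), 100, tolerance = 1e-9)
  expect_equal(em$n_exp["A", "A"], 0)
  # closed form N_o(a) N_o(b) / M for every pair
  no_i <- em$n_obs_i; no_j <- em$n_obs_j
  expect_equal(unname(em$n_exp), outer(unname(no_i), unname(no_j)) / 100,
               tolerance = 1e-12)
})

test_that("a single match concentrates all expected mass on its own pair", {
  pm <- planted_model()
  ens <- generate_planted_ensemble(pm, n_matches = 1, seed = 3)
  em <- expected_pair_counts(ens, flat_background())
  a <- ens$matches$aa_i[1]; b <- ens$matches$aa_j[1]
  expect_equal(em$n_exp[a, b], 1, tolerance = 1e-12)
  expect_equal(sum(em$n_exp), 1, tolerance = 1e-12)
})

test_that("expected counts equal term-by-term evaluation of the double softmax", {
  db <- fixture_db(6, seed = 33, sigma = 10)
  bg <- train_background(db)
  pm <- random_planted_model(5)
  ens <- generate_planted_ensemble(pm, generator_spec(sigma = 8), 20, seed = 9)
  em <- expected_pair_counts(ens, bg)
  m <- ens$matches
  aa <- aa_alphabet()
  # direct summation oracle, scalar arithmetic per match and amino acid
  e1_at <- function(a, phi, psi, omega, bur) e1(bg, a, phi, psi, omega, bur)
  n_e_i <- stats::setNames(numeric(20), aa)
  for (k in seq_len(nrow(m))) {
    den <- sum(vapply(aa, function(a)
      exp(-e1_at(a, m$phi_i[k], m$psi_i[k], m$omega_i[k], m$burial_i[k])),
      numeric(1)))
    for (a in aa) {
      n_e_i[a] <- n_e_i[a] +
        exp(-e1_at(a, m$phi_i[k], m$psi_i[k], m$omega_i[k], m$burial_i[k])) / den
    }
  }
  expect_equal(unname(em$n_e_i), unname(n_e_i), tolerance = 1e-9)
  n_o_i <- vapply(aa, function(a) sum(m$aa_i == a), numeric(1))
  n_o_j <- vapply(aa, function(a) sum(m$aa_j == a), numeric(1))
  n_exp_o <- matrix(0, 20, 20, dimnames = list(aa, aa))
  ratio_i <- ifelse(n_e_i > 0, n_o_i / n_e_i, 0)
  n_e_j <- stats::setNames(numeric(20), aa)
  for (k in seq_len(nrow(m))) {
    den <- sum(vapply(aa, function(a)
      exp(-e1_at(a, m$phi_j[k], m$psi_j[k], m$omega_j[k], m$burial_j[k])),
      numeric(1)))
    for (a in aa) n_e_j[a] <- n_e_j[a] +
      exp(-e1_at(a, m$phi_j[k], m$psi_j[k], m$omega_j[k], m$burial_j[k])) / den
  }
  ratio_j <- ifelse(n_e_j > 0, n_o_j / n_e_j, 0)
  for (k in seq_len(nrow(m))) {
    wi <- vapply(aa, function(a)
      exp(-e1_at(a, m$phi_i[k], m$psi_i[k], m$omega_i[k], m$burial_i[k])) *
        ratio_i[a], numeric(1))
    wj <- vapply(aa, function(a)
      exp(-e1_at(a, m$phi_j[k], m$psi_j[k], m$omega_j[k], m$burial_j[k])) *
        ratio_j[a], numeric(1))
    n_exp_o <- n_exp_o + outer(wi / sum(wi), wj / sum(wj))
  }
  expect_equal(unclass(em$n_exp), n_exp_o, tolerance = 1e-9)
  # conservation: total expectation equals the ensemble size
  expect_equal(sum(em$n_exp), nrow(m), tolerance = 1e-9)
})

test_that("marginal preservation is exact at the flat-E1 limit and reported otherwise", {
  pm <- random_planted_model(13, j_sd = 0.8)
  ens <- generate_planted_ensemble(pm, n_matches = 400, seed = 2)
  em_flat <- expected_pair_counts(ens, flat_background())
  expect_equal(unname(rowSums(em_flat$n_exp)), unname(em_flat$n_obs_i),
               tolerance = 1e-9)
  expect_equal(unname(colSums(em_flat$n_exp)), unname(em_flat$n_obs_j),
               tolerance = 1e-9)
})

test_that("SCE reduces to plain log-odds under flat E1 and is exactly 0 at N_obs = N_exp", {
  pm <- random_planted_model(17)
  ens <- generate_planted_ensemble(pm, n_matches = 2000, seed = 4)
  sce <- suppressWarnings(sce_matrix(ens, flat_background(), epsilon_mode = "max"))
  m <- ens$matches
  aa <- aa_alphabet()
  n_obs <- scpot:::.pair_count_matrix(m$aa_i, m$aa_j)
  no_i <- rowSums(n_obs); no_j <- colSums(n_obs)
  n_exp <- outer(no_i, no_j) / nrow(m)
  eps <- pmax(n_obs, n_exp, 1) / 20
  expect_equal(unclass(sce), -log((n_obs + eps) / (n_exp + eps)),
               tolerance = 1e-12, ignore_attr = TRUE)
  # pairs where observation equals expectation get exactly zero
  ez <- -log((n_obs + eps) / (n_exp + eps))
  hit <- abs(n_obs - n_exp) < 1e-12
  expect_true(all(ez[hit] == 0))
})

test_that("null-coupling ensembles give SCEs at the counting-noise scale", {
  # 10,000 draws over 400 uniform cells leave ~25 counts per cell, so the
  # per-cell log-odds noise is ~1/sqrt(25) = 0.2; the energies must look like
  # that noise (mean ~0.16) and nothing larger
  pm <- planted_model()                       # J = 0, h = 0
  ens <- generate_planted_ensemble(pm, n_matches = 10000, seed = 6)
  sce <- sce_matrix(ens, flat_background())
  expect_lt(max(abs(unclass(sce))), 1)
  expect_lt(mean(abs(unclass(sce))), 0.25)
  expect_equal(mean(unclass(sce)), 0, tolerance = 0.05)
})

test_that("small ensembles warn about sparse statistics", {
  pm <- planted_model()
  ens <- generate_planted_ensemble(pm, n_matches = 50, seed = 8)
  expect_warning(sce_matrix(ens, flat_background()), "sparse")
})

test_that("symmetrization averages the two orders", {
  set.seed(4)
  v <- matrix(stats::rnorm(400), 20, 20)
  e <- new_energy_matrix(v)
  s <- symmetrize(e)
  expect_identical(unclass(s), t(unclass(s)))
  expect_equal(unclass(s)[2, 5], (v[2, 5] + v[5, 2]) / 2)
  e2 <- new_energy_matrix((v + t(v)) / 2, symmetric = TRUE)
  expect_equal(unclass(symmetrize(e2)), unclass(e2))
})

test_that("energy matrices tidy, glance and serialize round-trip", {
  cp <- contact_potential(null_contact_records(300, seed = 41))
  td <- generics::tidy(cp)
  expect_equal(nrow(td), 400L)
  expect_equal(td$energy[td$aa_i == "R" & td$aa_j == "C"], unclass(cp)["R", "C"])
  gl <- generics::glance(cp)
  expect_equal(gl$type, "CP")
  for (ext in c(".tsv", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_energy_matrix(cp, path)
    back <- read_energy_matrix(path)
    expect_equal(unclass(back), unclass(cp), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})
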