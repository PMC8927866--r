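# brute-force CD oracle: explicit loop over all (a, b, r_i, r_j) tuples with
# scalar distance checks — no vectorised shortcuts shared with the package
oracle_cd <- function(s, ci, pi, cj, pj, lib, p_aa, interfere = 3) {
  ri <- allowed_rotamers(s, ci, pi, lib)
  rj <- allowed_rotamers(s, cj, pj, lib)
  total <- 0
  for (a in aa_alphabet()) {
    for (b in aa_alphabet()) {
      ra <- ri[ri$aa == a, ]; rb <- rj[rj$aa == b, ]
      if (nrow(ra) == 0L || nrow(rb) == 0L) next
      for (x in seq_len(nrow(ra))) {
        for (y in seq_len(nrow(rb))) {
          ax <- ra$atoms[[x]]; ay <- rb$atoms[[y]]
          clash <- FALSE
          for (u in seq_len(nrow(ax))) {
            for (v in seq_len(nrow(ay))) {
              if (sqrt(sum((ax[u, ] - ay[v, ])^2)) <= interfere) clash <- TRUE
            }
          }
          if (clash) total <- total + p_aa[[a]] * p_aa[[b]] * ra$prob[x] * rb$prob[y]
        }
      }
    }
  }
  total
}

test_that("CD bins follow the 11-interval half-open scheme", {
  expect_equal(length(cd_bin_edges()), 12L)
  expect_equal(cd_bin(0), 1L)
  expect_equal(cd_bin(2^-10), 2L)          # half-open: boundary starts bin 2
  expect_equal(cd_bin(2^-10 - 1e-12), 1L)
  expect_equal(cd_bin(0.49), 10L)
  expect_equal(cd_bin(0.5), 11L)
  expect_equal(cd_bin(1), 11L)
  # every value maps to exactly one bin
  x <- seq(0, 1, length.out = 1000)
  expect_true(all(cd_bin(x) %in% 1:11))
})

test_that("CD equals the exhaustive brute-force sum on a toy library", {
  db <- fixture_db(2, seed = 5)
  s <- db[[1]]
  lib <- toy_rotamer_library(2)
  p_aa <- uniform_aa_freq()
  cd <- contact_degree(s, "A", 3, "B", 3, lib, p_aa = p_aa)
  expect_equal(cd, oracle_cd(s, "A", 3, "B", 3, lib, p_aa), tolerance = 1e-12)
  # a non-uniform background too
  set.seed(2)
  p2 <- stats::runif(20); p2 <- p2 / sum(p2)
  names(p2) <- aa_alphabet()
  expect_equal(contact_degree(s, "A", 3, "B", 3, lib, p_aa = p2),
               oracle_cd(s, "A", 3, "B", 3, lib, p2), tolerance = 1e-12)
})

test_that("CD is symmetric, bounded, and 0 for distant residues", {
  db <- fixture_db(2, seed = 7)
  s <- db[[1]]
  lib <- toy_rotamer_library(2)
  cd_ij <- contact_degree(s, "A", 3, "B", 3, lib)
  cd_ji <- contact_degree(s, "B", 3, "A", 3, lib)
  expect_equal(cd_ij, cd_ji)
  expect_gte(cd_ij, 0); expect_lte(cd_ij, 1)
  # 50 A apart -> no reachable rotamer pair
  far <- make_linear_structure(2, id = "far")
  far$ca_x[2] <- far$ca_x[1] + 50
  far$n_x[2] <- far$n_x[1] + 50; far$c_x[2] <- far$c_x[1] + 50
  far$o_x[2] <- far$o_x[1] + 50
  expect_equal(contact_degree(far, "A", 0, "A", 1, lib), 0)
})

test_that("CD reaches 1 when every placeable rotamer pair interferes", {
  # two isolated residues facing each other 3.5 A apart, all probability on
  # Ala (single CB-atom rotamer): the only placeable rotamer pair clashes
  d <- 3.5
  res <- tibble::tibble(
    chain = c("A", "B"), resno = c(1L, 1L), aa = c("A", "A"),
    n_x = c(-1, -1), n_y = c(1, -d - 1), n_z = 0,
    ca_x = c(0, 0), ca_y = c(0, -d), ca_z = 0,
    c_x = c(1, 1), c_y = c(1, -d - 1), c_z = 0,
    o_x = c(2, 2), o_y = c(2, -d - 2), o_z = 0)
  s <- new_structure(res, id = "pair")
  lib <- toy_rotamer_library(1, aas = "A")
  p_aa <- stats::setNames(c(1, rep(0, 19)), aa_alphabet())
  cd <- contact_degree(s, "A", 0, "B", 0, lib, p_aa = p_aa)
  expect_equal(cd, 1)
})

test_that("CD is non-increasing under rigid separation and hits 0 beyond reach", {
  lib <- toy_rotamer_library(2)
  cds <- vapply(c(5, 8, 12, 16, 25, 45), function(d) {
    res <- dplyr::bind_rows(
      tibble::as_tibble(make_linear_structure(1, chain = "A")),
      tibble::as_tibble(make_linear_structure(1, chain = "B",
                                              offset = c(0, d, 0))))
    s <- new_structure(res, id = "sep")
    contact_degree(s, "A", 0, "B", 0, lib)
  }, numeric(1))
  expect_true(all(diff(cds) <= 1e-12))
  expect_equal(cds[length(cds)], 0)
})

test_that("rotamers clashing with the main chain are excluded and can renormalize", {
  db <- fixture_db(1, seed = 13)
  s <- db[[1]]
  lib <- toy_rotamer_library(3)
  free <- allowed_rotamers(s, "A", 0, lib)         # terminal, mostly exposed
  expect_true(nrow(free) > 0)
  # probabilities unrenormalized: per-aa mass never exceeds 1
  mass <- tapply(free$prob, free$aa, sum)
  expect_true(all(mass <= 1 + 1e-12))
  ren <- allowed_rotamers(s, "A", 0, lib, renormalize = TRUE)
  mass2 <- tapply(ren$prob, ren$aa, sum)
  expect_true(all(abs(mass2 - 1) < 1e-12))
  # an absurdly large clash radius disallows everything with atoms
  none <- allowed_rotamers(s, "A", 3, lib, clash_radius = 30)
  expect_true(all(none$aa == "G"))
})

test_that("contact enumeration respects separation and window completeness", {
  s <- compute_dihedrals(make_linear_structure(30))
  lib <- toy_rotamer_library(1, aas = "A")
  ct <- enumerate_contacts(s, lib, min_seq_sep = 5, flank = 2)
  # positions 10 and 15 have 4 residues between -> excluded
  expect_false(any(ct$pos_i == 10 & ct$pos_j == 15))
  expect_true(any(ct$pos_i == 10 & ct$pos_j == 16))
  expect_equal(ct$seq_sep[ct$pos_i == 10 & ct$pos_j == 16], 5L)
  # flank-2 windows: nothing involving positions 0, 1, 28, 29
  expect_false(any(ct$pos_i <= 1 | ct$pos_j >= 28))
  # an interior incomplete residue knocks out its window
  s2 <- s; s2$n_x[13] <- NA_real_
  s2 <- new_structure(tibble::as_tibble(s2), id = "brk")
  s2 <- compute_dihedrals(s2)
  ct2 <- enumerate_contacts(s2, lib, min_seq_sep = 5, flank = 2)
  expect_false(any(ct2$pos_i %in% 10:14 | ct2$pos_j %in% 10:14))
})

test_that("stratified sampling draws per-bin counts deterministically", {
  set.seed(99)
  rec <- tibble::tibble(aa_i = "A", aa_j = "V",
                        cd = stats::runif(2000))   # dense high bins
  db1 <- sample_contact_database(rec, per_bin = 3, seed = 4)
  expect_s3_class(db1, "scp_contact_db")
  counts <- table(db1$bin)
  expect_true(all(counts <= 3))
  # dense bins contribute exactly per_bin
  expect_equal(as.integer(counts[as.character(10:11)]), c(3L, 3L))
  # degenerate bin contributes what it has
  rec2 <- tibble::tibble(aa_i = "A", aa_j = "V", cd = c(0.6, 0.001, 0.002, 0.3))
  expect_message(db2 <- sample_contact_database(rec2, per_bin = 3, seed = 1))
  expect_equal(nrow(db2), 4L)
  # determinism
  db3 <- sample_contact_database(rec, per_bin = 3, seed = 4)
  expect_identical(tibble::as_tibble(db1), tibble::as_tibble(db3))
  expect_error(sample_contact_database(rec[0, ], 3), "no contact")
})
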