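# naive double-loop search oracle: enumerates every pair of complete windows
# in every structure and scores both assignment orders with kabsch_rmsd
oracle_search <- function(q, db, cutoff) {
  L <- 2L * q$flank + 1L
  hits <- NULL
  for (s in db) {
    for (ch_a in unique(s$chain)) {
      for (ch_b in unique(s$chain)) {
        rows_a <- which(s$chain == ch_a); rows_b <- which(s$chain == ch_b)
        for (sa in seq_len(max(0, length(rows_a) - L + 1L))) {
          for (sb in seq_len(max(0, length(rows_b) - L + 1L))) {
            wa <- rows_a[sa:(sa + L - 1L)]; wb <- rows_b[sb:(sb + L - 1L)]
            if (ch_a == ch_b) {
              if (sb <= sa) next                       # unordered pairs once
              if (sb - (sa + L - 1L) - 1L < 1L) next   # gap >= 1 residue
            } else if (ch_a > ch_b) next
            if (!all(s$complete[c(wa, wb)])) next
            if (any(diff(s$resno[wa]) != 1L) || any(diff(s$resno[wb]) != 1L)) next
            c_ab <- rbind(scpot:::.bb_coords(s[wa, ]), scpot:::.bb_coords(s[wb, ]))
            c_ba <- rbind(scpot:::.bb_coords(s[wb, ]), scpot:::.bb_coords(s[wa, ]))
            r <- min(kabsch_rmsd(q$coords, c_ab), kabsch_rmsd(q$coords, c_ba))
            if (r <= cutoff) {
              hits <- rbind(hits, data.frame(
                structure_id = structure_id(s),
                pos_a = s$pos[wa[q$flank + 1L]], pos_b = s$pos[wb[q$flank + 1L]],
                rmsd = r))
            }
          }
        }
      }
    }
  }
  hits[order(hits$rmsd, hits$structure_id), ]
}

test_that("Kabsch RMSD: identity, rigid invariance, quaternion oracle", {
  set.seed(21)
  a <- matrix(stats::rnorm(24, sd = 4), 8, 3)
  expect_equal(kabsch_rmsd(a, a), 0)
  # random rotation + translation
  ax <- stats::rnorm(3); th <- 1.1
  R <- scpot:::.rot_about(ax, th * 180 / pi)
  b <- a %*% t(R) + matrix(c(3, -2, 7), 8, 3, byrow = TRUE)
  expect_lt(kabsch_rmsd(a, b), 1e-9)
  for (k in 1:50) {
    x <- matrix(stats::rnorm(24, sd = 3), 8, 3)
    y <- matrix(stats::rnorm(24, sd = 3), 8, 3)
    expect_equal(kabsch_rmsd(x, y), oracle_quaternion_rmsd(x, y),
                 tolerance = 1e-9)
  }
  expect_error(kabsch_rmsd(a, a[1:5, ]), "point counts differ")
})

test_that("superposition transform reproduces the minimal RMSD", {
  set.seed(3)
  x <- matrix(stats::rnorm(30), 10, 3); y <- matrix(stats::rnorm(30), 10, 3)
  sup <- kabsch_superpose(x, y)
  expect_equal(sup$rmsd, kabsch_rmsd(x, y), tolerance = 1e-12)
  expect_equal(sup$coords, y %*% t(sup$rotation) +
                 matrix(sup$translation, 10, 3, byrow = TRUE), tolerance = 1e-9)
  expect_equal(det(sup$rotation), 1, tolerance = 1e-9)
})

test_that("default ensemble cutoffs are flank-dependent", {
  expect_identical(default_rmsd_cutoff(0), 1.0)
  expect_identical(default_rmsd_cutoff(1), 0.79)
  expect_identical(default_rmsd_cutoff(2), 0.77)
  expect_error(default_rmsd_cutoff(3), "flank")
})

test_that("motif extraction orders segments and validates windows", {
  db <- fixture_db(2, seed = 31)
  s <- db[[1]]
  m <- extract_motif(s, "B", 3, "A", 3, flank = 1)   # reversed input order
  expect_equal(m$chain_i, "A")                        # canonical order first
  expect_equal(nrow(m$coords), 24L)
  expect_error(extract_motif(s, "A", 0, "B", 3, flank = 2), "window")
  expect_error(extract_motif(s, "A", 1, "A", 3, flank = 1), "overlap")
})

test_that("search recovers the query itself at RMSD 0 and respects the cutoff", {
  db <- fixture_db(4, seed = 8)
  q <- extract_motif(db[[2]], "A", 3, "B", 3, flank = 1)
  ens <- search_matches(q, db, cutoff = 1.5)
  expect_gt(n_matches(ens), 0)
  top <- ens$matches[1, ]
  expect_equal(top$rmsd, 0)
  expect_equal(top$structure_id, "synth_002")
  expect_equal(top$aa_i, q$aa_i); expect_equal(top$aa_j, q$aa_j)
  # self-exclusion flag
  ens2 <- search_matches(q, db, cutoff = 1.5, include_self = FALSE)
  expect_false(any(ens2$matches$structure_id == "synth_002" &
                     ens2$matches$pos_i == 3 & ens2$matches$pos_j == 3))
  # tight cutoff on distant fragments -> empty
  far <- generate_synthetic_database(generator_spec(template = "strand",
                                                    n_structures = 2, seed = 77))
  expect_equal(n_matches(search_matches(q, far, cutoff = 1e-4)), 0L)
})

test_that("search equals the naive double-loop oracle on a toy database", {
  db <- fixture_db(5, seed = 15, sigma = 6)
  q <- extract_motif(db[[1]], "A", 3, "B", 3, flank = 1)
  cutoff <- 1.2
  got <- search_matches(q, db, cutoff = cutoff)$matches
  want <- oracle_search(q, db, cutoff)
  expect_equal(nrow(got), nrow(want))
  expect_equal(got$rmsd, want$rmsd, tolerance = 1e-6)
  expect_setequal(paste(got$structure_id, pmin(got$pos_i, got$pos_j),
                        pmax(got$pos_i, got$pos_j)),
                  paste(want$structure_id, pmin(want$pos_a, want$pos_b),
                        pmax(want$pos_a, want$pos_b)))
})

test_that("stored match RMSDs re-score identically and results ignore db order", {
  db <- fixture_db(4, seed = 23)
  q <- extract_motif(db[[1]], "A", 3, "B", 3, flank = 1)
  ens <- search_matches(q, db, cutoff = 1.5)
  for (k in seq_len(min(5, n_matches(ens)))) {
    m <- ens$matches[k, ]
    s <- db[[m$structure_id]]
    mm <- extract_motif(s, m$chain_i, m$pos_i, m$chain_j, m$pos_j, flank = 1)
    # the stored orientation may be swapped relative to canonical order
    r <- min(kabsch_rmsd(q$coords, mm$coords),
             kabsch_rmsd(q$coords, rbind(mm$coords[13:24, ], mm$coords[1:12, ])))
    expect_equal(r, m$rmsd, tolerance = 1e-6)
  }
  ens_rev <- search_matches(q, rev(db), cutoff = 1.5)
  expect_equal(dplyr::arrange(ens$matches, structure_id, pos_i, pos_j),
               dplyr::arrange(ens_rev$matches, structure_id, pos_i, pos_j))
})

test_that("match RMSD grows with the generating dihedral noise", {
  q <- extract_motif(generate_synthetic_database(
    generator_spec(sigma = 0, n_structures = 1, seed = 1))[[1]],
    "A", 3, "B", 3, flank = 1)
  meds <- vapply(c(1, 4, 10), function(sg) {
    db <- generate_synthetic_database(
      generator_spec(sigma = sg, n_structures = 6, seed = 101))
    ens <- search_matches(q, db, cutoff = 10)
    stats::median(ens$matches$rmsd[ens$matches$pos_i == 3 & ens$matches$pos_j == 3])
  }, numeric(1))
  expect_true(all(diff(meds) > 0))
})

test_that("truncation by count and RMSD cap behaves and serializes round-trip", {
  pm <- random_planted_model(2)
  ens <- generate_planted_ensemble(pm, n_matches = 200, seed = 5)
  t1 <- truncate_ensemble(ens, max_matches = 50)
  expect_equal(n_matches(t1), 50L)
  expect_true(all(t1$matches$rmsd <= max(ens$matches$rmsd)))
  t2 <- truncate_ensemble(ens, rmsd_max = 0.3)
  expect_true(all(t2$matches$rmsd <= 0.3))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ensemble(ens, path)
  back <- read_ensemble(path, flank = 1)
  expect_equal(as.data.frame(back$matches), as.data.frame(ens$matches),
               tolerance = 1e-9)
})
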