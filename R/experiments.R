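# Self-contained synthetic experiments reproducing the method's qualitative
# properties at desk scale. Each driver builds its own inputs from the
# synthetic generators, runs the standard pipeline and returns the measured
# quantities. All randomness derives from the single seed argument.
#
# Problem sizes are chosen so each experiment runs in minutes on one core
# while keeping the measured statistics stable; the methods vignette discusses
# the choices.

#' Null reference-state experiment
#'
#' Measures the three reference-state nulls: the contact potential of
#' product-distributed contacts, the SCEs of a coupling-free planted ensemble,
#' and the hierarchical background trained on a database whose residue types
#' are independent of geometry. Also measures the mean energetic distance
#' between independent random matrices.
#'
#' @param seed Integer seed.
#' @param n_contacts Contacts for the null contact potential.
#' @param n_matches Matches for the coupling-free ensemble.
#' @param n_large Pooled draws for the large-ensemble null SCE.
#' @return Named list of measured quantities.
#' @export
experiment_nulls <- function(seed = 1L, n_contacts = 50000L,
                             n_matches = 10000L, n_large = 400000L) {
  base <- as.integer(seed)
  # product-distributed contacts via a coupling-free planted model
  ens_cp <- generate_planted_ensemble(planted_model(), n_matches = n_contacts,
                                      seed = base + 11L)
  cp <- contact_potential(ens_cp$matches[, c("aa_i", "aa_j")])
  # coupling-free ensemble at the prescribed and at a large ensemble size
  ens0 <- generate_planted_ensemble(planted_model(), n_matches = n_matches,
                                    seed = base + 23L)
  sce0 <- sce_matrix(ens0, flat_background())
  ens_big <- generate_planted_ensemble(planted_model(), n_matches = n_large,
                                       seed = base + 29L)
  sce_big <- sce_matrix(ens_big, flat_background())
  # geometry-independent training database
  db <- c(generate_synthetic_database(
            generator_spec("helix", sigma = 8, n_structures = 30,
                           seed = base + 31L)),
          generate_synthetic_database(
            generator_spec("strand", sigma = 8, n_structures = 30,
                           seed = base + 37L)))
  bg <- train_background(db)
  set.seed(base + 41L)
  re <- replicate(1000, energy_distance(matrix(stats::rnorm(400), 20, 20),
                                        matrix(stats::rnorm(400), 20, 20)))
  list(cp_null_max_abs = max(abs(unclass(cp))),
       cp_null_mean_abs = mean(abs(unclass(cp))),
       sce_null_max_abs = max(abs(unclass(sce0))),
       sce_null_mean_abs = mean(abs(unclass(sce0))),
       sce_null_max_abs_large = max(abs(unclass(sce_big))),
       e1_null_mean_abs = mean(c(mean(abs(bg$phi_psi_energy)),
                                 mean(abs(bg$omega_energy)),
                                 mean(abs(bg$burial_energy)))),
       re_random_mean = mean(re))
}

#' Planted-coupling recovery experiment
#'
#' Samples a match ensemble from a known 20x20 coupling matrix and measures
#' the Pearson correlation between the double-centered SCE matrix and the
#' double-centered planted couplings.
#'
#' @param seed Integer seed.
#' @param n_matches Ensemble size (default 5,000).
#' @param j_sd Planted coupling scale.
#' @return Named list with `recovery_r` and `n_matches`.
#' @export
experiment_recovery <- function(seed = 1L, n_matches = 5000L, j_sd = 1) {
  base <- as.integer(seed)
  pm <- random_planted_model(base + 53L, j_sd = j_sd)
  ens <- generate_planted_ensemble(pm, n_matches = n_matches, seed = base + 59L)
  sce <- sce_matrix(ens, flat_background())
  list(recovery_r = stats::cor(as.numeric(double_center(unclass(sce))),
                               as.numeric(double_center(pm$J))),
       n_matches = n_matches)
}

#' SCE-to-contact-potential convergence experiment
#'
#' Builds many match ensembles whose couplings share a common component plus
#' context-specific deviations (and context-specific marginals), averages
#' their symmetrized SCE matrices, and correlates the average with the
#' contact potential of the pooled contacts. The shared component is what
#' both averages converge to; purely context-specific couplings would leave
#' the pooled potential without signal.
#'
#' @param seed Integer seed.
#' @param n_ensembles Number of contexts.
#' @param n_matches Matches per context (pooled draws =
#'   `n_ensembles * n_matches`).
#' @param common_sd,dev_sd,h_sd Scales of the shared couplings, the
#'   per-context coupling deviations and the per-context fields.
#' @return Named list with `convergence_r` and `n_pooled`.
#' @export
experiment_convergence <- function(seed = 1L, n_ensembles = 40L,
                                   n_matches = 3000L, common_sd = 1,
                                   dev_sd = 1, h_sd = 0.2) {
  base <- as.integer(seed)
  set.seed(base + 5L)
  j_common <- matrix(stats::rnorm(400, 0, common_sd), 20, 20)
  mean_sce <- matrix(0, 20, 20)
  pooled <- vector("list", n_ensembles)
  for (e in seq_len(n_ensembles)) {
    set.seed(base + 100L + e)
    pm <- planted_model(h_i = stats::rnorm(20, 0, h_sd),
                        h_j = stats::rnorm(20, 0, h_sd),
                        J = j_common + matrix(stats::rnorm(400, 0, dev_sd), 20, 20))
    ens <- generate_planted_ensemble(pm, n_matches = n_matches,
                                     seed = base + 500L + e)
    mean_sce <- mean_sce +
      unclass(symmetrize(sce_matrix(ens, flat_background()))) / n_ensembles
    pooled[[e]] <- ens$matches[, c("aa_i", "aa_j")]
  }
  cp <- contact_potential(dplyr::bind_rows(pooled))
  list(convergence_r = stats::cor(as.numeric(mean_sce),
                                  as.numeric(unclass(cp))),
       n_pooled = n_ensembles * n_matches)
}

#' Native-pair identification experiment
#'
#' Families of interaction contexts with distinct planted couplings: each
#' native pair is drawn from its family's coupling distribution and predicted
#' either with the family's SCE matrix or with a single contact potential
#' pooled over all families. Reports the identification enrichment over the
#' 1/400 chance rate for both.
#'
#' @param seed Integer seed.
#' @param n_families Number of coupling families.
#' @param n_matches Ensemble size per family.
#' @param n_trials Native pairs drawn.
#' @return Named list with `enrichment_sce`, `enrichment_cp`.
#' @export
experiment_identification <- function(seed = 1L, n_families = 6L,
                                      n_matches = 3000L, n_trials = 1000L) {
  base <- as.integer(seed)
  fams <- lapply(seq_len(n_families), function(f) {
    # each family strongly favors one family-specific pair over a weakly
    # coupled background
    set.seed(base + 1000L + f)
    J <- matrix(stats::rnorm(400, 0, 0.5), 20, 20)
    J[sample.int(20, 1L), sample.int(20, 1L)] <- -4
    pm <- planted_model(h_i = stats::rnorm(20, 0, 0.3),
                        h_j = stats::rnorm(20, 0, 0.3), J = J)
    ens <- generate_planted_ensemble(pm, n_matches = n_matches,
                                     seed = base + 2000L + f)
    list(pm = pm, sce = sce_matrix(ens, flat_background()),
         records = ens$matches[, c("aa_i", "aa_j")])
  })
  cp <- contact_potential(dplyr::bind_rows(lapply(fams, `[[`, "records")))
  set.seed(base + 71L)
  aa <- aa_alphabet()
  res_sce <- res_cp <- vector("list", n_trials)
  for (t in seq_len(n_trials)) {
    f <- sample.int(n_families, 1L)
    p <- pair_distribution(fams[[f]]$pm)
    draw <- sample.int(400L, 1L, prob = as.numeric(p))
    native <- c(aa[(draw - 1L) %% 20L + 1L], aa[(draw - 1L) %/% 20L + 1L])
    res_sce[[t]] <- identify_native(fams[[f]]$sce, native)
    res_cp[[t]] <- identify_native(cp, native)
  }
  list(enrichment_sce = enrichment(dplyr::bind_rows(res_sce)),
       enrichment_cp = enrichment(dplyr::bind_rows(res_cp)),
       n_trials = n_trials)
}

# build one family motif set: structures + motifs + per-motif SCEs
.family_motifs <- function(angle, pm, n_motifs, n_matches, seed) {
  spec <- generator_spec("helix", sigma = 3, n_structures = n_motifs,
                         seed = seed, angle = angle,
                         placement_noise = list(distance = 0.05, angles = 2))
  db <- generate_synthetic_database(spec)
  motifs <- lapply(db, extract_motif, chain_i = "A", pos_i = 3L,
                   chain_j = "B", pos_j = 3L, flank = 1L)
  sces <- lapply(seq_along(db), function(k) {
    ens <- generate_planted_ensemble(pm, n_matches = n_matches,
                                     seed = seed + 10000L + k)
    symmetrize(sce_matrix(ens, flat_background()))
  })
  list(motifs = motifs, sces = sces)
}

#' Structure/energy clustering experiment
#'
#' Generates geometric motif families with family-specific couplings,
#' computes per-motif SCE matrices, clusters the motifs greedily by backbone
#' RMSD (radius 0.5) and by energetic distance (radius 0.3), and compares the
#' within-cluster cohesion of each against size-matched random-assignment
#' controls.
#'
#' @param seed Integer seed.
#' @param n_families Number of geometric families.
#' @param per_family Motifs per family.
#' @param n_matches Ensemble size behind each motif's SCE.
#' @return Named list of mean member-to-medoid distances: `re_structure`,
#'   `re_random`, `rmsd_energy`, `rmsd_random` (plus cluster counts).
#' @export
experiment_clustering <- function(seed = 1L, n_families = 8L,
                                  per_family = 15L, n_matches = 3000L) {
  base <- as.integer(seed)
  angles <- seq(0, 315, length.out = n_families)
  motifs <- list(); sces <- list()
  for (f in seq_len(n_families)) {
    pm <- random_planted_model(base + 3000L + f, h_sd = 0.3, j_sd = 2)
    fam <- .family_motifs(angles[f], pm, per_family, n_matches,
                          seed = base + 4000L + 100L * f)
    motifs <- c(motifs, fam$motifs)
    sces <- c(sces, fam$sces)
  }
  d_rmsd <- rmsd_distance_matrix(motifs)
  d_re <- energy_distance_matrix(sces)
  n <- length(motifs)
  cl_s <- greedy_cluster(d_rmsd, d = 0.5, n = n, rounds = 100L,
                         seed = base + 83L)
  cl_e <- greedy_cluster(d_re, d = 0.3, n = n, rounds = 100L,
                         seed = base + 89L)
  # cross-metric cohesion: distances in the other metric to the same medoid
  cross_mean <- function(cl, dmat) {
    mean(unlist(lapply(cl$clusters, function(c) dmat[c$medoid, c$members])))
  }
  rc_s <- random_cluster_control(d_re, sizes = cluster_sizes(cl_s),
                                 seed = base + 97L)
  rc_e <- random_cluster_control(d_rmsd, sizes = cluster_sizes(cl_e),
                                 seed = base + 101L)
  list(re_structure = cross_mean(cl_s, d_re),
       re_random = mean_medoid_distance(rc_s),
       rmsd_energy = cross_mean(cl_e, d_rmsd),
       rmsd_random = mean_medoid_distance(rc_e),
       n_clusters_structure = length(cl_s$clusters),
       n_clusters_energy = length(cl_e$clusters))
}

#' Structural-versus-energetic similarity profile experiment
#'
#' A geometric continuum of motifs whose planted couplings interpolate
#' smoothly with the placement geometry; all motif pairs are binned by
#' backbone RMSD and the mean energetic distance r_E is summarised per bin.
#'
#' @param seed Integer seed.
#' @param n_motifs Number of motifs along the continuum.
#' @param n_matches Ensemble size per motif.
#' @return List with the profile tibble and the low/high-bin means.
#' @export
experiment_re_profile <- function(seed = 1L, n_motifs = 48L,
                                  n_matches = 3000L) {
  base <- as.integer(seed)
  j0 <- random_planted_model(base + 5000L, h_sd = 0, j_sd = 2)$J
  j1 <- random_planted_model(base + 5001L, h_sd = 0, j_sd = 2)$J
  ts <- seq(0, 1, length.out = n_motifs)
  motifs <- list(); sces <- list()
  for (k in seq_len(n_motifs)) {
    spec <- generator_spec("helix", sigma = 2, n_structures = 1,
                           seed = base + 6000L + k,
                           angle = 120 + 120 * ts[k],
                           placement_noise = list(distance = 0.03, angles = 1))
    s <- generate_synthetic_database(spec)[[1]]
    motifs[[k]] <- extract_motif(s, "A", 3L, "B", 3L, flank = 1L)
    pm <- planted_model(J = cos(ts[k] * pi / 2) * j0 + sin(ts[k] * pi / 2) * j1)
    ens <- generate_planted_ensemble(pm, n_matches = n_matches,
                                     seed = base + 7000L + k)
    sces[[k]] <- symmetrize(sce_matrix(ens, flat_background()))
  }
  prof <- rmsd_re_profile(motifs, sces)
  pop <- prof[prof$n_pairs > 0, , drop = FALSE]
  list(profile = prof,
       re_low_bin = pop$mean_re[1],
       re_high_bin = pop$mean_re[nrow(pop)],
       max_bin_decrease = max(-diff(pop$mean_re)))
}

#' Decoy model-scoring experiment
#'
#' The full scoring pipeline on noise-graded torsion-space decoys: a
#' synthetic structure database with planted favorable pairs, a native
#' assembly of several contact units carrying those pairs, decoys of graded
#' backbone quality, and mean-SCE / mean-CE scores per model with Spearman
#' rank ordering and ROC/AUC against the RMSD-to-native label.
#'
#' @param seed Integer seed.
#' @param n_db Database structures.
#' @param n_units Contact units per model.
#' @param noise_levels Decoy dihedral noise levels (degrees).
#' @param per_level Decoys per level.
#' @return Named list with `spearman`, `auc_sce`, `auc_cp` and the score
#'   tibble.
#' @export
experiment_decoy_scoring <- function(seed = 1L, n_db = 50L, n_units = 8L,
                                     noise_levels = c(4, 8, 12, 16, 20),
                                     per_level = 4L) {
  base <- as.integer(seed)
  fav <- rep(list(c("K", "E"), c("L", "I"), c("F", "V"), c("D", "R")),
             length.out = n_units)
  J <- matrix(0, 20, 20)
  for (p in unique(fav)) J[aa_index(p[1]), aa_index(p[2])] <- -4.5
  pm <- planted_model(J = J)
  spec <- generator_spec("helix", sigma = 3, n_structures = n_db,
                         seed = base + 8000L,
                         placement_noise = list(distance = 0.15, angles = 4))
  db <- generate_synthetic_database(spec)
  db <- plant_central_pair(db, pm, seed = base + 8001L)
  # native: n_units family units fused into one multi-chain assembly, each
  # unit carrying one of the planted favorable pairs
  units <- generate_synthetic_database(
    generator_spec("helix", sigma = 3, n_structures = n_units,
                   seed = base + 8002L,
                   placement_noise = list(distance = 0.15, angles = 4)))
  rows <- NULL
  for (k in seq_len(n_units)) {
    u <- units[[k]]
    u$aa[u$chain == "A" & u$pos == 3L] <- fav[[k]][1]
    u$aa[u$chain == "B" & u$pos == 3L] <- fav[[k]][2]
    tb <- tibble::as_tibble(u)
    tb$chain <- ifelse(tb$chain == "A", LETTERS[2 * k - 1], LETTERS[2 * k])
    for (col in grep("_x$", names(tb), value = TRUE)) {
      tb[[col]] <- tb[[col]] + (k - 1) * 60
    }
    rows <- dplyr::bind_rows(rows, tb)
  }
  native <- compute_dihedrals(new_structure(rows, id = "native"))
  ms <- generate_torsion_decoys(native, noise_levels = noise_levels,
                                per_level = per_level, placement_scale = 0.8,
                                seed = base + 8003L)
  models <- c(list(native = native), ms$decoys)
  labels <- c(0, ms$labels$rmsd)
  lib <- toy_rotamer_library(2)
  bg <- flat_background()
  rec <- tibble::tibble(
    aa_i = vapply(db, function(s) s$aa[s$chain == "A" & s$pos == 3L], ""),
    aa_j = vapply(db, function(s) s$aa[s$chain == "B" & s$pos == 3L], ""))
  cp <- contact_potential(rec)
  prepared <- prepare_search_db(db, flank = 1L)
  scores <- purrr::map_dfr(models, function(m)
    score_model(m, prepared, bg, lib, cp, flank = 1L, cd_min = 0.1))
  scores$rmsd <- labels
  # a model in which no contact qualifies carries no favorable native
  # interactions: score 0
  scores$mean_sce[is.na(scores$mean_sce)] <- 0
  scores$mean_ce[is.na(scores$mean_ce)] <- 0
  decoys_only <- scores[-1, ]
  med <- stats::median(labels)
  list(spearman = stats::cor(decoys_only$mean_sce, decoys_only$rmsd,
                             method = "spearman"),
       auc_sce = roc_auc(-scores$mean_sce, scores$rmsd, med, "le")$auc,
       auc_cp = roc_auc(-scores$mean_ce, scores$rmsd, med, "le")$auc,
       scores = scores)
}
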