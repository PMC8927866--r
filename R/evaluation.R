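# Evaluation procedures: native-pair identification and enrichment, the
# modified z-score, ensemble-size sweeps against experimental coupling
# energies, model scoring by mean SCE/CE, and ROC/AUC analysis.

#' Modified z-score of a pair energy within its matrix
#'
#' `Z = (E_pair - median(E)) / median(|E - median(E)|)` over all 400 entries:
#' a z-score with the mean replaced by the median and the standard deviation
#' by the median absolute deviation, robust to the heavy tails of sparse
#' log-odds energies. Negative values mean the pair is more favorable than
#' typical.
#'
#' @param e A `scp_energy`.
#' @param pair Length-2 character vector of one-letter amino acids
#'   `c(aa_i, aa_j)`.
#' @return The modified z-score; NA (with a warning) when the MAD is zero.
#' @export
modified_zscore <- function(e, pair) {
  v <- as.numeric(unclass(e))
  med <- stats::median(v)
  mad0 <- stats::median(abs(v - med))
  ei <- unclass(e)[aa_index(pair[1]), aa_index(pair[2])]
  if (mad0 == 0) {
    warning("zero median absolute deviation; modified z-score undefined")
    return(NA_real_)
  }
  (ei - med) / mad0
}

#' Identify the most favorable pair of an energy matrix
#'
#' Finds the argmin of the 400 energies (ties broken by canonical
#' lexicographic pair order) and ranks the native pair among all entries in
#' ascending energy order (rank 1 = most favorable; ties take the lowest
#' applicable rank, again lexicographic).
#'
#' @param e A `scp_energy`.
#' @param native Length-2 character vector, the native pair `c(aa_i, aa_j)`.
#' @param motif_id Optional identifier carried into the result.
#' @return One-row tibble: `motif_id`, `native_i`, `native_j`, `best_i`,
#'   `best_j`, `identified`, `rank` (1..400), `zscore`.
#' @export
identify_native <- function(e, native, motif_id = NA_character_) {
  aa <- aa_alphabet()
  v <- as.numeric(unclass(e))          # column-major: i runs fastest
  # lexicographic (aa_i, aa_j) tie-break: order by energy, then row, then col
  ii <- rep(1:20, times = 20); jj <- rep(1:20, each = 20)
  o <- order(v, ii, jj)
  best <- o[1]
  ni <- aa_index(native[1]); nj <- aa_index(native[2])
  native_flat <- (nj - 1L) * 20L + ni
  rank <- which(o == native_flat)
  tibble::tibble(motif_id = motif_id,
                 native_i = native[1], native_j = native[2],
                 best_i = aa[ii[best]], best_j = aa[jj[best]],
                 identified = rank == 1L, rank = rank,
                 zscore = suppressWarnings(modified_zscore(e, native)))
}

#' Enrichment of native-pair identification over chance
#'
#' The fraction of identification results whose most favorable pair is the
#' native one, divided by the chance rate 1/400.
#'
#' @param results Tibble of [identify_native()] rows.
#' @return Fold enrichment (400 = always identified; 1 = chance).
#' @export
enrichment <- function(results) {
  stopifnot(nrow(results) >= 1L)
  mean(results$identified) / (1 / 400)
}

#' Correlation sweep against experimental coupling energies
#'
#' Recomputes SCEs on progressively constrained versions of a match ensemble
#' and reports the Pearson correlation against an experimental coupling-energy
#' table at each constraint. Heterotypic experimental pairs measured in one
#' order are compared against the symmetrized SCE.
#'
#' @param ens A `scp_ensemble` (typically from [search_matches()] with a
#'   permissive cutoff).
#' @param bg A `scp_background`.
#' @param constraints List of constraints, each either
#'   `list(max_matches = n)` or `list(rmsd_max = x)`.
#' @param experimental Tibble with columns `aa_i`, `aa_j`, `energy`.
#' @param epsilon_mode Passed to [sce_matrix()].
#' @return Tibble of sweep points: constraint description, `n_matches`, `r`
#'   (NA with fewer than 3 overlapping pairs).
#' @export
coupling_sweep <- function(ens, bg, constraints, experimental,
                           epsilon_mode = "max") {
  stopifnot(all(c("aa_i", "aa_j", "energy") %in% names(experimental)))
  purrr::map_dfr(constraints, function(con) {
    sub <- truncate_ensemble(ens, max_matches = con$max_matches,
                             rmsd_max = con$rmsd_max)
    nm <- n_matches(sub)
    if (nm < 1L) {
      return(tibble::tibble(constraint = .describe_constraint(con),
                            n_matches = 0L, r = NA_real_))
    }
    e <- symmetrize(suppressWarnings(
      sce_matrix(sub, bg, epsilon_mode = epsilon_mode)))
    pred <- unclass(e)[cbind(aa_index(experimental$aa_i),
                             aa_index(experimental$aa_j))]
    r <- if (length(pred) >= 3L && stats::sd(pred) > 0 &&
             stats::sd(experimental$energy) > 0) {
      stats::cor(pred, experimental$energy)
    } else NA_real_
    tibble::tibble(constraint = .describe_constraint(con), n_matches = nm, r = r)
  })
}

.describe_constraint <- function(con) {
  if (!is.null(con$max_matches)) paste0("max_matches=", con$max_matches)
  else if (!is.null(con$rmsd_max)) paste0("rmsd_max=", con$rmsd_max)
  else "none"
}

#' Score a structural model by mean SCE and mean contact energy
#'
#' Enumerates the model's contacts with CD at or above `cd_min`, builds the
#' flank-k motif of each, searches the database for its match ensemble, and
#' averages the SCE of the model's native amino-acid pair over all contacts.
#' The same contacts are also scored with a plain contact potential. Contacts
#' whose ensemble is empty contribute a zero SCE (no statistical support for
#' or against the pair).
#'
#' @param s The model structure (dihedrals computed).
#' @param db Structure database to search.
#' @param bg A `scp_background`.
#' @param lib A `scp_rotlib` for contact enumeration.
#' @param cp A contact potential (`scp_energy`) for the CE control score.
#' @param flank Motif flank width (default 1, 3x3 motifs).
#' @param cd_min Minimum contact degree (default 0.1).
#' @param cutoff,max_count Search parameters (defaults: flank cutoff, 50,000).
#' @param min_seq_sep Minimum same-chain separation (default 5).
#' @param epsilon_mode Passed to [sce_matrix()].
#' @return One-row tibble: `model_id`, `mean_sce`, `mean_ce`, `n_contacts`,
#'   `flagged` (TRUE when no contact qualified).
#' @export
score_model <- function(s, db, bg, lib, cp, flank = 1L, cd_min = 0.1,
                        cutoff = NULL, max_count = 50000L, min_seq_sep = 5L,
                        epsilon_mode = "max") {
  contacts <- enumerate_contacts(s, lib, min_seq_sep = min_seq_sep,
                                 flank = flank, cd_min = cd_min)
  if (nrow(contacts) == 0L) {
    return(tibble::tibble(model_id = structure_id(s), mean_sce = NA_real_,
                          mean_ce = NA_real_, n_contacts = 0L, flagged = TRUE))
  }
  if (!inherits(db, "scp_search_db")) db <- prepare_search_db(db, flank = flank)
  sces <- ces <- numeric(nrow(contacts))
  for (k in seq_len(nrow(contacts))) {
    motif <- extract_motif(s, contacts$chain_i[k], contacts$pos_i[k],
                           contacts$chain_j[k], contacts$pos_j[k], flank = flank)
    ensk <- search_matches(motif, db, cutoff = cutoff, max_count = max_count)
    native <- c(contacts$aa_i[k], contacts$aa_j[k])
    sces[k] <- if (n_matches(ensk) == 0L) 0 else {
      e <- suppressWarnings(sce_matrix(ensk, bg, epsilon_mode = epsilon_mode))
      unclass(e)[aa_index(native[1]), aa_index(native[2])]
    }
    ces[k] <- unclass(cp)[aa_index(native[1]), aa_index(native[2])]
  }
  tibble::tibble(model_id = structure_id(s), mean_sce = mean(sces),
                 mean_ce = mean(ces), n_contacts = nrow(contacts),
                 flagged = FALSE)
}

#' ROC curve and AUC for model-quality discrimination
#'
#' Labels models as positive when their quality meets the threshold
#' (`direction = "ge"`, e.g. GDT_TS >= 50; use `"le"` for RMSD-like metrics
#' where lower is better) and evaluates how well the classifier score
#' separates the classes. More favorable (lower) mean energies should predict
#' higher quality, so pass `score = -mean_energy` or any score where larger
#' means predicted-better. The AUC is computed by the rank (Mann-Whitney U)
#' statistic with midpoint handling of ties, which equals the trapezoidal area
#' under the full ROC curve.
#'
#' @param score Numeric classifier scores (larger = predicted higher quality).
#' @param quality Numeric quality labels (e.g. GDT_TS, TM-score, RMSD).
#' @param threshold Quality threshold splitting positives from negatives.
#' @param direction `"ge"` (quality >= threshold is positive) or `"le"`.
#' @return List with `auc`, `n_pos`, `n_neg` and `curve` (tibble of `fpr`,
#'   `tpr` points).
#' @export
roc_auc <- function(score, quality, threshold, direction = c("ge", "le")) {
  direction <- match.arg(direction)
  stopifnot(length(score) == length(quality))
  ok <- is.finite(score) & is.finite(quality)
  score <- score[ok]; quality <- quality[ok]
  pos <- if (direction == "ge") quality >= threshold else quality <= threshold
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) {
    warning("one class is empty after thresholding; AUC undefined")
    return(list(auc = NA_real_, n_pos = n_pos, n_neg = n_neg, curve = NULL))
  }
  r <- rank(score, ties.method = "average")
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  # full ROC curve over score thresholds, descending
  o <- order(score, decreasing = TRUE)
  tp <- cumsum(pos[o]); fp <- cumsum(!pos[o])
  # collapse tied scores to a single operating point
  last_of_tie <- c(diff(score[o]) != 0, TRUE)
  curve <- tibble::tibble(fpr = c(0, fp[last_of_tie] / n_neg),
                          tpr = c(0, tp[last_of_tie] / n_pos))
  list(auc = auc, n_pos = n_pos, n_neg = n_neg, curve = curve)
}

#' Alternate best/worst model selection
#'
#' Orders models best-to-worst by quality and alternately takes the next-best
#' and next-worst remaining entries until `n` are selected, yielding a subset
#' spanning the quality range.
#'
#' @param models Tibble with a `quality` column (larger = better unless
#'   `direction = "le"`).
#' @param n Number of models to keep.
#' @param direction `"ge"` if larger quality is better, `"le"` otherwise.
#' @return The selected rows, in selection order.
#' @export
select_models_alternating <- function(models, n = 20L, direction = c("ge", "le")) {
  direction <- match.arg(direction)
  o <- order(models$quality, decreasing = direction == "ge")
  n <- min(n, nrow(models))
  lo <- 1L; hi <- length(o); take <- integer(0)
  for (k in seq_len(n)) {
    if (k %% 2L == 1L) { take <- c(take, o[lo]); lo <- lo + 1L }
    else { take <- c(take, o[hi]); hi <- hi - 1L }
  }
  models[take, , drop = FALSE]
}

#' Read an experimental coupling-energy table
#'
#' TSV with columns `aa_i`, `aa_j`, `energy` (kcal/mol).
#'
#' @param path File path.
#' @return Tibble.
#' @export
read_coupling_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
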