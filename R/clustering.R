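# Greedy clustering of interaction motifs by structural distance (best-fit
# RMSD) or energetic distance (r_E), plus random-assignment controls and the
# binned r_E-versus-RMSD relationship.

#' Energetic distance between two energy matrices
#'
#' `r_E = 1 - r`, with `r` the Pearson correlation of the two matrices viewed
#' as 400-vectors. 0 means perfectly correlated energies, 1 uncorrelated, 2
#' perfectly anti-correlated.
#'
#' @param a,b `scp_energy` matrices (or plain 20x20 matrices).
#' @return `r_E` in `[0, 2]`; NA (with a warning) if either matrix has zero
#'   variance.
#' @export
energy_distance <- function(a, b) {
  va <- as.numeric(unclass(a)); vb <- as.numeric(unclass(b))
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    warning("zero variance in an energy matrix; r_E undefined")
    return(NA_real_)
  }
  1 - stats::cor(va, vb)
}

#' Pairwise distance matrix helpers
#'
#' `rmsd_distance_matrix()` computes all pairwise best-fit backbone RMSDs of a
#' list of motifs (or coordinate matrices); `energy_distance_matrix()` the
#' pairwise `r_E` of a list of energy matrices.
#'
#' @param motifs List of `scp_motif` objects or n x 3 coordinate matrices.
#' @return Symmetric distance matrix.
#' @export
rmsd_distance_matrix <- function(motifs) {
  coords <- lapply(motifs, function(m) if (inherits(m, "scp_motif")) m$coords else m)
  n <- length(coords)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- kabsch_rmsd(coords[[i]], coords[[j]])
    }
  }
  d
}

#' @rdname rmsd_distance_matrix
#' @param matrices List of `scp_energy` (symmetrized for energy clustering).
#' @export
energy_distance_matrix <- function(matrices) {
  v <- vapply(matrices, function(m) as.numeric(unclass(m)), numeric(400))
  cm <- suppressWarnings(stats::cor(v))
  d <- 1 - cm
  diag(d) <- 0
  d
}

#' Greedy radius clustering
#'
#' Per round: sample `n` items without replacement from the remaining set S,
#' pick as medoid the sampled item with the largest number of sampled
#' neighbours within distance `d` (ties to the lowest index), form the cluster
#' from every member of S within `d` of the medoid, and remove it from S.
#' With `n >= |S|` the medoid choice is exhaustive. Deterministic given
#' `seed`.
#'
#' @param dist_mat Symmetric pairwise distance matrix.
#' @param d Cluster radius.
#' @param n Sampling count per round (default 1,000).
#' @param rounds Maximum number of clusters (default 100).
#' @param seed Integer seed.
#' @return A `scp_clusters` object: list with `clusters` (each holding
#'   `medoid`, `members`, `distances`), `unassigned`, and the parameters.
#' @export
greedy_cluster <- function(dist_mat, d, n = 1000L, rounds = 100L, seed = 1L) {
  stopifnot(n >= 1L, d > 0, isSymmetric(unname(dist_mat)))
  set.seed(seed)
  S <- seq_len(nrow(dist_mat))
  clusters <- list()
  for (round in seq_len(rounds)) {
    if (length(S) == 0L) break
    samp <- if (length(S) <= n) S else sort(sample(S, n))
    within <- dist_mat[samp, samp, drop = FALSE] <= d
    score <- rowSums(within) - 1L          # neighbours excluding self
    medoid <- samp[which.max(score)]       # ties -> lowest index (sorted samp)
    members <- S[dist_mat[medoid, S] <= d]
    clusters[[round]] <- list(medoid = medoid, members = members,
                              distances = dist_mat[medoid, members])
    S <- setdiff(S, members)
  }
  structure(list(clusters = clusters, unassigned = S,
                 params = list(d = d, n = n, rounds = rounds, seed = seed,
                               method = "greedy")),
            class = "scp_clusters")
}

#' @export
print.scp_clusters <- function(x, ...) {
  cat(sprintf("<scp_clusters> %d clusters (%s), %d unassigned\n",
              length(x$clusters), x$params$method, length(x$unassigned)))
  invisible(x)
}

#' Tidy a clustering result
#'
#' @param x A `scp_clusters`.
#' @param ... Unused.
#' @return Tibble with one row per member: `cluster`, `medoid`, `item`,
#'   `distance`.
#' @exportS3Method generics::tidy
tidy.scp_clusters <- function(x, ...) {
  purrr::imap_dfr(x$clusters, function(cl, k) {
    tibble::tibble(cluster = as.integer(k), medoid = cl$medoid,
                   item = cl$members, distance = as.numeric(cl$distances))
  })
}

#' Cluster sizes
#' @param x A `scp_clusters`.
#' @return Integer vector of member counts.
#' @export
cluster_sizes <- function(x) vapply(x$clusters, function(cl) length(cl$members), integer(1))

#' Mean member-to-medoid distance over all clusters
#' @param x A `scp_clusters`.
#' @return Mean of all member distances pooled over clusters.
#' @export
mean_medoid_distance <- function(x) {
  mean(unlist(lapply(x$clusters, function(cl) cl$distances)))
}

#' Random-assignment clustering control
#'
#' Partitions randomly chosen items into clusters of exactly the given sizes
#' (matching, e.g., the sizes obtained when clustering by structure); the
#' medoid of each random cluster is its member minimizing the summed distance
#' to the others.
#'
#' @param dist_mat Symmetric pairwise distance matrix.
#' @param sizes Integer vector of cluster sizes; their sum must not exceed the
#'   number of items.
#' @param seed Integer seed.
#' @return A `scp_clusters` object.
#' @export
random_cluster_control <- function(dist_mat, sizes, seed = 1L) {
  n_items <- nrow(dist_mat)
  if (sum(sizes) > n_items) stop("cluster sizes exceed the number of items")
  set.seed(seed)
  pool <- sample(n_items, sum(sizes))
  clusters <- list(); at <- 1L
  for (k in seq_along(sizes)) {
    members <- pool[at:(at + sizes[k] - 1L)]
    at <- at + sizes[k]
    dsub <- dist_mat[members, members, drop = FALSE]
    medoid <- members[which.min(rowSums(dsub))]
    clusters[[k]] <- list(medoid = medoid, members = members,
                          distances = dist_mat[medoid, members])
  }
  structure(list(clusters = clusters, unassigned = setdiff(seq_len(n_items), pool),
                 params = list(sizes = sizes, seed = seed, method = "random")),
            class = "scp_clusters")
}

#' Binned r_E-versus-RMSD profile
#'
#' Computes, over all motif pairs, the structural distance (best-fit RMSD) and
#' energetic distance (r_E of their energy matrices), partitions the pairs
#' into RMSD bins and summarises r_E per bin.
#'
#' @param motifs List of motifs or coordinate matrices.
#' @param matrices List of corresponding `scp_energy` matrices.
#' @param bin_edges RMSD bin edges (default `c(0, 0.2, ..., 1.8, 4)`).
#' @return Tibble per bin: `rmsd_lo`, `rmsd_hi`, `n_pairs`, `mean_re`,
#'   `median_re`, `se_re` (empty bins reported with `n_pairs = 0`).
#' @export
rmsd_re_profile <- function(motifs, matrices,
                            bin_edges = c(seq(0, 1.8, by = 0.2), 4)) {
  stopifnot(length(motifs) == length(matrices), length(motifs) >= 2L)
  dr <- rmsd_distance_matrix(motifs)
  de <- energy_distance_matrix(matrices)
  ut <- upper.tri(dr)
  pairs <- tibble::tibble(rmsd = dr[ut], re = de[ut])
  pairs$bin <- findInterval(pairs$rmsd, bin_edges, rightmost.closed = TRUE)
  purrr::map_dfr(seq_len(length(bin_edges) - 1L), function(b) {
    sub <- pairs[pairs$bin == b & !is.na(pairs$re), , drop = FALSE]
    tibble::tibble(rmsd_lo = bin_edges[b], rmsd_hi = bin_edges[b + 1],
                   n_pairs = nrow(sub),
                   mean_re = if (nrow(sub)) mean(sub$re) else NA_real_,
                   median_re = if (nrow(sub)) stats::median(sub$re) else NA_real_,
                   se_re = if (nrow(sub) > 1L) stats::sd(sub$re) / sqrt(nrow(sub)) else NA_real_)
  })
}

#' Write a clustering report
#'
#' JSON with the parameters and per-cluster medoid/member/distance summary,
#' plus an optional TSV member table.
#'
#' @param x A `scp_clusters`.
#' @param path JSON output path.
#' @param tsv_path Optional member-table TSV path.
#' @return `path` invisibly.
#' @export
write_cluster_report <- function(x, path, tsv_path = NULL) {
  jsonlite::write_json(list(
    params = x$params,
    unassigned = x$unassigned,
    clusters = lapply(x$clusters, function(cl) {
      list(medoid = cl$medoid, members = cl$members,
           mean_distance = mean(cl$distances), max_distance = max(cl$distances))
    })), path, digits = NA, auto_unbox = TRUE)
  if (!is.null(tsv_path)) readr::write_tsv(tidy.scp_clusters(x), tsv_path)
  invisible(path)
}
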