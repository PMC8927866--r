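# Run configuration and manifests for reproducible pipelines.

#' Default run configuration
#'
#' Central defaults shared by the command-line wrapper and scripted
#' workflows. The values mirror the method's standard settings: search max
#' count 50,000, minimum-ensemble warning at 1,000 matches, CD threshold 0.1
#' for model scoring, flank-dependent RMSD cutoffs.
#'
#' @param flank Motif flank width (0, 1 or 2; default 1).
#' @param ... Overrides for any default field.
#' @return A named list of configuration values.
#' @export
scp_config <- function(flank = 1L, ...) {
  cfg <- list(
    flank = as.integer(flank),
    rmsd_cutoff = default_rmsd_cutoff(flank),
    max_count = 50000L,
    min_ensemble = 1000L,
    epsilon_mode = "max",
    cd_min = 0.1,
    min_seq_sep = 5L,
    burial_radius = 12,
    seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown configuration field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  if (!cfg$flank %in% 0:2) stop("flank must be 0, 1 or 2")
  cfg
}

#' Write a run manifest
#'
#' Records the configuration, seed, input file digests and package version so
#' a run can be replayed bit-identically.
#'
#' @param path Output JSON path.
#' @param config Configuration list (e.g. [scp_config()]).
#' @param inputs Character vector of input file paths to digest (md5).
#' @param command Free-form command description.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, config, inputs = character(), command = "") {
  digests <- if (length(inputs)) {
    stats::setNames(as.character(tools::md5sum(inputs)), inputs)
  } else NULL
  manifest <- list(command = command, config = config,
                   inputs = as.list(digests),
                   package_version = as.character(utils::packageVersion("scpot")),
                   r_version = R.version.string,
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data
#' @importFrom tibble tibble
NULL
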