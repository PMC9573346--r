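#' Run configuration
#'
#' A flat, human-editable YAML file holds every tunable constant of a
#' run: the heuristic score ledger, the sOTU clustering threshold, the
#' rank band bounds and the RNG seed. Defaults equal the shipped
#' constants (motif floor 2 bits, V1 rule 35 aa / 5 bits, confidence
#' threshold 20, species threshold 90%, bands 90/70/45). Values
#' round-trip losslessly through [writeRunConfig()]/[readRunConfig()].
#'
#' @param heuristics a \linkS4class{HeuristicConfig}.
#' @param clusterThreshold sOTU identity threshold (percent).
#' @param rankBands named numeric: species/genus/family lower bounds.
#' @param seed integer RNG seed.
#' @param verbosity 0 (quiet), 1 (normal), 2 (debug).
#' @return A list of class \code{"palmprint_run_config"}.
#' @examples
#' cfg <- runConfig()
#' cfg$clusterThreshold
#' @export
runConfig <- function(heuristics = heuristicConfig(),
                      clusterThreshold = 90,
                      rankBands = c(species = 90, genus = 70, family = 45),
                      seed = 1L, verbosity = 1L) {
    stopifnot(is(heuristics, "HeuristicConfig"),
              clusterThreshold > 0, clusterThreshold <= 100,
              identical(names(rankBands), c("species", "genus", "family")))
    structure(list(heuristics = heuristics,
                   clusterThreshold = clusterThreshold,
                   rankBands = rankBands, seed = as.integer(seed),
                   verbosity = as.integer(verbosity)),
              class = "palmprint_run_config")
}

.heuristic_slots <- c("minMotifScore", "v1Min", "v1Penalty", "v1Max",
                      "v2Min", "v2Max", "ppMinLen", "ppMaxLen",
                      "outOfRangePenalty", "highConfidenceThreshold")

#' @rdname runConfig
#' @param cfg a run configuration.
#' @param path YAML file.
#' @export
writeRunConfig <- function(cfg, path) {
    h <- lapply(setNames(.heuristic_slots, .heuristic_slots),
                function(s) slot(cfg$heuristics, s))
    yaml::write_yaml(list(heuristics = h,
                          cluster_threshold = cfg$clusterThreshold,
                          rank_bands = as.list(cfg$rankBands),
                          seed = cfg$seed, verbosity = cfg$verbosity),
                     path)
    invisible(path)
}

#' @rdname runConfig
#' @param overrides named list applied on top of the file values
#'   (e.g. command-line flags); names as in the YAML schema, heuristic
#'   fields under \code{heuristics}.
#' @export
readRunConfig <- function(path = NULL, overrides = list()) {
    vals <- if (!is.null(path)) yaml::read_yaml(path) else list()
    vals <- utils::modifyList(vals, overrides)
    h <- do.call(heuristicConfig, vals$heuristics %||% list())
    runConfig(heuristics = h,
              clusterThreshold = vals$cluster_threshold %||% 90,
              rankBands = unlist(vals$rank_bands %||%
                  list(species = 90, genus = 70, family = 45)),
              seed = vals$seed %||% 1L,
              verbosity = vals$verbosity %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
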