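## Run configuration: scoring thresholds, the organ-system -> suitable-routes
## map, manual overrides, and the RNG seed. Defaults reproduce the packaged
## worked examples without any override.

#' Default organ-system to suitable-route map
#'
#' Which routes of administration count as "well-suited" delivery for each
#' infected organ system. Only a few cells are fixed by clinical common sense
#' (inhalation for respiratory infection, intravenous for cardiovascular or
#' systemic infection); the remainder are declared defaults and fully
#' user-overridable through [run_config()].
#'
#' @return Named list mapping each infected-system value to a character vector
#'   of routes.
#' @export
default_route_suitability <- function() {
  list(
    respiratory = c("inhalation", "oral"),
    digestive = "oral",
    cardiovascular = "intravenous",
    nervous = c("intravenous", "oral"),
    integumentary = c("topical", "oral"),
    urogenital = c("oral", "intravenous"),
    multiple = c("oral", "intravenous")
  )
}

#' Build a run configuration
#'
#' @param similarity_threshold Tanimoto similarity at or above which two
#'   compounds count as structurally similar for the C_SAR = 0.5 rule
#'   (default 0.4, a conventional ECFP4 similarity floor).
#' @param cluster_cutoff Flat-cut distance (1 - Tanimoto) for sub-cluster
#'   extraction (default 0.6).
#' @param effectiveness_delta A combination is flagged effective when its BCC
#'   score exceeds the sum of its components' BSA scores by strictly more than
#'   this margin (default 5).
#' @param route_suitability Organ-system to route map; see
#'   [default_route_suitability()]. Partial maps are merged over the default.
#' @param overrides Manual overrides, a list with optional elements `bsa`
#'   (`overrides$bsa[[drug_id]][[virus_id]]` = named numeric of component
#'   values, e.g. `c(c_ic = 1)`) and `coeff`
#'   (`overrides$coeff[[pair_key]]` = named numeric of coefficient values,
#'   where `pair_key` is `"drug1|drug2|virus"` with the pair in canonical
#'   order). Every override applied is recorded in the result's provenance.
#' @param seed Integer seed used by every randomized operation.
#' @param log_level One of `"quiet"`, `"info"`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(similarity_threshold = 0.4,
                       cluster_cutoff = 0.6,
                       effectiveness_delta = 5,
                       route_suitability = default_route_suitability(),
                       overrides = list(),
                       seed = 1L,
                       log_level = "info") {
  stopifnot(
    is.numeric(similarity_threshold), similarity_threshold > 0, similarity_threshold <= 1,
    is.numeric(cluster_cutoff), cluster_cutoff >= 0, cluster_cutoff <= 1,
    is.numeric(effectiveness_delta), effectiveness_delta > 0
  )
  base <- default_route_suitability()
  for (nm in names(route_suitability)) base[[nm]] <- route_suitability[[nm]]
  structure(
    list(similarity_threshold = similarity_threshold,
         cluster_cutoff = cluster_cutoff,
         effectiveness_delta = effectiveness_delta,
         route_suitability = base,
         overrides = overrides,
         seed = as.integer(seed),
         log_level = log_level),
    class = "run_config"
  )
}

#' Read a run configuration from a JSON file
#'
#' Values present in the file are merged over the defaults of [run_config()].
#'
#' @param path Path to a JSON configuration file.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- raw[intersect(names(raw), names(formals(run_config)))]
  if (!is.null(args$route_suitability)) {
    args$route_suitability <- lapply(args$route_suitability, as.character)
  }
  do.call(run_config, args)
}

#' @export
print.run_config <- function(x, ...) {
  cat("run_config:\n",
      sprintf("  similarity_threshold: %g\n", x$similarity_threshold),
      sprintf("  cluster_cutoff: %g\n", x$cluster_cutoff),
      sprintf("  effectiveness_delta: %g\n", x$effectiveness_delta),
      sprintf("  overrides: %d\n", length(unlist(x$overrides))),
      sprintf("  seed: %d\n", x$seed), sep = "")
  invisible(x)
}

bsa_override <- function(config, drug_id, virus_id) {
  ov <- config$overrides$bsa
  if (is.null(ov)) return(NULL)
  o <- ov[[drug_id]]
  if (is.null(o)) return(NULL)
  o[[virus_id]]
}

coeff_override <- function(config, pair, virus_id) {
  ov <- config$overrides$coeff
  if (is.null(ov)) return(NULL)
  ov[[paste(pair[1], pair[2], virus_id, sep = "|")]]
}
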