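## Four-coefficient multiplicative score for a two-drug BSA-containing
## combination (BCC) against a virus of interest:
##
##   BCC score = k_DI * k_DTI * k_DRS * k_RoA * (BSA score 1 + BSA score 2)
##
## A combination is called effective when its BCC score exceeds the sum of the
## two BSA scores by strictly more than the configured margin (default 5).

#' Drug-interaction coefficient (k_DI)
#'
#' 0.5 when both drugs share the same mechanism-of-action class (redundant
#' pharmacology, e.g. two nucleoside analogs); 1 when the mechanisms differ.
#'
#' @param d1,d2 One-row drug annotations.
#' @return 0.5 or 1.
#' @export
coeff_di <- function(d1, d2) {
  if (identical(d1$moa_class, d2$moa_class)) 0.5 else 1
}

#' Drug-target-interaction coefficient (k_DTI) and target class
#'
#' 1.2 when both drugs target viral factors (minimum expected side effects),
#' 1.1 for one viral and one host target, 1.0 for two host targets (maximum
#' expected side effects). An unknown target kind takes the conservative floor
#' 1.0 with class `"unknown"`; a drug targeting both viral and host factors is
#' treated like a host-directed drug for the coefficient.
#'
#' @param d1,d2 One-row drug annotations.
#' @return List with `k` and `target_class` (one of `"virus_virus"`,
#'   `"virus_host"`, `"host_host"`, `"unknown"`).
#' @export
coeff_dti <- function(d1, d2) {
  kinds <- c(d1$target_kind, d2$target_kind)
  if (any(kinds == "unknown")) return(list(k = 1.0, target_class = "unknown"))
  kinds[kinds == "both"] <- "host"  # host involvement carries the side-effect risk
  n_virus <- sum(kinds == "virus")
  if (n_virus == 2L) list(k = 1.2, target_class = "virus_virus")
  else if (n_virus == 1L) list(k = 1.1, target_class = "virus_host")
  else list(k = 1.0, target_class = "host_host")
}

#' Replication-stage coefficient (k_DRS)
#'
#' 1.2 when both drugs act on the same stage of the viral life cycle (entry,
#' replication or exit); 1.0 when the stages differ or either is unknown.
#'
#' @param d1,d2 One-row drug annotations.
#' @return 1.2 or 1.0.
#' @export
coeff_drs <- function(d1, d2) {
  s1 <- d1$replication_stage
  s2 <- d2$replication_stage
  if (identical(s1, s2) && s1 != "unknown") 1.2 else 1.0
}

#' Route-of-administration coefficient (k_RoA)
#'
#' 0.8 when the two drugs share no route (they cannot be co-administered the
#' same way); 1.2 when a shared route is also suited to at least one organ
#' system the virus infects; 1.0 when routes are shared but none is suited. A
#' drug with no annotated route gives 0.8 with a warning.
#'
#' @param d1,d2 One-row drug annotations.
#' @param virus One-row virus annotation.
#' @param suitability Organ-system to route map.
#' @return 0.8, 1.0 or 1.2.
#' @export
coeff_roa <- function(d1, d2, virus, suitability = default_route_suitability()) {
  r1 <- split_set(d1$routes)
  r2 <- split_set(d2$routes)
  if (!length(r1) || !length(r2)) {
    warning("missing route annotation on ",
            paste(c(d1$drug_id, d2$drug_id)[c(!length(r1), !length(r2))], collapse = ", "),
            "; k_RoA scored 0.8", call. = FALSE)
    return(0.8)
  }
  shared <- intersect(r1, r2)
  if (!length(shared)) return(0.8)
  systems <- split_set(virus$infected_systems)
  suitable <- unique(unlist(suitability[systems], use.names = FALSE))
  if (length(intersect(shared, suitable))) 1.2 else 1.0
}

#' Compute the full BCC score for a drug pair
#'
#' Computes both component BSA scores (or takes them from `bsa` when
#' supplied), derives the four coefficients from the pair's annotations, and
#' applies the multiplicative formula. Coefficient overrides supplied in
#' `config$overrides$coeff[["drug1|drug2|virus"]]` (canonical pair order)
#' replace computed values and are recorded in the provenance.
#'
#' @param drug_id_1,drug_id_2 The two drug ids (order irrelevant).
#' @param virus_id Virus of interest.
#' @param bundle An `annotation_bundle`.
#' @param config A [run_config()].
#' @param bsa Optional list of two precomputed `bsa_breakdown` objects (or
#'   bare numeric totals, named by drug id) to use instead of recomputing.
#' @return A `bcc_breakdown`: list with `pair`, `virus_id`, the four
#'   coefficients, `bsa_sum`, `bcc_score`, `delta`, `effective`,
#'   `target_class`, the two component breakdowns and `provenance`.
#' @examples
#' b <- ebov_fixture()
#' compute_bcc_score("favipiravir", "merimepodib", "ebov", b)
#' @export
compute_bcc_score <- function(drug_id_1, drug_id_2, virus_id, bundle,
                              config = run_config(), bsa = NULL) {
  pair <- canonical_pair(drug_id_1, drug_id_2)
  virus_id <- normalize_id(virus_id)
  d1 <- get_drug(bundle, pair[1])
  d2 <- get_drug(bundle, pair[2])
  voi <- get_virus(bundle, virus_id)

  totals <- numeric(2)
  breakdowns <- vector("list", 2)
  for (i in 1:2) {
    supplied <- if (!is.null(bsa)) bsa[[pair[i]]] else NULL
    if (is.null(supplied)) {
      breakdowns[[i]] <- compute_bsa_score(pair[i], virus_id, bundle, config)
      totals[i] <- breakdowns[[i]]$total
    } else if (inherits(supplied, "bsa_breakdown")) {
      breakdowns[[i]] <- supplied
      totals[i] <- supplied$total
    } else {
      totals[i] <- as.numeric(supplied)
    }
  }

  dti <- coeff_dti(d1, d2)
  k <- c(
    k_di = coeff_di(d1, d2),
    k_dti = dti$k,
    k_drs = coeff_drs(d1, d2),
    k_roa = coeff_roa(d1, d2, voi, config$route_suitability)
  )
  target_class <- dti$target_class
  prov <- c(
    sprintf("k_DI=%g: moa %s vs %s", k[["k_di"]], d1$moa_class, d2$moa_class),
    sprintf("k_DTI=%g: target kinds %s/%s (%s)", k[["k_dti"]],
            d1$target_kind, d2$target_kind, target_class),
    sprintf("k_DRS=%g: stages %s/%s", k[["k_drs"]],
            d1$replication_stage, d2$replication_stage),
    sprintf("k_RoA=%g: routes {%s} and {%s} vs systems {%s}", k[["k_roa"]],
            d1$routes, d2$routes, voi$infected_systems)
  )

  ov <- coeff_override(config, pair, virus_id)
  if (!is.null(ov)) {
    ov <- unlist(ov)
    bad <- setdiff(names(ov), names(k))
    if (length(bad)) stop("unknown coefficient override(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    for (nm in names(ov)) {
      k[[nm]] <- as.numeric(ov[[nm]])
      prov <- c(prov, sprintf("override: %s=%g (manual)", nm, k[[nm]]))
    }
  }

  bsa_sum <- sum(totals)
  bcc_score <- prod(k) * bsa_sum
  delta <- bcc_score - bsa_sum
  structure(
    list(pair = pair, virus_id = virus_id,
         k_di = k[["k_di"]], k_dti = k[["k_dti"]],
         k_drs = k[["k_drs"]], k_roa = k[["k_roa"]],
         bsa_sum = bsa_sum, bcc_score = bcc_score, delta = delta,
         effective = delta > config$effectiveness_delta,
         target_class = target_class,
         bsa_breakdowns = breakdowns, provenance = prov),
    class = "bcc_breakdown"
  )
}

#' @export
print.bcc_breakdown <- function(x, ...) {
  cat(sprintf("BCC score: %s + %s vs %s\n", x$pair[1], x$pair[2], x$virus_id))
  cat(sprintf("  k_DI=%g k_DTI=%g k_DRS=%g k_RoA=%g (%s)\n",
              x$k_di, x$k_dti, x$k_drs, x$k_roa, x$target_class))
  cat(sprintf("  BSA sum %s -> BCC %s (delta %s) %s\n",
              display_score(x$bsa_sum, 1), display_score(x$bcc_score, 1),
              display_score(x$delta, 2),
              if (x$effective) "EFFECTIVE" else "not effective"))
  invisible(x)
}

#' Score and rank all drug pairs against a virus
#'
#' Scores every unordered pair from `drug_ids` (all drugs in the bundle by
#' default) against the virus of interest and returns a ranked table: BCC
#' score descending, then delta descending, then canonical pair name.
#'
#' @param virus_id Virus of interest.
#' @param bundle An `annotation_bundle`.
#' @param drug_ids Drugs to pair up (default: all in the bundle; at least 2).
#' @param config A [run_config()].
#' @param effective_only Keep only pairs whose delta exceeds the configured
#'   effectiveness margin.
#' @param top Optionally truncate to the first `top` rows after ranking.
#' @return Data frame with columns `drug_1`, `drug_2`, `virus`, the four
#'   coefficients, `bsa_sum`, `bcc_score`, `delta`, `effective`,
#'   `target_class`, `published` (joined from the bundle's combinations table
#'   when present).
#' @export
rank_combinations <- function(virus_id, bundle, drug_ids = NULL,
                              config = run_config(), effective_only = FALSE,
                              top = NULL) {
  if (is.null(drug_ids)) drug_ids <- bundle$drugs$drug_id
  drug_ids <- unique(normalize_id(drug_ids))
  if (length(drug_ids) < 2L) stop("ranking needs at least 2 drugs", call. = FALSE)
  virus_id <- normalize_id(virus_id)

  pairs <- utils::combn(sort(drug_ids, method = "radix"), 2)
  rows <- vector("list", ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    s <- compute_bcc_score(pairs[1, j], pairs[2, j], virus_id, bundle, config)
    rows[[j]] <- data.frame(
      drug_1 = s$pair[1], drug_2 = s$pair[2], virus = virus_id,
      k_di = s$k_di, k_dti = s$k_dti, k_drs = s$k_drs, k_roa = s$k_roa,
      bsa_sum = s$bsa_sum, bcc_score = s$bcc_score, delta = s$delta,
      effective = s$effective, target_class = s$target_class,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)

  out$published <- FALSE
  cmb <- bundle$combinations
  if (!is.null(cmb) && nrow(cmb)) {
    pub <- cmb[cmb$published & cmb$virus_id == virus_id, , drop = FALSE]
    key <- paste(out$drug_1, out$drug_2)
    out$published <- key %in% paste(pub$drug_id_1, pub$drug_id_2)
  }

  ord <- order(-out$bcc_score, -out$delta, out$drug_1, out$drug_2, method = "radix")
  out <- out[ord, , drop = FALSE]
  if (effective_only) out <- out[out$effective, , drop = FALSE]
  if (!is.null(top)) out <- utils::head(out, top)
  rownames(out) <- NULL
  out
}

#' Format a score for display
#'
#' Scores are computed, compared and ranked at full precision; rounding is a
#' presentation concern only. Rounds half away from zero to the requested
#' number of decimals and keeps trailing zeros (`10 -> "10.0"`).
#'
#' @param value Numeric score(s).
#' @param precision Number of decimals (default 1, matching the published
#'   tables; use 2 for the full coefficient product resolution).
#' @return Character vector.
#' @examples
#' display_score(15.84)        # "15.8"
#' display_score(15.05, 2)     # "15.05"
#' @export
display_score <- function(value, precision = 1) {
  stopifnot(is.numeric(value), precision >= 0)
  p <- 10^precision
  rounded <- sign(value) * floor(abs(value) * p + 0.5) / p
  formatC(rounded, format = "f", digits = precision)
}
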