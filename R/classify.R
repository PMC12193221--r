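## Reference-panel classification with the 0.15 degC decision rule: peak
## separations of at least the threshold imply distinct sequences, smaller
## separations imply identity.  Equality at the threshold is treated as
## distinct (the rule states "exceeds -> distinct" and "less than ->
## identical" without covering equality; distinct keeps the ten-species
## COXII panel's 0.15-apart pair species-specific).  Ambiguity is surfaced,
## never resolved by panel order; Tm values are compared after rounding to
## the 0.01 degC storage precision.

#' Classifier configuration
#'
#' @param delta_tm_threshold Decision threshold in degrees Celsius
#'   (default 0.15); separations `>= threshold` count as distinct
#'   (comparisons at 1e-9 tolerance).
#' @param peak_match_mode `"nearest_single"` (default): candidates are
#'   species whose closest panel peak lies within the threshold of the
#'   query's principal peak.  `"full_signature"`: additionally requires
#'   equal peak counts with every matched peak within the threshold;
#'   count mismatches yield status `"partial_signature"`.
#' @return Object of class `ClassifierConfig`.
#' @export
classifier_config <- function(delta_tm_threshold = 0.15,
                              peak_match_mode = c("nearest_single",
                                                  "full_signature")) {
  if (delta_tm_threshold <= 0) {
    stop("delta_tm_threshold must be > 0", call. = FALSE)
  }
  structure(
    list(delta_tm_threshold = delta_tm_threshold,
         peak_match_mode = match.arg(peak_match_mode)),
    class = "ClassifierConfig"
  )
}

.query_peaks <- function(query) {
  if (inherits(query, "PeakSet")) {
    if (nrow(query) == 0L) stop("query has no peaks", call. = FALSE)
    list(peaks = round(query$tm, 2L),
         principal = round(query$tm[which.max(query$height)], 2L))
  } else {
    p <- round(as.numeric(query), 2L)
    if (length(p) == 0L || anyNA(p)) stop("query has no peaks", call. = FALSE)
    list(peaks = p, principal = p[1L])
  }
}

## TRUE when a separation means "distinct" under the boundary rule
.is_distinct <- function(delta, threshold) delta >= threshold - 1e-9

#' Classify an unknown sample against a reference Tm panel
#'
#' The query's principal peak (highest derivative peak; first value of a
#' plain numeric vector) is compared against each panel species' closest
#' peak.  Species within the threshold are candidates: exactly one gives
#' status `"match"`, several give `"ambiguous"` with all candidates
#' reported, none gives `"novel"`.  In `"full_signature"` mode a candidate
#' must also present the same number of peaks, each within the threshold of
#' its rank-matched query peak; when the only species within the threshold
#' disagree in peak count the status is `"partial_signature"` and the
#' nearest such species is reported.  Classification is deterministic and
#' invariant to panel order; distance ties are reported as ambiguous.
#'
#' @param query A `PeakSet` from [call_peaks()] or a numeric vector of peak
#'   Tm (principal first).
#' @param panel A [reference_panel()].
#' @param config A [classifier_config()].
#' @param query_id Identifier carried into the result.
#' @param query_batch Optional acquisition batch of the query; when given it
#'   is checked against the panel batches via [batch_consistency_guard()].
#' @return Object of class `ClassificationResult`: `query_id`,
#'   `assigned_species` (or `NA`), `delta_tm`, `status`, `candidates`
#'   (data.frame `species`, `delta_tm`).
#' @examples
#' classify_sample(77.50, hrm_panel("cox2_larva"))
#' @export
classify_sample <- function(query, panel, config = classifier_config(),
                            query_id = "query", query_batch = NULL) {
  q <- .query_peaks(query)
  thr <- config$delta_tm_threshold
  empty_cand <- data.frame(species = character(0), delta_tm = numeric(0))
  res <- function(status, assigned, delta, candidates) {
    structure(
      list(query_id = query_id, assigned_species = assigned,
           delta_tm = delta, status = status, candidates = candidates),
      class = "ClassificationResult")
  }
  if (length(panel$species) == 0L) {
    return(res("novel", NA_character_, NA_real_, empty_cand))
  }
  if (!is.null(query_batch)) {
    batch_consistency_guard(query_batch, panel$batch)
  }
  nearest <- vapply(panel$peaks,
                    function(p) min(abs(round(p, 2L) - q$principal)),
                    numeric(1L))
  within <- !.is_distinct(nearest, thr)
  if (config$peak_match_mode == "nearest_single") {
    cand <- data.frame(species = panel$species[within],
                       delta_tm = nearest[within])
    cand <- cand[order(cand$delta_tm, cand$species), , drop = FALSE]
    rownames(cand) <- NULL
    if (nrow(cand) == 0L) {
      i <- which.min(nearest)
      return(res("novel", NA_character_, nearest[i], cand))
    }
    if (nrow(cand) == 1L) {
      return(res("match", cand$species[1L], cand$delta_tm[1L], cand))
    }
    res("ambiguous", NA_character_, min(cand$delta_tm), cand)
  } else {
    full <- vapply(seq_along(panel$peaks), function(i) {
      p <- sort(round(panel$peaks[[i]], 2L))
      qq <- sort(q$peaks)
      length(p) == length(qq) && !any(.is_distinct(abs(p - qq), thr))
    }, logical(1L))
    cand <- data.frame(species = panel$species[full],
                       delta_tm = nearest[full])
    cand <- cand[order(cand$delta_tm, cand$species), , drop = FALSE]
    rownames(cand) <- NULL
    if (nrow(cand) == 1L) {
      return(res("match", cand$species[1L], cand$delta_tm[1L], cand))
    }
    if (nrow(cand) >= 2L) {
      return(res("ambiguous", NA_character_, min(cand$delta_tm), cand))
    }
    ## no full-signature candidate; is anything within threshold on the
    ## nearest-peak basis but with a different peak count?
    if (any(within)) {
      i <- which(within)[which.min(nearest[within])]
      part <- data.frame(species = panel$species[i], delta_tm = nearest[i])
      return(res("partial_signature", panel$species[i], nearest[i], part))
    }
    i <- which.min(nearest)
    res("novel", NA_character_, nearest[i], empty_cand)
  }
}

#' @export
print.ClassificationResult <- function(x, ...) {
  cat(sprintf("<ClassificationResult> %s: %s", x$query_id, x$status))
  if (!is.na(x$assigned_species)) {
    cat(sprintf(" -> %s (delta Tm %.2f degC)", x$assigned_species, x$delta_tm))
  }
  cat("\n")
  if (nrow(x$candidates)) {
    for (i in seq_len(nrow(x$candidates))) {
      cat(sprintf("  candidate %-22s delta %.2f\n",
                  x$candidates$species[i], x$candidates$delta_tm[i]))
    }
  }
  invisible(x)
}

#' Serialize a classification result to JSON
#'
#' @param result A [classify_sample()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_classification_json <- function(result, path) {
  jsonlite::write_json(
    list(query_id = result$query_id, status = result$status,
         assigned_species = result$assigned_species,
         delta_tm = result$delta_tm,
         candidates = result$candidates),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Audit a panel for indistinguishable species pairs
#'
#' Exhaustively compares principal peaks of all species pairs; pairs whose
#' separation is below the threshold (boundary equality counts as distinct)
#' cannot be told apart by a single-peak Tm reading.  The result is
#' symmetric and invariant to species order.
#'
#' @param panel A [reference_panel()] with >= 2 species.
#' @param config A [classifier_config()].
#' @return data.frame `species_a`, `species_b`, `delta_tm`, one row per
#'   indistinguishable unordered pair.
#' @export
pairwise_discriminability <- function(panel, config = classifier_config()) {
  if (length(panel$species) < 2L) {
    stop("panel needs >= 2 species", call. = FALSE)
  }
  tm <- principal_peaks(panel)
  ord <- order(names(tm))
  tm <- tm[ord]
  rows <- list()
  for (i in seq_len(length(tm) - 1L)) {
    for (j in (i + 1L):length(tm)) {
      d <- abs(tm[[i]] - tm[[j]])
      if (!.is_distinct(d, config$delta_tm_threshold)) {
        rows[[length(rows) + 1L]] <- data.frame(
          species_a = names(tm)[i], species_b = names(tm)[j], delta_tm = d)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(species_a = character(0), species_b = character(0),
                      delta_tm = numeric(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Replicate drift between two acquisitions of the same panel
#'
#' For each species present in both panels, the absolute difference of
#' principal-peak Tm, with a signed direction tally and min/max summary;
#' species present in only one panel are listed separately.
#'
#' @param panel_a,panel_b Two [reference_panel()]s sharing >= 1 species.
#' @return List: `per_species` (data.frame `species`, `tm_a`, `tm_b`,
#'   `delta` signed, `abs_delta`), `min_abs`, `max_abs`, `n_up` (species
#'   whose Tm increased), `only_a`, `only_b`.
#' @export
replicate_error <- function(panel_a, panel_b) {
  shared <- intersect(panel_a$species, panel_b$species)
  if (length(shared) == 0L) {
    stop("panels share no species", call. = FALSE)
  }
  pa <- principal_peaks(panel_a)[shared]
  pb <- principal_peaks(panel_b)[shared]
  per <- data.frame(species = shared, tm_a = unname(pa), tm_b = unname(pb),
                    delta = unname(pb - pa),
                    abs_delta = abs(unname(pb - pa)))
  list(per_species = per,
       min_abs = min(per$abs_delta), max_abs = max(per$abs_delta),
       n_up = sum(per$delta > 0),
       only_a = setdiff(panel_a$species, shared),
       only_b = setdiff(panel_b$species, shared))
}

#' Guard against cross-batch Tm comparison
#'
#' Melt-peak positions drift slightly between acquisition runs, so unknowns
#' should be co-amplified with the reference standards.  Comparing across
#' batches is allowed but triggers a warning recommending co-amplified
#' references; missing batch identifiers warn that the batch is unknown.
#'
#' @param query_batch Batch identifier(s) of the query.
#' @param panel_batch Batch identifier(s) of the panel.
#' @return `"pass"` or `"warning"`, invisibly; warnings carry class
#'   `hrmid_batch_warning`.
#' @export
batch_consistency_guard <- function(query_batch, panel_batch) {
  warn <- function(msg) {
    warning(warningCondition(msg, class = "hrmid_batch_warning"))
    invisible("warning")
  }
  if (is.null(query_batch) || is.null(panel_batch) ||
      anyNA(query_batch) || anyNA(panel_batch) ||
      !all(nzchar(query_batch)) || !all(nzchar(panel_batch))) {
    return(warn("batch unknown: cannot verify co-amplification"))
  }
  if (!all(unique(query_batch) %in% unique(panel_batch))) {
    return(warn(paste(
      "query and panel come from different batches; melt peaks drift",
      "between runs - co-amplify references with the unknown")))
  }
  invisible("pass")
}
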