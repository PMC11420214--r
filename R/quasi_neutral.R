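#' Activity records for ribozyme variants
#'
#' One row per (sequence, substrate chemistry) measurement: observed rate
#' constant, matched background (uncatalyzed) rate, and the implied rate
#' enhancement. Chemistries are `"AIP"` (2-aminoimidazolide-activated
#' substrate), `"PPP"` (5'-triphosphate) and `"MeIP"` (2-methylimidazolide).
#'
#' @param sequence character vector.
#' @param chemistry character vector in AIP/PPP/MeIP.
#' @param k_obs observed rate constants (per hour, >= 0).
#' @param k_background matched background rates (per hour, > 0).
#' @return data frame of class `activity_records` with a derived
#'   `rate_enhancement` column.
#' @export
activity_records <- function(sequence, chemistry, k_obs, k_background) {
  chemistry <- toupper(chemistry)
  if (!all(chemistry %in% c("AIP", "PPP", "MEIP"))) {
    stop("chemistry must be one of AIP, PPP, MeIP")
  }
  chemistry[chemistry == "MEIP"] <- "MeIP"
  stopifnot(all(k_obs >= 0), all(k_background > 0))
  df <- data.frame(sequence = normalize_rna(sequence), chemistry = chemistry,
                   k_obs = k_obs, k_background = k_background,
                   rate_enhancement = k_obs / k_background,
                   stringsAsFactors = FALSE)
  class(df) <- c("activity_records", "data.frame")
  df
}

#' Read activity records from TSV
#'
#' Expects columns `sequence`, `chemistry`, `k_obs`, `k_background`.
#'
#' @param path file path.
#' @return an [activity_records()] data frame.
#' @export
read_activity_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  activity_records(df$sequence, df$chemistry, df$k_obs, df$k_background)
}

#' Quasi-neutrality criterion
#'
#' A mutational intermediate is quasi-neutral when its rate enhancement in at
#' least one measured chemistry reaches `fraction` of the reference ribozyme's
#' enhancement in that chemistry. With the defaults — reference enhancements
#' of 100-fold (AIP) and 1000-fold (PPP) and fraction 0.10 — the derived
#' thresholds are 10-fold for AIP-ligation and 100-fold for PPP-ligation.
#' The boundary is inclusive (>= threshold).
#'
#' @param reference_enhancement_AIP reference AIP rate enhancement (fold).
#' @param reference_enhancement_PPP reference PPP rate enhancement (fold).
#' @param fraction required fraction of the reference enhancement, in (0, 1].
#' @return object of class `quasi_neutral_criterion` with derived per-chemistry
#'   `thresholds`.
#' @export
quasi_neutral_criterion <- function(reference_enhancement_AIP = 100,
                                    reference_enhancement_PPP = 1000,
                                    fraction = 0.10) {
  stopifnot(fraction > 0, fraction <= 1,
            reference_enhancement_AIP > 0, reference_enhancement_PPP > 0)
  structure(
    list(reference_enhancement_AIP = reference_enhancement_AIP,
         reference_enhancement_PPP = reference_enhancement_PPP,
         fraction = fraction,
         thresholds = c(AIP = fraction * reference_enhancement_AIP,
                        PPP = fraction * reference_enhancement_PPP)),
    class = "quasi_neutral_criterion")
}

#' Classify one sequence's activity as quasi-neutral or not
#'
#' @param records [activity_records()] rows for a single sequence (at least
#'   one of AIP/PPP measured).
#' @param criterion a [quasi_neutral_criterion()].
#' @return list with `quasi_neutral` (logical) and `passing_chemistries`.
#' @export
is_quasi_neutral <- function(records, criterion = quasi_neutral_criterion()) {
  stopifnot(inherits(criterion, "quasi_neutral_criterion"))
  rec <- records[records$chemistry %in% names(criterion$thresholds), ,
                 drop = FALSE]
  if (!nrow(rec)) stop("no AIP or PPP measurement in records")
  pass <- rec$rate_enhancement >= criterion$thresholds[rec$chemistry]
  list(quasi_neutral = any(pass),
       passing_chemistries = unique(rec$chemistry[pass]))
}

#' Annotate a mutational path with activity classifications
#'
#' Labels every path member by which chemistries meet the quasi-neutrality
#' criterion: `"AIP+PPP"`, `"AIP-only"`, `"PPP-only"` or `"fails"`, and
#' reports where PPP-ligase function first emerges along the path.
#'
#' @param path character vector of sequences (consecutive single mutations).
#' @param records [activity_records()] covering the path members.
#' @param criterion a [quasi_neutral_criterion()].
#' @return list with `labels` (one per path member), `ppp_emergence_index`
#'   (first 1-based index with PPP activity, NA if never), `break_indices`
#'   (members failing both chemistries) and `missing` (path members without
#'   records; these are listed, never guessed).
#' @export
annotate_path <- function(path, records, criterion = quasi_neutral_criterion()) {
  path <- normalize_rna(path)
  labels <- character(length(path))
  missing <- character(0)
  for (i in seq_along(path)) {
    rec <- records[records$sequence == path[i], , drop = FALSE]
    if (!nrow(rec)) {
      labels[i] <- NA_character_
      missing <- c(missing, path[i])
      next
    }
    res <- is_quasi_neutral(rec, criterion)
    has <- res$passing_chemistries
    labels[i] <- if (all(c("AIP", "PPP") %in% has)) "AIP+PPP"
      else if ("AIP" %in% has) "AIP-only"
      else if ("PPP" %in% has) "PPP-only"
      else "fails"
  }
  ppp <- which(labels %in% c("AIP+PPP", "PPP-only"))
  list(labels = labels,
       ppp_emergence_index = if (length(ppp)) ppp[1] else NA_integer_,
       break_indices = which(labels == "fails"),
       missing = missing)
}

#' JSON path report
#'
#' Serializes an annotated mutational path (sequences, per-step Hamming
#' checks, labels, PPP emergence index) to JSON.
#'
#' @param path character vector of sequences.
#' @param annotation result of [annotate_path()].
#' @param file optional output path; if NULL the JSON string is returned.
#' @return JSON string (invisibly, if written to file).
#' @export
path_report_json <- function(path, annotation, file = NULL) {
  steps <- if (length(path) > 1) {
    vapply(seq_len(length(path) - 1L),
           function(i) hamming_distance(path[i], path[i + 1L]), integer(1))
  } else integer(0)
  obj <- list(sequences = path, step_hamming = steps,
              labels = annotation$labels,
              ppp_emergence_index = annotation$ppp_emergence_index,
              break_indices = annotation$break_indices,
              missing = annotation$missing)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null", digits = NA)
  if (is.null(file)) return(json)
  writeLines(json, file)
  invisible(json)
}
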