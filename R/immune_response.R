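#' Triplicate proliferation assay
#'
#' One 3H-thymidine incorporation assay: PBMCs pre-stimulated in vitro with
#' vaccine peptides, then re-stimulated with or without peptide and counted
#' in at least triplicate wells (counts per minute).
#'
#' @param patient_id Patient identifier.
#' @param timepoint Timepoint label (`"baseline"` marks the pre-treatment
#'   assay).
#' @param peptide One of `"p719-20"`, `"p725"`, `"p728"`, `"mix"`.
#' @param stimulated_counts,unstimulated_counts Numeric vectors of at least
#'   3 non-negative counts per minute.
#' @param positive_control_counts Optional counts for the positive-control
#'   (SEC3) wells; logged but not used for calling.
#' @return A list of class `proliferation_assay`.
#' @export
proliferation_assay <- function(patient_id, timepoint,
                                peptide = c("mix", "p719-20", "p725",
                                            "p728"),
                                stimulated_counts, unstimulated_counts,
                                positive_control_counts = NULL) {
  peptide <- match.arg(peptide)
  if (length(stimulated_counts) < 3L || length(unstimulated_counts) < 3L)
    stop("at least 3 replicates per condition are required", call. = FALSE)
  if (any(stimulated_counts < 0) || any(unstimulated_counts < 0))
    stop("proliferation counts must be non-negative", call. = FALSE)
  structure(list(patient_id = as.character(patient_id),
                 timepoint = as.character(timepoint), peptide = peptide,
                 stimulated_counts = as.numeric(stimulated_counts),
                 unstimulated_counts = as.numeric(unstimulated_counts),
                 positive_control_counts = positive_control_counts),
            class = "proliferation_assay")
}

#' Stimulation index of a proliferation assay
#'
#' SI = mean count in peptide-stimulated wells / mean count in unstimulated
#' wells. SI is dimensionless and invariant to rescaling all counts. A zero
#' unstimulated mean makes the assay invalid (NA) rather than an infinite
#' SI.
#'
#' @param assay A [proliferation_assay()].
#' @return The SI, or `NA` for an invalid assay.
#' @export
stimulation_index <- function(assay) {
  stopifnot(inherits(assay, "proliferation_assay"))
  mu_un <- mean(assay$unstimulated_counts)
  if (mu_un <= 0) {
    warning(sprintf("assay %s/%s/%s has zero unstimulated mean; flagged invalid",
                    assay$patient_id, assay$timepoint, assay$peptide))
    return(NA_real_)
  }
  mean(assay$stimulated_counts) / mu_un
}

#' Per-patient immune-response call
#'
#' A patient is immune-response positive when any peptide (or the peptide
#' mixture) reaches a stimulation index of at least `threshold` (default
#' SI >= 3) in any post-baseline assay within the evaluation window. A
#' patient with no evaluable post-baseline assay is non-evaluable (`NA`),
#' which is distinct from a non-responder.
#'
#' @param assays List of [proliferation_assay()] for one patient.
#' @param threshold Positivity threshold on the SI (inclusive); default 3.
#' @param window Optional character vector of timepoints to evaluate;
#'   `NULL` evaluates every post-baseline assay. Use it to restrict to the
#'   treatment period.
#' @param relative_to_baseline If TRUE, the criterion is instead a
#'   `threshold`-fold rise of the post-baseline SI over the patient's
#'   baseline SI (requires a baseline assay).
#' @return A list of class `immune_response_call`: `patient_id`, `si_table`
#'   (per-assay SI), `per_peptide_si` (max SI per peptide in window),
#'   `max_si`, `responder` (TRUE/FALSE/NA), `evaluable`.
#' @export
call_response <- function(assays, threshold = 3, window = NULL,
                          relative_to_baseline = FALSE) {
  stopifnot(length(assays) >= 1L)
  pid <- unique(vapply(assays, function(a) a$patient_id, character(1)))
  if (length(pid) > 1L)
    stop("assays must come from a single patient", call. = FALSE)
  si_table <- data.frame(
    patient_id = pid,
    timepoint = vapply(assays, function(a) a$timepoint, character(1)),
    peptide = vapply(assays, function(a) a$peptide, character(1)),
    si = vapply(assays, stimulation_index, numeric(1)),
    stringsAsFactors = FALSE)

  is_baseline <- tolower(si_table$timepoint) == "baseline"
  in_window <- !is_baseline & !is.na(si_table$si)
  if (!is.null(window)) in_window <- in_window & si_table$timepoint %in% window

  effective_si <- si_table$si
  if (relative_to_baseline) {
    base_si <- si_table$si[is_baseline & !is.na(si_table$si)]
    if (!length(base_si))
      stop("relative_to_baseline = TRUE requires a baseline assay",
           call. = FALSE)
    effective_si <- si_table$si / mean(base_si)
  }

  if (!any(in_window)) {
    call <- list(patient_id = pid, si_table = si_table,
                 per_peptide_si = numeric(), max_si = NA_real_,
                 responder = NA, evaluable = FALSE)
  } else {
    sel <- si_table[in_window, , drop = FALSE]
    sel$effective <- effective_si[in_window]
    per_pep <- tapply(sel$effective, sel$peptide, max)
    call <- list(patient_id = pid, si_table = si_table,
                 per_peptide_si = per_pep,
                 max_si = max(sel$effective),
                 responder = any(sel$effective >= threshold),
                 evaluable = TRUE)
  }
  structure(call, class = "immune_response_call")
}

#' @export
print.immune_response_call <- function(x, ...) {
  status <- if (!x$evaluable) "non-evaluable"
  else if (x$responder) "responder" else "non-responder"
  cat(sprintf("<immune_response_call> %s: %s (max SI %.1f)\n",
              x$patient_id, status,
              if (is.na(x$max_si)) NA else x$max_si))
  invisible(x)
}

#' Cohort immune-response summary
#'
#' @param calls List of [call_response()] results, one per patient.
#' @return A list: `n_evaluable`, `n_responders`, `responder_fraction`,
#'   `responder_pct` (rounded to the nearest integer percent; non-evaluable
#'   patients are excluded from the denominator), `median_max_si`,
#'   `range_max_si`.
#' @export
cohort_summary <- function(calls) {
  ev <- Filter(function(x) isTRUE(x$evaluable), calls)
  if (!length(ev)) stop("no evaluable patients", call. = FALSE)
  resp <- vapply(ev, function(x) isTRUE(x$responder), logical(1))
  max_si <- vapply(ev, function(x) x$max_si, numeric(1))
  frac <- sum(resp) / length(ev)
  list(n_evaluable = length(ev), n_responders = sum(resp),
       responder_fraction = frac,
       responder_pct = round(100 * frac),
       median_max_si = stats::median(max_si),
       range_max_si = range(max_si))
}

#' Objective response rate
#'
#' Fraction of enrolled patients with a complete or partial best overall
#' response, as an integer percentage.
#'
#' @param best_response Character vector of per-patient best overall
#'   responses (`"CR"`, `"PR"`, `"SD"`, `"PD"`, `"NE"`), one per enrolled
#'   patient.
#' @return A list: `n_enrolled`, `n_responses`, `orr_pct`.
#' @export
objective_response_rate <- function(best_response) {
  if (!length(best_response)) stop("no patients", call. = FALSE)
  n_resp <- sum(toupper(best_response) %in% c("CR", "PR"))
  list(n_enrolled = length(best_response), n_responses = n_resp,
       orr_pct = round(100 * n_resp / length(best_response)))
}

#' Read proliferation assays from a long-format CSV
#'
#' Expected columns: `patient_id`, `timepoint`, `peptide`, `condition`
#' (`stimulated` / `unstimulated` / `control`), `count`; one row per well.
#'
#' @param path CSV path.
#' @return A list of [proliferation_assay()] grouped by (patient,
#'   timepoint, peptide).
#' @export
read_assays <- function(path) {
  if (!file.exists(path))
    stop(sprintf("assay file not found: %s", path), call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "timepoint", "peptide", "condition", "count")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop(sprintf("assay file missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  key <- paste(tab$patient_id, tab$timepoint, tab$peptide, sep = "\r")
  lapply(split(tab, factor(key, levels = unique(key))), function(g) {
    ctrl <- g$count[g$condition == "control"]
    proliferation_assay(
      g$patient_id[1], g$timepoint[1], g$peptide[1],
      stimulated_counts = g$count[g$condition == "stimulated"],
      unstimulated_counts = g$count[g$condition == "unstimulated"],
      positive_control_counts = if (length(ctrl)) ctrl else NULL)
  })
}
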