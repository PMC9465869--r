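# Depth-match a list of repertoires to their minimum depth (seeded); a
# single repertoire is returned untouched.
depth_match <- function(reps, seed) {
  if (length(reps) < 2L) return(reps)
  n <- common_depth(reps)
  lapply(seq_along(reps),
         function(i) downsample(reps[[i]], n, seed + i - 1L))
}

#' Track clonotypes across a patient's samples
#'
#' Follows a set of clonotypes (typically the vaccine-enriched keys from
#' [vaccine_enriched()]) across every available sample of one patient.
#' Samples are depth-matched within each compartment by seeded downsampling
#' before repertoire fractions are computed. Clones are ranked by the order
#' of `clone_keys` (pass keys ranked by log fold change to reproduce the
#' rank labelling of enrichment volcano plots).
#'
#' @param clone_keys Character vector of CDR3 keys, in rank order.
#' @param samples List of `tcr_repertoire` from a single patient.
#' @param seed Integer seed for depth matching.
#' @return A data.frame of class `tracked_clones`, long format, one row per
#'   clone x sample: `cdr3_aa`, `rank`, `patient_id`, `timepoint`,
#'   `compartment`, `stimulation`, `count`, `fraction`, plus a logical
#'   `detected_in_tumor` (constant per clone: count >= 1 in any tumor
#'   sample). Rows are ordered by rank, then compartment, then timepoint;
#'   the output is invariant to the order in which samples are supplied.
#' @export
track_clones <- function(clone_keys, samples, seed) {
  stopifnot(length(samples) >= 1L)
  pats <- unique(vapply(samples, function(s) s$meta$patient_id,
                        character(1)))
  if (length(pats) > 1L)
    stop("samples must come from a single patient", call. = FALSE)

  # canonical sample order: compartment, stimulation, then timepoint
  meta <- data.frame(
    patient_id = vapply(samples, function(s) s$meta$patient_id, character(1)),
    timepoint = vapply(samples, function(s) s$meta$timepoint, character(1)),
    compartment = vapply(samples, function(s) s$meta$compartment,
                         character(1)),
    stimulation = vapply(samples, function(s) s$meta$stimulation,
                         character(1)),
    stringsAsFactors = FALSE)
  ord <- order(meta$compartment, meta$stimulation,
               timepoint_key(meta$timepoint), meta$timepoint)
  samples <- samples[ord]
  meta <- meta[ord, , drop = FALSE]

  for (comp in unique(meta$compartment)) {
    idx <- which(meta$compartment == comp)
    samples[idx] <- depth_match(samples[idx], seed)
  }

  rows <- lapply(seq_along(samples), function(i) {
    cc <- clone_counts(samples[[i]])
    cnt <- unname(cc[clone_keys])
    cnt[is.na(cnt)] <- 0L
    data.frame(cdr3_aa = clone_keys, rank = seq_along(clone_keys),
               meta[rep(i, length(clone_keys)), , drop = FALSE],
               count = as.integer(cnt),
               fraction = cnt / samples[[i]]$depth,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  in_tumor <- tapply(out$count >= 1 & out$compartment == "tumor",
                     out$cdr3_aa, any)
  out$detected_in_tumor <- as.vector(in_tumor[out$cdr3_aa])
  out <- out[order(out$rank, out$compartment, out$stimulation,
                   timepoint_key(out$timepoint), out$timepoint), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("tracked_clones", "data.frame")
  out
}

#' Relative abundance of persisting intratumoral clonotypes
#'
#' Depth-matches a patient's baseline and post-treatment tumor repertoires,
#' restricts to the clonotypes shared between them, and compares their
#' normalized read counts with a paired two-sided Wilcoxon signed-rank test
#' (exact null for up to 25 shared clones). With fewer than two shared
#' clones the test is skipped; when every paired difference is zero the
#' test is degenerate and p is reported as 1.
#'
#' @param baseline_tumor,post_tumor Tumor `tcr_repertoire` objects from one
#'   patient.
#' @param seed Integer seed for depth matching.
#' @return A list: `table` (data.frame `cdr3_aa`, `count_baseline`,
#'   `count_post`), `statistic`, `p_value`, `test_skipped`, `degenerate`,
#'   `depth`.
#' @export
persisting_abundance <- function(baseline_tumor, post_tumor, seed) {
  reps <- depth_match(list(baseline_tumor, post_tumor), seed)
  ov <- tryCatch(overlap(reps[[1]], reps[[2]]),
                 error = function(e) list(shared = character()))
  shared <- ov$shared
  tab <- data.frame(
    cdr3_aa = shared,
    count_baseline = as.integer(unname(clone_counts(reps[[1]])[shared])),
    count_post = as.integer(unname(clone_counts(reps[[2]])[shared])),
    stringsAsFactors = FALSE)
  if (length(shared) < 2L)
    return(list(table = tab, statistic = NA_real_, p_value = NA_real_,
                test_skipped = TRUE, degenerate = FALSE,
                depth = reps[[1]]$depth))
  d <- tab$count_post - tab$count_baseline
  if (all(d == 0))
    return(list(table = tab, statistic = 0, p_value = 1,
                test_skipped = FALSE, degenerate = TRUE,
                depth = reps[[1]]$depth))
  wt <- suppressWarnings(
    stats::wilcox.test(tab$count_post, tab$count_baseline, paired = TRUE,
                       exact = length(shared) <= 25,
                       alternative = "two.sided"))
  list(table = tab, statistic = unname(wt$statistic),
       p_value = wt$p.value, test_skipped = FALSE, degenerate = FALSE,
       depth = reps[[1]]$depth)
}

#' Blood detection of clonotypes unique to the post-treatment biopsy
#'
#' Defines the key set as clonotypes present in the post-treatment tumor
#' but absent from the baseline tumor, then reports, for each PBMC sample
#' in a depth-matched longitudinal series, how many of these clonotypes are
#' detected (count >= 1) and their summed repertoire fraction.
#'
#' @param baseline_tumor,post_tumor Tumor `tcr_repertoire` objects from one
#'   patient; `post_tumor` must be non-empty.
#' @param pbmc_series List of unstimulated PBMC `tcr_repertoire` across
#'   timepoints.
#' @param seed Integer seed for depth matching of the PBMC series.
#' @return A data.frame, one row per PBMC sample ordered by timepoint:
#'   `timepoint`, `n_detected`, `fraction`, `depth`; the key set is in
#'   `attr(, "clone_keys")`.
#' @export
post_unique_in_blood <- function(baseline_tumor, post_tumor, pbmc_series,
                                 seed) {
  stopifnot(inherits(post_tumor, "tcr_repertoire"))
  if (!nrow(post_tumor$clones))
    stop("post-treatment tumor repertoire is empty", call. = FALSE)
  keys <- setdiff(post_tumor$clones$cdr3_aa,
                  baseline_tumor$clones$cdr3_aa)
  pbmc_series <- depth_match(pbmc_series, seed)
  tps <- vapply(pbmc_series, function(r) r$meta$timepoint, character(1))
  ord <- order(timepoint_key(tps), tps)
  pbmc_series <- pbmc_series[ord]
  out <- do.call(rbind, lapply(pbmc_series, function(r) {
    cc <- clone_counts(r)
    present <- intersect(keys, names(cc))
    data.frame(timepoint = r$meta$timepoint,
               n_detected = length(present),
               fraction = if (r$depth > 0) sum(cc[present]) / r$depth else 0,
               depth = r$depth, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "clone_keys") <- keys
  out
}
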