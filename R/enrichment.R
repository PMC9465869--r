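#' Two-sided Fisher exact p-value for a clone-vs-rest 2x2 table
#'
#' Conditional on a clone having `t = count_ref + count_alt` reads across
#' two depth-matched samples of `n_ref` and `n_alt` total reads, the count
#' observed in the alt sample follows a hypergeometric distribution. The
#' two-sided p-value follows the minimum-likelihood convention: the sum of
#' the probabilities of all tables no more probable than the observed one
#' (a relative tolerance of 1e-7 guards the equality comparison, the
#' standard convention for this test).
#'
#' @param x_alt Clone count observed in the alt sample.
#' @param t Clone count summed over both samples.
#' @param n_ref,n_alt Total read counts of the two samples.
#' @return p-value in `(0, 1]`.
#' @export
fisher_p2 <- function(x_alt, t, n_ref, n_alt) {
  if (t == 0) return(1)
  lo <- max(0, t - n_ref)
  hi <- min(t, n_alt)
  xs <- lo:hi
  pr <- stats::dhyper(xs, t, n_ref + n_alt - t, n_alt)
  p_obs <- pr[x_alt - lo + 1L]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
}

#' Differential clone-abundance test between paired repertoires
#'
#' Identifies clonotypes significantly expanded from a reference sample
#' (e.g. unstimulated week-7 PBMCs) to a comparison sample (e.g. the same
#' PBMCs after a 10-day in vitro peptide stimulation). Both repertoires are
#' first downsampled to their common depth (seeded), then every clone
#' present in either sample is tested with a two-sided Fisher exact test on
#' its clone-vs-rest 2x2 table; p-values are Benjamini-Hochberg adjusted
#' over all tested clones. The log2 fold change uses a 0.5 pseudocount on
#' both counts so it is defined for clones absent from one sample.
#'
#' Tiers follow the volcano-plot convention: `nominal` for log2 fold change
#' above 5 with unadjusted p < 0.05, `significant` when additionally the
#' adjusted p < 0.05, else `none`.
#'
#' @param ref,alt Non-empty `tcr_repertoire` objects from the same patient.
#' @param seed Integer seed for the depth-matching downsampling.
#' @param normalize Downsample both repertoires to [common_depth()] before
#'   testing (default TRUE; set FALSE only if already depth-matched).
#' @param lfc_threshold,p_threshold Tier thresholds (defaults 5 and 0.05).
#' @return A data.frame of class `enrichment_result`, one row per tested
#'   clone, ordered by descending `log_fc` with CDR3 tie-break: columns
#'   `cdr3_aa`, `count_ref`, `count_alt`, `log_fc`, `p_value`, `p_adj`,
#'   `tier` (factor none < nominal < significant). The depth used is in
#'   `attr(, "depth")`.
#' @export
expansion_test <- function(ref, alt, seed, normalize = TRUE,
                           lfc_threshold = 5, p_threshold = 0.05) {
  stopifnot(inherits(ref, "tcr_repertoire"),
            inherits(alt, "tcr_repertoire"))
  if (!nrow(ref$clones) || !nrow(alt$clones))
    stop("both repertoires must be non-empty", call. = FALSE)
  if (normalize) {
    n <- common_depth(list(ref, alt))
    ref <- downsample(ref, n, seed)
    alt <- downsample(alt, n, seed + 1L)
  }
  if (ref$depth != alt$depth)
    stop("internal error: repertoires not depth-matched after normalization",
         call. = FALSE)
  n_ref <- ref$depth
  n_alt <- alt$depth

  keys <- sort(union(ref$clones$cdr3_aa, alt$clones$cdr3_aa))
  cr <- clone_counts(ref)[keys]
  ca <- clone_counts(alt)[keys]
  cr[is.na(cr)] <- 0L
  ca[is.na(ca)] <- 0L

  log_fc <- log2((ca + 0.5) / (cr + 0.5))
  tt <- cr + ca
  # p depends only on (x_alt, t); enumerate the hypergeometric support once
  # per distinct clone total
  p <- numeric(length(keys))
  for (t in unique(tt)) {
    idx <- which(tt == t)
    if (t == 0) { p[idx] <- 1; next }
    lo <- max(0, t - n_ref)
    pr <- stats::dhyper(lo:min(t, n_alt), t, n_ref + n_alt - t, n_alt)
    cum <- function(x) min(1, sum(pr[pr <= pr[x - lo + 1L] * (1 + 1e-7)]))
    p[idx] <- vapply(ca[idx], cum, numeric(1))
  }
  p_adj <- stats::p.adjust(p, method = "BH")

  tier <- rep("none", length(keys))
  nominal <- log_fc > lfc_threshold & p < p_threshold
  tier[nominal] <- "nominal"
  tier[nominal & p_adj < p_threshold] <- "significant"

  res <- data.frame(cdr3_aa = keys, count_ref = as.integer(cr),
                    count_alt = as.integer(ca), log_fc = unname(log_fc),
                    p_value = p, p_adj = p_adj,
                    tier = factor(tier,
                                  levels = c("none", "nominal",
                                             "significant"),
                                  ordered = TRUE),
                    stringsAsFactors = FALSE)
  res <- res[order(-res$log_fc, res$cdr3_aa), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  attr(res, "depth") <- n_ref
  res
}

#' Remove clones already present at baseline
#'
#' Clones expanded by in vitro stimulation but already detectable in the
#' patient's pre-treatment unstimulated sample cannot be attributed to
#' vaccination and are filtered out (any baseline count >= 1 removes the
#' clone). Row order is preserved.
#'
#' @param results An `enrichment_result` from [expansion_test()].
#' @param baseline The patient's baseline unstimulated PBMC
#'   `tcr_repertoire`.
#' @return The filtered `enrichment_result`.
#' @export
filter_baseline <- function(results, baseline) {
  stopifnot(inherits(results, "data.frame"),
            inherits(baseline, "tcr_repertoire"))
  keep <- !(results$cdr3_aa %in% baseline$clones$cdr3_aa)
  out <- results[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Vaccine-enriched clonotype keys at a given evidence tier
#'
#' @param results An `enrichment_result`, typically after
#'   [filter_baseline()].
#' @param tier `"nominal"` (log2 FC > 5 and p < 0.05) or `"significant"`
#'   (additionally adjusted p < 0.05). The significant set is always a
#'   subset of the nominal set.
#' @return Character vector of CDR3 keys ordered by descending log fold
#'   change, CDR3 tie-break.
#' @export
vaccine_enriched <- function(results, tier = c("nominal", "significant")) {
  tier <- match.arg(tier)
  sel <- results[as.character(results$tier) %in%
                   (if (tier == "nominal") c("nominal", "significant")
                    else "significant"), , drop = FALSE]
  sel <- sel[order(-sel$log_fc, sel$cdr3_aa), , drop = FALSE]
  sel$cdr3_aa
}
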