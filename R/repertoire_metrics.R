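#' Downsample a repertoire to a fixed depth
#'
#' Count normalization across samples is performed by downsampling: reads
#' are drawn without replacement from the multiset of the sample's reads
#' (multivariate hypergeometric), so no clone's count can increase and the
#' result keeps integer counts. Clones reduced to zero reads are removed.
#' The draw is deterministic given `seed`.
#'
#' @param rep A `tcr_repertoire`.
#' @param target_depth Number of reads to keep, `1 <= target_depth <=
#'   rep$depth`. Use [common_depth()] to pick the depth for a compared set.
#' @param seed Integer seed.
#' @return A `tcr_repertoire` with depth exactly `target_depth`.
#' @export
downsample <- function(rep, target_depth, seed) {
  stopifnot(inherits(rep, "tcr_repertoire"))
  if (target_depth < 1 || target_depth != round(target_depth))
    stop("target_depth must be a positive integer", call. = FALSE)
  if (target_depth > rep$depth)
    stop(sprintf("target_depth (%d) exceeds repertoire depth (%d)",
                 target_depth, rep$depth), call. = FALSE)
  if (target_depth == rep$depth) return(rep)
  counts <- rep$clones$count
  new_counts <- with_seed(seed, rmvhyper(counts, target_depth))
  keep <- new_counts > 0L
  df <- rep$clones[keep, , drop = FALSE]
  df$count <- new_counts[keep]
  df <- df[order(-df$count, df$cdr3_aa), , drop = FALSE]
  rownames(df) <- NULL
  out <- rep
  out$clones <- df
  out$depth <- sum(df$count)
  out
}

# One multivariate hypergeometric draw by sequential conditioning: clone i
# receives rhyper(count_i, remaining_other, remaining_draws).
rmvhyper <- function(counts, k) {
  remaining <- sum(counts)
  out <- integer(length(counts))
  for (i in seq_along(counts)) {
    if (k == 0L) break
    ni <- counts[i]
    remaining <- remaining - ni
    if (remaining == 0L) {  # everything left must be taken
      out[i] <- k
      k <- 0L
      break
    }
    x <- stats::rhyper(1L, ni, remaining, k)
    out[i] <- x
    k <- k - x
  }
  out
}

#' Common comparison depth for a set of repertoires
#'
#' Cross-sample analyses downsample every repertoire in the compared set to
#' the minimum depth of the set.
#'
#' @param reps A list of `tcr_repertoire`.
#' @return The minimum depth (integer).
#' @export
common_depth <- function(reps) {
  if (!length(reps)) stop("empty repertoire set", call. = FALSE)
  min(vapply(reps, function(r) r$depth, numeric(1)))
}

#' Shannon entropy of clone frequencies
#'
#' @param rep A non-empty `tcr_repertoire`.
#' @return Entropy in nats.
#' @export
shannon_entropy <- function(rep) {
  stopifnot(inherits(rep, "tcr_repertoire"))
  if (rep$depth == 0) stop("empty repertoire", call. = FALSE)
  p <- rep$clones$count / rep$depth
  -sum(p * log(p))
}

#' Repertoire clonality
#'
#' Clonality is one minus the Shannon entropy of clone frequencies
#' normalized by its maximum, `1 - H / ln(R)` with `R` the number of unique
#' clonotypes: 0 for a perfectly even repertoire, 1 for a monoclonal one
#' (the single-clone case is 1 by convention).
#'
#' @param rep A non-empty `tcr_repertoire`.
#' @return Clonality in `[0, 1]`.
#' @export
clonality <- function(rep) {
  stopifnot(inherits(rep, "tcr_repertoire"))
  r <- nrow(rep$clones)
  if (r == 0) stop("empty repertoire", call. = FALSE)
  if (r == 1) return(1)
  1 - shannon_entropy(rep) / log(r)
}

#' Diversity report for a depth-normalized repertoire
#'
#' Reports observed richness (the primary diversity readout on
#' depth-matched repertoires), Shannon entropy, clonality and the depth at
#' which they were computed. Compare samples only after downsampling them
#' to a [common_depth()].
#'
#' @param rep A non-empty `tcr_repertoire`.
#' @return A one-row data.frame with columns `richness`, `shannon_entropy`,
#'   `clonality`, `depth_used`.
#' @export
diversity <- function(rep) {
  stopifnot(inherits(rep, "tcr_repertoire"))
  if (rep$depth == 0) stop("empty repertoire", call. = FALSE)
  data.frame(richness = nrow(rep$clones),
             shannon_entropy = shannon_entropy(rep),
             clonality = clonality(rep),
             depth_used = rep$depth)
}

#' Clonotype overlap between two repertoires
#'
#' Partitions the union of CDR3 keys into shared, unique-to-a and
#' unique-to-b.
#'
#' @param rep_a,rep_b Non-empty `tcr_repertoire` objects.
#' @return A list with character vectors `shared`, `unique_a`, `unique_b`
#'   and integer counts `n_shared`, `n_unique_a`, `n_unique_b`.
#' @export
overlap <- function(rep_a, rep_b) {
  stopifnot(inherits(rep_a, "tcr_repertoire"),
            inherits(rep_b, "tcr_repertoire"))
  if (!nrow(rep_a$clones) || !nrow(rep_b$clones))
    stop("both repertoires must be non-empty", call. = FALSE)
  a <- rep_a$clones$cdr3_aa
  b <- rep_b$clones$cdr3_aa
  shared <- sort(intersect(a, b))
  ua <- sort(setdiff(a, b))
  ub <- sort(setdiff(b, a))
  list(shared = shared, unique_a = ua, unique_b = ub,
       n_shared = length(shared), n_unique_a = length(ua),
       n_unique_b = length(ub))
}

#' Repertoire fraction of a clone set
#'
#' The repertoire fraction of a set of clonotypes is the sum of their read
#' counts divided by the sample's total read count; clones absent from the
#' sample contribute zero. When comparing across samples, normalize depths
#' first with [downsample()].
#'
#' @param clone_keys Character vector of CDR3 amino-acid keys.
#' @param rep A non-empty `tcr_repertoire`.
#' @return A fraction in `[0, 1]`.
#' @export
repertoire_fraction <- function(clone_keys, rep) {
  stopifnot(inherits(rep, "tcr_repertoire"))
  if (rep$depth == 0) stop("empty repertoire", call. = FALSE)
  cc <- clone_counts(rep)
  sum(cc[intersect(unique(clone_keys), names(cc))]) / rep$depth
}
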