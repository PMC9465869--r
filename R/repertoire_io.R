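#' Sample metadata for one sequenced repertoire
#'
#' @param patient_id Patient identifier, e.g. `"N02"`.
#' @param timepoint Timepoint label, e.g. `"baseline"`, `"week7"`, `"week18"`.
#' @param compartment Either `"PBMC"` or `"tumor"`.
#' @param stimulation Either `"unstimulated"` or `"stimulated"` (10-day in
#'   vitro peptide stimulation status of the sequenced cells).
#'
#' @return A list of class `sample_meta`.
#' @export
sample_meta <- function(patient_id = NA_character_, timepoint = NA_character_,
                        compartment = c("PBMC", "tumor"),
                        stimulation = c("unstimulated", "stimulated")) {
  compartment <- match.arg(compartment)
  stimulation <- match.arg(stimulation)
  structure(list(patient_id = as.character(patient_id),
                 timepoint = as.character(timepoint),
                 compartment = compartment,
                 stimulation = stimulation),
            class = "sample_meta")
}

#' Construct a clone-level TCR repertoire
#'
#' Collapses receptor rows sharing a CDR3 amino-acid sequence into clones:
#' clone identity is the CDR3 amino-acid sequence only, V/J gene calls are
#' carried as annotation and blanked when merged rows disagree. Rows with an
#' empty or invalid CDR3 (letters outside the 20 amino acids plus `*`) or a
#' non-positive count are dropped and tallied in `attr(, "skipped")`.
#'
#' @param clones A data.frame with columns `cdr3_aa`, `count` and optionally
#'   `v_gene`, `j_gene`.
#' @param meta A [sample_meta()] object (optional).
#' @param extraction_fraction Fraction of raw reads with a successfully
#'   extracted receptor, in `[0, 1]`; `NA` if unknown.
#'
#' @return An object of class `tcr_repertoire`: a list with elements `meta`,
#'   `clones` (one row per clonotype, descending count, CDR3 tie-break),
#'   `depth` (total reads) and `extraction_fraction`.
#' @export
repertoire <- function(clones, meta = sample_meta(),
                       extraction_fraction = NA_real_) {
  stopifnot(is.data.frame(clones))
  if (!all(c("cdr3_aa", "count") %in% names(clones)))
    stop("`clones` needs columns cdr3_aa and count", call. = FALSE)
  cdr3 <- as.character(clones$cdr3_aa)
  count <- suppressWarnings(as.numeric(clones$count))
  v <- if ("v_gene" %in% names(clones)) as.character(clones$v_gene) else
    rep("", nrow(clones))
  j <- if ("j_gene" %in% names(clones)) as.character(clones$j_gene) else
    rep("", nrow(clones))
  v[is.na(v)] <- ""
  j[is.na(j)] <- ""

  empty_cdr3 <- is.na(cdr3) | !nzchar(cdr3)
  bad_letters <- !empty_cdr3 & !is_valid_cdr3(cdr3)
  bad_cdr3 <- empty_cdr3 | bad_letters
  bad_count <- is.na(count) | count <= 0
  keep <- !bad_cdr3 & !bad_count
  skipped <- c(empty_cdr3 = sum(empty_cdr3),
               invalid_cdr3 = sum(bad_letters),
               nonpositive_count = sum(bad_count & !bad_cdr3))
  if (any(bad_letters))
    warning(sprintf(paste("%d row(s) with non-standard amino-acid letters",
                          "skipped (ambiguous clones cannot be matched",
                          "across samples)"), sum(bad_letters)),
            call. = FALSE)

  cdr3 <- cdr3[keep]; count <- count[keep]; v <- v[keep]; j <- j[keep]
  if (any(count != round(count)))
    stop("clone counts must be integers (read counts)", call. = FALSE)

  if (length(cdr3)) {
    key <- factor(cdr3, levels = unique(cdr3))
    agg_count <- as.vector(tapply(count, key, sum))
    uniq_or_blank <- function(x) {
      u <- unique(x[nzchar(x)])
      if (length(u) == 1L) u else ""
    }
    agg_v <- as.vector(tapply(v, key, uniq_or_blank))
    agg_j <- as.vector(tapply(j, key, uniq_or_blank))
    df <- data.frame(cdr3_aa = levels(key), v_gene = agg_v, j_gene = agg_j,
                     count = as.integer(round(agg_count)),
                     stringsAsFactors = FALSE)
    df <- df[order(-df$count, df$cdr3_aa), , drop = FALSE]
    rownames(df) <- NULL
  } else {
    df <- data.frame(cdr3_aa = character(), v_gene = character(),
                     j_gene = character(), count = integer(),
                     stringsAsFactors = FALSE)
  }

  if (!is.na(extraction_fraction) &&
      (extraction_fraction < 0 || extraction_fraction > 1))
    stop("extraction_fraction must be in [0, 1]", call. = FALSE)

  structure(list(meta = meta, clones = df, depth = sum(df$count),
                 extraction_fraction = extraction_fraction),
            class = "tcr_repertoire",
            skipped = skipped)
}

#' @export
print.tcr_repertoire <- function(x, ...) {
  m <- x$meta
  cat(sprintf("<tcr_repertoire> %s %s %s %s\n",
              m$patient_id %||% NA, m$timepoint %||% NA,
              m$compartment %||% NA, m$stimulation %||% NA))
  cat(sprintf("  %d clonotypes, depth %d reads\n", nrow(x$clones), x$depth))
  if (!is.na(x$extraction_fraction))
    cat(sprintf("  receptor extraction fraction %.3f\n",
                x$extraction_fraction))
  invisible(x)
}

# named count vector keyed by CDR3 (internal convenience)
clone_counts <- function(rep) {
  stats::setNames(rep$clones$count, rep$clones$cdr3_aa)
}

# Default AIRR Rearrangement column names; override for other dialects.
airr_columns <- function(cdr3 = "junction_aa", count = "duplicate_count",
                         v = "v_call", j = "j_call") {
  list(cdr3 = cdr3, count = count, v = v, j = j)
}

#' Read an AIRR-style rearrangement TSV into a clone-level repertoire
#'
#' Reads a tab-separated rearrangement table (one row per receptor
#' read/clone), collapses rows by CDR3 amino-acid sequence and returns a
#' [repertoire()]. Rows with a missing/empty/invalid CDR3 or a count of zero
#' or less are skipped; the tally is in `attr(, "skipped")`.
#'
#' @param path Path to the TSV file.
#' @param meta A [sample_meta()] for the sample.
#' @param columns Column mapping, see [airr_columns()]. The CDR3 and count
#'   columns are required; V/J columns are optional annotation.
#' @param extraction_fraction Optional QC fraction of raw reads with an
#'   extracted receptor, stored on the repertoire.
#' @param productive_only Drop non-productive clones (CDR3 containing a
#'   stop codon `*`)? Default FALSE: non-productive receptors are retained,
#'   since they carry clone-tracking information even without surface
#'   expression.
#'
#' @return A `tcr_repertoire`.
#' @export
read_repertoire <- function(path, meta = sample_meta(),
                            columns = airr_columns(),
                            extraction_fraction = NA_real_,
                            productive_only = FALSE) {
  if (!file.exists(path))
    stop(sprintf("repertoire file not found: %s", path), call. = FALSE)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
  for (col in c(columns$cdr3, columns$count))
    if (!col %in% names(tab))
      stop(sprintf("required column '%s' missing from %s", col, path),
           call. = FALSE)
  df <- data.frame(
    cdr3_aa = tab[[columns$cdr3]],
    v_gene = if (columns$v %in% names(tab)) tab[[columns$v]] else "",
    j_gene = if (columns$j %in% names(tab)) tab[[columns$j]] else "",
    count = suppressWarnings(as.numeric(tab[[columns$count]])),
    stringsAsFactors = FALSE)
  if (productive_only)
    df <- df[!grepl("*", df$cdr3_aa, fixed = TRUE), , drop = FALSE]
  repertoire(df, meta = meta, extraction_fraction = extraction_fraction)
}

#' Write a repertoire as an AIRR-style TSV
#'
#' One row per clonotype, ordered by descending count with lexicographic
#' CDR3 tie-break, columns `junction_aa`, `v_call`, `j_call`,
#' `duplicate_count`. Reading the file back with [read_repertoire()]
#' reproduces the clone map exactly.
#'
#' @param rep A `tcr_repertoire`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_repertoire <- function(rep, path) {
  stopifnot(inherits(rep, "tcr_repertoire"))
  df <- rep$clones[order(-rep$clones$count, rep$clones$cdr3_aa), ,
                   drop = FALSE]
  out <- data.frame(junction_aa = df$cdr3_aa, v_call = df$v_gene,
                    j_call = df$j_gene, duplicate_count = df$count,
                    stringsAsFactors = FALSE)
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop(sprintf("cannot write repertoire to %s: %s", path,
                 conditionMessage(ok)), call. = FALSE)
  invisible(path)
}

#' Read-extraction QC flag
#'
#' Flags a sample whose fraction of raw reads with a successfully extracted
#' receptor falls at or below the threshold. A `warn` flag never excludes
#' the sample from analysis; low-extraction samples are retained.
#'
#' @param extraction_fraction Fraction in `[0, 1]`.
#' @param threshold Pass threshold (strict inequality); default 0.95.
#' @return `"pass"` or `"warn"`.
#' @export
qc_extraction <- function(extraction_fraction, threshold = 0.95) {
  if (is.na(extraction_fraction) || extraction_fraction < 0 ||
      extraction_fraction > 1)
    stop("extraction_fraction must be in [0, 1]", call. = FALSE)
  if (extraction_fraction > threshold) "pass" else "warn"
}

#' Read a sample manifest
#'
#' A manifest is a CSV with columns `patient_id`, `timepoint`,
#' `compartment`, `stimulation`, `path` — one row per sequenced sample. The
#' (patient, timepoint, compartment, stimulation) combination must be
#' unique.
#'
#' @param path Manifest CSV path.
#' @return A data.frame of the manifest rows.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path))
    stop(sprintf("manifest not found: %s", path), call. = FALSE)
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "timepoint", "compartment", "stimulation", "path")
  miss <- setdiff(need, names(man))
  if (length(miss))
    stop(sprintf("manifest is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  key <- do.call(paste, c(man[need[1:4]], sep = "\r"))
  if (anyDuplicated(key))
    stop("duplicate (patient, timepoint, compartment, stimulation) in manifest",
         call. = FALSE)
  man
}

#' Load every repertoire listed in a manifest
#'
#' @param manifest A data.frame from [read_manifest()].
#' @param dir Directory against which relative `path` entries are resolved.
#' @param columns Column mapping passed to [read_repertoire()].
#' @return A list of `tcr_repertoire`, one per manifest row.
#' @export
load_manifest <- function(manifest, dir = ".", columns = airr_columns()) {
  lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    p <- row$path
    if (!file.exists(p)) p <- file.path(dir, row$path)
    read_repertoire(p,
                    meta = sample_meta(row$patient_id, row$timepoint,
                                       row$compartment, row$stimulation),
                    columns = columns)
  })
}
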