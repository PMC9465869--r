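# internal helpers shared across modules

# Standard amino-acid alphabet plus '*' (stop codon, kept for
# non-productive junctions). Ambiguity codes (B, J, O, U, X, Z) are not
# accepted: an ambiguous CDR3 cannot be matched across samples.
AA_VALID <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
              "P", "Q", "R", "S", "T", "V", "W", "Y", "*")

is_valid_cdr3 <- function(x) {
  !is.na(x) & nzchar(x) &
    vapply(strsplit(x, "", fixed = TRUE),
           function(ch) all(ch %in% AA_VALID), logical(1))
}

# Evaluate `code` under a fixed RNG stream without disturbing the caller's
# RNG state. All seeded operations in the package route through this.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# Sortable key for timepoint labels: "baseline" first, then "week<N>" /
# "day<N>" by the embedded number (in days), then anything else last.
# Callers sort with order(timepoint_key(tp), tp) so residual ties fall back
# to the alphabet.
timepoint_key <- function(tp) {
  tp <- as.character(tp)
  key <- rep(Inf, length(tp))
  key[tolower(tp) %in% c("baseline", "pre", "screening")] <- -1
  wk <- grepl("^week[0-9]+(-[0-9]+)?$", tolower(tp))
  key[wk] <- 7 * as.numeric(sub("^week([0-9]+).*$", "\\1", tolower(tp[wk])))
  dy <- grepl("^day[0-9]+$", tolower(tp))
  key[dy] <- as.numeric(sub("^day", "", tolower(tp[dy])))
  key
}

`%||%` <- function(a, b) if (is.null(a)) b else a
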