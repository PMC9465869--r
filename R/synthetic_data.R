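#' Configuration for the synthetic repertoire generator
#'
#' The generator emulates the statistical structure the downstream analysis
#' assumes: Zipf (power-law) clone-size distributions, partial clone
#' persistence between consecutive timepoints, blood-tumor clonotype
#' sharing, 10-day in vitro stimulation spike-ins with a known fold change,
#' and triplicate proliferation counts around a known true stimulation
#' index.
#'
#' @param n_clones Clones in each blood repertoire (default 5000).
#' @param zipf_exponent Power-law exponent: clone frequencies are
#'   proportional to `rank^(-zipf_exponent)` (default 1).
#' @param depth Reads per sample (default 50000).
#' @param persistence Fraction of clones shared between consecutive
#'   timepoints within a compartment (default 0.3: most clonotypes turn
#'   over between serial samples).
#' @param tumor_share Fraction of blood clones also seeded into the tumor
#'   (default 0.1).
#' @param n_spike Number of vaccine-reactive spike-in clones (default 10).
#' @param spike_fold Multiplicative expansion of spiked clone frequencies
#'   under in vitro stimulation, before renormalization (default 64, i.e.
#'   log2 fold 6).
#' @param spike_freq_range Pre-stimulation frequency range of the spiked
#'   clones; `n_spike` frequencies are log-spaced across it (default
#'   `c(1e-3, 5e-5)`, spanning clones well above and near the detection
#'   limit at the default depth).
#' @param si_true True stimulation index for the simulated proliferation
#'   assays (default 11.5).
#' @param noise_cv Coefficient of variation of replicate proliferation
#'   counts (default 0.1).
#' @param leak_to_baseline If TRUE, spiked clones are also planted in the
#'   baseline sample (to exercise the baseline filter); default FALSE.
#' @param n_tumor_clones Clones per tumor repertoire (default
#'   `n_clones / 5`, biopsies being shallower than blood).
#' @param seed Master seed; the same seed reproduces every output exactly.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_clones = 5000, zipf_exponent = 1, depth = 50000,
                       persistence = 0.3, tumor_share = 0.1, n_spike = 10,
                       spike_fold = 64, spike_freq_range = c(1e-3, 5e-5),
                       si_true = 11.5, noise_cv = 0.1,
                       leak_to_baseline = FALSE,
                       n_tumor_clones = round(n_clones / 5), seed = 1L) {
  cfg <- list(n_clones = n_clones, zipf_exponent = zipf_exponent,
              depth = depth, persistence = persistence,
              tumor_share = tumor_share, n_spike = n_spike,
              spike_fold = spike_fold, spike_freq_range = spike_freq_range,
              si_true = si_true, noise_cv = noise_cv,
              leak_to_baseline = leak_to_baseline,
              n_tumor_clones = n_tumor_clones, seed = seed)
  with(cfg, {
    if (n_clones < 1 || depth < 1 || n_tumor_clones < 1)
      stop("n_clones, depth and n_tumor_clones must be positive",
           call. = FALSE)
    if (zipf_exponent <= 0) stop("zipf_exponent must be > 0", call. = FALSE)
    if (persistence < 0 || persistence > 1 || tumor_share < 0 ||
        tumor_share > 1)
      stop("persistence and tumor_share must be fractions in [0, 1]",
           call. = FALSE)
    if (spike_fold < 1) stop("spike_fold must be >= 1", call. = FALSE)
    if (n_spike < 0) stop("n_spike must be >= 0", call. = FALSE)
    if (si_true <= 0) stop("si_true must be > 0", call. = FALSE)
    if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  })
  structure(cfg, class = "sim_config")
}

# n unique plausible CDR3 keys: "CASS" + 4-10 random residues + "F"
make_cdr3 <- function(n, existing = character()) {
  aa <- setdiff(AA_VALID, "*")
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    mid <- vapply(sample(4:10, need, replace = TRUE), function(k)
      paste(sample(aa, k, replace = TRUE), collapse = ""), character(1))
    cand <- paste0("CASS", mid, "F")
    out <- unique(c(out, setdiff(cand, existing)))
  }
  out[seq_len(n)]
}

zipf_freq <- function(n, s) {
  f <- seq_len(n)^(-s)
  f / sum(f)
}

# multinomial counts -> tcr_repertoire (zero-count clones dropped)
freq_to_repertoire <- function(freq, depth, meta) {
  counts <- as.vector(stats::rmultinom(1, depth, freq))
  keep <- counts > 0
  repertoire(data.frame(cdr3_aa = names(freq)[keep], count = counts[keep],
                        stringsAsFactors = FALSE), meta = meta)
}

#' Simulate one patient's longitudinal multi-compartment repertoires
#'
#' Generates, from a single master seed, the sample set the analysis
#' pipeline expects for one patient: baseline PBMC, week-7 PBMC before and
#' after in vitro peptide stimulation, a later (week-18) PBMC sample, and
#' baseline / post-treatment tumor biopsies. Blood clone frequencies follow
#' a Zipf law; a `persistence` fraction of clones carries over between
#' consecutive timepoints (the rest are replaced by fresh clonotypes);
#' a `tumor_share` fraction of contemporaneous blood clones is seeded into
#' each tumor repertoire. The `n_spike` vaccine-reactive clones are absent
#' from baseline (unless `leak_to_baseline`), present in the week-7 sample
#' at known frequencies, multiplied by `spike_fold` (then renormalized) in
#' the stimulated aliquot, and carried into the later PBMC sample and into
#' the post-treatment tumor's shared-clone draw. Counts are multinomial at
#' the configured depth.
#'
#' @param config A [sim_config()].
#' @param patient_id Identifier for the simulated patient.
#' @return A list: `samples` (named list of `tcr_repertoire`:
#'   `baseline_pbmc`, `week7_pbmc_unstim`, `week7_pbmc_stim`,
#'   `week18_pbmc`, `baseline_tumor`, `post_tumor`), `truth` (data.frame of
#'   spiked clones: `cdr3_aa`, `base_freq`, `stim_freq`, `true_fold`,
#'   `realized_fold`, `in_baseline`) and `frequencies` (the exact sampling
#'   distributions, each summing to 1).
#' @export
simulate_patient <- function(config, patient_id = "SIM01") {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_clones
    base_freq <- zipf_freq(n, config$zipf_exponent)

    blood_keys <- make_cdr3(n)
    spike_keys <- if (config$n_spike > 0)
      make_cdr3(config$n_spike, existing = blood_keys) else character(0)

    # frequencies stay attached to rank slots; turnover swaps in fresh keys
    turnover <- function(keys, existing) {
      stay <- sample(length(keys),
                     round(config$persistence * length(keys)))
      fresh <- make_cdr3(length(keys) - length(stay),
                         existing = c(existing, keys))
      out <- keys
      out[setdiff(seq_along(keys), stay)] <- fresh
      out
    }

    spike_freq <- if (config$n_spike > 0)
      exp(seq(log(config$spike_freq_range[1]),
              log(config$spike_freq_range[2]),
              length.out = config$n_spike)) else numeric(0)
    s_mass <- sum(spike_freq)

    # baseline PBMC: no spikes unless deliberately leaked
    if (config$leak_to_baseline && config$n_spike > 0) {
      f_base <- stats::setNames(c(base_freq * (1 - s_mass), spike_freq),
                                c(blood_keys, spike_keys))
    } else {
      f_base <- stats::setNames(base_freq, blood_keys)
    }

    # week 7: partial turnover of the background, spikes appear
    week7_keys <- turnover(blood_keys, spike_keys)
    f_w7_un <- stats::setNames(c(base_freq * (1 - s_mass), spike_freq),
                               c(week7_keys, spike_keys))
    stim_raw <- c(base_freq * (1 - s_mass),
                  spike_freq * config$spike_fold)
    f_w7_st <- stats::setNames(stim_raw / sum(stim_raw),
                               c(week7_keys, spike_keys))

    # week 18: background turns over again, spikes persist
    week18_keys <- turnover(week7_keys, c(spike_keys, blood_keys))
    f_w18 <- stats::setNames(c(base_freq * (1 - s_mass), spike_freq),
                             c(week18_keys, spike_keys))

    # tumors: own Zipf background, sharing clones with contemporaneous blood
    nt <- config$n_tumor_clones
    tumor_freq <- zipf_freq(nt, config$zipf_exponent)
    seed_tumor <- function(blood_pool, existing) {
      n_shared <- round(config$tumor_share * nt)
      shared <- sample(blood_pool, min(n_shared, length(blood_pool)))
      private <- make_cdr3(nt - length(shared),
                           existing = c(existing, shared))
      keys <- c(shared, private)
      keys[sample(nt)]  # shuffle across frequency ranks
    }
    tumor0_keys <- seed_tumor(blood_keys, c(week7_keys, spike_keys))
    f_t0 <- stats::setNames(tumor_freq, tumor0_keys)
    # post-treatment tumor: persistence from baseline tumor, plus sharing
    # with the week-7 blood pool (spikes included)
    t1_keys <- turnover(tumor0_keys, c(week7_keys, spike_keys))
    n_shared <- round(config$tumor_share * nt)
    w7_pool <- c(week7_keys, spike_keys)
    swap <- sample(nt, min(n_shared, nt))
    t1_keys[swap] <- sample(w7_pool, length(swap))
    t1_keys <- make_unique_keys(t1_keys)
    f_t1 <- stats::setNames(tumor_freq, t1_keys)

    mk <- function(tp, comp, stim) sample_meta(patient_id, tp, comp, stim)
    samples <- list(
      baseline_pbmc = freq_to_repertoire(f_base, config$depth,
                                         mk("baseline", "PBMC",
                                            "unstimulated")),
      week7_pbmc_unstim = freq_to_repertoire(f_w7_un, config$depth,
                                             mk("week7", "PBMC",
                                                "unstimulated")),
      week7_pbmc_stim = freq_to_repertoire(f_w7_st, config$depth,
                                           mk("week7", "PBMC",
                                              "stimulated")),
      week18_pbmc = freq_to_repertoire(f_w18, config$depth,
                                       mk("week18", "PBMC",
                                          "unstimulated")),
      baseline_tumor = freq_to_repertoire(f_t0, config$depth,
                                          mk("baseline", "tumor",
                                             "unstimulated")),
      post_tumor = freq_to_repertoire(f_t1, config$depth,
                                      mk("week14", "tumor",
                                         "unstimulated")))

    truth <- data.frame(
      cdr3_aa = spike_keys,
      base_freq = unname(spike_freq),
      stim_freq = if (config$n_spike > 0)
        unname(f_w7_st[spike_keys]) else numeric(0),
      true_fold = rep(config$spike_fold, config$n_spike),
      realized_fold = if (config$n_spike > 0)
        unname(f_w7_st[spike_keys] / f_w7_un[spike_keys]) else numeric(0),
      in_baseline = rep(isTRUE(config$leak_to_baseline), config$n_spike),
      stringsAsFactors = FALSE)

    list(samples = samples, truth = truth,
         frequencies = list(baseline_pbmc = f_base,
                            week7_pbmc_unstim = f_w7_un,
                            week7_pbmc_stim = f_w7_st,
                            week18_pbmc = f_w18, baseline_tumor = f_t0,
                            post_tumor = f_t1))
  })
}

# resolve accidental key collisions after tumor seeding (keeps length)
make_unique_keys <- function(keys) {
  dup <- duplicated(keys)
  if (any(dup)) keys[dup] <- make_cdr3(sum(dup), existing = keys)
  keys
}

#' Simulate triplicate proliferation assays with a known stimulation index
#'
#' Unstimulated replicate counts are log-normal around `base_mean` with
#' coefficient of variation `noise_cv`; stimulated replicates are log-normal
#' around `base_mean * si_true`. With `noise_cv = 0` the recovered SI is
#' exactly `si_true`.
#'
#' @param config A [sim_config()] (`si_true`, `noise_cv`, `seed` are used).
#' @param patient_id Identifier for the simulated patient.
#' @param timepoints Timepoint labels to generate assays for.
#' @param peptides Peptide conditions per timepoint.
#' @param base_mean Mean unstimulated count (counts per minute).
#' @param n_replicates Wells per condition (default 3).
#' @return A list of [proliferation_assay()].
#' @export
simulate_assays <- function(config, patient_id = "SIM01",
                            timepoints = "week7", peptides = "mix",
                            base_mean = 1000, n_replicates = 3) {
  stopifnot(inherits(config, "sim_config"))
  cv <- config$noise_cv
  draw <- function(mu, n) {
    if (cv == 0) return(rep(mu, n))
    sdlog <- sqrt(log1p(cv^2))
    stats::rlnorm(n, meanlog = log(mu) - sdlog^2 / 2, sdlog = sdlog)
  }
  with_seed(config$seed, {
    out <- list()
    for (tp in timepoints) for (pep in peptides) {
      out[[length(out) + 1L]] <- proliferation_assay(
        patient_id, tp, pep,
        stimulated_counts = draw(base_mean * config$si_true, n_replicates),
        unstimulated_counts = draw(base_mean, n_replicates))
    }
    out
  })
}

#' Write a simulated patient to disk
#'
#' Writes AIRR-style TSVs for every sample, a manifest CSV, a long-format
#' assay CSV and a ground-truth CSV, so a full pipeline run can start from
#' files.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @param patient_id Identifier for the simulated patient.
#' @return Invisibly, the manifest data.frame.
#' @export
write_simulation <- function(config, dir, patient_id = "SIM01") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_patient(config, patient_id)
  rows <- lapply(names(sim$samples), function(nm) {
    rep <- sim$samples[[nm]]
    fn <- paste0(patient_id, "_", nm, ".tsv")
    write_repertoire(rep, file.path(dir, fn))
    data.frame(patient_id = rep$meta$patient_id,
               timepoint = rep$meta$timepoint,
               compartment = rep$meta$compartment,
               stimulation = rep$meta$stimulation, path = fn,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  assays <- simulate_assays(config, patient_id)
  long <- do.call(rbind, lapply(assays, function(a) {
    data.frame(patient_id = a$patient_id, timepoint = a$timepoint,
               peptide = a$peptide,
               condition = rep(c("stimulated", "unstimulated"),
                               c(length(a$stimulated_counts),
                                 length(a$unstimulated_counts))),
               count = c(a$stimulated_counts, a$unstimulated_counts),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(long, file.path(dir, "assays.csv"), row.names = FALSE)
  invisible(manifest)
}
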