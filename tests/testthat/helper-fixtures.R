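# build a repertoire from a named count vector
make_rep <- function(counts, patient = "P1", timepoint = "baseline",
                     compartment = "PBMC", stimulation = "unstimulated") {
  repertoire(data.frame(cdr3_aa = names(counts), count = unname(counts),
                        stringsAsFactors = FALSE),
             meta = sample_meta(patient, timepoint, compartment,
                                stimulation))
}

# independent two-sided Fisher oracle: enumerate the full hypergeometric
# support with log-binomial coefficients (minimum-likelihood convention,
# same equality guard as the implementation under test)
oracle_fisher <- function(x_alt, t, n_ref, n_alt) {
  if (t == 0) return(1)
  lo <- max(0, t - n_ref)
  hi <- min(t, n_alt)
  xs <- lo:hi
  lp <- lchoose(t, xs) + lchoose(n_ref + n_alt - t, n_alt - xs) -
    lchoose(n_ref + n_alt, n_alt)
  pr <- exp(lp)
  min(1, sum(pr[pr <= pr[x_alt - lo + 1L] * (1 + 1e-7)]))
}

# exact paired signed-rank two-sided p by enumerating all sign assignments
oracle_signed_rank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  v_null <- as.matrix(signs) %*% r
  mean_v <- n * (n + 1) / 4
  min(1, 2 * min(mean(v_null >= v_obs), mean(v_null <= v_obs)))
}
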