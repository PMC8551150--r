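#' Names of the 14 clustering features
#'
#' Firing rate, PPC and burst fraction per cell type, low/high-band peak
#' frequencies, log10 power at those peaks, and PAC.
#'
#' @return character vector of length 14.
#' @export
feature_names <- function() {
  c("rate_RS", "rate_FS", "rate_LTS",
    "ppc_RS", "ppc_FS", "ppc_LTS",
    "burst_RS", "burst_FS", "burst_LTS",
    "peak_freq_low", "peak_freq_high",
    "log_power_low", "log_power_high", "pac")
}

#' Feature vector of one simulation
#'
#' Computes the 14 features from one `sim_result`. Features that cannot be
#' computed for this seed (PPC with < 2 spikes, burst fraction with no
#' eligible neuron, PAC when ineligible, any feature of an absent cell type)
#' are `NA` here; the seed-aggregation step decides whether to zero them.
#'
#' @param sim a `sim_result`.
#' @param ... passed to [spike_summary()].
#' @return one-row data.frame: condition keys (`motif_id`, `rs_rate`,
#'   `fs_rate`, `lts_rate`, `seed`), the 14 features, and the mean spike
#'   phases per type (reported but not clustered).
#' @export
condition_features <- function(sim, ...) {
  sp <- spectral_summary(sim)
  sk <- spike_summary(sim, summary = sp, ...)
  g <- function(lst, ty) if (ty %in% sim$type_names)
    lst[[ty]] %||% NA_real_ else NA_real_
  data.frame(
    motif_id = sim$motif_id,
    rs_rate = sim$drive$rate_rs, fs_rate = sim$drive$rate_fs,
    lts_rate = sim$drive$rate_lts, seed = sim$seed,
    rate_RS = g(sk$rate, "RS"), rate_FS = g(sk$rate, "FS"),
    rate_LTS = g(sk$rate, "LTS"),
    ppc_RS = g(sk$ppc, "RS"), ppc_FS = g(sk$ppc, "FS"),
    ppc_LTS = g(sk$ppc, "LTS"),
    burst_RS = g(sk$burst, "RS"), burst_FS = g(sk$burst, "FS"),
    burst_LTS = g(sk$burst, "LTS"),
    peak_freq_low = sp$peak_freq_low, peak_freq_high = sp$peak_freq_high,
    log_power_low = log10(max(sp$power_low, 1e-20)),
    log_power_high = log10(max(sp$power_high, 1e-20)),
    pac = if (sp$pac_eligible) sp$pac else NA_real_,
    phase_RS = g(sk$phase, "RS"), phase_FS = g(sk$phase, "FS"),
    phase_LTS = g(sk$phase, "LTS"),
    stringsAsFactors = FALSE)
}

#' Aggregate per-seed features into per-condition features
#'
#' For every (motif, drive condition), each feature is averaged over the
#' seeds in which it could be computed. A feature computable in fewer than
#' `min_valid` of the seeds (5 of 10 at the full protocol; the threshold
#' scales proportionally when fewer repeats are run) is set to 0 and flagged
#' invalid.
#'
#' @param per_seed data.frame of [condition_features()] rows.
#' @param min_valid minimum number of valid seeds; default
#'   `ceiling(n_seeds / 2)`.
#' @return data.frame with one row per condition: keys, the 14 features, and
#'   logical `valid_*` columns.
#' @export
assemble_features <- function(per_seed, min_valid = NULL) {
  keys <- c("motif_id", "rs_rate", "fs_rate", "lts_rate")
  feats <- feature_names()
  cond <- unique(per_seed[keys])
  rownames(cond) <- NULL
  n_seeds <- max(table(interaction(per_seed[keys], drop = TRUE)))
  if (is.null(min_valid)) min_valid <- ceiling(n_seeds / 2)
  out <- vector("list", nrow(cond))
  for (i in seq_len(nrow(cond))) {
    sel <- rep(TRUE, nrow(per_seed))
    for (k in keys) sel <- sel & per_seed[[k]] == cond[[k]][i]
    rows <- per_seed[sel, , drop = FALSE]
    vals <- numeric(length(feats)); ok <- logical(length(feats))
    for (j in seq_along(feats)) {
      v <- rows[[feats[j]]]
      ok[j] <- sum(!is.na(v)) >= min_valid
      vals[j] <- if (ok[j]) mean(v, na.rm = TRUE) else 0
    }
    row <- cond[i, , drop = FALSE]
    row[feats] <- as.list(vals)
    row[paste0("valid_", feats)] <- as.list(ok)
    out[[i]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
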