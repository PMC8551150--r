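#' Grid-experiment specification
#'
#' A scan of motifs over a grid of background input rates with repeated
#' seeds. The canonical protocol is 0-5000 Hz in 250 Hz steps (21 x 21
#' conditions) and 10 repeats; smaller grids (e.g. 500 Hz steps, 3 repeats)
#' are used for desk-scale runs. For three-cell motifs the two grid axes
#' drive the RS and FS populations, and the LTS population receives a fixed
#' `lts_rate` whenever its regime includes external input. The two-cell
#' RS-LTS motif (II) has no FS population, so its second axis drives the LTS
#' population instead.
#'
#' @param motifs character vector of numerals or list of [motif_spec()].
#' @param rs_rates,in_rates grid axes, Hz (defaults `seq(0, 5000, 250)`).
#' @param lts_rate external LTS drive for three-cell motifs whose regime
#'   includes external input, Hz.
#' @param n_repeats seeds per condition.
#' @param master_seed seed from which per-repeat seeds are derived.
#' @param out_dir optional directory for incremental CSV output (enables
#'   resuming).
#' @return object of class `grid_spec`.
#' @export
grid_spec <- function(motifs, rs_rates = seq(0, 5000, 250),
                      in_rates = seq(0, 5000, 250), lts_rate = 2000,
                      n_repeats = 10, master_seed = 1, out_dir = NULL) {
  if (is.character(motifs)) motifs <- lapply(motifs, get_motif)
  if (inherits(motifs, "motif_spec")) motifs <- list(motifs)
  stopifnot(all(vapply(motifs, inherits, TRUE, "motif_spec")),
            n_repeats >= 1, all(rs_rates >= 0), all(in_rates >= 0))
  structure(list(motifs = motifs, rs_rates = rs_rates, in_rates = in_rates,
                 lts_rate = lts_rate, n_repeats = n_repeats,
                 master_seed = as.integer(master_seed), out_dir = out_dir),
            class = "grid_spec")
}

condition_drive <- function(motif, rs, axis2, lts_rate) {
  if (motif$has_lts && !motif$has_fs)        # two-cell RS-LTS circuit
    drive_spec(rs, 0, axis2)
  else if (motif$lts_input_regime %in% c("external_only", "both"))
    drive_spec(rs, axis2, lts_rate)
  else
    drive_spec(rs, axis2, 0)
}

#' Run a grid experiment
#'
#' Simulates every (motif, condition, repeat) combination, extracts the
#' per-seed features, and aggregates them across seeds (see
#' [assemble_features()]). When the grid has an `out_dir`, per-seed rows are
#' written after every (motif, repeat) chunk and completed chunks are
#' skipped on re-run, so an interrupted scan resumes to an identical table.
#'
#' @param grid a [grid_spec()].
#' @param noise a [noise_spec()].
#' @param progress print progress to stderr?
#' @param ... passed to [run_simulation()] (e.g. `t_total`).
#' @return list with `per_seed` (one row per simulation), `features`
#'   (seed-aggregated, one row per condition) and the `grid`.
#' @export
run_grid <- function(grid, noise = noise_spec(), progress = FALSE, ...) {
  stopifnot(inherits(grid, "grid_spec"))
  seeds <- derive_seeds(grid$master_seed, grid$n_repeats)
  seed_file <- if (!is.null(grid$out_dir)) {
    dir.create(grid$out_dir, showWarnings = FALSE, recursive = TRUE)
    file.path(grid$out_dir, "features_per_seed.csv")
  }
  done <- NULL
  rows <- list()
  if (!is.null(seed_file) && file.exists(seed_file)) {
    prev <- read.csv(seed_file, stringsAsFactors = FALSE)
    rows <- list(prev)
    done <- unique(prev[c("motif_id", "seed")])
  }
  for (motif in grid$motifs) {
    for (r in seq_len(grid$n_repeats)) {
      sd_r <- seeds[r]
      if (!is.null(done) &&
          any(done$motif_id == motif$motif_id & done$seed == sd_r)) next
      if (progress)
        message(sprintf("motif %s repeat %d/%d (seed %d)",
                        motif$motif_id, r, grid$n_repeats, sd_r))
      prep <- prepare_simulation(motif, seed = sd_r, noise = noise)
      chunk <- list()
      for (rs in grid$rs_rates) for (ax2 in grid$in_rates) {
        drv <- condition_drive(motif, rs, ax2, grid$lts_rate)
        sim <- execute_simulation(prep, drv, ...)
        chunk[[length(chunk) + 1L]] <- condition_features(sim)
      }
      chunk <- do.call(rbind, chunk)
      # record the grid axis, not the population mapping, as the condition key
      chunk$fs_rate <- rep(grid$in_rates, length(grid$rs_rates))
      rows[[length(rows) + 1L]] <- chunk
      if (!is.null(seed_file)) {
        all_rows <- do.call(rbind, rows)
        write.csv(all_rows, seed_file, row.names = FALSE)
      }
    }
  }
  per_seed <- do.call(rbind, rows)
  rownames(per_seed) <- NULL
  features <- assemble_features(per_seed)
  if (!is.null(grid$out_dir)) {
    write.csv(features, file.path(grid$out_dir, "features.csv"),
              row.names = FALSE)
    meta <- list(motifs = vapply(grid$motifs, `[[`, "", "motif_id"),
                 rs_rates = grid$rs_rates, in_rates = grid$in_rates,
                 lts_rate = grid$lts_rate, n_repeats = grid$n_repeats,
                 master_seed = grid$master_seed, seeds = seeds)
    jsonlite::write_json(meta, file.path(grid$out_dir, "run_meta.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(per_seed = per_seed, features = features, grid = grid)
}

#' Run a step-current / step-rate protocol
#'
#' Simulates a motif under a drive whose schedule applies piecewise-constant
#' rate or current offsets to one population (e.g. switching the external
#' LTS drive on during a window). The returned result carries the segment
#' table so windows can be analyzed separately with [window_features()].
#'
#' @inheritParams run_simulation
#' @return a `sim_result` with a `segments` element.
#' @export
run_switch_protocol <- function(motif, drive, seed = 1,
                                noise = noise_spec(), ...) {
  sim <- run_simulation(motif, drive, noise = noise, seed = seed, ...)
  sim$segments <- drive$schedule
  sim
}

#' Spectral features of a time window
#'
#' [spectral_summary()] restricted to `[t_start, t_end]` ms of a simulation,
#' for comparing schedule-on and schedule-off windows.
#'
#' @param sim a `sim_result`.
#' @param t_start,t_end window, ms.
#' @param ... passed to [spectral_summary()].
#' @export
window_features <- function(sim, t_start, t_end, ...) {
  win <- analysis_window(sim, t_start, t_end)
  spectral_summary(win$lfp, fs = sim$fs, ...)
}
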