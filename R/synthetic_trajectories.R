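# Synthetic chi1 trajectory generator: von Mises rotamer wells with
# Markov-chain switching between them.  Emulates the statistical structure
# the analysis assumes — a single stable well at neutral pH, stochastic
# two-well switching at acidic pH — so the pipeline is testable without MD
# trajectories.  Ground-truth hidden states are always retained.

#' Specify a rotamer well
#'
#' A von Mises well centered at `mu` whose concentration is set from the
#' angular spread via `kappa = 1 / sigma_rad^2`, the circular analog of a
#' Gaussian well of standard deviation `sigma`.
#'
#' @param mu well center, degrees.
#' @param sigma angular spread, degrees; must lie in (0, 60).
#' @param label state name.
#' @return an object of class `well_spec`.
#' @export
well_spec <- function(mu, sigma, label = "state") {
  if (sigma <= 0 || sigma >= 60)
    stop_chisno("sigma must lie in (0, 60) degrees", "chisno_spec_error")
  structure(list(mu = mu %% 360, sigma = sigma,
                 kappa = 1 / deg2rad(sigma)^2, label = label),
            class = "well_spec")
}

#' Draw von Mises angles (degrees)
#'
#' Best-Fisher (1979) acceptance-rejection sampler for the von Mises
#' distribution, returned in degrees on `[0, 360)`.
#'
#' @param n number of draws.
#' @param mu mean direction, degrees.
#' @param kappa concentration parameter (> 0; 0 falls back to uniform).
#' @return numeric vector of angles in `[0, 360)`.
#' @export
rvonmises <- function(n, mu, kappa) {
  if (n == 0L) return(numeric(0))
  if (kappa < 1e-10) return(runif(n, 0, 360))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- ceiling((n - length(out)) * 1.6) + 8L
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    acc <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    theta <- sign(u3[acc] - 0.5) * acos(pmin(pmax(f[acc], -1), 1))
    out <- c(out, theta)
  }
  (mu + rad2deg(out[seq_len(n)])) %% 360
}

#' Specify a generative chi1 regime
#'
#' One or more von Mises wells plus a row-stochastic per-frame switching
#' matrix; the hidden state follows the Markov chain and each frame's angle
#' is drawn from its state's well.  The defaults elsewhere in the package
#' emulate 100-ns trajectories sampled every 0.1 ns (1000 frames).
#'
#' @param wells a [well_spec()] or list of them.
#' @param transition square row-stochastic matrix of per-frame switching
#'   probabilities, side equal to the number of wells.  Defaults to the
#'   identity (no switching).
#' @param n_frames number of frames.
#' @param frame_dt frame interval, ns.
#' @param seed optional RNG seed for [sample_regime()].
#' @return an object of class `regime_spec`.
#' @export
regime_spec <- function(wells, transition = NULL, n_frames = 1000L,
                        frame_dt = 0.1, seed = NULL) {
  if (inherits(wells, "well_spec")) wells <- list(wells)
  if (!length(wells) || !all(vapply(wells, inherits, logical(1), "well_spec")))
    stop_chisno("wells must be well_spec objects", "chisno_spec_error")
  k <- length(wells)
  if (is.null(transition)) transition <- diag(k)
  transition <- as.matrix(transition)
  if (!all(dim(transition) == c(k, k)))
    stop_chisno("transition matrix side must equal the number of wells",
                "chisno_spec_error")
  if (any(transition < 0) || any(abs(rowSums(transition) - 1) > 1e-8))
    stop_chisno("transition matrix must be row-stochastic", "chisno_spec_error")
  if (n_frames < 1L)
    stop_chisno("n_frames must be positive", "chisno_spec_error")
  structure(list(wells = wells, transition = transition,
                 n_frames = as.integer(n_frames), frame_dt = frame_dt,
                 seed = seed),
            class = "regime_spec")
}

#' Single-well regime (neutral-pH-like)
#'
#' @param mu,sigma well center and spread, degrees (defaults 190 and 9, the
#'   stable in-site catalytic-histidine well).
#' @param label state label.
#' @param ... passed to [regime_spec()].
#' @return a `regime_spec`.
#' @export
single_well_regime <- function(mu = 190, sigma = 9, label = "in_site", ...) {
  regime_spec(well_spec(mu, sigma, label), ...)
}

#' Two-well switching regime (acidic-pH-like)
#'
#' In-site and out-of-site wells with per-frame switching probabilities
#' `p_out` (in -> out) and `p_in` (out -> in).  The defaults
#' (`p_out = 0.10`, `p_in = 0.05` per 0.1-ns frame) give a stationary
#' out-of-site occupancy of 2/3, an excessively flexible side chain that
#' spends most of its time outside the competent rotamer.
#'
#' @param mu,sigma length-2 vectors of well centers and spreads, degrees
#'   (defaults 190 +/- 9 in-site, 285 +/- 12 out-of-site).
#' @param labels state labels.
#' @param p_out,p_in per-frame switching probabilities.
#' @param ... passed to [regime_spec()].
#' @return a `regime_spec`.
#' @export
two_well_regime <- function(mu = c(190, 285), sigma = c(9, 12),
                            labels = c("in_site", "out_site"),
                            p_out = 0.10, p_in = 0.05, ...) {
  wells <- list(well_spec(mu[1], sigma[1], labels[1]),
                well_spec(mu[2], sigma[2], labels[2]))
  transition <- rbind(c(1 - p_out, p_out), c(p_in, 1 - p_in))
  regime_spec(wells, transition, ...)
}

#' Stationary distribution of a regime's switching chain
#'
#' @param spec a [regime_spec()].
#' @return numeric vector of stationary state probabilities, named by well
#'   label.
#' @export
stationary_occupancy <- function(spec) {
  P <- spec$transition
  k <- nrow(P)
  # solve pi (P - I) = 0 with sum(pi) = 1
  A <- rbind(t(P) - diag(k), rep(1, k))
  pi_hat <- qr.solve(A, c(rep(0, k), 1))
  setNames(pmax(pi_hat, 0) / sum(pmax(pi_hat, 0)),
           vapply(spec$wells, `[[`, character(1), "label"))
}

#' Sample a chi1 trajectory from a regime
#'
#' Hidden states follow the Markov chain from `initial_state`; each frame's
#' angle is drawn from its state's von Mises well.  Fully reproducible from
#' the spec's seed.
#'
#' @param spec a [regime_spec()].
#' @param initial_state index of the starting well.
#' @param residue_id,residue_name metadata for the emitted series.
#' @return list with `series` (a [dihedral_series()], angles in `[0, 360)`)
#'   and `states` (character vector of hidden state labels per frame).
#' @export
sample_regime <- function(spec, initial_state = 1L, residue_id = 1L,
                          residue_name = "HIS") {
  if (!inherits(spec, "regime_spec"))
    stop_chisno("expected a regime_spec", "chisno_spec_error")
  k <- length(spec$wells)
  if (initial_state < 1L || initial_state > k)
    stop_chisno("initial_state out of range", "chisno_spec_error")
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n_frames
  s <- integer(n)
  s[1] <- initial_state
  if (k > 1L && n > 1L) {
    cp <- t(apply(spec$transition, 1, cumsum))
    u <- runif(n - 1L)
    for (i in 2:n) {
      s[i] <- 1L + sum(u[i - 1L] > cp[s[i - 1L], ])
    }
  } else if (n > 1L) {
    s[] <- 1L
  }
  angles <- numeric(n)
  for (w in seq_len(k)) {
    idx <- which(s == w)
    if (length(idx))
      angles[idx] <- rvonmises(length(idx), spec$wells[[w]]$mu,
                               spec$wells[[w]]$kappa)
  }
  times <- (seq_len(n) - 1) * spec$frame_dt
  labels <- vapply(spec$wells, `[[`, character(1), "label")[s]
  list(series = dihedral_series(times, angles, residue_id = residue_id,
                                residue_name = residue_name),
       states = labels)
}

# deterministic per-series seed derivation, kept below 2^31
derive_seed <- function(base_seed, index) {
  as.integer((as.numeric(base_seed) * 100003 + index * 7919) %% 2147483647)
}

#' Generate a full synthetic two-condition study set
#'
#' Emulates the replicated MD design of a pH study: `n_replicates`
#' trajectories per residue per condition.  Non-responsive residues follow
#' the single-well template under both conditions (with distinct seeds, so
#' replicates differ); responsive residues follow the single-well template
#' under the first (neutral-pH-like) condition and the two-well switching
#' template under the second (acidic-pH-like) condition.
#'
#' @param n_residues number of residues.
#' @param responsive_ids residue ids (within `residue_ids`) that switch
#'   regimes under the acidic condition.
#' @param ph7_template regime for the neutral-like condition (default
#'   [single_well_regime()]).
#' @param ph2_template regime for the acidic-like condition of responsive
#'   residues (default [two_well_regime()]).
#' @param n_replicates replicates per condition (default 3).
#' @param base_seed base seed; per-series seeds are derived from it
#'   deterministically and are pairwise distinct.
#' @param residue_ids integer ids (default `1:n_residues`).
#' @param conditions names of the two conditions.
#' @return an object of class `synthetic_dataset`: `series[[residue]][[condition]][[replicate]]`
#'   ([dihedral_series()]), `truth` (hidden state labels in the same nesting
#'   plus a per-residue `responsive` flag), and the generation parameters.
#' @export
make_study_set <- function(n_residues = 20L, responsive_ids = integer(),
                           ph7_template = single_well_regime(),
                           ph2_template = two_well_regime(),
                           n_replicates = 3L, base_seed = 1L,
                           residue_ids = seq_len(n_residues),
                           conditions = c("pH7", "pH2")) {
  if (length(residue_ids) != n_residues)
    stop_chisno("residue_ids must have length n_residues", "chisno_spec_error")
  if (!all(responsive_ids %in% residue_ids))
    stop_chisno("responsive_ids must be a subset of residue_ids",
                "chisno_spec_error")
  if (length(conditions) != 2L)
    stop_chisno("exactly two conditions expected", "chisno_spec_error")
  series <- list()
  states <- list()
  responsive <- setNames(residue_ids %in% responsive_ids,
                         as.character(residue_ids))
  for (r in seq_len(n_residues)) {
    rid <- residue_ids[r]
    rname <- if (responsive[r]) "HIS" else "VAL"
    series[[as.character(rid)]] <- list()
    states[[as.character(rid)]] <- list()
    for (ci in 1:2) {
      cond <- conditions[ci]
      template <- if (responsive[r] && ci == 2L) ph2_template else ph7_template
      reps <- vector("list", n_replicates)
      st <- vector("list", n_replicates)
      for (k in seq_len(n_replicates)) {
        idx <- ((r - 1L) * 2L + (ci - 1L)) * n_replicates + k
        spec_k <- template
        spec_k$seed <- derive_seed(base_seed, idx)
        draw <- sample_regime(spec_k, residue_id = rid, residue_name = rname)
        reps[[k]] <- draw$series
        st[[k]] <- draw$states
      }
      series[[as.character(rid)]][[cond]] <- reps
      states[[as.character(rid)]][[cond]] <- st
    }
  }
  structure(
    list(series = series,
         truth = list(states = states, responsive = responsive),
         conditions = conditions, n_replicates = n_replicates,
         base_seed = base_seed,
         n_frames = ph7_template$n_frames, frame_dt = ph7_template$frame_dt),
    class = "synthetic_dataset"
  )
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d residues (%d responsive) x {%s} x %d replicates, %d frames\n",
              length(x$series), sum(x$truth$responsive),
              paste(x$conditions, collapse = ", "), x$n_replicates, x$n_frames))
  invisible(x)
}

#' Extract one condition of a dataset as pairwise_sno() input
#'
#' @param dataset a [make_study_set()] result.
#' @param condition condition name.
#' @return named list (per residue) of lists of [dihedral_series()].
#' @export
condition_series <- function(dataset, condition) {
  if (!condition %in% dataset$conditions)
    stop_chisno(sprintf("unknown condition '%s'", condition),
                "chisno_config_error")
  lapply(dataset$series, `[[`, condition)
}

#' Write a synthetic dataset to disk with a manifest
#'
#' Lays out one angle file per residue/condition/replicate (xvg or CSV)
#' under `dir/<condition>/rep<k>/`, plus `manifest.json` (the file roster
#' the pipeline reader consumes) and `truth.json` (hidden states and
#' responsiveness flags).
#'
#' @param dataset a [make_study_set()] result.
#' @param dir output directory.
#' @param format `"xvg"` or `"csv"`.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return path to the manifest file, invisibly.
#' @export
write_study_set <- function(dataset, dir, format = c("xvg", "csv"),
                            overwrite = FALSE) {
  format <- match.arg(format)
  if (dir.exists(dir) && length(list.files(dir)) && !overwrite)
    stop_chisno(sprintf("directory %s is non-empty; use overwrite = TRUE", dir),
                "chisno_overwrite_error")
  rows <- list()
  for (rid in names(dataset$series)) {
    for (cond in dataset$conditions) {
      for (k in seq_len(dataset$n_replicates)) {
        s <- dataset$series[[rid]][[cond]][[k]]
        rel <- file.path(cond, sprintf("rep%d", k),
                         sprintf("chi1%s%s.%s", s$residue_name, rid,
                                 if (format == "xvg") "xvg" else "csv"))
        path <- file.path(dir, rel)
        dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
        if (format == "xvg") write_chi_xvg(s, path) else write_angle_table(s, path)
        rows[[length(rows) + 1L]] <- data.frame(
          residue_id = as.integer(rid), residue_name = s$residue_name,
          condition = cond, replicate = k, path = rel)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(responsive = as.list(dataset$truth$responsive),
         states = dataset$truth$states,
         base_seed = dataset$base_seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(manifest_path)
}
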