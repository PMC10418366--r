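# The integral of non-overlapping (S_NO) between binned chi1 distributions,
# the replicate-pair table, and the responsive-residue selection rule.

#' Bin a stacked angle series into a unit-area density
#'
#' Histogram density on the stacked 360-degree window.  Heights are
#' normalized so that `sum(heights) * binwidth == 1`.
#'
#' @param stacked a `stacked_series` from [stack_angles()].
#' @param binwidth bin width in degrees; must divide 360.
#' @return an object of class `chi_density` with fields `edges` (length
#'   `nbins + 1`), `heights`, `binwidth`, `window_start`, `n`.
#' @export
make_density <- function(stacked, binwidth = 5) {
  if (!inherits(stacked, "stacked_series"))
    stop_chisno("make_density expects a stacked_series (see stack_angles)",
                "chisno_schema_error")
  if (binwidth <= 0 || abs(360 / binwidth - round(360 / binwidth)) > 1e-9)
    stop_chisno("binwidth must be a positive divisor of 360",
                "chisno_config_error")
  a <- stacked$angles
  n <- length(a)
  if (n == 0L) stop_chisno("empty angle series", "chisno_empty_input")
  nbins <- as.integer(round(360 / binwidth))
  idx <- pmin(pmax(floor((a - stacked$window_start) / binwidth) + 1L, 1L), nbins)
  counts <- tabulate(idx, nbins)
  structure(
    list(edges = stacked$window_start + (0:nbins) * binwidth,
         heights = counts / (n * binwidth),
         binwidth = binwidth, window_start = stacked$window_start, n = n),
    class = "chi_density"
  )
}

#' @export
print.chi_density <- function(x, ...) {
  cat(sprintf("<chi_density> %d bins of %g deg on [%.1f, %.1f), n = %d\n",
              length(x$heights), x$binwidth, x$edges[1],
              x$edges[length(x$edges)], x$n))
  invisible(x)
}

#' Integral of non-overlapping (S_NO) between two densities
#'
#' The difference between the two areas under the curves divided by their
#' sum, `sum(|p_i - q_i|) / sum(p_i + q_i)` over common bins.  For unit-area
#' densities this equals one minus the overlap coefficient,
#' `1 - sum(min(p_i, q_i)) * binwidth`: zero for identical distributions,
#' one for non-overlapping ones.
#'
#' @param p,q [make_density()] objects built on identical bin edges (use a
#'   shared stacking window from the pooled angles, see [pair_sno()]).
#' @return S_NO in `[0, 1]`.
#' @export
sno <- function(p, q) {
  if (!inherits(p, "chi_density") || !inherits(q, "chi_density"))
    stop_chisno("sno expects two chi_density objects", "chisno_schema_error")
  if (length(p$edges) != length(q$edges) ||
      max(abs(p$edges - q$edges)) > 1e-6)
    stop_chisno("densities are binned on different edges; rebuild on a shared window",
                "chisno_binning_error")
  tot <- sum(p$heights + q$heights)
  if (tot == 0) return(0)
  sum(abs(p$heights - q$heights)) / tot
}

# Stack two raw series on the window cut from their pooled angles and return
# their densities on identical edges.
pooled_densities <- function(series_a, series_b, binwidth = 5) {
  pooled <- c(series_a$angles, series_b$angles) %% 360
  ws <- stack_cut(pooled)
  list(p = make_density(stack_angles(series_a, window_start = ws), binwidth),
       q = make_density(stack_angles(series_b, window_start = ws), binwidth))
}

#' S_NO between two raw dihedral series
#'
#' Convenience wrapper: pools the two series to choose one shared stacking
#' window, bins both on it and applies [sno()].
#'
#' @param series_a,series_b [dihedral_series()] objects.
#' @param binwidth bin width in degrees.
#' @return S_NO in `[0, 1]`.
#' @export
pair_sno <- function(series_a, series_b, binwidth = 5) {
  d <- pooled_densities(series_a, series_b, binwidth)
  sno(d$p, d$q)
}

#' Replicate-paired S_NO table across residues
#'
#' Compares the chi1 distribution of every residue between two simulation
#' conditions, replicate by replicate.  `"matched"` pairing compares
#' replicate i of condition A with replicate i of condition B (the
#' replicates originate from matched starting models); `"all_pairs"` takes
#' the full Cartesian product.
#'
#' @param cond_a,cond_b named lists (one element per residue, named by
#'   residue id) of lists of [dihedral_series()] replicates.
#' @param pairing `"matched"` or `"all_pairs"`.
#' @param binwidth bin width in degrees.
#' @return an object of class `pair_sno_table`: `residues` (integer ids),
#'   `residue_names`, `pairs` (data.frame of replicate indices), `values`
#'   (residues x pairs matrix of S_NO).
#' @export
pairwise_sno <- function(cond_a, cond_b, pairing = c("matched", "all_pairs"),
                         binwidth = 5) {
  pairing <- match.arg(pairing)
  ids <- names(cond_a)
  if (!setequal(ids, names(cond_b)))
    stop_chisno("conditions cover different residue sets", "chisno_pairing_error")
  cond_b <- cond_b[ids]
  n_a <- lengths(cond_a)
  n_b <- lengths(cond_b)
  if (any(n_a < 1L) || any(n_b < 1L))
    stop_chisno("each residue needs at least one replicate per condition",
                "chisno_pairing_error")
  if (length(unique(n_a)) != 1L || length(unique(n_b)) != 1L)
    stop_chisno("replicate counts must be uniform across residues",
                "chisno_pairing_error")
  if (pairing == "matched") {
    if (any(n_a != n_b))
      stop_chisno("matched pairing requires equal replicate counts",
                  "chisno_pairing_error")
    pairs <- data.frame(rep_a = seq_len(n_a[1]), rep_b = seq_len(n_a[1]))
  } else {
    pairs <- expand.grid(rep_a = seq_len(n_a[1]), rep_b = seq_len(n_b[1]))
  }
  values <- matrix(NA_real_, nrow = length(ids), ncol = nrow(pairs),
                   dimnames = list(ids, paste0("A", pairs$rep_a, "_B", pairs$rep_b)))
  for (r in seq_along(ids)) {
    for (k in seq_len(nrow(pairs))) {
      values[r, k] <- pair_sno(cond_a[[r]][[pairs$rep_a[k]]],
                               cond_b[[r]][[pairs$rep_b[k]]], binwidth)
    }
  }
  res_names <- vapply(cond_a, function(reps) reps[[1]]$residue_name, character(1))
  structure(
    list(residues = as.integer(ids), residue_names = unname(res_names),
         pairs = pairs, values = values),
    class = "pair_sno_table"
  )
}

#' @export
as.data.frame.pair_sno_table <- function(x, ...) {
  cbind(data.frame(residue_id = x$residues, residue_name = x$residue_names),
        as.data.frame(x$values, row.names = NULL))
}

#' @export
print.pair_sno_table <- function(x, ...) {
  cat(sprintf("<pair_sno_table> %d residues x %d replicate pairs\n",
              length(x$residues), nrow(x$pairs)))
  print(utils::head(as.data.frame(x), 10))
  if (length(x$residues) > 10) cat("...\n")
  invisible(x)
}

#' Select pH-responsive residues from a pair-S_NO table
#'
#' A residue is responsive when its S_NO exceeds `threshold` (strictly) in
#' at least `min_pairs` of the replicate pairs — the
#' reproducibility-across-replicates rule used to shortlist residues whose
#' rotameric state reorganizes on acidification.
#'
#' @param table a [pairwise_sno()] result.
#' @param threshold S_NO cutoff (default 0.5); comparison is strict (`>`).
#' @param min_pairs minimum number of exceeding pairs (default 2).
#' @param n_pairs optional consistency check on the number of pairs in the
#'   table (e.g. 3 for triplicate matched pairing).
#' @return integer vector of selected residue ids, ascending.
#' @export
select_responsive <- function(table, threshold = 0.5, min_pairs = 2L,
                              n_pairs = NULL) {
  if (!inherits(table, "pair_sno_table"))
    stop_chisno("expected a pair_sno_table", "chisno_schema_error")
  if (threshold < 0 || threshold > 1)
    stop_chisno("threshold must lie in [0, 1]", "chisno_config_error")
  if (min_pairs < 1L || min_pairs > ncol(table$values))
    stop_chisno("min_pairs must lie in [1, number of pairs]",
                "chisno_config_error")
  if (!is.null(n_pairs) && ncol(table$values) != n_pairs)
    stop_chisno(sprintf("table has %d pairs, expected %d",
                        ncol(table$values), n_pairs), "chisno_pairing_error")
  hits <- rowSums(table$values > threshold)
  sort(table$residues[hits >= min_pairs])
}

#' Mean and sample standard deviation of S_NO values
#'
#' The aggregation used when one point summarizes the replicate pairs of a
#' variant (mean over the three matched pairs, plus-minus sample s.d.).
#'
#' @param values numeric vector of at least two S_NO values.
#' @return named numeric vector `c(mean, sd)`.
#' @export
aggregate_sno <- function(values) {
  if (length(values) < 2L)
    stop_chisno("need at least two values for mean +/- s.d.",
                "chisno_config_error")
  c(mean = mean(values), sd = stats::sd(values))
}
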