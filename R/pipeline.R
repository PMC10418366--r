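# End-to-end orchestration: manifest -> stacked densities -> pairwise S_NO
# -> responsive-residue selection -> rotamer stability summary -> charge
# table -> serialized report.

#' Read an angle-file manifest
#'
#' The manifest lists one angle file per residue/condition/replicate with
#' columns `residue_id`, `residue_name`, `condition`, `replicate`, `path`
#' (relative to the manifest's directory).  JSON (as written by
#' [write_study_set()]) and TSV are accepted.
#'
#' @param path manifest file (`.json` or `.tsv`).
#' @return data.frame with a `base_dir` attribute.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path))
    stop_chisno(sprintf("manifest not found: %s", path), "chisno_manifest_error")
  ext <- tolower(tools::file_ext(path))
  df <- if (ext == "json") {
    jsonlite::fromJSON(path)
  } else {
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  }
  req <- c("residue_id", "residue_name", "condition", "replicate", "path")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop_chisno(sprintf("manifest lacks column(s): %s",
                        paste(missing_cols, collapse = ", ")),
                "chisno_manifest_error")
  attr(df, "base_dir") <- dirname(normalizePath(path))
  df
}

# load all replicates of one condition as pairwise_sno() input
load_condition <- function(manifest, condition, base_dir = NULL) {
  base_dir <- base_dir %||% attr(manifest, "base_dir") %||% "."
  sub <- manifest[manifest$condition == condition, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop_chisno(sprintf("manifest has no files for condition '%s'", condition),
                "chisno_manifest_error")
  paths <- file.path(base_dir, sub$path)
  absent <- !file.exists(paths)
  if (any(absent))
    stop_chisno(sprintf("missing replicate file(s): %s",
                        paste(sub$path[absent], collapse = ", ")),
                "chisno_manifest_error")
  out <- list()
  for (rid in unique(sub$residue_id)) {
    rows <- sub[sub$residue_id == rid, , drop = FALSE]
    rows <- rows[order(rows$replicate), , drop = FALSE]
    out[[as.character(rid)]] <- lapply(seq_len(nrow(rows)), function(i) {
      p <- file.path(base_dir, rows$path[i])
      reader <- if (tolower(tools::file_ext(p)) %in% c("csv", "tsv", "txt"))
        function(x) read_angle_table(x, residue_id = rows$residue_id[i],
                                     residue_name = rows$residue_name[i])
      else
        function(x) read_chi_xvg(x, residue_id = rows$residue_id[i],
                                 residue_name = rows$residue_name[i])
      reader(p)
    })
  }
  out
}

#' Run the full chi1 rotamer destabilization analysis
#'
#' Loads angle series for two conditions, computes the replicate-paired
#' S_NO table, applies the responsive-residue selection rule, classifies
#' every trace into rotamer states and summarizes native-state stability,
#' and (optionally) computes the variant/scheme net-charge table from a
#' FASTA sequence.
#'
#' @param manifest a [read_manifest()] data.frame or path to a manifest.
#' @param condition_a,condition_b names of the two conditions to compare
#'   (A is the reference, e.g. neutral pH).
#' @param binwidth histogram bin width, degrees.
#' @param pairing replicate pairing mode, `"matched"` or `"all_pairs"`.
#' @param threshold,min_pairs responsive-selection rule: S_NO strictly above
#'   `threshold` in at least `min_pairs` pairs.
#' @param windows [rotamer_windows()] for state classification.
#' @param min_dwell minimum violation duration, ns.
#' @param sequence optional FASTA path for the charge table.
#' @param numbering_offset precursor-numbering offset of that sequence.
#' @param mutations character vector of variant mutations for the charge
#'   table.
#' @param his_target catalytic histidine position for the `pH2_his` scheme.
#' @param out_dir if non-`NULL`, report artifacts are written there via
#'   [write_report()].
#' @return an object of class `sno_report`.
#' @export
run_pipeline <- function(manifest,
                         condition_a = "pH7", condition_b = "pH2",
                         binwidth = 5, pairing = "matched",
                         threshold = 0.5, min_pairs = 2L,
                         windows = rotamer_windows(), min_dwell = 1,
                         sequence = NULL, numbering_offset = 115L,
                         mutations = character(), his_target = 275L,
                         out_dir = NULL) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  cond_a <- load_condition(manifest, condition_a)
  cond_b <- load_condition(manifest, condition_b)

  table <- pairwise_sno(cond_a, cond_b, pairing = pairing, binwidth = binwidth)
  selected <- select_responsive(table, threshold = threshold,
                                min_pairs = min_pairs)

  traces <- list()
  meta_rows <- list()
  for (cond in c(condition_a, condition_b)) {
    cl <- if (cond == condition_a) cond_a else cond_b
    for (rid in names(cl)) {
      for (k in seq_along(cl[[rid]])) {
        traces[[length(traces) + 1L]] <- classify_states(cl[[rid]][[k]], windows)
        meta_rows[[length(meta_rows) + 1L]] <- data.frame(
          variant = "WT", condition = cond, replicate = k,
          residue_id = as.integer(rid))
      }
    }
  }
  stability <- summarize_stability(traces, do.call(rbind, meta_rows),
                                   min_dwell = min_dwell)

  charges <- NULL
  if (!is.null(sequence)) {
    seq <- if (inherits(sequence, "protein_sequence")) sequence
           else read_protein_fasta(sequence, numbering_offset = numbering_offset)
    charges <- charge_table(seq, mutations = mutations,
                            his_target = his_target)
  }

  mean_sno <- aggregate_sno(as.vector(table$values))
  report <- structure(
    list(sno_table = table, selected = selected, stability = stability,
         charges = charges,
         mean_sno = mean_sno,
         provenance = list(
           package = "chisno",
           version = as.character(utils::packageVersion("chisno")),
           r_version = R.version.string,
           parameters = list(condition_a = condition_a,
                             condition_b = condition_b,
                             binwidth = binwidth, pairing = pairing,
                             threshold = threshold, min_pairs = min_pairs,
                             min_dwell = min_dwell,
                             windows = windows$states,
                             native = windows$native),
           n_series = length(traces))),
    class = "sno_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.sno_report <- function(x, ...) {
  cat("<sno_report>\n")
  cat(sprintf("  residues: %d; replicate pairs: %d (%s)\n",
              length(x$sno_table$residues), nrow(x$sno_table$pairs),
              x$provenance$parameters$pairing))
  cat(sprintf("  mean S_NO over all pairs: %.3f +/- %.3f\n",
              x$mean_sno[["mean"]], x$mean_sno[["sd"]]))
  cat(sprintf("  responsive residues (S_NO > %g in >= %d pairs): %s\n",
              x$provenance$parameters$threshold,
              x$provenance$parameters$min_pairs,
              if (length(x$selected)) paste(x$selected, collapse = ", ")
              else "none"))
  if (!is.null(x$charges)) {
    cat("  charge table:\n")
    print(x$charges)
  }
  invisible(x)
}

#' Write report artifacts
#'
#' Writes `report.tsv` (per-residue pair-S_NO table, 4 significant digits),
#' `selection.tsv`, `stability.tsv`, optionally `charges.tsv`, plus
#' `report.json` (full precision) and `run.log`.
#'
#' @param report a [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sno_df <- as.data.frame(report$sno_table)
  num <- vapply(sno_df, is.numeric, logical(1)) & names(sno_df) != "residue_id"
  sno_df[num] <- lapply(sno_df[num], signif, digits = 4)
  sno_df$selected <- report$sno_table$residues %in% report$selected
  utils::write.table(sno_df, file.path(dir, "report.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(
    data.frame(residue_id = report$selected),
    file.path(dir, "selection.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  utils::write.table(report$stability$per_trace,
                     file.path(dir, "stability.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  if (!is.null(report$charges))
    utils::write.table(report$charges, file.path(dir, "charges.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(sno = as.data.frame(report$sno_table),
         selected = report$selected,
         mean_sno = as.list(report$mean_sno),
         stability = report$stability$per_trace,
         by_group = report$stability$by_group,
         charges = report$charges,
         provenance = report$provenance),
    file.path(dir, "report.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA)
  writeLines(c(
    sprintf("chisno %s report", report$provenance$version),
    sprintf("series analysed: %d", report$provenance$n_series),
    sprintf("selected residues: %s",
            paste(report$selected, collapse = ", "))),
    file.path(dir, "run.log"))
  invisible(dir)
}
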