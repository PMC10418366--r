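# Discrete protonation-state charge schemes and net protein charge.
#
# Classical MD cannot model pH explicitly; the conventional alternative is a
# fixed assignment of ionization states at topology level.  Three named
# schemes are supported for an enzyme carried from neutral to strongly
# acidic pH:
#   pH7     — Asp/Glu deprotonated (-1), His neutral, Lys/Arg +1;
#   pH2_all — Asp/Glu neutralized, every His protonated (+1), Lys/Arg +1;
#   pH2_his — as pH7 but with one designated catalytic His protonated (+1),
#             isolating the effect of that single protonation.
# Termini and cysteines (including the catalytic Cys, kept protonated and
# uncharged) contribute 0 in all schemes.

AA1 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
IONIZABLE <- c("D", "E", "H", "K", "R")

#' Construct a protein sequence with precursor numbering
#'
#' @param residues one-letter amino-acid codes, as a single string or a
#'   character vector.
#' @param numbering_offset integer such that chain position `i` carries the
#'   precursor label `i + numbering_offset`.  For a mature papain-family
#'   protease whose signal peptide plus propeptide span 115 residues, the
#'   offset is 115 (placing the catalytic triad at 138/275/295).
#' @return an object of class `protein_sequence`.
#' @export
protein_sequence <- function(residues, numbering_offset = 0L) {
  if (length(residues) == 1L && nchar(residues[1]) > 1L)
    residues <- strsplit(residues, "")[[1]]
  residues <- toupper(residues)
  bad <- setdiff(unique(residues), AA1)
  if (length(bad))
    stop_chisno(sprintf("non-canonical residue code(s): %s",
                        paste(bad, collapse = ", ")), "chisno_sequence_error")
  structure(
    list(residues = residues, numbering_offset = as.integer(numbering_offset)),
    class = "protein_sequence"
  )
}

#' @export
print.protein_sequence <- function(x, ...) {
  cat(sprintf("<protein_sequence> %d residues, labels %d-%d\n",
              length(x$residues), x$numbering_offset + 1L,
              x$numbering_offset + length(x$residues)))
  invisible(x)
}

#' Read a protein chain from a FASTA file
#'
#' @param path FASTA file with (at least) one amino-acid record; the first
#'   record is used.
#' @param numbering_offset precursor-numbering offset, see
#'   [protein_sequence()].
#' @return a `protein_sequence`.
#' @export
read_protein_fasta <- function(path, numbering_offset = 0L) {
  if (!file.exists(path))
    stop_chisno(sprintf("file not found: %s", path), "chisno_io_error")
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = FALSE,
                             set.attributes = FALSE)
  if (length(recs) == 0L)
    stop_chisno(sprintf("no sequences in %s", path), "chisno_empty_input")
  protein_sequence(toupper(recs[[1]]), numbering_offset = numbering_offset)
}

#' Path of the packaged synthetic mature-chain fixture
#'
#' A synthetic stand-in for the mature chain of the insect digestive
#' cathepsin L studied with this pipeline.  It is not the biological
#' sequence: it is constructed to carry exactly the ionizable-residue
#' composition of that enzyme's mature chain (14 Asp, 10 Glu, 2 His, 4 Lys,
#' 5 Arg) with the catalytic triad at precursor positions 138/275/295,
#' valine at 277, alanine at 251 and tryptophan at 297, under a
#' numbering offset of 115.  It exists so charge-scheme arithmetic can be
#' exercised end-to-end from FASTA input.
#'
#' @return path to the FASTA file.
#' @export
synthetic_mature_fasta <- function() {
  system.file("extdata", "tccathl1_mature_synthetic.fasta",
              package = "chisno", mustWork = TRUE)
}

#' Define a protonation charge scheme
#'
#' @param name one of `"pH7"`, `"pH2_all"`, `"pH2_his"`.
#' @param his_target precursor-numbered position of the catalytic histidine;
#'   required for `"pH2_his"` (default 275).
#' @return an object of class `charge_scheme` with a per-residue-type charge
#'   map.
#' @export
charge_scheme <- function(name = c("pH7", "pH2_all", "pH2_his"),
                          his_target = if (match.arg(name) == "pH2_his") 275L else NULL) {
  name <- match.arg(name)
  charges <- setNames(rep(0L, length(AA1)), AA1)
  if (name == "pH7") {
    charges[c("D", "E")] <- -1L
    charges[c("K", "R")] <- +1L
  } else if (name == "pH2_all") {
    charges[c("H", "K", "R")] <- +1L
  } else {
    charges[c("D", "E")] <- -1L
    charges[c("K", "R")] <- +1L
    if (is.null(his_target))
      stop_chisno("pH2_his scheme requires a his_target position",
                  "chisno_scheme_error")
  }
  structure(list(name = name, charges = charges,
                 his_target = if (!is.null(his_target)) as.integer(his_target)),
            class = "charge_scheme")
}

#' @export
print.charge_scheme <- function(x, ...) {
  nz <- x$charges[x$charges != 0]
  cat(sprintf("<charge_scheme> %s: %s%s\n", x$name,
              paste(sprintf("%s=%+d", names(nz), nz), collapse = " "),
              if (x$name == "pH2_his")
                sprintf("; His %d -> +1", x$his_target) else ""))
  invisible(x)
}

#' Count ionizable residues
#'
#' @param seq a [protein_sequence()] (or plain character vector of one-letter
#'   codes).
#' @return named integer vector with counts of D, E, H, K, R.
#' @export
count_ionizables <- function(seq) {
  res <- if (inherits(seq, "protein_sequence")) seq$residues else toupper(seq)
  vapply(setNames(IONIZABLE, IONIZABLE),
         function(a) sum(res == a), integer(1))
}

#' Net protein charge under a protonation scheme
#'
#' Sums per-residue integer charges; N/C termini and cysteines contribute
#' zero.  Accepts either a full sequence or bare ionizable counts.  With a
#' sequence and the `pH2_his` scheme, the designated position must resolve to
#' a histidine; with bare counts that check is impossible and the pH7 total
#' is incremented by one for the single protonated histidine.
#'
#' @param x a [protein_sequence()], or a named numeric vector of ionizable
#'   counts (names among D, E, H, K, R).
#' @param scheme a [charge_scheme()] or a scheme name.
#' @return integer net charge in elementary charge units.
#' @export
net_charge <- function(x, scheme) {
  if (is.character(scheme)) scheme <- charge_scheme(scheme)
  if (inherits(x, "protein_sequence")) {
    per_res <- scheme$charges[x$residues]
    if (scheme$name == "pH2_his") {
      pos <- scheme$his_target - x$numbering_offset
      if (pos < 1L || pos > length(x$residues) || x$residues[pos] != "H")
        stop_chisno(sprintf("pH2_his target %d is not a histidine in this chain",
                            scheme$his_target), "chisno_scheme_error")
      per_res[pos] <- per_res[pos] + 1L
    }
    return(as.integer(sum(per_res)))
  }
  counts <- x
  if (is.null(names(counts)) || !all(names(counts) %in% AA1))
    stop_chisno("counts must be named by one-letter residue codes",
                "chisno_schema_error")
  total <- sum(scheme$charges[names(counts)] * counts)
  if (scheme$name == "pH2_his") total <- total + 1L
  as.integer(total)
}

#' Parse a point mutation in X###Y notation
#'
#' @param x mutation string such as `"V277A"` (wild-type letter, precursor
#'   position, mutant letter).
#' @return an object of class `mutation`.
#' @export
parse_mutation <- function(x) {
  m <- regmatches(x, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", x))[[1]]
  if (length(m) != 4L)
    stop_chisno(sprintf("cannot parse mutation '%s' (expect e.g. V277A)", x),
                "chisno_mutation_error")
  structure(list(wild_type = toupper(m[2]), position = as.integer(m[3]),
                 mutant = toupper(m[4]), label = toupper(x)),
            class = "mutation")
}

#' Apply a point mutation to a protein sequence
#'
#' @param seq a [protein_sequence()].
#' @param m a [parse_mutation()] object or mutation string (`"V277A"`),
#'   positions in precursor numbering.
#' @return a new `protein_sequence` differing only at the mutated position.
#' @export
apply_mutation <- function(seq, m) {
  if (is.character(m)) m <- parse_mutation(m)
  pos <- m$position - seq$numbering_offset
  if (pos < 1L || pos > length(seq$residues))
    stop_chisno(sprintf("mutation %s: position outside the chain", m$label),
                "chisno_mutation_error")
  if (seq$residues[pos] != m$wild_type)
    stop_chisno(sprintf("mutation %s: wild-type letter is %s at position %d",
                        m$label, seq$residues[pos], m$position),
                "chisno_mutation_error")
  res <- seq$residues
  res[pos] <- m$mutant
  protein_sequence(res, numbering_offset = seq$numbering_offset)
}

#' Net-charge table over variants and schemes
#'
#' Convenience wrapper reproducing the variant-by-scheme charge roster of a
#' mutational study: net charge of the wild type and of each single mutant
#' under each requested scheme.
#'
#' @param seq a [protein_sequence()] (wild type).
#' @param mutations character vector of mutation strings (may be empty).
#' @param schemes character vector of scheme names.
#' @param his_target catalytic-histidine position for the `pH2_his` scheme.
#' @return data.frame with columns `variant`, `scheme`, `net_charge`.
#' @export
charge_table <- function(seq, mutations = character(),
                         schemes = c("pH7", "pH2_all", "pH2_his"),
                         his_target = 275L) {
  variants <- c(list(WT = seq),
                setNames(lapply(mutations, function(m) apply_mutation(seq, m)),
                         toupper(mutations)))
  rows <- lapply(names(variants), function(v) {
    data.frame(
      variant = v, scheme = schemes,
      net_charge = vapply(schemes, function(s) {
        sch <- charge_scheme(s, his_target = if (s == "pH2_his") his_target)
        net_charge(variants[[v]], sch)
      }, integer(1)),
      row.names = NULL
    )
  })
  do.call(rbind, rows)
}
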