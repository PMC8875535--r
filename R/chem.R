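# Atomic masses. Average: IUPAC standard atomic weights (2021, abridged);
# monoisotopic: lightest-isotope masses (AME).
ELEMENT_MASS <- list(
  average = c(C = 12.011, H = 1.008, N = 14.007, O = 15.999, S = 32.06,
              Br = 79.904),
  monoisotopic = c(C = 12, H = 1.00782503, N = 14.00307401, O = 15.99491462,
                   S = 31.97207117, Br = 78.91833760)
)

# residue mass lookup, memoized per mass kind
.chem_cache <- new.env(parent = emptyenv())

residue_masses <- function(kind = c("average", "monoisotopic")) {
  kind <- match.arg(kind)
  key <- paste0("residues_", kind)
  if (!is.null(.chem_cache[[key]])) return(.chem_cache[[key]])
  path <- system.file("extdata", "residue_masses.tsv", package = "haptenms")
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  el <- ELEMENT_MASS[[kind]]
  m <- as.matrix(tab[, c("C", "H", "N", "O", "S")]) %*%
    el[c("C", "H", "N", "O", "S")]
  out <- stats::setNames(drop(m), tab$aa)
  .chem_cache[[key]] <- out
  out
}

formula_mass <- function(counts, kind = c("average", "monoisotopic")) {
  kind <- match.arg(kind)
  el <- ELEMENT_MASS[[kind]]
  sum(el[names(counts)] * counts)
}

#' Describe a synthetic conjugation peptide
#'
#' Captures the construction pattern used for carrier-conjugation peptides:
#' `repeats` copies of the epitope, each followed by a linker (e.g. "GG"),
#' closed by a C-terminal cysteine whose thiol is the conjugation handle,
#' with optional N-terminal acetylation (serum-half-life extension) and a
#' free-acid or amidated C-terminus.
#'
#' @param epitope_sequence one-letter amino-acid string (20 canonical
#'   residues only).
#' @param repeats integer number of epitope copies per peptide (>= 1).
#' @param linker inter-repeat / pre-cysteine linker sequence
#'   (default `"GG"`); may be `""`.
#' @param terminal_cys append the C-terminal conjugation cysteine
#'   (default `TRUE`).
#' @param n_term_mod `"acetyl"` or `"none"`.
#' @param c_term `"free_acid"` or `"amide"`.
#' @return An object of class `peptide_design`.
#' @export
peptide_design <- function(epitope_sequence, repeats = 1L, linker = "GG",
                           terminal_cys = TRUE,
                           n_term_mod = c("acetyl", "none"),
                           c_term = c("free_acid", "amide")) {
  n_term_mod <- match.arg(n_term_mod)
  c_term <- match.arg(c_term)
  epitope_sequence <- toupper(epitope_sequence)
  linker <- toupper(linker)
  validate_sequence(epitope_sequence)
  if (nzchar(linker)) validate_sequence(linker)
  stopifnot(repeats >= 1)
  structure(list(epitope_sequence = epitope_sequence,
                 repeats = as.integer(repeats), linker = linker,
                 terminal_cys = terminal_cys,
                 n_term_mod = n_term_mod, c_term = c_term),
            class = "peptide_design")
}

validate_sequence <- function(seq) {
  letters1 <- strsplit(seq, "")[[1]]
  canon <- c("G","A","S","P","V","T","C","L","I","N","D","Q","K","E","M",
             "H","F","R","Y","W")
  bad <- setdiff(letters1, canon)
  if (length(bad)) {
    stop(sprintf("invalid residue letter(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  invisible(seq)
}

#' @export
print.peptide_design <- function(x, ...) {
  cat(sprintf("<peptide_design: %s(%s + %s) x %d %s, N-term %s, C-term %s>\n",
              if (x$n_term_mod == "acetyl") "Ac-" else "",
              x$epitope_sequence, x$linker, x$repeats,
              if (x$terminal_cys) "+ C" else "", x$n_term_mod, x$c_term))
  invisible(x)
}

design_sequence <- function(design) {
  paste0(strrep(paste0(design$epitope_sequence, design$linker), design$repeats),
         if (design$terminal_cys) "C" else "")
}

#' Mass of a sequence or peptide design
#'
#' Sums residue masses plus one water, plus terminal-modification deltas:
#' acetylation adds C2H2O (+42.011 mono / +42.037 average); amidation
#' replaces the C-terminal OH by NH2 (-0.984).  For a [peptide_design()]
#' the full assembled sequence `(epitope + linker) x repeats + Cys` is
#' used.
#'
#' @param design a [peptide_design()] or a plain one-letter sequence
#'   string (treated as unmodified, free termini).
#' @param kind `"average"` (default; appropriate for isotopically
#'   unresolved linear-MALDI work) or `"monoisotopic"`.
#' @return Neutral mass in Da.
#' @export
peptide_mass <- function(design, kind = c("average", "monoisotopic")) {
  kind <- match.arg(kind)
  if (is.character(design)) {
    design <- peptide_design(design, repeats = 1L, linker = "",
                             terminal_cys = FALSE, n_term_mod = "none")
  }
  stopifnot(inherits(design, "peptide_design"))
  seq <- design_sequence(design)
  rm_ <- residue_masses(kind)
  letters1 <- strsplit(seq, "")[[1]]
  m <- sum(rm_[letters1]) + formula_mass(c(H = 2, O = 1), kind)
  if (design$n_term_mod == "acetyl") m <- m + formula_mass(c(C = 2, H = 2, O = 1), kind)
  if (design$c_term == "amide") {
    m <- m + formula_mass(c(N = 1, H = 1), kind) - formula_mass(c(O = 1), kind)
  }
  unname(m)
}

#' Describe the conjugation chemistry
#'
#' @param linker_remnant_mass mass (Da) added per conjugated peptide beyond
#'   the peptide mass: the crosslinker remnant bridging carrier and peptide
#'   after coupling and leaving-group loss.
#' @param capping_adduct_mass mass (Da) carried by each activated but
#'   unconjugated site after capping.
#' @param n_activatable_sites number of reactive carrier sites.
#' @return An object of class `conjugation_chemistry`.
#' @seealso [sbap_chemistry()]
#' @export
conjugation_chemistry <- function(linker_remnant_mass, capping_adduct_mass = 0,
                                  n_activatable_sites = 20L) {
  stopifnot(linker_remnant_mass >= 0, capping_adduct_mass >= 0,
            n_activatable_sites >= 1)
  structure(list(linker_remnant_mass = linker_remnant_mass,
                 capping_adduct_mass = capping_adduct_mass,
                 n_activatable_sites = as.integer(n_activatable_sites)),
            class = "conjugation_chemistry")
}

#' SBAP / cysteine-capping chemistry constants
#'
#' Arithmetic for the heterobifunctional crosslinker SBAP (succinimidyl
#' 3-(bromoacetamido)propionate), which acylates carrier lysine amines
#' (NHS leaves) and then alkylates a peptide cysteine thiol (HBr leaves).
#' The bridging remnant beyond the intact peptide mass is C5H6NO2; an
#' activated site capped with free cysteine instead carries C8H13N2O4S.
#' Both are computed from their element compositions, not hard-coded.
#'
#' @param n_sites number of activatable (solvent-accessible lysine) sites
#'   per carrier; ~20 of the 39 lysines of CRM197.
#' @param kind `"average"` or `"monoisotopic"`.
#' @return A [conjugation_chemistry()].
#' @export
sbap_chemistry <- function(n_sites = 20L, kind = c("average", "monoisotopic")) {
  kind <- match.arg(kind)
  remnant <- formula_mass(c(C = 5, H = 6, N = 1, O = 2), kind)
  capped <- formula_mass(c(C = 8, H = 13, N = 2, O = 4, S = 1), kind)
  conjugation_chemistry(linker_remnant_mass = remnant,
                        capping_adduct_mass = capped,
                        n_activatable_sites = n_sites)
}

#' Neutral mass gained by the carrier per conjugated peptide
#'
#' `delta = peptide_mass(design) + linker_remnant_mass`.
#'
#' @param design a [peptide_design()].
#' @param chem a [conjugation_chemistry()].
#' @param kind `"average"` or `"monoisotopic"`.
#' @return The ladder spacing in Da.
#' @export
ladder_spacing <- function(design, chem, kind = c("average", "monoisotopic")) {
  stopifnot(inherits(chem, "conjugation_chemistry"))
  peptide_mass(design, kind) + chem$linker_remnant_mass
}

#' Strict percent identity of two aligned sequences
#'
#' `100 * matches / length` over two equal-length, ungapped sequences.
#' This is strict identity: conservative substitutions are not counted, so
#' values can differ from published "similarity" figures computed with a
#' substitution scheme.
#'
#' @param seq_a,seq_b one-letter sequences of equal length.
#' @return The percentage (numeric; round as needed for reporting).
#' @export
percent_identity <- function(seq_a, seq_b) {
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  if (length(a) != length(b)) {
    stop("sequences must have equal length (ungapped alignment)", call. = FALSE)
  }
  100 * sum(a == b) / length(a)
}

#' Neutral masses of the conjugate species ladder
#'
#' `mass(n) = carrier_mass + n_capped * capping_adduct_mass + n * delta`
#' with `delta` from [ladder_spacing()].  Under the default `"all_capped"`
#' policy every activated but unconjugated site is capped
#' (`n_capped = n_activatable_sites - n`), so the observable spacing
#' between consecutive species is `delta - capping_adduct_mass` (a capped
#' site is replaced by a conjugated one); with `capping = "none"`,
#' `n_capped = 0` and the spacing is `delta` exactly.
#'
#' @param carrier_mass neutral mass (Da) of the bare carrier protein.
#' @param design a [peptide_design()].
#' @param chem a [conjugation_chemistry()].
#' @param n_range integer `c(n_min, n_max)` within
#'   `[0, n_activatable_sites]`.
#' @param capping `"all_capped"` (default) or `"none"`.
#' @param kind `"average"` or `"monoisotopic"`.
#' @return Data frame with columns `load` and `mass` (Da).
#' @export
predict_species_masses <- function(carrier_mass, design, chem,
                                   n_range = c(0L, 10L),
                                   capping = c("all_capped", "none"),
                                   kind = c("average", "monoisotopic")) {
  capping <- match.arg(capping)
  kind <- match.arg(kind)
  stopifnot(inherits(chem, "conjugation_chemistry"),
            length(n_range) == 2, n_range[1] >= 0)
  if (n_range[2] > chem$n_activatable_sites) {
    stop("n_max exceeds the number of activatable sites", call. = FALSE)
  }
  n <- seq.int(n_range[1], n_range[2])
  delta <- ladder_spacing(design, chem, kind)
  n_capped <- if (capping == "all_capped") chem$n_activatable_sites - n else 0
  data.frame(load = n,
             mass = carrier_mass + n_capped * chem$capping_adduct_mass +
               n * delta)
}

#' Build a fit-ready conjugate ladder from a design
#'
#' Convenience bridge from chemistry to deconvolution: computes the
#' species masses with [predict_species_masses()] and returns a
#' [conjugate_ladder()] with `M0` the load-0 species mass and `delta` the
#' observable inter-species spacing.
#'
#' @inheritParams predict_species_masses
#' @param z charge state of the series to fit.
#' @return A [conjugate_ladder()].
#' @export
design_ladder <- function(carrier_mass, design, chem, z = 2L,
                          n_range = c(0L, 10L),
                          capping = c("all_capped", "none"),
                          kind = c("average", "monoisotopic")) {
  sm <- predict_species_masses(carrier_mass, design, chem,
                               n_range = c(0L, max(1L, n_range[2])),
                               capping = capping, kind = kind)
  conjugate_ladder(M0 = sm$mass[1], delta = sm$mass[2] - sm$mass[1], z = z,
                   n_min = n_range[1], n_max = n_range[2])
}

#' Bundled IL-17RB inactivation-site (IRIS) epitope sequences
#'
#' The 13-residue linear epitope at positions 19-31 of IL-17RB in three
#' species, and the synthesized peptide designs built on the mouse and
#' human homologs (N-terminal acetyl, GG linker after each epitope copy,
#' C-terminal conjugation cysteine; the tandem designs carry two epitope
#' copies).
#'
#' @return `iris_sequences()`: named character vector of the bovine, mouse
#'   and human epitopes.  `iris_design(name)`: a [peptide_design()] for
#'   `"mIRIS1"`, `"mIRIS2"`, `"hIRIS1"` or `"hIRIS2"`.
#' @export
iris_sequences <- function() {
  c(bIRIS = "VRHTLTPGDLRDL",
    mIRIS = "VQHTLTPGDLRDL",
    hIRIS = "LQHDLIPGDLRDL")
}

#' @rdname iris_sequences
#' @param name design name.
#' @export
iris_design <- function(name = c("mIRIS1", "mIRIS2", "hIRIS1", "hIRIS2")) {
  name <- match.arg(name)
  seqs <- iris_sequences()
  epitope <- if (startsWith(name, "m")) seqs[["mIRIS"]] else seqs[["hIRIS"]]
  repeats <- if (endsWith(name, "2")) 2L else 1L
  peptide_design(epitope, repeats = repeats, linker = "GG",
                 terminal_cys = TRUE, n_term_mod = "acetyl")
}

#' Read peptide sequences from a FASTA file
#'
#' @param path FASTA file of amino-acid sequences (via \pkg{Biostrings}).
#' @return Named character vector of sequences.
#' @export
read_sequences_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("FASTA support requires the 'Biostrings' package", call. = FALSE)
  }
  ss <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(ss), names(ss))
}
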