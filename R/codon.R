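# Standard genetic code, DNA alphabet (T == U). Housed here because
# recoding consequences of A-to-I edits are called against it directly.
.CODON_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

# Four-class amino-acid property scheme used to flag chemistry-changing
# substitutions.
.AA_PROPERTY <- c(
  A = "nonpolar", V = "nonpolar", L = "nonpolar", I = "nonpolar",
  P = "nonpolar", M = "nonpolar", F = "nonpolar", W = "nonpolar",
  G = "nonpolar",
  S = "polar-uncharged", T = "polar-uncharged", C = "polar-uncharged",
  Y = "polar-uncharged", N = "polar-uncharged", Q = "polar-uncharged",
  K = "positively-charged", R = "positively-charged",
  H = "positively-charged",
  D = "negatively-charged", E = "negatively-charged")

#' Translate a DNA/RNA codon with the standard genetic code
#'
#' @param codon 3-letter string; U is accepted as T.
#' @return One-letter amino acid code, `"*"` for stop.
#' @export
translate_codon <- function(codon) {
  codon <- gsub("U", "T", toupper(codon))
  if (!codon %in% names(.CODON_TABLE)) stop("not a codon: ", codon)
  unname(.CODON_TABLE[codon])
}

#' Recoding consequence of a single-base codon substitution
#'
#' Substitutes `edited_base` at `edit_offset` (0-based, 0..2) within
#' `codon` and compares the translations. In A-to-I mode (the default)
#' the reference base at the offset must be `A`: inosine is read as
#' guanosine by the translation machinery, so the edited base is `G`.
#'
#' @param codon reference codon (sense-strand, 3 letters, T==U).
#' @param edit_offset 0-based offset of the edited base within the codon.
#' @param edited_base replacement base (default `"G"`).
#' @param require_a enforce that the reference base at the offset is `A`.
#' @return List with `consequence` (one of `synonymous`, `missense`,
#'   `stop_gained`, `stop_lost`, `stop_retained`), `aa_before`,
#'   `aa_after`, `property_change` (TRUE iff both are amino acids whose
#'   property classes differ), `codon_before`, `codon_after`.
#' @export
codon_consequence <- function(codon, edit_offset, edited_base = "G",
                              require_a = TRUE) {
  codon <- gsub("U", "T", toupper(codon))
  stopifnot(edit_offset >= 0, edit_offset <= 2)
  if (!codon %in% names(.CODON_TABLE)) stop("not a codon: ", codon)
  ref_base <- substr(codon, edit_offset + 1, edit_offset + 1)
  if (require_a && ref_base != "A")
    stop("inconsistent site call: reference base at offset ", edit_offset,
         " of codon ", codon, " is ", ref_base, ", not A")
  after <- codon
  substr(after, edit_offset + 1, edit_offset + 1) <- toupper(edited_base)
  aa_before <- translate_codon(codon)
  aa_after <- translate_codon(after)
  consequence <-
    if (aa_before == "*" && aa_after == "*") "stop_retained"
    else if (aa_before == "*") "stop_lost"
    else if (aa_after == "*") "stop_gained"
    else if (aa_before == aa_after) "synonymous"
    else "missense"
  property_change <- aa_before != "*" && aa_after != "*" &&
    .AA_PROPERTY[[aa_before]] != .AA_PROPERTY[[aa_after]]
  list(consequence = consequence, aa_before = aa_before,
       aa_after = aa_after, property_change = property_change,
       codon_before = codon, codon_after = after)
}
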