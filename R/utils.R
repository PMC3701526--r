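# Canonical 37-gene vocabulary of the insect mitogenome ---------------------

#' Canonical mitochondrial gene names
#'
#' The 37 genes usually present in animal mitochondrial genomes, in the
#' naming convention used throughout the package: 13 protein-coding genes
#' (PCGs), 22 tRNAs (with the two leucine and two serine isoacceptors
#' distinguished as `trnL1`/`trnL2` and `trnS1`/`trnS2`), the two rRNAs,
#' plus the control region label `CR`.
#'
#' @return A character vector of gene labels.
#' @export
mito_gene_vocabulary <- function() {
  c(pcg_genes(), trna_genes(), rrna_genes(), "CR")
}

pcg_genes <- function() {
  c("atp6", "atp8", "cox1", "cox2", "cox3", "cob",
    "nad1", "nad2", "nad3", "nad4", "nad4L", "nad5", "nad6")
}

trna_genes <- function() {
  paste0("trn", c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L1", "L2",
                  "M", "N", "P", "Q", "R", "S1", "S2", "T", "V", "W", "Y"))
}

rrna_genes <- function() c("rrnS", "rrnL")

# Conventional anticodons (DNA alphabet) for the 22 insect mito tRNAs.
trna_anticodons <- function() {
  c(trnA = "TGC", trnC = "GCA", trnD = "GTC", trnE = "TTC", trnF = "GAA",
    trnG = "TCC", trnH = "GTG", trnI = "GAT", trnK = "TTT", trnL1 = "TAG",
    trnL2 = "TAA", trnM = "CAT", trnN = "GTT", trnP = "TGG", trnQ = "TTG",
    trnR = "TCG", trnS1 = "TCT", trnS2 = "TGA", trnT = "TGT", trnV = "TAC",
    trnW = "TCA", trnY = "GTA")
}

# Sequence helpers -----------------------------------------------------------

revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  comp <- chartr("ACGTN", "TGCAN", seq)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

#' The invertebrate mitochondrial genetic code
#'
#' Returns the codon-to-amino-acid map of NCBI translation table 5
#' (invertebrate mitochondrial), in which AGA/AGG encode serine, TGA encodes
#' tryptophan and ATA encodes methionine, leaving TAA and TAG as the only
#' stop codons (62 sense codons).
#'
#' @param code Genetic code identifier understood by
#'   [Biostrings::getGeneticCode()]; default `"5"`.
#' @return Named character vector mapping DNA codons to one-letter amino
#'   acids, with `"*"` for stops.
#' @export
mito_genetic_code <- function(code = "5") {
  Biostrings::getGeneticCode(code)
}

translate_codon <- function(codon, code) {
  aa <- unname(code[codon])
  if (is.na(aa)) NA_character_ else aa
}

# Name canonicalization ------------------------------------------------------

gene_alias_map <- function() {
  aliases <- c(
    COI = "cox1", COII = "cox2", COIII = "cox3", CO1 = "cox1", CO2 = "cox2",
    CO3 = "cox3", COX1 = "cox1", COX2 = "cox2", COX3 = "cox3",
    CYTB = "cob", CYB = "cob", COB = "cob",
    ND1 = "nad1", ND2 = "nad2", ND3 = "nad3", ND4 = "nad4", ND4L = "nad4L",
    ND5 = "nad5", ND6 = "nad6", NAD4L = "nad4L",
    ATP6 = "atp6", ATP8 = "atp8", ATPASE6 = "atp6", ATPASE8 = "atp8",
    `12S` = "rrnS", `16S` = "rrnL", SRRNA = "rrnS", LRRNA = "rrnL",
    RRN12 = "rrnS", RRN16 = "rrnL", RRNS = "rrnS", RRNL = "rrnL",
    `D-LOOP` = "CR", DLOOP = "CR", `A+T-RICH` = "CR", `AT-RICH` = "CR",
    `CONTROL REGION` = "CR", `CONTROL_REGION` = "CR"
  )
  aliases
}

# One-letter amino acid to three-letter, for tRNA product names.
aa_three_letter <- function() {
  c(A = "Ala", C = "Cys", D = "Asp", E = "Glu", F = "Phe", G = "Gly",
    H = "His", I = "Ile", K = "Lys", L = "Leu", M = "Met", N = "Asn",
    P = "Pro", Q = "Gln", R = "Arg", S = "Ser", T = "Thr", V = "Val",
    W = "Trp", Y = "Tyr")
}

#' Canonicalize a mitochondrial gene name
#'
#' Maps common aliases (`COI`, `ND5`, `lrRNA`, `D-loop`, `tRNA-Ser`, ...) onto
#' the package's canonical vocabulary. tRNA product names are disambiguated
#' by anticodon where the amino acid has two isoacceptors (Leu, Ser).
#'
#' @param name Gene name as found in an annotation.
#' @param anticodon Optional anticodon triplet (DNA or RNA alphabet), used to
#'   resolve `trnL1`/`trnL2` and `trnS1`/`trnS2`.
#' @return Canonical gene label; the input (unchanged) if unrecognized.
#' @export
canonical_gene_name <- function(name, anticodon = NA_character_) {
  if (is.na(name) || !nzchar(name)) return(NA_character_)
  if (name %in% mito_gene_vocabulary()) return(name)
  up <- toupper(trimws(name))
  amap <- gene_alias_map()
  if (up %in% names(amap)) return(unname(amap[[up]]))
  # tRNA styles: "tRNA-Ser", "trnS", "trnS1", "tRNA-Leu(UAG)"
  m <- regmatches(up, regexec("^TRNA?[-_ ]?([A-Z]{1,3})([0-9]?)", up))[[1]]
  if (length(m) == 3 && nzchar(m[2])) {
    aa3 <- aa_three_letter()
    one <- if (m[2] %in% toupper(aa3)) names(aa3)[toupper(aa3) == m[2]] else
      if (m[2] %in% names(aa3)) m[2] else NA_character_
    if (!is.na(one)) {
      base <- paste0("trn", one)
      if (one %in% c("L", "S")) {
        if (nzchar(m[3])) return(paste0(base, m[3]))
        ac <- toupper(chartr("U", "T", anticodon %||% NA_character_))
        if (!is.na(ac)) {
          if (one == "L") return(if (ac == "TAG") "trnL1" else "trnL2")
          if (one == "S") return(if (ac %in% c("TCT", "GCT")) "trnS1" else "trnS2")
        }
        return(paste0(base, "2"))
      }
      return(base)
    }
  }
  name
}

stop_codons <- function(code) names(code)[code == "*"]
sense_codons <- function(code) names(code)[code != "*"]

all_codons <- function() {
  b <- c("T", "C", "A", "G")
  g <- expand.grid(p3 = b, p2 = b, p1 = b, stringsAsFactors = FALSE)
  paste0(g$p1, g$p2, g$p3)
}
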