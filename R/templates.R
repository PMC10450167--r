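#' @title Idealized nucleotide templates
#' @description The package ships idealized heavy-atom monomer geometries for
#'   the eight standard ribo-/deoxyribonucleotides plus two modified residues
#'   (pseudouridine, 1-methyladenosine) used in tests. They provide the base
#'   atoms for rebuilding, the guanine geometry that defines the descriptor
#'   sampling cloud, and the building blocks of the idealized duplex
#'   generator.
#' @name templates
NULL

.na_cache <- new.env(parent = emptyenv())

# sugar-phosphate atom names shared across nucleotide templates (RNA also O2')
BACKBONE_ATOMS <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "C3'", "O3'",
                    "C2'", "C1'", "O4'")
RIBOSE_RING_ATOMS <- c("C1'", "C2'", "C3'", "C4'", "O4'")
ANCHOR_ATOMS <- c("C2'", "C1'", "O4'")

template_table <- function() {
  if (!is.null(.na_cache$templates)) return(.na_cache$templates)
  path <- system.file("extdata", "nucleotide_templates.tsv",
                      package = "nucassign", mustWork = TRUE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           comment.char = "#", stringsAsFactors = FALSE)
  .na_cache$templates <- tab
  tab
}

#' Retrieve an idealized nucleotide template as a residue object
#'
#' @param code residue code, e.g. "G", "DA", "PSU"
#' @return a `na_residue` (see [new_residue()]) with idealized coordinates
#' @export
nucleotide_template <- function(code) {
  tab <- template_table()
  sel <- tab[tab$res == code, , drop = FALSE]
  if (nrow(sel) == 0L) stop("no template for residue code '", code, "'")
  new_residue(name = code, seqid = 1L, chain_id = "T",
              xyz = as.matrix(sel[, c("x", "y", "z")]),
              atom_names = sel$atom, elements = sel$element)
}

is_purine_code <- function(code) code %in% c("A", "G", "DA", "DG")
is_pyrimidine_code <- function(code) code %in% c("C", "U", "T", "DC", "DT", "DU")
is_standard_code <- function(code) is_purine_code(code) || is_pyrimidine_code(code)

#' One-letter base identity from a residue code ("DA" -> "A"); NA if unknown
#' @keywords internal
base_letter <- function(code) {
  map <- c(A = "A", G = "G", C = "C", U = "U", T = "T",
           DA = "A", DG = "G", DC = "C", DT = "T", DU = "U")
  unname(map[code])
}

#' Residue code for a base letter in a given chain kind ("A","RNA" -> "A";
#' "A","DNA" -> "DA")
#' @keywords internal
residue_code <- function(letter, kind) {
  letter <- toupper(letter)
  if (kind == "RNA") {
    if (letter == "T") letter <- "U"
    return(letter)
  }
  if (letter == "U") letter <- "T"
  paste0("D", letter)
}

wc_complement_letter <- function(letter, kind) {
  comp <- c(A = if (kind == "RNA") "U" else "T", G = "C", C = "G",
            U = "A", T = "A")
  unname(comp[toupper(letter)])
}

letter_class <- function(letters) {
  # 1 = purine, 2 = pyrimidine, 0 = unknown/N
  cls <- integer(length(letters))
  up <- toupper(letters)
  cls[up %in% c("A", "G", "R")] <- 1L
  cls[up %in% c("C", "U", "T", "Y")] <- 2L
  cls
}

#' Glycosidic nitrogen name for a residue ("N9" purine, "N1" pyrimidine)
#' @keywords internal
glycosidic_atom <- function(residue) {
  cls <- base_moiety_class(residue)
  if (cls == "PURINE") "N9" else "N1"
}

# atoms belonging to the base moiety = everything not sugar/phosphate
base_atom_names <- function(residue) {
  setdiff(residue$atom_names, c(BACKBONE_ATOMS, "O2'", "OP3"))
}
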