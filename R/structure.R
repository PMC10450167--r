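#' @title Atomic models: residues, chains, structures
#' @description Lightweight S3 containers for nucleic-acid models. A residue
#'   holds a named coordinate matrix; a chain is an ordered list of residues
#'   classified as RNA or DNA; a structure is a set of chains plus optional
#'   unit cell. PDB/mmCIF parsing is delegated to bio3d.
#' @name structure
NULL

#' Construct a residue
#'
#' @param name residue code (up to 3 characters)
#' @param seqid integer author sequence id
#' @param icode insertion code ("" if none)
#' @param chain_id chain identifier
#' @param xyz n x 3 coordinate matrix (Angstrom)
#' @param atom_names character vector of atom names (unique)
#' @param elements element symbols
#' @param occ occupancies (default 1)
#' @param b isotropic B factors (default 0)
#' @return object of class `na_residue`
#' @export
new_residue <- function(name, seqid, chain_id, xyz, atom_names, elements,
                        icode = "", occ = NULL, b = NULL) {
  xyz <- as.matrix(xyz)
  dimnames(xyz) <- NULL
  stopifnot(ncol(xyz) == 3, nrow(xyz) == length(atom_names),
            all(is.finite(xyz)))
  if (anyDuplicated(atom_names)) stop("duplicate atom names in residue")
  if (is.null(occ)) occ <- rep(1, nrow(xyz))
  if (is.null(b)) b <- rep(0, nrow(xyz))
  structure(list(name = name, seqid = as.integer(seqid), icode = icode,
                 chain_id = chain_id, xyz = xyz,
                 atom_names = as.character(atom_names),
                 elements = as.character(elements),
                 occ = occ, b = b),
            class = "na_residue")
}

#' Look up atom coordinates in a residue by name
#' @param residue a `na_residue`
#' @param names atom names
#' @param required error if missing (default) or return NULL
#' @return length(names) x 3 matrix (single name: numeric length 3)
#' @export
atom_xyz <- function(residue, names, required = TRUE) {
  idx <- match(names, residue$atom_names)
  if (anyNA(idx)) {
    if (required) {
      stop("residue ", residue$chain_id, "/", residue$seqid, " (",
           residue$name, ") lacks atom(s): ",
           paste(names[is.na(idx)], collapse = ", "))
    }
    return(NULL)
  }
  out <- residue$xyz[idx, , drop = FALSE]
  if (length(names) == 1L) as.numeric(out) else out
}

has_atoms <- function(residue, names) all(names %in% residue$atom_names)

residue_key <- function(residue) {
  paste(residue$chain_id, residue$seqid, residue$icode, sep = ":")
}

#' Construct a nucleic chain
#' @param chain_id chain identifier
#' @param residues list of `na_residue`, ordered by (seqid, icode)
#' @param kind "RNA" or "DNA"; if NULL, inferred by majority vote on the
#'   presence of O2' atoms
#' @return object of class `na_chain`
#' @export
new_chain <- function(chain_id, residues, kind = NULL) {
  ord <- order(vapply(residues, function(r) r$seqid, integer(1)),
               vapply(residues, function(r) r$icode, character(1)))
  residues <- residues[ord]
  if (is.null(kind)) {
    n_o2 <- sum(vapply(residues, function(r) "O2'" %in% r$atom_names,
                       logical(1)))
    kind <- if (n_o2 * 2 >= length(residues)) "RNA" else "DNA"
  }
  structure(list(chain_id = chain_id, residues = residues, kind = kind),
            class = "na_chain")
}

#' Construct a structure
#' @param chains list of `na_chain` (unique chain ids)
#' @param cell unit-cell parameters (a,b,c,alpha,beta,gamma) or NULL
#' @param title free-text title
#' @return object of class `na_structure`
#' @export
new_structure <- function(chains, cell = NULL, title = "") {
  ids <- vapply(chains, function(ch) ch$chain_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate chain ids")
  names(chains) <- ids
  structure(list(chains = chains, cell = cell, title = title),
            class = "na_structure")
}

#' @export
print.na_structure <- function(x, ...) {
  cat("<na_structure>", x$title, "\n")
  for (ch in x$chains) {
    cat(sprintf("  chain %s: %d %s residues\n", ch$chain_id,
                length(ch$residues), ch$kind))
  }
  invisible(x)
}

#' All nucleic residues of a structure, chain by chain
#' @param model `na_structure`
#' @return flat list of `na_residue`
#' @export
all_residues <- function(model) {
  unlist(lapply(model$chains, function(ch) ch$residues), recursive = FALSE,
         use.names = FALSE)
}

#' Find a residue by key "chain:seqid:icode" (or chain + seqid)
#' @keywords internal
get_residue <- function(model, chain_id, seqid, icode = "") {
  ch <- model$chains[[chain_id]]
  if (is.null(ch)) return(NULL)
  for (r in ch$residues) {
    if (r$seqid == seqid && r$icode == icode) return(r)
  }
  NULL
}

#' Apply a rigid transform to every atom of a structure
#' @param model `na_structure`
#' @param tr rigid transform from [kabsch()] or `rigid()`
#' @return transformed structure (metadata preserved)
#' @export
transform_structure <- function(model, tr) {
  model$chains <- lapply(model$chains, function(ch) {
    ch$residues <- lapply(ch$residues, function(r) {
      r$xyz <- apply_rigid(tr, r$xyz)
      r
    })
    ch
  })
  model
}

NUCLEIC_CODES <- c("A", "G", "C", "U", "T", "DA", "DG", "DC", "DT", "DU",
                   "PSU", "1MA", "I", "DI")

looks_nucleic <- function(res_name, atom_names) {
  res_name %in% NUCLEIC_CODES ||
    (("C1'" %in% atom_names) && any(c("N9", "N1") %in% atom_names) &&
       any(c("O4'", "C4'") %in% atom_names))
}

#' Read an atomic model from PDB or mmCIF
#'
#' Dialect is chosen by extension (`.cif`/`.mmcif` vs anything else), falling
#' back on content sniffing. Polynucleotide chains are captured as ordered
#' [new_chain()] objects; everything else (protein, ligands, waters) is
#' ignored by downstream operations. For alternate conformations the highest
#' occupancy conformer is kept (ties favour altloc "A"). Hydrogens are
#' dropped.
#'
#' @param path file path
#' @return `na_structure`
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  is_cif <- ext %in% c("cif", "mmcif")
  if (!is_cif && !ext %in% c("pdb", "ent", "brk")) {
    head_lines <- readLines(path, n = 50L, warn = FALSE)
    is_cif <- any(grepl("^data_|^loop_", head_lines))
  }
  pdb <- tryCatch(
    suppressWarnings(
      if (is_cif) bio3d::read.cif(path, verbose = FALSE)
      else bio3d::read.pdb(path, verbose = FALSE)),
    error = function(e) stop("failed to parse '", path, "': ",
                             conditionMessage(e)))
  at <- pdb$atom
  # mmCIF values may come back with their surrounding quotes; strip only
  # matching pairs (atom names like C5' end in a legitimate prime)
  for (col in c("elety", "resid", "chain", "elesy")) {
    at[[col]] <- sub("^'(.*)'$", "\\1", sub('^"(.*)"$', "\\1", at[[col]]))
  }
  at <- at[at$elesy != "H" & !grepl("^H", at$elety), , drop = FALSE]
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  at$b[is.na(at$b)] <- 0
  chains <- list()
  for (cid in unique(at$chain)) {
    ca <- at[at$chain == cid, , drop = FALSE]
    keys <- paste(ca$resno, ca$insert, ca$resid, sep = "|")
    residues <- list()
    for (k in unique(keys)) {
      ra <- ca[keys == k, , drop = FALSE]
      # altloc policy: per atom name keep highest occupancy, ties -> "A"
      if (any(ra$alt != "")) {
        ra <- ra[order(ra$elety, -ra$o, ra$alt), , drop = FALSE]
        ra <- ra[!duplicated(ra$elety), , drop = FALSE]
      }
      if (!looks_nucleic(ra$resid[1], ra$elety)) next
      residues[[length(residues) + 1L]] <- new_residue(
        name = ra$resid[1], seqid = ra$resno[1], icode = ra$insert[1],
        chain_id = cid, xyz = cbind(ra$x, ra$y, ra$z),
        atom_names = ra$elety, elements = ra$elesy, occ = ra$o, b = ra$b)
    }
    if (length(residues) > 0L) {
      chains[[length(chains) + 1L]] <- new_chain(cid, residues)
    }
  }
  cell <- NULL
  if (!is.null(pdb$cryst1) && length(pdb$cryst1$abc) == 3 &&
      all(is.finite(pdb$cryst1$abc))) {
    cell <- c(pdb$cryst1$abc, pdb$cryst1$angles)
  }
  new_structure(chains, cell = cell, title = basename(path))
}

#' Write a structure to PDB or mmCIF
#'
#' @param model `na_structure`
#' @param path output path; format chosen by extension (`.cif` -> mmCIF,
#'   otherwise PDB)
#' @return `path`, invisibly
#' @export
write_structure <- function(model, path) {
  res <- all_residues(model)
  n <- sum(vapply(res, function(r) nrow(r$xyz), integer(1)))
  df <- data.frame(
    serial = seq_len(n),
    name = unlist(lapply(res, `[[`, "atom_names")),
    resn = rep(vapply(res, `[[`, "", "name"),
               vapply(res, function(r) nrow(r$xyz), integer(1))),
    chain = rep(vapply(res, `[[`, "", "chain_id"),
                vapply(res, function(r) nrow(r$xyz), integer(1))),
    seqid = rep(vapply(res, function(r) r$seqid, integer(1)),
                vapply(res, function(r) nrow(r$xyz), integer(1))),
    icode = rep(vapply(res, `[[`, "", "icode"),
                vapply(res, function(r) nrow(r$xyz), integer(1))),
    stringsAsFactors = FALSE)
  xyz <- do.call(rbind, lapply(res, `[[`, "xyz"))
  df$occ <- unlist(lapply(res, `[[`, "occ"))
  df$b <- unlist(lapply(res, `[[`, "b"))
  df$element <- unlist(lapply(res, `[[`, "elements"))
  if (tolower(tools::file_ext(path)) %in% c("cif", "mmcif")) {
    qn <- paste0('"', df$name, '"')
    ic <- ifelse(df$icode == "", "?", df$icode)
    lines <- c("data_nucassign",
               "#",
               "loop_",
               paste0("_atom_site.",
                      c("group_PDB", "id", "type_symbol", "label_atom_id",
                        "label_alt_id", "label_comp_id", "label_asym_id",
                        "label_entity_id", "label_seq_id",
                        "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y",
                        "Cartn_z", "occupancy", "B_iso_or_equiv",
                        "pdbx_formal_charge", "auth_seq_id",
                        "auth_comp_id", "auth_asym_id", "auth_atom_id",
                        "pdbx_PDB_model_num")),
               sprintf("ATOM %d %s %s . %s %s 1 %d %s %.3f %.3f %.3f %.2f %.2f ? %d %s %s %s 1",
                       df$serial, df$element, qn, df$resn, df$chain,
                       df$seqid, ic, xyz[, 1], xyz[, 2], xyz[, 3], df$occ,
                       df$b, df$seqid, df$resn, df$chain, qn),
               "#")
    writeLines(lines, path)
  } else {
    fmt_name <- function(nm) {
      # PDB atom-name column convention: pad to 4, start in column 14
      ifelse(nchar(nm) >= 4, substr(nm, 1, 4), sprintf(" %-3s", nm))
    }
    lines <- sprintf(
      "ATOM  %5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      df$serial %% 100000, fmt_name(df$name), "", df$resn, df$chain,
      df$seqid %% 10000, df$icode, xyz[, 1], xyz[, 2], xyz[, 3], df$occ,
      df$b, df$element)
    header <- character(0)
    if (!is.null(model$cell)) {
      header <- sprintf(
        "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1", model$cell[1],
        model$cell[2], model$cell[3], model$cell[4], model$cell[5],
        model$cell[6])
    }
    writeLines(c(header, lines, "END"), path)
  }
  invisible(path)
}

#' Split a chain into continuous polynucleotide fragments
#'
#' Fragments are maximal runs of residues where the O3'(i) to P(i+1) distance
#' does not exceed `bond_cutoff`. Connectivity, not residue numbering,
#' decides: numbering gaps with bonded geometry stay in one fragment.
#' Residues missing both P and O3' break the chain (and are reported via a
#' message).
#'
#' @param chain `na_chain`
#' @param bond_cutoff maximum O3'-P distance treated as a covalent linkage
#'   (Angstrom; the covalent bond is about 1.6)
#' @return list of fragments; each is a list with `chain_id`, `start`
#'   (seqid), `length` and `residues`
#' @export
chain_fragments <- function(chain, bond_cutoff = 2.5) {
  res <- chain$residues
  if (length(res) == 0L) stop("empty chain")
  breaks <- logical(length(res) - 1L)
  if (length(res) > 1L) {
    for (i in seq_len(length(res) - 1L)) {
      o3 <- atom_xyz(res[[i]], "O3'", required = FALSE)
      p <- atom_xyz(res[[i + 1L]], "P", required = FALSE)
      if (is.null(o3) || is.null(p)) {
        if (is.null(o3) && is.null(atom_xyz(res[[i]], "P", required = FALSE))) {
          message("residue ", residue_key(res[[i]]),
                  " lacks both P and O3'; treated as chain break")
        }
        breaks[i] <- TRUE
      } else {
        breaks[i] <- vnorm(as.numeric(o3) - as.numeric(p)) > bond_cutoff
      }
    }
  }
  grp <- cumsum(c(0L, as.integer(breaks)))
  lapply(split(seq_along(res), grp), function(ii) {
    list(chain_id = chain$chain_id, start = res[[ii[1]]]$seqid,
         length = length(ii), residues = res[ii])
  })
}

#' Letters (base identities) of a run of residues
#' @keywords internal
fragment_letters <- function(residues) {
  vapply(residues, function(r) {
    l <- base_letter(r$name)
    if (is.na(l)) "N" else l
  }, character(1))
}
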