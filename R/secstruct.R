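#' @title Sequence-independent secondary-structure assignment
#' @description Base pairs are inferred purely from sugar-phosphate backbone
#'   geometry: short search fragments of known secondary structure are
#'   superposed onto the model via phosphate-triplet alignment, matches are
#'   refined on all shared backbone atoms, and the fragment's annotated
#'   pairs are transferred when the refined RMSD is below a threshold
#'   (default 1.0 Angstrom). Base identities and conformations are never
#'   consulted, which makes the approach robust for preliminary models where
#'   the sequence is not yet known.
#' @name secstruct
NULL

#' Build a search fragment from residues and annotated interactions
#' @param id fragment identifier
#' @param residues flat list of `na_residue` (each must carry a P atom)
#' @param pairs data.frame with columns `i`, `j` (1-based indices into
#'   `residues`) and `interaction` ("WC", "NONCANONICAL" or "STACKING")
#' @param source "HELIX" or "MOTIF_LIBRARY"
#' @return object of class `na_search_fragment`
#' @export
new_search_fragment <- function(id, residues, pairs, source = "MOTIF_LIBRARY") {
  stopifnot(length(residues) >= 2L)
  if (!all(vapply(residues, function(r) "P" %in% r$atom_names, logical(1)))) {
    stop("every search-fragment residue must have a P atom")
  }
  stopifnot(all(pairs$i >= 1), all(pairs$j <= length(residues)),
            all(pairs$interaction %in% c("WC", "NONCANONICAL", "STACKING")))
  structure(list(id = id, residues = residues, pairs = pairs,
                 source = source),
            class = "na_search_fragment")
}

#' Ideal double-helical search fragment
#'
#' The default search model for Watson-Crick pair detection: an ideal
#' 2-base-pair (optionally 3) duplex generated by [make_duplex()], annotated
#' with its cross-strand WC pairs and intra-strand stackings.
#'
#' @param form "A_RNA" or "B_DNA"
#' @param n_bp 2 or 3 base pairs
#' @return `na_search_fragment`
#' @export
make_helical_fragment <- function(form = c("A_RNA", "B_DNA"), n_bp = 2L) {
  form <- match.arg(form)
  stopifnot(n_bp %in% c(2L, 3L))
  seq1 <- paste(rep(c("G", "C"), length.out = n_bp), collapse = "")
  d <- make_duplex(seq1, form)
  residues <- c(d$chains[[1]]$residues, d$chains[[2]]$residues)
  n <- n_bp
  pairs <- data.frame(i = seq_len(n), j = 2L * n + 1L - seq_len(n),
                      interaction = "WC", stringsAsFactors = FALSE)
  stack <- data.frame(i = c(seq_len(n - 1L), n + seq_len(n - 1L)),
                      j = c(seq_len(n - 1L) + 1L, n + seq_len(n - 1L) + 1L),
                      interaction = "STACKING", stringsAsFactors = FALSE)
  new_search_fragment(id = sprintf("%s_%dbp", form, n_bp), residues,
                      rbind(pairs, stack), source = "HELIX")
}

# all residues of a model that carry a P atom, with P coordinates
model_p_atoms <- function(model) {
  res <- all_residues(model)
  keep <- vapply(res, function(r) "P" %in% r$atom_names, logical(1))
  res <- res[keep]
  list(residues = res,
       p = do.call(rbind, lapply(res, function(r) atom_xyz(r, "P"))))
}

#' Match a search fragment against a model
#'
#' All phosphate triplets of the fragment are aligned with
#' distance-compatible phosphate triplets of the model (each of the three
#' pairwise P-P distances must agree within `triplet_tolerance`); the
#' resulting rigid transformation maps every fragment residue to its nearest
#' model phosphate (within 3 Angstrom, injectively, otherwise the candidate
#' is discarded) and the match is refined by least squares on all shared
#' sugar-phosphate backbone atoms. Matches with refined RMSD below
#' `rmsd_cutoff` are returned, deduplicated by residue mapping (keeping the
#' lowest RMSD).
#'
#' @param fragment `na_search_fragment`
#' @param model `na_structure` (or a list of residues)
#' @param rmsd_cutoff acceptance threshold on the refined all-backbone RMSD
#'   (default 1.0 Angstrom)
#' @param triplet_tolerance P-P distance compatibility tolerance (default
#'   1.0 Angstrom)
#' @return list of matches: each `list(fragment_id, residues, keys, rmsd)`
#'   where `residues` are the mapped model residues in fragment order
#' @export
match_fragment <- function(fragment, model, rmsd_cutoff = 1.0,
                           triplet_tolerance = 1.0) {
  mp <- if (inherits(model, "na_structure")) model_p_atoms(model)
        else list(residues = model,
                  p = do.call(rbind, lapply(model, function(r)
                    atom_xyz(r, "P"))))
  nm <- length(mp$residues)
  if (nm < 3L) return(list())
  fp <- do.call(rbind, lapply(fragment$residues, function(r)
    atom_xyz(r, "P")))
  nf <- nrow(fp)
  mtri <- t(utils::combn(nm, 3L))
  dmat <- as.matrix(stats::dist(mp$p))
  md <- cbind(dmat[mtri[, 1:2, drop = FALSE]],
              dmat[mtri[, c(1, 3), drop = FALSE]],
              dmat[mtri[, 2:3, drop = FALSE]])
  md_sorted <- t(apply(md, 1, sort))
  ftri <- t(utils::combn(nf, 3L))
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                 c(3, 1, 2), c(3, 2, 1))
  matches <- list()
  seen <- character(0)
  for (t_i in seq_len(nrow(ftri))) {
    fidx <- ftri[t_i, ]
    fd <- c(vnorm(fp[fidx[1], ] - fp[fidx[2], ]),
            vnorm(fp[fidx[1], ] - fp[fidx[3], ]),
            vnorm(fp[fidx[2], ] - fp[fidx[3], ]))
    fd_sorted <- sort(fd)
    cand <- which(abs(md_sorted[, 1] - fd_sorted[1]) <= triplet_tolerance &
                    abs(md_sorted[, 2] - fd_sorted[2]) <= triplet_tolerance &
                    abs(md_sorted[, 3] - fd_sorted[3]) <= triplet_tolerance)
    for (ci in cand) {
      mi <- mtri[ci, ]
      for (pi in seq_len(nrow(perms))) {
        mo <- mi[perms[pi, ]]
        pd <- c(vnorm(mp$p[mo[1], ] - mp$p[mo[2], ]),
                vnorm(mp$p[mo[1], ] - mp$p[mo[3], ]),
                vnorm(mp$p[mo[2], ] - mp$p[mo[3], ]))
        if (any(abs(pd - fd) > triplet_tolerance)) next
        fit <- kabsch(fp[fidx, , drop = FALSE],
                      mp$p[mo, , drop = FALSE])
        fpt <- apply_rigid(fit, fp)
        d2 <- outer(rowSums(fpt^2), rowSums(mp$p^2), "+") -
          2 * fpt %*% t(mp$p)
        nearest <- apply(d2, 1, which.min)
        ndist <- sqrt(pmax(d2[cbind(seq_len(nf), nearest)], 0))
        if (any(ndist > 3.0) || anyDuplicated(nearest)) next
        key <- paste(nearest, collapse = ",")
        if (key %in% seen) next
        # refinement on all shared backbone atoms
        fx <- list(); mx <- list()
        ok <- TRUE
        for (k in seq_len(nf)) {
          fres <- fragment$residues[[k]]
          mres <- mp$residues[[nearest[k]]]
          shared <- intersect(intersect(BACKBONE_ATOMS, fres$atom_names),
                              mres$atom_names)
          if (length(shared) < 3L) { ok <- FALSE; break }
          fx[[k]] <- atom_xyz(fres, shared)
          mx[[k]] <- atom_xyz(mres, shared)
        }
        if (!ok) next
        ref <- kabsch(do.call(rbind, fx), do.call(rbind, mx))
        if (ref$rmsd >= rmsd_cutoff) next
        seen <- c(seen, key)
        matches[[length(matches) + 1L]] <- list(
          fragment_id = fragment$id,
          residues = mp$residues[nearest],
          keys = vapply(mp$residues[nearest], residue_key, ""),
          rmsd = ref$rmsd)
      }
    }
  }
  if (length(matches) == 0L) return(list())
  # dedup by mapping, lowest rmsd first
  ord <- order(vapply(matches, `[[`, 0, "rmsd"))
  matches <- matches[ord]
  keys <- vapply(matches, function(m) paste(m$keys, collapse = ","), "")
  matches[!duplicated(keys)]
}

pairs_from_matches <- function(matches, fragment_pairs_list, step) {
  rows <- list()
  for (m in matches) {
    fp <- fragment_pairs_list[[m$fragment_id]]
    for (r in seq_len(nrow(fp))) {
      ri <- m$residues[[fp$i[r]]]; rj <- m$residues[[fp$j[r]]]
      ki <- residue_key(ri); kj <- residue_key(rj)
      if (ki == kj) next
      swap <- ki > kj
      rows[[length(rows) + 1L]] <- data.frame(
        key_i = if (swap) kj else ki, key_j = if (swap) ki else kj,
        chain_i = (if (swap) rj else ri)$chain_id,
        seqid_i = (if (swap) rj else ri)$seqid,
        chain_j = (if (swap) ri else rj)$chain_id,
        seqid_j = (if (swap) ri else rj)$seqid,
        interaction = fp$interaction[r], best_rmsd = m$rmsd,
        step = step, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(NULL)
  do.call(rbind, rows)
}

# enforce: unique unordered pairs (prefer step 2, then lowest rmsd) and at
# most one WC partner per residue
resolve_conflicts <- function(pairs) {
  if (is.null(pairs) || nrow(pairs) == 0L) return(pairs)
  ord <- order(-pairs$step, pairs$best_rmsd)
  pairs <- pairs[ord, , drop = FALSE]
  pairs <- pairs[!duplicated(paste(pairs$key_i, pairs$key_j)), , drop = FALSE]
  wc <- pairs$interaction == "WC"
  taken <- character(0)
  keep <- logical(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    if (!wc[r]) { keep[r] <- TRUE; next }
    if (pairs$key_i[r] %in% taken || pairs$key_j[r] %in% taken) next
    keep[r] <- TRUE
    taken <- c(taken, pairs$key_i[r], pairs$key_j[r])
  }
  out <- pairs[keep, , drop = FALSE]
  out[order(out$chain_i, out$seqid_i, out$chain_j, out$seqid_j), ,
      drop = FALSE]
}

# residues interior to stacked WC runs of >= min_run consecutive pairs
stem_interior_keys <- function(model, pairs, min_run = 3L) {
  wc <- pairs[pairs$interaction == "WC", , drop = FALSE]
  if (nrow(wc) == 0L) return(character(0))
  partner <- c(stats::setNames(wc$key_j, wc$key_i),
               stats::setNames(wc$key_i, wc$key_j))
  partner_chain <- c(stats::setNames(wc$chain_j, wc$key_i),
                     stats::setNames(wc$chain_i, wc$key_j))
  partner_seqid <- c(stats::setNames(wc$seqid_j, wc$key_i),
                     stats::setNames(wc$seqid_i, wc$key_j))
  interior <- character(0)
  for (ch in model$chains) {
    res <- ch$residues
    keys <- vapply(res, residue_key, "")
    run <- integer(0)
    flush <- function(run) {
      if (length(run) >= min_run) {
        inner <- run[-c(1L, length(run))]
        c(keys[inner], unname(partner[keys[inner]]))
      } else character(0)
    }
    for (i in seq_along(res)) {
      paired <- keys[i] %in% names(partner)
      extends <- FALSE
      if (paired && length(run) > 0L) {
        prev <- run[length(run)]
        extends <- (i - 1L == prev) &&
          partner_chain[keys[i]] == partner_chain[keys[prev]] &&
          abs(partner_seqid[keys[i]] - partner_seqid[keys[prev]]) == 1L
      }
      if (paired && (length(run) == 0L || extends)) {
        run <- c(run, i)
      } else {
        interior <- c(interior, flush(run))
        run <- if (paired) i else integer(0)
      }
    }
    interior <- c(interior, flush(run))
  }
  unique(interior)
}

#' Assign base pairs to a model by fragment superposition
#'
#' Two-step protocol: first an ideal 2-base-pair double helix (A-RNA or
#' B-DNA, chosen by the model's nucleic-acid kind) detects Watson-Crick
#' pairs and helical stackings; then, for RNA models with a non-empty motif
#' library, interior residues of stacked WC runs (three or more consecutive
#' pairs; the flanking pairs are kept) are removed and each library fragment
#' is matched against the remainder, contributing its annotated pairs.
#' Conflicts are resolved in favour of second-step assignments, then lowest
#' RMSD; a residue keeps at most one WC partner.
#'
#' @param model `na_structure`
#' @param motif_library list of `na_search_fragment` (possibly empty), e.g.
#'   from [read_motif_library()]
#' @param rmsd_cutoff match acceptance threshold (default 1.0 Angstrom)
#' @param triplet_tolerance see [match_fragment()]
#' @return object of class `na_secondary_structure`: list(pairs, model_ref)
#' @export
assign_base_pairs <- function(model, motif_library = list(),
                              rmsd_cutoff = 1.0, triplet_tolerance = 1.0) {
  if (length(model$chains) == 0L) stop("model has no nucleic chains")
  kinds <- vapply(model$chains, `[[`, "", "kind")
  kind <- if (sum(kinds == "RNA") * 2 >= length(kinds)) "RNA" else "DNA"
  frag <- make_helical_fragment(if (kind == "RNA") "A_RNA" else "B_DNA", 2L)
  m1 <- match_fragment(frag, model, rmsd_cutoff, triplet_tolerance)
  fp_list <- stats::setNames(list(frag$pairs), frag$id)
  pairs <- pairs_from_matches(m1, fp_list, step = 1L)
  if (kind == "RNA" && length(motif_library) > 0L) {
    resolved1 <- resolve_conflicts(pairs)
    drop_keys <- if (!is.null(resolved1)) {
      stem_interior_keys(model, resolved1)
    } else character(0)
    res <- all_residues(model)
    remaining <- res[!vapply(res, residue_key, "") %in% drop_keys]
    remaining <- remaining[vapply(remaining, function(r)
      "P" %in% r$atom_names, logical(1))]
    if (length(remaining) >= 3L) {
      fp2 <- stats::setNames(lapply(motif_library, `[[`, "pairs"),
                             vapply(motif_library, `[[`, "", "id"))
      for (mf in motif_library) {
        m2 <- match_fragment(mf, remaining, rmsd_cutoff, triplet_tolerance)
        p2 <- pairs_from_matches(m2, fp2, step = 2L)
        if (!is.null(p2)) pairs <- rbind(pairs, p2)
      }
    }
  }
  pairs <- resolve_conflicts(pairs)
  if (is.null(pairs)) {
    pairs <- data.frame(key_i = character(0), key_j = character(0),
                        chain_i = character(0), seqid_i = integer(0),
                        chain_j = character(0), seqid_j = integer(0),
                        interaction = character(0), best_rmsd = numeric(0),
                        step = integer(0), stringsAsFactors = FALSE)
  }
  structure(list(pairs = pairs, model_ref = model$title),
            class = "na_secondary_structure")
}

#' @export
print.na_secondary_structure <- function(x, ...) {
  tab <- table(x$pairs$interaction)
  cat("<na_secondary_structure>",
      paste(names(tab), tab, collapse = ", "), "\n")
  invisible(x)
}

#' Read a motif library from a directory
#'
#' Each motif is a coordinate file (`<name>.pdb`) with a sidecar annotation
#' table `<name>.pairs.tsv` holding columns `i`, `j` (1-based residue
#' indices in file order) and `interaction` (WC/NONCANONICAL/STACKING).
#'
#' @param dir directory path
#' @return list of `na_search_fragment`
#' @export
read_motif_library <- function(dir) {
  files <- list.files(dir, pattern = "\\.pdb$", full.names = TRUE)
  lapply(files, function(f) {
    s <- read_structure(f)
    ann <- utils::read.table(sub("\\.pdb$", ".pairs.tsv", f), header = TRUE,
                             sep = "\t", quote = "",
                             stringsAsFactors = FALSE)
    new_search_fragment(id = sub("\\.pdb$", "", basename(f)),
                        residues = all_residues(s), pairs = ann,
                        source = "MOTIF_LIBRARY")
  })
}

WC_RESTRAINT_ATOMS <- list(
  GC = list(c("O6", "N4"), c("N1", "N3"), c("N2", "O2")),
  AU = list(c("N1", "N3"), c("N6", "O4")))

# hydrogen-bond restraint table for one pair; falls back to a single
# glycosidic-N distance when base identities are unknown or incompatible
pair_restraints <- function(model, pr) {
  ri <- get_residue(model, pr$chain_i, pr$seqid_i)
  rj <- get_residue(model, pr$chain_j, pr$seqid_j)
  if (is.null(ri) || is.null(rj)) return(NULL)
  li <- base_letter(ri$name); lj <- base_letter(rj$name)
  norm <- function(l) if (is.na(l)) NA_character_ else sub("T", "U", l)
  li <- norm(li); lj <- norm(lj)
  mk <- function(res1, res2, atoms, target, sigma) {
    data.frame(chain_1 = res1$chain_id, seqid_1 = res1$seqid,
               atom_1 = atoms[1], chain_2 = res2$chain_id,
               seqid_2 = res2$seqid, atom_2 = atoms[2], target = target,
               sigma = sigma, stringsAsFactors = FALSE)
  }
  known <- !is.na(li) && !is.na(lj)
  if (known && setequal(c(li, lj), c("G", "C"))) {
    g <- if (li == "G") ri else rj; c_ <- if (li == "G") rj else ri
    return(do.call(rbind, lapply(WC_RESTRAINT_ATOMS$GC, function(a)
      mk(g, c_, a, 2.9, 0.15))))
  }
  if (known && setequal(c(li, lj), c("A", "U"))) {
    a_ <- if (li == "A") ri else rj; u <- if (li == "A") rj else ri
    return(do.call(rbind, lapply(WC_RESTRAINT_ATOMS$AU, function(a)
      mk(a_, u, a, 2.9, 0.15))))
  }
  gi <- tryCatch(glycosidic_atom(ri), error = function(e) NULL)
  gj <- tryCatch(glycosidic_atom(rj), error = function(e) NULL)
  if (is.null(gi) || is.null(gj)) return(NULL)
  mk(ri, rj, c(gi, gj), 8.9, 0.3)
}

#' Export base-pair restraints for refinement and visualization
#'
#' Watson-Crick pairs emit hydrogen-bond distance restraints between the
#' standard donor/acceptor atoms (G.C: O6-N4, N1-N3, N2-O2; A.U/A.T: N1-N3,
#' N6-O4; target 2.9 Angstrom, sigma 0.15). Pairs whose base identities are
#' unknown (or not Watson-Crick compatible, as in preliminary models) emit a
#' single glycosidic-nitrogen distance restraint (8.9 Angstrom, sigma 0.3).
#' The PYMOL dialect draws a dashed distance object per pair instead.
#'
#' @param ss `na_secondary_structure`
#' @param model `na_structure` the pairs refer to
#' @param dialect one of "REFMAC", "PHENIX", "ISOLDE", "COOT", "PYMOL"
#' @return character vector of output lines
#' @export
write_restraints <- function(ss, model,
                             dialect = c("REFMAC", "PHENIX", "ISOLDE",
                                         "COOT", "PYMOL")) {
  dialect <- match.arg(dialect)
  wc <- ss$pairs[ss$pairs$interaction %in% c("WC", "NONCANONICAL"), ,
                 drop = FALSE]
  tab <- NULL
  for (r in seq_len(nrow(wc))) {
    tab <- rbind(tab, pair_restraints(model, wc[r, ]))
  }
  header <- sprintf("# base-pair restraints (%d pairs) generated by nucassign",
                    nrow(wc))
  if (dialect == "REFMAC") {
    body <- if (is.null(tab)) character(0) else sprintf(
      "exte dist first chain %s resi %d atom %s second chain %s resi %d atom %s value %.2f sigma %.2f",
      tab$chain_1, tab$seqid_1, tab$atom_1, tab$chain_2, tab$seqid_2,
      tab$atom_2, tab$target, tab$sigma)
    return(c(header, body))
  }
  if (dialect == "PHENIX") {
    body <- character(0)
    if (!is.null(tab)) {
      for (r in seq_len(nrow(tab))) {
        body <- c(body, "refinement.geometry_restraints.edits.bond {",
                  sprintf("  atom_selection_1 = chain %s and resseq %d and name %s",
                          tab$chain_1[r], tab$seqid_1[r], tab$atom_1[r]),
                  sprintf("  atom_selection_2 = chain %s and resseq %d and name %s",
                          tab$chain_2[r], tab$seqid_2[r], tab$atom_2[r]),
                  sprintf("  distance_ideal = %.2f", tab$target[r]),
                  sprintf("  sigma = %.2f", tab$sigma[r]),
                  "}")
      }
    }
    return(c(header, body))
  }
  if (dialect %in% c("ISOLDE", "COOT")) {
    body <- if (is.null(tab)) character(0) else if (dialect == "ISOLDE") {
      sprintf("adjust_distance_restraints /%s:%d@%s /%s:%d@%s target %.2f kappa %.2f",
              tab$chain_1, tab$seqid_1, tab$atom_1, tab$chain_2,
              tab$seqid_2, tab$atom_2, tab$target, 1 / tab$sigma^2)
    } else {
      sprintf("add_extra_bond_restraint(0, \"%s\", %d, \"\", \"%s\", \"%s\", %d, \"\", \"%s\", %.2f, %.2f)",
              tab$chain_1, tab$seqid_1, tab$atom_1, tab$chain_2,
              tab$seqid_2, tab$atom_2, tab$target, tab$sigma)
    }
    return(c(header, body))
  }
  # PYMOL: one dashed distance object per assigned pair
  preamble <- c(header, "set dash_gap, 0.4", "set dash_radius, 0.08")
  pair_lines <- character(0)
  all_pairs <- ss$pairs
  for (r in seq_len(nrow(all_pairs))) {
    pr <- all_pairs[r, ]
    ri <- get_residue(model, pr$chain_i, pr$seqid_i)
    rj <- get_residue(model, pr$chain_j, pr$seqid_j)
    if (is.null(ri) || is.null(rj)) next
    ai <- tryCatch(glycosidic_atom(ri), error = function(e) "P")
    aj <- tryCatch(glycosidic_atom(rj), error = function(e) "P")
    pair_lines <- c(pair_lines, sprintf(
      "distance pair_%04d, (chain %s and resi %d and name %s), (chain %s and resi %d and name %s)",
      r, pr$chain_i, pr$seqid_i, ai, pr$chain_j, pr$seqid_j, aj))
  }
  c(preamble, pair_lines)
}

#' Dot-bracket string of the Watson-Crick pairing within one chain
#'
#' A maximal nested subset of the chain's WC pairs is rendered as
#' parentheses (computed by exact dynamic programming over the fixed pair
#' set); remaining, pseudoknotted pairs as square brackets; unpaired
#' positions as dots.
#'
#' @param ss `na_secondary_structure`
#' @param chain `na_chain` (or list of residues defining the positions)
#' @return character string with one symbol per residue
#' @export
to_dotbracket <- function(ss, chain) {
  residues <- if (inherits(chain, "na_chain")) chain$residues else chain
  keys <- vapply(residues, residue_key, "")
  n <- length(keys)
  wc <- ss$pairs[ss$pairs$interaction == "WC", , drop = FALSE]
  partner <- rep(NA_integer_, n)
  for (r in seq_len(nrow(wc))) {
    pi <- match(wc$key_i[r], keys); pj <- match(wc$key_j[r], keys)
    if (!is.na(pi) && !is.na(pj)) {
      partner[pi] <- pj; partner[pj] <- pi
    }
  }
  dotbracket_from_partners(partner)
}

#' Dot-bracket from a partner vector (internal workhorse)
#' @param partner integer vector; `partner[i]` is the position paired with
#'   `i`, or NA
#' @return dot-bracket string
#' @keywords internal
dotbracket_from_partners <- function(partner) {
  n <- length(partner)
  out <- rep(".", n)
  brackets <- list(c("(", ")"), c("[", "]"), c("{", "}"))
  level <- 0L
  while (any(!is.na(partner)) && level < length(brackets)) {
    level <- level + 1L
    memo <- new.env(parent = emptyenv())
    best <- function(i, j) {
      if (i >= j) return(list(score = 0L, pairs = NULL))
      key <- paste(i, j)
      if (!is.null(memo[[key]])) return(memo[[key]])
      r1 <- best(i + 1L, j)
      res <- list(score = r1$score, pairs = r1$pairs)
      k <- partner[i]
      if (!is.na(k) && k > i && k <= j) {
        inner <- best(i + 1L, k - 1L)
        outer_ <- best(k + 1L, j)
        sc <- 1L + inner$score + outer_$score
        if (sc > res$score) {
          res <- list(score = sc, pairs = rbind(c(i, k), inner$pairs,
                                                outer_$pairs))
        }
      }
      memo[[key]] <- res
      res
    }
    sol <- best(1L, n)
    if (is.null(sol$pairs)) break
    for (r in seq_len(nrow(sol$pairs))) {
      i <- sol$pairs[r, 1]; j <- sol$pairs[r, 2]
      out[i] <- brackets[[level]][1]
      out[j] <- brackets[[level]][2]
      partner[i] <- NA_integer_; partner[j] <- NA_integer_
    }
  }
  paste(out, collapse = "")
}
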