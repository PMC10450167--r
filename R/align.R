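#' @title Probabilistic sequence assignment of model fragments
#' @description A continuous polynucleotide fragment is assigned to a target
#'   sequence by scanning all gapless placements. Each placement is scored
#'   by the product of the classifier's per-residue purine/pyrimidine
#'   probabilities (assuming independence), times a 0.1 correction factor
#'   for every fragment-internal Watson-Crick pair whose two aligned target
#'   letters fall in the same base class (a same-class Watson-Crick pair is
#'   very unlikely; the factor is 1 otherwise). Significance is assessed
#'   against an extreme-value background: best scores over many random
#'   decoy targets of the same length.
#' @name align
NULL

#' Construct a target sequence
#' @param id sequence identifier
#' @param letters string over A/C/G/U/T/N
#' @param kind "RNA" or "DNA" (default guessed from letters)
#' @return object of class `na_target_sequence`
#' @export
target_sequence <- function(id, letters, kind = NULL) {
  letters <- toupper(gsub("[ \n]", "", letters))
  stopifnot(nchar(letters) >= 1)
  if (!grepl("^[ACGUTN]+$", letters)) {
    stop("target sequence may only contain A/C/G/U/T/N")
  }
  if (is.null(kind)) kind <- if (grepl("T", letters)) "DNA" else "RNA"
  structure(list(id = id, letters = letters, kind = kind),
            class = "na_target_sequence")
}

#' Read target sequences from a FASTA file
#' @param path FASTA file
#' @param kind "RNA" or "DNA" (default guessed per record)
#' @return named list of `na_target_sequence`
#' @export
read_target_fasta <- function(path, kind = NULL) {
  set <- Biostrings::readBStringSet(path)
  out <- lapply(seq_along(set), function(i) {
    id <- strsplit(names(set)[i], "\\s+")[[1]][1]
    target_sequence(id, as.character(set[[i]]), kind = kind)
  })
  stats::setNames(out, vapply(out, `[[`, "", "id"))
}

#' Construct a probability profile
#'
#' @param probs n x 2 matrix of (p_purine, p_pyrimidine) per residue; rows
#'   are renormalized after clipping into `[1e-3, 1 - 1e-3]`
#' @param pairs_internal 2-column matrix/data.frame of fragment-internal
#'   Watson-Crick pairs (1-based positions), or NULL
#' @param fragment list(chain_id, start, length) provenance (optional)
#' @return object of class `na_probability_profile`
#' @export
new_probability_profile <- function(probs, pairs_internal = NULL,
                                    fragment = NULL) {
  probs <- as.matrix(probs)
  stopifnot(ncol(probs) == 2, all(is.finite(probs)), all(probs >= 0))
  probs <- probs / rowSums(probs)
  probs <- pmin(pmax(probs, 1e-3), 1 - 1e-3)
  probs <- probs / rowSums(probs)
  if (!is.null(pairs_internal) && length(pairs_internal) > 0) {
    pairs_internal <- as.matrix(pairs_internal)[, 1:2, drop = FALSE]
    stopifnot(all(pairs_internal >= 1), all(pairs_internal <= nrow(probs)))
  } else {
    pairs_internal <- matrix(integer(0), 0, 2)
  }
  structure(list(fragment = fragment, probs = probs,
                 pairs_internal = pairs_internal),
            class = "na_probability_profile")
}

#' Estimate a purine/pyrimidine probability profile for a model fragment
#'
#' @param model `na_structure`
#' @param map `na_density_map`
#' @param fragment a fragment from [chain_fragments()] (or a list of
#'   residues)
#' @param classifier trained [train_classifier()] model
#' @param ss optional `na_secondary_structure`; its WC pairs with both
#'   partners inside the fragment become `pairs_internal`
#' @param cloud sampling cloud (default canonical)
#' @return `na_probability_profile`
#' @export
base_probability_profile <- function(model, map, fragment, classifier,
                                     ss = NULL, cloud = canonical_cloud()) {
  residues <- if (!is.null(fragment$residues)) fragment$residues else fragment
  n <- length(residues)
  lp <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    desc <- extract_descriptor(map, residues[[i]], cloud)
    lp[i, ] <- predict_base_class(classifier, desc)
  }
  pairs <- NULL
  if (!is.null(ss)) {
    keys <- vapply(residues, residue_key, "")
    wc <- ss$pairs[ss$pairs$interaction == "WC", , drop = FALSE]
    pi <- match(wc$key_i, keys); pj <- match(wc$key_j, keys)
    ok <- !is.na(pi) & !is.na(pj)
    if (any(ok)) pairs <- cbind(pi[ok], pj[ok])
  }
  new_probability_profile(exp(lp), pairs,
                          fragment = list(
                            chain_id = residues[[1]]$chain_id,
                            start = residues[[1]]$seqid, length = n))
}

# classes of target letters at every offset window, vectorized scoring;
# returns numeric vector of log-scores for offsets 0 .. L - n (0-based)
score_all_offsets <- function(profile, cls) {
  n <- nrow(profile$probs)
  L <- length(cls)
  m <- L - n + 1L
  if (m < 1L) stop("fragment longer than target")
  logp <- log(profile$probs)
  s <- numeric(m)
  half <- log(0.5)
  for (i in seq_len(n)) {
    ci <- cls[i:(i + m - 1L)]
    v <- numeric(m)
    v[ci == 1L] <- logp[i, 1]
    v[ci == 2L] <- logp[i, 2]
    v[ci == 0L] <- half
    s <- s + v
  }
  if (nrow(profile$pairs_internal) > 0) {
    for (r in seq_len(nrow(profile$pairs_internal))) {
      a <- profile$pairs_internal[r, 1]; b <- profile$pairs_internal[r, 2]
      ca <- cls[a:(a + m - 1L)]; cb <- cls[b:(b + m - 1L)]
      s <- s + log(0.1) * (ca == cb & ca > 0L)
    }
  }
  s
}

count_corrected_pairs <- function(profile, cls, offset) {
  if (nrow(profile$pairs_internal) == 0) return(0L)
  a <- profile$pairs_internal[, 1] + offset
  b <- profile$pairs_internal[, 2] + offset
  sum(cls[a] == cls[b] & cls[a] > 0L)
}

#' Score one gapless placement of a profile on a target
#'
#' @param profile `na_probability_profile`
#' @param target `na_target_sequence`
#' @param offset 0-based start position in the target
#' @return list(offset, log_score, n_corrected_pairs); `log_score` is the
#'   natural-log alignment probability
#' @export
alignment_score <- function(profile, target, offset) {
  n <- nrow(profile$probs)
  cls <- letter_class(strsplit(target$letters, "")[[1]])
  if (offset < 0 || offset + n > length(cls)) {
    stop("alignment window [", offset, ", ", offset + n,
         ") out of target range")
  }
  win <- cls[(offset + 1L):(offset + n)]
  logp <- log(profile$probs)
  s <- sum(ifelse(win == 0L, log(0.5),
                  logp[cbind(seq_len(n), pmax(win, 1L))]))
  npen <- count_corrected_pairs(profile, cls, offset)
  s <- s + npen * log(0.1)
  list(offset = offset, log_score = s, n_corrected_pairs = npen)
}

#' Enumerate and rank all gapless placements of a profile on a target
#'
#' @param profile `na_probability_profile`
#' @param target `na_target_sequence`
#' @return data.frame of candidates sorted by decreasing `log_score` (ties
#'   broken by smaller offset), with columns `offset` (0-based),
#'   `log_score`, `n_corrected_pairs`
#' @export
enumerate_alignments <- function(profile, target) {
  cls <- letter_class(strsplit(target$letters, "")[[1]])
  s <- score_all_offsets(profile, cls)
  npen <- vapply(seq_along(s) - 1L, function(o)
    count_corrected_pairs(profile, cls, o), integer(1))
  out <- data.frame(offset = seq_along(s) - 1L, log_score = s,
                    n_corrected_pairs = npen)
  out[order(-out$log_score, out$offset), , drop = FALSE]
}

#' Extreme-value background for alignment scores
#'
#' Simulates the null distribution of the *best* placement score on random
#' targets: a long i.i.d. uniform random sequence is split into `n_random`
#' blocks of `target_len` letters and the maximum placement score within
#' each block recorded. A Gumbel distribution is fitted to the block maxima
#' by the method of moments (block maxima are the regime where the
#' extreme-value limit applies; the fit also supports tail extrapolation
#' beyond the sample).
#'
#' @param profile `na_probability_profile`
#' @param target_len length of the target the p-value will refer to
#' @param n_random number of background blocks (>= 200)
#' @param seed RNG seed
#' @return object of class `na_background`: list(samples, gumbel_mu,
#'   gumbel_beta, n_positions)
#' @export
alignment_background <- function(profile, target_len, n_random = 500L,
                                 seed = 1L) {
  n <- nrow(profile$probs)
  stopifnot(n_random >= 200L, target_len >= n)
  m <- target_len - n + 1L
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  set.seed(seed)
  cls <- sample(c(1L, 2L), n_random * target_len, replace = TRUE)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  s <- score_all_offsets(profile, cls)
  off0 <- (seq_len(n_random) - 1L) * target_len
  maxima <- vapply(seq_len(n_random), function(b) {
    max(s[(off0[b] + 1L):(off0[b] + m)])
  }, numeric(1))
  beta <- stats::sd(maxima) * sqrt(6) / pi
  mu <- mean(maxima) - 0.5772156649015329 * beta
  structure(list(samples = maxima, gumbel_mu = mu, gumbel_beta = beta,
                 n_positions = m, target_len = target_len, n = n),
            class = "na_background")
}

#' p-value of an alignment score under the random-sequence null
#'
#' The probability of observing, by chance, a best placement score at least
#' as good on a random target of the same length: the empirical exceedance
#' fraction among the background block maxima, with the fitted Gumbel tail
#' taking over beyond the sampled range. A zero-variance background yields
#' p = 1 with a warning.
#'
#' @param best a candidate from [enumerate_alignments()] /
#'   [alignment_score()] (or a bare log-score)
#' @param profile `na_probability_profile`
#' @param target_len target length (defines the placement multiplicity)
#' @param n_random background blocks (default 500)
#' @param seed RNG seed
#' @param background optional precomputed [alignment_background()]
#' @return p-value in (0, 1], with the background fit in attributes
#' @export
estimate_pvalue <- function(best, profile, target_len, n_random = 500L,
                            seed = 1L, background = NULL) {
  x <- if (is.list(best)) best$log_score else best
  if (is.null(background)) {
    background <- alignment_background(profile, target_len, n_random, seed)
  }
  bg <- background$samples
  if (stats::sd(bg) < 1e-12) {
    warning("degenerate (zero-variance) alignment background; p = 1")
    p <- 1
  } else {
    p <- (1 + sum(bg >= x - 1e-12)) / (length(bg) + 1)
    if (all(bg < x - 1e-12) && background$gumbel_beta > 0) {
      # beyond the sampled maxima: Gumbel tail extrapolation
      z <- (x - background$gumbel_mu) / background$gumbel_beta
      p_tail <- -expm1(-exp(-z))
      p <- max(min(p, p_tail), 1e-300)
    }
  }
  attr(p, "background") <- background[c("gumbel_mu", "gumbel_beta",
                                        "n_positions")]
  p
}

# replace the base of a residue with an idealized template base of `letter`,
# keeping the backbone untouched
rebuild_base <- function(residue, letter, kind) {
  code <- residue_code(letter, kind)
  tmpl <- nucleotide_template(code)
  ring <- intersect(intersect(RIBOSE_RING_ATOMS, tmpl$atom_names),
                    residue$atom_names)
  if (length(ring) < 3L) stop("residue ", residue_key(residue),
                              " lacks ribose atoms for base rebuilding")
  old_chi <- tryCatch(residue_chi(residue), error = function(e) NULL)
  fit <- kabsch(atom_xyz(tmpl, ring), atom_xyz(residue, ring))
  base_nm <- base_atom_names(tmpl)
  base_xyz <- apply_rigid(fit, atom_xyz(tmpl, base_nm))
  base_idx <- match(base_nm, tmpl$atom_names)
  keep <- !residue$atom_names %in% base_atom_names(residue)
  out <- new_residue(name = code, seqid = residue$seqid,
                     icode = residue$icode, chain_id = residue$chain_id,
                     xyz = rbind(residue$xyz[keep, , drop = FALSE], base_xyz),
                     atom_names = c(residue$atom_names[keep], base_nm),
                     elements = c(residue$elements[keep],
                                  tmpl$elements[base_idx]),
                     occ = c(residue$occ[keep], rep(1, length(base_nm))),
                     b = c(residue$b[keep], rep(0, length(base_nm))))
  if (!is.null(old_chi)) out <- set_chi(out, old_chi)
  out
}

#' Assign a model fragment to a target sequence
#'
#' Builds the fragment's probability profile from the map and classifier,
#' scans all placements on the target, estimates the p-value of the best
#' one, and rebuilds the fragment's bases to the assigned letters
#' (idealized template bases superposed on the ribose; backbone untouched).
#'
#' @param model `na_structure`
#' @param map `na_density_map`
#' @param fragment a fragment from [chain_fragments()]
#' @param target `na_target_sequence`
#' @param classifier trained classifier
#' @param ss optional `na_secondary_structure` supplying WC pairs
#' @param n_random,seed background parameters (see [estimate_pvalue()])
#' @return object of class `na_assignment`: list(profile, best, pvalue,
#'   target_id, assigned_letters, model) where `model` carries the rebuilt
#'   fragment
#' @export
assign_fragment <- function(model, map, fragment, target, classifier,
                            ss = NULL, n_random = 500L, seed = 1L) {
  n <- fragment$length
  if (n > nchar(target$letters)) {
    stop("fragment (", n, " nt) longer than target (",
         nchar(target$letters), " nt)")
  }
  profile <- base_probability_profile(model, map, fragment, classifier, ss)
  cands <- enumerate_alignments(profile, target)
  best <- as.list(cands[1, ])
  if (nrow(cands) > 1 &&
      cands$log_score[2] > cands$log_score[1] - 1e-12) {
    message("tied best alignments at offsets ", cands$offset[1], " and ",
            cands$offset[2], "; keeping the smaller offset")
  }
  p <- estimate_pvalue(best, profile, nchar(target$letters), n_random, seed)
  letters <- substr(target$letters, best$offset + 1L, best$offset + n)
  kind <- model$chains[[fragment$chain_id]]$kind
  lets <- strsplit(letters, "")[[1]]
  ch <- model$chains[[fragment$chain_id]]
  frag_keys <- vapply(fragment$residues, residue_key, "")
  for (i in seq_along(ch$residues)) {
    k <- match(residue_key(ch$residues[[i]]), frag_keys)
    if (!is.na(k) && lets[k] != "N") {
      ch$residues[[i]] <- rebuild_base(ch$residues[[i]], lets[k], kind)
    }
  }
  model$chains[[fragment$chain_id]] <- ch
  structure(list(profile = profile, best = best, pvalue = as.numeric(p),
                 target_id = target$id, assigned_letters = letters,
                 model = model),
            class = "na_assignment")
}
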