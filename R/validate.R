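#' @title Sequence-assignment validation and sequence randomization
#' @description Validation scans a model's chains with overlapping windows,
#'   comparing the p-value of the deposited alignment position against the
#'   best alternative placement on the chain's own reference sequence; a
#'   window is flagged when the alternative is both significant and far
#'   more probable, which is the signature of register-shift errors. The
#'   randomization utility class-swaps a random subset of nucleobases while
#'   preserving Watson-Crick complementarity, producing the kind of
#'   sequence-scrambled decoy model used to benchmark identification and
#'   assignment under map bias.
#' @name validate
NULL

#' Validate the sequence assignment of a model
#'
#' Each nucleic chain is matched to a reference sequence by chain id. For
#' every window (length `window`, stride `stride`) of every continuous
#' fragment, the probability profile is scored at the deposited position
#' (chain residue i is assumed to carry sequence position i) and at all
#' alternatives. The deposited score's p-value uses a single-placement
#' background; the best alternative's p-value accounts for the full
#' placement multiplicity. Windows where the alternative's p-value is below
#' `alpha` and at least `ratio` times smaller than the deposited one are
#' flagged with the suggested register shift.
#'
#' @param model `na_structure`
#' @param map `na_density_map`
#' @param sequences named list of `na_target_sequence` (names = chain ids)
#'   or a FASTA path with one record per chain
#' @param classifier trained classifier
#' @param window window length in residues (default 20)
#' @param stride window stride (default 5)
#' @param alpha significance threshold on the alternative (default 0.05)
#' @param ratio required p-value ratio deposited/alternative (default 100,
#'   i.e. two orders of magnitude)
#' @param ss optional precomputed secondary structure
#' @param n_random,seed background parameters
#' @return data.frame of flagged segments: chain, seqid_start, seqid_end,
#'   deposited_offset, suggested_offset, shift, p_deposited, p_alternative
#' @export
validate_model <- function(model, map, sequences, classifier, window = 20L,
                           stride = 5L, alpha = 0.05, ratio = 100,
                           ss = NULL, n_random = 300L, seed = 1L) {
  if (is.character(sequences)) sequences <- read_target_fasta(sequences)
  if (is.null(ss)) ss <- assign_base_pairs(model)
  flags <- NULL
  for (ch in model$chains) {
    target <- sequences[[ch$chain_id]]
    if (is.null(target)) {
      message("chain ", ch$chain_id, " has no matching sequence; skipped")
      next
    }
    cls <- letter_class(strsplit(target$letters, "")[[1]])
    L <- length(cls)
    chain_pos <- 0L
    for (frag in chain_fragments(ch)) {
      frag_start_pos <- chain_pos + 1L
      chain_pos <- chain_pos + frag$length
      if (frag$length < window) next
      fprofile <- base_probability_profile(model, map, frag, classifier, ss)
      frag_keys <- vapply(frag$residues, residue_key, "")
      starts <- seq(1L, frag$length - window + 1L, by = stride)
      for (s in starts) {
        idx <- s:(s + window - 1L)
        pr <- fprofile$pairs_internal
        keep <- pr[, 1] %in% idx & pr[, 2] %in% idx
        wpairs <- if (any(keep)) {
          cbind(pr[keep, 1] - s + 1L, pr[keep, 2] - s + 1L)
        } else NULL
        wprofile <- new_probability_profile(fprofile$probs[idx, ,
                                                           drop = FALSE],
                                            wpairs)
        dep_off <- frag_start_pos + s - 2L  # 0-based deposited offset
        if (dep_off + window > L) next
        scores <- score_all_offsets(wprofile, cls)
        dep_score <- scores[dep_off + 1L]
        alt_off <- order(-scores)
        alt_off <- alt_off[alt_off != dep_off + 1L][1L] - 1L
        alt_score <- scores[alt_off + 1L]
        p_dep <- estimate_pvalue(dep_score, wprofile, target_len = window,
                                 n_random = n_random, seed = seed)
        p_alt <- estimate_pvalue(alt_score, wprofile, target_len = L,
                                 n_random = n_random, seed = seed + 1L)
        if (p_alt < alpha && p_alt <= as.numeric(p_dep) / ratio) {
          flags <- rbind(flags, data.frame(
            chain = ch$chain_id,
            seqid_start = frag$residues[[s]]$seqid,
            seqid_end = frag$residues[[s + window - 1L]]$seqid,
            deposited_offset = dep_off, suggested_offset = alt_off,
            shift = alt_off - dep_off,
            p_deposited = as.numeric(p_dep),
            p_alternative = as.numeric(p_alt),
            stringsAsFactors = FALSE))
        }
      }
    }
  }
  if (is.null(flags)) {
    flags <- data.frame(chain = character(0), seqid_start = integer(0),
                        seqid_end = integer(0), deposited_offset = integer(0),
                        suggested_offset = integer(0), shift = integer(0),
                        p_deposited = numeric(0), p_alternative = numeric(0),
                        stringsAsFactors = FALSE)
  }
  flags
}

#' Class-swap a random subset of nucleobases, keeping WC complementarity
#'
#' A seeded random subset of about `floor(fraction * N)` nucleotides is
#' mutated purine -> pyrimidine and vice versa (the replacement letter is
#' drawn uniformly within the new class). When a mutated residue is
#' Watson-Crick paired, its partner is co-mutated to the exact WC
#' complement (and counts towards the total), so every canonical pair in
#' the output remains complementary. Base atoms are rebuilt from idealized
#' templates; the backbone is untouched.
#'
#' @param model `na_structure`
#' @param fraction fraction of nucleotides to mutate, in `[0, 1]`
#' @param ss secondary structure whose WC pairs define the partners
#'   (default: computed with [assign_base_pairs()])
#' @param seed RNG seed
#' @return mutated `na_structure`
#' @export
randomize_sequence <- function(model, fraction, ss = NULL, seed = 1L) {
  stopifnot(fraction >= 0, fraction <= 1)
  if (fraction == 0) return(model)
  if (is.null(ss)) ss <- assign_base_pairs(model)
  wc <- ss$pairs[ss$pairs$interaction == "WC", , drop = FALSE]
  partner <- c(stats::setNames(wc$key_j, wc$key_i),
               stats::setNames(wc$key_i, wc$key_j))
  res_index <- list()
  for (ci in seq_along(model$chains)) {
    for (ri in seq_along(model$chains[[ci]]$residues)) {
      r <- model$chains[[ci]]$residues[[ri]]
      if (!is.na(base_letter(r$name))) {
        res_index[[residue_key(r)]] <- c(ci, ri)
      }
    }
  }
  keys <- names(res_index)
  n_total <- length(keys)
  k <- floor(fraction * n_total)
  if (k == 0L) return(model)
  set.seed(seed)
  order_keys <- sample(keys)
  mutated <- character(0)
  get_res <- function(key) {
    ij <- res_index[[key]]
    model$chains[[ij[1]]]$residues[[ij[2]]]
  }
  set_res <- function(key, r) {
    ij <- res_index[[key]]
    model$chains[[ij[1]]]$residues[[ij[2]]] <<- r
  }
  swap_letter <- function(letter, kind) {
    if (letter_class(letter) == 1L) {
      sample(c("C", if (kind == "RNA") "U" else "T"), 1L)
    } else {
      sample(c("A", "G"), 1L)
    }
  }
  for (key in order_keys) {
    if (length(mutated) >= k) break
    if (key %in% mutated) next
    r <- get_res(key)
    kind <- model$chains[[res_index[[key]][1]]]$kind
    new_letter <- swap_letter(base_letter(r$name), kind)
    set_res(key, rebuild_base(r, new_letter, kind))
    mutated <- c(mutated, key)
    pk <- partner[key]
    if (!is.na(pk) && !pk %in% mutated && pk %in% keys) {
      pr <- get_res(pk)
      pkind <- model$chains[[res_index[[pk]][1]]]$kind
      comp <- wc_complement_letter(new_letter, pkind)
      set_res(pk, rebuild_base(pr, comp, pkind))
      mutated <- c(mutated, pk)
    }
  }
  model
}
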