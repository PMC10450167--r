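#' @title Composite synthetic fixtures
#' @description Beyond plain duplexes, the generator can build a hairpin
#'   (stem-loop) in a single chain and emit complete fixture bundles
#'   (model + simulated map + sequences + ground truth) for end-to-end
#'   runs. Loop residues are placed along a smooth arc bulging away from
#'   the helix axis; their conformation is deliberately non-helical so the
#'   loop carries no spurious double-helical backbone signal.
#' @name fixtures
NULL

# rotation taking orthonormal pair (u1,v1) to (u2,v2)
rotation_between <- function(u1, v1, u2, v2) {
  o1 <- cbind(unit(u1), unit(v1 - sum(v1 * unit(u1)) * unit(u1)))
  o1 <- cbind(o1, cross3(o1[, 1], o1[, 2]))
  o2 <- cbind(unit(u2), unit(v2 - sum(v2 * unit(u2)) * unit(u2)))
  o2 <- cbind(o2, cross3(o2[, 1], o2[, 2]))
  o2 %*% t(o1)
}

#' Build a single-chain hairpin: helical stem plus modeled loop
#'
#' @param stem_seq 5' strand of the stem (paired region)
#' @param loop_seq loop sequence joining the two strands
#' @param form "A_RNA" or "B_DNA"
#' @param bulge how far the loop arc bulges outwards (Angstrom, default 8)
#' @return `na_structure` with one chain "A"; `ground_truth` attribute as in
#'   [make_duplex()]
#' @export
make_hairpin <- function(stem_seq, loop_seq, form = "A_RNA", bulge = 8) {
  hp <- helix_params(form)
  d <- make_duplex(stem_seq, form)
  n <- nchar(stem_seq); L <- nchar(loop_seq)
  stopifnot(L >= 1)
  res1 <- d$chains[["A"]]$residues
  res2 <- d$chains[["B"]]$residues
  p0 <- atom_xyz(res1[[n]], "O3'")
  p1 <- atom_xyz(res2[[1]], "P")
  mid <- (p0 + p1) / 2
  outward <- c(mid[1], mid[2], 0)
  outward <- if (vnorm(outward) < 1e-6) c(1, 0, 0) else unit(outward)
  ctrl <- mid + bulge * outward
  bezier <- function(t) {
    (1 - t)^2 * p0 + 2 * (1 - t) * t * ctrl + t^2 * p1
  }
  loop_letters <- strsplit(toupper(loop_seq), "")[[1]]
  loop_res <- vector("list", L)
  for (i in seq_len(L)) {
    t_i <- i / (L + 1)
    pt <- bezier(t_i)
    tangent <- unit(bezier(min(t_i + 0.01, 1)) - bezier(max(t_i - 0.01, 0)))
    tmpl <- nucleotide_template(residue_code(loop_letters[i], hp$kind))
    u_src <- unit(atom_xyz(tmpl, "O3'") - atom_xyz(tmpl, "P"))
    v_src <- atom_xyz(tmpl, "C1'") - atom_xyz(tmpl, "P")
    R <- rotation_between(u_src, v_src, tangent, outward)
    r <- tmpl
    r$xyz <- sweep(sweep(tmpl$xyz, 2, atom_xyz(tmpl, "P")) %*% t(R), 2, pt,
                   "+")
    r$seqid <- n + i
    r$chain_id <- "A"
    loop_res[[i]] <- r
  }
  for (j in seq_along(res2)) {
    res2[[j]]$seqid <- n + L + j
    res2[[j]]$chain_id <- "A"
  }
  chain <- new_chain("A", c(res1, loop_res, res2), kind = hp$kind)
  out <- new_structure(list(chain), title = paste0("hairpin ", form))
  gt_pairs <- data.frame(chain_i = "A", seqid_i = seq_len(n),
                         chain_j = "A", seqid_j = 2 * n + L + 1 - seq_len(n),
                         stringsAsFactors = FALSE)
  comp <- vapply(rev(strsplit(toupper(stem_seq), "")[[1]]),
                 wc_complement_letter, "", kind = hp$kind)
  attr(out, "ground_truth") <- list(
    pairs = gt_pairs,
    sequence = paste0(stem_seq, loop_seq, paste(comp, collapse = "")))
  out
}

#' Write a complete synthetic fixture bundle to a directory
#'
#' Emits `model.pdb`, `map.ccp4`, `sequences.fasta` (one record per chain)
#' and `ground_truth.json` (construction pairs and sequences).
#'
#' @param dir output directory (created if needed)
#' @param sequence strand sequence (default a seeded random 20-mer)
#' @param form duplex form
#' @param resolution map resolution (Angstrom)
#' @param noise_sd map noise fraction
#' @param seed RNG seed
#' @return invisibly, a list of written paths
#' @export
write_fixture_bundle <- function(dir, sequence = NULL, form = "A_RNA",
                                 resolution = 3.0, noise_sd = 0.1,
                                 seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(sequence)) {
    sequence <- random_rna_sequence(20L, seed = seed)
    if (form == "B_DNA") sequence <- gsub("U", "T", sequence)
  }
  model <- make_duplex(sequence, form)
  map <- simulate_map(model, resolution = resolution, noise_sd = noise_sd,
                      seed = seed)
  gt <- attr(model, "ground_truth")
  paths <- list(model = file.path(dir, "model.pdb"),
                map = file.path(dir, "map.ccp4"),
                fasta = file.path(dir, "sequences.fasta"),
                truth = file.path(dir, "ground_truth.json"))
  write_structure(model, paths$model)
  write_ccp4_map(map, paths$map)
  kind <- helix_params(form)$kind
  seq2 <- paste(vapply(rev(strsplit(sequence, "")[[1]]),
                       wc_complement_letter, "", kind = kind), collapse = "")
  writeLines(c(">A", sequence, ">B", seq2), paths$fasta)
  jsonlite::write_json(list(sequence = sequence, form = form,
                            resolution = resolution, noise_sd = noise_sd,
                            seed = seed, pairs = gt$pairs),
                       paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
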