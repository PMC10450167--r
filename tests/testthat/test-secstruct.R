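# Fragment matching, two-step base-pair assignment, restraints, dot-bracket.

test_that("helical search fragments have the constructed pair/stacking
           annotation, reproducible geometry, and the B-DNA rise", {
  fr <- make_helical_fragment("A_RNA", 2)
  expect_length(fr$residues, 4)
  expect_equal(sum(fr$pairs$interaction == "WC"), 2)
  expect_equal(sum(fr$pairs$interaction == "STACKING"), 2)

  fr2 <- make_helical_fragment("A_RNA", 2)
  x1 <- do.call(rbind, lapply(fr$residues, `[[`, "xyz"))
  x2 <- do.call(rbind, lapply(fr2$residues, `[[`, "xyz"))
  expect_lt(superposed_rmsd(x1, x2), 1e-9)

  # axial P displacement per step equals the B-DNA fibre rise
  db <- make_duplex("GGGG", "B_DNA", include_complement = FALSE)
  pz <- vapply(db$chains[[1]]$residues, function(r) atom_xyz(r, "P")[3],
               numeric(1))
  expect_equal(abs(diff(pz)), rep(3.38, 3), tolerance = 1e-3)
  expect_error(make_helical_fragment("A_RNA", 5), "n_bp")
})

test_that("a 2-bp fragment finds all stem steps of a pristine duplex with
           tiny RMSD, survives 0.2 A noise, and ignores extended strands", {
  d <- make_duplex("GAUCGAUCGA", "A_RNA")
  frag <- make_helical_fragment("A_RNA", 2)
  mm <- match_fragment(frag, d)
  # 9 distinct stem steps (each may be matched in two strand orientations)
  sets <- unique(vapply(mm, function(m) paste(sort(m$keys), collapse = "|"),
                        ""))
  expect_length(sets, 9)
  expect_true(all(vapply(mm, `[[`, 0, "rmsd") < 0.05))

  dn <- perturb_structure(d, sd = 0.2, seed = 31)
  mmn <- match_fragment(frag, dn)
  setsn <- unique(vapply(mmn, function(m) paste(sort(m$keys), collapse = "|"),
                         ""))
  expect_length(setsn, 9)
  expect_true(all(vapply(mmn, `[[`, 0, "rmsd") < 1.0))

  ext <- make_extended_strand(10)
  expect_length(match_fragment(frag, ext), 0)
})

test_that("reported match RMSDs agree with an independent standalone
           superposition to 1e-6 A", {
  d <- perturb_structure(make_duplex("GGCAUGCC", "A_RNA"), sd = 0.15,
                         seed = 5)
  frag <- make_helical_fragment("A_RNA", 2)
  mm <- match_fragment(frag, d)
  expect_gt(length(mm), 0)
  for (m in mm) {
    fx <- NULL; mx <- NULL
    for (k in seq_along(m$residues)) {
      shared <- intersect(
        intersect(BACKBONE_ATOMS, frag$residues[[k]]$atom_names),
        m$residues[[k]]$atom_names)
      fx <- rbind(fx, atom_xyz(frag$residues[[k]], shared))
      mx <- rbind(mx, atom_xyz(m$residues[[k]], shared))
    }
    expect_lt(abs(bio3d_rmsd(fx, mx) - m$rmsd), 1e-6)
  }
})

test_that("assign_base_pairs recovers every pair of a pristine duplex and is
           orientation invariant", {
  d <- make_duplex("GCAUGCAUGC", "A_RNA")
  ss <- assign_base_pairs(d)
  wc <- ss$pairs[ss$pairs$interaction == "WC", ]
  gt <- attr(d, "ground_truth")$pairs
  truth <- paste0("A:", gt$seqid_i, ": B:", gt$seqid_j, ":")
  got <- paste(wc$key_i, wc$key_j)
  expect_setequal(got, truth)

  set.seed(9)
  d2 <- transform_structure(d, random_rigid())
  ss2 <- assign_base_pairs(d2)
  wc2 <- ss2$pairs[ss2$pairs$interaction == "WC", ]
  expect_setequal(paste(wc2$key_i, wc2$key_j), got)
})

test_that("a hairpin gets stem pairs only, and a loop motif with an
           annotated non-canonical pair is found in step 2", {
  h <- make_hairpin("GGCGCC", "UUCG")
  ss <- assign_base_pairs(h)
  wc <- ss$pairs[ss$pairs$interaction == "WC", ]
  expect_equal(nrow(wc), 6)
  loop_keys <- paste0("A:", 7:10, ":")
  expect_false(any(c(wc$key_i, wc$key_j) %in% loop_keys))
  expect_equal(to_dotbracket(ss, h$chains[["A"]]), "((((((....))))))")

  # inject the loop itself as a motif with one annotated pair
  loop_res <- h$chains[["A"]]$residues[7:10]
  motif <- new_search_fragment(
    "uucg_like", loop_res,
    data.frame(i = 1L, j = 4L, interaction = "NONCANONICAL"),
    source = "MOTIF_LIBRARY")
  ss2 <- assign_base_pairs(h, motif_library = list(motif))
  nc <- ss2$pairs[ss2$pairs$interaction == "NONCANONICAL", ]
  expect_equal(nrow(nc), 1)
  expect_setequal(c(nc$key_i, nc$key_j), c("A:7:", "A:10:"))
  expect_equal(nc$step, 2L)
})

test_that("motif libraries round-trip through the directory format", {
  dir <- withr::local_tempdir()
  h <- make_hairpin("GGGC", "UUCG")
  loop <- new_structure(list(new_chain("L", h$chains[["A"]]$residues[5:8],
                                       kind = "RNA")))
  write_structure(loop, file.path(dir, "loop1.pdb"))
  writeLines("i\tj\tinteraction\n1\t4\tNONCANONICAL",
             file.path(dir, "loop1.pairs.tsv"))
  lib <- read_motif_library(dir)
  expect_length(lib, 1)
  expect_equal(lib[[1]]$id, "loop1")
  expect_equal(lib[[1]]$pairs$interaction, "NONCANONICAL")
  expect_length(lib[[1]]$residues, 4)
})

test_that("restraint dialects emit the expected records", {
  one_pair_ss <- function() {
    structure(list(pairs = data.frame(
      key_i = "A:1:", key_j = "B:1:", chain_i = "A", seqid_i = 1L,
      chain_j = "B", seqid_j = 1L, interaction = "WC", best_rmsd = 0,
      step = 1L, stringsAsFactors = FALSE)),
      class = "na_secondary_structure")
  }
  d <- make_duplex("G", "A_RNA")
  ss <- one_pair_ss()

  refmac <- write_restraints(ss, d, "REFMAC")
  expect_equal(sum(grepl("^exte dist", refmac)), 3)  # G.C donor/acceptors
  expect_true(any(grepl("value 2.90 sigma 0.15", refmac)))

  au <- make_duplex("A", "A_RNA")
  expect_equal(sum(grepl("^exte dist", write_restraints(one_pair_ss(), au,
                                                        "REFMAC"))), 2)

  phenix <- write_restraints(ss, d, "PHENIX")
  expect_equal(sum(grepl("geometry_restraints.edits.bond", phenix)), 3)
  expect_gt(length(write_restraints(ss, d, "COOT")), 1)
  expect_gt(length(write_restraints(ss, d, "ISOLDE")), 1)

  # unknown base identity falls back to one glycosidic N-N restraint
  d_unk <- d
  for (cid in names(d_unk$chains)) {
    d_unk$chains[[cid]]$residues <- lapply(d_unk$chains[[cid]]$residues,
                                           function(r) {
                                             r$name <- "N"; r
                                           })
  }
  ss_unk <- ss
  unk <- write_restraints(ss_unk, d_unk, "REFMAC")
  expect_equal(sum(grepl("^exte dist", unk)), 1)
  expect_true(any(grepl("value 8.90 sigma 0.30", unk)))

  pml <- write_restraints(ss, d, "PYMOL")
  expect_equal(sum(grepl("^distance pair_", pml)), nrow(ss$pairs))

  expect_error(write_restraints(ss, d, "BUCCANEER"))

  empty <- ss
  empty$pairs <- empty$pairs[0, ]
  expect_equal(sum(grepl("^exte dist", write_restraints(empty, d,
                                                        "REFMAC"))), 0)
})

test_that("dot-bracket renders nesting, pseudoknots and unpaired chains", {
  d <- make_duplex("GAUC", "A_RNA")
  ch <- d$chains[["A"]]
  no_pairs <- structure(list(pairs = data.frame(
    key_i = character(0), key_j = character(0), chain_i = character(0),
    seqid_i = integer(0), chain_j = character(0), seqid_j = integer(0),
    interaction = character(0), best_rmsd = numeric(0), step = integer(0))),
    class = "na_secondary_structure")
  expect_equal(to_dotbracket(no_pairs, ch), "....")

  # two crossing pairs on a 4-residue toy: brute force says the maximum
  # nested subset has size one, so one () and one []
  crossing <- no_pairs
  crossing$pairs <- data.frame(
    key_i = c("A:1:", "A:2:"), key_j = c("A:3:", "A:4:"),
    chain_i = "A", seqid_i = c(1L, 2L), chain_j = "A",
    seqid_j = c(3L, 4L), interaction = "WC", best_rmsd = 0, step = 1L)
  db <- to_dotbracket(crossing, ch)
  # brute force: the maximum nested subset among two crossing pairs has
  # size one, so exactly one pair is rendered () and the other []
  expect_equal(sort(strsplit(db, "")[[1]]), sort(c("(", ")", "[", "]")))
  expect_true(db %in% c("([)]", "[(])"))
})
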