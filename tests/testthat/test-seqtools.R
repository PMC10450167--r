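# Alignment scoring, p-values, Stockholm encoding, database search,
# validation and sequence randomization.

test_that("alignment scores follow the product model with the same-class
           pair correction", {
  # confident profile over GAUC, clipped at 0.999
  probs <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  prof <- new_probability_profile(probs)
  tgt <- target_sequence("t", "GAUC")
  sc <- alignment_score(prof, tgt, 0)
  expect_equal(sc$log_score, 4 * log(0.999), tolerance = 1e-12)

  # one internal WC pair aligned to opposite classes: correction 1
  prof_p <- new_probability_profile(probs, pairs_internal = cbind(1, 4))
  expect_equal(alignment_score(prof_p, tgt, 0)$log_score, sc$log_score,
               tolerance = 1e-12)
  # aligned to same-class letters: exactly log 10 down
  tgt_gg <- target_sequence("t", "GAUG")
  delta <- alignment_score(prof_p, tgt_gg, 0)$log_score -
    alignment_score(new_probability_profile(probs), tgt_gg, 0)$log_score
  expect_equal(delta, log(0.1), tolerance = 1e-12)
  expect_equal(alignment_score(prof_p, tgt_gg, 0)$n_corrected_pairs, 1L)

  # uniform profile scores n log 0.5 everywhere; N letters count as 0.5
  uni <- new_probability_profile(matrix(0.5, 3, 2))
  tgt2 <- target_sequence("t", "GANUA")
  for (off in 0:2) {
    expect_equal(alignment_score(uni, tgt2, off)$log_score, 3 * log(0.5),
                 tolerance = 1e-12)
  }
  expect_error(alignment_score(uni, tgt2, 4), "range")
})

test_that("enumerate_alignments matches a brute-force oracle on 100 random
           instances and breaks ties by smaller offset", {
  set.seed(14)
  for (rep in 1:100) {
    n <- sample(2:15, 1)
    L <- sample((n + 1):60, 1)
    probs <- matrix(runif(2 * n, 0.01, 1), n, 2)
    n_pairs <- sample(0:2, 1)
    pairs <- if (n_pairs > 0 && n >= 4) {
      t(replicate(n_pairs, sort(sample(n, 2))))
    } else NULL
    prof <- new_probability_profile(probs, pairs)
    letters <- sample(c("A", "C", "G", "U", "N"), L, replace = TRUE)
    tgt <- target_sequence("t", paste(letters, collapse = ""))
    cands <- enumerate_alignments(prof, tgt)
    expect_equal(nrow(cands), L - n + 1)
    oracle <- brute_force_scores(prof$probs, prof$pairs_internal, letters)
    expect_equal(cands$log_score[order(cands$offset)], oracle,
                 tolerance = 1e-12)
    expect_equal(cands$offset[1], which.max(oracle) - 1L)
  }

  # exact ties resolve to the smallest offset
  uni <- new_probability_profile(matrix(0.5, 2, 2))
  cands <- enumerate_alignments(uni, target_sequence("t", "AAAA"))
  expect_equal(cands$offset[1], 0L)
})

test_that("raising the correct-class probability never lowers the
           true-offset score", {
  set.seed(15)
  tgt <- target_sequence("t", random_rna_sequence(30, seed = 6))
  cls <- letter_class(strsplit(tgt$letters, "")[[1]])
  for (rep in 1:20) {
    n <- 8
    off <- sample(0:(30 - n), 1)
    probs <- matrix(runif(2 * n, 0.1, 0.9), n, 2)
    prof <- new_probability_profile(probs)
    s0 <- alignment_score(prof, tgt, off)$log_score
    i <- sample(n, 1)
    correct <- cls[off + i]
    probs2 <- probs
    probs2[i, correct] <- min(probs2[i, correct] + 0.3, 1)
    probs2[i, 3 - correct] <- 1 - probs2[i, correct]
    s1 <- alignment_score(new_probability_profile(probs2), tgt,
                          off)$log_score
    expect_gte(s1, s0 - 1e-12)
  }
})

test_that("p-values reduce to the single-placement empirical exceedance when
           the target is fragment-sized, and saturate sensibly", {
  set.seed(16)
  probs <- matrix(runif(16, 0.05, 0.95), 8, 2)
  prof <- new_probability_profile(probs)
  bg <- alignment_background(prof, target_len = 8, n_random = 300, seed = 4)
  expect_equal(bg$n_positions, 1L)
  x <- mean(bg$samples)
  p <- estimate_pvalue(x, prof, target_len = 8, background = bg)
  expect_equal(as.numeric(p),
               (1 + sum(bg$samples >= x - 1e-12)) / 301)

  # best score below the whole background: p ~ 1
  p_low <- estimate_pvalue(min(bg$samples) - 10, prof, target_len = 8,
                           background = bg)
  expect_equal(as.numeric(p_low), 1, tolerance = 1e-6)

  # far above the background: Gumbel tail extrapolation below the floor
  p_hi <- estimate_pvalue(0, prof, target_len = 8, background = bg)
  expect_lt(as.numeric(p_hi), 1 / 301)

  # degenerate background
  const <- new_probability_profile(matrix(0.5, 5, 2))
  expect_warning(p1 <- estimate_pvalue(5 * log(0.5), const, target_len = 20,
                                       n_random = 200, seed = 2),
                 "degenerate")
  expect_equal(as.numeric(p1), 1)

  expect_error(alignment_background(prof, target_len = 8, n_random = 50),
               "n_random")
})

test_that("null p-values are roughly uniform (sanity scale)", {
  set.seed(2)
  n <- 10
  # continuous per-position confidences, as a classifier produces; exactly
  # repeated probabilities would tie scores and make p conservative
  p_pur <- ifelse(runif(n) < 0.5, 0.95, 0.05) + rnorm(n, 0, 0.015)
  prof <- new_probability_profile(cbind(p_pur, 1 - p_pur))
  ps <- vapply(1:80, function(i) {
    tgt <- target_sequence("t", random_rna_sequence(50, seed = 7000 + i))
    best <- enumerate_alignments(prof, tgt)[1, ]
    as.numeric(estimate_pvalue(as.list(best), prof, 50, n_random = 200,
                               seed = 8000 + i))
  }, numeric(1))
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
  expect_gt(min(ps), 0)
  expect_lte(max(ps), 1)
})

test_that("stockholm encoding reproduces column probabilities and is valid
           Stockholm 1.0", {
  probs <- rbind(c(0.999, 0.001), c(0.5, 0.5), c(0.25, 0.75))
  prof <- new_probability_profile(probs)
  sto <- stockholm_from_profile(prof, "...", n_rows = 100)
  expect_equal(sto[1], "# STOCKHOLM 1.0")
  expect_equal(sto[length(sto)], "//")
  rows <- sto[grepl("^seq", sto)]
  expect_length(rows, 100)
  mat <- do.call(rbind, strsplit(sub("^seq\\d+\\s+", "", rows), ""))
  # column 1: p_purine clipped to 0.999 -> 100 purines, 50 A + 50 G
  expect_equal(sum(mat[, 1] %in% c("A", "G")), 100)
  expect_equal(sum(mat[, 1] == "A"), 50)
  # column 2: exactly half purine
  expect_equal(sum(mat[, 2] %in% c("A", "G")), 50)
  # column 3: frequencies match probabilities within 1/n_rows
  expect_lt(abs(mean(mat[, 3] %in% c("A", "G")) - 0.25), 0.01 + 1e-9)

  ss_line <- sto[grepl("SS_cons", sto)]
  expect_length(ss_line, 1)
  expect_error(stockholm_from_profile(prof, "...."), "length")
})

test_that("profile-HMM identification through nhmmer ranks the true sequence
           first against decoys, and decoy-only databases stay insignificant",
          {
  cl <- get_demo_classifier()
  truth <- random_rna_sequence(120, seed = 91)
  d <- make_duplex(truth, "A_RNA", include_complement = FALSE)
  dd <- make_duplex(truth, "A_RNA")
  map <- simulate_map(dd, 3.0, noise_sd = 0.1, seed = 8)
  db <- withr::local_tempfile(fileext = ".fasta")
  write_decoy_db(db, truth = truth, n_decoys = 50, len = 120, seed = 3)
  hits <- identify_sequence(dd, map, db, cl, mode = "HMM", engine = "hmmer")
  expect_equal(hits$target_id[1], "truth")
  expect_lt(hits$e_value[1], 0.1)

  db2 <- withr::local_tempfile(fileext = ".fasta")
  write_decoy_db(db2, truth = NULL, n_decoys = 50, len = 120, seed = 3)
  hits2 <- identify_sequence(dd, map, db2, cl, mode = "HMM",
                             engine = "hmmer")
  expect_true(nrow(hits2) == 0 || min(hits2$e_value) > 0.1)
})

test_that("CM searches demand INFERNAL and fail with an actionable message
           when it is absent", {
  cl <- get_demo_classifier()
  d <- make_duplex("GAUCGAUCGAUCGAUCGAUC", "A_RNA")
  map <- simulate_map(d, 3.0, seed = 1)
  db <- withr::local_tempfile(fileext = ".fasta")
  write_decoy_db(db, truth = NULL, n_decoys = 2, len = 60, seed = 1)
  expect_error(identify_sequence(d, map, db, cl, mode = "CM",
                                 engine = "hmmer"),
               "INFERNAL")
  withr::with_envvar(c(PATH = ""), {
    expect_error(identify_sequence(d, map, db, cl, mode = "CM",
                                   engine = "infernal"),
                 "cmbuild|INFERNAL")
  })
})

test_that("assign_fragment recovers the planted offset, rebuilds bases, and
           degenerate repeats tie to the smallest offset", {
  cl <- get_demo_classifier()
  tgt_full <- random_rna_sequence(150, seed = 55)
  frag_seq <- substr(tgt_full, 61, 90)
  d <- make_duplex(frag_seq, "A_RNA")
  map <- simulate_map(d, 3.0, noise_sd = 0.1, seed = 12)
  ss <- assign_base_pairs(d)
  frag <- chain_fragments(d$chains[["A"]])[[1]]
  target <- target_sequence("tgt", tgt_full)
  a <- assign_fragment(d, map, frag, target, cl, ss = ss, seed = 6)
  expect_equal(a$best$offset, 60L)
  expect_equal(a$assigned_letters, frag_seq)
  expect_lt(a$pvalue, 0.01)
  # the fragment's residues now carry the assigned identities
  new_names <- vapply(a$model$chains[["A"]]$residues, `[[`, "", "name")
  expect_equal(paste(new_names, collapse = ""), frag_seq)

  # purine/pyrimidine-degenerate repeat: tied offsets, smallest returned
  rep_target <- target_sequence("rep", strrep("AG", 20))
  probs <- matrix(rep(c(0.9, 0.1), 4), 4, 2, byrow = TRUE)
  prof <- new_probability_profile(probs)
  cands <- enumerate_alignments(prof, rep_target)
  expect_equal(cands$offset[1], 0L)
  expect_equal(cands$log_score[1], cands$log_score[2], tolerance = 1e-12)

  expect_error(assign_fragment(d, map, frag, target_sequence("s", "GAUC"),
                               cl, ss = ss),
               "longer than target")
})

test_that("validation flags an engineered +1 register shift beyond the
           breakpoint and stays silent on the correct model", {
  cl <- get_demo_classifier()
  X <- random_rna_sequence(51, seed = 77)
  lets <- strsplit(X, "")[[1]]
  k <- 25
  shifted <- c(lets[1:k], lets[(k + 2):51])
  mod_sh <- make_duplex(paste(shifted, collapse = ""), "A_RNA")
  map_sh <- simulate_map(mod_sh, 3.0, noise_sd = 0.1, seed = 5)
  seqs <- list(A = target_sequence("A", X))
  fl <- suppressMessages(
    validate_model(mod_sh, map_sh, seqs, cl, window = 20, stride = 5,
                   seed = 2))
  expect_gt(nrow(fl), 0)
  expect_true(all(fl$shift == 1L))
  expect_true(all(fl$seqid_end > k))

  mod_ok <- make_duplex(paste(lets[1:50], collapse = ""), "A_RNA")
  map_ok <- simulate_map(mod_ok, 3.0, noise_sd = 0.1, seed = 5)
  fl0 <- suppressMessages(
    validate_model(mod_ok, map_ok, seqs, cl, window = 20, stride = 5,
                   seed = 2))
  expect_equal(nrow(fl0), 0)

  # chains without a matching sequence are reported and skipped
  expect_message(
    validate_model(mod_ok, map_ok, list(Z = target_sequence("Z", X)), cl,
                   window = 20, seed = 2),
    "no matching sequence")
})

test_that("randomize_sequence swaps classes while preserving WC
           complementarity and honours the fraction", {
  d <- make_duplex("GAUCGAUCGG", "A_RNA")
  expect_identical(randomize_sequence(d, 0), d)

  strand <- make_duplex("GAUCGA", "A_RNA", include_complement = FALSE)
  ss0 <- assign_base_pairs(strand)
  r1 <- randomize_sequence(strand, 1, ss = ss0, seed = 3)
  old <- letter_class(vapply(all_residues(strand),
                             function(r) base_letter(r$name), ""))
  new <- letter_class(vapply(all_residues(r1),
                             function(r) base_letter(r$name), ""))
  expect_true(all(old != new))

  ss <- assign_base_pairs(d)
  rd <- randomize_sequence(d, 0.9, ss = ss, seed = 4)
  la <- vapply(rd$chains[["A"]]$residues, function(r) base_letter(r$name), "")
  lb <- vapply(rd$chains[["B"]]$residues, function(r) base_letter(r$name), "")
  expect_true(all(mapply(function(a, b) wc_complement_letter(a, "RNA") == b,
                         la, rev(lb))))
  n_changed <- sum(la != strsplit("GAUCGAUCGG", "")[[1]]) +
    sum(lb != vapply(rev(strsplit("GAUCGAUCGG", "")[[1]]),
                     wc_complement_letter, "", kind = "RNA"))
  expect_gte(n_changed, floor(0.9 * 20))
})
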