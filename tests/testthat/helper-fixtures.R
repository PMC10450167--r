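# Shared fixtures for the test suite. Everything is generated in code and
# cached per test run; nothing is read from disk except shipped package data.

.test_cache <- new.env(parent = emptyenv())

# small classifier for pipeline tests: cheap but accurate on clean 3 A maps
get_demo_classifier <- function() {
  if (is.null(.test_cache$demo_classifier)) {
    ts <- training_set(n_per_class = 150, resolutions = 3, noise_sd = 0.1,
                       seed = 7)
    .test_cache$demo_classifier <-
      train_classifier(ts, training_config(epochs = 60, seed = 3))
  }
  .test_cache$demo_classifier
}

# add seeded Gaussian coordinate noise to every atom of a structure
perturb_structure <- function(model, sd, seed) {
  set.seed(seed)
  model$chains <- lapply(model$chains, function(ch) {
    ch$residues <- lapply(ch$residues, function(r) {
      r$xyz <- r$xyz + matrix(stats::rnorm(length(r$xyz), sd = sd), ncol = 3)
      r
    })
    ch
  })
  model
}

# a deliberately non-helical extended strand (evenly spaced along a line)
make_extended_strand <- function(n = 10L) {
  tmpl <- nucleotide_template("U")
  res <- lapply(seq_len(n), function(i) {
    r <- tmpl
    r$xyz <- sweep(tmpl$xyz, 2, c(-6.5 * i, 0, 0), "+")
    r$seqid <- i
    r$chain_id <- "E"
    r
  })
  new_structure(list(new_chain("E", res, kind = "RNA")))
}

# independent superposition oracle (bio3d), for cross-checking kabsch()
bio3d_rmsd <- function(x, y) {
  fit <- bio3d::fit.xyz(fixed = as.numeric(t(y)), mobile = as.numeric(t(x)),
                        fixed.inds = seq_len(3 * nrow(y)),
                        mobile.inds = seq_len(3 * nrow(x)))
  sqrt(mean(rowSums((matrix(fit, ncol = 3, byrow = TRUE) - y)^2)))
}

# brute-force alignment scorer, independent of the package implementation:
# direct per-offset product evaluation from first principles
brute_force_scores <- function(probs, pairs, letters) {
  cls_of <- function(l) {
    if (l %in% c("A", "G")) 1L else if (l %in% c("C", "U", "T")) 2L else 0L
  }
  n <- nrow(probs)
  L <- length(letters)
  vapply(0:(L - n), function(off) {
    s <- 0
    for (i in seq_len(n)) {
      ci <- cls_of(letters[off + i])
      s <- s + if (ci == 0L) log(0.5) else log(probs[i, ci])
    }
    if (!is.null(pairs) && nrow(pairs) > 0) {
      for (r in seq_len(nrow(pairs))) {
        ca <- cls_of(letters[off + pairs[r, 1]])
        cb <- cls_of(letters[off + pairs[r, 2]])
        if (ca == cb && ca > 0L) s <- s + log(0.1)
      }
    }
    s
  }, numeric(1))
}

# write a small P1 MTZ through gemmi (independent oracle for the MTZ reader)
write_gemmi_mtz <- function(path, cell, hkl_f_phi) {
  py <- tempfile(fileext = ".py")
  dat <- tempfile(fileext = ".txt")
  utils::write.table(hkl_f_phi, dat, row.names = FALSE, col.names = FALSE)
  writeLines(c(
    "import gemmi, numpy as np, sys",
    "mtz = gemmi.Mtz(with_base=False)",
    "mtz.spacegroup = gemmi.SpaceGroup('P 1')",
    sprintf("mtz.set_cell_for_all(gemmi.UnitCell(%f, %f, %f, %f, %f, %f))",
            cell[1], cell[2], cell[3], cell[4], cell[5], cell[6]),
    "mtz.add_dataset('d')",
    "for lab, typ in [('H','H'),('K','H'),('L','H'),('FWT','F'),('PHWT','P')]:",
    "    mtz.add_column(lab, typ)",
    sprintf("data = np.loadtxt('%s', ndmin=2).astype(np.float32)", dat),
    "mtz.set_data(data)",
    sprintf("mtz.write_to_file('%s')", path)), py)
  status <- system2("python", py, stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(status, "status")) && attr(status, "status") != 0) {
    stop("gemmi MTZ fixture generation failed: ",
         paste(status, collapse = "\n"))
  }
  path
}

# decoy FASTA database: shuffled/random sequences plus (optionally) a truth
write_decoy_db <- function(path, truth = NULL, n_decoys = 50L, len = 200L,
                           seed = 1L) {
  lines <- character(0)
  for (i in seq_len(n_decoys)) {
    lines <- c(lines, paste0(">decoy", i),
               random_rna_sequence(len, seed = seed * 1000L + i))
  }
  if (!is.null(truth)) lines <- c(lines, ">truth", truth)
  writeLines(lines, path)
  path
}

# the full-scale classifier used by the acceptance checks: 2000 balanced
# descriptors from simulated 3.0 A maps, 200 training epochs, with 100
# examples per class held out for evaluation
get_full_classifier <- function() {
  if (is.null(.test_cache$full_classifier)) {
    ts <- training_set(n_per_class = 1000, resolutions = 3.0,
                       noise_sd = 0.1, seed = 101)
    pur <- which(ts$labels == "PURINE")
    pyr <- which(ts$labels == "PYRIMIDINE")
    test_idx <- c(pur[1:100], pyr[1:100])
    train <- list(x = ts$x[-test_idx, ], labels = ts$labels[-test_idx])
    test <- list(x = ts$x[test_idx, ], labels = ts$labels[test_idx])
    model <- train_classifier(train, training_config(epochs = 200,
                                                     seed = 202))
    .test_cache$full_classifier <- list(model = model,
                                        holdout_acc = evaluate(model, test))
  }
  .test_cache$full_classifier
}
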