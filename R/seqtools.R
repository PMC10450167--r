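#' @title Sequence identification via covariance-model / profile-HMM search
#' @description The per-residue purine/pyrimidine probabilities of a model
#'   fragment are encoded as a multiple sequence alignment whose column
#'   letter frequencies equal the predicted probabilities; together with the
#'   backbone-derived base-pairing pattern (as an SS_cons line) this forms a
#'   Stockholm file. The Stockholm alignment is compiled into a covariance
#'   model with the INFERNAL suite (cmbuild, cmcalibrate) and used to query
#'   sequence databases with cmsearch; profile-HMM queries add `--hmmonly`
#'   and skip calibration. When INFERNAL is not installed the package can
#'   alternatively run profile-HMM searches through HMMER's nhmmer, which
#'   ignores the base-pairing information.
#' @name seqtools
NULL

#' Is the INFERNAL suite (cmbuild/cmcalibrate/cmsearch) on the PATH?
#' @return logical
#' @export
infernal_available <- function() {
  all(nzchar(Sys.which(c("cmbuild", "cmcalibrate", "cmsearch"))))
}

#' Is HMMER's nhmmer on the PATH?
#' @return logical
#' @export
hmmer_available <- function() nzchar(Sys.which("nhmmer"))

#' Encode a probability profile as a Stockholm alignment
#'
#' Each column of the `n_rows`-sequence alignment carries
#' `round(n_rows * p_purine)` purine letters (split as evenly as possible
#' between A and G) and pyrimidine letters (split between C and U, or C and
#' T for DNA) otherwise; rows are shuffled column-independently with a
#' fixed seed so no row is systematically purine-rich. The base-pairing
#' pattern goes into the `#=GC SS_cons` line (only the maximal nested
#' subset is kept; pseudoknotted pairs are dropped to dots).
#'
#' @param profile `na_probability_profile`
#' @param ss_string dot-bracket string, same length as the profile
#' @param n_rows alignment depth (default 100)
#' @param seed shuffling seed
#' @param kind "RNA" or "DNA"
#' @param id alignment identifier
#' @return character vector of Stockholm 1.0 lines
#' @export
stockholm_from_profile <- function(profile, ss_string, n_rows = 100L,
                                   seed = 1L, kind = "RNA",
                                   id = "nucassign_profile") {
  n <- nrow(profile$probs)
  if (nchar(ss_string) != n) {
    stop("ss_string length ", nchar(ss_string), " != profile length ", n)
  }
  pyr2 <- if (kind == "RNA") "U" else "T"
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  set.seed(seed)
  cols <- matrix("", n_rows, n)
  for (j in seq_len(n)) {
    k <- round(n_rows * profile$probs[j, 1])
    letters_j <- c(rep("A", ceiling(k / 2)), rep("G", floor(k / 2)),
                   rep("C", ceiling((n_rows - k) / 2)),
                   rep(pyr2, floor((n_rows - k) / 2)))
    cols[, j] <- sample(letters_j)
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  # keep only nested round brackets in SS_cons
  ss <- strsplit(ss_string, "")[[1]]
  ss[!ss %in% c("(", ")")] <- "."
  rows <- apply(cols, 1, paste, collapse = "")
  names_w <- max(nchar("#=GC SS_cons"), nchar("seq0000"))
  pad <- function(x) formatC(x, width = names_w, flag = "-")
  c("# STOCKHOLM 1.0",
    paste0("#=GF ID ", id),
    "",
    sprintf("%s %s", pad(sprintf("seq%04d", seq_len(n_rows))), rows),
    sprintf("%s %s", pad("#=GC SS_cons"), paste(ss, collapse = "")),
    "//")
}

run_tool <- function(cmd, args) {
  out <- suppressWarnings(system2(cmd, args, stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop(cmd, " failed (exit ", status, "):\n",
         paste(utils::tail(out, 20), collapse = "\n"))
  }
  out
}

parse_tblout <- function(path, evalue_col, from_col, to_col) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L) return(NULL)
  f <- strsplit(trimws(lines), "[ \t]+")
  data.frame(target_id = vapply(f, `[[`, "", 1L),
             e_value = as.numeric(vapply(f, `[[`, "", evalue_col)),
             start = as.integer(vapply(f, `[[`, "", from_col)),
             end = as.integer(vapply(f, `[[`, "", to_col)),
             stringsAsFactors = FALSE)
}

#' Identify the most plausible database sequence for a model
#'
#' For every continuous polynucleotide fragment of at least `min_fragment`
#' residues a probability profile and a backbone-derived secondary
#' structure string are computed, encoded in Stockholm format and used to
#' query the FASTA database `db`. With `engine = "infernal"`, CM mode runs
#' cmbuild + cmcalibrate + cmsearch, and HMM mode runs cmbuild + cmsearch
#' --hmmonly (no calibration). With `engine = "hmmer"` (HMM mode only) the
#' query runs through nhmmer. Hits are merged across fragments and the
#' `top_n` with the lowest E-values returned.
#'
#' @param model `na_structure`
#' @param map `na_density_map`
#' @param db path to a FASTA sequence database
#' @param classifier trained classifier
#' @param mode "CM" (uses base-pairing) or "HMM"
#' @param top_n hits to return (default 3)
#' @param engine "infernal" or "hmmer"
#' @param min_fragment minimum fragment length queried (default 20)
#' @param ss optional precomputed secondary structure
#' @param verbose log the external calls
#' @return data.frame of hits sorted by E-value: target_id, e_value, mode,
#'   start, end, fragment
#' @export
identify_sequence <- function(model, map, db, classifier,
                              mode = c("CM", "HMM"), top_n = 3L,
                              engine = c("infernal", "hmmer"),
                              min_fragment = 20L, ss = NULL,
                              verbose = FALSE) {
  mode <- match.arg(mode)
  engine <- match.arg(engine)
  if (!file.exists(db)) stop("sequence database not found: ", db)
  if (engine == "infernal" && !infernal_available()) {
    stop("INFERNAL executables (cmbuild/cmcalibrate/cmsearch) not found ",
         "on PATH; install INFERNAL or use engine = \"hmmer\" for ",
         "profile-HMM searches")
  }
  if (engine == "hmmer") {
    if (mode == "CM") {
      stop("covariance-model (CM) searches require INFERNAL; ",
           "engine = \"hmmer\" supports mode = \"HMM\" only")
    }
    if (!hmmer_available()) stop("nhmmer not found on PATH")
  }
  if (is.null(ss)) ss <- assign_base_pairs(model)
  hits <- NULL
  frag_i <- 0L
  for (ch in model$chains) {
    for (frag in chain_fragments(ch)) {
      if (frag$length < min_fragment) next
      frag_i <- frag_i + 1L
      profile <- base_probability_profile(model, map, frag, classifier, ss)
      partner <- rep(NA_integer_, frag$length)
      if (nrow(profile$pairs_internal) > 0) {
        partner[profile$pairs_internal[, 1]] <- profile$pairs_internal[, 2]
        partner[profile$pairs_internal[, 2]] <- profile$pairs_internal[, 1]
      }
      ss_string <- dotbracket_from_partners(partner)
      if (mode == "HMM") {
        # profile-HMM search ignores base-pairing information
        ss_string <- strrep(".", frag$length)
      }
      sto <- tempfile(fileext = ".sto")
      writeLines(stockholm_from_profile(profile, ss_string, kind = ch$kind,
                                        id = sprintf("frag%03d", frag_i)),
                 sto)
      tbl <- tempfile(fileext = ".tbl")
      if (engine == "infernal") {
        cm <- tempfile(fileext = ".cm")
        run_tool("cmbuild", c("-F", cm, sto))
        if (mode == "CM") {
          if (verbose) message("cmcalibrate ", cm)
          run_tool("cmcalibrate", cm)
          run_tool("cmsearch", c("--tblout", tbl, cm, db))
        } else {
          if (verbose) message("HMM mode: skipping cmcalibrate")
          run_tool("cmsearch", c("--hmmonly", "--tblout", tbl, cm, db))
        }
        h <- parse_tblout(tbl, evalue_col = 16L, from_col = 8L, to_col = 9L)
      } else {
        if (verbose) message("nhmmer ", sto)
        run_tool("nhmmer", c("--tblout", tbl, sto, db))
        h <- parse_tblout(tbl, evalue_col = 13L, from_col = 7L, to_col = 8L)
      }
      if (!is.null(h)) {
        h$mode <- mode
        h$fragment <- sprintf("%s:%d+%d", frag$chain_id, frag$start,
                              frag$length)
        hits <- rbind(hits, h)
      }
    }
  }
  if (frag_i == 0L) stop("no fragment of >= ", min_fragment, " residues")
  if (is.null(hits)) {
    return(data.frame(target_id = character(0), e_value = numeric(0),
                      start = integer(0), end = integer(0),
                      mode = character(0), fragment = character(0)))
  }
  hits <- hits[order(hits$e_value, hits$target_id), , drop = FALSE]
  utils::head(hits, top_n)
}
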