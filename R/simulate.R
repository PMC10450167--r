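#' @title Simulated density maps and synthetic training data
#' @description Maps are simulated as sums of atom-centred Gaussians with
#'   width tied to the nominal resolution (sigma = 0.225 * resolution, so
#'   the Fourier amplitude falls to about 1/e at spatial frequency
#'   1/resolution), weighted by atomic number and occupancy, with optional
#'   seeded white noise expressed as a fraction of the map standard
#'   deviation. This emulates the blurring of experimental reconstructions
#'   well enough for descriptor/classifier work; it deliberately ignores
#'   scattering-factor detail, solvent, CTF and radiation damage.
#' @name simulate
NULL

Z_EFF <- c(C = 6, N = 7, O = 8, P = 15, H = 1, S = 16)

#' Simulate a density map from an atomic model
#'
#' @param model `na_structure`
#' @param resolution nominal resolution in Angstrom
#' @param grid_spacing voxel size (default `resolution / 3`)
#' @param noise_sd white-noise level as a fraction of the noise-free map
#'   standard deviation (default 0)
#' @param b_factor extra isotropic blurring in Angstrom^2 added to the
#'   resolution term (default 0)
#' @param padding box padding beyond the model extent (default 5 Angstrom)
#' @param seed RNG seed for the noise (default 1)
#' @return non-periodic `na_density_map` in an orthogonal box
#' @export
simulate_map <- function(model, resolution, grid_spacing = resolution / 3,
                         noise_sd = 0, b_factor = 0, padding = 5, seed = 1) {
  stopifnot(resolution > 0, noise_sd >= 0)
  res <- all_residues(model)
  if (length(res) == 0L) stop("empty model")
  xyz <- do.call(rbind, lapply(res, `[[`, "xyz"))
  elements <- unlist(lapply(res, `[[`, "elements"))
  occ <- unlist(lapply(res, `[[`, "occ"))
  keep <- elements != "H"
  xyz <- xyz[keep, , drop = FALSE]
  w <- Z_EFF[elements[keep]]
  w[is.na(w)] <- 6
  w <- w * occ[keep]
  lo <- apply(xyz, 2, min) - padding
  hi <- apply(xyz, 2, max) + padding
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / grid_spacing)))
  cell <- c(dims * grid_spacing, 90, 90, 90)
  sigma2 <- (0.225 * resolution)^2 + b_factor / (8 * pi^2)
  sigma <- sqrt(sigma2)
  rcut <- 3.5 * sigma
  nc <- ceiling(rcut / grid_spacing)
  vals <- array(0, dim = dims)
  ax <- lapply(1:3, function(k) lo[k] + (seq_len(dims[k]) - 1) * grid_spacing)
  for (a in seq_len(nrow(xyz))) {
    ctr <- xyz[a, ]
    i0 <- pmax(1L, pmin(dims, as.integer(floor((ctr - lo) / grid_spacing)) +
                          1L))
    ii <- max(1L, i0[1] - nc):min(dims[1], i0[1] + nc)
    jj <- max(1L, i0[2] - nc):min(dims[2], i0[2] + nc)
    kk <- max(1L, i0[3] - nc):min(dims[3], i0[3] + nc)
    gx <- exp(-(ax[[1]][ii] - ctr[1])^2 / (2 * sigma2))
    gy <- exp(-(ax[[2]][jj] - ctr[2])^2 / (2 * sigma2))
    gz <- exp(-(ax[[3]][kk] - ctr[3])^2 / (2 * sigma2))
    vals[ii, jj, kk] <- vals[ii, jj, kk] +
      w[a] * (gx %o% gy %o% gz)
  }
  if (noise_sd > 0) {
    s <- stats::sd(as.numeric(vals))
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    set.seed(seed)
    vals <- vals + array(stats::rnorm(prod(dims), sd = noise_sd * s),
                         dim = dims)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }
  m <- new_density_map(vals, cell, periodic = FALSE)
  # voxel (1,1,1) sits at Cartesian `lo`: record it as a fractional offset
  m$origin_frac <- as.numeric(m$frac %*% lo)
  m
}

#' Seeded random RNA sequence
#'
#' @param n length
#' @param seed RNG seed
#' @param gc G+C fraction (default 0.5)
#' @return single character string over A/C/G/U
#' @export
random_rna_sequence <- function(n, seed = 1, gc = 0.5) {
  stopifnot(n >= 1, gc >= 0, gc <= 1)
  set.seed(seed)
  paste(sample(c("G", "C", "A", "U"), n, replace = TRUE,
               prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Generate a balanced labelled descriptor set from synthetic duplexes
#'
#' Random-sequence ideal A-RNA duplexes are generated, maps simulated at the
#' requested resolutions (cycled), and a residue descriptor extracted for
#' every nucleotide with ground-truth purine/pyrimidine labels.
#'
#' @param n_per_class descriptors per class in the returned set
#' @param resolutions resolutions to simulate at (default 3.0)
#' @param noise_sd map noise level (default 0.1)
#' @param seed RNG seed
#' @param duplex_length residues per strand of each generated duplex
#' @return list with `x` (n x 403 descriptor matrix), `labels` (character
#'   "PURINE"/"PYRIMIDINE"), `meta` (data.frame of provenance)
#' @export
training_set <- function(n_per_class, resolutions = 3.0, noise_sd = 0.1,
                         seed = 1, duplex_length = 20L) {
  stopifnot(n_per_class >= 1)
  cloud <- canonical_cloud()
  set.seed(seed)
  cap <- 4L * n_per_class
  x <- matrix(NA_real_, cap, 403L)
  labels <- character(cap)
  meta <- vector("list", cap)
  n_got <- 0L
  duplex_i <- 0L
  enough <- function() {
    sum(labels[seq_len(n_got)] == "PURINE") >= n_per_class &&
      sum(labels[seq_len(n_got)] == "PYRIMIDINE") >= n_per_class
  }
  while (!enough() && n_got < cap) {
    duplex_i <- duplex_i + 1L
    sequence <- paste(sample(c("A", "C", "G", "U"), duplex_length,
                             replace = TRUE), collapse = "")
    resol <- resolutions[1L + (duplex_i - 1L) %% length(resolutions)]
    d <- make_duplex(sequence, "A_RNA")
    map <- simulate_map(d, resolution = resol, noise_sd = noise_sd,
                        seed = sample.int(2^31 - 1L, 1L))
    for (r in all_residues(d)) {
      if (n_got >= cap) break
      n_got <- n_got + 1L
      x[n_got, ] <- extract_descriptor(map, r, cloud)$values
      labels[n_got] <- base_moiety_class(r)
      meta[[n_got]] <- data.frame(duplex = duplex_i, resolution = resol,
                                  residue = residue_key(r), name = r$name)
    }
  }
  x <- x[seq_len(n_got), , drop = FALSE]
  labels <- labels[seq_len(n_got)]
  meta <- do.call(rbind, meta[seq_len(n_got)])
  # balance classes, preserving generation order
  idx_pur <- which(labels == "PURINE")[seq_len(n_per_class)]
  idx_pyr <- which(labels == "PYRIMIDINE")[seq_len(n_per_class)]
  if (anyNA(idx_pur) || anyNA(idx_pyr)) {
    stop("could not generate enough residues of both classes")
  }
  keep <- sort(c(idx_pur, idx_pyr))
  list(x = x[keep, , drop = FALSE], labels = labels[keep],
       meta = meta[keep, , drop = FALSE])
}
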