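#' @title Crystallographic maps from MTZ amplitudes and phases
#' @description A minimal binary MTZ reader (machine-stamped little-endian
#'   files, the common case) feeding an inverse Fourier synthesis:
#'   rho(x) = (1/V) * sum_h F(h) exp(-2 pi i h.x), evaluated by FFT on a
#'   grid at least three times finer than the high-resolution limit in each
#'   dimension, rounded up to FFT-friendly (5-smooth) sizes. Intended for a
#'   single amplitude/phase column pair (typically a maximum-likelihood
#'   weighted 2mFo-DFc map); symmetry expansion beyond the stored
#'   reflections is out of scope (P1 or pre-expanded files).
#' @name mtz
NULL

read_mtz <- function(path) {
  info <- file.info(path)
  if (is.na(info$size) || info$size < 84) stop("not an MTZ file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 4, useBytes = TRUE)
  if (!identical(magic, "MTZ ")) stop("bad MTZ magic in ", path)
  headerposn <- readBin(con, "integer", 1, size = 4, endian = "little")
  seek(con, (headerposn - 1) * 4)
  n_hdr_bytes <- info$size - (headerposn - 1) * 4
  hdr <- readChar(con, min(n_hdr_bytes, 80 * 1000), useBytes = TRUE)
  recs <- substring(hdr, seq(1, nchar(hdr) - 79, by = 80),
                    seq(80, nchar(hdr), by = 80))
  grab <- function(key) trimws(sub(paste0("^", key, "\\s+"), "",
                                   recs[startsWith(recs, key)]))
  ncol_rec <- strsplit(grab("NCOL")[1], "\\s+")[[1]]
  ncols <- as.integer(ncol_rec[1]); nref <- as.integer(ncol_rec[2])
  cell <- as.numeric(strsplit(grab("CELL")[1], "\\s+")[[1]])[1:6]
  col_recs <- recs[startsWith(recs, "COLUMN")]
  labels <- vapply(strsplit(col_recs, "\\s+"), `[[`, "", 2L)
  seek(con, 80)
  data <- readBin(con, "numeric", n = ncols * nref, size = 4,
                  endian = "little")
  data <- matrix(data, nrow = nref, ncol = ncols, byrow = TRUE)
  colnames(data) <- labels
  list(cell = cell, data = data, labels = labels)
}

next_5smooth <- function(x) {
  n <- max(2L, as.integer(ceiling(x)))
  repeat {
    m <- n
    for (p in c(2L, 3L, 5L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 1L
  }
}

#' Real-space map from MTZ structure-factor amplitudes and phases
#'
#' @param path MTZ file
#' @param amp_label amplitude column label (default "FWT")
#' @param phase_label phase column label in degrees (default "PHWT")
#' @param oversample grid points per high-resolution-limit spacing
#'   (default 3)
#' @return periodic `na_density_map` covering one unit cell
#' @export
map_from_mtz <- function(path, amp_label = "FWT", phase_label = "PHWT",
                         oversample = 3) {
  mtz <- read_mtz(path)
  for (lab in c(amp_label, phase_label)) {
    if (!lab %in% mtz$labels) {
      stop("column '", lab, "' not in MTZ; available: ",
           paste(mtz$labels, collapse = ", "))
    }
  }
  need <- c("H", "K", "L")
  if (!all(need %in% mtz$labels)) stop("MTZ lacks H/K/L columns")
  hkl <- mtz$data[, need, drop = FALSE]
  amp <- mtz$data[, amp_label]
  phi <- mtz$data[, phase_label] * pi / 180
  keep <- is.finite(amp) & is.finite(phi)
  hkl <- round(hkl[keep, , drop = FALSE]); amp <- amp[keep]; phi <- phi[keep]
  cm <- cell_matrices(mtz$cell)
  svec <- hkl %*% cm$frac          # reciprocal-space coordinates (1/A)
  smax <- sqrt(max(rowSums(svec^2)))
  d_min <- if (smax > 0) 1 / smax else Inf
  dims <- integer(3)
  for (i in 1:3) {
    n_res <- if (is.finite(d_min)) oversample * mtz$cell[i] / d_min else 2
    n_idx <- 2 * max(abs(hkl[, i])) + 1
    dims[i] <- next_5smooth(max(n_res, n_idx, 2))
  }
  grid <- array(complex(real = 0), dim = dims)
  fill <- function(h, G) {
    idx <- (h %% dims) + 1L
    grid[idx[1], idx[2], idx[3]] <<- G
  }
  for (r in seq_len(nrow(hkl))) {
    G <- amp[r] * exp(1i * phi[r])
    fill(hkl[r, ], G)
    if (any(hkl[r, ] != 0)) fill(-hkl[r, ], Conj(G))
  }
  rho <- Re(stats::fft(grid)) / cm$volume
  new_density_map(rho, mtz$cell, origin_frac = c(0, 0, 0), periodic = TRUE)
}
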