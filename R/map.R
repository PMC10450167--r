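#' @title Density maps
#' @description 3-D scalar grids with unit-cell geometry. Values are stored
#'   in an array indexed along the a, b, c cell axes (axis order is
#'   normalized on read); `origin_frac` gives the fractional coordinate of
#'   the first voxel. Crystallographic maps are periodic; simulated or
#'   cryo-EM maps are not and interpolate to 0 outside the grid.
#' @name densitymap
NULL

#' Fractionalization/orthogonalization matrices for a unit cell
#' @param cell numeric(6): a, b, c (Angstrom), alpha, beta, gamma (degrees)
#' @return list(orth = frac->cart 3x3, frac = cart->frac 3x3, volume)
#' @export
cell_matrices <- function(cell) {
  stopifnot(length(cell) == 6, all(cell[1:3] > 0))
  a <- cell[1]; b <- cell[2]; c_ <- cell[3]
  ca <- cos(deg2rad(cell[4])); cb <- cos(deg2rad(cell[5]))
  cg <- cos(deg2rad(cell[6])); sg <- sin(deg2rad(cell[6]))
  v <- sqrt(max(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg, 0))
  orth <- matrix(c(a, b * cg, c_ * cb,
                   0, b * sg, c_ * (ca - cb * cg) / sg,
                   0, 0, c_ * v / sg), 3, 3, byrow = TRUE)
  list(orth = orth, frac = solve(orth), volume = a * b * c_ * v)
}

#' Construct a density map
#' @param values 3-D numeric array indexed along a, b, c
#' @param cell unit-cell parameters (a,b,c,alpha,beta,gamma)
#' @param origin_frac fractional coordinate of voxel (1,1,1)
#' @param periodic TRUE for crystallographic maps
#' @param grid_full full-cell sampling counts (defaults to `dim(values)`)
#' @return object of class `na_density_map`
#' @export
new_density_map <- function(values, cell, origin_frac = c(0, 0, 0),
                            periodic = FALSE, grid_full = dim(values)) {
  stopifnot(length(dim(values)) == 3, all(dim(values) >= 2))
  cm <- cell_matrices(cell)
  structure(list(values = values, cell = cell, origin_frac = origin_frac,
                 periodic = periodic, grid_full = grid_full,
                 orth = cm$orth, frac = cm$frac, volume = cm$volume),
            class = "na_density_map")
}

#' @export
print.na_density_map <- function(x, ...) {
  cat(sprintf("<na_density_map> %d x %d x %d, cell %.1f %.1f %.1f, %s\n",
              dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
              x$cell[1], x$cell[2], x$cell[3],
              if (x$periodic) "periodic" else "non-periodic"))
  invisible(x)
}

frac_coords <- function(map, xyz) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
  as.matrix(xyz) %*% t(map$frac)
}

cart_coords <- function(map, frac) {
  if (is.null(dim(frac))) frac <- matrix(frac, ncol = 3)
  as.matrix(frac) %*% t(map$orth)
}

#' Trilinear interpolation of map values at Cartesian points
#'
#' Periodic maps wrap; non-periodic maps return 0 outside the grid.
#'
#' @param map `na_density_map`
#' @param xyz n x 3 matrix (or length-3 vector) of Cartesian coordinates
#' @return numeric vector of interpolated values
#' @export
interpolate_density <- function(map, xyz) {
  fr <- frac_coords(map, xyz)
  dims <- dim(map$values)
  n <- nrow(fr)
  tcoord <- sweep(fr, 2, map$origin_frac) *
    matrix(map$grid_full, n, 3, byrow = TRUE)
  i0 <- floor(tcoord)
  w <- tcoord - i0
  val <- numeric(n)
  periodic <- map$periodic && all(dims == map$grid_full)
  get_vals <- function(ii, jj, kk) {
    # ii, jj, kk are 0-based voxel indices
    if (periodic) {
      ii <- ii %% dims[1]; jj <- jj %% dims[2]; kk <- kk %% dims[3]
      ok <- rep(TRUE, length(ii))
    } else {
      ok <- ii >= 0 & ii < dims[1] & jj >= 0 & jj < dims[2] &
        kk >= 0 & kk < dims[3]
    }
    out <- numeric(length(ii))
    lin <- 1 + ii[ok] + dims[1] * (jj[ok] + dims[2] * kk[ok])
    out[ok] <- map$values[lin]
    out
  }
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    wt <- (if (di == 1) w[, 1] else 1 - w[, 1]) *
      (if (dj == 1) w[, 2] else 1 - w[, 2]) *
      (if (dk == 1) w[, 3] else 1 - w[, 3])
    val <- val + wt * get_vals(i0[, 1] + di, i0[, 2] + dj, i0[, 3] + dk)
  }
  val
}

.ccp4_machine_stamp <- function() as.raw(c(0x44, 0x41, 0x00, 0x00))

#' Write a map in CCP4/MRC format (mode 2, 32-bit float)
#'
#' @param map `na_density_map`
#' @param path output path
#' @param axis_order permutation of c("X","Y","Z") giving the storage order
#'   (fastest first); default "X","Y","Z"
#' @return `path`, invisibly
#' @export
write_ccp4_map <- function(map, path, axis_order = c("X", "Y", "Z")) {
  perm <- match(axis_order, c("X", "Y", "Z"))
  if (anyNA(perm) || length(perm) != 3 || anyDuplicated(perm)) {
    stop("axis_order must be a permutation of X, Y, Z")
  }
  dims <- dim(map$values)
  nstart_f <- map$origin_frac * map$grid_full
  use_start <- all(abs(nstart_f - round(nstart_f)) < 1e-6)
  nstart <- if (use_start) as.integer(round(nstart_f)) else c(0L, 0L, 0L)
  origin_cart <- if (use_start) c(0, 0, 0) else
    as.numeric(cart_coords(map, map$origin_frac))
  vals <- aperm(map$values, perm)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(dim(vals))                      # NC NR NS
  wi(2L)                             # MODE
  wi(nstart[perm])                   # NCSTART NRSTART NSSTART
  wi(map$grid_full)                  # MX MY MZ (full cell sampling)
  wf(map$cell)                       # CELL
  wi(perm)                           # MAPC MAPR MAPS
  wf(c(min(vals), max(vals), mean(vals)))  # AMIN AMAX AMEAN
  wi(c(1L, 0L))                      # ISPG, NSYMBT
  wi(rep(0L, 25))                    # EXTRA (words 26-50)
  seek(con, 4 * 49)                  # ORIGIN words 50-52 (0-based 49)
  wf(origin_cart)
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(.ccp4_machine_stamp(), con)
  wf(stats::sd(as.numeric(vals)))    # RMS
  wi(1L)                             # NLABL
  lab <- sprintf("%-80s", "written by nucassign")
  writeChar(paste0(lab, strrep(" ", 80 * 9)), con, nchars = 800, eos = NULL)
  wf(as.numeric(vals))
  invisible(path)
}

#' Read a CCP4/MRC map (mode 2)
#'
#' Axis order is normalized to X, Y, Z; start offsets (or the MRC ORIGIN
#' field) are preserved in `origin_frac`.
#'
#' @param path file path
#' @param periodic mark the map as crystallographically periodic
#' @return `na_density_map`
#' @export
read_ccp4_map <- function(path, periodic = FALSE) {
  info <- file.info(path)
  if (is.na(info$size) || info$size < 1024 + 4) {
    stop("not a CCP4/MRC map (file too small): ", path)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n = n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n = n, size = 4, endian = "little")
  nc <- ri(3); mode <- ri(1); nstart <- ri(3); mgrid <- ri(3); cell <- rf(6)
  axes <- ri(3)
  rf(3); ri(2); ri(25)
  origin_cart <- rf(3)
  magic <- readChar(con, 4, useBytes = TRUE)
  if (!identical(magic, "MAP ")) stop("bad CCP4/MRC magic in ", path)
  if (mode != 2L) stop("unsupported CCP4/MRC mode ", mode, " (expected 2)")
  if (anyNA(axes) || !setequal(axes, 1:3)) stop("bad axis order in ", path)
  seek(con, 1024)
  n_total <- prod(nc)
  vals <- rf(n_total)
  if (length(vals) < n_total) stop("truncated CCP4/MRC map: ", path)
  arr <- array(vals, dim = nc)
  # current storage: fastest axis = cell axis axes[1], etc. Permute to a,b,c.
  arr <- aperm(arr, order(axes))
  nstart_xyz <- nstart[order(axes)]
  cm <- cell_matrices(cell)
  origin_frac <- nstart_xyz / mgrid +
    as.numeric(cm$frac %*% origin_cart)
  new_density_map(arr, cell, origin_frac = origin_frac, periodic = periodic,
                  grid_full = mgrid)
}
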