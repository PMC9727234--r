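# Separable multilevel 3D discrete wavelet transform.
#
# The decomposition follows the classical MATLAB wavedec-style scheme:
# half-point symmetric signal extension by (filter length - 1) samples on
# each side, valid-part convolution, dyadic downsampling keeping the even
# samples. The scheme is non-expansive in spirit but slightly redundant
# (coefficient length floor((n + L - 1) / 2)), which is what buys exact
# reconstruction on arbitrary, non-dyadic grid sizes.

# Orthonormal scaling filters (decomposition low-pass, standard published
# constants; "sym" = least-asymmetric Daubechies a.k.a. symlets).
.WT_FILTERS <- list(
  haar = c(0.7071067811865476, 0.7071067811865476),
  db2  = c(-0.12940952255126037, 0.2241438680420134, 0.8365163037378079,
           0.48296291314453416),
  db4  = c(-0.010597401785069032, 0.0328830116668852, 0.030841381835560764,
           -0.18703481171909309, -0.027983769416859854, 0.6308807679298589,
           0.7148465705529157, 0.2303778133088965),
  sym2 = c(-0.12940952255092145, 0.22414386804185735, 0.836516303737469,
           0.48296291314469025),
  sym3 = c(0.035226291882100656, -0.08544127388224149, -0.13501102001039084,
           0.4598775021193313, 0.8068915093133388, 0.3326705529509569),
  sym4 = c(-0.07576571478927333, -0.02963552764599851, 0.49761866763201545,
           0.8037387518059161, 0.29785779560527736, -0.09921954357684722,
           -0.012603967262037833, 0.0322231006040427),
  sym5 = c(0.027333068345077982, 0.029519490925774643, -0.039134249302383094,
           0.1993975339773936, 0.7234076904024206, 0.6339789634582119,
           0.01660210576452232, -0.17532808990845047, -0.021101834024758855,
           0.019538882735286728),
  sym6 = c(0.015404109327027373, 0.0034907120842174702, -0.11799011114819057,
           -0.048311742585633, 0.4910559419267466, 0.787641141030194,
           0.3379294217276218, -0.07263752278646252, -0.021060292512300564,
           0.04472490177066578, 0.0017677118642428036, -0.007800708325034148),
  sym8 = c(-0.0033824159510061256, -0.0005421323317911481, 0.03169508781149298,
           0.007607487324917605, -0.1432942383508097, -0.061273359067658524,
           0.4813596512583722, 0.7771857517005235, 0.3644418948353314,
           -0.05194583810770904, -0.027219029917056003, 0.049137179673607506,
           0.003808752013890615, -0.01495225833704823, -0.0003029205147213668,
           0.0018899503327594609)
)

#' Wavelet filter bank
#'
#' Returns the four-filter bank (decomposition/reconstruction low/high pass)
#' for a named orthonormal wavelet. `sym4` is the package default basis: a
#' near-symmetric (least-asymmetric) compactly supported wavelet.
#'
#' @param name One of `r paste(names(wmcov:::.WT_FILTERS), collapse = ", ")`.
#' @return A list with `dec_lo`, `dec_hi`, `rec_lo`, `rec_hi`, `length`, `name`.
#' @export
wt_filter <- function(name = "sym4") {
  if (!name %in% names(.WT_FILTERS))
    stop_wmcov("unknown wavelet basis '%s' (available: %s)", name,
               paste(names(.WT_FILTERS), collapse = ", "))
  dec_lo <- .WT_FILTERS[[name]]
  L <- length(dec_lo)
  dec_hi <- rev(dec_lo) * (-1)^(1:L)
  list(dec_lo = dec_lo, dec_hi = dec_hi,
       rec_lo = rev(dec_lo), rec_hi = rev(dec_hi),
       length = L, name = name)
}

# Half-point symmetric extension indices for a signal of length n padded by
# p on each side (period 2n: ... x2 x1 | x1 .. xn | xn xn-1 ...).
.symext_idx <- function(n, p) {
  t <- (1 - p):(n + p)
  m <- ((t - 1) %% (2 * n) + 2 * n) %% (2 * n)
  ifelse(m < n, m + 1, 2 * n - m)
}

# One decomposition step along the rows of a matrix (n x k) -> (nc x k).
.dwt_rows <- function(x, f) {
  n <- nrow(x); L <- length(f); p <- L - 1
  e <- x[.symext_idx(n, p), , drop = FALSE]
  m <- nrow(e)
  nv <- m - L + 1
  z <- matrix(0, nv, ncol(x))
  for (j in 1:L)
    z <- z + f[j] * e[(1 + L - j):(m - j + 1), , drop = FALSE]
  z[seq(2, nv, by = 2), , drop = FALSE]
}

# One reconstruction step along rows: combine approximation and detail
# (each na x k) into out_n x k using reconstruction filters.
.idwt_rows <- function(a, d, rec_lo, rec_hi, out_n) {
  la <- nrow(a); L <- length(rec_lo); k <- ncol(a)
  up <- matrix(0, 2 * la - 1, k)
  s <- matrix(0, 2 * la - 1 + L - 1, k)
  up[seq(1, 2 * la - 1, by = 2), ] <- a
  for (j in 1:L)
    s[j:(j + 2 * la - 2), ] <- s[j:(j + 2 * la - 2), ] + rec_lo[j] * up
  up[seq(1, 2 * la - 1, by = 2), ] <- d
  for (j in 1:L)
    s[j:(j + 2 * la - 2), ] <- s[j:(j + 2 * la - 2), ] + rec_hi[j] * up
  start <- floor((nrow(s) - out_n) / 2) + 1
  s[start:(start + out_n - 1), , drop = FALSE]
}

# Apply a rows-operation along a chosen axis of a 3D array.
.along_axis <- function(arr, axis, fun) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  x <- aperm(arr, perm)
  dp <- dim(x)
  m <- fun(matrix(x, nrow = dp[1]))
  out <- array(m, dim = c(nrow(m), dp[2], dp[3]))
  aperm(out, order(perm))
}

.ORIENTATIONS <- c("LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")

#' Multilevel 3D discrete wavelet transform
#'
#' Decomposes a 3D volume into `7 * levels` detail subbands plus one final
#' approximation, using a separable DWT with symmetric boundary extension.
#' Orientation letters refer to low/high-pass filtering along the first,
#' second and third array axis, e.g. `HLL` is high-pass along x.
#'
#' @param volume Finite-valued 3D numeric array.
#' @param basis Wavelet name (see [wt_filter()]); default `"sym4"`.
#' @param levels Decomposition depth (default 3).
#' @param boundary_mode Signal extension; only `"symmetric"` is implemented.
#' @return An object of class `wmcov_subbands`: `approximation` (3D array),
#'   `details` (named list of `list(level, orientation, coef)`), plus
#'   bookkeeping (`basis`, `levels`, `boundary_mode`, `original_shape`,
#'   `level_input_dims`).
#' @examples
#' ss <- dwt3(array(rnorm(16^3), c(16, 16, 16)), levels = 2)
#' length(ss$details)  # 14
#' @export
dwt3 <- function(volume, basis = "sym4", levels = 3L,
                 boundary_mode = "symmetric") {
  if (!is.array(volume) || length(dim(volume)) != 3)
    stop_wmcov("volume must be a 3D array")
  if (!all(is.finite(volume)))
    stop_wmcov("volume contains non-finite voxels")
  levels <- as.integer(levels)
  if (levels < 1) stop_wmcov("levels must be >= 1")
  if (min(dim(volume)) < 2^levels)
    stop_wmcov("volume dims %s too small for a level-%d decomposition",
               paste(dim(volume), collapse = "x"), levels)
  if (!identical(boundary_mode, "symmetric"))
    stop_wmcov("only boundary_mode = 'symmetric' is implemented")
  flt <- wt_filter(basis)

  cur <- volume
  details <- list()
  level_input_dims <- vector("list", levels)
  for (lev in 1:levels) {
    level_input_dims[[lev]] <- dim(cur)
    # split along each axis in turn; parts named by accumulated letters
    parts <- stats::setNames(list(cur), "")
    for (ax in 1:3) {
      nxt <- list()
      for (idx in seq_along(parts)) {
        nm <- names(parts)[idx]
        nxt[[paste0(nm, "L")]] <-
          .along_axis(parts[[idx]], ax, function(m) .dwt_rows(m, flt$dec_lo))
        nxt[[paste0(nm, "H")]] <-
          .along_axis(parts[[idx]], ax, function(m) .dwt_rows(m, flt$dec_hi))
      }
      parts <- nxt
    }
    for (ori in .ORIENTATIONS)
      details[[paste0("L", lev, "-", ori)]] <-
        list(level = lev, orientation = ori, coef = parts[[ori]])
    cur <- parts[["LLL"]]
  }
  structure(list(approximation = cur, details = details, basis = basis,
                 levels = levels, boundary_mode = boundary_mode,
                 original_shape = dim(volume),
                 level_input_dims = level_input_dims),
            class = "wmcov_subbands")
}

#' Inverse multilevel 3D discrete wavelet transform
#'
#' Reconstructs the original volume from a [dwt3()] decomposition. Round
#' trips are exact to floating point (max abs error well below 1e-8),
#' including non-dyadic grids.
#'
#' @param ss A `wmcov_subbands` object.
#' @return 3D array of the original shape.
#' @export
inverse_dwt3 <- function(ss) {
  stopifnot(inherits(ss, "wmcov_subbands"))
  flt <- wt_filter(ss$basis)
  if (length(ss$details) != 7L * ss$levels)
    stop_wmcov("malformed subband set: expected %d detail arrays, found %d",
               7L * ss$levels, length(ss$details))
  cur <- ss$approximation
  for (lev in ss$levels:1) {
    parts <- list(LLL = cur)
    for (ori in .ORIENTATIONS) {
      d <- ss$details[[paste0("L", lev, "-", ori)]]
      if (is.null(d)) stop_wmcov("missing subband L%d-%s", lev, ori)
      parts[[ori]] <- d$coef
    }
    in_dims <- ss$level_input_dims[[lev]]
    ref <- dim(parts[["LLL"]])
    for (ori in .ORIENTATIONS)
      if (!identical(dim(parts[[ori]]), ref))
        stop_wmcov("inconsistent subband shapes at level %d (%s)", lev, ori)
    # invert axis 3, then 2, then 1; at each stage names hold the letters
    # for the axes still in coefficient space (axes 1..ax)
    for (ax in 3:1) {
      nxt <- list()
      keys <- unique(substr(names(parts), 1, ax - 1))
      for (key in keys) {
        a <- parts[[paste0(key, "L")]]
        d <- parts[[paste0(key, "H")]]
        val <- .along_axis_pair(a, d, ax, flt, in_dims[ax])
        if (nzchar(key)) nxt[[key]] <- val else nxt <- list(val)
      }
      parts <- nxt
    }
    cur <- parts[[1]]
  }
  cur
}

# idwt along an axis for a pair of arrays
.along_axis_pair <- function(a, d, axis, flt, out_n) {
  dm <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  am <- aperm(a, perm); dmat <- aperm(d, perm)
  dp <- dim(am)
  m <- .idwt_rows(matrix(am, nrow = dp[1]), matrix(dmat, nrow = dp[1]),
                  flt$rec_lo, flt$rec_hi, out_n)
  out <- array(m, dim = c(out_n, dp[2], dp[3]))
  aperm(out, order(perm))
}

#' Assemble the 4D wavelet feature volume
#'
#' Resamples every subband back to the native voxel grid by block
#' replication (each level-`l` coefficient covers its `2^l` dyadic support
#' per axis, cropped to the original shape) and stacks them along a fourth
#' axis, approximation first, then details coarse-to-fine. A level-3
#' decomposition yields `C = 7 * 3 + 1 = 22` channels, so each voxel carries
#' a 22-vector of wavelet features.
#'
#' @param ss A `wmcov_subbands` object from [dwt3()].
#' @param interp `"block"` (default, value-preserving nearest-neighbor) or
#'   `"linear"` for smooth trilinear upsampling of each subband.
#' @return Object of class `wmcov_feature_volume`: `data` (X x Y x Z x C
#'   array), `channel_labels`, `basis`, `levels`, `boundary_mode`.
#' @export
build_feature_volume <- function(ss, interp = c("block", "linear")) {
  stopifnot(inherits(ss, "wmcov_subbands"))
  interp <- match.arg(interp)
  os <- ss$original_shape
  C <- 7L * ss$levels + 1L
  data <- array(0, dim = c(os, C))
  labels <- character(C)
  L <- wt_filter(ss$basis)$length

  upsample <- function(coef, lev) {
    f <- 2^lev
    if (interp == "block") {
      ix <- .coef_of_voxel(os[1], dim(coef)[1], lev, L)
      iy <- .coef_of_voxel(os[2], dim(coef)[2], lev, L)
      iz <- .coef_of_voxel(os[3], dim(coef)[3], lev, L)
      coef[ix, iy, iz, drop = FALSE]
    } else {
      .trilinear_upsample(coef, os, f, L)
    }
  }

  labels[1] <- paste0("L", ss$levels, "-approx")
  data[, , , 1] <- upsample(ss$approximation, ss$levels)
  ch <- 2L
  for (lev in ss$levels:1) {
    for (ori in .ORIENTATIONS) {
      nm <- paste0("L", lev, "-", ori)
      labels[ch] <- nm
      data[, , , ch] <- upsample(ss$details[[nm]]$coef, lev)
      ch <- ch + 1L
    }
  }
  structure(list(data = data, channel_labels = labels, basis = ss$basis,
                 levels = ss$levels, boundary_mode = ss$boundary_mode),
            class = "wmcov_feature_volume")
}

# Receptive-field alignment: after l cascaded decimations with a length-L
# filter, coefficient k at level l summarizes original samples centered on
# 2^l * k - (2^l - 1)(L - 1)/2. Nearest-neighbor assignment of voxels to
# coefficient centers gives the dyadic block map (runs of 2^l voxels,
# truncated at the boundary by clamping).
.coef_of_voxel <- function(n_vox, n_coef, lev, L) {
  f <- 2^lev
  D <- (f - 1) * (L - 1) / 2
  k <- round((seq_len(n_vox) + D) / f)
  pmin(pmax(k, 1L), n_coef)
}

# Trilinear interpolation of a coefficient grid onto the native grid,
# using the same receptive-field centers as the block map.
.trilinear_upsample <- function(coef, os, f, L) {
  d <- dim(coef)
  D <- (f - 1) * (L - 1) / 2
  pos <- function(n_out, n_in) {
    x <- (seq_len(n_out) + D) / f  # coefficient-axis coordinate
    x <- pmin(pmax(x, 1), n_in)
    i0 <- pmin(floor(x), n_in - 1); w <- x - i0
    list(i0 = i0, w = w)
  }
  px <- pos(os[1], d[1]); py <- pos(os[2], d[2]); pz <- pos(os[3], d[3])
  out <- array(0, dim = os)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wx <- if (dx == 0) 1 - px$w else px$w
    wy <- if (dy == 0) 1 - py$w else py$w
    wz <- if (dz == 0) 1 - pz$w else pz$w
    blk <- coef[px$i0 + dx, py$i0 + dy, pz$i0 + dz, drop = FALSE]
    w3 <- outer(outer(wx, wy), wz)
    out <- out + blk * w3
  }
  out
}

#' @export
print.wmcov_subbands <- function(x, ...) {
  cat(sprintf("3D DWT subband set: basis %s, %d level(s), original %s\n",
              x$basis, x$levels, paste(x$original_shape, collapse = "x")))
  cat(sprintf("  approximation %s + %d detail subbands\n",
              paste(dim(x$approximation), collapse = "x"), length(x$details)))
  invisible(x)
}

#' @export
print.wmcov_feature_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("wavelet feature volume %s (%d channels, basis %s, L=%d)\n",
              paste(d[1:3], collapse = "x"), d[4], x$basis, x$levels))
  invisible(x)
}
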