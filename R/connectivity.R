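#' Pairwise symmetric orthogonalization
#'
#' Removes zero-lag (instantaneous) shared signal between two series, the
#' source-leakage component that inflates amplitude correlations. Both series
#' are demeaned; `y_on_x` is `y` minus its least-squares projection onto `x`,
#' and `x_on_y` symmetrically. Each residual has zero sample correlation with
#' its regressor by construction.
#'
#' @param x,y Numeric vectors of equal length; neither may be constant.
#' @return List with elements `y_on_x` and `x_on_y`.
#' @examples
#' o <- orthogonalize_pair(rnorm(100), rnorm(100))
#' @export
orthogonalize_pair <- function(x, y) {
  if (length(x) != length(y))
    stop("series must have equal length", call. = FALSE)
  x <- x - mean(x)
  y <- y - mean(y)
  sx <- sum(x^2)
  sy <- sum(y^2)
  if (sx == 0 || sy == 0)
    stop("cannot orthogonalize against a constant series", call. = FALSE)
  sxy <- sum(x * y)
  list(y_on_x = y - (sxy / sx) * x, x_on_y = x - (sxy / sy) * y)
}

#' Corrected amplitude envelope correlation of one epoch pair
#'
#' The AEC-c of two band-filtered epoch-length series: after pairwise
#' orthogonalization, the amplitude envelopes (magnitude of the analytic
#' signal) of `x` and `y_on_x` are correlated, likewise `y` and `x_on_y`; the
#' two directed correlation coefficients are averaged and affinely rescaled
#' as `(r + 1) / 2`, giving a value in `[0, 1]` with 0.5 indicating absence
#' of coupling. A fraction of samples at each epoch edge (default 5%) is
#' discarded before correlating, to suppress transform edge effects.
#'
#' @param x,y Band-filtered numeric vectors of equal length.
#' @param trim_fraction Fraction of samples dropped at each end before the
#'   envelope correlation; default 0.05.
#' @return AEC-c value in `[0, 1]`, or `NA` (with a warning) if an envelope
#'   is degenerate.
#' @export
aec_pair <- function(x, y, trim_fraction = 0.05) {
  o <- orthogonalize_pair(x, y)
  x <- x - mean(x)
  y <- y - mean(y)
  L <- length(x)
  tr <- floor(trim_fraction * L)
  idx <- (tr + 1L):(L - tr)
  ex <- .signal_envelope(x)[idx]
  ey <- .signal_envelope(y)[idx]
  eyx <- .signal_envelope(o$y_on_x)[idx]
  exy <- .signal_envelope(o$x_on_y)[idx]
  if (stats::sd(ex) == 0 || stats::sd(ey) == 0 ||
      stats::sd(eyx) == 0 || stats::sd(exy) == 0) {
    warning("degenerate envelope (zero variance); AEC-c undefined for this epoch",
            call. = FALSE)
    return(NA_real_)
  }
  r <- (stats::cor(ex, eyx) + stats::cor(ey, exy)) / 2
  (r + 1) / 2
}

#' Connectivity matrix container
#'
#' Symmetric region x region AEC-c adjacency with an absent (NA) diagonal.
#'
#' @param values Symmetric numeric matrix with entries in `[0, 1]` (NA
#'   allowed); the diagonal is forced to NA and excluded from all reductions.
#' @param band The [frequency_band()] the values were computed in.
#' @param n_epochs Number of epochs averaged per entry.
#' @return An object of class `connectivity_matrix`.
#' @export
connectivity_matrix <- function(values, band = NULL, n_epochs = NA_integer_) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values))
    stop("connectivity matrix must be square", call. = FALSE)
  diag(values) <- NA_real_
  if (!isTRUE(all.equal(values, t(values))))
    stop("connectivity matrix must be symmetric", call. = FALSE)
  rng <- range(values, na.rm = TRUE)
  if (rng[1L] < 0 || rng[2L] > 1)
    stop("connectivity values must lie in [0, 1]", call. = FALSE)
  structure(list(values = values, band = band, n_epochs = n_epochs),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %d x %d AEC-c%s, %s epochs averaged\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$band)) "" else sprintf(" [%s]", x$band$name),
              x$n_epochs))
  invisible(x)
}

#' AEC-c adjacency matrix of an epoch set
#'
#' Computes [aec_pair()] for every unordered region pair in every epoch and
#' averages the corrected values over epochs, yielding the symmetric
#' region x region adjacency (for 90 regions: 4005 unique off-diagonal
#' values). Pairs that are degenerate in every epoch get an NA entry and a
#' warning.
#'
#' @param es A band-tagged [epoch_set()].
#' @param trim_fraction Passed to the envelope correlation; default 0.05.
#' @return A [connectivity_matrix()].
#' @export
aec_matrix <- function(es, trim_fraction = 0.05) {
  stopifnot(inherits(es, "epoch_set"))
  if (is.null(es$band))
    stop("epoch set must be band-filtered before computing AEC-c", call. = FALSE)
  d <- dim(es$epochs)
  E <- d[1L]; R <- d[2L]; L <- d[3L]
  tr <- floor(trim_fraction * L)
  idx <- (tr + 1L):(L - tr)
  acc <- matrix(0, R, R)
  cnt <- matrix(0L, R, R)
  for (e in seq_len(E)) {
    X <- es$epochs[e, , , drop = TRUE]
    if (R == 1L) X <- matrix(X, nrow = 1L)
    X <- X - rowMeans(X)
    ss <- rowSums(X^2)
    env <- matrix(0, R, length(idx))
    for (r in seq_len(R))
      if (ss[r] > 0) env[r, ] <- .signal_envelope(X[r, ])[idx]
    env_sd <- apply(env, 1L, stats::sd)
    for (i in seq_len(R - 1L)) {
      if (ss[i] == 0) next
      for (j in (i + 1L):R) {
        if (ss[j] == 0) next
        sxy <- sum(X[i, ] * X[j, ])
        eyx <- .signal_envelope(X[j, ] - (sxy / ss[i]) * X[i, ])[idx]
        exy <- .signal_envelope(X[i, ] - (sxy / ss[j]) * X[j, ])[idx]
        if (env_sd[i] == 0 || env_sd[j] == 0 ||
            stats::sd(eyx) == 0 || stats::sd(exy) == 0) next
        r12 <- (stats::cor(env[i, ], eyx) + stats::cor(env[j, ], exy)) / 2
        acc[i, j] <- acc[i, j] + (r12 + 1) / 2
        cnt[i, j] <- cnt[i, j] + 1L
      }
    }
  }
  vals <- matrix(NA_real_, R, R)
  ok <- cnt > 0L
  vals[ok] <- acc[ok] / cnt[ok]
  vals[lower.tri(vals)] <- t(vals)[lower.tri(vals)]
  if (any(!ok[upper.tri(ok)]))
    warning(sprintf("%d region pair(s) degenerate in all epochs; entries set to NA",
                    sum(!ok[upper.tri(ok)])), call. = FALSE)
  dimnames(vals) <- list(rownames(es$epochs), rownames(es$epochs))
  connectivity_matrix(vals, band = es$band, n_epochs = E)
}

#' Per-region connectivity profile
#'
#' Reduces the adjacency matrix to one value per region: the mean AEC-c of
#' that region with the other 89 regions (row mean excluding the diagonal).
#' Absent (NA) entries are excluded from the mean; the number of entries that
#' contributed is reported in the `"n_used"` attribute.
#'
#' @param cm A [connectivity_matrix()].
#' @return Numeric vector of per-region mean connectivity, with attribute
#'   `n_used`.
#' @examples
#' m <- matrix(c(NA, .6, .5, .6, NA, .7, .5, .7, NA), 3)
#' roi_profile(connectivity_matrix(m))
#' @export
roi_profile <- function(cm) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  v <- cm$values
  prof <- rowMeans(v, na.rm = TRUE)
  structure(prof, n_used = rowSums(!is.na(v)))
}

#' Write a connectivity matrix as square CSV
#'
#' Region labels as header and row names; one file per subject-visit-band.
#'
#' @param cm A [connectivity_matrix()].
#' @param path Output path.
#' @param labels Optional region labels (default taken from the matrix or
#'   `R1..Rn`).
#' @return `path`, invisibly.
#' @export
write_connectivity_csv <- function(cm, path, labels = NULL) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  v <- cm$values
  if (is.null(labels))
    labels <- if (!is.null(rownames(v))) rownames(v) else
      paste0("R", seq_len(nrow(v)))
  dimnames(v) <- list(labels, labels)
  utils::write.csv(v, path)
  invisible(path)
}
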