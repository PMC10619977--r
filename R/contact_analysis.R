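#' Per-frame boolean contact series
#'
#' @param indicator Logical matrix, frames x pairs.
#' @param pairs Data frame with residue indices `i`, `j` per column.
#' @param frame_interval Time per frame (ps).
#' @param condition_label Condition name.
#' @return An object of class `ContactSeries`.
#' @export
contact_series <- function(indicator, pairs, frame_interval = 1,
                           condition_label = "") {
  indicator <- as.matrix(indicator)
  mode(indicator) <- "logical"
  pairs <- as.data.frame(pairs)
  stopifnot(ncol(indicator) == nrow(pairs))
  structure(list(indicator = indicator,
                 pairs = pairs[, c("i", "j"), drop = FALSE],
                 frame_interval = frame_interval,
                 condition_label = condition_label),
            class = "ContactSeries")
}

#' @export
print.ContactSeries <- function(x, ...) {
  cat(sprintf("ContactSeries '%s': %d frames, %d pairs\n",
              x$condition_label, nrow(x$indicator), nrow(x$pairs)))
  invisible(x)
}

#' Residue-residue contacts along a trajectory
#'
#' A residue pair is in contact in a frame iff the minimum distance between
#' any of their particles is at most `cutoff`. Pairs closer than
#' `min_seq_sep` in sequence (|i - j| <= min_seq_sep) are excluded, the
#' standard native-contact convention that removes trivially bonded
#' neighbours.
#'
#' @param ensemble A [trajectory_ensemble()] (replicates are concatenated).
#' @param cutoff Distance cutoff, nm (> 0); default 0.45 nm.
#' @param min_seq_sep Chain-separation exclusion; pairs with
#'   `|i - j| <= min_seq_sep` are dropped (default 2).
#' @param residues Optional subset of residue indices to consider.
#' @return A [contact_series()] over all retained residue pairs.
#' @export
compute_contacts <- function(ensemble, cutoff = 0.45, min_seq_sep = 2,
                             residues = NULL) {
  stopifnot(inherits(ensemble, "TrajectoryEnsemble"), cutoff > 0)
  res <- sort(unique(ensemble$residue_index))
  if (!is.null(residues)) res <- res[res %in% residues]
  pr <- t(utils::combn(res, 2))
  keep <- abs(pr[, 1] - pr[, 2]) > min_seq_sep
  pr <- pr[keep, , drop = FALSE]
  if (nrow(pr) == 0) stop("no residue pairs left after chain exclusion")
  members <- lapply(res, function(r) which(ensemble$residue_index == r))
  names(members) <- as.character(res)
  total_frames <- sum(n_frames(ensemble))
  ind <- matrix(FALSE, total_frames, nrow(pr))
  f0 <- 0L
  for (rep_arr in ensemble$replicates) {
    nf <- dim(rep_arr)[1]
    for (f in seq_len(nf)) {
      X <- rep_arr[f, , , drop = TRUE]
      if (is.null(dim(X))) X <- matrix(X, ensemble$n_particles, ensemble$dim)
      for (p in seq_len(nrow(pr))) {
        a <- members[[as.character(pr[p, 1])]]
        b <- members[[as.character(pr[p, 2])]]
        dmin <- min(sqrt(outer(rowSums(X[a, , drop = FALSE]^2),
                               rowSums(X[b, , drop = FALSE]^2), "+") -
                         2 * X[a, , drop = FALSE] %*% t(X[b, , drop = FALSE])))
        ind[f0 + f, p] <- dmin <= cutoff
      }
    }
    f0 <- f0 + nf
  }
  contact_series(ind, data.frame(i = pr[, 1], j = pr[, 2]),
                 frame_interval = ensemble$frame_interval,
                 condition_label = ensemble$condition_label)
}

#' Per-pair contact occupancy
#'
#' Fraction of frames each pair is in contact.
#'
#' @param series A [contact_series()].
#' @return Data frame with columns `i`, `j`, `occupancy`.
#' @export
occupancy <- function(series) {
  stopifnot(inherits(series, "ContactSeries"), nrow(series$indicator) >= 1)
  data.frame(series$pairs, occupancy = colMeans(series$indicator))
}

#' Contact conservation between a reference and a test condition
#'
#' Native pairs are those with occupancy at least `min_occ` in the reference;
#' a native pair is conserved when its occupancy in the test condition is
#' also at least `min_occ`. The default 10% cutoff is the occupancy floor
#' used when comparing interfaces before and after an enhanced-sampling
#' conformational change.
#'
#' @param reference_occ,test_occ Occupancy tables from [occupancy()] over the
#'   same pair universe.
#' @param min_occ Occupancy cutoff in `[0, 1)`, default 0.10.
#' @return An object of class `ConservationReport`: list with `native`
#'   (data frame of native pairs with both occupancies and a `conserved`
#'   flag), `n_native`, `n_conserved`, `fraction` (NA with a warning when no
#'   pair is native) and `min_occ`.
#' @export
conservation <- function(reference_occ, test_occ, min_occ = 0.10) {
  key <- function(d) paste(d$i, d$j, sep = "_")
  if (!setequal(key(reference_occ), key(test_occ)))
    stop("occupancy tables must cover the same pair universe")
  test_occ <- test_occ[match(key(reference_occ), key(test_occ)), ]
  native <- reference_occ$occupancy >= min_occ
  n_native <- sum(native)
  tab <- data.frame(reference_occ[native, c("i", "j")],
                    occ_reference = reference_occ$occupancy[native],
                    occ_test = test_occ$occupancy[native])
  tab$conserved <- tab$occ_test >= min_occ
  n_cons <- sum(tab$conserved)
  frac <- if (n_native == 0) {
    warning("no native pairs at this occupancy cutoff; fraction undefined")
    NA_real_
  } else n_cons / n_native
  structure(list(native = tab, n_native = n_native, n_conserved = n_cons,
                 fraction = frac, min_occ = min_occ),
            class = "ConservationReport")
}

#' @export
print.ConservationReport <- function(x, ...) {
  cat(sprintf("ConservationReport: %d of %d native pairs conserved (%.1f%%) at occupancy >= %g\n",
              x$n_conserved, x$n_native, 100 * x$fraction, x$min_occ))
  invisible(x)
}

#' Per-frame fraction of native contacts
#'
#' For each frame, the fraction of the native pair set currently in contact
#' ("sum of contacts per frame", normalised per native pair). The dispersion
#' reported is the mean absolute deviation of the per-frame fractions from
#' `reference_mean` when given (the comparison condition's mean), otherwise
#' from this series' own mean.
#'
#' @param series A [contact_series()].
#' @param native_pairs Data frame with columns `i`, `j`; must be non-empty
#'   and a subset of the series' pairs.
#' @param reference_mean Optional comparison mean for the dispersion.
#' @param normalize If `FALSE`, return raw per-frame contact counts instead
#'   of fractions.
#' @return List with `per_frame` (numeric vector), `mean` and
#'   `mean_abs_deviation`.
#' @export
native_fraction_per_frame <- function(series, native_pairs,
                                      reference_mean = NULL,
                                      normalize = TRUE) {
  stopifnot(inherits(series, "ContactSeries"), nrow(native_pairs) >= 1)
  key <- paste(series$pairs$i, series$pairs$j, sep = "_")
  want <- paste(native_pairs$i, native_pairs$j, sep = "_")
  idx <- match(want, key)
  if (anyNA(idx)) stop("native pairs absent from the contact series")
  counts <- rowSums(series$indicator[, idx, drop = FALSE])
  per_frame <- if (normalize) counts / length(idx) else counts
  m <- mean(per_frame)
  center <- if (is.null(reference_mean)) m else reference_mean
  list(per_frame = per_frame, mean = m,
       mean_abs_deviation = mean(abs(per_frame - center)))
}
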