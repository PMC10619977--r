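#' Write a two-column series in XVG dialect
#'
#' The Grace-style dialect used by MD pull/CV outputs: lines starting with
#' `@` or `#` are comments, data lines are whitespace-separated
#' `time value` pairs.
#'
#' @param time,value Numeric vectors of equal length.
#' @param path Output path.
#' @param comment Character vector of comment lines (written with a leading
#'   `#`).
#' @return `path`, invisibly.
#' @export
write_xvg <- function(time, value, path, comment = "time  xi") {
  stopifnot(length(time) == length(value))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", comment), con)
  writeLines(sprintf("%.8g %.10g", time, value), con)
  invisible(path)
}

#' Read a two-column XVG-dialect series
#'
#' Skips `@` and `#` comment lines; returns the first two numeric columns.
#'
#' @param path Input path.
#' @return Data frame with columns `time` and `value`.
#' @export
read_xvg <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*[@#]", lines) & nzchar(trimws(lines))
  if (!any(keep)) stop("no data lines in ", path)
  con <- textConnection(lines[keep])
  on.exit(close(con))
  tab <- utils::read.table(con)
  data.frame(time = tab[[1]], value = tab[[2]])
}

#' Write an umbrella window set as XVG files plus a metadata TSV
#'
#' One XVG file per window (`window_001.xvg`, ...) with sample index as the
#' time column, and `windows.tsv` listing `file`, `center_nm`,
#' `k_kJ_mol_nm2`.
#'
#' @param windows An [umbrella_window_set()].
#' @param dir Output directory (created if missing).
#' @return Path of the metadata TSV, invisibly.
#' @export
write_umbrella_windows <- function(windows, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- data.frame(file = character(), center_nm = numeric(),
                     k_kJ_mol_nm2 = numeric())
  for (w in seq_along(windows$windows)) {
    win <- windows$windows[[w]]
    fn <- sprintf("window_%03d.xvg", w)
    write_xvg(seq_along(win$samples), win$samples, file.path(dir, fn),
              comment = sprintf("umbrella window center=%g k=%g",
                                win$center, win$k))
    meta <- rbind(meta, data.frame(file = fn, center_nm = win$center,
                                   k_kJ_mol_nm2 = win$k))
  }
  meta_path <- file.path(dir, "windows.tsv")
  utils::write.table(meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(meta_path)
}

#' Read an umbrella window set from XVG files and a metadata TSV
#'
#' @param meta_path Path to the metadata TSV (`file`, `center_nm`,
#'   `k_kJ_mol_nm2`); window files are resolved relative to it.
#' @param temperature Temperature, K.
#' @return An [umbrella_window_set()].
#' @export
read_umbrella_windows <- function(meta_path, temperature = 300) {
  meta <- utils::read.table(meta_path, header = TRUE, sep = "\t")
  dir <- dirname(meta_path)
  windows <- lapply(seq_len(nrow(meta)), function(w) {
    xvg <- read_xvg(file.path(dir, meta$file[w]))
    list(center = meta$center_nm[w], k = meta$k_kJ_mol_nm2[w],
         samples = xvg$value)
  })
  umbrella_window_set(windows, temperature = temperature)
}

#' Write a trajectory as a multi-model PDB
#'
#' Beads are written as CA atoms of residues numbered by the ensemble's
#' residue labels, one MODEL per frame, coordinates converted nm -> Angstrom.
#' Only 3-D ensembles can be written.
#'
#' @param ensemble A [trajectory_ensemble()] (first replicate is written
#'   unless `replicate` says otherwise).
#' @param path Output path.
#' @param replicate Replicate index.
#' @return `path`, invisibly.
#' @export
write_pdb_trajectory <- function(ensemble, path, replicate = 1) {
  stopifnot(inherits(ensemble, "TrajectoryEnsemble"), ensemble$dim == 3)
  arr <- ensemble$replicates[[replicate]]
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(dim(arr)[1])) {
    writeLines(sprintf("MODEL     %4d", f), con)
    X <- arr[f, , ] * 10     # nm -> Angstrom
    if (is.null(dim(X))) X <- matrix(X, ensemble$n_particles, 3)
    writeLines(sprintf(
      "ATOM  %5d  CA  GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      seq_len(nrow(X)), ensemble$residue_index, X[, 1], X[, 2], X[, 3]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model PDB into a trajectory ensemble
#'
#' Parses via `bio3d::read.pdb(multi = TRUE)`; coordinates are converted
#' Angstrom -> nm.
#'
#' @param path PDB path.
#' @param condition_label Condition name.
#' @return A [trajectory_ensemble()] with one replicate.
#' @export
read_pdb_trajectory <- function(path, condition_label = "") {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  xyz <- pdb$xyz
  n <- ncol(xyz) / 3
  nf <- nrow(xyz)
  arr <- array(NA_real_, c(nf, n, 3))
  for (f in seq_len(nf)) arr[f, , ] <- matrix(xyz[f, ], n, 3, byrow = TRUE) / 10
  trajectory_ensemble(list(arr), condition_label = condition_label,
                      residue_index = pdb$atom$resno)
}

#' Write a pair-force series as a sparse table
#'
#' Whitespace-separated columns `frame`, `i`, `j`, `force_pN`.
#'
#' @param series A [pair_force_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_force_series <- function(series, path) {
  nf <- nrow(series$forces_pN); np <- nrow(series$pairs)
  tab <- data.frame(frame = rep(seq_len(nf), each = np),
                    i = rep(series$pairs$i, nf),
                    j = rep(series$pairs$j, nf),
                    force_pN = as.numeric(t(series$forces_pN)))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pair-force series written by [write_force_series()]
#'
#' @param path Input path.
#' @param condition_label Condition name.
#' @return A [pair_force_series()].
#' @export
read_force_series <- function(path, condition_label = "") {
  tab <- utils::read.table(path, header = TRUE)
  pairs <- unique(tab[, c("i", "j")])
  pairs <- pairs[order(pairs$i, pairs$j), ]
  key <- paste(pairs$i, pairs$j)
  frames <- sort(unique(tab$frame))
  m <- matrix(NA_real_, length(frames), nrow(pairs))
  col <- match(paste(tab$i, tab$j), key)
  row <- match(tab$frame, frames)
  m[cbind(row, col)] <- tab$force_pN
  pair_force_series(m, pairs, condition_label = condition_label)
}

#' Write a contact series as a sparse table
#'
#' Rows list only frames where a pair is in contact: `frame`, `i`, `j`.
#' A header comment records the full pair universe and frame count so the
#' series round-trips exactly.
#'
#' @param series A [contact_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contact_series <- function(series, path) {
  con <- file(path, "w")
  writeLines(sprintf("# frames=%d pairs=%s", nrow(series$indicator),
                     paste(series$pairs$i, series$pairs$j, sep = ":",
                           collapse = ",")), con)
  writeLines("frame\ti\tj", con)
  idx <- which(series$indicator, arr.ind = TRUE)
  if (nrow(idx) > 0) {
    ord <- order(idx[, 1], idx[, 2])
    idx <- idx[ord, , drop = FALSE]
    writeLines(sprintf("%d\t%d\t%d", idx[, 1],
                       series$pairs$i[idx[, 2]], series$pairs$j[idx[, 2]]),
               con)
  }
  close(con)
  invisible(path)
}

#' Read a contact series written by [write_contact_series()]
#' @param path Input path.
#' @param condition_label Condition name.
#' @return A [contact_series()].
#' @export
read_contact_series <- function(path, condition_label = "") {
  header <- readLines(path, n = 1)
  m <- regmatches(header, regexec("frames=(\\d+) pairs=(\\S+)", header))[[1]]
  nf <- as.integer(m[2])
  pl <- strsplit(strsplit(m[3], ",")[[1]], ":")
  pairs <- data.frame(i = as.integer(vapply(pl, `[`, "", 1)),
                      j = as.integer(vapply(pl, `[`, "", 2)))
  ind <- matrix(FALSE, nf, nrow(pairs))
  tab <- utils::read.table(path, header = TRUE, skip = 1, sep = "\t")
  if (nrow(tab) > 0) {
    col <- match(paste(tab$i, tab$j), paste(pairs$i, pairs$j))
    ind[cbind(tab$frame, col)] <- TRUE
  }
  contact_series(ind, pairs, condition_label = condition_label)
}
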