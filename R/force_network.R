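#' Time-averaged residue-pairwise force matrix
#'
#' Replicates are concatenated and the signed scalar force of each unordered
#' residue pair is averaged over all frames (arithmetic time mean), the
#' frame-count-weighted mean of the per-replicate averages. Particle pairs
#' mapping to the same residue pair are summed before averaging.
#'
#' @param series A [pair_force_series()].
#' @param per_replicate If `TRUE`, additionally return per-replicate averages
#'   (diagnostic mode).
#' @return An object of class `PairForceMatrix`: list with `pairs` (data
#'   frame `i`, `j`, `mean_force_pN` over residue pairs), `residues`,
#'   `n_frames`, and optionally `per_replicate`.
#' @export
average_pair_forces <- function(series, per_replicate = FALSE) {
  stopifnot(inherits(series, "PairForceSeries"))
  if (nrow(series$forces_pN) < 1) stop("force series has no frames")
  res <- series$residue_index
  ri <- res[series$pairs$i]
  rj <- res[series$pairs$j]
  if (any(is.na(ri)) || any(is.na(rj))) stop("pair indices out of range")
  lo <- pmin(ri, rj); hi <- pmax(ri, rj)
  key <- paste(lo, hi, sep = "_")
  groups <- split(seq_along(key), key)
  col_mean <- colMeans(series$forces_pN)
  agg <- vapply(groups, function(cols) sum(col_mean[cols]), numeric(1))
  ij <- do.call(rbind, strsplit(names(groups), "_"))
  pairs <- data.frame(i = as.integer(ij[, 1]), j = as.integer(ij[, 2]),
                      mean_force_pN = unname(agg))
  pairs <- pairs[order(pairs$i, pairs$j), ]
  rownames(pairs) <- NULL
  out <- structure(list(pairs = pairs,
                        residues = sort(unique(c(pairs$i, pairs$j, res))),
                        n_frames = nrow(series$forces_pN),
                        condition_label = series$condition_label),
                   class = "PairForceMatrix")
  if (per_replicate) {
    out$per_replicate <- lapply(split(seq_len(nrow(series$forces_pN)),
                                      series$replicate), function(rows) {
      cm <- colMeans(series$forces_pN[rows, , drop = FALSE])
      vapply(groups, function(cols) sum(cm[cols]), numeric(1))
    })
  }
  out
}

#' @export
print.PairForceMatrix <- function(x, ...) {
  cat(sprintf("PairForceMatrix '%s': %d residue pairs, averaged over %d frames\n",
              x$condition_label, nrow(x$pairs), x$n_frames))
  invisible(x)
}

#' Thresholded force-difference network between two conditions
#'
#' For every residue pair present in either condition, the difference of the
#' time-averaged signed forces is formed (missing pairs count as zero mean
#' force); pairs with `|delta| >= threshold` become edges of an undirected
#' graph weighted by `|delta|`. By construction the result is symmetric in
#' its two arguments. With `mode = "magnitude"` the difference of average
#' force magnitudes is used instead of the (default) difference of signed
#' averages.
#'
#' @param matrix_a,matrix_b `PairForceMatrix` objects over identical residue
#'   sets.
#' @param threshold Force-difference threshold, pN (> 0). Typical sweeps run
#'   20-100 pN.
#' @param mode `"signed"` (default) or `"magnitude"`.
#' @return An object of class `ForceDiffGraph`: list with `edges` (data frame
#'   `i`, `j`, `weight_pN`, `component`), `residues`, `threshold`,
#'   `components` (list of integer vectors of residues, ordered by size
#'   descending then smallest residue id).
#' @export
difference_network <- function(matrix_a, matrix_b, threshold,
                               mode = c("signed", "magnitude")) {
  stopifnot(inherits(matrix_a, "PairForceMatrix"),
            inherits(matrix_b, "PairForceMatrix"))
  mode <- match.arg(mode)
  if (threshold <= 0) stop("threshold must be > 0")
  if (!setequal(matrix_a$residues, matrix_b$residues)) {
    offenders <- union(setdiff(matrix_a$residues, matrix_b$residues),
                       setdiff(matrix_b$residues, matrix_a$residues))
    stop("residue sets differ between conditions: ",
         paste(offenders, collapse = ", "))
  }
  key <- function(m) paste(m$pairs$i, m$pairs$j, sep = "_")
  all_keys <- union(key(matrix_a), key(matrix_b))
  get <- function(m, keys) {
    v <- m$pairs$mean_force_pN[match(keys, key(m))]
    v[is.na(v)] <- 0
    v
  }
  fa <- get(matrix_a, all_keys)
  fb <- get(matrix_b, all_keys)
  delta <- if (mode == "signed") abs(fa - fb) else abs(abs(fa) - abs(fb))
  keep <- delta >= threshold
  ij <- do.call(rbind, strsplit(all_keys[keep], "_"))
  edges <- if (sum(keep) == 0) {
    data.frame(i = integer(), j = integer(), weight_pN = numeric())
  } else {
    data.frame(i = as.integer(ij[, 1]), j = as.integer(ij[, 2]),
               weight_pN = delta[keep])
  }
  edges <- edges[order(edges$i, edges$j), ]
  rownames(edges) <- NULL
  force_diff_graph(edges, residues = matrix_a$residues,
                   threshold = threshold)
}

# Build a ForceDiffGraph from an edge list: components via igraph,
# deterministically ordered (size desc, then smallest residue id).
force_diff_graph <- function(edges, residues, threshold) {
  if (nrow(edges) > 0) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(edges$i), to = as.character(edges$j)),
      directed = FALSE)
    comp <- igraph::components(g)
    membership <- comp$membership
    comps <- split(as.integer(names(membership)), membership)
    comps <- lapply(comps, sort)
    ord <- order(-vapply(comps, length, integer(1)),
                 vapply(comps, min, integer(1)))
    comps <- comps[ord]
    names(comps) <- NULL
    edge_comp <- vapply(seq_len(nrow(edges)), function(e) {
      which(vapply(comps, function(cc) edges$i[e] %in% cc, logical(1)))[1]
    }, integer(1))
    edges$component <- edge_comp
  } else {
    edges$component <- integer()
    comps <- list()
  }
  structure(list(edges = edges, residues = residues, threshold = threshold,
                 components = comps),
            class = "ForceDiffGraph")
}

#' @export
print.ForceDiffGraph <- function(x, ...) {
  cat(sprintf("ForceDiffGraph: %d edges, %d component(s), threshold %g pN\n",
              nrow(x$edges), length(x$components), x$threshold))
  invisible(x)
}

#' Remove small connected components
#'
#' Keeps only components whose size meets the minimum -- by default at least
#' 3 connected residues (nodes); `unit = "edges"` instead requires at least
#' `min_size` residue pairs (edges) per component.
#'
#' @param graph A `ForceDiffGraph`.
#' @param min_size Minimum component size (default 3).
#' @param unit `"residues"` (nodes, default) or `"edges"` (residue pairs).
#' @return A filtered `ForceDiffGraph`.
#' @export
filter_components <- function(graph, min_size = 3,
                              unit = c("residues", "edges")) {
  stopifnot(inherits(graph, "ForceDiffGraph"))
  unit <- match.arg(unit)
  if (length(graph$components) == 0) return(graph)
  sizes <- if (unit == "residues") {
    vapply(graph$components, length, integer(1))
  } else {
    vapply(seq_along(graph$components), function(k) {
      sum(graph$edges$component == k)
    }, integer(1))
  }
  keep <- which(sizes >= min_size)
  keep_nodes <- unlist(graph$components[keep])
  edges <- graph$edges[graph$edges$i %in% keep_nodes &
                       graph$edges$j %in% keep_nodes, , drop = FALSE]
  force_diff_graph(edges[, c("i", "j", "weight_pN")],
                   residues = graph$residues, threshold = graph$threshold)
}

#' Largest connected component
#'
#' The single biggest component by residue count; ties broken by total edge
#' weight, then by smallest residue id. An empty graph returns an empty
#' graph with a warning.
#'
#' @param graph A `ForceDiffGraph`.
#' @return A `ForceDiffGraph` restricted to the winning component.
#' @export
largest_component <- function(graph) {
  stopifnot(inherits(graph, "ForceDiffGraph"))
  if (length(graph$components) == 0) {
    warning("graph is empty: largest component undefined")
    return(graph)
  }
  n_nodes <- vapply(graph$components, length, integer(1))
  wts <- vapply(seq_along(graph$components), function(k) {
    sum(graph$edges$weight_pN[graph$edges$component == k])
  }, numeric(1))
  mins <- vapply(graph$components, min, integer(1))
  ord <- order(-n_nodes, -wts, mins)
  win <- graph$components[[ord[1]]]
  edges <- graph$edges[graph$edges$i %in% win & graph$edges$j %in% win,
                       c("i", "j", "weight_pN"), drop = FALSE]
  force_diff_graph(edges, residues = graph$residues,
                   threshold = graph$threshold)
}

#' Precision and recall of a difference network against planted pairs
#'
#' @param graph A `ForceDiffGraph`.
#' @param planted_pairs Data frame with columns `i`, `j` of true pairs.
#' @return List with `precision`, `recall`, `n_edges`, `n_planted`.
#' @export
planted_edge_recovery <- function(graph, planted_pairs) {
  key <- function(i, j) paste(pmin(i, j), pmax(i, j), sep = "_")
  found <- key(graph$edges$i, graph$edges$j)
  truth <- key(planted_pairs$i, planted_pairs$j)
  tp <- sum(found %in% truth)
  list(precision = if (length(found)) tp / length(found) else NA_real_,
       recall = tp / length(truth),
       n_edges = length(found), n_planted = length(truth))
}

#' Write a force-difference network to an edge-list TSV
#'
#' Columns: `res_i`, `res_j`, `dF_pN`, `component`. Optionally annotates a
#' PDB structure copy with the component id of each residue in the B-factor
#' column (0 for residues outside any component); residues missing from the
#' structure trigger a warning and skip the annotation.
#'
#' @param graph A `ForceDiffGraph`.
#' @param path Output TSV path.
#' @param pdb_in,pdb_out Optional input structure and annotated output path.
#' @return `path`, invisibly.
#' @export
export_network <- function(graph, path, pdb_in = NULL, pdb_out = NULL) {
  tab <- data.frame(res_i = graph$edges$i, res_j = graph$edges$j,
                    dF_pN = graph$edges$weight_pN,
                    component = graph$edges$component)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(pdb_in) && !is.null(pdb_out)) {
    pdb <- bio3d::read.pdb(pdb_in)
    comp_of <- integer(0)
    for (k in seq_along(graph$components))
      comp_of[as.character(graph$components[[k]])] <- k
    resno <- pdb$atom$resno
    if (length(comp_of) > 0 && !all(names(comp_of) %in% as.character(resno))) {
      warning("structure lacks some network residues: annotation skipped")
    } else {
      b <- comp_of[as.character(resno)]
      b[is.na(b)] <- 0
      pdb$atom$b <- as.numeric(b)
      bio3d::write.pdb(pdb, file = pdb_out)
    }
  }
  invisible(path)
}

#' Read a network edge-list TSV written by [export_network()]
#'
#' @param path TSV path.
#' @param residues Residue universe of the graph (defaults to the residues
#'   appearing in the file).
#' @param threshold Threshold annotation to carry (default: minimum edge
#'   weight in the file).
#' @return A `ForceDiffGraph`.
#' @export
read_network <- function(path, residues = NULL, threshold = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  edges <- data.frame(i = tab$res_i, j = tab$res_j, weight_pN = tab$dF_pN)
  if (is.null(residues)) residues <- sort(unique(c(edges$i, edges$j)))
  if (is.null(threshold))
    threshold <- if (nrow(edges)) min(edges$weight_pN) else 0
  force_diff_graph(edges, residues = residues, threshold = threshold)
}
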