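#' Weighted connectome matrix with explicit missing-edge mask
#'
#' Symmetric weighted adjacency for one subject and one modality. Missingness
#' is carried as a logical `present` mask, never as a sentinel value: absent
#' structural edges (no streamline support) are `NA` in `weights` and `FALSE`
#' in `present`. The diagonal is always excluded. Structural modalities
#' (`FD`, `FDC`, `streamline`) must be nonnegative where present; `logFbC`
#' may be negative (log of a ratio) and `FC` is a signed, fully connected
#' Fisher-Z correlation matrix.
#'
#' @param weights N x N numeric matrix; `NA` marks missing edges.
#' @param modality One of `"FD"`, `"logFbC"`, `"FDC"`, `"streamline"`, `"FC"`.
#' @param present Optional N x N logical mask; defaults to `!is.na(weights)`
#'   with the diagonal forced absent.
#' @return An object of class `connectome_matrix`.
#' @examples
#' w <- matrix(c(NA, 1, 2, 1, NA, NA, 2, NA, NA), 3, 3)
#' m <- connectome_matrix(w, "FD")
#' node_strength(m)
#' @export
connectome_matrix <- function(weights, modality, present = NULL) {
  modality <- match.arg(modality, ALL_MODALITIES)
  weights <- as.matrix(weights)
  if (is.null(present)) present <- !is.na(weights)
  diag(present) <- FALSE
  weights[!present] <- NA_real_
  diag(weights) <- NA_real_
  m <- structure(list(modality = modality, weights = weights,
                      present = present),
                 class = "connectome_matrix")
  validate_connectome(m)
  m
}

validate_connectome <- function(m, tol = 1e-8) {
  w <- m$weights; p <- m$present
  if (nrow(w) != ncol(w)) stop("connectome matrix must be square")
  if (!identical(dim(w), dim(p))) stop("weights/present dimension mismatch")
  if (!identical(p, t(p))) stop("present mask must be symmetric")
  if (any(diag(p))) stop("diagonal must be excluded (present = FALSE)")
  both <- p & t(p)
  if (any(both)) {
    d <- abs(w[both] - t(w)[both])
    scale <- pmax(abs(w[both]), abs(t(w)[both]), 1)
    if (any(d > tol * scale))
      stop("weights asymmetric beyond tolerance for modality ", m$modality)
  }
  if (m$modality %in% c("FD", "FDC", "streamline") &&
      any(w[p] < 0, na.rm = TRUE))
    stop(m$modality, " weights must be nonnegative where present")
  if (m$modality == "FC") {
    off <- !diag(TRUE, nrow(p))
    if (!all(p[off])) stop("FC must be present on every off-diagonal edge")
    if (any(!is.finite(w[off]))) stop("FC weights must be finite")
  }
  invisible(m)
}

#' @export
print.connectome_matrix <- function(x, ...) {
  n <- nrow(x$weights)
  cat(sprintf("<connectome_matrix> %s, %d nodes, %d/%d edges present\n",
              x$modality, n, sum(x$present) / 2L, n_edges(n)))
  invisible(x)
}

#' Map between edge positions and node pairs
#'
#' Edges are ordered along the upper triangle in row-major order:
#' (0,1), (0,2), ..., (0,N-1), (1,2), ... with 0-based node ids `i < j`.
#'
#' @param n Node count.
#' @return `data.frame` with columns `i`, `j` (0-based), one row per edge.
#' @export
edge_index_map <- function(n) {
  i <- rep.int(0:(n - 2L), times = (n - 1L):1L)
  j <- unlist(lapply(1:(n - 1L), function(k) k:(n - 1L)), use.names = FALSE)
  data.frame(i = as.integer(i), j = as.integer(j))
}

#' Vectorize a connectome to its upper-triangle edge vector
#'
#' Each subject's matrix becomes one vector of edge weights covering all
#' region pairs, without the diagonal or reverse directions. Lossless inverse
#' of [devectorize()].
#'
#' @param m A [connectome_matrix()].
#' @return An `edge_vector`: list with `values` (length N(N-1)/2, `NA` where
#'   absent), `present`, `index_map`, and `modality`.
#' @export
vectorize <- function(m) {
  stopifnot(inherits(m, "connectome_matrix"))
  tw <- t(m$weights); tp <- t(m$present)
  low <- lower.tri(tw)          # row-major traversal of the upper triangle
  structure(list(values = tw[low], present = tp[low],
                 index_map = edge_index_map(nrow(tw)),
                 modality = m$modality),
            class = "edge_vector")
}

#' @rdname vectorize
#' @param ev An `edge_vector`.
#' @export
devectorize <- function(ev) {
  stopifnot(inherits(ev, "edge_vector"))
  n <- max(ev$index_map$j) + 1L
  w <- matrix(NA_real_, n, n)
  p <- matrix(FALSE, n, n)
  idx <- cbind(ev$index_map$i + 1L, ev$index_map$j + 1L)
  w[idx] <- ev$values
  p[idx] <- ev$present
  w[idx[, 2:1]] <- ev$values
  p[idx[, 2:1]] <- ev$present
  connectome_matrix(w, ev$modality, p)
}

#' Read / write a connectome matrix as delimited text
#'
#' Square TSV with a header row and first column of node labels and the
#' token `NA` for missing edges. On read the two triangles must agree within
#' a relative tolerance; the stored matrix is their exact symmetrization.
#'
#' @param path File path.
#' @param modality Modality tag (see [connectome_matrix()]).
#' @param atlas Optional [atlas_definition()]; if given, dimension and labels
#'   are checked against it.
#' @param tol Relative symmetry tolerance (guards foreign files; files
#'   written by [write_connectome()] are exactly symmetric).
#' @return `read_connectome`: a validated [connectome_matrix()];
#'   `write_connectome` returns `path` invisibly and round-trips exactly.
#' @export
read_connectome <- function(path, modality, atlas = NULL, tol = 1e-8) {
  tab <- as.matrix(read.table(path, header = TRUE, sep = "\t", row.names = 1,
                              check.names = FALSE))
  storage.mode(tab) <- "double"
  if (nrow(tab) != ncol(tab)) stop("connectome file must be square")
  if (!is.null(atlas)) {
    if (nrow(tab) != n_nodes(atlas))
      stop("dimension ", nrow(tab), " does not match atlas (",
           n_nodes(atlas), " nodes)")
    if (!identical(unname(rownames(tab)), atlas$label))
      stop("node labels do not match atlas")
  }
  p <- !is.na(tab); diag(p) <- FALSE
  if (!identical(unname(p), unname(t(p))))
    stop("missing-edge pattern is asymmetric")
  both <- p
  d <- abs(tab[both] - t(tab)[both])
  scale <- pmax(abs(tab[both]), abs(t(tab)[both]), 1)
  if (any(d > tol * scale, na.rm = TRUE))
    stop("matrix asymmetric beyond tolerance ", tol)
  w <- (tab + t(tab)) / 2
  w[!p] <- NA_real_
  if (modality == "streamline" && any(w[p] < 0, na.rm = TRUE))
    stop("negative streamline counts")
  dimnames(w) <- NULL
  connectome_matrix(w, modality, unname(p))
}

#' @rdname read_connectome
#' @param m A [connectome_matrix()].
#' @param labels Optional node labels for the header (defaults to `V1..VN`).
#' @export
write_connectome <- function(m, path, labels = NULL) {
  validate_connectome(m)
  w <- m$weights
  if (is.null(labels)) labels <- paste0("V", seq_len(nrow(w)))
  out <- as.data.frame(w)
  names(out) <- labels
  rownames(out) <- labels
  write.table(format(out, digits = 17, trim = TRUE, scientific = TRUE),
              path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' Fixel-based edge weight
#'
#' An edge's structural weight is the mean of the nonzero fixel values along
#' the connection's fixel mask, multiplied by the number of streamlines
#' assigned to the edge (so edges with the same average fixel metric but more
#' streamline support weigh more). An edge whose fixel values are all zero
#' has no usable fixel support and is marked missing (`NA`).
#'
#' Linear in `n_streamlines` and invariant to permutation of `fixel_values`.
#'
#' @param fixel_values Numeric vector of fixel metric values along the edge.
#' @param n_streamlines Streamline count assigned to the edge (>= 1).
#' @return Mean of nonzero values times `n_streamlines`, or `NA_real_`.
#' @examples
#' fixel_edge_weight(c(0.5, 0, 0.7), 10)  # 6
#' @export
fixel_edge_weight <- function(fixel_values, n_streamlines) {
  if (length(n_streamlines) != 1L || is.na(n_streamlines) ||
      n_streamlines < 1) stop("n_streamlines must be a single value >= 1")
  nz <- fixel_values[!is.na(fixel_values) & fixel_values != 0]
  if (length(nz) == 0L) return(NA_real_)
  mean(nz) * n_streamlines
}

#' Nodal strength
#'
#' The sum of weights of present edges incident to each node. Signed: negative
#' FC weights subtract. A node with no present incident edge gets `NA`.
#'
#' @param m A [connectome_matrix()].
#' @param node Optional 0-based node id(s); default all nodes.
#' @return Numeric vector of strengths.
#' @export
node_strength <- function(m, node = NULL) {
  stopifnot(inherits(m, "connectome_matrix"))
  w <- m$weights; w[!m$present] <- 0
  s <- rowSums(w)
  s[rowSums(m$present) == 0L] <- NA_real_
  if (!is.null(node)) s <- s[node + 1L]
  s
}
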