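#' Atlas definition
#'
#' A parcellation table fixing node identity, network membership and
#' default-mode-network (DMN) flags for all connectomes in an analysis. Node
#' ids are 0-based and contiguous (`0..N-1`); matrix rows/columns map to
#' `node_id + 1`.
#'
#' @param node_id Integer vector `0..N-1` (any order; validated contiguous).
#' @param label Character node labels, unique.
#' @param network Character network membership: one of the seven cortical
#'   resting-state networks or `"Subcortical"`.
#' @param is_dmn Logical DMN membership; must be a nonempty strict subset.
#' @return A `data.frame` of class `atlas_definition`, ordered by `node_id`.
#' @examples
#' atl <- atlas_definition(0:3, paste0("n", 1:4),
#'                         c("Default", "Default", "Visual", "Subcortical"),
#'                         c(TRUE, TRUE, FALSE, FALSE))
#' n_nodes(atl)
#' @export
atlas_definition <- function(node_id, label, network, is_dmn) {
  atl <- data.frame(node_id = as.integer(node_id), label = as.character(label),
                    network = as.character(network), is_dmn = as.logical(is_dmn),
                    stringsAsFactors = FALSE)
  atl <- atl[order(atl$node_id), , drop = FALSE]
  rownames(atl) <- NULL
  class(atl) <- c("atlas_definition", "data.frame")
  validate_atlas(atl)
  atl
}

validate_atlas <- function(atlas) {
  n <- nrow(atlas)
  if (n < 2L) stop("atlas needs at least 2 nodes")
  if (!identical(atlas$node_id, 0:(n - 1L)))
    stop("node_id must be contiguous 0..N-1 and unique")
  if (anyDuplicated(atlas$label)) stop("node labels must be unique")
  ndmn <- sum(atlas$is_dmn)
  if (ndmn == 0L || ndmn >= n)
    stop("DMN must be a nonempty strict subset of nodes")
  invisible(atlas)
}

#' @rdname atlas_definition
#' @param atlas An `atlas_definition`.
#' @export
n_nodes <- function(atlas) nrow(atlas)

#' Number of undirected off-diagonal edges for an N-node connectome
#'
#' @param n Node count.
#' @return `n * (n - 1) / 2`, e.g. 7021 for the 119-node atlas.
#' @export
n_edges <- function(n) as.integer(n * (n - 1L) / 2L)

#' Read / write an atlas table
#'
#' TSV with columns `node_id`, `label`, `network`, `is_dmn`. Files written by
#' external tooling may index nodes from 1; `offset` is subtracted on read so
#' ids are 0-based internally.
#'
#' @param path File path.
#' @param offset Integer subtracted from `node_id` on read (default 0).
#' @return `read_atlas`: an [atlas_definition()].
#' @export
read_atlas <- function(path, offset = 0L) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("node_id", "label", "network", "is_dmn")
  if (!all(need %in% names(tab)))
    stop("atlas file must have columns: ", paste(need, collapse = ", "))
  atlas_definition(tab$node_id - as.integer(offset), tab$label,
                   tab$network, tab$is_dmn)
}

#' @rdname read_atlas
#' @param atlas An `atlas_definition`.
#' @export
write_atlas <- function(atlas, path) {
  validate_atlas(atlas)
  write.table(as.data.frame(atlas), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Edge subsets ("scopes") from an atlas
#'
#' Resolves a scope descriptor to the set of edge positions (in the
#' vectorization order of [vectorize()]) whose *both* endpoints belong to the
#' subset: `"whole"` keeps every edge, `"dmn"` keeps within-DMN edges,
#' `"network:<name>"` keeps edges within one named network.
#'
#' @param atlas An [atlas_definition()].
#' @param scope `"whole"`, `"dmn"`, or `"network:<name>"`.
#' @return Logical vector of length `n_edges(N)`.
#' @export
scope_edges <- function(atlas, scope = "whole") {
  n <- n_nodes(atlas)
  map <- edge_index_map(n)
  if (identical(scope, "whole")) return(rep(TRUE, nrow(map)))
  if (identical(scope, "dmn")) {
    keep <- atlas$is_dmn
  } else if (startsWith(scope, "network:")) {
    nm <- sub("^network:", "", scope)
    if (!nm %in% atlas$network) stop("unknown network: ", nm)
    keep <- atlas$network == nm
  } else stop("unknown scope: ", scope)
  keep[map$i + 1L] & keep[map$j + 1L]
}
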