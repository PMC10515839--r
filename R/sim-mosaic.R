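#' Simulate extrachromosomal-array loss over a lineage tree
#'
#' Each simulated animal starts with the array in the root cell; every cell
#' division (edge of the lineage tree) transmits the array independently
#' with probability `p`. A terminal cell retains the array iff every
#' division on its path from the root transmitted it.
#'
#' @param tree an `ape::phylo` lineage tree (edges are mitotic divisions).
#' @param p per-division transmission probability, in `[0, 1]`.
#' @param n_animals number of simulated animals, `>= 1`.
#' @param seed integer seed.
#' @param chunk_size animals simulated per block (memory control).
#' @return logical matrix `n_animals x n_tips` of terminal-cell retention
#'   states, columns named by tip label.
#' @export
simulate_mosaic_population <- function(tree, p, n_animals, seed,
                                       chunk_size = 20000L) {
  if (!inherits(tree, "phylo")) {
    stopf("tree must be an ape 'phylo' object", class = "wormpcd_config_error")
  }
  if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p > 1) {
    stopf("p must be a single probability in [0, 1]",
          class = "wormpcd_domain_error")
  }
  if (n_animals < 1) {
    stopf("n_animals must be >= 1", class = "wormpcd_config_error")
  }
  n_animals <- as.integer(n_animals)
  paths <- tip_edge_paths(tree)
  n_tip <- length(tree$tip.label)
  n_edge <- nrow(tree$edge)
  out <- matrix(FALSE, n_animals, n_tip,
                dimnames = list(NULL, tree$tip.label))
  set.seed(derive_seed(seed, "mosaic"))
  done <- 0L
  while (done < n_animals) {
    nc <- min(chunk_size, n_animals - done)
    ok <- matrix(stats::runif(nc * n_edge) < p, nc, n_edge)
    for (j in seq_len(n_tip)) {
      pe <- paths[[j]]
      out[done + seq_len(nc), j] <-
        rowSums(!ok[, pe, drop = FALSE]) == 0L
    }
    done <- done + nc
  }
  out
}

# For each tip, the indices (rows of tree$edge) of the divisions on its path
# from the root.
tip_edge_paths <- function(tree) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  parent_edge <- integer(max(tree$edge))
  parent_edge[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  parent_node <- integer(max(tree$edge))
  parent_node[tree$edge[, 2]] <- tree$edge[, 1]
  lapply(seq_len(n_tip), function(tip) {
    path <- integer(0)
    node <- tip
    while (node != root) {
      path <- c(path, parent_edge[node])
      node <- parent_node[node]
    }
    path
  })
}
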