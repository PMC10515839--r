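#' Default bilateral cell pairs scored in the mosaic model
#'
#' Terminal labels of the seven bilateral neuron pairs (plus the RIM pair)
#' carried by the reduced fixture lineage.
#' @export
MOSAIC_CELL_PAIRS <- list(
  ASI = c("ASIL", "ASIR"), ADL = c("ADLL", "ADLR"),
  ASK = c("ASKL", "ASKR"), ADA = c("ADAL", "ADAR"),
  PHB = c("PHBL", "PHBR"), PVQ = c("PVQL", "PVQR"),
  RIC = c("RICL", "RICR")
)

# Post-divergence division counts k encoded by the fixture (total over both
# sides of each bilateral pair).
FIXTURE_K <- c(ASI = 16, ADL = 18, ASK = 20, ADA = 16, PHB = 16,
               PVQ = 14, RIC = 8)

# Newick for a chain of `len` divisions ending at `terminal`; each internal
# chain node carries a terminal stub child so every division is binary.
chain_newick <- function(terminal, len, stub_prefix) {
  s <- terminal
  if (len > 1) {
    for (i in seq_len(len - 1)) {
      s <- sprintf("(%s,%s_d%d)", s, stub_prefix, i)
    }
  }
  s
}

#' Reduced synthetic lineage fixture in Newick form
#'
#' A reduced encoding of the division counts the array-transmission model
#' needs, not a reconstruction of the full somatic lineage: two shared
#' divisions from the zygote P0 (via AB) to the divergence node ABp, eight
#' divisions from ABp to each RIM sister, and for each scored bilateral pair
#' two private chains from ABp totalling its post-divergence division count
#' (ASI 16, ADL 18, ASK 20, ADA 16, PHB 16, PVQ 14, RIC 8). The divergence
#' node is multifurcating by design: hanging every pair's private chains off
#' one node is what keeps the pair lineages disjoint from the RIM lineage
#' below the shared stem, which the conditional retention model requires.
#' Chain nodes carry stub leaves (suffix `_d*`) so all other divisions are
#' binary.
#'
#' @return a single Newick string (rooted, with internal node labels
#'   P0/AB/ABp).
#' @export
rim_lineage_newick <- function() {
  per_side <- FIXTURE_K / 2
  kids <- c(
    chain_newick("RIML", 8, "riml"),
    chain_newick("RIMR", 8, "rimr"),
    unlist(lapply(names(per_side), function(nm) {
      c(chain_newick(paste0(nm, "L"), per_side[[nm]], paste0(tolower(nm), "l")),
        chain_newick(paste0(nm, "R"), per_side[[nm]], paste0(tolower(nm), "r")))
    }))
  )
  sprintf("(((%s)ABp,ABa)AB,P1)P0;", paste(kids, collapse = ","))
}

#' Load the reduced lineage fixture as a phylo tree
#'
#' @param from_file read the copy shipped under `extdata` instead of
#'   rebuilding the Newick in code (both are identical; the file is the
#'   on-disk interface).
#' @return an `ape::phylo` tree with node labels.
#' @export
rim_lineage_tree <- function(from_file = FALSE) {
  txt <- if (from_file) {
    path <- system.file("extdata", "rim_lineage_synthetic.nwk",
                        package = "wormpcd")
    paste(readLines(path, warn = FALSE), collapse = "")
  } else {
    rim_lineage_newick()
  }
  ape::read.tree(text = txt)
}

resolve_node <- function(tree, label) {
  if (is.numeric(label)) {
    return(as.integer(label))
  }
  i <- match(label, tree$tip.label)
  if (!is.na(i)) {
    return(i)
  }
  j <- match(label, tree$node.label)
  if (!is.na(j)) {
    return(length(tree$tip.label) + j)
  }
  stopf("cell '%s' not found in the lineage tree", label,
        class = "wormpcd_unknown_cell_error")
}

root_edge_path <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  parent_edge <- integer(max(tree$edge))
  parent_edge[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  parent_node <- integer(max(tree$edge))
  parent_node[tree$edge[, 2]] <- tree$edge[, 1]
  path <- integer(0)
  while (node != root) {
    path <- c(path, parent_edge[node])
    node <- parent_node[node]
  }
  path
}

#' Count divisions spanning a set of cells
#'
#' Number of edges (mitotic divisions) in the minimal subtree connecting the
#' conditioning node to all target cells. For the fixture this gives 18 from
#' P0 to the two RIM sisters, and each pair's post-divergence count from its
#' divergence node.
#'
#' @param tree an `ape::phylo` lineage tree.
#' @param conditioning_node node label (tip or internal) or numeric node id.
#' @param target_labels character vector of cell labels (or numeric ids).
#' @return integer edge count `k`.
#' @export
divisions_spanning <- function(tree, conditioning_node, target_labels) {
  cond <- resolve_node(tree, conditioning_node)
  targets <- vapply(target_labels, resolve_node, integer(1), tree = tree)
  cond_path <- root_edge_path(tree, cond)
  edges <- integer(0)
  for (tg in targets) {
    tg_path <- root_edge_path(tree, tg)
    # path between cond and tg = symmetric difference of root paths
    between <- c(setdiff(cond_path, tg_path), setdiff(tg_path, cond_path))
    edges <- union(edges, between)
  }
  length(edges)
}

#' Estimate the per-division array transmission probability
#'
#' Given the observed fraction `f` of animals whose array survived all `D`
#' divisions of a reference path, the average per-division transmission
#' probability is the `D`-th root: `p = f^(1/D)`. The reference measurement
#' is 39 of 181 assayed animals with two RIM neurons over the 18 divisions
#' into both RIM sisters, giving p = 0.21547^(1/18).
#'
#' @param f observed retention frequency, in `(0, 1]`.
#' @param D number of divisions survived, `>= 1`.
#' @return object of class `transmission_estimate`: `f`, `D`, `p` (full
#'   precision), `p_truncated` (4-decimal truncation, the headline form),
#'   `p_rounded` (4-decimal half-up rounding).
#' @export
estimate_transmission <- function(f, D) {
  if (!is.numeric(f) || length(f) != 1 || is.na(f)) {
    stopf("f must be a single number", class = "wormpcd_domain_error")
  }
  if (f == 0) {
    stopf("f = 0: transmission root undefined", class = "wormpcd_domain_error")
  }
  if (f < 0 || f > 1) {
    stopf("f must lie in (0, 1]", class = "wormpcd_domain_error")
  }
  if (D < 1) {
    stopf("D must be >= 1", class = "wormpcd_domain_error")
  }
  p <- f^(1 / D)
  structure(list(f = f, D = D, p = p,
                 p_truncated = floor(p * 1e4) / 1e4,
                 p_rounded = round_half_up(p, 4)),
            class = "transmission_estimate")
}

#' @export
print.transmission_estimate <- function(x, ...) {
  cat(sprintf("<transmission_estimate> f=%.5f over D=%d divisions -> p=%.6f (%.4f truncated)\n",
              x$f, x$D, x$p, x$p_truncated))
  invisible(x)
}

#' Predicted fraction of animals retaining the array through k divisions
#'
#' Closed form of the transmission model: each division transmits
#' independently with probability `p`, so retention through `k` divisions
#' occurs with probability `p^k`.
#'
#' @param p per-division transmission probability, in `[0, 1]`.
#' @param k number of divisions, non-negative integer.
#' @return `p^k`.
#' @export
predict_retention <- function(p, k) {
  if (any(p < 0) || any(p > 1)) {
    stopf("p must lie in [0, 1]", class = "wormpcd_domain_error")
  }
  if (any(k < 0) || any(k != round(k))) {
    stopf("k must be a non-negative integer", class = "wormpcd_domain_error")
  }
  p^k
}

#' Retention predictions for every scored cell pair
#'
#' For each bilateral pair, counts the spanning divisions from the stated
#' conditioning node and applies the closed form `p^k`. Under
#' `"divergence"` conditioning the array is known to be present at the
#' pair's divergence node (the situation in 2-RIM animals, where the whole
#' RIM lineage retained the array), so `k` is the pair's post-divergence
#' count. Under `"P0"` conditioning only the zygote is known to carry the
#' array (the situation in 4-RIM animals) and the shared divisions from P0
#' to the divergence node are added.
#'
#' @param tree lineage tree (default: the shipped fixture).
#' @param p per-division transmission probability.
#' @param conditioning `"divergence"` or `"P0"`.
#' @param cell_pairs named list of terminal-label pairs.
#' @return data.frame with `cell_type`, `k` (divisions used), `shared`
#'   (divisions from P0 to the divergence node), `fraction` (full
#'   precision), `fraction_rounded` (half-up, 2 decimals).
#' @export
predict_retention_table <- function(tree = rim_lineage_tree(), p,
                                    conditioning = c("divergence", "P0"),
                                    cell_pairs = MOSAIC_CELL_PAIRS) {
  conditioning <- match.arg(conditioning)
  root_label <- tree$node.label[1]
  rows <- lapply(names(cell_pairs), function(nm) {
    pair <- cell_pairs[[nm]]
    mrca <- ape::getMRCA(tree, pair)
    k_div <- divisions_spanning(tree, mrca, pair)
    k_p0 <- divisions_spanning(tree, root_label, pair)
    k <- if (conditioning == "divergence") k_div else k_p0
    data.frame(cell_type = nm, k = k, shared = k_p0 - k_div,
               fraction = predict_retention(p, k),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fraction_rounded <- round_half_up(out$fraction, 2)
  out
}

#' Reproduce the published retention-fraction tables
#'
#' Reconstructs both report tables of the array-transmission analysis from
#' its inputs (39 two-RIM animals out of 181, 18 divisions). The 2-RIM
#' column is the closed form `p^k` rounded to two decimals. The published
#' 4-RIM column was derived by multiplying the already-rounded 2-RIM
#' fractions by `p^2` (the two shared divisions) and re-rounding; this
#' chained rounding differs from the full-precision model `p^(k+2)` by 0.01
#' for ADL and PVQ, so both columns are returned.
#'
#' @param tree lineage tree (default: the shipped fixture).
#' @param f,D observed retention frequency and division count behind `p`.
#' @return list with `estimate` (the [estimate_transmission()] result) and
#'   `table`: data.frame with `cell_type`, `k`, `two_rim` (rounded `p^k`),
#'   `four_rim_published` (chained rounding), `four_rim_model` (rounded
#'   `p^(k+2)`), plus full-precision columns.
#' @export
published_retention_tables <- function(tree = rim_lineage_tree(),
                                       f = 39 / 181, D = 18) {
  est <- estimate_transmission(f, D)
  div_tab <- predict_retention_table(tree, est$p, "divergence")
  p0_tab <- predict_retention_table(tree, est$p, "P0")
  two_rim <- div_tab$fraction_rounded
  tab <- data.frame(
    cell_type = div_tab$cell_type,
    k = div_tab$k,
    two_rim = two_rim,
    four_rim_published = round_half_up(two_rim * est$p^div_tab$shared, 2),
    four_rim_model = p0_tab$fraction_rounded,
    two_rim_full = div_tab$fraction,
    four_rim_full = p0_tab$fraction,
    stringsAsFactors = FALSE
  )
  list(estimate = est, table = tab)
}

#' Monte Carlo validation of the closed-form retention predictions
#'
#' Simulates array loss over the lineage with
#' [simulate_mosaic_population()], conditions on the stated event (under
#' `"divergence"` conditioning: the array retained in both RIM sisters,
#' i.e. the 2-RIM class; under `"P0"`: presence in the zygote, which always
#' holds), and reports the conditional retention frequency of each cell
#' pair with its binomial standard error next to the closed form.
#'
#' @param tree lineage tree.
#' @param p per-division transmission probability.
#' @param conditioning `"divergence"` or `"P0"`.
#' @param n number of simulated animals, `>= 1000`.
#' @param seed integer seed.
#' @param cell_pairs named list of terminal-label pairs.
#' @param rim_pair labels of the two RIM sisters.
#' @return data.frame with `cell_type`, `empirical`, `se`, `predicted`,
#'   `n_conditioned`.
#' @export
validate_by_simulation <- function(tree = rim_lineage_tree(), p,
                                   conditioning = c("divergence", "P0"),
                                   n = 200000, seed = 1,
                                   cell_pairs = MOSAIC_CELL_PAIRS,
                                   rim_pair = c("RIML", "RIMR")) {
  conditioning <- match.arg(conditioning)
  if (n < 1000) {
    stopf("n must be >= 1000 for a meaningful validation",
          class = "wormpcd_config_error")
  }
  pop <- simulate_mosaic_population(tree, p, n, seed)
  keep <- if (conditioning == "divergence") {
    pop[, rim_pair[1]] & pop[, rim_pair[2]]
  } else {
    rep(TRUE, nrow(pop))
  }
  m <- sum(keep)
  if (m == 0) {
    stopf("conditioning event never observed in %d simulated animals", n,
          class = "wormpcd_insufficient_sample_error")
  }
  pred <- predict_retention_table(tree, p, conditioning, cell_pairs)
  emp <- vapply(names(cell_pairs), function(nm) {
    pair <- cell_pairs[[nm]]
    mean(pop[keep, pair[1]] & pop[keep, pair[2]])
  }, numeric(1))
  data.frame(
    cell_type = names(cell_pairs),
    empirical = unname(emp),
    se = sqrt(pmax(emp * (1 - emp), 1e-12) / m),
    predicted = pred$fraction[match(names(cell_pairs), pred$cell_type)],
    n_conditioned = m,
    stringsAsFactors = FALSE
  )
}

#' Programmed-cell-death census percentages
#'
#' Arithmetic over the lineage census: the share of programmed cell deaths
#' that are neural-proximate, the share occurring in exclusively neuronal
#' lineages, the share of neurons among all somatic cells, and the relative
#' increase in total neurons if every neuronal-lineage undead cell became a
#' neuron. Percentages are rounded to whole numbers.
#'
#' @param census named list/vector with `n_pcd` (total programmed cell
#'   deaths), `n_neural_proximate`, `n_neuronal_lineage`, `n_neurons`,
#'   `n_cells`.
#' @return named list of integer percentages: `neural_proximate_pct`,
#'   `neuronal_lineage_pct`, `neuron_pct`, `undead_increase_pct`.
#' @export
compute_census <- function(census) {
  cn <- as.list(census)
  need <- c("n_pcd", "n_neural_proximate", "n_neuronal_lineage",
            "n_neurons", "n_cells")
  missing <- setdiff(need, names(cn))
  if (length(missing)) {
    stopf("census missing counts: %s", paste(missing, collapse = ", "),
          class = "wormpcd_domain_error")
  }
  vals <- unlist(cn[need])
  if (any(vals < 0)) {
    stopf("census counts must be non-negative", class = "wormpcd_domain_error")
  }
  if (cn$n_pcd == 0 || cn$n_cells == 0 || cn$n_neurons == 0) {
    stopf("census denominators must be positive", class = "wormpcd_domain_error")
  }
  if (cn$n_neural_proximate > cn$n_pcd ||
      cn$n_neuronal_lineage > cn$n_pcd || cn$n_neurons > cn$n_cells) {
    stopf("census subsets exceed their totals", class = "wormpcd_domain_error")
  }
  list(
    neural_proximate_pct = round_half_up(100 * cn$n_neural_proximate / cn$n_pcd),
    neuronal_lineage_pct = round_half_up(100 * cn$n_neuronal_lineage / cn$n_pcd),
    neuron_pct = round_half_up(100 * cn$n_neurons / cn$n_cells),
    undead_increase_pct = round_half_up(100 * cn$n_neuronal_lineage / cn$n_neurons)
  )
}
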