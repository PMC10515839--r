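# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Brute-force sorted-voxel mean: sort descending, average the first k.
oracle_top_mean <- function(vals, k) {
  v <- sort(as.numeric(vals), decreasing = TRUE)
  mean(v[seq_len(min(k, length(v)))])
}

# Welch's t statistic, Satterthwaite df and two-tailed p, straight from the
# formulas.
oracle_welch <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- var(a) / na; vb <- var(b) / nb
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# Poisson central interval by brute-force CDF enumeration: smallest lo and
# largest hi with P(X < lo) <= alpha/2 and P(X > hi) <= alpha/2.
oracle_poisson_interval <- function(lambda, alpha = 0.01) {
  cdf <- 0
  k <- -1
  lo <- 0
  repeat {
    k <- k + 1
    term <- exp(-lambda + k * log(lambda) - lgamma(k + 1))
    if (cdf + term > alpha / 2 && lo == 0) lo <- k
    cdf <- cdf + term
    if (cdf >= 1 - alpha / 2) break
  }
  c(lo = lo, hi = k)
}

# Edge count of the minimal subtree connecting a node set: union of the
# root-edge paths of all members, minus the edges above their common
# ancestor (edges shared by every root path).
oracle_spanning_edges <- function(tree, labels) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  parent_edge <- integer(max(tree$edge))
  parent_edge[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  parent_node <- integer(max(tree$edge))
  parent_node[tree$edge[, 2]] <- tree$edge[, 1]
  to_node <- function(lab) {
    if (is.numeric(lab)) return(as.integer(lab))
    i <- match(lab, tree$tip.label)
    if (!is.na(i)) return(i)
    n_tip + match(lab, tree$node.label)
  }
  root_path <- function(node) {
    path <- integer(0)
    while (node != root) {
      path <- c(path, parent_edge[node])
      node <- parent_node[node]
    }
    path
  }
  paths <- lapply(labels, function(l) root_path(to_node(l)))
  all_edges <- Reduce(union, paths)
  shared <- Reduce(intersect, paths)
  length(setdiff(all_edges, shared))
}

# Window extraction by direct index arithmetic on the raw vector.
oracle_align <- function(values, fr, onset, pre_s, post_s) {
  idx0 <- round(onset * fr) + 1
  lo <- idx0 - round(pre_s * fr)
  hi <- idx0 + round(post_s * fr)
  if (lo < 1 || hi > length(values)) return(NULL)
  values[lo:hi]
}

# Small deterministic movie with known voxel values for extraction tests.
make_test_movie <- function(dims = c(t = 3, z = 7, y = 13, x = 13),
                            fill = 0, frame_rate = 4) {
  arr <- array(fill, dims)
  two_channel_movie(arr, arr, frame_rate, c(x = 0.4, y = 0.4, z = 1.2))
}

# One-neuron annotation table covering all volumes.
make_annotation <- function(n_t, x, y, z, id = "N1") {
  data.frame(t_index = seq_len(n_t), neuron_id = id,
             x_vox = x, y_vox = y, z_vox = z, stringsAsFactors = FALSE)
}

# Reduced-size imaging config for unit tests (geometry and processes as the
# defaults, shorter and smaller for speed). Overrides in ... win.
small_movie_config <- function(seed = 1, duration = 150, ...) {
  args <- modifyList(
    list(random_seed = seed, duration = duration,
         voxel_counts = c(x = 22, y = 22, z = 8),
         neuron_positions = list(RIML = c(x = 8, y = 11, z = 4),
                                 RIMR = c(x = 15, y = 11, z = 4))),
    list(...)
  )
  do.call(sim_config, args)
}

# Noise-free, bleach-free, artifact-free variant: the identity conditions.
clean_movie_config <- function(seed = 1, duration = 60, ...) {
  args <- modifyList(
    list(seed = seed, duration = duration,
         bleach = list(red = c(a1 = 0, l1 = 0, a2 = 1, l2 = 0),
                       green = c(a1 = 0, l1 = 0, a2 = 1, l2 = 0)),
         artifact = c(sd = 0, tau = 10),
         noise_floor = c(red = 0, green = 0),
         shot_noise_sd = 0),
    list(...)
  )
  do.call(small_movie_config, args)
}
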