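#' Network topologies
#'
#' A `topology` object holds the directed, mono-synaptic connectivity of a
#' network of `n_e` excitatory and `n_i` inhibitory cells, split into the
#' four connection classes E-E, E-I, I-E and I-I, together with the synaptic
#' weights.  Neuron ids are 0-based and global: excitatory cells are
#' `0 .. n_e-1`, inhibitory cells `n_e .. n_e+n_i-1`.  Optionally, per-cell
#' positions on the unit torus `[0,1)^2` are attached.
#'
#' @name topology
#' @keywords internal
NULL

CLASSES <- c("ee", "ei", "ie", "ii")

new_topology <- function(n_e, n_i, edges, positions = NULL) {
  for (cl in CLASSES) {
    e <- edges[[cl]]
    stopifnot(is.data.frame(e), all(c("pre", "post", "w") %in% names(e)))
  }
  structure(list(n_e = as.integer(n_e), n_i = as.integer(n_i),
                 edges = edges, positions = positions),
            class = "topology")
}

edge_df <- function(pre, post, w = 1) {
  data.frame(pre = as.integer(pre), post = as.integer(post),
             w = rep_len(as.numeric(w), length(pre)))
}

split_edge_classes <- function(pre, post, n_e, w = 1) {
  pre_e <- pre < n_e
  post_e <- post < n_e
  w <- rep_len(w, length(pre))
  list(ee = edge_df(pre[pre_e & post_e], post[pre_e & post_e], w[pre_e & post_e]),
       ei = edge_df(pre[pre_e & !post_e], post[pre_e & !post_e], w[pre_e & !post_e]),
       ie = edge_df(pre[!pre_e & post_e], post[!pre_e & post_e], w[!pre_e & post_e]),
       ii = edge_df(pre[!pre_e & !post_e], post[!pre_e & !post_e], w[!pre_e & !post_e]))
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("topology: %d excitatory + %d inhibitory cells\n", x$n_e, x$n_i))
  for (cl in CLASSES)
    cat(sprintf("  %s: %d edges (mean weight %.4g)\n", toupper(gsub("(.)(.)", "\\1-\\2", cl)),
                nrow(x$edges[[cl]]),
                if (nrow(x$edges[[cl]])) mean(x$edges[[cl]]$w) else NA))
  if (!is.null(x$positions)) cat("  positions: on unit torus\n")
  invisible(x)
}

# sample k ordered non-self pairs uniformly among the n_pre x n_post grid
# (self-pairs excluded when the id ranges overlap); returns 0-based local ids
sample_pairs <- function(n_pre, n_post, p, same_pop) {
  n_pairs <- if (same_pop) n_pre * (n_post - 1) else n_pre * n_post
  if (n_pairs <= 0 || p <= 0) return(list(pre = integer(0), post = integer(0)))
  k <- rbinom(1, n_pairs, p)
  if (k == 0) return(list(pre = integer(0), post = integer(0)))
  idx <- sample.int(n_pairs, k) - 1
  if (same_pop) {
    pre <- idx %/% (n_post - 1)
    off <- idx %% (n_post - 1)
    post <- off + (off >= pre)
  } else {
    pre <- idx %/% n_post
    post <- idx %% n_post
  }
  list(pre = pre, post = post)
}

#' Build an Erdos-Renyi random topology
#'
#' Connects every ordered pair of distinct cells independently with
#' probability `p`, in all four connection classes.  The reference network
#' uses 4000 excitatory and 1000 inhibitory cells with `p = 0.02`.  All
#' weights are initialized to 1 (see [init_weights()]).
#'
#' @param n_e,n_i numbers of excitatory and inhibitory cells.
#' @param p connection probability.
#' @param seed integer seed (`NULL` uses the current RNG stream).
#' @return A [topology] object.
#' @export
#' @examples
#' topo <- build_random_topology(100, 25, 0.05, seed = 1)
#' topo
build_random_topology <- function(n_e, n_i, p, seed = NULL) {
  if (n_e < 0 || n_i < 0) stop("n_e and n_i must be non-negative")
  if (p < 0 || p > 1) stop("p must be in [0, 1]")
  with_seed(seed, {
    ee <- sample_pairs(n_e, n_e, p, TRUE)
    ei <- sample_pairs(n_e, n_i, p, FALSE)
    ie <- sample_pairs(n_i, n_e, p, FALSE)
    ii <- sample_pairs(n_i, n_i, p, TRUE)
    new_topology(n_e, n_i, list(
      ee = edge_df(ee$pre, ee$post),
      ei = edge_df(ei$pre, n_e + ei$post),
      ie = edge_df(n_e + ie$pre, ie$post),
      ii = edge_df(n_e + ii$pre, n_e + ii$post)))
  })
}

#' Build a homogeneous in-degree topology
#'
#' Every cell receives exactly `k_e_in` excitatory and `k_i_in` inhibitory
#' presynaptic partners, sampled without replacement and excluding
#' self-connections.  In-degrees are thus strictly identical across the
#' population (out-degrees still fluctuate).
#'
#' @inheritParams build_random_topology
#' @param k_e_in,k_i_in excitatory / inhibitory in-degree of every cell.
#' @return A [topology] object.
#' @export
build_homogeneous_topology <- function(n_e, n_i, k_e_in, k_i_in, seed = NULL) {
  if (k_e_in >= n_e || (k_i_in >= n_i && k_i_in > 0) || k_i_in > n_i)
    stop("requested in-degree exceeds the available presynaptic pool")
  if (k_e_in < 0 || k_i_in < 0) stop("in-degrees must be non-negative")
  n <- n_e + n_i
  with_seed(seed, {
    pre <- vector("list", 2L * n)
    post <- vector("list", 2L * n)
    for (tgt in seq_len(n) - 1L) {
      e_pool <- setdiff(seq_len(n_e) - 1L, tgt)
      i_pool <- setdiff(n_e + seq_len(n_i) - 1L, tgt)
      pe <- if (k_e_in > 0) sample(e_pool, k_e_in) else integer(0)
      pi_ <- if (k_i_in > 0) sample(i_pool, k_i_in) else integer(0)
      pre[[2L * tgt + 1L]] <- pe
      pre[[2L * tgt + 2L]] <- pi_
      post[[2L * tgt + 1L]] <- rep.int(tgt, length(pe))
      post[[2L * tgt + 2L]] <- rep.int(tgt, length(pi_))
    }
    pre <- unlist(pre); post <- unlist(post)
    new_topology(n_e, n_i, split_edge_classes(pre, post, n_e))
  })
}

#' Torus distance
#'
#' Euclidean distance between points on the unit torus `[0,1)^2` with
#' per-axis wraparound (`min(|d|, 1-|d|)` per axis).  The maximal distance
#' is `sqrt(2)/2`.
#'
#' @param a,b numeric length-2 vectors or 2-column matrices of coordinates.
#' @return Numeric distances.
#' @export
#' @examples
#' torus_distance(c(0.9, 0.5), c(0.1, 0.5)) # 0.2
torus_distance <- function(a, b) {
  a <- matrix(a, ncol = 2); b <- matrix(b, ncol = 2)
  d <- abs(a - b)
  d <- pmin(d, 1 - d)
  sqrt(rowSums(d^2))
}

#' Distance-dependent connection probability
#'
#' Gaussian profile `epsilon * exp(-d^2 / (2 sigma^2))`: equals `epsilon`
#' at distance 0 and decays monotonically with distance.
#'
#' @param d distance(s) on the torus.
#' @param profile a [connectivity_profile()].
#' @return Connection probabilities.
#' @export
#' @examples
#' torus_connection_probability(0.1, connectivity_profile(0.2, 0.1))
torus_connection_probability <- function(d, profile) {
  stopifnot(all(d >= 0))
  profile$epsilon * exp(-d^2 / (2 * profile$sigma^2))
}

#' Build a topographic topology on the unit torus
#'
#' Cells are placed on the unit torus (excitatory positions uniform;
#' inhibitory positions uniform or on a regular grid with offset
#' `1/(2 sqrt(n_i))`) and every ordered pair of distinct cells is connected
#' with probability given by the Gaussian profile of the presynaptic cell's
#' class.  The reference parameters are `epsilon = 0.2, sigma = 0.1` for
#' excitatory and `epsilon = 0.8, sigma = 0.05` for inhibitory cells, on a
#' network of 10,000 cells.
#'
#' @inheritParams build_random_topology
#' @param e_profile,i_profile [connectivity_profile()] of the two classes.
#' @param i_placement `"uniform"` or `"grid"` placement of inhibitory cells
#'   (`n_i` must be a perfect square for grid placement).
#' @return A [topology] object with a `positions` data frame (id, u, v).
#' @export
build_torus_topology <- function(n_e, n_i,
                                 e_profile = connectivity_profile(0.2, 0.1),
                                 i_profile = connectivity_profile(0.8, 0.05),
                                 i_placement = c("uniform", "grid"),
                                 seed = NULL) {
  i_placement <- match.arg(i_placement)
  if (i_placement == "grid") {
    side <- round(sqrt(n_i))
    if (side * side != n_i)
      stop("grid placement requires n_i to be a perfect square")
  }
  with_seed(seed, {
    u_e <- runif(n_e); v_e <- runif(n_e)
    if (i_placement == "uniform") {
      u_i <- runif(n_i); v_i <- runif(n_i)
    } else {
      side <- round(sqrt(n_i))
      g <- (seq_len(side) - 1) / side + 1 / (2 * side)
      u_i <- rep(g, each = side); v_i <- rep(g, times = side)
    }
    u <- c(u_e, u_i); v <- c(v_e, v_i)
    ed <- cpp_torus_edges(u, v, n_e, e_profile$epsilon, e_profile$sigma,
                          i_profile$epsilon, i_profile$sigma)
    topo <- new_topology(n_e, n_i, split_edge_classes(ed$pre, ed$post, n_e),
                         positions = data.frame(id = seq_len(n_e + n_i) - 1L,
                                                u = u, v = v))
    topo
  })
}

#' Initialize synaptic weights
#'
#' Sets all weights of a topology according to a scheme: `constant` (the
#' reference initial condition, all weights 1), `gaussian`, or `uniform`.
#' Weights are clipped to `[0, w_max]` of their class (excitatory classes
#' E-E/E-I use `w_e_max`, inhibitory classes I-E/I-I use `w_i_max`).
#'
#' @param topology a [topology] object.
#' @param scheme `"constant"`, `"gaussian"` or `"uniform"`.
#' @param value constant value (constant scheme).
#' @param mean,sd Gaussian parameters.
#' @param min,max uniform bounds.
#' @param synapse a [synapse_params()] record supplying the class maxima.
#' @param seed integer seed.
#' @return The topology with new weights.
#' @export
init_weights <- function(topology, scheme = c("constant", "gaussian", "uniform"),
                         value = 1, mean = 1, sd = 0, min = 0, max = 2,
                         synapse = synapse_params(), seed = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(topology, "topology"))
  if (scheme == "gaussian" && sd < 0) stop("gaussian sd must be >= 0")
  with_seed(seed, {
    for (cl in CLASSES) {
      n <- nrow(topology$edges[[cl]])
      w <- switch(scheme,
                  constant = rep(value, n),
                  gaussian = rnorm(n, mean, sd),
                  uniform = runif(n, min, max))
      cap <- if (cl %in% c("ee", "ei")) synapse$w_e_max else synapse$w_i_max
      topology$edges[[cl]]$w <- pmin(pmax(w, 0), cap)
    }
    topology
  })
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Prune inhibitory inputs of selected cells
#'
#' Removes, for every target cell, `round(fraction * k)` of its `k`
#' incoming inhibitory (I-E) synapses, chosen uniformly at random
#' (rounding half away from zero).  All other edges are untouched.
#'
#' @param topology a [topology] object.
#' @param target_ids 0-based excitatory ids.
#' @param fraction fraction of incoming inhibitory synapses to remove.
#' @param seed integer seed.
#' @return The pruned topology.
#' @export
prune_inhibitory_inputs <- function(topology, target_ids, fraction,
                                    seed = NULL) {
  stopifnot(inherits(topology, "topology"), fraction >= 0, fraction <= 1)
  target_ids <- as.integer(target_ids)
  if (any(target_ids < 0 | target_ids >= topology$n_e))
    stop("target_ids must be excitatory cell ids")
  with_seed(seed, {
    ie <- topology$edges$ie
    drop <- logical(nrow(ie))
    for (tgt in target_ids) {
      idx <- which(ie$post == tgt)
      n_rm <- round_half_away(fraction * length(idx))
      if (n_rm > 0) drop[sample(idx, n_rm)] <- TRUE
    }
    topology$edges$ie <- ie[!drop, , drop = FALSE]
    rownames(topology$edges$ie) <- NULL
    topology
  })
}

#' Expected number of connections inside a random subgroup
#'
#' For `n` cells sampled from an Erdos-Renyi network with connection
#' probability `p`, the expected number of directed edges inside the group
#' is `n (n-1) p` (7.6 for a 20-cell group at `p = 0.02`).
#'
#' @param n subgroup size.
#' @param p connection probability.
#' @return Expected directed edge count.
#' @export
#' @examples
#' expected_subgroup_connections(20, 0.02) # 7.6
expected_subgroup_connections <- function(n, p) {
  stopifnot(n >= 0, p >= 0, p <= 1)
  n * (n - 1) * p
}

#' In- and out-degrees per connection class
#'
#' @param topology a [topology] object.
#' @param class one of `"ee"`, `"ei"`, `"ie"`, `"ii"`.
#' @return Integer vector of degrees indexed by 0-based target (source) id
#'   of the class's postsynaptic (presynaptic) population.
#' @export
in_degrees <- function(topology, class = "ee") {
  e <- topology$edges[[match.arg(class, CLASSES)]]
  post_pop <- if (class %in% c("ee", "ie")) seq_len(topology$n_e) - 1L
              else topology$n_e + seq_len(topology$n_i) - 1L
  tabulate(match(e$post, post_pop), length(post_pop))
}

#' @rdname in_degrees
#' @export
out_degrees <- function(topology, class = "ee") {
  e <- topology$edges[[match.arg(class, CLASSES)]]
  pre_pop <- if (class %in% c("ee", "ei")) seq_len(topology$n_e) - 1L
             else topology$n_e + seq_len(topology$n_i) - 1L
  tabulate(match(e$pre, pre_pop), length(pre_pop))
}

# flatten the four classes into single edge arrays for the C++ engine
flatten_edges <- function(topology) {
  pre <- integer(0); post <- integer(0); w <- numeric(0)
  for (cl in CLASSES) {
    e <- topology$edges[[cl]]
    pre <- c(pre, e$pre); post <- c(post, e$post); w <- c(w, e$w)
  }
  list(pre = pre, post = post, w = w,
       class_sizes = vapply(topology$edges, nrow, integer(1)))
}

# write flattened weights back into the per-class data frames
unflatten_weights <- function(topology, w) {
  at <- 0L
  for (cl in CLASSES) {
    n <- nrow(topology$edges[[cl]])
    if (n > 0) topology$edges[[cl]]$w <- w[at + seq_len(n)]
    at <- at + n
  }
  topology
}
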