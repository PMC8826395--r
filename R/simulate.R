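#' Species-tree specification for family simulation
#'
#' @param tree Rooted ultrametric `phylo` tree with branch lengths in My
#'   (tips at age 0).
#' @param rate Substitution rate in expected substitutions/site/My; a scalar,
#'   or a vector of per-edge rates in `tree$edge` order.
#' @return Object of class `species_tree_spec` with precomputed node ages.
#' @export
species_tree_spec <- function(tree, rate) {
  if (!inherits(tree, "phylo")) stop("tree must be a phylo object")
  if (is.null(tree$edge.length)) stop("tree needs branch lengths (My)")
  if (any(rate <= 0)) stop("rates must be positive")
  nedge <- nrow(tree$edge)
  if (!length(rate) %in% c(1L, nedge))
    stop("rate must be scalar or one per edge")
  ages <- node_ages_from_edges(tree)
  tips <- seq_len(length(tree$tip.label))
  if (max(abs(ages[tips])) > 1e-8 * max(ages))
    stop("tree must be ultrametric (all tips at age 0)")
  ages[tips] <- 0
  structure(list(tree = tree, rate = rep(rate, length.out = nedge),
                 ages = ages), class = "species_tree_spec")
}

node_ages_from_edges <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  n <- ntip + tree$Nnode
  depth <- numeric(n) # time below root
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (i in seq_len(nrow(ord$edge)))
    depth[ord$edge[i, 2]] <- depth[ord$edge[i, 1]] + ord$edge.length[i]
  max(depth[seq_len(ntip)]) - depth
}

#' Transfer scenario for family simulation
#'
#' `mode = "vertical"` simulates pure vertical descent. For `"hgt"` and
#' `"egt"`, the recipient lineage's sequence is replaced at `time_ma` by the
#' donor lineage's sequence at that same time, and evolves onward in the
#' recipient; EGT is the same mechanism with the transfer placed at the
#' recipient clade's stem. Donor and recipient lineages are named by a tip
#' label (the branch above that tip's path at `time_ma`) or a vector of tip
#' labels (the branch above their MRCA); `time_ma` must fall within both
#' branches' durations.
#'
#' @param mode `"vertical"`, `"hgt"` or `"egt"`.
#' @param donor,recipient Tip label(s) identifying the donor and recipient
#'   branches (required unless vertical).
#' @param time_ma Transfer time in Ma.
#' @return Object of class `transfer_scenario`.
#' @export
scenario <- function(mode = c("vertical", "hgt", "egt"), donor = NULL,
                     recipient = NULL, time_ma = NULL) {
  mode <- match.arg(mode)
  if (mode != "vertical") {
    if (is.null(donor) || is.null(recipient) || is.null(time_ma))
      stop("hgt/egt scenarios need donor, recipient and time_ma")
  }
  structure(list(mode = mode, donor = donor, recipient = recipient,
                 time_ma = time_ma), class = "transfer_scenario")
}

# Evolve integer-coded amino acids (1..20) along a branch under the 20-state
# Poisson (equal-exchangeability) model: substitution events arrive at rate
# `rate` per site per My and each event moves to one of the 19 other states
# uniformly. Vectorized in rounds over sites with remaining events.
evolve_poisson <- function(states, rate, t_my) {
  if (rate * t_my <= 0) return(states)
  n_events <- rpois(length(states), rate * t_my)
  while (any(n_events > 0L)) {
    hot <- which(n_events > 0L)
    u <- sample.int(19L, length(hot), replace = TRUE)
    states[hot] <- u + (u >= states[hot])
    n_events[hot] <- n_events[hot] - 1L
  }
  states
}

lineage_node <- function(tree, taxa) {
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing))
    stop("unknown taxa: ", paste(missing, collapse = ", "))
  if (length(taxa) == 1L) match(taxa, tree$tip.label)
  else ape::getMRCA(tree, taxa)
}

#' Simulate a protein family along a species tree
#'
#' Draws a root sequence uniformly over the 20 amino acids and evolves it
#' along the tree under the 20-state Poisson substitution model (no indels,
#' fixed length). Under an HGT/EGT scenario the recipient branch's descendant
#' inherits the donor lineage's sequence at the transfer time instead of its
#' own ancestor's. Fully deterministic per seed.
#'
#' @param spec A [species_tree_spec()].
#' @param scen A [scenario()].
#' @param length Sequence length in residues (>= 50).
#' @param seed Random seed.
#' @return Object of class `family_sim`: `sequences` (named character, tips),
#'   `truth` (scenario, rate, root sequence, seed).
#' @export
simulate_family <- function(spec, scen = scenario("vertical"), length = 300L,
                            seed = 1L) {
  stopifnot(inherits(spec, "species_tree_spec"),
            inherits(scen, "transfer_scenario"))
  if (length < 50L) stop("length must be >= 50")
  tree <- spec$tree
  ages <- spec$ages
  ntip <- base::length(tree$tip.label)
  root <- ntip + 1L
  edge <- tree$edge
  rates <- spec$rate
  transfer <- NULL
  if (scen$mode != "vertical") {
    dnode <- lineage_node(tree, scen$donor)
    rnode <- lineage_node(tree, scen$recipient)
    dedge <- which(edge[, 2] == dnode)
    redge <- which(edge[, 2] == rnode)
    if (!base::length(dedge) || !base::length(redge))
      stop("donor/recipient lineage cannot be the root")
    t <- scen$time_ma
    span_ok <- function(e) ages[edge[e, 1]] >= t && t >= ages[edge[e, 2]]
    if (!span_ok(dedge) || !span_ok(redge))
      stop("transfer time ", t, " Ma lies outside a lineage's branch span")
    if (dedge == redge) stop("donor and recipient lineages are identical")
    transfer <- list(dedge = dedge, redge = redge, t = t)
  }
  set.seed(seed)
  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[root]] <- sample.int(20L, length, replace = TRUE)
  donor_seq_t <- NULL
  ord <- ape::reorder.phylo(tree, "cladewise")
  # map reordered edges back to original edge indices for rate lookup
  eidx <- match(paste(ord$edge[, 1], ord$edge[, 2]),
                paste(edge[, 1], edge[, 2]))
  # first pass: vertical evolution everywhere, splitting the donor edge at
  # the transfer time so the donor's own descendant stays consistent
  for (i in seq_len(nrow(ord$edge))) {
    e <- eidx[i]
    p <- edge[e, 1]; ch <- edge[e, 2]
    r <- rates[e]
    if (!is.null(transfer) && e == transfer$dedge) {
      mid <- evolve_poisson(seqs[[p]], r, ages[p] - transfer$t)
      donor_seq_t <- mid
      seqs[[ch]] <- evolve_poisson(mid, r, transfer$t - ages[ch])
    } else {
      seqs[[ch]] <- evolve_poisson(seqs[[p]], r, ages[p] - ages[ch])
    }
  }
  # second pass: replace the recipient subtree from the transferred sequence
  if (!is.null(transfer)) {
    e <- transfer$redge
    ch <- edge[e, 2]
    seqs[[ch]] <- evolve_poisson(donor_seq_t, rates[e],
                                 transfer$t - ages[ch])
    # re-evolve everything below the recipient node
    below <- which(eidx %in% which_below(edge, ch))
    for (i in sort(below)) {
      e2 <- eidx[i]
      p <- edge[e2, 1]; c2 <- edge[e2, 2]
      seqs[[c2]] <- evolve_poisson(seqs[[p]], rates[e2], ages[p] - ages[c2])
    }
  }
  tip_seqs <- vapply(seq_len(ntip), function(i)
    paste(AA20[seqs[[i]]], collapse = ""), "")
  names(tip_seqs) <- tree$tip.label
  structure(list(sequences = tip_seqs,
                 truth = list(scenario = scen, rate = rates,
                              root_sequence = paste(AA20[seqs[[root]]],
                                                    collapse = ""),
                              seed = seed)),
            class = "family_sim")
}

# indices of edges strictly below node (edges whose parent is node or deeper)
which_below <- function(edge, node) {
  out <- integer(0)
  frontier <- node
  while (length(frontier)) {
    es <- which(edge[, 1] %in% frontier)
    out <- c(out, es)
    frontier <- edge[es, 2]
  }
  out
}

#' Simulate a genome with an inserted compositional island
#'
#' Draws an i.i.d. host sequence from `host_freqs` and inserts an island
#' drawn from `island_freqs` at `position`, emulating a horizontally
#' transferred or misattributed segment of distinct base composition. Truth
#' coordinates are 0-based half-open.
#'
#' @param host_len Host length in bp.
#' @param host_freqs Base frequencies (A, C, G, T), summing to 1.
#' @param island_len Island length in bp (0 for no island).
#' @param island_freqs Island base frequencies.
#' @param position 0-based insertion offset into the host (0..host_len).
#' @param seed Random seed.
#' @return Object of class `genome_sim`: `genome` (string), `island`
#'   (`c(start, end)` 0-based half-open, or `NULL`), `seed`.
#' @export
simulate_genome_with_island <- function(host_len, host_freqs = rep(0.25, 4),
                                        island_len = 0L,
                                        island_freqs = rep(0.25, 4),
                                        position = host_len %/% 2L,
                                        seed = 1L) {
  check_freqs <- function(f, what) {
    if (length(f) != 4L || any(f < 0) || abs(sum(f) - 1) > 1e-8)
      stop(what, " must be 4 non-negative frequencies summing to 1")
  }
  check_freqs(host_freqs, "host_freqs")
  check_freqs(island_freqs, "island_freqs")
  if (position < 0 || position > host_len)
    stop("position must lie in [0, host_len]")
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  host <- sample(bases, host_len, replace = TRUE, prob = host_freqs)
  if (island_len > 0) {
    island <- sample(bases, island_len, replace = TRUE, prob = island_freqs)
    genome <- paste(c(host[seq_len(position)], island,
                      host[seq_len(host_len - position) + position]),
                    collapse = "")
    coords <- c(start = position, end = position + island_len)
  } else {
    genome <- paste(host, collapse = "")
    coords <- NULL
  }
  structure(list(genome = genome, island = coords, seed = seed),
            class = "genome_sim")
}

#' Simulate a clock-like tree with noisy branch lengths
#'
#' Generates a random coalescent-style ultrametric topology scaled to
#' `root_age`, records the true node ages, and sets each branch length to
#' `rate * duration * (1 + N(0, noise_sd))`, truncated at 0. Feeds the
#' strict-clock recovery tests.
#'
#' @param n_taxa Number of tips (>= 3).
#' @param root_age True root age in Ma.
#' @param rate True substitution rate (substitutions/site/My).
#' @param noise_sd Relative noise standard deviation (0 = exactly clock-like).
#' @param seed Random seed.
#' @return List: `tree` (phylo, branch lengths in substitutions/site),
#'   `true_ages` (per node, Ma), `root_age`, `rate`, `seed`.
#' @export
simulate_clocklike_tree <- function(n_taxa, root_age = 900, rate = 1e-3,
                                    noise_sd = 0, seed = 1L) {
  if (n_taxa < 3L) stop("need at least 3 taxa")
  set.seed(seed)
  tr <- ape::rcoal(n_taxa, tip.label = paste0("t", seq_len(n_taxa)))
  ages <- node_ages_from_edges(tr)
  ages <- ages * root_age / max(ages)
  ages[seq_len(n_taxa)] <- 0
  dur <- ages[tr$edge[, 1]] - ages[tr$edge[, 2]]
  noise <- if (noise_sd > 0) rnorm(length(dur), 0, noise_sd) else 0
  tr$edge.length <- pmax(rate * dur * (1 + noise), 0)
  list(tree = tr, true_ages = ages, root_age = root_age, rate = rate,
       seed = seed)
}

#' Three-taxon species tree for AGD simulations
#'
#' Convenience constructor for the reference/bridge/distal layout behind the
#' AGD statistic: topology `((reference, bridge), distal)` with the
#' reference-bridge split at `split_age` and the distal lineage diverging at
#' `root_age`, in My.
#'
#' @param root_age Age of the root (distal divergence), Ma.
#' @param split_age Age of the reference-bridge split, Ma.
#' @param rate Substitution rate (substitutions/site/My).
#' @return A [species_tree_spec()] with tips `reference`, `bridge`, `distal`.
#' @export
agd_species_tree <- function(root_age = 2700, split_age = 700, rate = 2.2e-4) {
  nwk <- sprintf("((reference:%f,bridge:%f):%f,distal:%f);",
                 split_age, split_age, root_age - split_age, root_age)
  species_tree_spec(ape::read.tree(text = nwk), rate)
}
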