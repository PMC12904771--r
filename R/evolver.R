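# Protein divergence simulator: LG substitutions with gamma rate
# heterogeneity and invariant sites, plus an overlaid insertion/deletion
# process, applied along a rooted tree with branch lengths in expected
# substitutions per site.

#' Simulation parameter set
#'
#' @param alpha Gamma shape for among-site rate variation (> 0). The rate
#'   distribution has mean 1, so small alpha is L-shaped: most sites slow,
#'   few fast.
#' @param p_inv Proportion of invariant (rate 0) sites, in `[0, 1]`.
#' @param ins_rate Insertions per site per unit branch length (>= 0).
#' @param del_rate Deletions per site per unit branch length (>= 0).
#' @param indel_len_mean Expected indel length (geometric law, >= 1).
#' @param seed Optional integer seed; fixing it makes [evolve_tree]
#'   byte-reproducible.
#' @return A list of class `evolution_params`.
#' @export
evolution_params <- function(alpha = 0.5, p_inv = 0, ins_rate = 0,
                             del_rate = 0, indel_len_mean = 3, seed = NULL) {
  stopifnot(alpha > 0, p_inv >= 0, p_inv <= 1, ins_rate >= 0, del_rate >= 0,
            indel_len_mean >= 1)
  structure(list(alpha = alpha, p_inv = p_inv, ins_rate = ins_rate,
                 del_rate = del_rate, indel_len_mean = indel_len_mean,
                 substitution_model = "LG", seed = seed),
            class = "evolution_params")
}

#' Draw per-site relative rates
#'
#' Each site is invariant (rate 0) with probability `p_inv`, otherwise its
#' rate is a continuous Gamma(shape = alpha, mean = 1) draw. Rates are drawn
#' once at the root and inherited down the tree; sites created by insertion
#' get fresh draws from the same law.
#'
#' @param n_sites Number of sites (>= 1).
#' @param alpha Gamma shape (> 0).
#' @param p_inv Proportion of invariant sites.
#' @return Numeric vector of length `n_sites`.
#' @export
draw_site_rates <- function(n_sites, alpha, p_inv = 0) {
  stopifnot(n_sites >= 1)
  if (alpha <= 0) stop("alpha must be > 0")
  rates <- stats::rgamma(n_sites, shape = alpha, rate = alpha)
  if (p_inv > 0) rates[stats::runif(n_sites) < p_inv] <- 0
  rates
}

# internal integer coding: 1..20 canonical (LG order), 21 = X (held fixed)
seq_to_int <- function(sequence) {
  codes <- match(strsplit(sequence, "", fixed = TRUE)[[1L]],
                 c(AA_ALPHABET_LG, "X"))
  if (anyNA(codes)) stop("sequence contains non-amino-acid characters")
  codes
}

int_to_seq <- function(codes) {
  paste(c(AA_ALPHABET_LG, "X")[codes], collapse = "")
}

#' Evolve a sequence along one branch
#'
#' Substitutions are applied exactly under the model: site `i` is replaced by
#' a draw from row `seq[i]` of the LG transition matrix at distance
#' `rates[i] * t` (one matrix-exponential transition per branch, not event
#' simulation). Indel event counts are Poisson in the branch-start length,
#' applied in random order at uniform positions with geometric lengths;
#' inserted residues come from the LG equilibrium and receive fresh rates.
#' The sequence never shrinks below length 1. Consumes the current RNG
#' stream.
#'
#' @param codes Integer-coded sequence (see details; `X` sites are held
#'   fixed).
#' @param rates Per-site rates aligned to `codes`.
#' @param t Branch length (>= 0).
#' @param params An [evolution_params] object.
#' @return List with elements `codes`, `rates`, and realized event counts
#'   `n_sub`, `n_ins`, `n_del`.
#' @export
evolve_branch <- function(codes, rates, t, params) {
  n <- length(codes)
  if (n == 0L) stop("empty sequence")
  stopifnot(length(rates) == n, t >= 0)
  n_sub <- 0L
  if (t > 0) {
    live <- which(codes <= 20L & rates > 0)
    if (length(live)) {
      p <- lg_transition_rows(codes[live], rates[live] * t)
      cs <- matrixStats::rowCumsums(p)
      u <- stats::runif(length(live))
      new <- rowSums(cs < u) + 1L
      new[new > 20L] <- 20L
      codes[live] <- new
      # diagnostic: realized substitution events are Poisson in rate * t
      n_sub <- sum(stats::rpois(length(live), rates[live] * t))
    }
  }
  n_ins <- 0L; n_del <- 0L
  if (t > 0 && (params$ins_rate > 0 || params$del_rate > 0)) {
    L0 <- length(codes)
    n_ins <- stats::rpois(1L, params$ins_rate * L0 * t)
    n_del <- stats::rpois(1L, params$del_rate * L0 * t)
    events <- sample(rep(c("I", "D"), c(n_ins, n_del)))
    pgeo <- 1 / params$indel_len_mean
    pi <- lg_frequencies()
    for (ev in events) {
      L <- length(codes)
      len <- 1L + stats::rgeom(1L, pgeo)
      if (ev == "I") {
        at <- sample.int(L + 1L, 1L) - 1L  # insert after position `at`
        ins <- sample.int(20L, len, replace = TRUE, prob = pi)
        ins_rates <- draw_site_rates(len, params$alpha, params$p_inv)
        codes <- append(codes, ins, after = at)
        rates <- append(rates, ins_rates, after = at)
      } else {
        if (L <= 1L) next
        at <- sample.int(L, 1L)
        len <- min(len, L - at + 1L, L - 1L)
        if (len < 1L) next
        keep <- setdiff(seq_len(L), at:(at + len - 1L))
        codes <- codes[keep]
        rates <- rates[keep]
      }
    }
  }
  list(codes = codes, rates = rates, n_sub = n_sub,
       n_ins = as.integer(n_ins), n_del = as.integer(n_del))
}

#' Simulate a protein family along a tree
#'
#' Pre-order traversal from the root, applying [evolve_branch] on every edge.
#' Site rates are drawn once at the root and inherited at internal nodes
#' (inserted sites draw fresh rates). With `ins_rate = del_rate = 0` every
#' descendant has exactly the root length.
#'
#' @param root A single-row [protein_records] entry (or list with `id`,
#'   `sequence`).
#' @param tree An `ape::phylo` tree with branch lengths.
#' @param params An [evolution_params] object. If `params$seed` is set, the
#'   simulation is reproducible.
#' @return A list of class `simulated_family`: `root`, `descendants` (a
#'   [protein_records] frame, one row per terminal, ids `<rootid>_<taxon>`),
#'   `params`, and `events` (per-taxon realized substitution/indel counts).
#' @export
evolve_tree <- function(root, tree, params) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  if (!is.null(params$seed)) set.seed(params$seed)
  codes <- seq_to_int(root$sequence[1L])
  rates <- draw_site_rates(length(codes), params$alpha, params$p_inv)

  ntip <- length(tree$tip.label)
  root_node <- ntip + 1L
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])

  out_seq <- character(ntip)
  events <- data.frame(taxon_label = tree$tip.label, n_sub = 0L,
                       n_ins = 0L, n_del = 0L, path_length = 0,
                       stringsAsFactors = FALSE)

  walk <- function(node, codes, rates, acc) {
    for (e in kids[[as.character(node)]]) {
      child <- tree$edge[e, 2L]
      st <- evolve_branch(codes, rates, tree$edge.length[e], params)
      acc2 <- list(n_sub = acc$n_sub + st$n_sub, n_ins = acc$n_ins + st$n_ins,
                   n_del = acc$n_del + st$n_del,
                   path = acc$path + tree$edge.length[e])
      if (child <= ntip) {
        out_seq[child] <<- int_to_seq(st$codes)
        events[child, c("n_sub", "n_ins", "n_del")] <<-
          c(acc2$n_sub, acc2$n_ins, acc2$n_del)
        events$path_length[child] <<- acc2$path
      } else {
        walk(child, st$codes, st$rates, acc2)
      }
    }
  }
  walk(root_node, codes, rates, list(n_sub = 0L, n_ins = 0L, n_del = 0L, path = 0))

  desc <- protein_records(paste0(root$id[1L], "_", tree$tip.label), out_seq,
                          provenance = "simulated", taxon_label = tree$tip.label)
  structure(list(root = root, descendants = desc, params = params,
                 events = events),
            class = "simulated_family")
}
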