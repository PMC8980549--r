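#' Simulation configuration for founder descent
#'
#' Describes a forward simulation of a founder haplotype transmitted `g`
#' generations under per-meiosis recombination (Haldane, no interference) at
#' the map's cM/Mb rate and per-site marker mutation at rate `mu`, against a
#' background pool of haplotypes with given frequencies, plus a control
#' population of random-mating diplotypes drawn from the same pool.
#'
#' @param map a [marker_map()].
#' @param founder character vector of founder alleles, one per marker.
#' @param pool character matrix of background haplotypes (rows) x markers.
#' @param pool_freqs frequencies of the pool haplotypes (sum to 1).
#' @param g generations of descent (`>= 0`).
#' @param n_chromosomes sampled carrier chromosomes.
#' @param n_controls control diplotypes.
#' @param mu per-site per-generation mutation rate.
#' @param seed mandatory integer seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(map, founder, pool, pool_freqs, g, n_chromosomes,
                       n_controls = 0, mu = 1e-8, seed) {
  if (missing(seed) || !is.numeric(seed)) stop("an integer seed is mandatory")
  pool <- as.matrix(pool)
  stopifnot(length(founder) == nrow(map), ncol(pool) == nrow(map),
            length(pool_freqs) == nrow(pool),
            abs(sum(pool_freqs) - 1) < 1e-9, all(pool_freqs >= 0),
            g >= 0, n_chromosomes >= 1, mu >= 0)
  structure(list(map = map, founder = founder, pool = pool,
                 pool_freqs = pool_freqs, g = as.integer(g),
                 n_chromosomes = as.integer(n_chromosomes),
                 n_controls = as.integer(n_controls),
                 mu = mu, seed = as.integer(seed)),
            class = "sim_config")
}

draw_pool <- function(config, n) {
  idx <- sample.int(nrow(config$pool), n, replace = TRUE,
                    prob = config$pool_freqs)
  config$pool[idx, , drop = FALSE]
}

#' Forward simulation of carrier chromosomes descending from a founder
#'
#' Each sampled chromosome starts as the founder haplotype. Over `g`
#' generations, recombination events fall as a Poisson process on the
#' genetic map (Haldane model), so the distance from the focal site to the
#' nearest breakpoint on each side is Exponential(`g`) in Morgans; material
#' beyond that breakpoint is replaced by an independent draw from the
#' background pool (only the breakpoint nearest the focal site matters for
#' the retained ancestral segment, so only it is tracked). Each marker of
#' the retained ancestral segment (the focal site excepted — carriers are
#' ascertained on the risk allele) mutates with probability
#' `1 - (1 - mu)^g`, moving to one of the three other bases uniformly.
#'
#' @param config a [sim_config()].
#' @return List with `carriers` (a [carrier_matrix()]) and `truth` (class
#'   `sim_truth`): per-chromosome one-sided breakpoint distances in Morgans
#'   (`Inf` when no recombination occurred), censored-at-map flags, mutation
#'   events, and the global `g` and `seed`.
#' @export
simulate_carriers <- function(config) {
  set.seed(config$seed)
  map <- config$map
  fi <- focal_index(map)
  cmmb <- attr(map, "cm_per_mb")
  pos_m <- (map$pos - map$pos[fi]) * cmmb * 1e-8   # signed Morgans from focal
  n <- config$n_chromosomes
  g <- config$g

  L <- if (g > 0) stats::rexp(n, rate = g) else rep(Inf, n)
  R <- if (g > 0) stats::rexp(n, rate = g) else rep(Inf, n)
  p_mut <- 1 - (1 - config$mu)^g

  alleles <- matrix(rep(config$founder, each = n), n, nrow(map))
  mut_events <- list()
  for (i in seq_len(n)) {
    repl_left <- pos_m < -L[i]
    repl_right <- pos_m > R[i]
    if (any(repl_left)) {
      alleles[i, repl_left] <- draw_pool(config, 1)[1, repl_left]
    }
    if (any(repl_right)) {
      alleles[i, repl_right] <- draw_pool(config, 1)[1, repl_right]
    }
    ancestral <- which(!repl_left & !repl_right)
    ancestral <- setdiff(ancestral, fi)
    if (p_mut > 0 && length(ancestral)) {
      hit <- ancestral[stats::runif(length(ancestral)) < p_mut]
      for (j in hit) {
        alleles[i, j] <- sample(setdiff(c("A", "C", "G", "T"), alleles[i, j]), 1)
        mut_events[[length(mut_events) + 1L]] <-
          data.frame(chromosome = i, marker = map$rsid[j],
                     generation = sample.int(max(g, 1L), 1),
                     stringsAsFactors = FALSE)
      }
    }
  }
  rownames(alleles) <- sprintf("SIM%03d-%s", rep(seq_len(ceiling(n / 2)), each = 2,
                                                 length.out = n),
                               rep(c("a", "b"), length.out = n))
  truth <- structure(list(
    g = g, seed = config$seed,
    breakpoints = data.frame(
      chromosome = rownames(alleles),
      left_morgans = L, right_morgans = R,
      left_censored = L > abs(pos_m[1]),
      right_censored = R > pos_m[length(pos_m)],
      stringsAsFactors = FALSE),
    mutations = if (length(mut_events)) do.call(rbind, mut_events) else
      data.frame(chromosome = integer(0), marker = character(0),
                 generation = integer(0))),
    class = "sim_truth")
  list(carriers = carrier_matrix(alleles, map), truth = truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("Simulation truth: g =", x$g, "| seed =", x$seed, "|",
      nrow(x$breakpoints), "chromosomes |", nrow(x$mutations),
      "mutation event(s)\n")
  invisible(x)
}

#' Simulate an unphased control population
#'
#' Draws `2 * n_controls` chromosomes independently from the background pool
#' (random mating, Hardy-Weinberg), pairs them into diplotypes and discards
#' phase.
#'
#' @param config a [sim_config()] with `n_controls > 0`.
#' @return A [genotype_matrix()].
#' @export
simulate_controls <- function(config) {
  stopifnot(config$n_controls > 0)
  set.seed(config$seed + 1L)
  h1 <- draw_pool(config, config$n_controls)
  h2 <- draw_pool(config, config$n_controls)
  rownames(h1) <- rownames(h2) <- sprintf("CTRL%03d", seq_len(config$n_controls))
  genotype_matrix(h1, h2, rsid = config$map$rsid)
}
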