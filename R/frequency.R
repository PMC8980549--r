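#' Unphased control genotype matrix
#'
#' Stores unordered allele pairs for control samples at a set of markers.
#'
#' @param a1,a2 character matrices (samples x markers) of the two alleles of
#'   each genotype; the order carries no phase information. `NA` for missing.
#' @param rsid marker identifiers (column names).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(a1, a2, rsid = colnames(a1)) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  if (!identical(dim(a1), dim(a2))) stop("a1 and a2 dimensions differ")
  ok <- function(m) all(m %in% c("A", "C", "G", "T") | is.na(m))
  if (!ok(a1) || !ok(a2)) stop("alleles must be A, C, G, T or NA")
  if ((anyNA(a1) || anyNA(a2)) && !all(is.na(a1) == is.na(a2))) {
    # half-missing genotypes are treated as fully missing
    miss <- is.na(a1) | is.na(a2)
    a1[miss] <- NA_character_; a2[miss] <- NA_character_
  }
  if (!is.null(rsid)) colnames(a1) <- colnames(a2) <- rsid
  structure(list(a1 = a1, a2 = a2), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("Genotype matrix:", nrow(x$a1), "samples x", ncol(x$a1), "markers;",
      sum(is.na(x$a1)), "missing genotypes\n")
  invisible(x)
}

# column indices for a marker selection (indices or rsids); NULL = all
resolve_markers <- function(geno, markers) {
  if (is.null(markers)) return(seq_len(ncol(geno$a1)))
  if (is.character(markers)) {
    idx <- match(markers, colnames(geno$a1))
    if (anyNA(idx)) stop("unknown marker(s): ",
                         paste(markers[is.na(idx)], collapse = ", "))
    idx
  } else as.integer(markers)
}

# All phase resolutions of one sample at the chosen markers: a list of
# unordered haplotype pairs (2-element character vectors of concatenated
# alleles). Missing markers range over `alphabet[[j]]`.
phase_resolutions <- function(g1, g2, alphabet) {
  m <- length(g1)
  opts <- vector("list", m)   # per marker: 2-column matrix of ordered pairs
  for (j in seq_len(m)) {
    if (is.na(g1[j])) {
      ab <- alphabet[[j]]
      grid <- expand.grid(a = ab, b = ab, stringsAsFactors = FALSE)
      # unordered genotype: keep a <= b, but both orientations as phases
      grid <- grid[grid$a <= grid$b, , drop = FALSE]
      pairs <- unique(rbind(as.matrix(grid), as.matrix(grid)[, 2:1, drop = FALSE]))
    } else if (g1[j] == g2[j]) {
      pairs <- matrix(c(g1[j], g2[j]), 1)
    } else {
      pairs <- matrix(c(g1[j], g2[j], g2[j], g1[j]), 2, byrow = TRUE)
    }
    opts[[j]] <- pairs
  }
  n_comb <- prod(vapply(opts, nrow, integer(1)))
  if (n_comb > 4096) stop("too many phase resolutions (", n_comb,
                          ") for one sample; reduce the marker set")
  idx <- do.call(expand.grid, lapply(opts, function(p) seq_len(nrow(p))))
  res <- vector("list", nrow(idx))
  for (r in seq_len(nrow(idx))) {
    h1 <- paste(vapply(seq_len(m), function(j) opts[[j]][idx[r, j], 1],
                       character(1)), collapse = "")
    h2 <- paste(vapply(seq_len(m), function(j) opts[[j]][idx[r, j], 2],
                       character(1)), collapse = "")
    res[[r]] <- sort(c(h1, h2))
  }
  unique(res)
}

# shared setup for both frequency estimators
frequency_setup <- function(geno, markers) {
  idx <- resolve_markers(geno, markers)
  g1 <- geno$a1[, idx, drop = FALSE]
  g2 <- geno$a2[, idx, drop = FALSE]
  complete <- rowSums(is.na(g1)) == 0
  if (!any(complete)) stop("no sample with complete genotypes at the chosen markers")
  alphabet <- lapply(seq_along(idx), function(j) {
    a <- unique(c(g1[, j], g2[, j])); sort(a[!is.na(a)])
  })
  res <- lapply(seq_len(nrow(g1)),
                function(i) phase_resolutions(g1[i, ], g2[i, ], alphabet))
  haps <- sort(unique(unlist(res)))
  list(resolutions = res, haplotypes = haps, n = nrow(g1),
       rsid = colnames(geno$a1)[idx])
}

freq_estimate <- function(freq, method, loglik = NA_real_, n_iter = NA_integer_,
                          converged = NA, rsid = NULL) {
  structure(list(frequencies = freq, all_frequencies = freq, method = method,
                 loglik = loglik, n_iter = n_iter, converged = converged,
                 markers = rsid),
            class = "freq_estimate")
}

#' @export
print.freq_estimate <- function(x, ...) {
  cat("Haplotype frequencies (", x$method, ") over markers: ",
      paste(x$markers, collapse = ","), "\n", sep = "")
  f <- x$frequencies
  print(round(sort(f[f > 1e-9], decreasing = TRUE), 5))
  if (!is.na(x$loglik)) cat("log-likelihood:", x$loglik,
                            "| iterations:", x$n_iter,
                            "| converged:", x$converged, "\n")
  invisible(x)
}

#' Multilocus haplotype frequencies by expectation-maximization
#'
#' Standard gene-counting EM over unphased genotypes: the E-step distributes
#' each ambiguous multi-heterozygote over its compatible phase resolutions in
#' proportion to the product of current haplotype frequencies; the M-step
#' re-estimates frequencies from expected counts. Missing genotypes are
#' marginalised by enumerating alleles observed at the marker, weighted by
#' the current frequencies. Initialisation is uniform over the compatible
#' haplotype set; optional seeded random restarts can be used to probe
#' multimodality (the best log-likelihood is kept).
#'
#' @param geno a [genotype_matrix()].
#' @param markers marker rsids or column indices (default: all).
#' @param tol convergence tolerance on the maximum absolute frequency change.
#' @param max_iter iteration cap.
#' @param restarts number of additional random (Dirichlet) initialisations.
#' @param seed integer seed, used only when `restarts > 0`.
#' @return An object of class `freq_estimate` with elements `frequencies`
#'   (named, sums to 1), `loglik`, `n_iter`, `converged`.
#' @export
em_frequencies <- function(geno, markers = NULL, tol = 1e-8, max_iter = 1e4,
                           restarts = 0, seed = NULL) {
  setup <- frequency_setup(geno, markers)
  haps <- setup$haplotypes
  K <- length(haps)
  # per sample: matrix of haplotype-index pairs (unordered)
  pair_idx <- lapply(setup$resolutions, function(r) {
    t(vapply(r, function(p) match(p, haps), integer(2)))
  })

  run_em <- function(f) {
    ll_prev <- -Inf
    for (it in seq_len(max_iter)) {
      counts <- numeric(K)
      ll <- 0
      for (i in seq_along(pair_idx)) {
        pi <- pair_idx[[i]]
        w <- f[pi[, 1]] * f[pi[, 2]] * ifelse(pi[, 1] == pi[, 2], 1, 2)
        tw <- sum(w)
        if (tw <= 0) { w <- rep(1 / nrow(pi), nrow(pi)); tw <- 1e-300 }
        else w <- w / tw
        ll <- ll + log(tw)
        for (r in seq_len(nrow(pi))) {
          counts[pi[r, 1]] <- counts[pi[r, 1]] + w[r]
          counts[pi[r, 2]] <- counts[pi[r, 2]] + w[r]
        }
      }
      if (ll < ll_prev - 1e-9) stop("EM log-likelihood decreased; internal error")
      f_new <- counts / (2 * setup$n)
      delta <- max(abs(f_new - f))
      f <- f_new
      ll_prev <- ll
      if (delta < tol) return(list(f = f, loglik = ll, n_iter = it, converged = TRUE))
    }
    warning("EM did not converge in ", max_iter, " iterations")
    list(f = f, loglik = ll_prev, n_iter = max_iter, converged = FALSE)
  }

  starts <- list(rep(1 / K, K))
  if (restarts > 0) {
    if (!is.null(seed)) set.seed(seed)
    for (s in seq_len(restarts)) {
      g <- stats::rgamma(K, 1); starts[[s + 1L]] <- g / sum(g)
    }
  }
  fits <- lapply(starts, run_em)
  best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]]
  freq_estimate(stats::setNames(best$f, haps), "EM", best$loglik,
                best$n_iter, best$converged, setup$rsid)
}

#' Multilocus haplotype frequencies by composite counting (CHM)
#'
#' Single-pass phase-free counting: each sample's compatible phase
#' resolutions receive equal fractional weight and contribute their two
#' haplotypes to the counts; frequencies are counts over total chromosomes.
#' Samples with at most one heterozygous marker are phase-unambiguous and
#' contribute whole counts. This is an equal-weight reimplementation of the
#' composite haplotype idea and is not bit-compatible with proprietary
#' implementations.
#'
#' @inheritParams em_frequencies
#' @return An object of class `freq_estimate` (no log-likelihood).
#' @export
chm_frequencies <- function(geno, markers = NULL) {
  setup <- frequency_setup(geno, markers)
  haps <- setup$haplotypes
  counts <- stats::setNames(numeric(length(haps)), haps)
  for (r in setup$resolutions) {
    w <- 1 / length(r)
    for (p in r) {
      counts[p[1]] <- counts[p[1]] + w
      counts[p[2]] <- counts[p[2]] + w
    }
  }
  freq_estimate(counts / (2 * setup$n), "CHM", rsid = setup$rsid)
}

#' Founder block-haplotype probability on carrier and control sides
#'
#' Reports (i) `carrier`: the fraction of carrier chromosomes carrying the
#' founder haplotype intact from the focal site through the block (the
#' `P_D` consumed by the age estimators; missing genotypes count as
#' matching), (ii) `local`: the fraction matching the founder over the
#' block's own markers regardless of what happens nearer the mutation, and
#' (iii) `population`: when a control-side frequency estimate is supplied,
#' the probability that a chromosome drawn from the control pool matches
#' the founder across the block markers.
#'
#' @param carriers a [carrier_matrix()].
#' @param founder a [infer_founder()] result.
#' @param block one row of a [partition_blocks()] blocks data frame.
#' @param freqs optional `freq_estimate` over the block's markers.
#' @return List with `carrier`, `local` and `population` (the latter `NA`
#'   without `freqs`).
#' @export
carrier_block_probability <- function(carriers, founder, block, freqs = NULL) {
  core <- founder$core
  idx <- seq(block$from, block$to)
  # markers from the core edge out through the block's outer edge
  through <- if (block$side == "left") seq(block$from, core$from - 1L)
             else if (block$side == "right") seq(core$to + 1L, block$to)
             else idx
  matches <- function(range) {
    fa <- founder$alleles[range]
    vapply(seq_len(nrow(carriers)), function(chr) {
      a <- carriers[chr, range]
      all(is.na(a) | is.na(fa) | a == fa)
    }, logical(1))
  }
  pop <- NA_real_
  if (!is.null(freqs)) {
    fa <- founder$alleles[idx]
    hapstr <- paste(ifelse(is.na(fa), ".", fa), collapse = "")
    hit <- grepl(paste0("^", hapstr, "$"), names(freqs$all_frequencies))
    pop <- sum(freqs$all_frequencies[hit])
  }
  list(carrier = mean(matches(through)), local = mean(matches(idx)),
       population = pop)
}
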