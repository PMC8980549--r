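#' Fully shared autozygous core around the focal site
#'
#' Finds the maximal contiguous run of markers containing the focal site at
#' which all carrier chromosomes carry identical non-missing alleles.
#' Missing genotypes are compatible with any allele.
#'
#' @param carriers a [carrier_matrix()].
#' @param map the matching [marker_map()].
#' @return A list of class `core_interval` with integer `from`, `to`
#'   (marker indices), `n_markers`, and the flanking rsids.
#' @export
find_shared_core <- function(carriers, map) {
  unanimous <- function(j) {
    a <- unique(carriers[, j])
    length(a[!is.na(a)]) <= 1L
  }
  fi <- focal_index(map)
  from <- to <- fi
  while (from > 1L && unanimous(from - 1L)) from <- from - 1L
  while (to < nrow(map) && unanimous(to + 1L)) to <- to + 1L
  structure(list(from = from, to = to, n_markers = to - from + 1L,
                 rsid_from = map$rsid[from], rsid_to = map$rsid[to]),
            class = "core_interval")
}

#' @export
print.core_interval <- function(x, ...) {
  cat("Shared core:", x$n_markers, "markers,", x$rsid_from, "..", x$rsid_to, "\n")
  invisible(x)
}

#' Infer the founder (ancestral) haplotype by outward maximal-sharing extension
#'
#' Within the shared core the founder allele is the allele common to all
#' chromosomes. Outward of the core, one marker at a time on each side, the
#' founder allele is the plurality allele among chromosomes still consistent
#' with the founder on that side ("active"); chromosomes carrying a different
#' non-missing allele become inactive for all farther markers on that side.
#' Plurality ties are broken deterministically in favour of the
#' alphabetically smallest allele and flagged; this keeps the least-recombined
#' carrier lineage intact, which is the behaviour wanted when the founder
#' haplotype is anchored to an observed intact carrier chromosome.
#'
#' @param carriers a [carrier_matrix()].
#' @param map the matching [marker_map()].
#' @param core optionally a precomputed [find_shared_core()] result.
#' @return An object of class `founder_haplotype`: list with `alleles`
#'   (character, `NA` where unresolvable), `support` (active-and-matching
#'   chromosome count per marker), `tie` (logical per marker), and the core.
#' @export
infer_founder <- function(carriers, map, core = NULL) {
  if (is.null(core)) core <- find_shared_core(carriers, map)
  n_mark <- nrow(map)
  n_chr <- nrow(carriers)
  alleles <- rep(NA_character_, n_mark)
  support <- integer(n_mark)
  tie <- logical(n_mark)
  for (j in core$from:core$to) {
    a <- unique(carriers[, j])
    a <- a[!is.na(a)]
    alleles[j] <- if (length(a)) a else NA_character_
    support[j] <- n_chr
  }
  extend <- function(idx) {
    active <- rep(TRUE, n_chr)
    for (j in idx) {
      if (!any(active)) break
      obs <- carriers[active, j]
      tab <- sort(table(obs[!is.na(obs)]), decreasing = TRUE)
      if (!length(tab)) {            # all active missing: founder undetermined
        support[j] <<- sum(active)
        next
      }
      top <- names(tab)[tab == max(tab)]
      if (length(top) > 1L) {
        tie[j] <<- TRUE
        top <- sort(top)
      }
      alleles[j] <<- top[1]
      mismatch <- active & !is.na(carriers[, j]) & carriers[, j] != top[1]
      support[j] <<- sum(active) - sum(mismatch)
      active[mismatch] <- FALSE
    }
  }
  if (core$from > 1L) extend((core$from - 1L):1L)
  if (core$to < n_mark) extend((core$to + 1L):n_mark)
  structure(list(alleles = alleles, support = support, tie = tie, core = core),
            class = "founder_haplotype")
}

#' @export
print.founder_haplotype <- function(x, ...) {
  cat("Founder haplotype over", length(x$alleles), "markers;",
      sum(is.na(x$alleles)), "unresolved;",
      sum(x$tie), "tie-broken marker(s)\n")
  print(x$core)
  invisible(x)
}

# Per-chromosome first-mismatch marker index on each side of the focal site,
# scanning outward; NA when the chromosome never leaves the founder within
# the map (missing and founder-unresolved markers are compatible).
divergence_points <- function(carriers, map, founder) {
  fi <- focal_index(map)
  n_mark <- nrow(map)
  first_mismatch <- function(chr, idx) {
    for (j in idx) {
      a <- carriers[chr, j]
      if (!is.na(a) && !is.na(founder$alleles[j]) && a != founder$alleles[j]) {
        return(j)
      }
    }
    NA_integer_
  }
  left <- right <- rep(NA_integer_, nrow(carriers))
  for (chr in seq_len(nrow(carriers))) {
    if (fi > 1L) left[chr] <- first_mismatch(chr, (fi - 1L):1L)
    if (fi < n_mark) right[chr] <- first_mismatch(chr, (fi + 1L):n_mark)
  }
  data.frame(chromosome = rownames(carriers), left = left, right = right,
             stringsAsFactors = FALSE)
}

# TRUE for chromosomes conserved (founder-matching) from the focal site
# through marker index j on the given side.
conserved_through <- function(div, j, side) {
  if (side == "left") is.na(div$left) | div$left < j
  else                is.na(div$right) | div$right > j
}

#' Partition markers into recombination-free haplotype blocks
#'
#' Scanning outward from the focal site, each marker at which one or more
#' carrier chromosomes first leave the founder haplotype (a divergence
#' marker) delimits a block. A block runs from its divergence marker — its
#' label, the member nearest the focal site — outward to just before the
#' next divergence marker; the central (focal) block is the fully shared
#' core. Two layouts are offered:
#'
#' * `"scan"`: every divergence marker opens a block; all markers are
#'   assigned.
#' * `"published"` (default): the layout convention of the published CLCC1
#'   analysis for the distal arm ends. A divergence that leaves at most two
#'   conserved families and is followed by a further divergence on the same
#'   arm closes the current block at that marker instead of opening a new
#'   one; the divergence that breaks the final conserved family pair opens a
#'   terminal block of exactly two markers (analysed downstream as a paired-
#'   marker system); markers not covered are reported as unassigned tail
#'   markers.
#'
#' @param carriers a [carrier_matrix()].
#' @param map the matching [marker_map()].
#' @param founder a [infer_founder()] result.
#' @param layout `"published"` or `"scan"` (see Details).
#' @return An object of class `block_partition`: list with `blocks` (data
#'   frame: `label`, `from`, `to`, `n_markers`, `side`, `theta`, `n_shared`),
#'   `tail_markers` (rsids left unassigned), and the divergence table.
#' @export
partition_blocks <- function(carriers, map, founder,
                             layout = c("published", "scan")) {
  layout <- match.arg(layout)
  fi <- focal_index(map)
  div <- divergence_points(carriers, map, founder)
  fam <- family_of(rownames(carriers))
  core <- founder$core

  n_families_after <- function(j, side) {
    keep <- conserved_through(div, j, side)
    length(unique(fam[keep]))
  }

  arm_blocks <- function(side) {
    d <- if (side == "left") sort(unique(div$left[!is.na(div$left)]), decreasing = TRUE)
         else sort(unique(div$right[!is.na(div$right)]))
    if (!length(d)) return(NULL)
    outermost <- if (side == "left") 1L else nrow(map)
    step <- if (side == "left") -1L else 1L
    res <- list()
    k <- 1L
    while (k <= length(d)) {
      start <- d[k]
      if (layout == "published" && n_families_after(start, side) < 2L) {
        # this divergence broke the final conserved family pair: emit a
        # two-marker terminal block; anything farther out is tail
        t_end <- start + step
        if (t_end < 1L || t_end > nrow(map)) t_end <- start
        res[[length(res) + 1L]] <- c(start, t_end)
        break
      }
      nxt <- if (k < length(d)) d[k + 1L] else NA_integer_
      if (is.na(nxt)) {
        res[[length(res) + 1L]] <- c(start, outermost)
        break
      }
      if (layout == "published" && n_families_after(nxt, side) == 2L &&
          k + 1L < length(d)) {
        # a divergence leaving two conserved families, with more divergence
        # beyond: it closes the current block (inclusive); the markers up to
        # the next divergence are tail
        res[[length(res) + 1L]] <- c(start, nxt)
        k <- k + 2L
      } else {
        res[[length(res) + 1L]] <- c(start, nxt - step)
        k <- k + 1L
      }
    }
    res
  }

  rows <- list()
  add_block <- function(from, to, side) {
    lo <- min(from, to); hi <- max(from, to)
    label_idx <- if (side == "left") hi else if (side == "right") lo
                 else which.min(abs(lo:hi - fi)) + lo - 1L
    rows[[length(rows) + 1L]] <<- data.frame(
      label = map$rsid[label_idx], label_index = label_idx,
      from = lo, to = hi, n_markers = hi - lo + 1L, side = side,
      stringsAsFactors = FALSE)
  }
  for (b in arm_blocks("left")) add_block(b[1], b[2], "left")
  add_block(core$from, core$to, "focal")
  for (b in arm_blocks("right")) add_block(b[1], b[2], "right")
  blocks <- do.call(rbind, rows)
  blocks <- blocks[order(blocks$from), , drop = FALSE]
  rownames(blocks) <- NULL

  assigned <- unlist(mapply(seq, blocks$from, blocks$to, SIMPLIFY = FALSE))
  tail_markers <- map$rsid[setdiff(seq_len(nrow(map)), assigned)]

  blocks$theta <- abs(map$pos[blocks$label_index] - map$pos[fi]) *
    attr(map, "cm_per_mb") * 1e-8
  blocks$n_shared <- vapply(seq_len(nrow(blocks)), function(i) {
    if (blocks$side[i] == "focal") return(nrow(carriers))
    sum(conserved_through(div, blocks$label_index[i], blocks$side[i]))
  }, integer(1))

  structure(list(blocks = blocks, tail_markers = tail_markers,
                 divergence = div, layout = layout),
            class = "block_partition")
}

#' @export
print.block_partition <- function(x, ...) {
  cat("Block partition (", x$layout, " layout): ", nrow(x$blocks),
      " blocks, ", length(x$tail_markers), " unassigned tail marker(s)\n",
      sep = "")
  print(x$blocks[, c("label", "n_markers", "side", "theta", "n_shared")])
  invisible(x)
}

#' Recombination fraction from the focal site to a block
#'
#' The recombination fraction is the genetic distance (under the map's
#' constant cM/Mb rate) between the focal site and the block's label marker,
#' expressed as a unitless fraction (cM/100).
#'
#' @param partition a [partition_blocks()] result (or its `blocks` entry).
#' @param map the matching [marker_map()].
#' @param label block label rsid; if `NULL`, all blocks.
#' @return Named numeric vector of recombination fractions.
#' @export
block_theta <- function(partition, map, label = NULL) {
  blocks <- if (inherits(partition, "block_partition")) partition$blocks else partition
  th <- stats::setNames(abs(map$pos[blocks$label_index] - map$pos[focal_index(map)]) *
                          attr(map, "cm_per_mb") * 1e-8, blocks$label)
  if (is.null(label)) th else th[label]
}

#' Per-block founder-haplotype sharing counts
#'
#' For each block, the number of carrier chromosomes carrying the founder
#' haplotype intact from the focal site through the block's label (proximal)
#' marker; missing genotypes count as matching. Counts are non-increasing
#' with block distance from the focal block on each side and equal the total
#' chromosome count at the focal block.
#'
#' @param partition a [partition_blocks()] result.
#' @return Named integer vector, one count per block, in block order.
#' @export
sharing_counts <- function(partition) {
  stats::setNames(partition$blocks$n_shared, partition$blocks$label)
}

# family identifier from chromosome labels like "FAM3-a"/"FAM3-b"
family_of <- function(labels) sub("-[^-]*$", "", labels)

#' Per-family recombination events and shared-ancestor groups
#'
#' The two chromosomes of a family are collapsed to one haplotype (the
#' carriers are autozygous); non-missing discordances between them are
#' reported in `data_errors`. For each family the left/right breakpoints are
#' the outermost marker intervals where the family haplotype stops matching
#' the founder; `n_events` counts the non-empty sides. Families diverging at
#' the same marker on a side, with identical alleles (missing-compatible)
#' across the block containing that divergence marker, are assigned a common
#' shared-ancestor group.
#'
#' @param carriers a [carrier_matrix()].
#' @param map the matching [marker_map()].
#' @param founder a [infer_founder()] result.
#' @param partition optionally a precomputed [partition_blocks()] result
#'   (used to bound the group identity check); recomputed if `NULL`.
#' @return An object of class `family_derivation`: data frame with one row
#'   per family (`family`, `left_break`, `right_break` as marker-interval
#'   text, `n_events`, `level`, `group`), plus `data_errors`.
#' @export
derive_family_events <- function(carriers, map, founder, partition = NULL) {
  if (is.null(partition)) partition <- partition_blocks(carriers, map, founder)
  fam <- family_of(rownames(carriers))
  fams <- unique(fam)
  fi <- focal_index(map)

  data_errors <- character(0)
  hap <- matrix(NA_character_, length(fams), nrow(map),
                dimnames = list(fams, map$rsid))
  for (f in fams) {
    rows <- which(fam == f)
    sub <- carriers[rows, , drop = FALSE]
    for (j in seq_len(nrow(map))) {
      a <- unique(sub[, j]); a <- a[!is.na(a)]
      if (length(a) > 1L) {
        data_errors <- c(data_errors,
                         sprintf("family %s discordant at %s (%s)",
                                 f, map$rsid[j], paste(a, collapse = "/")))
        a <- a[1]
      }
      hap[f, j] <- if (length(a)) a else NA_character_
    }
    if (!is.na(hap[f, fi]) && hap[f, fi] != founder$alleles[fi]) {
      stop("family ", f, " does not carry the risk allele at the focal site")
    }
  }

  fdiv <- divergence_points(
    carrier_matrix(hap, map), map, founder)
  first_div <- function(f, side) fdiv[[side]][match(f, fdiv$chromosome)]

  interval_txt <- function(j, side) {
    if (is.na(j)) return(NA_character_)
    inner <- if (side == "left") j + 1L else j - 1L
    paste0("(", map$rsid[min(j, inner)], ",", map$rsid[max(j, inner)], ")")
  }

  # shared-ancestor grouping: same divergence marker on a side + identical
  # post-divergence alleles over the block containing that marker
  blocks <- partition$blocks
  block_of <- function(j) {
    hit <- which(blocks$from <= j & blocks$to >= j)
    if (length(hit)) hit[1] else NA_integer_
  }
  identical_over <- function(f1, f2, idx) {
    a <- hap[f1, idx]; b <- hap[f2, idx]
    ok <- is.na(a) | is.na(b) | a == b
    all(ok)
  }
  parent <- stats::setNames(seq_along(fams), fams)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (side in c("left", "right")) {
    dv <- vapply(fams, first_div, integer(1), side = side)
    for (j in unique(dv[!is.na(dv)])) {
      here <- fams[!is.na(dv) & dv == j]
      if (length(here) < 2L) next
      bi <- block_of(j)
      idx <- if (is.na(bi)) j else seq(blocks$from[bi], blocks$to[bi])
      for (i1 in seq_along(here)[-1]) for (i2 in seq_len(i1 - 1L)) {
        if (identical_over(here[i1], here[i2], idx)) {
          r1 <- find(match(here[i1], fams)); r2 <- find(match(here[i2], fams))
          if (r1 != r2) parent[r1] <- r2
        }
      }
    }
  }
  roots <- vapply(seq_along(fams), find, integer(1))
  grp <- rep(NA_character_, length(fams))
  shared <- table(roots)
  gid <- 0L
  for (r in names(shared)[shared > 1]) {
    gid <- gid + 1L
    grp[roots == as.integer(r)] <- paste0("G", gid)
  }

  left <- vapply(fams, first_div, integer(1), side = "left")
  right <- vapply(fams, first_div, integer(1), side = "right")
  out <- data.frame(
    family = fams,
    left_break = vapply(left, interval_txt, character(1), side = "left"),
    right_break = vapply(right, interval_txt, character(1), side = "right"),
    left_index = left, right_index = right,
    n_events = (!is.na(left)) + (!is.na(right)),
    group = grp, stringsAsFactors = FALSE)
  out$level <- out$n_events
  structure(list(families = out, data_errors = data_errors,
                 family_haplotypes = hap),
            class = "family_derivation")
}

#' @export
print.family_derivation <- function(x, ...) {
  print(x$families[, c("family", "left_break", "right_break", "n_events", "group")])
  if (length(x$data_errors)) {
    cat("Data errors:\n"); cat(paste0("  ", x$data_errors, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' One-sided conserved ancestral segment lengths
#'
#' Per carrier chromosome and side, the genetic distance (Morgans) from the
#' focal site to the estimated recombination point. By default the
#' recombination point is placed at the midpoint between the last
#' founder-matching marker and the first discordant marker. When no
#' discordant marker is observed before the end of the map the length runs
#' to the outermost genotyped (non-missing) marker and is flagged censored.
#'
#' @param carriers a [carrier_matrix()].
#' @param map the matching [marker_map()].
#' @param founder a [infer_founder()] result.
#' @param censoring recombination-point convention: `"midpoint"` (default),
#'   `"last-match"` or `"first-mismatch"`.
#' @return Data frame of class `segment_lengths`: `chromosome`,
#'   `left_morgans`, `right_morgans`, `left_censored`, `right_censored`.
#' @export
segment_lengths <- function(carriers, map, founder,
                            censoring = c("midpoint", "last-match", "first-mismatch")) {
  censoring <- match.arg(censoring)
  fi <- focal_index(map)
  div <- divergence_points(carriers, map, founder)
  cmmb <- attr(map, "cm_per_mb")
  one_side <- function(chr, side) {
    j <- div[[side]][chr]
    step <- if (side == "left") -1L else 1L
    if (is.na(j)) {
      idx <- which(!is.na(carriers[chr, ]))
      idx <- if (side == "left") idx[idx < fi] else idx[idx > fi]
      endpoint <- if (length(idx)) {
        map$pos[if (side == "left") min(idx) else max(idx)]
      } else map$pos[fi]
      return(c(abs(endpoint - map$pos[fi]) * cmmb * 1e-8, TRUE))
    }
    last_match <- j - step
    point <- switch(censoring,
      "midpoint" = (map$pos[j] + map$pos[last_match]) / 2,
      "last-match" = map$pos[last_match],
      "first-mismatch" = map$pos[j])
    c(abs(point - map$pos[fi]) * cmmb * 1e-8, FALSE)
  }
  n <- nrow(carriers)
  L <- t(vapply(seq_len(n), one_side, numeric(2), side = "left"))
  R <- t(vapply(seq_len(n), one_side, numeric(2), side = "right"))
  structure(data.frame(chromosome = rownames(carriers),
                       left_morgans = L[, 1], right_morgans = R[, 1],
                       left_censored = as.logical(L[, 2]),
                       right_censored = as.logical(R[, 2]),
                       stringsAsFactors = FALSE),
            class = c("segment_lengths", "data.frame"))
}
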