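# Small in-code fixtures shared across test files.

# toy map: m markers, 100 kb apart, focal in the middle (1 cM/Mb)
toy_map <- function(m = 5, focal = ceiling(m / 2), cm_per_mb = 1) {
  marker_map(rsid = paste0("m", seq_len(m)),
             pos = seq(1e6, by = 1e5, length.out = m),
             focal_rsid = paste0("m", focal), cm_per_mb = cm_per_mb)
}

toy_carriers <- function(rows, map) {
  al <- do.call(rbind, lapply(rows, function(s) strsplit(s, "")[[1]]))
  al[al == "-"] <- NA_character_
  if (is.null(names(rows))) {
    rownames(al) <- sprintf("F%d-%s", rep(seq_len(ceiling(length(rows) / 2)),
                                          each = 2, length.out = length(rows)),
                            rep(c("a", "b"), length.out = length(rows)))
  } else rownames(al) <- names(rows)
  carrier_matrix(al, map)
}

# background pool for simulations over an arbitrary map: the founder
# haplotype at a small frequency plus distinct background haplotypes
test_pool <- function(map, founder, founder_freq = 0.02, k = 5, seed = 42) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  pool <- rbind(founder,
                t(replicate(k, vapply(founder, function(a)
                  sample(setdiff(bases, a), 1), character(1)))))
  rownames(pool) <- NULL
  freqs <- c(founder_freq, rep((1 - founder_freq) / k, k))
  list(pool = pool, freqs = freqs)
}

# write a carrier table TSV and return its path
write_toy_table <- function(map, carriers, dir = tempdir()) {
  path <- tempfile("markers", fileext = ".tsv", tmpdir = dir)
  write_marker_table(map, carriers, path)
  path
}

# brute-force minimal total recombination events over all candidate founder
# haplotypes (alleles restricted to those observed per column); an event is
# one side on which a chromosome leaves the candidate before the map end
brute_force_min_events <- function(carriers, map) {
  fi <- focal_index(map)
  cols <- lapply(seq_len(ncol(carriers)), function(j) {
    a <- unique(carriers[, j]); a <- a[!is.na(a)]
    if (length(a)) a else "A"
  })
  cand <- expand.grid(cols, stringsAsFactors = FALSE)
  events_for <- function(fnd) {
    tot <- 0
    for (chr in seq_len(nrow(carriers))) {
      x <- carriers[chr, ]
      mism <- !is.na(x) & x != fnd
      tot <- tot + any(mism[seq_len(fi - 1)]) + any(mism[-seq_len(fi)])
    }
    tot
  }
  min(apply(cand, 1, events_for))
}

observed_events <- function(carriers, map, founder) {
  div <- founderage:::divergence_points(carriers, map, founder)
  sum(!is.na(div$left)) + sum(!is.na(div$right))
}
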