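#' Ordered marker map with a physical-to-genetic distance rule
#'
#' A marker map holds the ordered marker positions around a focal mutation
#' site together with the conversion rate from physical to genetic distance.
#' Genetic distances are obtained from physical distances assuming a constant
#' recombination rate (default 1 cM per Mb).
#'
#' @param rsid character vector of marker identifiers (unique).
#' @param pos integer vector of 1-based physical positions (GRCh38 for the
#'   packaged data), strictly increasing.
#' @param focal_rsid identifier of the focal mutation site; must name one of
#'   the markers.
#' @param chrom chromosome name, recycled over markers.
#' @param cm_per_mb genetic map rate, centimorgan per megabase.
#' @return An object of class `marker_map`: a data frame with columns
#'   `rsid`, `chrom`, `pos` and attributes `focal_index` and `cm_per_mb`.
#' @export
marker_map <- function(rsid, pos, focal_rsid, chrom = "1", cm_per_mb = 1) {
  rsid <- as.character(rsid)
  pos <- as.integer(pos)
  if (anyNA(pos) || any(pos < 1L)) stop("marker positions must be integers >= 1")
  if (length(rsid) != length(pos)) stop("rsid and pos lengths differ")
  if (anyDuplicated(rsid)) {
    stop("duplicate marker id(s): ", paste(rsid[duplicated(rsid)], collapse = ", "))
  }
  bad <- which(diff(pos) <= 0)
  if (length(bad)) {
    stop("marker positions not strictly increasing at row ", bad[1] + 1L,
         " (", rsid[bad[1] + 1L], ")")
  }
  focal_index <- match(focal_rsid, rsid)
  if (is.na(focal_index)) stop("focal marker '", focal_rsid, "' not found in map")
  if (!is.numeric(cm_per_mb) || cm_per_mb <= 0) stop("cm_per_mb must be positive")
  map <- data.frame(rsid = rsid, chrom = rep_len(as.character(chrom), length(rsid)),
                    pos = pos, stringsAsFactors = FALSE)
  attr(map, "focal_index") <- as.integer(focal_index)
  attr(map, "cm_per_mb") <- as.numeric(cm_per_mb)
  class(map) <- c("marker_map", "data.frame")
  map
}

#' @rdname marker_map
#' @param map a `marker_map`.
#' @export
focal_index <- function(map) attr(map, "focal_index")

#' Genetic distance between two markers
#'
#' @param map a `marker_map`.
#' @param i,j marker indices.
#' @param units `"cM"` or `"morgan"`.
#' @return Non-negative genetic distance; zero iff `i == j`.
#' @export
genetic_distance <- function(map, i, j, units = c("cM", "morgan")) {
  units <- match.arg(units)
  d <- abs(map$pos[i] - map$pos[j]) * attr(map, "cm_per_mb") * 1e-6
  if (units == "morgan") d <- d / 100
  d
}

#' Carrier-chromosome allele matrix
#'
#' One row per carrier chromosome, one column per marker. Missing genotypes
#' are `NA` and are treated as compatible with any allele throughout the
#' package. Every chromosome must carry the (non-missing) risk allele at the
#' focal site.
#'
#' @param alleles character matrix over `A`,`C`,`G`,`T`, `NA` for missing;
#'   row names are chromosome labels (two per family, e.g. `FAM3-a`).
#' @param map the matching `marker_map`.
#' @return An object of class `carrier_matrix`.
#' @export
carrier_matrix <- function(alleles, map) {
  alleles <- as.matrix(alleles)
  if (ncol(alleles) != nrow(map)) stop("allele matrix has ", ncol(alleles),
                                       " columns but map has ", nrow(map), " markers")
  ok <- alleles %in% c("A", "C", "G", "T") | is.na(alleles)
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, ]
    stop("invalid allele '", alleles[bad[1], bad[2]], "' at marker ",
         map$rsid[bad[2]], ", chromosome ", rownames(alleles)[bad[1]])
  }
  if (is.null(rownames(alleles))) {
    rownames(alleles) <- paste0("chr", seq_len(nrow(alleles)))
  }
  colnames(alleles) <- map$rsid
  fi <- focal_index(map)
  risk <- unique(alleles[, fi])
  if (anyNA(alleles[, fi])) stop("missing risk allele at focal site for chromosome ",
                                 rownames(alleles)[which(is.na(alleles[, fi]))[1]])
  if (length(risk) > 1) stop("carrier chromosomes disagree at the focal site: ",
                             paste(risk, collapse = "/"))
  structure(alleles, class = c("carrier_matrix", class(alleles)))
}

#' Read a carrier-haplotype marker table
#'
#' Parses a tab-separated table with columns `pos`, `rsid` and one column per
#' carrier chromosome. `-` encodes a missing genotype. The focal mutation row
#' is identified by a reserved rsid token.
#'
#' @param path path to the TSV file.
#' @param focal_rsid rsid token of the focal mutation row
#'   (default `"CLCC1-MUTATION"`, the token used by the packaged panel).
#' @param chrom,cm_per_mb passed to [marker_map()].
#' @return A list with elements `map` (a [marker_map()]) and
#'   `carriers` (a [carrier_matrix()]).
#' @export
parse_marker_table <- function(path, focal_rsid = "CLCC1-MUTATION",
                               chrom = "1", cm_per_mb = 1) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (!all(c("pos", "rsid") %in% names(tab))) {
    stop("marker table must have 'pos' and 'rsid' columns")
  }
  pos <- suppressWarnings(as.integer(gsub(",", "", tab$pos)))
  if (anyNA(pos)) stop("non-numeric position at row ", which(is.na(pos))[1])
  map <- marker_map(tab$rsid, pos, focal_rsid = focal_rsid,
                    chrom = chrom, cm_per_mb = cm_per_mb)
  chrom_cols <- setdiff(names(tab), c("pos", "rsid"))
  if (!length(chrom_cols)) stop("marker table has no chromosome columns")
  al <- t(as.matrix(tab[, chrom_cols, drop = FALSE]))
  al[al == "-"] <- NA_character_
  rownames(al) <- chrom_cols
  list(map = map, carriers = carrier_matrix(al, map))
}

#' Write a carrier-haplotype marker table
#'
#' Inverse of [parse_marker_table()]; missing genotypes are written as `-`.
#'
#' @param map a `marker_map`.
#' @param carriers a `carrier_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_marker_table <- function(map, carriers, path) {
  al <- t(unclass(carriers))
  al[is.na(al)] <- "-"
  tab <- data.frame(pos = map$pos, rsid = map$rsid, al,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Packaged carrier-haplotype panel for the CLCC1 c.75C>A founder mutation
#'
#' The published marker panel around the CLCC1 c.75C>A
#' (chr1:108,950,376 G>T, GRCh38) retinitis pigmentosa founder mutation:
#' 98 SNPs plus the focal mutation site, for the 18 carrier chromosomes of
#' nine consanguineous families.
#'
#' @param cm_per_mb genetic map rate used for the panel (1 cM/Mb).
#' @return As [parse_marker_table()]: a list with `map` and `carriers`.
#' @export
clcc1_panel <- function(cm_per_mb = 1) {
  path <- system.file("extdata", "clcc1_carrier_haplotypes.tsv",
                      package = "founderage", mustWork = TRUE)
  parse_marker_table(path, focal_rsid = "CLCC1-MUTATION", cm_per_mb = cm_per_mb)
}

#' Packaged per-block summary inputs for the CLCC1 founder mutation
#'
#' Per-block inputs for the age estimators as published for the CLCC1
#' c.75C>A analysis: number of carrier chromosomes sharing the founder
#' haplotype through the block, control-population block-haplotype
#' frequencies estimated by EM and by composite counting (CHM), the
#' recombination fraction from the block to the mutation, block sizes, and
#' the carrier-side block probabilities.
#'
#' @return A data frame with one row per haplotype block, ordered by
#'   genomic position; the focal block carries `NA` control frequencies.
#' @export
clcc1_block_inputs <- function() {
  path <- system.file("extdata", "clcc1_block_inputs.tsv",
                      package = "founderage", mustWork = TRUE)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' @export
print.marker_map <- function(x, ...) {
  cat("Marker map:", nrow(x), "markers on chr", x$chrom[1],
      sprintf("(%s..%s)", format(min(x$pos), big.mark = ","),
              format(max(x$pos), big.mark = ",")), "\n")
  fi <- focal_index(x)
  cat("Focal site:", x$rsid[fi], "at", format(x$pos[fi], big.mark = ","),
      "| map rate:", attr(x, "cm_per_mb"), "cM/Mb\n")
  invisible(x)
}

#' @export
print.carrier_matrix <- function(x, ...) {
  cat("Carrier matrix:", nrow(x), "chromosomes x", ncol(x), "markers;",
      sum(is.na(x)), "missing genotypes\n")
  invisible(x)
}
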