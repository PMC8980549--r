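#' Run the full founder-haplotype and age-estimation pipeline
#'
#' Orchestrates parse -> shared core -> founder inference -> block partition
#' -> recombination fractions -> sharing counts -> family derivations ->
#' segment lengths -> age table (decay and transition-matrix estimators on
#' every block and frequency source, Gamma method on the segment lengths).
#' With no arguments it reproduces the packaged CLCC1 c.75C>A analysis.
#'
#' @param marker_table path to a carrier marker table
#'   (see [parse_marker_table()]); default: the packaged panel.
#' @param block_inputs path to, or data frame of, per-block control
#'   frequencies with columns `label`, `fn_em`, `fn_chm` (optional: missing
#'   control frequencies disable the frequency-based estimators); default:
#'   the packaged per-block inputs.
#' @param focal_rsid focal mutation row token.
#' @param cm_per_mb genetic map rate.
#' @param mu marker mutation rate for the transition-matrix estimator.
#' @param generation_years calendar years per generation.
#' @param bootstrap bootstrap replicates for age CIs (0 = none).
#' @param seed integer seed (bootstrap only; the pipeline is otherwise
#'   deterministic).
#' @param censoring segment-length convention, see [segment_lengths()].
#' @param layout block layout, see [partition_blocks()].
#' @param quiet suppress stage messages.
#' @return List of class `founder_report` with the core interval, founder
#'   haplotype, block table, family derivations, age table, Gamma estimates
#'   and a min/max summary.
#' @export
run_pipeline <- function(marker_table = NULL, block_inputs = NULL,
                         focal_rsid = "CLCC1-MUTATION", cm_per_mb = 1,
                         mu = 1e-8, generation_years = 25, bootstrap = 0,
                         seed = 1, censoring = "midpoint",
                         layout = "published", quiet = FALSE) {
  say <- function(...) if (!quiet) message("[founderage] ", ...)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    say(sprintf("%-18s %.2fs", name, proc.time()[["elapsed"]] - t0))
    out
  }

  parsed <- stage("parse", {
    if (is.null(marker_table)) clcc1_panel(cm_per_mb = cm_per_mb)
    else parse_marker_table(marker_table, focal_rsid = focal_rsid,
                            cm_per_mb = cm_per_mb)
  })
  map <- parsed$map; carriers <- parsed$carriers

  core <- stage("shared_core", find_shared_core(carriers, map))
  founder <- stage("founder", infer_founder(carriers, map, core))
  partition <- stage("blocks", partition_blocks(carriers, map, founder,
                                                layout = layout))
  events <- stage("family_events",
                  derive_family_events(carriers, map, founder, partition))
  segments <- stage("segments",
                    segment_lengths(carriers, map, founder,
                                    censoring = censoring))

  inputs <- stage("age_inputs", {
    blocks <- partition$blocks
    tab <- data.frame(label = blocks$label, n_shared = blocks$n_shared,
                      theta = blocks$theta, n_snps = blocks$n_markers,
                      stringsAsFactors = FALSE)
    fin <- if (is.null(block_inputs)) clcc1_block_inputs()
           else if (is.character(block_inputs)) {
             utils::read.delim(block_inputs, sep = "\t", stringsAsFactors = FALSE)
           } else block_inputs
    if (!is.null(fin)) {
      m <- match(tab$label, fin$label)
      tab$fn_em <- fin$fn_em[m]
      tab$fn_chm <- fin$fn_chm[m]
    } else {
      tab$fn_em <- tab$fn_chm <- NA_real_
    }
    tab
  })

  ages <- stage("ages", age_table(inputs, n_chrom = nrow(carriers), mu = mu,
                                  boot_B = bootstrap, seed = seed))
  gamma <- stage("gamma", {
    ind <- tryCatch(gamma_age(segments, genealogy = "independent"),
                    error = function(e) NULL)
    cor <- tryCatch(gamma_age(segments, genealogy = "correlated",
                              events = events),
                    error = function(e) NULL)
    list(independent = ind, correlated = cor)
  })

  rng <- age_range(ages, generation_years = generation_years)
  report <- structure(list(
    core = core, founder = founder, map = map,
    blocks = partition$blocks, tail_markers = partition$tail_markers,
    families = events$families, data_errors = events$data_errors,
    segments = segments, age_inputs = inputs, ages = ages,
    gamma = gamma, summary = rng,
    params = list(focal_rsid = focal_rsid, cm_per_mb = cm_per_mb, mu = mu,
                  generation_years = generation_years, bootstrap = bootstrap,
                  seed = seed, censoring = censoring, layout = layout)),
    class = "founder_report")
  say(sprintf("age range: %s-%s generations (%s-%s years)",
              rng$min_generations, rng$max_generations,
              rng$min_years, rng$max_years))
  report
}

#' @export
print.founder_report <- function(x, ...) {
  print(x$core)
  cat("Blocks (", nrow(x$blocks), "), tail markers: ",
      length(x$tail_markers), "\n", sep = "")
  print(x$blocks[, c("label", "n_markers", "side", "theta", "n_shared")])
  cat("\nFamily derivations:\n")
  print(x$families[, c("family", "left_break", "right_break", "n_events", "group")])
  cat("\nAge estimates (generations):\n")
  print(x$ages[x$ages$estimable,
               c("label", "method", "source", "rounded")], row.names = FALSE)
  if (!is.null(x$gamma$independent)) {
    cat("\nGamma (independent):", round(x$gamma$independent$generations, 1),
        sprintf("(%.1f-%.1f)\n", x$gamma$independent$ci_low,
                x$gamma$independent$ci_high))
  }
  if (!is.null(x$gamma$correlated)) {
    cat("Gamma (correlated): ", round(x$gamma$correlated$generations, 1),
        sprintf("(%.1f-%.1f)\n", x$gamma$correlated$ci_low,
                x$gamma$correlated$ci_high))
  }
  s <- x$summary
  cat(sprintf("\nSummary: %s-%s generations, about %s-%s years\n",
              s$min_generations, s$max_generations, s$min_years, s$max_years))
  invisible(x)
}

report_lists <- function(report) {
  list(
    core = unclass(report$core),
    founder = list(alleles = report$founder$alleles,
                   support = report$founder$support,
                   tie = report$founder$tie),
    blocks = report$blocks,
    tail_markers = report$tail_markers,
    families = report$families,
    ages = as.data.frame(report$ages),
    gamma = list(
      independent = if (!is.null(report$gamma$independent)) {
        report$gamma$independent[c("generations", "ci_low", "ci_high")]
      },
      correlated = if (!is.null(report$gamma$correlated)) {
        report$gamma$correlated[c("generations", "ci_low", "ci_high")]
      }),
    summary = report$summary,
    params = report$params)
}

#' Serialize a pipeline report
#'
#' `"json"` writes the full report; `"tsv"` writes the block/age table in
#' the published layout (one row per block, columns for sharing, control
#' frequencies, theta, block size and the per-estimator ages); `"text"`
#' writes a human-readable grid.
#'
#' @param report a [run_pipeline()] result.
#' @param path output file.
#' @param format `"json"`, `"tsv"` or `"text"`.
#' @return `path`, invisibly.
#' @export
render_report <- function(report, path, format = c("json", "tsv", "text")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(report_lists(report), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
  } else if (format == "tsv") {
    utils::write.table(block_grid(report), path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    sink(con); on.exit(sink(), add = TRUE, after = FALSE)
    print(report)
  }
  invisible(path)
}

# one row per block in published order with age columns
block_grid <- function(report) {
  b <- report$blocks
  g <- data.frame(label = b$label, n_shared = b$n_shared,
                  n_markers = b$n_markers, theta = b$theta,
                  stringsAsFactors = FALSE)
  ag <- report$ages
  for (meth in c("risch", "goldstein")) for (src in c("EM", "CHM")) {
    col <- paste0("age_", meth, "_", tolower(src))
    m <- ag[ag$method == meth & ag$source == src, ]
    g[[col]] <- m$rounded[match(g$label, m$label)]
  }
  g
}

#' Reload a JSON report written by [render_report()]
#'
#' @param path JSON file path.
#' @return The report as plain lists/data frames.
#' @export
report_from_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
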