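#' Linkage-disequilibrium constant delta
#'
#' `delta = (P_D - P_N) / (1 - P_N)`, the excess of the ancestral
#' allele/haplotype on carrier chromosomes over its control-population
#' frequency. A non-positive delta (carrier frequency at or below the
#' control frequency) cannot be dated by the decay formula and is flagged.
#'
#' @param p_d frequency of the ancestral haplotype among carrier chromosomes.
#' @param p_n its frequency among control chromosomes; must be `< 1`.
#' @return delta, with attribute `estimable` (`FALSE` when `delta <= 0`).
#' @export
ld_delta <- function(p_d, p_n) {
  stopifnot(p_d >= 0, p_d <= 1, p_n >= 0)
  if (p_n >= 1) stop("p_n must be < 1")
  d <- (p_d - p_n) / (1 - p_n)
  attr(d, "estimable") <- d > 0
  d
}

round_half_up <- function(x) floor(x + 0.5)

age_estimate <- function(generations, method, ci = c(NA_real_, NA_real_),
                         details = list()) {
  structure(c(list(generations = generations,
                   rounded = round_half_up(generations),
                   ci_low = ci[1], ci_high = ci[2], method = method),
              details),
            class = "age_estimate")
}

#' @export
print.age_estimate <- function(x, ...) {
  ci <- if (!is.na(x$ci_low)) sprintf(" (%.1f-%.1f)", x$ci_low, x$ci_high) else ""
  cat(sprintf("Mutation age [%s]: %d generations (%.2f)%s\n",
              x$method, x$rounded, x$generations, ci))
  invisible(x)
}

#' Allele age from linkage-disequilibrium decay (closed form)
#'
#' Under one recombination opportunity per generation at fraction `theta`,
#' the excess association delta decays as `(1 - theta)^g`, giving
#' `g = ln(delta) / ln(1 - theta)`.
#'
#' @param p_d,p_n as in [ld_delta()].
#' @param theta recombination fraction between the block and the mutation,
#'   in `(0, 1)`.
#' @return An `age_estimate` (generations as float plus half-up rounding).
#' @export
risch_age <- function(p_d, p_n, theta) {
  d <- ld_delta(p_d, p_n)
  if (!attr(d, "estimable")) {
    stop("not estimable by the decay formula: delta = ", signif(d, 4), " <= 0")
  }
  if (theta <= 0 || theta >= 1) stop("theta must be in (0, 1)")
  g <- log(as.numeric(d)) / log(1 - theta)
  age_estimate(g, "risch", details = list(delta = as.numeric(d),
                                          p_d = p_d, p_n = p_n, theta = theta))
}

#' Two-state transition model of founder-allele decay
#'
#' Builds the column-stochastic per-generation transition matrix
#' `K = c R + mu M + (1 - c - mu) I` acting on the state vector
#' (ancestral, non-ancestral) of carrier chromosomes: `R` resets to
#' population frequencies (`R11 = R12 = a`, `R21 = R22 = 1 - a`), `M` is the
#' marker-mutation matrix with `M11 = 0`, `M12 = 1/3`, `M21 = 1`,
#' `M22 = 2/3` (a mutation always removes an ancestral allele but hits the
#' ancestral base in only one of three changes), and `I` is the identity.
#'
#' @param a ancestral allele/haplotype frequency in controls.
#' @param c recombination rate to the marker or block per generation.
#' @param mu per-generation marker mutation rate.
#' @return List of class `goldstein_model` with `K`, `R`, `M`, `a`, `c`, `mu`.
#' @export
goldstein_model <- function(a, c, mu = 1e-8) {
  stopifnot(a >= 0, a < 1, c >= 0, c < 1, mu >= 0, c + mu < 1)
  R <- matrix(c(a, 1 - a, a, 1 - a), 2)
  M <- matrix(c(0, 1, 1 / 3, 2 / 3), 2)
  K <- c * R + mu * M + (1 - c - mu) * diag(2)
  stopifnot(all(abs(colSums(K) - 1) < 1e-12))
  structure(list(K = K, R = R, M = M, a = a, c = c, mu = mu),
            class = "goldstein_model")
}

#' Allele age by iterated transition-matrix decay
#'
#' Starting from the founder state `(1, 0)`, the state is multiplied by the
#' transition matrix `K` once per generation until the ancestral-state
#' frequency falls to the observed carrier frequency `target_p_d`; the age is
#' the linear interpolation between the bracketing generations. With
#' `mu = 0` this equals the closed form [risch_age()] analytically.
#'
#' @param model a [goldstein_model()], or `NULL` to build one from
#'   `p_n`/`theta`/`mu`.
#' @param target_p_d observed ancestral-haplotype frequency among carriers.
#' @param p_n,theta,mu used when `model` is `NULL`.
#' @param max_iter generation cap.
#' @return An `age_estimate`.
#' @export
goldstein_age <- function(target_p_d, model = NULL, p_n = NULL, theta = NULL,
                          mu = 1e-8, max_iter = 1e5) {
  if (is.null(model)) model <- goldstein_model(p_n, theta, mu)
  stopifnot(target_p_d > 0, target_p_d <= 1)
  if (target_p_d == 1) {
    return(age_estimate(0, "goldstein", details = list(model = model)))
  }
  # the two-state chain decays exactly geometrically toward its stationary
  # ancestral frequency p*, at rate lambda (the subdominant eigenvalue);
  # interpolation between the bracketing generations uses that geometry so
  # the fractional age is exact, not a linear approximation
  K <- model$K
  p_star <- K[1, 2] / (1 - K[1, 1] + K[1, 2])
  lambda <- K[1, 1] - K[1, 2]
  if (target_p_d <= p_star) {
    stop("not estimable: target ", target_p_d,
         " does not exceed the asymptotic ancestral frequency ",
         signif(p_star, 4))
  }
  v <- c(1, 0)
  p_prev <- 1
  for (g in seq_len(max_iter)) {
    v <- as.vector(K %*% v)
    stopifnot(all(v >= -1e-12), abs(sum(v) - 1) < 1e-9)
    if (v[1] <= target_p_d) {
      frac <- log((p_prev - p_star) / (target_p_d - p_star)) /
        log((p_prev - p_star) / (v[1] - p_star))
      gen <- (g - 1) + frac
      return(age_estimate(gen, "goldstein",
                          details = list(model = model, p_d = target_p_d,
                                         p_star = p_star, lambda = lambda)))
    }
    p_prev <- v[1]
  }
  stop("iteration cap reached without bracketing the target frequency")
}

#' Allele age from conserved ancestral segment lengths (Gamma method)
#'
#' One-sided conserved segment lengths around the mutation are modelled as
#' Exponential with rate equal to the age in generations. With `S` the sum
#' of the `2n` one-sided lengths (Morgans) and `d` the number of uncensored
#' segments, the bias-corrected point estimate is `(d - 1) / S` (the
#' maximum-likelihood estimate `d / S` is available via `correction`), and
#' the equal-tail confidence interval is `qgamma(alpha/2, d) / S` to
#' `qgamma(1 - alpha/2, d) / S`. Censored segments (no recombination
#' observed within the map) contribute their censored length to `S` but not
#' to the shape. With `genealogy = "correlated"`, chromosomes sharing a
#' post-founder ancestor are collapsed to a single effective lineage on
#' their shared side before forming `S` and the shape (see
#' [derive_family_events()]).
#'
#' @param segments a [segment_lengths()] data frame, or a numeric vector of
#'   one-sided lengths in Morgans (then `censored` applies).
#' @param censored logical vector matching a numeric `segments`.
#' @param alpha confidence level complement (default 0.05 for 95% CI).
#' @param correction `"bias"` (default, `(d-1)/S`) or `"mle"` (`d/S`).
#' @param genealogy `"independent"` or `"correlated"`.
#' @param events a [derive_family_events()] result; required for
#'   `genealogy = "correlated"` with a `segment_lengths` input.
#' @return An `age_estimate` with analytic CI.
#' @export
gamma_age <- function(segments, censored = NULL, alpha = 0.05,
                      correction = c("bias", "mle"),
                      genealogy = c("independent", "correlated"),
                      events = NULL) {
  correction <- match.arg(correction)
  genealogy <- match.arg(genealogy)
  if (inherits(segments, "segment_lengths") || is.data.frame(segments)) {
    df <- segments
    if (genealogy == "correlated") {
      if (is.null(events)) stop("correlated genealogy needs a family-derivation result")
      df <- collapse_correlated_segments(df, events)
    }
    lengths <- c(df$left_morgans, df$right_morgans)
    censored <- c(df$left_censored, df$right_censored)
  } else {
    lengths <- as.numeric(segments)
    if (is.null(censored)) censored <- rep(FALSE, length(lengths))
  }
  stopifnot(length(lengths) == length(censored), all(is.finite(lengths)),
            all(lengths >= 0))
  S <- sum(lengths)
  if (S <= 0) stop("total segment length is zero")
  d <- sum(!censored)
  if (d < 1) stop("no uncensored segment; age not estimable")
  num <- if (correction == "bias") max(d - 1, 1) else d
  g <- num / S
  ci <- stats::qgamma(c(alpha / 2, 1 - alpha / 2), shape = d, rate = 1) / S
  age_estimate(g, paste0("gamma_", substr(genealogy, 1, 3)), ci = ci,
               details = list(S = S, n_segments = length(lengths),
                              n_uncensored = d, genealogy = genealogy))
}

# Collapse chromosomes of one family, and families of one shared-ancestor
# group on their shared side, to a single effective lineage: within a set of
# identical-by-descent segments only one independent recombination history
# is observed.
collapse_correlated_segments <- function(seg, events) {
  fam <- family_of(seg$chromosome)
  df <- events$families
  # one lineage per family on each side
  keep_first <- !duplicated(fam)
  out <- seg[keep_first, , drop = FALSE]
  out_fam <- fam[keep_first]
  # drop the shared side of all but one member of each ancestor group
  drop_left <- drop_right <- rep(FALSE, nrow(out))
  for (g in unique(df$group[!is.na(df$group)])) {
    members <- df$family[!is.na(df$group) & df$group == g]
    for (side in c("left", "right")) {
      idxcol <- paste0(side, "_index")
      dv <- df[[idxcol]][match(members, df$family)]
      if (length(unique(dv)) == 1L && !anyNA(dv)) {  # shared-side divergence
        extra <- match(members[-1], out_fam)
        if (side == "left") drop_left[extra] <- TRUE else drop_right[extra] <- TRUE
      }
    }
  }
  long <- data.frame(
    chromosome = c(out$chromosome, out$chromosome),
    side = rep(c("left", "right"), each = nrow(out)),
    morgans = c(out$left_morgans, out$right_morgans),
    censored = c(out$left_censored, out$right_censored),
    drop = c(drop_left, drop_right), stringsAsFactors = FALSE)
  long <- long[!long$drop, , drop = FALSE]
  # gamma_age only concatenates the two sides, so pack the retained
  # one-sided lengths into left_* and leave right_* empty (zero-length
  # censored entries contribute nothing to S or the shape)
  data.frame(chromosome = long$chromosome,
             left_morgans = long$morgans, right_morgans = numeric(nrow(long)),
             left_censored = long$censored,
             right_censored = rep(TRUE, nrow(long)), stringsAsFactors = FALSE)
}

#' Parametric bootstrap confidence interval for frequency-based age estimators
#'
#' Resamples the carrier-chromosome sharing count as
#' `Binomial(n_chrom, p_d)`, re-estimates the age for each replicate and
#' returns the percentile interval. Deterministic under a fixed seed.
#'
#' @param estimator function of one argument (the resampled `p_d`) returning
#'   an `age_estimate` or a number.
#' @param p_d observed carrier frequency.
#' @param n_chrom number of carrier chromosomes resampled.
#' @param B replicates.
#' @param seed integer seed.
#' @param conf confidence level.
#' @return Numeric `c(low, high)` with attribute `n_failed`.
#' @export
bootstrap_ci <- function(estimator, p_d, n_chrom, B = 2000, seed = 1,
                         conf = 0.95) {
  set.seed(seed)
  x <- stats::rbinom(B, n_chrom, p_d) / n_chrom
  vals <- vapply(x, function(p) {
    out <- tryCatch(estimator(p), error = function(e) NA_real_)
    if (inherits(out, "age_estimate")) out$generations else as.numeric(out)
  }, numeric(1))
  ok <- !is.na(vals)
  if (mean(ok) < 0.5) stop("estimator failed in more than half of the replicates")
  q <- stats::quantile(vals[ok], c((1 - conf) / 2, 1 - (1 - conf) / 2),
                       names = FALSE)
  structure(q, n_failed = sum(!ok))
}

#' Per-block age table over both estimators and frequency sources
#'
#' For each non-focal haplotype block and each control-frequency source
#' (EM, CHM), computes the decay closed form and the iterated
#' transition-matrix age from `P_D = n_shared / n_chrom`, the control
#' frequency, and the block's recombination fraction. Blocks with
#' `delta <= 0` are flagged not-estimable. Optional parametric bootstrap CIs.
#'
#' @param inputs data frame with columns `label`, `n_shared`, `fn_em`,
#'   `fn_chm`, `theta` (as from [clcc1_block_inputs()] or a pipeline run).
#' @param n_chrom total carrier chromosomes (18 for the packaged panel).
#' @param mu marker mutation rate for the transition-matrix method.
#' @param boot_B bootstrap replicates for CIs (0 = no CIs).
#' @param seed bootstrap seed.
#' @return Data frame of class `age_table`: one row per block x estimator x
#'   frequency source with `generations`, `rounded`, `estimable`, CI columns;
#'   attribute `summary` holds the min/max over estimable rows.
#' @export
age_table <- function(inputs, n_chrom = 18, mu = 1e-8, boot_B = 0, seed = 1) {
  rows <- list()
  bseed <- seed
  for (i in seq_len(nrow(inputs))) {
    th <- inputs$theta[i]
    if (!is.finite(th) || th <= 0) next   # focal block: undated
    p_d <- inputs$n_shared[i] / n_chrom
    for (src in c("em", "chm")) {
      p_n <- inputs[[paste0("fn_", src)]][i]
      if (is.na(p_n)) next
      for (meth in c("risch", "goldstein")) {
        est <- tryCatch({
          if (meth == "risch") risch_age(p_d, p_n, th)
          else goldstein_age(p_d, p_n = p_n, theta = th, mu = mu)
        }, error = function(e) NULL)
        ci <- c(NA_real_, NA_real_)
        if (!is.null(est) && boot_B > 0) {
          bseed <- bseed + 1L
          ci <- tryCatch(bootstrap_ci(function(p) {
            if (meth == "risch") risch_age(p, p_n, th)
            else goldstein_age(p, p_n = p_n, theta = th, mu = mu)
          }, p_d, n_chrom, B = boot_B, seed = bseed), error = function(e) ci)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          label = inputs$label[i], method = meth, source = toupper(src),
          p_d = p_d, p_n = p_n, theta = th,
          generations = if (is.null(est)) NA_real_ else est$generations,
          rounded = if (is.null(est)) NA_real_ else est$rounded,
          estimable = !is.null(est), ci_low = ci[1], ci_high = ci[2],
          stringsAsFactors = FALSE)
      }
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = character(0), method = character(0),
               source = character(0), p_d = numeric(0), p_n = numeric(0),
               theta = numeric(0), generations = numeric(0),
               rounded = numeric(0), estimable = logical(0),
               ci_low = numeric(0), ci_high = numeric(0))
  est <- tab$rounded[tab$estimable]
  attr(tab, "summary") <- if (length(est)) {
    list(min_generations = min(est), max_generations = max(est))
  } else list(min_generations = NA_real_, max_generations = NA_real_)
  class(tab) <- c("age_table", "data.frame")
  tab
}

#' Summary range of an age table, optionally in years
#'
#' @param tab an [age_table()].
#' @param generation_years calendar years per generation (25 by default).
#' @return List with `min_generations`, `max_generations`, `min_years`,
#'   `max_years`.
#' @export
age_range <- function(tab, generation_years = 25) {
  s <- attr(tab, "summary")
  list(min_generations = s$min_generations,
       max_generations = s$max_generations,
       min_years = s$min_generations * generation_years,
       max_years = s$max_generations * generation_years)
}
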