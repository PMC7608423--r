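# Synthetic case-control studies: a neutral null model for threshold
# calibration and a logistic disease model for power studies.

#' Configuration for a null (no-association) simulated study
#'
#' Variant MAFs are drawn from a density proportional to 1/x truncated to
#' `[maf_min, maf_max]` — a crude but standard stand-in for the neutral
#' site-frequency spectrum — or uniformly on the same interval. Genotypes are
#' independent Hardy-Weinberg draws, dosage ~ Binomial(2, MAF). Positions are
#' strictly increasing integers with mean spacing ~100 bp.
#'
#' @param n_individuals total sample size N.
#' @param n_case number of cases (first `n_case` individuals are labeled
#'   case; labels carry no information under the null).
#' @param chrom_lengths integer vector of variant counts per chromosome.
#' @param maf_max upper MAF bound of the simulated spectrum (default 0.05).
#' @param maf_min lower bound; default 1/(2N), the frequency of a singleton
#'   allele.
#' @param maf_spectrum `"one_over_x"` (default) or `"uniform"`.
#' @return list of class `null_sim_config`.
#' @export
null_sim_config <- function(n_individuals, n_case,
                            chrom_lengths = c(500L, 500L),
                            maf_max = 0.05, maf_min = NULL,
                            maf_spectrum = c("one_over_x", "uniform")) {
  maf_spectrum <- match.arg(maf_spectrum)
  if (is.null(maf_min)) maf_min <- 1 / (2 * n_individuals)
  stopifnot(n_case >= 1, n_case < n_individuals, all(chrom_lengths >= 1),
            maf_max > 0, maf_max <= 0.5, maf_min > 0, maf_min < maf_max)
  structure(list(n_individuals = as.integer(n_individuals),
                 n_case = as.integer(n_case),
                 chrom_lengths = as.integer(chrom_lengths),
                 maf_max = maf_max, maf_min = maf_min,
                 maf_spectrum = maf_spectrum),
            class = "null_sim_config")
}

#' Configuration for a simulated disease study
#'
#' Extends the null model with a causal window of `window_size` consecutive
#' variants on one chromosome. Each causal variant is independently
#' detrimental (probability `pdv`, per-allele odds ratio drawn uniformly from
#' `or_interval`), neutral (probability `pnv`, OR = 1), or protective
#' (remaining probability, OR = reciprocal of a draw from `or_interval`).
#' Disease follows a logistic model on the summed per-variant log-OR burden,
#' with intercept solved so the population prevalence equals `prevalence`.
#'
#' @param base a [null_sim_config()] describing sample size and genome.
#' @param prevalence population disease prevalence K in (0, 1).
#' @param window_size number of consecutive causal variants w.
#' @param pdv proportion of detrimental variants in the window.
#' @param pnv proportion of neutral variants in the window (pdv + pnv <= 1).
#' @param or_interval length-2 numeric, 1 <= low <= high: per-allele odds
#'   ratio range for detrimental variants.
#' @param causal_chrom index of the chromosome carrying the window.
#' @return list of class `disease_sim_config`.
#' @export
disease_sim_config <- function(base, prevalence, window_size, pdv, pnv,
                               or_interval, causal_chrom = 1L) {
  stopifnot(inherits(base, "null_sim_config"),
            prevalence > 0, prevalence < 1,
            pdv >= 0, pnv >= 0, pdv + pnv <= 1,
            length(or_interval) == 2L, or_interval[1] >= 1,
            or_interval[1] <= or_interval[2],
            causal_chrom >= 1, causal_chrom <= length(base$chrom_lengths),
            window_size >= 1,
            window_size <= base$chrom_lengths[causal_chrom])
  structure(c(base, list(prevalence = prevalence,
                         window_size = as.integer(window_size),
                         pdv = pdv, pnv = pnv,
                         or_interval = as.numeric(or_interval),
                         causal_chrom = as.integer(causal_chrom))),
            class = "disease_sim_config")
}

# Draw m MAFs from the configured spectrum.
draw_mafs <- function(config, m) {
  a <- config$maf_min
  b <- config$maf_max
  if (config$maf_spectrum == "one_over_x") {
    # inverse CDF of density ~ 1/x on [a, b]: x = a * (b/a)^u
    a * (b / a)^runif(m)
  } else {
    runif(m, a, b)
  }
}

# Site metadata for one simulated genome.
sim_sites <- function(config) {
  m_total <- sum(config$chrom_lengths)
  chrom <- rep(as.character(seq_along(config$chrom_lengths)),
               config$chrom_lengths)
  pos <- unlist(lapply(config$chrom_lengths,
                       function(m) cumsum(1L + rpois(m, 99))), use.names = FALSE)
  data.frame(chrom = chrom, pos = as.integer(pos),
             id = paste0("v", seq_len(m_total)), ref = "A", alt = "C",
             stringsAsFactors = FALSE)
}

as_genotypes <- function(dosage, sites, samples) {
  structure(list(dosage = dosage, sites = sites, samples = samples),
            class = "gecs_genotypes")
}

#' Simulate a null case-control study
#'
#' @param config a [null_sim_config()].
#' @param seed optional integer seed.
#' @return list with `genotypes` (a `gecs_genotypes`), `phenotype`
#'   (a [phenotype()]), and `mafs` (the drawn population MAFs).
#' @export
simulate_null_study <- function(config, seed = NULL) {
  stopifnot(inherits(config, "null_sim_config"))
  if (!is.null(seed)) set.seed(seed)
  N <- config$n_individuals
  m <- sum(config$chrom_lengths)
  sites <- sim_sites(config)
  mafs <- draw_mafs(config, m)
  dosage <- matrix(rbinom(m * N, 2L, rep(mafs, N)), m, N)
  samples <- sprintf("s%04d", seq_len(N))
  ph <- phenotype(c(rep(1L, config$n_case), rep(0L, N - config$n_case)))
  list(genotypes = as_genotypes(dosage, sites, samples), phenotype = ph,
       mafs = mafs)
}

# Solve the logistic intercept so the population prevalence is K for burden
# scores s (Monte-Carlo sample of sum(dosage * logOR) over the population).
solve_beta0 <- function(scores, K) {
  f <- function(b0) mean(plogis(b0 + scores)) - K
  lo <- -50; hi <- 50
  if (f(lo) > 0 || f(hi) < 0)
    stop("prevalence ", K, " unattainable for the configured effect sizes")
  uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Simulate a case-control study under a logistic disease model
#'
#' Draws the causal-window genotypes by rejection sampling from the
#' population (only the causal window affects disease risk, so non-causal
#' genotypes are generated after individuals are selected; the joint
#' distribution is identical to rejecting fully simulated genomes). Cases are
#' collected until `n_case` and controls until `N - n_case`.
#'
#' @param config a [disease_sim_config()].
#' @param seed optional integer seed.
#' @return list with `genotypes`, `phenotype` (cases first), and `truth`:
#'   list with `causal_chrom`, `window` (variant index range on that
#'   chromosome), `site_index` (rows in the genotype table), `log_or`
#'   per causal variant, `role` ("detrimental"/"neutral"/"protective"),
#'   `beta0`, and the population `mafs`.
#' @export
simulate_disease_study <- function(config, seed = NULL) {
  stopifnot(inherits(config, "disease_sim_config"))
  if (!is.null(seed)) set.seed(seed)
  N <- config$n_individuals
  n_case <- config$n_case
  n_control <- N - n_case
  m <- sum(config$chrom_lengths)
  sites <- sim_sites(config)
  mafs <- draw_mafs(config, m)
  w <- config$window_size
  m_causal_chrom <- config$chrom_lengths[config$causal_chrom]
  chrom_offset <- c(0L, cumsum(config$chrom_lengths))[config$causal_chrom]
  win_start <- if (m_causal_chrom == w) 1L else
    sample.int(m_causal_chrom - w + 1L, 1L)
  win <- win_start:(win_start + w - 1L)
  site_index <- chrom_offset + win

  u <- runif(w)
  role <- ifelse(u < config$pdv, "detrimental",
                 ifelse(u < config$pdv + config$pnv, "neutral", "protective"))
  or_draw <- runif(w, config$or_interval[1], config$or_interval[2])
  log_or <- ifelse(role == "detrimental", log(or_draw),
                   ifelse(role == "neutral", 0, -log(or_draw)))
  maf_win <- mafs[site_index]

  # intercept from a Monte-Carlo population sample of burden scores
  n_mc <- 50000L
  g_mc <- matrix(rbinom(n_mc * w, 2L, rep(maf_win, each = n_mc)), n_mc, w)
  beta0 <- solve_beta0(as.vector(g_mc %*% log_or), config$prevalence)

  # rejection sampling on the causal window only
  got_case <- 0L; got_control <- 0L
  case_g <- matrix(0L, n_case, w)
  control_g <- matrix(0L, n_control, w)
  batch <- max(1000L, min(100000L, ceiling(n_case / config$prevalence / 10)))
  draws <- 0L
  max_draws <- ceiling(50 * (n_case / config$prevalence +
                             n_control / (1 - config$prevalence)))
  while (got_case < n_case || got_control < n_control) {
    if (draws > max_draws)
      stop("rejection sampling exceeded its draw budget; prevalence and ",
           "sample size are incompatible")
    g <- matrix(rbinom(batch * w, 2L, rep(maf_win, each = batch)), batch, w)
    pr <- plogis(beta0 + as.vector(g %*% log_or))
    is_case <- rbinom(batch, 1L, pr) == 1L
    draws <- draws + batch
    need_case <- n_case - got_case
    idx_case <- which(is_case)[seq_len(min(need_case, sum(is_case)))]
    if (length(idx_case)) {
      case_g[got_case + seq_along(idx_case), ] <- g[idx_case, , drop = FALSE]
      got_case <- got_case + length(idx_case)
    }
    need_control <- n_control - got_control
    idx_control <- which(!is_case)[seq_len(min(need_control, sum(!is_case)))]
    if (length(idx_control)) {
      control_g[got_control + seq_along(idx_control), ] <-
        g[idx_control, , drop = FALSE]
      got_control <- got_control + length(idx_control)
    }
  }

  # fill the genome: non-causal sites are independent of disease status
  dosage <- matrix(rbinom(m * N, 2L, rep(mafs, N)), m, N)
  dosage[site_index, ] <- t(rbind(case_g, control_g))
  samples <- sprintf("s%04d", seq_len(N))
  ph <- phenotype(c(rep(1L, n_case), rep(0L, n_control)))
  truth <- list(causal_chrom = config$causal_chrom, window = win,
                site_index = site_index, log_or = log_or, role = role,
                beta0 = beta0, mafs = mafs)
  list(genotypes = as_genotypes(dosage, sites, samples), phenotype = ph,
       truth = truth)
}

#' Estimate power of the exhaustive scan and of single-marker analysis
#'
#' Simulates `n_reps` independent disease studies and, for each, computes the
#' genome-wide minimum COLL p over all locally distinct bins (across the
#' given MAF thresholds) and the minimum single-marker p. Power is the
#' fraction of replicates whose minimum p falls strictly below the
#' corresponding pre-computed significance threshold.
#'
#' @param config a [disease_sim_config()].
#' @param alpha_gecs significance threshold for the combined exhaustive scan.
#' @param alpha_sma significance threshold for single-marker analysis.
#' @param n_reps number of simulation replicates.
#' @param maf_t MAF thresholds for the scan (default `c(0.01, 0.03, 0.05)`).
#' @param seed optional integer seed.
#' @return list with `power_gecs`, `power_sma`, `se_gecs`, `se_sma`,
#'   `n_reps`, and the per-replicate minima `minp_gecs`, `minp_sma`.
#' @export
estimate_power <- function(config, alpha_gecs, alpha_sma, n_reps,
                           maf_t = c(0.01, 0.03, 0.05), seed = NULL) {
  stopifnot(inherits(config, "disease_sim_config"))
  if (n_reps < 1) stop("n_reps must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  minp_gecs <- numeric(n_reps)
  minp_sma <- numeric(n_reps)
  for (k in seq_len(n_reps)) {
    study <- simulate_disease_study(config)
    panels <- build_panels(study$genotypes, maf_t)
    if (length(panels)) {
      sc <- scan_study(panels, study$phenotype)
      minp_gecs[k] <- sc$min_p_combined
    } else {
      minp_gecs[k] <- 1
    }
    minp_sma[k] <- sma_scan(study$genotypes, study$phenotype)$min_p
  }
  p_g <- mean(minp_gecs < alpha_gecs)
  p_s <- mean(minp_sma < alpha_sma)
  list(power_gecs = p_g, power_sma = p_s,
       se_gecs = sqrt(p_g * (1 - p_g) / n_reps),
       se_sma = sqrt(p_s * (1 - p_s) / n_reps),
       n_reps = n_reps, minp_gecs = minp_gecs, minp_sma = minp_sma)
}
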