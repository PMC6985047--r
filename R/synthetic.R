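#' Synthetic cohort generation
#'
#' Generates case-level cohorts with the structure the analysis assumes:
#' ages drawn from two-component normal mixtures truncated to an
#' ascertainment window (default 20-74 years), with the mixing proportion
#' varying by molecular stratum, and ER percent positivity, ESR1 expression
#' and PAM50 labels statistically linked to the latent onset component
#' (early-onset cases are ER-low / Basal-enriched, late-onset cases ER-high
#' / Luminal-A-enriched).
#'
#' Truncation is implemented by joint rejection of (component, age) draws,
#' so the retained ages are exactly a truncated mixture with the nominal
#' mixing weight, while the marginal share of latent-early cases shifts to
#' the effective (post-truncation) weight reported alongside the cohort.
#'
#' @name synthetic
NULL

#' Define one cohort stratum
#'
#' @param label stratum name
#' @param fraction share of the cohort (all fractions must sum to 1)
#' @param mixture a `mixture_params` of two normal components giving the
#'   stratum's age distribution before truncation
#' @param er_range optional `c(lo, hi)`: ER percent drawn uniformly in the
#'   band (used when the stratum itself encodes an ER category); when NULL,
#'   ER is drawn from latent-linked defaults (early: half the cases < 1%,
#'   rest uniform 0-100; late: 85% uniform 80-100, rest uniform 0-80)
#' @param esr1_shift additive shift on the stratum's standardized ESR1 scale
#' @param pam50_probs optional list with `early` and `late` named probability
#'   vectors over LumA, LumB, Her2, Basal, Normal
#' @return a `stratum_spec` list
#' @export
stratum_spec <- function(label, fraction, mixture, er_range = NULL,
                         esr1_shift = 0, pam50_probs = NULL) {
  stopifnot(inherits(mixture, "mixture_params"),
            fraction > 0, fraction <= 1)
  structure(list(label = label, fraction = fraction, mixture = mixture,
                 er_range = er_range, esr1_shift = esr1_shift,
                 pam50_probs = pam50_probs),
            class = "stratum_spec")
}

#' Define a synthetic cohort
#'
#' @param n_total number of cases (>= 1)
#' @param strata list of [stratum_spec()] objects; fractions must sum to 1
#'   within 1e-9
#' @param truncation ascertainment window in years, default `c(20, 74)`
#' @param seed master seed; per-stratum substreams are derived from it
#' @return a `cohort_spec` list
#' @export
cohort_spec <- function(n_total, strata, truncation = c(20, 74), seed = 1L) {
  stopifnot(n_total >= 1)
  fr <- vapply(strata, `[[`, numeric(1), "fraction")
  if (abs(sum(fr) - 1) > 1e-9)
    stop("stratum fractions must sum to 1 (got ", sum(fr), ")", call. = FALSE)
  stopifnot(length(truncation) == 2L, truncation[1] < truncation[2])
  structure(list(n_total = as.integer(n_total), strata = strata,
                 truncation = truncation, seed = as.integer(seed)),
            class = "cohort_spec")
}

default_pam50_probs <- list(
  early = c(LumA = 0.20, LumB = 0.20, Her2 = 0.15, Basal = 0.40, Normal = 0.05),
  late  = c(LumA = 0.60, LumB = 0.18, Her2 = 0.08, Basal = 0.09, Normal = 0.05)
)

# largest-remainder apportionment of n into shares summing to n exactly
apportion <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# effective (post-truncation) early weight of a normal mixture
effective_early_weight <- function(mixture, truncation) {
  me <- window_mass(mixture$comp_early, truncation)
  ml <- window_mass(mixture$comp_late, truncation)
  p <- mixture$pi_early
  p * me / (p * me + (1 - p) * ml)
}

draw_stratum <- function(st, n, truncation, seed) {
  withr::with_seed(seed, {
    ages <- numeric(0); latent <- logical(0)
    while (length(ages) < n) {
      m <- max(2L * (n - length(ages)), 64L)
      z <- stats::runif(m) < st$mixture$pi_early
      a <- ifelse(z,
                  stats::rnorm(m, st$mixture$comp_early$mu, st$mixture$comp_early$sigma),
                  stats::rnorm(m, st$mixture$comp_late$mu, st$mixture$comp_late$sigma))
      keep <- a >= truncation[1] & a <= truncation[2]
      ages <- c(ages, a[keep]); latent <- c(latent, z[keep])
    }
    ages <- ages[seq_len(n)]; latent <- latent[seq_len(n)]
    er <- if (!is.null(st$er_range)) {
      stats::runif(n, st$er_range[1], st$er_range[2])
    } else {
      ifelse(latent,
             ifelse(stats::runif(n) < 0.5, stats::runif(n, 0, 1),
                    stats::runif(n, 0, 100)),
             ifelse(stats::runif(n) < 0.85, stats::runif(n, 80, 100),
                    stats::runif(n, 0, 80)))
    }
    esr1 <- stats::rnorm(n, ifelse(latent, -0.6, 0.6) + st$esr1_shift, 1)
    probs <- if (is.null(st$pam50_probs)) default_pam50_probs else st$pam50_probs
    pam50 <- ifelse(latent,
                    sample(names(probs$early), n, TRUE, probs$early),
                    sample(names(probs$late), n, TRUE, probs$late))
    grade <- ifelse(latent,
                    sample(1:3, n, TRUE, c(0.15, 0.35, 0.50)),
                    sample(1:3, n, TRUE, c(0.35, 0.45, 0.20)))
    tumor_size <- stats::rlnorm(n, ifelse(latent, log(2.2), log(1.8)), 0.4)
    node_status <- stats::rpois(n, ifelse(latent, 1.2, 0.6))
    data.frame(age = ages, er_percent = pmin(pmax(er, 0), 100),
               esr1_raw = esr1, pam50 = pam50,
               race = NA_character_, grade = grade,
               tumor_size = round(tumor_size, 1), node_status = node_status,
               stratum = st$label,
               latent_onset = ifelse(latent, "early", "late"),
               stringsAsFactors = FALSE)
  })
}

#' Generate a synthetic cohort
#'
#' Deterministic given the spec's seed. The returned table carries the
#' latent onset class of every case (column `latent_onset`) and, as
#' attribute `effective_weights`, the analytic post-truncation early weight
#' of each stratum.
#'
#' @param spec a [cohort_spec()]
#' @return a `case_table` data.frame with `n_total` rows
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  fr <- vapply(spec$strata, `[[`, numeric(1), "fraction")
  sizes <- apportion(spec$n_total, fr)
  parts <- vector("list", length(spec$strata))
  for (i in seq_along(spec$strata)) {
    if (sizes[i] == 0L) next
    sub_seed <- (spec$seed + 7919L * i) %% 2147483647L
    parts[[i]] <- draw_stratum(spec$strata[[i]], sizes[i], spec$truncation,
                               sub_seed)
  }
  out <- do.call(rbind, parts[!vapply(parts, is.null, logical(1))])
  out <- cbind(case_id = sprintf("case_%06d", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  class(out) <- c("case_table", "data.frame")
  eff <- vapply(spec$strata, function(st)
    effective_early_weight(st$mixture, spec$truncation), numeric(1))
  names(eff) <- vapply(spec$strata, `[[`, character(1), "label")
  attr(out, "effective_weights") <- eff
  attr(out, "spec") <- spec
  out
}

# printed per-stratum truth used by the preset: label, cohort count,
# nominal early weight, early/late component means, ER band
table1_strata_truth <- function() {
  data.frame(
    label = c("er_lt1", "er_1_10", "er_10_40", "er_40_80", "er_80_95", "er_ge95"),
    count = c(757, 217, 313, 733, 707, 133),
    pi_early = c(0.77, 0.88, 0.75, 0.74, 0.58, 0.50),
    mean_early = c(45, 47, 45, 46, 48, 51),
    mean_late = c(64, 67, 66, 65, 66, 67),
    er_lo = c(0, 1, 10, 40, 80, 95),
    er_hi = c(0.999, 9.999, 39.999, 79.999, 94.999, 100),
    stringsAsFactors = FALSE
  )
}

#' Cohort spec mirroring the protein-based results-table strata
#'
#' Six ER-percent strata with component means set to the printed per-stratum
#' modes and weights to the printed mixing proportions; the high (>= 80%)
#' band is split into 80-95 and >= 95 so the nested very-high subanalysis
#' has its own generative truth. Component SDs default to 9 (early) and 7
#' (late) years — a declared simulation choice, not a printed value.
#'
#' @param n_total cohort size (>= 100)
#' @param seed master seed
#' @param sd_early,sd_late within-component age SDs in years
#' @return a [cohort_spec()]
#' @export
table1_like_spec <- function(n_total, seed = 1L, sd_early = 9, sd_late = 7) {
  stopifnot(n_total >= 100)
  tr <- table1_strata_truth()
  strata <- lapply(seq_len(nrow(tr)), function(i) {
    stratum_spec(
      label = tr$label[i],
      fraction = tr$count[i] / sum(tr$count),
      mixture = mixture_params(normal_params(tr$mean_early[i], sd_early),
                               normal_params(tr$mean_late[i], sd_late),
                               tr$pi_early[i]),
      er_range = c(tr$er_lo[i], tr$er_hi[i])
    )
  })
  cohort_spec(n_total, strata, truncation = c(20, 74), seed = seed)
}

#' Serialize a cohort spec to JSON
#' @param spec a [cohort_spec()]
#' @param path output path
#' @return `path`, invisibly
#' @export
spec_to_json <- function(spec, path) {
  x <- list(n_total = spec$n_total, truncation = spec$truncation,
            seed = spec$seed,
            strata = lapply(spec$strata, function(st) {
              list(label = st$label, fraction = st$fraction,
                   pi_early = st$mixture$pi_early,
                   comp_early = params_to_list(st$mixture$comp_early),
                   comp_late = params_to_list(st$mixture$comp_late),
                   er_range = st$er_range, esr1_shift = st$esr1_shift,
                   pam50_probs = st$pam50_probs)
            }))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' Read a cohort spec from JSON
#' @param path JSON file written by [spec_to_json()]
#' @return a [cohort_spec()]
#' @export
spec_from_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  strata <- lapply(x$strata, function(st) {
    stratum_spec(st$label, st$fraction,
                 mixture_params(params_from_list(st$comp_early),
                                params_from_list(st$comp_late),
                                st$pi_early),
                 er_range = if (is.null(st$er_range)) NULL else unlist(st$er_range),
                 esr1_shift = if (is.null(st$esr1_shift)) 0 else st$esr1_shift,
                 pam50_probs = if (is.null(st$pam50_probs)) NULL else
                   lapply(st$pam50_probs, unlist))
  })
  cohort_spec(x$n_total, strata, truncation = unlist(x$truncation),
              seed = x$seed)
}
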