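# Synthetic-data generators. These emulate the statistical structure of a
# paired litterbag/bulk-soil warming experiment (four groups: warmed litterbag
# WL, control litterbag CL, warmed soil WS, control soil CS; 12 samples each =
# 4 blocks x 3 years), a functional-gene microarray, daily environmental
# forcing with a warming offset, and observation series produced by the MEND
# model itself plus noise — so every downstream stage is testable with no
# external data.

#' Evaluate an expression under a temporary RNG seed
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Design of a synthetic paired community experiment
#'
#' @param n_taxa total number of taxa in the regional pool (>= 10).
#' @param n_samples_per_group samples per group (default 12: 4 blocks x 3
#'   years, the litterbag experiment's layout).
#' @param shared_fraction fraction of the litterbag taxon pool also present in
#'   soil (default 0.79, emulating the ~79% observed sharing).
#' @param enrichment_effects list of planted effects, each a list with
#'   elements `taxa` (character ids), `fold` (> 0) and optionally `groups`
#'   (default `c("WL", "CL")`: a habitat enrichment).
#' @param dispersion_scale within-group heterogeneity multiplier; a scalar
#'   (applied to litterbag groups, soil = 1) or a named vector
#'   `c(litterbag = , soil = )`. The default `c(litterbag = 5, soil = 1)`
#'   together with `theta = 70` gives mean Bray-Curtis distances to the group
#'   centroid of roughly 0.48 (litterbag) and 0.38 (soil), the dispersion
#'   contrast the litterbag experiment showed.
#' @param litterbag_pool_fraction fraction of the regional pool colonising
#'   litterbags (default 0.6; soil hosts the shared taxa plus everything
#'   else, so soil is the richer habitat).
#' @param theta Dirichlet concentration controlling baseline within-group
#'   heterogeneity (default 70).
#' @param depth sequencing depth per sample (default 30236).
#' @param sad_sdlog log-normal species-abundance-distribution spread
#'   (default 1.5).
#' @param habitat_sdlog log-scale tilt between habitat base compositions
#'   (default 1.0).
#' @param seed integer seed.
#' @return list of class `synthetic_design`.
#' @export
synthetic_design <- function(n_taxa = 400, n_samples_per_group = 12,
                             shared_fraction = 0.79,
                             enrichment_effects = list(),
                             dispersion_scale = c(litterbag = 5, soil = 1),
                             litterbag_pool_fraction = 0.6,
                             theta = 70, depth = 30236, sad_sdlog = 1.5,
                             habitat_sdlog = 1.0, seed = 1) {
  if (n_taxa < 10) abort_fmt("n_taxa must be >= 10")
  if (shared_fraction < 0 || shared_fraction > 1)
    abort_fmt("shared_fraction must lie in [0, 1]")
  if (length(dispersion_scale) == 1L && is.null(names(dispersion_scale)))
    dispersion_scale <- c(litterbag = unname(dispersion_scale), soil = 1)
  if (!all(c("litterbag", "soil") %in% names(dispersion_scale)))
    abort_fmt("dispersion_scale must be a scalar or named over litterbag/soil")
  if (any(dispersion_scale <= 0)) abort_fmt("dispersion_scale must be > 0")
  for (ef in enrichment_effects) {
    if (is.null(ef$taxa) || is.null(ef$fold))
      abort_fmt("each enrichment effect needs 'taxa' and 'fold'")
    if (any(ef$fold <= 0)) abort_fmt("fold-changes must be > 0")
  }
  structure(list(n_taxa = as.integer(n_taxa),
                 n_samples_per_group = as.integer(n_samples_per_group),
                 shared_fraction = shared_fraction,
                 enrichment_effects = enrichment_effects,
                 dispersion_scale = dispersion_scale,
                 litterbag_pool_fraction = litterbag_pool_fraction,
                 theta = theta, depth = as.integer(depth),
                 sad_sdlog = sad_sdlog, habitat_sdlog = habitat_sdlog,
                 seed = as.integer(seed)),
            class = "synthetic_design")
}

.taxon_ids <- function(n) sprintf("taxon%05d", seq_len(n))

.rdirichlet <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  s <- sum(x)
  if (s <= 0) { # degenerate: all-zero gamma draws at tiny alpha
    x[which.max(alpha)] <- 1
    s <- 1
  }
  x / s
}

#' Generate paired litterbag/soil communities for four experimental groups
#'
#' Taxa are drawn from a regional pool with a log-normal species-abundance
#' distribution. The litterbag pool is a subset of the regional pool; a
#' `shared_fraction` of it also occurs in soil, the rest is litterbag-specific
#' (soil additionally hosts every taxon outside the litterbag pool). Sample
#' compositions are Dirichlet-multinomial around each group's base
#' composition; planted enrichment fold-changes are applied multiplicatively
#' to the base composition before normalisation.
#'
#' @param design a [synthetic_design()].
#' @return a [community_table()] with groups WL, CL, WS, CS and metadata
#'   columns habitat, treatment, year, block.
#' @export
gen_paired_communities <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  d <- design
  taxa <- .taxon_ids(d$n_taxa)
  for (ef in d$enrichment_effects) {
    missing <- setdiff(ef$taxa, taxa)
    if (length(missing))
      abort_fmt("enrichment taxon not in taxon list: %s",
                paste(utils::head(missing, 3), collapse = ", "))
  }
  with_seed(derive_seed(d$seed, 101), {
    n_lit <- max(2L, round(d$litterbag_pool_fraction * d$n_taxa))
    lit_pool <- sample(taxa, n_lit)
    n_shared <- round(d$shared_fraction * n_lit)
    shared <- if (n_shared > 0) sample(lit_pool, n_shared) else character(0)
    soil_pool <- union(shared, setdiff(taxa, lit_pool))
    if (length(soil_pool) < 2L) soil_pool <- taxa  # degenerate tiny designs

    base_fit <- stats::setNames(stats::rlnorm(d$n_taxa, 0, d$sad_sdlog), taxa)
    habitat_base <- function(pool) {
      tilt <- stats::rlnorm(length(pool), 0, d$habitat_sdlog)
      p <- base_fit[pool] * tilt
      p / sum(p)
    }
    base <- list(litterbag = habitat_base(lit_pool),
                 soil = habitat_base(soil_pool))

    groups <- c(WL = "litterbag", CL = "litterbag", WS = "soil", CS = "soil")
    treat <- c(WL = "warm", CL = "control", WS = "warm", CS = "control")
    n_g <- d$n_samples_per_group
    counts <- matrix(0L, nrow = 4L * n_g, ncol = d$n_taxa,
                     dimnames = list(NULL, taxa))
    sample_ids <- character(4L * n_g)
    meta <- vector("list", 4L)
    row <- 0L
    for (gi in seq_along(groups)) {
      g <- names(groups)[gi]
      hab <- groups[[gi]]
      p <- base[[hab]]
      for (ef in d$enrichment_effects) {
        target <- ef$groups %||% c("WL", "CL")
        if (g %in% target) {
          hit <- intersect(ef$taxa, names(p))
          p[hit] <- p[hit] * ef$fold
        }
      }
      p <- p / sum(p)
      disp <- d$dispersion_scale[[hab]]
      alpha <- p * d$theta / disp
      for (i in seq_len(n_g)) {
        row <- row + 1L
        pi <- .rdirichlet(alpha)
        cnt <- stats::rmultinom(1L, d$depth, pi)[, 1L]
        counts[row, names(p)] <- cnt
        sample_ids[row] <- sprintf("%s_%02d", g, i)
      }
      meta[[gi]] <- data.frame(
        sample_id = sprintf("%s_%02d", g, seq_len(n_g)),
        group = g, habitat = hab, treatment = treat[[gi]],
        year = 2015 + ((seq_len(n_g) - 1L) %% 3L) + 1L,
        block = ((seq_len(n_g) - 1L) %/% 3L) + 1L,
        stringsAsFactors = FALSE)
    }
    rownames(counts) <- sample_ids
    community_table(counts, do.call(rbind, meta))
  })
}

#' Generate a per-taxon genomic trait reference
#'
#' A stated fraction of the design's taxa carry traits (emulating the fraction
#' of sequences that can be matched to complete genomes); the rest are flagged
#' unmatched.
#'
#' @param design a [synthetic_design()] (supplies taxon ids and the seed).
#' @param match_fraction fraction of taxa with matched genomes, in (0, 1]
#'   (default 0.2156).
#' @param rrn_range integer range of rrn copy numbers (default c(1, 15)).
#' @param size_range_mbp genome size range in Mbp (default c(2, 10)).
#' @param gc_range_pct GC content range in percent (default c(30, 70)).
#' @return a [trait_reference()] with `round(match_fraction * n_taxa)` matched
#'   taxa.
#' @export
gen_trait_reference <- function(design, match_fraction = 0.2156,
                                rrn_range = c(1, 15),
                                size_range_mbp = c(2, 10),
                                gc_range_pct = c(30, 70)) {
  stopifnot(inherits(design, "synthetic_design"))
  if (design$n_taxa < 1L) abort_fmt("empty taxon list")
  if (match_fraction <= 0 || match_fraction > 1)
    abort_fmt("match_fraction must lie in (0, 1]")
  chk <- function(r, what) {
    if (length(r) != 2L || any(r <= 0) || r[1L] > r[2L])
      abort_fmt("%s must be a positive ordered range", what)
  }
  chk(rrn_range, "rrn_range"); chk(size_range_mbp, "size_range_mbp")
  chk(gc_range_pct, "gc_range_pct")
  if (rrn_range[1L] < 1) abort_fmt("rrn copies must be >= 1")
  if (gc_range_pct[2L] >= 100) abort_fmt("gc_range_pct must lie below 100")
  taxa <- .taxon_ids(design$n_taxa)
  n_match <- round(match_fraction * design$n_taxa)
  with_seed(derive_seed(design$seed, 202), {
    matched <- sample(taxa, n_match)
    rrn <- size <- gc <- rep(NA_real_, design$n_taxa)
    idx <- match(matched, taxa)
    rrn_values <- seq.int(rrn_range[1L], rrn_range[2L])
    rrn[idx] <- rrn_values[sample.int(length(rrn_values), n_match,
                                      replace = TRUE)]
    size[idx] <- stats::runif(n_match, size_range_mbp[1L], size_range_mbp[2L])
    gc[idx] <- stats::runif(n_match, gc_range_pct[1L], gc_range_pct[2L])
    trait_reference(taxa, rrn, size, gc)
  })
}

#' Catalogue of carbon-decomposition functional genes
#'
#' Gene names and carbon-substrate categories used as the default annotation
#' universe for [gen_probe_table()], covering cellulose, starch,
#' hemicellulose, chitin, pectin, lignin, cutin, terpene and glyoxylate-cycle
#' genes.
#'
#' @return data.frame with columns `gene` and `category`.
#' @export
carbon_gene_catalog <- function() {
  data.frame(
    gene = c("endoglucanase", "cellobiase", "exoglucanase", "axe",
             "amyA", "glucoamylase", "nplT", "pulA",
             "ara", "mannanase", "xylanase",
             "acetylglucosaminidase", "chitinase", "chitin_deacetylase",
             "aceA", "aceB", "cutinase",
             "mnp", "glx", "phenol_oxidase",
             "pme", "rgl", "endopolygalacturonase", "exopolygalacturonase",
             "cdh", "limEH", "vanA", "vdh"),
    category = c(rep("cellulose", 4), rep("starch", 4),
                 rep("hemicellulose", 3), rep("chitin", 3),
                 rep("glyoxylate_cycle", 2), "cutin",
                 rep("lignin", 3), rep("pectin", 4),
                 rep("terpenes", 2), rep("aromatics", 2)),
    stringsAsFactors = FALSE
  )
}

#' Generate a functional-gene probe intensity table
#'
#' Log-normal probe intensities with Bernoulli detection (zeros encode
#' non-detection) and planted per-gene warming effects.
#'
#' @param n_probes number of probes.
#' @param genes annotation universe: a character vector of gene names or a
#'   data.frame with `gene` and `category` columns (default
#'   [carbon_gene_catalog()]).
#' @param groups character vector of group labels, one per sample.
#' @param detection_rate probability a probe is detected in a sample, (0, 1].
#' @param effect_map named list or vector, gene -> fold-change applied to
#'   samples whose group is in `treatment_groups`.
#' @param seed integer seed.
#' @param treatment_groups groups receiving the planted effects (default: all
#'   groups starting with `"W"`, i.e. the warmed groups).
#' @param base_meanlog,base_sdlog log-scale location spread across probes
#'   (defaults log(1000) and 1).
#' @param noise_sdlog within-probe log-scale noise across samples
#'   (default 0.2).
#' @return a [probe_table()].
#' @export
gen_probe_table <- function(n_probes, genes = carbon_gene_catalog(), groups,
                            detection_rate = 0.8, effect_map = list(),
                            seed = 1,
                            treatment_groups = grep("^W", unique(groups),
                                                    value = TRUE),
                            base_meanlog = log(1000), base_sdlog = 1,
                            noise_sdlog = 0.2) {
  if (detection_rate <= 0 || detection_rate > 1)
    abort_fmt("detection_rate must lie in (0, 1]")
  if (is.character(genes)) genes <- data.frame(gene = genes,
                                               category = "unknown")
  unknown <- setdiff(names(effect_map), genes$gene)
  if (length(unknown)) abort_fmt("unknown gene in effect_map: %s",
                                 paste(unknown, collapse = ", "))
  groups <- as.character(groups)
  n_samp <- length(groups)
  sample_ids <- sprintf("%s_%02d", groups, stats::ave(seq_len(n_samp),
                                                      groups,
                                                      FUN = seq_along))
  if (n_probes == 0L) {
    return(probe_table(matrix(numeric(0), 0, n_samp,
                              dimnames = list(NULL, sample_ids)),
                       data.frame(probe_id = character(0),
                                  gene = character(0),
                                  category = character(0)),
                       groups))
  }
  with_seed(derive_seed(seed, 303), {
    gi <- sample.int(nrow(genes), n_probes, replace = TRUE)
    ann <- data.frame(probe_id = sprintf("probe%05d", seq_len(n_probes)),
                      gene = genes$gene[gi], category = genes$category[gi],
                      stringsAsFactors = FALSE)
    mu <- stats::rnorm(n_probes, base_meanlog, base_sdlog)
    treat <- groups %in% treatment_groups
    lfold <- rep(0, n_probes)
    for (g in names(effect_map))
      lfold[ann$gene == g] <- log(effect_map[[g]])
    intensity <- matrix(0, n_probes, n_samp,
                        dimnames = list(ann$probe_id, sample_ids))
    for (j in seq_len(n_samp)) {
      ml <- mu + if (treat[j]) lfold else 0
      v <- stats::rlnorm(n_probes, ml, noise_sdlog)
      det <- stats::runif(n_probes) <= detection_rate
      intensity[, j] <- v * det
    }
    probe_table(intensity, ann, groups)
  })
}

#' Design of a synthetic daily forcing series
#'
#' @param n_days series length (default 1095 = 3 years).
#' @param mean_temperature mean soil temperature, degree C (default 16.3).
#' @param seasonal_amplitude seasonal temperature amplitude, degree C
#'   (default 10).
#' @param warming_offset additive warming offset, degree C (default 1.8).
#' @param moisture_mean mean volumetric moisture (default 0.30).
#' @param moisture_reduction proportional moisture decrease under warming
#'   (default 0.17).
#' @param litter_input_mean mean litter-fall carbon input, mg C g^-1 soil
#'   d^-1 (default 0.002).
#' @param litter_seasonal_amplitude relative seasonal amplitude of litter
#'   input (default 0.8: input follows plant production seasonality).
#' @param noise_sd named list of daily noise standard deviations
#'   (`temperature` degree C, `moisture` v/v, `litter` mg C g^-1 d^-1).
#' @param seed integer seed.
#' @return list of class `forcing_design`.
#' @export
forcing_design <- function(n_days = 1095, mean_temperature = 16.3,
                           seasonal_amplitude = 10, warming_offset = 1.8,
                           moisture_mean = 0.30, moisture_reduction = 0.17,
                           litter_input_mean = 0.002,
                           litter_seasonal_amplitude = 0.8,
                           noise_sd = list(temperature = 0.8,
                                           moisture = 0.02,
                                           litter = 4e-4),
                           seed = 1) {
  if (n_days < 1) abort_fmt("n_days must be >= 1")
  if (seasonal_amplitude < 0) abort_fmt("negative seasonal amplitude")
  if (moisture_mean <= 0 || moisture_mean > 1)
    abort_fmt("moisture_mean must lie in (0, 1]")
  if (litter_input_mean < 0) abort_fmt("litter input must be >= 0")
  structure(list(n_days = as.integer(n_days),
                 mean_temperature = mean_temperature,
                 seasonal_amplitude = seasonal_amplitude,
                 warming_offset = warming_offset,
                 moisture_mean = moisture_mean,
                 moisture_reduction = moisture_reduction,
                 litter_input_mean = litter_input_mean,
                 litter_seasonal_amplitude = litter_seasonal_amplitude,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "forcing_design")
}

#' Generate a daily forcing series
#'
#' Temperature is sinusoidal-seasonal plus noise, with the design's warming
#' offset added when `warmed = TRUE`; moisture is multiplied by
#' `(1 - moisture_reduction)` under warming; litter input follows the same
#' seasonality and is truncated at zero. Warmed and control series from the
#' same design use independent noise streams (two sets of field plots).
#'
#' @param design a [forcing_design()].
#' @param warmed logical: warmed plots (TRUE) or control plots (FALSE).
#' @return a [mend_forcing()] data.frame.
#' @export
gen_forcing <- function(design, warmed = FALSE) {
  stopifnot(inherits(design, "forcing_design"))
  d <- design
  day <- seq_len(d$n_days)
  season <- sin(2 * pi * day / 365)
  with_seed(derive_seed(d$seed, if (warmed) 404 else 405), {
    temp <- d$mean_temperature + d$seasonal_amplitude * season +
      stats::rnorm(d$n_days, 0, d$noise_sd$temperature) +
      if (warmed) d$warming_offset else 0
    moist <- (d$moisture_mean +
                stats::rnorm(d$n_days, 0, d$noise_sd$moisture)) *
      (if (warmed) 1 - d$moisture_reduction else 1)
    moist <- pmin(1, pmax(1e-3, moist))
    litter <- d$litter_input_mean * (1 + d$litter_seasonal_amplitude * season) +
      stats::rnorm(d$n_days, 0, d$noise_sd$litter)
    litter <- pmax(0, litter)
    mend_forcing(day, temp, moist, litter)
  })
}

#' Generate observation series from the MEND model plus noise
#'
#' Runs [mend_simulate()] with the supplied parameters and adds noise:
#' heterotrophic respiration and microbial biomass carbon get multiplicative
#' log-normal noise (both are positive and right-skewed); the
#' cellulose-decomposing gene-abundance series is an affine transform of the
#' hydrolytic enzyme pool, `a * EP2(t) + b` (a > 0) plus additive Gaussian
#' noise scaled to the signal's standard deviation, so its noise-free
#' correlation with EP2 is exactly 1.
#'
#' @param params [mend_params()].
#' @param init [mend_state()].
#' @param forcing [mend_forcing()].
#' @param noise_sd_map named list: `rh` and `mbc` log-scale sdlog, `gene`
#'   noise-to-signal sd ratio (defaults all 0.1).
#' @param seed integer seed.
#' @param obs_days days with Rh/MBC observations (default every 7th day).
#' @param gene_days days with gene-abundance observations (default every 30th
#'   day).
#' @param gene_a,gene_b affine coefficients of the gene series (defaults 1000
#'   and 50; `gene_a` must be > 0).
#' @return object of class `mend_observations`: list with `series` (named
#'   list of data.frames date/day/value for `rh`, `mbc`, `gene`) and
#'   `trajectory` (the noise-free `mend_trajectory`).
#' @export
gen_observations <- function(params, init, forcing,
                             noise_sd_map = list(rh = 0.1, mbc = 0.1,
                                                 gene = 0.1),
                             seed = 1, obs_days = NULL, gene_days = NULL,
                             gene_a = 1000, gene_b = 50) {
  if (any(unlist(noise_sd_map) < 0)) abort_fmt("negative noise sd")
  if (gene_a <= 0) abort_fmt("gene_a must be > 0")
  traj <- mend_simulate(params, init, forcing)
  n <- nrow(forcing)
  if (is.null(obs_days)) obs_days <- seq.int(7L, n, by = 7L)
  if (is.null(gene_days)) gene_days <- seq.int(30L, n, by = 30L)
  if (!length(obs_days) || !length(gene_days))
    abort_fmt("forcing too short for the observation schedule")
  with_seed(derive_seed(seed, 506), {
    lnoise <- function(x, sdlog) {
      if (sdlog == 0) return(x)
      x * stats::rlnorm(length(x), -sdlog^2 / 2, sdlog)
    }
    rh <- lnoise(traj$rh[obs_days], noise_sd_map$rh)
    mbc <- lnoise(traj$states[obs_days, "BA"] + traj$states[obs_days, "BD"],
                  noise_sd_map$mbc)
    ep2 <- traj$states[gene_days, "EP2"]
    gene0 <- gene_a * ep2 + gene_b
    gsd <- noise_sd_map$gene * stats::sd(gene0)
    gene <- gene0 + if (gsd > 0) stats::rnorm(length(gene0), 0, gsd) else 0
    mk <- function(days, values) data.frame(date = forcing$date[days],
                                            day = days, value = values)
    structure(list(series = list(rh = mk(obs_days, rh),
                                 mbc = mk(obs_days, mbc),
                                 gene = mk(gene_days, gene)),
                   trajectory = traj),
              class = "mend_observations")
  })
}
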