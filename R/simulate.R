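# Synthetic study generator emulating the 4-site x 3-treatment x 3-replicate
# long-term fertilization design, plus planted-correlation and path-model
# fixtures for the network and SEM stages.
#
# Per sample, a gene's expected relative abundance is
#   baseline * input multipliers * exp(coupling * centered covariate) * lognormal noise,
# and its read count is negative-binomial around expectation * library size.
# All injected effects are recorded as ground truth.

# treatment -> contrast membership per site, mirroring a design where each
# site contributes one -P vs +P and one -N vs +N two-treatment comparison
.default_design <- function() {
  rbind(
    data.frame(site = "GZ", treatment = c("NPKM", "NKM", "PKM"),
               p_contrast = c("plusP", "minusP", NA),
               n_contrast = c("plusN", NA, "minusN"),
               stringsAsFactors = FALSE),
    data.frame(site = "JX", treatment = c("CK", "N", "P"),
               p_contrast = c("minusP", NA, "plusP"),
               n_contrast = c("minusN", "plusN", NA),
               stringsAsFactors = FALSE),
    data.frame(site = "SY", treatment = c("CK", "N", "NP"),
               p_contrast = c(NA, "minusP", "plusP"),
               n_contrast = c("minusN", "plusN", NA),
               stringsAsFactors = FALSE),
    data.frame(site = "HB", treatment = c("CK", "N", "P"),
               p_contrast = c("minusP", NA, "plusP"),
               n_contrast = c("minusN", "plusN", NA),
               stringsAsFactors = FALSE))
}

# default per-category effect multipliers: the group-level shifts the field
# study reports (+N: -11.5% solubilization/mineralization, -4.86% uptake,
# +16.1% phoR; +P: +2.09%, +6.27%, -10.7% phoR)
.default_multipliers <- function() {
  list(
    N = c(category.solubilization_mineralization = 0.885,
          category.uptake_transport = 0.9514,
          gene.phoR = 1.161),
    P = c(category.solubilization_mineralization = 1.0209,
          category.uptake_transport = 1.0627,
          gene.phoR = 0.893))
}

#' Configuration for the synthetic field study
#'
#' Defaults state the study design being emulated: 4 sites x 3 treatments x
#' 3 replicates (36 samples), ~35 million annotated reads per sample scaled
#' down by `library_scale` for desk-scale testing, group-level effect
#' multipliers equal to the reported category shifts, +N lowering pH by
#' 0.40-1.57 units, +P lowering the N:P ratio, lognormal per-gene noise and
#' negative-binomial read counts.
#'
#' @param catalog A `gene_catalog` (defaults to the packaged one).
#' @param design data.frame of site/treatment/contrast rows; defaults to the
#'   emulated 4-site design.
#' @param n_reps Replicates per treatment (>= 2, default 3).
#' @param baseline Named per-gene baseline mean relative abundance
#'   (percent); defaults to log-uniform values in \[0.002, 0.06\]% drawn once
#'   from the config seed.
#' @param library_mean Mean annotated reads per sample before scaling
#'   (default 3.5e7).
#' @param library_scale Depth scaling for testing (default 1e-3).
#' @param library_cv Coefficient of variation of library sizes.
#' @param multipliers List with `N` and `P` named multiplier vectors; names
#'   are `category.<label>` or `gene.<symbol>`.
#' @param ph_baseline Named per-site baseline pH.
#' @param ph_shift_n Range of pH decrease under +N (units).
#' @param np_baseline Named per-site baseline N:P ratio.
#' @param np_shift_p Range of the multiplicative N:P reduction under +P.
#' @param coupling Named per-gene coefficients linking centered pH to log
#'   abundance (default all 0; effects enter through multipliers).
#' @param sigma_ln Lognormal noise sd on the log scale (default 0.15).
#' @param nb_dispersion Negative-binomial dispersion (1/size; default 0.05).
#' @param seed Integer seed (mandatory).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(catalog = load_catalog(),
                              design = .default_design(),
                              n_reps = 3,
                              baseline = NULL,
                              library_mean = 3.5e7,
                              library_scale = 1e-3,
                              library_cv = 0.05,
                              multipliers = .default_multipliers(),
                              ph_baseline = c(GZ = 5.6, JX = 5.0, SY = 6.3,
                                              HB = 7.0),
                              ph_shift_n = c(0.40, 1.57),
                              np_baseline = c(GZ = 1.6, JX = 1.9, SY = 1.4,
                                              HB = 2.1),
                              np_shift_p = c(0.55, 0.80),
                              coupling = NULL,
                              sigma_ln = 0.15,
                              nb_dispersion = 0.05,
                              seed = 1) {
  abort_if(n_reps < 2, "simulation_config: n_reps must be >= 2")
  abort_if(is.null(seed), "simulation_config: seed is mandatory")
  genes <- catalog$gene_symbol
  if (is.null(baseline)) {
    baseline <- with_seed(seed + 101L,
      stats::setNames(exp(stats::runif(length(genes), log(0.002), log(0.06))),
                      genes))
  }
  abort_if(!all(genes %in% names(baseline)),
           "simulation_config: baseline must cover all catalog genes")
  for (cn in names(multipliers)) {
    abort_if(any(multipliers[[cn]] <= 0),
             "simulation_config: multipliers must be > 0")
  }
  if (is.null(coupling)) coupling <- stats::setNames(rep(0, length(genes)), genes)
  sites <- unique(design$site)
  abort_if(!all(sites %in% names(ph_baseline)) ||
             !all(sites %in% names(np_baseline)),
           "simulation_config: pH / N:P baselines must cover all sites")
  structure(list(catalog = catalog, design = design, n_reps = n_reps,
                 baseline = baseline[genes], library_mean = library_mean,
                 library_scale = library_scale, library_cv = library_cv,
                 multipliers = multipliers, ph_baseline = ph_baseline,
                 ph_shift_n = ph_shift_n, np_baseline = np_baseline,
                 np_shift_p = np_shift_p, coupling = coupling,
                 sigma_ln = sigma_ln, nb_dispersion = nb_dispersion,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# multiplier applying to one gene in one contrast arm
.gene_multiplier <- function(cfg, gene, contrast, flag) {
  if (is.na(flag) || flag %in% c("minusP", "minusN")) return(1)
  mult <- cfg$multipliers[[contrast]]
  if (is.null(mult)) return(1)
  out <- 1
  gkey <- paste0("gene.", gene)
  ckey <- paste0("category.",
                 cfg$catalog$category[cfg$catalog$gene_symbol == gene])
  # a gene-specific multiplier overrides the category-level one
  if (gkey %in% names(mult)) out <- unname(mult[gkey])
  else if (ckey %in% names(mult)) out <- unname(mult[ckey])
  out
}

.default_taxa <- function() {
  c("Alphaproteobacteria", "Betaproteobacteria", "Gammaproteobacteria",
    "Actinobacteria", "Acidobacteria", "Bacteroidetes", "Firmicutes",
    "Chloroflexi")
}

#' Simulate a synthetic long-term fertilization study
#'
#' Deterministic given `config$seed`. Produces a KO count table (one row per
#' catalog KO), sample metadata with soil covariates, a class-level taxon
#' count table, and a complete ground-truth record of every injected effect.
#'
#' @param config A `simulation_config`.
#' @return A `synthetic_study`: list with `ko_table`, `metadata`,
#'   `taxon_table`, `truth`.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  with_seed(cfg$seed, {
    design <- cfg$design[rep(seq_len(nrow(cfg$design)), each = cfg$n_reps), ]
    design$replicate <- rep(seq_len(cfg$n_reps), times = nrow(cfg$design))
    design$sample_id <- paste(design$site, design$treatment, design$replicate,
                              sep = "_")
    n <- nrow(design)
    genes <- cfg$catalog$gene_symbol
    komap <- catalog_ko_map(cfg$catalog)

    # covariates: pH drops under +N; N:P shrinks under +P; P pools rise with +P
    ph_shift <- stats::runif(n, cfg$ph_shift_n[1L], cfg$ph_shift_n[2L])
    plus_n <- !is.na(design$n_contrast) & design$n_contrast == "plusN"
    plus_p <- !is.na(design$p_contrast) & design$p_contrast == "plusP"
    ph <- cfg$ph_baseline[design$site] - ifelse(plus_n, ph_shift, 0) +
      stats::rnorm(n, 0, 0.08)
    np_mult <- stats::runif(n, cfg$np_shift_p[1L], cfg$np_shift_p[2L])
    np <- cfg$np_baseline[design$site] * ifelse(plus_p, np_mult, 1) *
      exp(stats::rnorm(n, 0, 0.05))
    total_p <- 0.65 + ifelse(plus_p, stats::runif(n, 0.18, 0.90), 0) +
      stats::rnorm(n, 0, 0.04)
    total_n <- np * total_p
    avail_p <- 25 + ifelse(plus_p, stats::runif(n, 33, 163), 0) +
      stats::rnorm(n, 0, 3)
    mbp <- 18 + ifelse(plus_p, stats::runif(n, 7.4, 44.5), 0) +
      stats::rnorm(n, 0, 2)
    pfrac <- sapply(c(al_p = 30, fe_p = 55, ca_p = 80, o_p = 45), function(b) {
      pmax(0.5, b * (1 + ifelse(plus_p, stats::runif(n, 0.2, 0.8), 0)) *
             exp(stats::rnorm(n, 0, 0.1)))
    })

    meta <- as_sample_metadata(data.frame(
      sample_id = design$sample_id, site = design$site,
      treatment = design$treatment, p_contrast = design$p_contrast,
      n_contrast = design$n_contrast, replicate = design$replicate,
      pH = round(ph, 3), np_ratio = round(np, 4),
      total_n = round(total_n, 4), total_p = round(total_p, 4),
      avail_p = round(avail_p, 2), mbp = round(mbp, 2),
      al_p = round(pfrac[, "al_p"], 2), fe_p = round(pfrac[, "fe_p"], 2),
      ca_p = round(pfrac[, "ca_p"], 2), o_p = round(pfrac[, "o_p"], 2),
      stringsAsFactors = FALSE))

    # library sizes (total annotated reads)
    lib <- round(cfg$library_mean * cfg$library_scale *
                   exp(stats::rnorm(n, 0, cfg$library_cv)))

    # expected relative abundance (percent) per gene x sample
    ph_centered <- ph - mean(ph)
    expected <- matrix(0, length(genes), n, dimnames = list(genes, design$sample_id))
    for (gi in seq_along(genes)) {
      g <- genes[gi]
      mult <- vapply(seq_len(n), function(si) {
        .gene_multiplier(cfg, g, "N", design$n_contrast[si]) *
          .gene_multiplier(cfg, g, "P", design$p_contrast[si])
      }, 0)
      expected[gi, ] <- cfg$baseline[g] * mult *
        exp(cfg$coupling[g] * ph_centered)
    }
    noisy <- expected * exp(matrix(stats::rnorm(length(expected), 0, cfg$sigma_ln),
                                   nrow(expected)))

    # counts: NB around expectation, split evenly across a gene's KO IDs
    all_kos <- unique(unlist(komap))
    counts <- matrix(0, length(all_kos), n,
                     dimnames = list(all_kos, design$sample_id))
    size <- 1 / cfg$nb_dispersion
    for (gi in seq_along(genes)) {
      kos <- komap[[genes[gi]]]
      mu <- (noisy[gi, ] / 100) * lib / length(kos)
      for (ko in kos) {
        counts[ko, ] <- counts[ko, ] +
          stats::rnbinom(n, mu = mu, size = size)
      }
    }
    ko_table <- ko_count_table(counts, total_annotated = stats::setNames(lib,
                                                        design$sample_id))

    # class-level taxon table with its own contrast multipliers
    taxa <- .default_taxa()
    taxon_mult <- list(
      P = c(Alphaproteobacteria = 1.25, Actinobacteria = 1.2,
            Betaproteobacteria = 0.8, Acidobacteria = 0.85),
      N = c(Alphaproteobacteria = 0.8, Actinobacteria = 0.75,
            Gammaproteobacteria = 0.8, Acidobacteria = 1.2))
    taxon_base <- stats::setNames(exp(stats::runif(length(taxa), log(0.001),
                                                   log(0.01))), taxa)
    taxon_counts <- matrix(0, length(taxa), n,
                           dimnames = list(taxa, design$sample_id))
    for (ti in seq_along(taxa)) {
      tx <- taxa[ti]
      mult <- rep(1, n)
      if (tx %in% names(taxon_mult$N)) {
        mult <- mult * ifelse(plus_n, taxon_mult$N[tx], 1)
      }
      if (tx %in% names(taxon_mult$P)) {
        mult <- mult * ifelse(plus_p, taxon_mult$P[tx], 1)
      }
      mu <- taxon_base[tx] * mult * lib *
        exp(stats::rnorm(n, 0, cfg$sigma_ln))
      taxon_counts[ti, ] <- stats::rnbinom(n, mu = mu, size = size)
    }

    truth <- list(baseline = cfg$baseline, multipliers = cfg$multipliers,
                  coupling = cfg$coupling, taxon_multipliers = taxon_mult,
                  taxon_baseline = taxon_base,
                  ph_shift_n = cfg$ph_shift_n, np_shift_p = cfg$np_shift_p,
                  expected_abundance = expected, library_sizes = lib,
                  seed = cfg$seed)
    structure(list(ko_table = ko_table, metadata = meta,
                   taxon_table = taxon_counts, truth = truth),
              class = "synthetic_study")
  })
}

#' Simulate a profile with planted correlation blocks
#'
#' Features within a block share a latent factor with loading
#' `sqrt(target_rho)`, giving within-block pairwise correlation close to
#' `target_rho`; across-block and background features are independent
#' standard normal. The fixture exercises RMT threshold detection and
#' network construction. Block sizes may be given as a plain numeric vector
#' (blocks then occupy consecutive feature indices); explicit index vectors
#' must have length >= 2.
#'
#' @param n_features Total feature count.
#' @param blocks List of integer vectors (disjoint feature indices) or of
#'   block sizes (then assigned consecutively from feature 1).
#' @param n_samples Number of samples.
#' @param target_rho Within-block correlation target (default 0.9).
#' @param seed RNG seed.
#' @return Feature x sample matrix with a `blocks` attribute.
#' @export
simulate_planted_network <- function(n_features, blocks, n_samples,
                                     target_rho = 0.9, seed = 1) {
  if (!is.list(blocks)) {
    # plain numeric vector = block sizes, assigned consecutive indices
    sizes <- as.integer(blocks)
    abort_if(any(sizes < 1) || sum(sizes) > n_features,
             "simulate_planted_network: block sizes invalid for n_features")
    ends <- cumsum(sizes)
    blocks <- Map(function(s, e) seq(e - s + 1L, e), sizes, ends)
  }
  idx_all <- unlist(blocks)
  abort_if(length(idx_all) > 0 && max(idx_all) > n_features,
           "simulate_planted_network: block index exceeds n_features")
  abort_if(anyDuplicated(idx_all) > 0,
           "simulate_planted_network: blocks must be disjoint")
  with_seed(seed, {
    x <- matrix(stats::rnorm(n_features * n_samples), n_features, n_samples)
    a <- sqrt(target_rho)
    for (b in blocks) {
      z <- stats::rnorm(n_samples)
      x[b, ] <- a * matrix(z, length(b), n_samples, byrow = TRUE) +
        sqrt(1 - target_rho) * matrix(stats::rnorm(length(b) * n_samples),
                                      length(b), n_samples)
    }
    dimnames(x) <- list(paste0("f", seq_len(n_features)),
                        paste0("s", seq_len(n_samples)))
    attr(x, "blocks") <- blocks
    x
  })
}

#' Simulate data from a recursive path model
#'
#' Generates variables in topological order: exogenous variables are
#' standard normal; each endogenous variable is the linear combination of
#' its parents plus a disturbance scaled so the variable has unit variance
#' when the implied variance permits (otherwise unit-variance disturbance).
#'
#' @param model A `path_model`.
#' @param coefficients Named numeric vector, names `"from->to"`, one per
#'   edge (missing edges default to 0).
#' @param n Sample size.
#' @param seed RNG seed.
#' @return data.frame n x variables, with a `truth` attribute holding the
#'   standardized generating coefficients.
#' @export
simulate_path_data <- function(model, coefficients, n, seed = 1) {
  stopifnot(inherits(model, "path_model"))
  keys <- paste0(model$edges$from, "->", model$edges$to)
  beta <- stats::setNames(rep(0, length(keys)), keys)
  known <- intersect(names(coefficients), keys)
  beta[known] <- coefficients[known]
  extra <- setdiff(names(coefficients), keys)
  abort_if(length(extra) > 0, "simulate_path_data: coefficient(s) for ",
           "non-model edge(s): ", paste(extra, collapse = ", "))
  with_seed(seed, {
    out <- matrix(0, n, length(model$variables),
                  dimnames = list(NULL, model$variables))
    for (v in model$variables) {
      if (v %in% model$exogenous) {
        out[, v] <- stats::rnorm(n)
      } else {
        parents <- model$edges$from[model$edges$to == v]
        b <- beta[paste0(parents, "->", v)]
        lin <- out[, parents, drop = FALSE] %*% b
        expl_var <- stats::var(as.numeric(lin)) * (n - 1) / n
        resid_sd <- if (expl_var < 1) sqrt(1 - expl_var) else 1
        out[, v] <- lin + stats::rnorm(n, 0, resid_sd)
      }
    }
    out <- as.data.frame(out)
    attr(out, "truth") <- beta
    out
  })
}
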