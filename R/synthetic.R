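#' Simulated control panels and two-group tumor cohorts
#'
#' Generates per-bin coverage with negative-binomial noise on a bin grid:
#' diploid controls, and tumors carrying arm-level copy-number events
#' drawn from a catalog with group-specific inclusion probabilities, mixed
#' with normal cells at a configurable purity. The default configuration
#' mirrors the reference study's conditions: an hg19 grid at 200-kb bins,
#' 24 metastatic-like vs 5 non-metastatic-like tumors, gains on 1q and 8q
#' and losses on 12q, 16q, 17p and 17q, and a depth of ~645 fragments per
#' bin (10 million read pairs spread over the ~15,500-bin grid).
#'
#' @name synthetic_data
NULL

#' Default arm-level aberration catalog
#'
#' Single-copy gains on 1q and 8q, single-copy losses on 12q, 16q, 17p
#' and 17q — the recurrent arm-level events the score is built to detect.
#'
#' @return data.frame with \code{arm}, \code{direction}, \code{copy_number}.
#' @export
default_aberration_catalog <- function() {
  data.frame(
    arm = c("1q", "8q", "12q", "16q", "17p", "17q"),
    direction = c("gain", "gain", "loss", "loss", "loss", "loss"),
    copy_number = c(3L, 3L, 1L, 1L, 1L, 1L))
}

#' Simulation configuration
#'
#' @param genome a \code{genome_build} (default \code{\link{hg19_genome}}).
#' @param bin_width bin width in bp (default 200 kb).
#' @param depth mean fragments per bin in a diploid sample (default 645,
#'   the 10-million-read-pair preset on the default grid).
#' @param dispersion negative-binomial size parameter; per-bin variance is
#'   \code{mu + mu^2/dispersion}, so larger values approach Poisson.
#'   The default 150 gives a ~9\% coefficient of variation at the default
#'   depth — overdispersed relative to Poisson (FFPE input) while keeping
#'   single-copy arm events at purity >= 0.6 above the fixed |Z| = 3 call
#'   threshold, which the scoring model presumes.
#' @param n_controls diploid panel size (default 20).
#' @param n_metastatic,n_non_metastatic tumor group sizes (defaults 24
#'   and 5).
#' @param p_event_metastatic,p_event_non_metastatic per-event inclusion
#'   probability over the catalog in each group (defaults 0.6 and 0.1).
#' @param purity_range tumor-cell fraction range, sampled uniformly
#'   (default c(0.6, 0.9)).
#' @param catalog aberration catalog data.frame
#'   (\code{\link{default_aberration_catalog}}).
#' @param seed integer seed; every simulated output is reproducible from
#'   it alone.
#' @return a \code{sim_config} list (with the derived \code{grid}).
#' @export
sim_config <- function(genome = hg19_genome(), bin_width = 200000,
                       depth = 645, dispersion = 150, n_controls = 20L,
                       n_metastatic = 24L, n_non_metastatic = 5L,
                       p_event_metastatic = 0.6,
                       p_event_non_metastatic = 0.1,
                       purity_range = c(0.6, 0.9),
                       catalog = default_aberration_catalog(),
                       seed = 1L) {
  stopifnot(depth > 0, dispersion > 0, n_controls >= 2,
            p_event_metastatic >= 0, p_event_metastatic <= 1,
            p_event_non_metastatic >= 0, p_event_non_metastatic <= 1,
            all(purity_range >= 0), all(purity_range <= 1))
  grid <- make_bins(genome, bin_width)
  arms <- arm_intervals(genome)
  missing_arms <- setdiff(catalog$arm, arms$label)
  if (length(missing_arms))
    stop("catalog arms not in build: ", paste(missing_arms, collapse = ", "))
  structure(list(genome = genome, bin_width = bin_width, grid = grid,
                 depth = depth, dispersion = dispersion,
                 n_controls = as.integer(n_controls),
                 n_metastatic = as.integer(n_metastatic),
                 n_non_metastatic = as.integer(n_non_metastatic),
                 p_event = c(metastatic = p_event_metastatic,
                             non_metastatic = p_event_non_metastatic),
                 purity_range = purity_range, catalog = catalog,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Expected coverage factor of a copy-number state at a given purity
#'
#' Standard two-population mixture: a fraction \code{purity} of cells at
#' \code{copy_number} copies, the rest diploid, relative to a fully
#' diploid sample: \code{(2 (1 - purity) + purity * cn) / 2}.
#'
#' @param copy_number integer copy number (>= 0).
#' @param purity tumor-cell fraction in [0, 1].
#' @return multiplicative coverage factor.
#' @export
expected_coverage_factor <- function(copy_number, purity) {
  if (any(copy_number < 0)) stop("copy number must be non-negative")
  stopifnot(all(purity >= 0), all(purity <= 1))
  (2 * (1 - purity) + purity * copy_number) / 2
}

#' Simulate one diploid control profile
#'
#' @param config a \code{sim_config}.
#' @param sample_id profile label.
#' @return a \code{coverage_profile} with independent NB(mu = depth,
#'   size = dispersion) bin counts.
#' @export
simulate_control <- function(config, sample_id = "control") {
  nb <- n_bins(config$grid)
  counts <- stats::rnbinom(nb, mu = config$depth, size = config$dispersion)
  coverage_profile(sample_id, config$grid, counts)
}

#' Simulate one tumor profile with known copy-number truth
#'
#' Events are sampled independently from the catalog at the group's
#' inclusion probability; purity is drawn uniformly from the configured
#' range; each bin's NB mean is the diploid depth times the expected
#' coverage factor of the bin's true copy number.
#'
#' @param config a \code{sim_config}.
#' @param group \code{"metastatic"} or \code{"non_metastatic"}.
#' @param sample_id profile label.
#' @return list with \code{profile} (a \code{coverage_profile}) and
#'   \code{truth} (events data.frame, \code{purity}, per-bin integer
#'   \code{copy_number}).
#' @export
simulate_tumor <- function(config, group = c("metastatic", "non_metastatic"),
                           sample_id = "tumor") {
  group <- match.arg(group)
  grid <- config$grid
  nb <- n_bins(grid)
  p <- config$p_event[[group]]
  take <- stats::runif(nrow(config$catalog)) < p
  events <- config$catalog[take, , drop = FALSE]
  purity <- stats::runif(1, config$purity_range[1], config$purity_range[2])
  cn <- rep(2L, nb)
  if (nrow(events)) {
    bin_arm <- arm_of(grid, 0:(nb - 1L))
    for (k in seq_len(nrow(events)))
      cn[bin_arm == events$arm[k]] <- events$copy_number[k]
  }
  mu <- config$depth * expected_coverage_factor(cn, purity)
  counts <- stats::rnbinom(nb, mu = mu, size = config$dispersion)
  list(profile = coverage_profile(sample_id, grid, counts),
       truth = list(events = events, purity = purity, copy_number = cn,
                    group = group))
}

#' Simulate a full cohort: control panel plus two tumor groups
#'
#' Reproducible from \code{config$seed} alone.
#'
#' @param config a \code{sim_config}.
#' @return a \code{simulated_cohort}: list with \code{config},
#'   \code{controls} (list of profiles), \code{tumors} (list of
#'   \code{simulate_tumor} results), and \code{groups} (character vector
#'   per tumor).
#' @export
simulate_cohort <- function(config = sim_config()) {
  old <- globalenv()$.Random.seed
  set.seed(config$seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  controls <- lapply(seq_len(config$n_controls), function(i)
    simulate_control(config, sprintf("control_%02d", i)))
  groups <- c(rep("metastatic", config$n_metastatic),
              rep("non_metastatic", config$n_non_metastatic))
  tumors <- lapply(seq_along(groups), function(i)
    simulate_tumor(config, groups[i], sprintf("tumor_%02d", i)))
  structure(list(config = config, controls = controls, tumors = tumors,
                 groups = groups),
            class = "simulated_cohort")
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(sprintf(
    "simulated_cohort: %d controls, %d + %d tumors on '%s' (%g-bp bins, seed %d)\n",
    length(x$controls), sum(x$groups == "metastatic"),
    sum(x$groups == "non_metastatic"), x$config$genome$name,
    x$config$bin_width, x$config$seed))
  invisible(x)
}

#' Write a simulated cohort's profiles and truth tables to a directory
#'
#' Per-sample coverage TSVs, a truth CSV (sample, group, purity, events)
#' and a JSON echo of the configuration (including the seed).
#'
#' @param cohort a \code{simulated_cohort}.
#' @param dir output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in cohort$controls)
    write_profile_tsv(p, file.path(dir, paste0(p$sample_id, ".tsv")))
  truth <- lapply(cohort$tumors, function(t) {
    write_profile_tsv(t$profile,
                      file.path(dir, paste0(t$profile$sample_id, ".tsv")))
    ev <- t$truth$events
    data.frame(sample = t$profile$sample_id, group = t$truth$group,
               purity = t$truth$purity,
               events = paste(paste0(ev$arm,
                                     ifelse(ev$direction == "gain", "+", "-")),
                              collapse = ";"))
  })
  utils::write.csv(do.call(rbind, truth), file.path(dir, "truth.csv"),
                   row.names = FALSE)
  cfg <- cohort$config
  jsonlite::write_json(
    list(genome = cfg$genome$name, bin_width = cfg$bin_width,
         depth = cfg$depth, dispersion = cfg$dispersion,
         n_controls = cfg$n_controls, n_metastatic = cfg$n_metastatic,
         n_non_metastatic = cfg$n_non_metastatic,
         p_event = as.list(cfg$p_event),
         purity_range = cfg$purity_range, seed = cfg$seed),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
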