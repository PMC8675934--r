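#' Configuration of the synthetic community generator
#'
#' Builds the full parameter set for simulating a salinity-gradient annual
#' plant survey: a landscape of plots subdivided into 1 m^2 subplots, soil
#' variables organised in correlated clusters, per-year precipitation, and a
#' species pool with Gaussian salinity niches, log-linear responses to soil
#' nutrients, year-level precipitation sensitivity, Beverton-Holt-style
#' competitive suppression, a suitability-dependent occupancy hurdle and
#' negative-binomial counting noise.
#'
#' The default configuration emulates the survey design this package
#' targets: 9 plots x 36 subplots (6 x 6 grid at 1 m spacing, plots ~110 m
#' apart along a 1 km transect) x 5 years x 23 species, with annual
#' precipitation spanning 384-625 mm. Species-level parameters are derived
#' deterministically (they do not depend on the simulation seed), so the
#' statistical calibration of the default dataset is stable across seeds.
#'
#' @param n_plots number of plots along the gradient.
#' @param grid subplot grid dimensions within a plot, `c(rows, cols)`.
#' @param years integer vector of season labels.
#' @param precipitation named numeric vector of annual precipitation (mm),
#'   one value per year.
#' @param n_species number of species in the pool.
#' @param species optional character vector of species codes.
#' @param plot_spacing distance between neighbouring plot origins (m).
#' @param soil soil model description; see [default_soil_model()].
#' @param niche per-species niche parameter table; derived deterministically
#'   from `n_species` when `NULL`.
#' @param competition non-negative competition matrix (m x m); derived when
#'   `NULL`. Row i, column j is the suppression exerted on species i by the
#'   latent density of species j.
#' @param hurdle occupancy hurdle parameters: `slope` and `threshold` of the
#'   logistic occupancy response to the species' standardized log latent
#'   suitability (each species occupies its better-quality sites and years,
#'   whatever its absolute abundance), and `cap`, the maximum occupancy
#'   probability (set `cap = 0` to force structural zeros everywhere).
#' @param latent_cap soft upper cap (log scale) on the centred environmental
#'   response: favourable sites saturate onto a density plateau instead of
#'   growing exponentially without bound, as carrying capacity does in the
#'   field.
#' @param dispersion negative-binomial dispersion model: `k0` (size at the
#'   median species) and `k_slope` (log-linear decay of size with species
#'   baseline abundance, making abundant species relatively patchier).
#' @param year_effects m x n_years matrix of idiosyncratic species-by-year
#'   fecundity deviations (log scale), or `NULL` for the deterministic
#'   default. These deviations are shared by all subplots of a year; within
#'   a sampled year they are absorbed through the year's precipitation
#'   label, but they do not transfer to a held-out year, reproducing the
#'   collapse of temporal prediction under strong interannual variability.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_plots = 9,
                             grid = c(6, 6),
                             years = 2015:2019,
                             precipitation = c(`2015` = 495, `2016` = 625,
                                               `2017` = 452, `2018` = 560,
                                               `2019` = 384),
                             n_species = 23,
                             species = NULL,
                             plot_spacing = 110,
                             soil = default_soil_model(),
                             niche = NULL,
                             competition = NULL,
                             hurdle = list(slope = 5, threshold = 0.15, cap = 1),
                             dispersion = list(k0 = 3.5, k_slope = 0.3),
                             latent_cap = 4.5, year_effects = NULL) {
  if (n_plots < 1 || any(grid < 1) || n_species < 1 || length(years) < 1) {
    stop_validation("generator dimensions must be positive")
  }
  if (length(precipitation) != length(years)) {
    stop_validation("precipitation must hold one value per year (%d years, %d values)",
                    length(years), length(precipitation))
  }
  if (is.null(species)) {
    pool <- default_schema()$species
    species <- if (n_species <= length(pool)) pool[seq_len(n_species)] else
      sprintf("SP%02d", seq_len(n_species))
  }
  stopifnot(length(species) == n_species)
  niche <- niche %||% default_species_niche(n_species, species)
  competition <- competition %||% default_competition_matrix(niche)
  year_effects <- year_effects %||%
    with_seed(151820, matrix(stats::rnorm(n_species * length(years), 0, 0.8),
                             n_species, length(years)))
  stopifnot(nrow(year_effects) == n_species,
            ncol(year_effects) == length(years))
  if (any(competition < 0)) stop_validation("competition matrix must be non-negative")
  stopifnot(nrow(competition) == n_species, ncol(competition) == n_species)
  structure(list(
    n_plots = n_plots, grid = grid, years = years,
    precipitation = precipitation, n_species = n_species, species = species,
    plot_spacing = plot_spacing, soil = soil, niche = niche,
    competition = competition, hurdle = hurdle, dispersion = dispersion,
    latent_cap = latent_cap, year_effects = year_effects
  ), class = "generator_config")
}

#' Default soil variable model
#'
#' Each soil variable is generated from one of three standardized sources —
#' the salinity gradient factor (`salt`), a fertility factor (`fert`), the
#' plot-level gradient itself (`grad`) — or from independent subplot noise
#' (`noise`), with a loading controlling the within-cluster rank
#' correlation. Values are mapped to measurement scales by an identity or
#' exponential transform. The two correlated clusters are
#' \{salinity, Na, Cl, K\} and \{C, organic_matter, N, cn_ratio\}.
#'
#' @param cluster_rho loading of cluster members on their shared factor.
#' @return a soil model list.
#' @export
default_soil_model <- function(cluster_rho = 0.93) {
  v <- function(source, loading, location, scale, transform = "identity") {
    list(source = source, loading = loading, location = location,
         scale = scale, transform = transform)
  }
  list(
    gradient_loading = 0.95, subplot_sd = 0.55,
    fert_plot_sd = 0.6, fert_subplot_sd = 0.8,
    vars = list(
      salinity       = v("salt", cluster_rho, 0.60, 0.70, "exp"),
      Na             = v("salt", cluster_rho, 5.20, 0.75, "exp"),
      Cl             = v("salt", cluster_rho, 5.50, 0.80, "exp"),
      K              = v("salt", cluster_rho, 4.60, 0.60, "exp"),
      C              = v("fert", cluster_rho, 0.20, 0.50, "exp"),
      organic_matter = v("fert", cluster_rho, 0.45, 0.50, "exp"),
      N              = v("fert", cluster_rho, -1.50, 0.50, "exp"),
      cn_ratio       = v("fert", cluster_rho, 10.0, 1.80, "identity"),
      carbonates     = v("grad", -0.45, 25.0, 8.00, "identity"),
      P              = v("noise", 1, 2.30, 0.50, "exp"),
      Ca             = v("noise", 1, 6.20, 0.40, "exp"),
      pH             = v("noise", 1, 8.20, 0.35, "identity"),
      Mg             = v("noise", 1, 5.10, 0.40, "exp")
    )
  )
}

# Deterministic species parameter ladder: abundance baselines span roughly
# 3.5 decades, salinity optima are spread across the gradient, nutrient
# slopes have species-specific signs, and precipitation sensitivity is
# strong with mixed signs (driving the year effects that defeat
# leave-one-year-out prediction). Independent of the simulation seed.
default_species_niche <- function(n_species, species) {
  with_seed(760149, {
    m <- n_species
    a <- seq(log(0.4), log(60), length.out = m) + stats::rnorm(m, 0, 0.15)
    ord <- sample.int(m)  # decouple abundance rank from code order
    a <- a[ord]
    rank01 <- (a - min(a)) / max(1e-9, diff(range(a)))
    # sparse, strong responses: each species is driven by the salinity
    # niche, at most one or two nutrient axes and the year signal, the way
    # real niches are low-dimensional; amplitudes grow with the abundance
    # baseline so abundant species are patchier (variance-mean exponents
    # above 2 require relative variability to grow with the mean)
    pick <- function(p, lo, hi) {
      sample(c(-1, 1), m, replace = TRUE) *
        stats::runif(m, lo, hi) * (stats::runif(m) < p)
    }
    out <- tibble::tibble(
      species = species,
      a = a,
      amp = 0.6 + 2.8 * rank01,
      o = stats::runif(m, -1.6, 1.6),
      w = stats::runif(m, 0.6, 1.0),
      b_carb = pick(0.45, 0.9, 1.7),
      b_C = pick(0.35, 0.8, 1.5),
      b_P = pick(0.25, 0.7, 1.2),
      b_Ca = stats::rnorm(m, 0, 0.05),
      r_prec = sample(c(-1, 1), m, replace = TRUE) * stats::runif(m, 0.5, 1.1),
      # species-level wobble around the community-wide variance-mean
      # relation: real Taylor plots scatter around the fitted power law
      h_off = stats::rnorm(m, 0, 0.55),
      k_mult = exp(stats::rnorm(m, 0, 0.45))
    )
    amp_jitter <- exp(stats::rnorm(m, 0, 0.15))
    # calibrated baseline ladder: expected abundances span roughly 0.2 to
    # 60 individuals per square metre
    out$a <- (out$a - min(out$a)) / max(1e-9, diff(range(out$a))) *
      (log(60) - log(0.22)) + log(0.22)
    out$amp <- out$amp * amp_jitter
    out
  })
}

# Suppression scaled inversely to the competitor's expected latent density
# (baseline times the lognormal inflation from its environmental spread) so
# the Beverton-Holt denominator stays O(1); intraspecific regulation is
# stronger than interspecific suppression.
default_competition_matrix <- function(niche, alpha0 = 0.035, alpha_intra = 0.3) {
  m <- nrow(niche)
  amp <- if ("amp" %in% names(niche)) niche$amp else rep(1, m)
  u <- with_seed(481207, stats::runif(m, 0.5, 1.5))
  expected_latent <- exp(niche$a + 0.5 * (amp * 1.1)^2)
  col_scale <- alpha0 * u / expected_latent
  alpha <- matrix(rep(col_scale, each = m), m, m)
  diag(alpha) <- alpha_intra / expected_latent
  dimnames(alpha) <- list(niche$species, niche$species)
  alpha
}

#' Generate the abiotic landscape
#'
#' Draws one abiotic profile per subplot: a salinity gradient along the plot
#' transect plus independent subplot-level variation, with the configured
#' correlated soil clusters. Soil is constant across years by construction.
#'
#' @param config a [generator_config()].
#' @param seed integer seed.
#' @return a list with `sites` (plot, subplot, x, y), `soil` (one row per
#'   subplot, 13 variables) and `z` (standardized driver scores used as
#'   ground truth).
#' @export
generate_landscape <- function(config, seed = 1) {
  sm <- config$soil
  known <- c("salt", "fert", "grad", "noise")
  bad <- setdiff(vapply(sm$vars, `[[`, "", "source"), known)
  if (length(bad) > 0) stop_validation("soil cluster references unknown source: %s", bad[1])

  n_plots <- config$n_plots
  per_plot <- prod(config$grid)
  n_sub <- n_plots * per_plot
  rows <- config$grid[1]; cols <- config$grid[2]
  plot_id <- rep(sprintf("P%d", seq_len(n_plots)), each = per_plot)
  sub_id <- rep(sprintf("S%02d", seq_len(per_plot)), times = n_plots)
  lx <- rep(rep(seq_len(cols) - 1, each = rows), times = n_plots)
  ly <- rep(rep(seq_len(rows) - 1, times = cols), times = n_plots)
  x <- (rep(seq_len(n_plots), each = per_plot) - 1) * config$plot_spacing + lx
  y <- ly
  sites <- tibble::tibble(plot = plot_id, subplot = sub_id, x = x, y = y)

  with_seed(derive_seed(seed, 11L), {
    g <- (rep(seq_len(n_plots), each = per_plot) - (n_plots + 1) / 2) /
      max(1, (n_plots - 1) / 2)
    std <- function(v) if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else v
    salt <- std(sm$gradient_loading * g + stats::rnorm(n_sub, 0, sm$subplot_sd))
    fert_plot <- stats::rnorm(n_plots, 0, sm$fert_plot_sd)
    fert <- std(fert_plot[rep(seq_len(n_plots), each = per_plot)] +
                  stats::rnorm(n_sub, 0, sm$fert_subplot_sd))
    grad <- std(g)
    source_z <- list(salt = salt, fert = fert, grad = grad)

    z <- list()
    soil <- tibble::as_tibble(sapply(names(sm$vars), function(nm) {
      vv <- sm$vars[[nm]]
      zsrc <- if (vv$source == "noise") stats::rnorm(n_sub) else {
        rho <- vv$loading
        rho * source_z[[vv$source]] + sqrt(max(0, 1 - rho^2)) * stats::rnorm(n_sub)
      }
      z[[nm]] <<- zsrc
      raw <- vv$location + vv$scale * zsrc
      if (vv$transform == "exp") exp(raw) else raw
    }, simplify = FALSE))
    z$salt_factor <- salt
    z$fert_factor <- fert
    list(sites = sites, soil = soil, z = z)
  })
}

#' Generate community abundances over a landscape
#'
#' Computes a latent expected abundance per (species, community) — Gaussian
#' salinity niche, log-linear soil responses, year-level precipitation
#' multiplier, divided by a Beverton-Holt competitive denominator over the
#' other species' latent densities — then draws counts from an occupancy
#' hurdle on top of a negative binomial.
#'
#' @param config a [generator_config()].
#' @param landscape output of [generate_landscape()] under the same config.
#' @param seed integer seed.
#' @return list with `table` (a [community_table()]) and `truth` (latent
#'   potential and realized means, occupancy probabilities, expected
#'   abundances and the parameters used).
#' @export
generate_abundances <- function(config, landscape, seed = 1) {
  sites <- landscape$sites
  n_sub <- nrow(sites)
  n_years <- length(config$years)
  n <- n_sub * n_years
  m <- config$n_species
  nich <- config$niche

  sub_ix <- rep(seq_len(n_sub), times = n_years)
  year <- rep(config$years, each = n_sub)
  prec <- rep(as.numeric(config$precipitation), each = n_sub)
  z_prec <- (prec - 500) / 120
  z <- landscape$z

  amp <- if ("amp" %in% names(nich)) nich$amp else rep(1, m)
  cap <- config$latent_cap %||% Inf
  eta <- matrix(0, n, m)
  for (i in seq_len(m)) {
    # spatial niche response: softly capped, so favourable subplots
    # saturate onto a density plateau (a carrying capacity) instead of
    # growing exponentially without bound
    spatial <- amp[i] * (nich$b_carb[i] * z$carbonates[sub_ix] +
                           nich$b_C[i] * z$C[sub_ix] +
                           nich$b_P[i] * z$P[sub_ix] +
                           nich$b_Ca[i] * z$Ca[sub_ix] -
                           (z$salinity[sub_ix] - nich$o[i])^2 / (2 * nich$w[i]^2))
    spatial <- spatial - mean(spatial)
    if (is.finite(cap)) {
      t <- cap - spatial
      spatial <- cap - ifelse(t > 30, t, log1p(exp(t)))  # stable soft-min
    }
    # the year signal multiplies the plateau itself: rainfall scales how
    # many individuals a favourable subplot carries
    temporal <- amp[i] * (nich$r_prec[i] * z_prec +
                            config$year_effects[i, match(year, config$years)])
    resp_c <- spatial + (temporal - mean(temporal))
    # lognormal correction pins the expected latent abundance at exp(a)
    eta[, i] <- nich$a[i] + resp_c - log(mean(exp(resp_c)))
  }
  M0 <- exp(eta)
  if (!all(is.finite(M0))) {
    bad <- which(!apply(is.finite(M0), 2, all))[1]
    stop_validation("non-finite latent mean for species '%s'; check niche parameters",
                    config$species[bad])
  }
  D <- 1 + M0 %*% t(config$competition)
  M <- M0 / D
  # occupancy responds to the species' own standardized suitability: each
  # species occupies its better-quality sites and years, whatever its
  # absolute abundance; absolute rarity then adds counting zeros on top
  hu <- config$hurdle
  zsuit <- scale(log(M))
  zsuit[!is.finite(zsuit)] <- 0
  h_off <- if ("h_off" %in% names(nich)) nich$h_off else numeric(m)
  pi_occ <- hu$cap * stats::plogis(hu$slope *
                                     sweep(zsuit, 2, hu$threshold + h_off))
  k_mult <- if ("k_mult" %in% names(nich)) nich$k_mult else rep(1, m)
  k <- pmax(0.3, config$dispersion$k0 * k_mult *
              exp(-config$dispersion$k_slope * (nich$a - mean(nich$a))))

  X <- with_seed(derive_seed(seed, 23L), {
    occ <- matrix(stats::rbinom(n * m, 1, as.vector(pi_occ)), n, m)
    cnt <- matrix(stats::rnbinom(n * m, mu = as.vector(M),
                                 size = rep(k, each = n)), n, m)
    occ * cnt
  })
  colnames(X) <- config$species

  df <- tibble::tibble(
    plot = sites$plot[sub_ix], subplot = sites$subplot[sub_ix],
    year = year, x = sites$x[sub_ix], y = sites$y[sub_ix],
    precipitation = prec
  )
  for (nm in names(landscape$soil)) df[[nm]] <- landscape$soil[[nm]][sub_ix]
  for (j in seq_len(m)) df[[config$species[j]]] <- as.integer(X[, j])

  table <- community_table(df, species = config$species,
                           abiotic = c(names(landscape$soil), "precipitation"),
                           validate = FALSE)
  truth <- list(potential = M0, latent = M, occupancy = pi_occ,
                expected = pi_occ * M, dispersion = k,
                niche = nich, competition = config$competition,
                hurdle = hu, z = z, sub_ix = sub_ix, z_prec = z_prec)
  list(table = table, truth = truth)
}

#' Simulate a full synthetic community dataset
#'
#' Convenience wrapper chaining [generate_landscape()] and
#' [generate_abundances()].
#'
#' @param config a [generator_config()] (default configuration if omitted).
#' @param seed integer seed; identical config and seed give a bit-identical
#'   table.
#' @return list with `table`, `truth` and `landscape`.
#' @export
simulate_community <- function(config = generator_config(), seed = 1) {
  landscape <- generate_landscape(config, seed = seed)
  out <- generate_abundances(config, landscape, seed = seed)
  out$landscape <- landscape
  out
}

#' Calibration report of a community table
#'
#' Summarises the statistical structure the generator is calibrated
#' against: the overall fraction of zero abundances, the Taylor's-law
#' power fit (OLS of log10 per-species variance on log10 per-species mean),
#' and per-species Moran's I spatial autocorrelation.
#'
#' @param table a [community_table()] carrying `x`, `y` coordinates.
#' @param morans compute per-species Moran's I (default `TRUE`; the Taylor
#'   fit and zero fraction are much cheaper).
#' @return a `calibration_report` list with `zero_fraction`, `taylor_slope`,
#'   `taylor_adj_r2`, `species_summary` and (optionally) `morans_i`.
#' @export
calibration_report <- function(table, morans = TRUE) {
  sp <- species_names(table)
  A <- as.matrix(tibble::as_tibble(unclass_table(table))[sp])
  if (nrow(A) == 0) stop_validation("empty table")
  mu <- colMeans(A)
  v <- apply(A, 2, stats::var)
  if (all(A == 0)) stop_validation("degenerate abundance distribution: all abundances are zero")
  ok <- mu > 0 & v > 0
  if (sum(ok) < 2) {
    stop_validation("degenerate abundance distribution: fewer than 2 species with positive mean and variance")
  }
  fit <- stats::lm(log10(v[ok]) ~ log10(mu[ok]))
  sfit <- summary(fit)
  rep <- list(
    zero_fraction = mean(A == 0),
    taylor_slope = unname(stats::coef(fit)[2]),
    taylor_adj_r2 = sfit$adj.r.squared,
    n_species_fitted = sum(ok),
    species_summary = tibble::tibble(species = sp, mean = mu, variance = v,
                                     zero_fraction = colMeans(A == 0))
  )
  if (morans) rep$morans_i <- species_morans_i(table)
  structure(rep, class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("Community calibration report (%d species fitted)\n", x$n_species_fitted))
  cat(sprintf("  zero fraction     : %.1f%%\n", 100 * x$zero_fraction))
  cat(sprintf("  Taylor slope      : %.3f (adj R2 = %.3f)\n",
              x$taylor_slope, x$taylor_adj_r2))
  if (!is.null(x$morans_i)) {
    cat(sprintf("  max Moran's I     : %.3f\n", max(x$morans_i$morans_i, na.rm = TRUE)))
  }
  invisible(x)
}

#' Read or write a generator configuration as YAML
#'
#' @param config a [generator_config()].
#' @param path file path.
#' @return `read_generator_config()` returns a [generator_config()];
#'   `write_generator_config()` returns `path` invisibly.
#' @export
write_generator_config <- function(config, path) {
  # doubles are serialized via their shortest exact decimal representation
  # so a written config reproduces bit-identical simulations when re-read
  num <- function(x) {
    out <- vapply(x, function(v) format(v, digits = 17, scientific = TRUE),
                  character(1))
    if (!is.null(names(x))) names(out) <- names(x) else out <- unname(out)
    out
  }
  ser <- function(x) {
    if (is.double(x)) as.list(num(x))
    else if (is.list(x)) lapply(x, ser)
    else x
  }
  out <- unclass(config)
  out$niche <- lapply(as.list(tibble::as_tibble(out$niche)), function(col) {
    if (is.double(col)) as.list(num(col)) else col
  })
  out$competition <- list(species = rownames(out$competition),
                          values = as.list(num(as.vector(out$competition))))
  out$year_effects <- as.list(num(as.vector(out$year_effects)))
  out$precipitation <- as.list(num(out$precipitation))
  out$soil <- ser(out$soil)
  out$hurdle <- ser(out$hurdle)
  out$dispersion <- ser(out$dispersion)
  out$latent_cap <- num(out$latent_cap)
  out$plot_spacing <- num(out$plot_spacing)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  raw <- yaml::read_yaml(path)
  num <- function(x) {
    v <- unlist(x)
    if (is.character(v)) stats::setNames(as.numeric(v), names(v)) else v
  }
  deser <- function(x) {
    if (is.list(x)) {
      if (length(x) > 0 && all(vapply(x, function(v) is.character(v) || is.numeric(v), logical(1))) &&
          all(grepl("^[-+0-9.eE]+$", unlist(x))) && is.null(names(x))) num(x)
      else lapply(x, deser)
    } else if (is.character(x) && all(grepl("^[-+0-9.eE]+$", x))) as.numeric(x)
    else x
  }
  m <- length(raw$competition$species)
  comp <- matrix(num(raw$competition$values), m, m,
                 dimnames = list(raw$competition$species, raw$competition$species))
  niche <- tibble::as_tibble(lapply(raw$niche, function(col) {
    v <- unlist(col)
    if (is.character(v) && !anyNA(suppressWarnings(as.numeric(v)))) as.numeric(v) else v
  }))
  generator_config(
    n_plots = raw$n_plots, grid = unlist(raw$grid), years = unlist(raw$years),
    precipitation = num(raw$precipitation), n_species = raw$n_species,
    species = unlist(raw$species), plot_spacing = num(raw$plot_spacing),
    soil = deser(raw$soil), niche = niche,
    competition = comp, hurdle = deser(raw$hurdle),
    dispersion = deser(raw$dispersion),
    latent_cap = num(raw$latent_cap),
    year_effects = matrix(num(raw$year_effects), m, length(unlist(raw$years)))
  )
}
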