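# Synthetic-data generators: a four-phase ABE fermentation time course, a
# samples x metabolites peak-area table with planted growth/production
# effects, and a fixture pathway library with planted enrichment structure.

#' Simulation design for a synthetic metabolome experiment
#'
#' Captures the sampling layout and planted-signal structure used by
#' [simulate_metabolome()]. Defaults mirror a typical batch ABE
#' (acetone-butanol-ethanol) profiling experiment: metabolome sampling at
#' 24, 48, 60 and 80 h (mid-log, early/late stationary, decline), five
#' parallel replicates per time, and 97 detected intracellular metabolites.
#'
#' Planted effects are expressed on the log scale of the true relative
#' abundance: `log R_js = intercept_j + beta_g[j] * z(mu_s) +
#' beta_b[j] * z(q_s) + eps`, with `z` the standardization of the phenotype
#' across sampling times and `eps ~ Normal(0, noise_sd)`. The default
#' `noise_sd = 0.2` (about 20\% CV) is a realistic GC-MS replicate error;
#' default planted effects sit at `3 * noise_sd` so recovery is expected but
#' not trivial.
#'
#' @param n_replicates Replicates per sampling time (>= 2).
#' @param sample_times_h Metabolome sampling times in hours.
#' @param n_metabolites Number of metabolite channels.
#' @param planted_effects Data frame with columns `index`, `beta_g`,
#'   `beta_b`, `class`; `NULL` for the default three planted classes
#'   (growth-positive, butanol-negative, dual).
#' @param noise_sd Log-scale replicate noise SD (> 0).
#' @param seed Integer seed; expanded into per-metabolite substreams so
#'   adding a metabolite never reshuffles the others.
#' @return A list of class `simulation_design`.
#' @export
simulation_design <- function(n_replicates = 5L,
                              sample_times_h = c(24, 48, 60, 80),
                              n_metabolites = 97L,
                              planted_effects = NULL,
                              noise_sd = 0.2,
                              seed = 1L) {
  ferm_assert(n_replicates >= 2, "n_replicates must be >= 2")
  ferm_assert(noise_sd > 0, "noise_sd must be > 0")
  ferm_assert(length(unique(sample_times_h)) == length(sample_times_h),
              "sample_times_h must be distinct")
  if (is.null(planted_effects)) {
    planted_effects <- default_planted_effects(n_metabolites, noise_sd)
  }
  ferm_assert(all(planted_effects$index >= 1) &&
                all(planted_effects$index <= n_metabolites),
              "every planted index must lie in 1..n_metabolites")
  ferm_assert(!anyDuplicated(planted_effects$index),
              "planted indices must be unique")
  structure(list(
    n_times = length(sample_times_h),
    sample_times_h = sample_times_h,
    n_replicates = as.integer(n_replicates),
    n_metabolites = as.integer(n_metabolites),
    planted_effects = planted_effects,
    noise_sd = noise_sd,
    seed = as.integer(seed),
    metabolite_ids = sprintf("C9%04d", seq_len(n_metabolites))
  ), class = "simulation_design")
}

# Default planted structure: three classes at the stated effect size
# 3 * noise_sd. Expected Table-1 types: E (growth-positive only),
# B (butanol-negative only), D (growth-positive and butanol-negative).
default_planted_effects <- function(n_metabolites, noise_sd) {
  ferm_assert(n_metabolites >= 25,
              "default planted effects need >= 25 metabolites")
  b <- 3 * noise_sd
  data.frame(
    index = 1:25,
    beta_g = c(rep(b, 10), rep(0, 10), rep(b, 5)),
    beta_b = c(rep(0, 10), rep(-b, 10), rep(-b, 5)),
    class = c(rep("E", 10), rep("B", 10), rep("D", 5)),
    stringsAsFactors = FALSE
  )
}

#' Simulate a four-phase ABE fermentation time course
#'
#' Generates OD600, dry cell weight, butanol, acetate, butyrate, glucose and
#' pH over a batch fermentation divided into lag, log, stationary and
#' decline phases. Growth is piecewise exponential (OD integrates the
#' per-phase rate exactly, so finite-difference rate estimators recover the
#' phase rates); butanol stays near zero until the acid peak, then rises
#' sigmoidally; acids rise to a peak at solvent onset and then fall; pH
#' drops sharply, bumps at onset, and drifts down.
#'
#' @param times Sampling grid in hours (strictly increasing).
#' @param od0 Inoculum OD600.
#' @param phase_bounds Phase boundaries `c(lag_end, log_end, stat_end)` in
#'   hours, strictly increasing.
#' @param growth_rates Per-phase specific growth rates
#'   `c(lag, log, stationary, decline)` in 1/h.
#' @param butanol_max,butanol_onset_h Final titer (g/L) and the acid-peak
#'   hour at which solventogenesis starts.
#' @param acid_peaks Peak concentrations `c(acetate, butyrate)` in g/L,
#'   reached at `butanol_onset_h`.
#' @param glucose0 Initial glucose (g/L).
#' @param od_to_dcw Dry cell weight per OD unit (g/L); the conventional
#'   conversion, configurable because it is strain- and instrument-specific.
#' @param noise_sd Multiplicative log-normal measurement noise on OD and
#'   concentrations (0 = noiseless, the default).
#' @param seed Seed used when `noise_sd > 0`.
#' @return A data.frame of class `fermentation_timecourse` with columns
#'   `time_h`, `od600`, `dcw`, `butanol`, `acetate`, `butyrate`, `glucose`,
#'   `ph`.
#' @export
simulate_fermentation <- function(times = seq(0, 84, by = 2),
                                  od0 = 0.25,
                                  phase_bounds = c(12, 45, 63),
                                  growth_rates = c(lag = 0.008, log = 0.085,
                                                   stationary = 0.005,
                                                   decline = -0.004),
                                  butanol_max = 12.5,
                                  butanol_onset_h = 32,
                                  acid_peaks = c(acetate = 3.2,
                                                 butyrate = 4.0),
                                  glucose0 = 60,
                                  od_to_dcw = 0.3,
                                  noise_sd = 0,
                                  seed = 1L) {
  ferm_assert(length(times) >= 2 && all(diff(times) > 0),
              "time grid must be strictly increasing")
  ferm_assert(length(phase_bounds) == 3 && all(diff(phase_bounds) > 0) &&
                phase_bounds[1] > min(times),
              "phase boundaries must be strictly increasing")
  ferm_assert(all(is.finite(growth_rates)), "growth rates must be finite")
  ferm_assert(od0 > 0, "inoculum OD must be positive")

  # exact integral of the piecewise-constant growth rate up to t
  t0 <- min(times)
  knots <- c(t0, phase_bounds, Inf)
  cum_rate <- function(t) {
    acc <- 0
    for (k in seq_len(4)) {
      lo <- knots[k]; hi <- min(t, knots[k + 1])
      if (hi > lo) acc <- acc + growth_rates[[k]] * (hi - lo)
    }
    acc
  }
  od <- od0 * exp(vapply(times, cum_rate, numeric(1)))

  # butanol: logistic centred past the onset, steep enough that titer at the
  # onset itself is ~0.05 g/L (a trace, matching solvent-switch kinetics)
  t_mid <- butanol_onset_h + 22
  butanol <- butanol_max / (1 + exp(-0.25 * (times - t_mid)))

  # acids: gamma-shaped pulse peaking at the solvent onset, then re-assimilated
  acid_shape <- function(peak) {
    s <- (pmax(times, 0) / butanol_onset_h)
    peak * s^2 * exp(2 * (1 - s))
  }
  acetate <- acid_shape(acid_peaks[["acetate"]])
  butyrate <- acid_shape(acid_peaks[["butyrate"]])

  glucose <- glucose0 * (1 - 0.85 / (1 + exp(-0.12 * (times - 48))))

  ph_knots_t <- c(t0, phase_bounds[1], butanol_onset_h, phase_bounds[2:3],
                  max(times))
  ph_knots_v <- c(6.8, 4.3, 4.45, 4.4, 4.15, 4.0)
  ph <- stats::approx(ph_knots_t, ph_knots_v, xout = times, rule = 2)$y

  if (noise_sd > 0) {
    with_seed(substream(seed, 7L), {
      jitter <- function(x) x * exp(stats::rnorm(length(x), 0, noise_sd))
      od <- jitter(od); butanol <- jitter(butanol)
      acetate <- jitter(acetate); butyrate <- jitter(butyrate)
      glucose <- jitter(glucose)
    })
  }

  structure(data.frame(
    time_h = times, od600 = od, dcw = od_to_dcw * od,
    butanol = pmax(butanol, 0), acetate = pmax(acetate, 0),
    butyrate = pmax(butyrate, 0), glucose = pmax(glucose, 0), ph = ph
  ), class = c("fermentation_timecourse", "data.frame"))
}

#' Simulate a GC-MS metabolome peak-area table with planted effects
#'
#' For each metabolite `j` the true relative abundance in sample `s` follows
#' `log R_js = intercept_j + beta_g[j] z(mu_s) + beta_b[j] z(q_s) + eps`,
#' where `z` standardizes the phenotype across sampling times and
#' `eps ~ Normal(0, noise_sd)` (log-normal noise: peak areas are positive
#' and errors multiplicative). The emitted peak area is
#' `A_i = R * DCW_s * A_s`, with `A_s` a deuterated internal-standard
#' channel (constant true level, small log-normal noise), so that the
#' internal-standard/DCW normalization recovers `R` and planted effects act
#' on the modeled quantity rather than on the biomass trend.
#'
#' @param phenotype Data frame with one row per sampling time and columns
#'   `time_h`, `mu`, `q`, `dcw` (see [phenotype_rates()]).
#' @param design A [simulation_design()].
#' @return A list with `table` (data.frame: `time_h`, `replicate`, one
#'   column per metabolite, and `IS_succinate_d4`) and `ground_truth`
#'   (data.frame: `metabolite`, `beta_g`, `beta_b`, `sign_g`, `sign_b`,
#'   `class`).
#' @export
simulate_metabolome <- function(phenotype, design) {
  stopifnot(inherits(design, "simulation_design"))
  ferm_assert(all(c("time_h", "mu", "q", "dcw") %in% names(phenotype)),
              "phenotype needs columns time_h, mu, q, dcw")
  ferm_assert(nrow(phenotype) >= 2 &&
                length(unique(phenotype$time_h)) == nrow(phenotype),
              "need >= 2 distinct sampling times")
  ferm_assert(setequal(phenotype$time_h, design$sample_times_h),
              "phenotype times must match the design's sampling times")
  phenotype <- phenotype[match(design$sample_times_h, phenotype$time_h), ]

  zscore <- function(v) {
    s <- stats::sd(v)
    ferm_assert(s > 0, "phenotype constant across times: nothing to model")
    (v - mean(v)) / s
  }
  z_mu <- zscore(phenotype$mu)
  z_q <- zscore(phenotype$q)

  n_t <- design$n_times
  n_r <- design$n_replicates
  time_idx <- rep(seq_len(n_t), each = n_r)
  n <- n_t * n_r

  beta_g <- beta_b <- numeric(design$n_metabolites)
  class_lab <- rep("null", design$n_metabolites)
  pe <- design$planted_effects
  beta_g[pe$index] <- pe$beta_g
  beta_b[pe$index] <- pe$beta_b
  class_lab[pe$index] <- pe$class

  areas <- matrix(NA_real_, n, design$n_metabolites,
                  dimnames = list(NULL, design$metabolite_ids))
  for (j in seq_len(design$n_metabolites)) {
    with_seed(substream(design$seed, 100L, j), {
      intercept <- stats::rnorm(1, log(5e4), 1)
      eps <- stats::rnorm(n, 0, design$noise_sd)
      areas[, j] <- exp(intercept + beta_g[j] * z_mu[time_idx] +
                          beta_b[j] * z_q[time_idx] + eps)
    })
  }
  is_area <- with_seed(substream(design$seed, 99L),
                       exp(log(1e5) + stats::rnorm(n, 0, 0.02)))
  dcw_s <- phenotype$dcw[time_idx]
  ferm_assert(all(dcw_s > 0), "dcw must be positive at every sampling time")
  raw <- areas * dcw_s * is_area  # peak areas; normalization undoes this

  tab <- data.frame(
    time_h = phenotype$time_h[time_idx],
    replicate = rep(seq_len(n_r), times = n_t),
    raw, check.names = FALSE
  )
  tab$IS_succinate_d4 <- is_area

  gt <- data.frame(
    metabolite = design$metabolite_ids,
    beta_g = beta_g, beta_b = beta_b,
    sign_g = sign(beta_g), sign_b = sign(beta_b),
    class = class_lab, stringsAsFactors = FALSE
  )
  list(table = tab, ground_truth = gt)
}

#' Build a fixture pathway library with planted enrichment structure
#'
#' Constructs named compound sets plus a directed acyclic reaction graph per
#' pathway. Planted pathways draw at least `planted_frac` of their members
#' from one planted metabolite class (so downstream over-representation
#' analysis should flag them); the remaining pathways sample members
#' uniformly. Each pathway's graph is a chain along a random member order
#' with extra forward edges, hence always acyclic with total out-degree
#' > 0.
#'
#' @param metabolites Character vector of compound ids (the background).
#' @param planted Named list mapping a class label to its member compound
#'   ids; one planted pathway is created per class. `NULL` for none.
#' @param n_pathways Total number of pathways (planted + neutral).
#' @param size_range Inclusive pathway-size range (sizes >= 2).
#' @param planted_frac Minimum fraction of a planted pathway drawn from its
#'   class (default 0.8; must be >= 0.6 for the pathway to count as
#'   planted).
#' @param extra_edge_prob Probability of each additional forward edge.
#' @param seed Integer seed.
#' @return A `pathway_library`; each pathway carries `planted` (logical) and
#'   `class` fields, and the GMT description records the same.
#' @export
make_pathway_library <- function(metabolites,
                                 planted = NULL,
                                 n_pathways = 12L,
                                 size_range = c(5L, 10L),
                                 planted_frac = 0.8,
                                 extra_edge_prob = 0.15,
                                 seed = 1L) {
  ferm_assert(size_range[1] >= 2, "pathway sizes must be >= 2")
  ferm_assert(size_range[2] >= size_range[1], "invalid size_range")
  n_planted <- length(planted)
  ferm_assert(n_pathways >= n_planted, "n_pathways < number of planted classes")
  if (n_planted) {
    ferm_assert(all(unlist(planted) %in% metabolites),
                "planted class members must be drawn from `metabolites`")
  }

  make_graph_edges <- function(members, s) {
    ord <- with_seed(s, sample(members))
    edges <- data.frame(from = ord[-length(ord)], to = ord[-1],
                        stringsAsFactors = FALSE)
    if (length(ord) > 2) {
      extra <- with_seed(substream(s, 3L), {
        idx <- utils::combn(length(ord), 2)
        keep <- idx[2, ] - idx[1, ] > 1
        idx <- idx[, keep, drop = FALSE]
        pick <- stats::runif(ncol(idx)) < extra_edge_prob
        idx[, pick, drop = FALSE]
      })
      if (ncol(extra)) {
        edges <- rbind(edges, data.frame(from = ord[extra[1, ]],
                                         to = ord[extra[2, ]],
                                         stringsAsFactors = FALSE))
      }
    }
    unique(edges)
  }

  pathways <- vector("list", n_pathways)
  for (i in seq_len(n_pathways)) {
    s_i <- substream(seed, 500L, i)
    if (i <= n_planted) {
      class_lab <- names(planted)[i]
      pool <- planted[[class_lab]]
      # a planted pathway can be no larger than its class supports
      size_max <- min(size_range[2], floor(length(pool) / planted_frac))
      ferm_assert(size_max >= size_range[1], sprintf(
        "planted pathway for class %s needs %d members but class has %d",
        class_lab, ceiling(planted_frac * size_range[1]), length(pool)))
      sizes <- seq(size_range[1], size_max)
      size <- with_seed(s_i, sizes[sample.int(length(sizes), 1)])
      k <- ceiling(planted_frac * size)
      rest_pool <- setdiff(metabolites, pool)
      members <- with_seed(substream(s_i, 1L), c(
        sample(pool, k),
        if (size - k > 0) sample(rest_pool, size - k) else character(0)
      ))
      is_planted <- TRUE
    } else {
      class_lab <- NA_character_
      sizes <- seq(size_range[1], size_range[2])
      size <- with_seed(s_i, sizes[sample.int(length(sizes), 1)])
      members <- with_seed(substream(s_i, 1L), sample(metabolites, size))
      is_planted <- FALSE
    }
    id <- sprintf("PW%03d", i)
    pathways[[i]] <- list(
      id = id,
      description = if (is_planted) paste0("planted:", class_lab) else "neutral",
      compounds = members,
      edges = make_graph_edges(members, substream(s_i, 2L)),
      planted = is_planted,
      class = class_lab
    )
  }
  names(pathways) <- vapply(pathways, `[[`, "", "id")
  new_pathway_library(pathways)
}
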