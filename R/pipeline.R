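# End-to-end pipeline: rates -> PLS (x2) -> typing -> enrichment -> network,
# with every intermediate written as plain text and a JSON manifest so a
# rerun with the same config is bit-identical.

read_config_file <- function(path) {
  if (!file.exists(path)) {
    stop(structure(class = c("ferm_config_error", "error", "condition"),
                   list(message = sprintf("config file not found: %s", path),
                        call = NULL)))
  }
  if (grepl("\\.(ya?ml)$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
}

config_error <- function(msg) {
  stop(structure(class = c("ferm_config_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    if (inherits(e, "ferm_stage_error")) stop(e)
    stop(ferm_stage_error(stage, conditionMessage(e)))
  })
}

default_params <- function() {
  list(is_col = "IS_succinate_d4", vip_threshold = 1, folds = 7,
       ncomp_max = 3, q2_increment = 0.01, neglog_base = 10,
       neglog_threshold = 1, centrality = "out_degree",
       rate_method = "fd", seed = 1)
}

#' Run the full profiling pipeline
#'
#' Executes, in order: specific-rate estimation at the metabolome sampling
#' times, internal-standard/biomass normalization, one PLS model per
#' response (growth rate and butanol production rate) with cross-validated
#' component selection, the nine-type classification, per-type pathway
#' over-representation + topology analysis, and assembly of the bipartite
#' metabolite-pathway network. Every intermediate table is written under
#' `out_dir` along with a JSON manifest (inputs with checksums, parameters,
#' seed, package version); a rerun with the same config and seed is
#' bit-identical. Any stage failure raises a stage-tagged error.
#'
#' @param config Path to a YAML/JSON config, or an equivalent list, with
#'   `inputs` (`timecourse`, `metabolome`, `gmt`, `sif`: file paths) and
#'   optional `params` (see Details: `is_col`, `vip_threshold`, `folds`,
#'   `ncomp_max`, `q2_increment`, `neglog_base`, `neglog_threshold`,
#'   `centrality`, `rate_method`, `seed`).
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the fitted models, typed table,
#'   enrichment results, network and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_config_file(config)
  if (is.null(config$inputs)) config_error("config lacks an 'inputs' section")
  need <- c("timecourse", "metabolome", "gmt", "sif")
  miss <- setdiff(need, names(config$inputs))
  if (length(miss)) {
    config_error(paste("config inputs missing:", paste(miss, collapse = ", ")))
  }
  for (f in need) {
    if (!file.exists(config$inputs[[f]])) {
      config_error(sprintf("input file not found (%s): %s", f,
                           config$inputs[[f]]))
    }
  }
  params <- utils::modifyList(default_params(), config$params %||% list())
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  tc <- run_stage("read", read_tsv_table(config$inputs$timecourse))
  met <- run_stage("read", read_tsv_table(config$inputs$metabolome))
  lib <- run_stage("read", read_pathway_library(config$inputs$gmt,
                                                config$inputs$sif))

  sample_times <- sort(unique(met$time_h))
  phen <- run_stage("rates", {
    ph <- phenotype_rates(tc, sample_times, method = params$rate_method)
    write_tsv_table(ph, file.path(out_dir, "phenotype.tsv"))
    ph
  })

  a_r <- run_stage("abundance", {
    dcw <- phen$dcw[match(met$time_h, phen$time_h)]
    ar <- relative_abundance(met, dcw, is_col = params$is_col)
    write_tsv_table(ar, file.path(out_dir, "abundance.tsv"))
    ar
  })

  met_cols <- setdiff(names(a_r), c("time_h", "replicate"))
  X <- as.matrix(a_r[met_cols])
  y_mu <- phen$mu[match(a_r$time_h, phen$time_h)]
  y_q <- phen$q[match(a_r$time_h, phen$time_h)]

  models <- run_stage("pls", {
    m_g <- fit_pls_cv(X, y_mu, ncomp_max = params$ncomp_max,
                      folds = params$folds, seed = params$seed,
                      q2_increment = params$q2_increment)
    m_b <- fit_pls_cv(X, y_q, ncomp_max = params$ncomp_max,
                      folds = params$folds,
                      seed = substream(params$seed, 2L),
                      q2_increment = params$q2_increment)
    summ <- list(
      growth = list(ncomp = m_g$ncomp, R2X = m_g$R2X, R2Y = m_g$R2Y,
                    Q2 = m_g$Q2),
      butanol = list(ncomp = m_b$ncomp, R2X = m_b$R2X, R2Y = m_b$R2Y,
                     Q2 = m_b$Q2))
    jsonlite::write_json(summ, file.path(out_dir, "model_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(growth = m_g, butanol = m_b)
  })

  typed <- run_stage("typing", {
    scores <- data.frame(
      metabolite = met_cols,
      VIPb = vip(models$butanol)[met_cols],
      Coeffb = coef(models$butanol)[met_cols],
      VIPg = vip(models$growth)[met_cols],
      Coeffg = coef(models$growth)[met_cols],
      stringsAsFactors = FALSE)
    rownames(scores) <- NULL
    write_tsv_table(scores, file.path(out_dir, "scores.tsv"))
    ty <- classify_metabolites(scores, vip_threshold = params$vip_threshold)
    write_tsv_table(ty, file.path(out_dir, "typed_metabolites.tsv"))
    ty
  })

  enr <- run_stage("enrichment", {
    # background = every metabolite measured in the experiment (the
    # over-representation universe), not only pathway-covered compounds
    background <- met_cols
    by_type <- list()
    for (lab in sort(unique(stats::na.omit(typed$type_label)))) {
      members <- typed$metabolite[!is.na(typed$type_label) &
                                    typed$type_label == lab]
      if (!length(members)) next
      e <- enrich_type(members, lib, background = background,
                       neglog_base = params$neglog_base,
                       neglog_threshold = params$neglog_threshold,
                       centrality = params$centrality)
      if (nrow(e)) by_type[[lab]] <- e
    }
    combined <- do.call(rbind, lapply(names(by_type), function(lab) {
      cbind(type = lab, as.data.frame(by_type[[lab]]))
    }))
    if (is.null(combined)) {
      combined <- data.frame(type = character(0))
    }
    write_tsv_table(combined, file.path(out_dir, "enrichment.tsv"))
    by_type
  })

  net <- run_stage("network", {
    g <- build_network(enr, typed)
    write_network(g, graphml = file.path(out_dir, "network.graphml"),
                  edges_tsv = file.path(out_dir, "network_edges.tsv"))
    g
  })

  manifest <- run_stage("report", {
    man <- list(
      package = "fermentomics",
      version = as.character(utils::packageVersion("fermentomics")),
      inputs = lapply(config$inputs[need], function(p) {
        list(path = p, md5 = unname(tools::md5sum(p)))
      }),
      params = params,
      n_samples = nrow(a_r),
      n_metabolites = length(met_cols),
      sample_times_h = sample_times)
    jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    type_counts <- table(factor(typed$type_label, levels = LETTERS[1:9]))
    n_pass <- sum(vapply(enr, function(e) sum(e$passes_filter), numeric(1)))
    lines <- c(
      "fermentomics pipeline summary",
      sprintf("samples: %d (%d times x replicates); metabolites: %d",
              nrow(a_r), length(sample_times), length(met_cols)),
      sprintf("growth model:  A=%d R2X=%.3f R2Y=%.3f Q2=%.3f",
              models$growth$ncomp, models$growth$R2X, models$growth$R2Y,
              models$growth$Q2),
      sprintf("butanol model: A=%d R2X=%.3f R2Y=%.3f Q2=%.3f",
              models$butanol$ncomp, models$butanol$R2X, models$butanol$R2Y,
              models$butanol$Q2),
      paste("type counts:",
            paste(sprintf("%s=%d", names(type_counts), type_counts),
                  collapse = " ")),
      sprintf("pathway results passing -log%g(p) > %g: %d",
              params$neglog_base, params$neglog_threshold, n_pass),
      sprintf("network: %d nodes, %d edges",
              igraph::vcount(net), igraph::ecount(net)))
    writeLines(lines, file.path(out_dir, "summary.txt"))
    man
  })

  invisible(list(phenotype = phen, abundance = a_r, models = models,
                 typed = typed, enrichment = enr, network = net,
                 manifest = manifest))
}

#' Simulate a complete synthetic study to a directory
#'
#' Generates the fermentation time course, the phenotype vector at the
#' metabolome sampling times, the peak-area table with planted effects, the
#' ground truth, and a planted pathway library; writes all of them (TSV,
#' GMT + SIF) plus a ready-to-run pipeline config (`run_config.yaml`).
#'
#' @param design A [simulation_design()] (or list of its arguments).
#' @param out_dir Output directory.
#' @param n_pathways,size_range Passed to [make_pathway_library()].
#' @return Invisibly, a list with the generated objects and file paths.
#' @export
simulate_study <- function(design = simulation_design(), out_dir,
                           n_pathways = 12L, size_range = c(5L, 10L)) {
  if (!inherits(design, "simulation_design")) {
    design <- do.call(simulation_design, design)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tc <- simulate_fermentation(seed = design$seed)
  phen <- phenotype_rates(tc, design$sample_times_h)
  sim <- simulate_metabolome(phen, design)
  gt <- sim$ground_truth
  # pathway planting follows the response-level ground-truth sets (all
  # metabolites favoring growth / opposing butanol production)
  planted_classes <- Filter(length, list(
    g_pos = gt$metabolite[gt$sign_g > 0],
    b_neg = gt$metabolite[gt$sign_b < 0]))
  lib <- make_pathway_library(sim$ground_truth$metabolite,
                              planted = planted_classes,
                              n_pathways = n_pathways,
                              size_range = size_range,
                              seed = substream(design$seed, 9L))
  paths <- list(
    timecourse = file.path(out_dir, "timecourse.tsv"),
    metabolome = file.path(out_dir, "metabolome.tsv"),
    ground_truth = file.path(out_dir, "ground_truth.tsv"),
    gmt = file.path(out_dir, "pathways.gmt"),
    sif = file.path(out_dir, "pathways.sif"),
    config = file.path(out_dir, "run_config.yaml"))
  write_tsv_table(as.data.frame(tc), paths$timecourse)
  write_tsv_table(sim$table, paths$metabolome)
  write_tsv_table(sim$ground_truth, paths$ground_truth)
  write_pathway_library(lib, paths$gmt, paths$sif)
  yaml::write_yaml(list(
    inputs = list(timecourse = paths$timecourse,
                  metabolome = paths$metabolome,
                  gmt = paths$gmt, sif = paths$sif),
    params = list(seed = design$seed)), paths$config)
  invisible(list(timecourse = tc, phenotype = phen, metabolome = sim$table,
                 ground_truth = sim$ground_truth, library = lib,
                 paths = paths))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
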