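test_that("build_network: counts, bipartiteness, attributes, round-trip", {
  # empty enrichment -> empty graph
  typed <- data.frame(metabolite = c("m1", "m2", "m3"),
                      type_code = c("+-", "+*", "-*"))
  e0 <- structure(
    data.frame(pathway = character(0), p = numeric(0),
               neg_log_p = numeric(0), impact = numeric(0),
               passes_filter = logical(0)),
    incidence = data.frame(pathway = character(0), metabolite = character(0)),
    class = c("pathway_enrichment", "data.frame"))
  expect_equal(igraph::vcount(build_network(e0, typed)), 0)

  # one pathway with three surviving metabolites -> 4 nodes, 3 edges
  e1 <- structure(
    data.frame(pathway = "PW1", p = 0.01, neg_log_p = 2, impact = 0.5,
               passes_filter = TRUE),
    incidence = data.frame(pathway = rep("PW1", 3),
                           metabolite = c("m1", "m2", "m3")),
    class = c("pathway_enrichment", "data.frame"))
  g <- build_network(e1, typed)
  expect_equal(igraph::vcount(g), 4)
  expect_equal(igraph::ecount(g), 3)
  expect_true(igraph::is_bipartite(g))
  expect_equal(sort(igraph::V(g)$type_code[igraph::V(g)$kind == "metabolite"]),
               sort(typed$type_code))
  expect_equal(igraph::V(g)$p[igraph::V(g)$name == "PW1"], 0.01)

  # unknown metabolite in an incidence -> error
  e_bad <- e1
  attr(e_bad, "incidence")$metabolite[1] <- "ghost"
  expect_error(build_network(e_bad, typed), "untyped")

  # GraphML + edge TSV round-trip
  gml <- tempfile(fileext = ".graphml")
  tsv <- tempfile(fileext = ".tsv")
  write_network(g, graphml = gml, edges_tsv = tsv)
  g2 <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g2), igraph::vcount(g))
  expect_equal(igraph::ecount(g2), igraph::ecount(g))
  expect_setequal(igraph::V(g2)$name, igraph::V(g)$name)
  edges <- read_tsv_table(tsv)
  expect_equal(nrow(edges), 3)
  expect_setequal(edges$metabolite, c("m1", "m2", "m3"))
  unlink(c(gml, tsv))
})

test_that("node/edge counts match an independent set-union recount", {
  st <- tiny_study(seed = 6)
  mg <- fit_pls_cv(st$X, st$y_mu, seed = 6)
  mb <- fit_pls_cv(st$X, st$y_q, seed = 7)
  sc <- data.frame(metabolite = colnames(st$X), VIPb = vip(mb),
                   Coeffb = coef(mb), VIPg = vip(mg), Coeffg = coef(mg))
  ty <- classify_metabolites(sc)
  enr <- lapply(split(ty$metabolite, ty$type_label), function(mem) {
    enrich_type(mem, st$lib, background = st$gt$metabolite)
  })
  g <- build_network(enr, ty)
  # recount from the raw incidences
  inc <- unique(do.call(rbind, lapply(enr, attr, "incidence")))
  expect_equal(igraph::ecount(g), nrow(inc))
  expect_equal(igraph::vcount(g),
               length(union(inc$metabolite, inc$pathway)))
  expect_true(igraph::is_bipartite(g))
  # no metabolite-metabolite or pathway-pathway edges
  el <- igraph::as_data_frame(g, what = "edges")
  kind <- setNames(igraph::V(g)$kind, igraph::V(g)$name)
  expect_true(all(kind[el$from] != kind[el$to]))
})

test_that("ratio trajectories: identity, construction and recount oracle", {
  a_r <- data.frame(time_h = rep(c(1, 2), each = 2), replicate = rep(1:2, 2),
                    u = c(26, 26, 5, 5), v = c(1, 1, 1, 1),
                    w = c(2, 4, 0, 0))
  pairs <- data.frame(numerator = "u", denominator = "u")
  expect_equal(ratio_trajectories(a_r, pairs)$ratio, c(1, 1))
  r <- ratio_trajectories(a_r, data.frame(numerator = "u",
                                          denominator = "v"))
  expect_equal(r$ratio, c(26, 5))
  expect_equal(r$display, c("26", "5.000"))
  # zero denominator mean -> NA with diagnostic
  expect_warning(
    rz <- ratio_trajectories(a_r, data.frame(numerator = "u",
                                             denominator = "w")),
    "zero denominator")
  expect_true(is.na(rz$ratio[2]) && !is.na(rz$ratio[1]))
  expect_error(ratio_trajectories(a_r, data.frame(numerator = "nope",
                                                  denominator = "v")),
               "absent")

  # random table vs groupby-mean-then-divide recomputation
  st <- tiny_study(seed = 3)
  mets <- colnames(st$X)[1:4]
  prs <- data.frame(numerator = mets[c(1, 3)], denominator = mets[c(2, 4)])
  rr <- ratio_trajectories(st$a_r, prs)
  for (i in 1:2) {
    num_means <- tapply(st$a_r[[prs$numerator[i]]], st$a_r$time_h, mean)
    den_means <- tapply(st$a_r[[prs$denominator[i]]], st$a_r$time_h, mean)
    sub <- rr[rr$numerator == prs$numerator[i], ]
    expect_equal(sub$ratio, as.vector(num_means / den_means),
                 tolerance = 1e-10)
  }
})

test_that("pipeline is deterministic and CLI exit codes are honoured", {
  root <- tempfile("ferm")
  dir.create(root)
  on.exit(unlink(root, recursive = TRUE))
  sim_dir <- file.path(root, "sim")
  design_file <- file.path(root, "design.yaml")
  yaml::write_yaml(list(seed = 42, n_metabolites = 40,
                        n_pathways = 6), design_file)
  expect_equal(fermentomics_cli(c("simulate", "--design", design_file,
                                  "--out", sim_dir)), 0L)
  cfg <- file.path(sim_dir, "run_config.yaml")
  out1 <- file.path(root, "out1"); out2 <- file.path(root, "out2")
  expect_equal(suppressWarnings(
    fermentomics_cli(c("run", "--config", cfg, "--out", out1))), 0L)
  expect_equal(suppressWarnings(
    fermentomics_cli(c("run", "--config", cfg, "--out", out2))), 0L)
  files <- list.files(out1)
  expect_setequal(files, c("abundance.tsv", "enrichment.tsv",
                           "manifest.json", "model_summary.json",
                           "network.graphml", "network_edges.tsv",
                           "phenotype.tsv", "scores.tsv", "summary.txt",
                           "typed_metabolites.tsv"))
  for (f in files) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)),
                     info = f)
  }

  # missing pathway file -> config error, exit 2
  bad_cfg <- file.path(root, "bad.yaml")
  conf <- yaml::read_yaml(cfg)
  conf$inputs$gmt <- file.path(root, "nope.gmt")
  yaml::write_yaml(conf, bad_cfg)
  expect_equal(fermentomics_cli(c("run", "--config", bad_cfg,
                                  "--out", file.path(root, "x"))), 2L)
  # malformed input table -> stage failure, exit 3
  broke_cfg <- file.path(root, "broke.yaml")
  conf2 <- yaml::read_yaml(cfg)
  broken_tc <- file.path(root, "broken_tc.tsv")
  writeLines(c("time_h\tnot_od", "1\t2"), broken_tc)
  conf2$inputs$timecourse <- broken_tc
  yaml::write_yaml(conf2, broke_cfg)
  expect_equal(suppressWarnings(
    fermentomics_cli(c("run", "--config", broke_cfg,
                       "--out", file.path(root, "y")))), 3L)
  # unknown subcommand -> config error
  expect_equal(fermentomics_cli(c("transmogrify", "--out", "z")), 2L)
})
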