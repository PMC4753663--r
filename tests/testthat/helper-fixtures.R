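# Shared fixtures and independent oracles.

# random regression instance with controllable signal
random_instance <- function(n, p, seed, noise = 1) {
  withr_seed <- function(s, code) fermentomics:::with_seed(s, code)
  withr_seed(seed, {
    X <- matrix(rnorm(n * p), n, p)
    beta <- rnorm(p)
    y <- drop(X %*% beta) + rnorm(n, 0, noise)
    list(X = X, y = y, beta = beta)
  })
}

# Independent PLS1 oracle (Helland): with autoscaled X, y, the fitted values
# of an A-component PLS1 model equal least squares on the Krylov basis
# K_A = [s, (X'X)s, ..., (X'X)^{A-1} s], s = X'y. Completely separate from
# the NIPALS deflation route.
krylov_pls_fitted <- function(X, y, ncomp) {
  xm <- colMeans(X); xs <- apply(X, 2, sd)
  ym <- mean(y); ys <- sd(y)
  Xs <- sweep(sweep(X, 2, xm, "-"), 2, xs, "/")
  yc <- (y - ym) / ys
  s <- crossprod(Xs, yc)
  K <- matrix(NA_real_, ncol(Xs), ncomp)
  v <- s
  for (a in seq_len(ncomp)) {
    K[, a] <- v
    v <- crossprod(Xs, Xs %*% v)
  }
  Z <- Xs %*% K
  fit <- qr.fitted(qr(Z), yc)
  ym + ys * fit
}

# exact hypergeometric upper-tail by rational enumeration (exact doubles for
# N <= 30: every binomial coefficient is an exact integer < 2^53)
enum_upper_tail <- function(x, n, K, N) {
  ks <- seq.int(x, min(n, K))
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# brute-force evaluation of the nine type predicates; returns the vector of
# labels whose predicate fires (should always have length 1)
brute_type <- function(vb, cb, vg, cg, thr = 1) {
  fired <- character(0)
  if (vb <= thr && vg <= thr) fired <- c(fired, "A")
  if (vb > thr && cb < 0 && vg <= thr) fired <- c(fired, "B")
  if (vb > thr && cb > 0 && vg <= thr) fired <- c(fired, "C")
  if (vb > thr && cb < 0 && vg > thr && cg > 0) fired <- c(fired, "D")
  if (vb <= thr && vg > thr && cg > 0) fired <- c(fired, "E")
  if (vb <= thr && vg > thr && cg < 0) fired <- c(fired, "F")
  if (vb > thr && cb > 0 && vg > thr && cg < 0) fired <- c(fired, "G")
  if (vb > thr && cb > 0 && vg > thr && cg > 0) fired <- c(fired, "H")
  if (vb > thr && cb < 0 && vg > thr && cg < 0) fired <- c(fired, "I")
  fired
}

# toy chain pathway a -> b -> c (out-degrees 1, 1, 0)
chain_pathway <- function() {
  list(id = "chain", description = "toy",
       compounds = c("a", "b", "c"),
       edges = data.frame(from = c("a", "b"), to = c("b", "c"),
                          stringsAsFactors = FALSE))
}

# small complete synthetic study kept in memory (no files)
tiny_study <- function(seed = 1, design = simulation_design(seed = seed)) {
  tc <- simulate_fermentation(seed = seed)
  phen <- phenotype_rates(tc, design$sample_times_h)
  sim <- simulate_metabolome(phen, design)
  gt <- sim$ground_truth
  classes <- Filter(length, list(g_pos = gt$metabolite[gt$sign_g > 0],
                                 b_neg = gt$metabolite[gt$sign_b < 0]))
  lib <- make_pathway_library(gt$metabolite, planted = classes,
                              seed = seed + 1000)
  a_r <- relative_abundance(sim$table,
                            phen$dcw[match(sim$table$time_h, phen$time_h)])
  list(tc = tc, phen = phen, table = sim$table, gt = gt, lib = lib,
       a_r = a_r, X = as.matrix(a_r[, setdiff(names(a_r),
                                              c("time_h", "replicate"))]),
       y_mu = phen$mu[match(a_r$time_h, phen$time_h)],
       y_q = phen$q[match(a_r$time_h, phen$time_h)])
}
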