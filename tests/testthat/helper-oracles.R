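# Independent oracles.  These deliberately re-derive results through
# different code paths (stats::dnbinom, literal definitions, base qr)
# than the implementations they check.

# Conditional NB exact test by direct enumeration of the joint
# probabilities of all splits of the total, via stats::dnbinom.
oracle_exact_p <- function(z1, z2, n1, n2, phi) {
  t <- z1 + z2
  if (t == 0) return(1)
  r <- 1 / phi
  mu <- t / (n1 + n2)
  y <- 0:t
  pr <- dnbinom(y, size = n1 * r, mu = n1 * mu) *
    dnbinom(t - y, size = n2 * r, mu = n2 * mu)
  obs <- pr[z1 + 1]
  min(1, sum(pr[pr <= obs * (1 + 1e-10)]) / sum(pr))
}

# Literal-definition BH: q_(i) = min over j >= i of m * p_(j) / j.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    js <- i:m
    q[o[i]] <- min(1, min(m * p[o[js]] / js))
  }
  q
}

# Truth-table oracle for the cessation pattern rules, written directly
# from the branch definitions (checked top to bottom, first match wins).
oracle_pattern <- function(s1, f1, s2, f2, s3, f3) {
  opp <- function(a, b) (a > 0 && b < 0) || (a < 0 && b > 0)
  same <- function(a, b) (a > 0 && b > 0) || (a < 0 && b < 0)
  if (s1 && s2 && opp(f2, f1) && !s3) return("reversible")
  if (s1 && s3 && same(f3, f1) && !s2) return("persistent")
  if (s1 && s2 && s3 && opp(f2, f1) && same(f3, f1)) {
    if (abs(f3) < abs(f2)) return("semi_reversible")
    return("semi_persistent")
  }
  if (s3 && same(f3, f1) && abs(f3) > abs(f1)) return("continuing")
  if (s2 && !s1 && !s3) return("recovery")
  "unclassified"
}

# Orthonormal polynomial contrasts through base qr().
oracle_qr_contrasts <- function(times) {
  q <- qr.Q(qr(cbind(1, times, times^2)))
  q[, 2:3, drop = FALSE]
}

# Small NB count matrix with a fixed two-group design at one time point.
make_two_group_counts <- function(G, n = 5, mu = NULL, phi = 0.1,
                                  lfc = numeric(G), time = "9mo",
                                  seed = 1) {
  set.seed(seed)
  if (is.null(mu)) mu <- exp(rnorm(G, 4, 1.5))
  cnt <- cbind(
    matrix(rnbinom(G * n, mu = rep(mu, n), size = 1 / phi), G, n),
    matrix(rnbinom(G * n, mu = rep(mu * 2^lfc, n), size = 1 / phi), G, n))
  dimnames(cnt) <- list(sprintf("g%05d", seq_len(G)),
                        sprintf("s%02d", seq_len(2 * n)))
  samples <- data.frame(
    sample_id = colnames(cnt),
    group = rep(c("AC", "CS"), each = n),
    time_label = time)
  count_matrix(cnt, samples)
}

# A null simulation spec with everything switched off except what the
# caller plants.
null_spec <- function(n_genes, phi = 0.1, seed = 1, ...) {
  zero_pat <- lapply(setNames(nm = c("reversible", "semi_reversible",
                                     "persistent", "semi_persistent",
                                     "continuing", "recovery")),
                     function(nm) list(n = 0, lfc = 2, prop_up = 0.5))
  zero_tr <- lapply(setNames(nm = c("group_plus_linear", "group_plus_quad",
                                    "linear_interaction",
                                    "quad_interaction", "time_only")),
                    function(nm) list(n = 0, amplitude = 2.4))
  simulation_spec(
    n_genes = n_genes,
    dispersion_model = list(type = "constant", phi = phi),
    planted_pattern_table = zero_pat,
    planted_trend_table = zero_tr,
    geneset_spec = list(n_sets = 0, size_range = c(5, 5), n_enriched = 0,
                        n_recurrent = 0, effect = 0, prop_up = 0.5,
                        persist = 0),
    metabolite_spec = list(n_metabolites = 2, shift_sd = 0,
                           missing_rate = 0, sigma_log = 0.5),
    seed = seed, ...)
}

modify_spec <- function(spec, ...) {
  mod <- list(...)
  for (nm in names(mod)) spec[[nm]] <- mod[[nm]]
  spec
}
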