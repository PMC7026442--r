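# Independent brute-force oracles used to cross-check the package's
# implementations. These are deliberately naive and share no code with R/.

# Benjamini-Hochberg step-up, computed from the definition: sort p, take
# p_(i) * n / i, enforce monotonicity from the largest rank down, cap at 1.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) if (n > 1) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Upper-tail hypergeometric probability P(X >= k) by explicit enumeration of
# the 2x2 tables: K term genes, N background, nq query genes drawn.
oracle_hyper_tail <- function(k, K, nq, N) {
  kmax <- min(K, nq)
  if (k > kmax) return(0)
  total <- choose(N, nq)
  sum(vapply(k:kmax, function(x) {
    choose(K, x) * choose(N - K, nq - x) / total
  }, numeric(1)))
}

# Product-limit estimator from the definition: walk the distinct event
# times in order; at each, n_j = subjects with observed time >= t_j (deaths
# processed before censorings at ties), d_j = events at t_j.
oracle_km <- function(times, events) {
  et <- sort(unique(times[events == 1]))
  s <- 1
  out <- data.frame(time = numeric(), n_risk = numeric(),
                    n_event = numeric(), surv = numeric())
  for (t in et) {
    n_j <- sum(times >= t)
    d_j <- sum(times == t & events == 1)
    s <- s * (1 - d_j / n_j)
    out <- rbind(out, data.frame(time = t, n_risk = n_j, n_event = d_j, surv = s))
  }
  out
}

# Two-group log-rank chi-square from the definition: at each distinct event
# time, observed deaths in group 1 minus the hypergeometric expectation,
# with the matching hypergeometric variance.
oracle_logrank <- function(t1, e1, t2, e2) {
  times <- c(t1, t2); events <- c(e1, e2)
  g1 <- c(rep(TRUE, length(t1)), rep(FALSE, length(t2)))
  et <- sort(unique(times[events == 1]))
  OmE <- 0; V <- 0
  for (t in et) {
    at <- times >= t
    n <- sum(at); n1 <- sum(at & g1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & g1)
    OmE <- OmE + d1 - d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- OmE^2 / V
  list(statistic = stat, p = pchisq(stat, df = 1, lower.tail = FALSE))
}

# Cox log partial likelihood for a single covariate vector, Breslow form
# (exact when there are no tied event times), written from the definition.
oracle_cox_loglik <- function(beta, x, times, events) {
  ll <- 0
  for (i in which(events == 1)) {
    risk <- times >= times[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# Maximize the written partial likelihood by golden-section search.
oracle_cox_fit <- function(x, times, events, lower = -10, upper = 10) {
  optimize(function(b) oracle_cox_loglik(b, x, times, events),
           interval = c(lower, upper), maximum = TRUE, tol = 1e-9)$maximum
}

# Brute-force diseasome reconstruction straight from the gene sets.
oracle_diseasome <- function(sets, exposure_id) {
  ids <- setdiff(names(sets), exposure_id)
  genes <- sort(unique(unlist(lapply(ids, function(d)
    intersect(sets[[exposure_id]], sets[[d]])))))
  edges <- list()
  for (d in names(sets)) {
    for (g in genes) if (g %in% sets[[d]]) {
      edges[[length(edges) + 1L]] <- c(d, g)
    }
  }
  assoc <- list()
  nm <- names(sets)
  for (a in seq_along(nm)) for (b in seq_along(nm)) if (a < b) {
    i <- nm[a]; j <- nm[b]
    n <- length(intersect(sets[[i]], sets[[j]]))
    if (n >= 1 || i == exposure_id || j == exposure_id) {
      assoc[[length(assoc) + 1L]] <- data.frame(
        i = i, j = j, n_shared = n,
        jaccard = n / length(union(sets[[i]], sets[[j]])),
        stringsAsFactors = FALSE)
    }
  }
  list(genes = genes,
       edges = if (length(edges)) do.call(rbind, lapply(edges, function(e)
         data.frame(disease = e[1], gene = e[2], stringsAsFactors = FALSE)))
       else data.frame(disease = character(), gene = character()),
       assoc = do.call(rbind, assoc))
}

random_gene_set <- function(universe, max_size = length(universe)) {
  n <- sample.int(max_size, 1L)
  sample(universe, n)
}

# Small expression study with a known planted signal, for DE tests.
tiny_linked_demo <- function(seed = 1, n_genes = 800) {
  universe <- sprintf("G%04d", seq_len(n_genes))
  expo <- study_spec("EXPO", n_genes, 20, 20,
                     de_up = universe[1:30], de_down = universe[31:60],
                     effect_size = 2, noise_sd = 0.5, seed = seed,
                     gene_ids = universe)
  d1 <- study_spec("D1", n_genes, 20, 20,
                   de_up = universe[101:120], de_down = universe[121:140],
                   effect_size = 2, noise_sd = 0.5, seed = seed + 1,
                   gene_ids = universe)
  d2 <- study_spec("D2", n_genes, 20, 20,
                   de_up = universe[141:150], de_down = universe[151:160],
                   effect_size = 2, noise_sd = 0.5, seed = seed + 2,
                   gene_ids = universe)
  generate_linked_studies(
    expo, list(d1, d2),
    shared_up = list(D1 = universe[1:5], D2 = universe[c(1, 6, 7)]),
    shared_down = list(D1 = universe[31:33], D2 = character()))
}

de_set_for <- function(study, id = study$study_id, p_cutoff = 0.01,
                       lfc_cutoff = 1) {
  norm <- zscore_normalize(study)
  select_significant(gene_stats(norm, lfc_study = study), disease_id = id,
                     p_cutoff = p_cutoff, lfc_cutoff = lfc_cutoff)
}
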