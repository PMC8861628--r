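# Independent brute-force oracles.  These deliberately avoid the package's
# code paths: plain edge-list scans, exhaustive walks, two-pass statistics.

# reachable set via relation edges, iterative frontier expansion on the raw
# data frame (no rdf_match)
oracle_reachable <- function(graph, start, relation, max_depth = 1000) {
  edges <- graph[graph$p == relation, c("s", "o")]
  seen <- character()
  frontier <- start
  depth <- 0
  while (length(frontier) && depth < max_depth) {
    nxt <- unique(edges$o[edges$s %in% frontier])
    nxt <- setdiff(nxt, c(seen, start))
    if (!length(nxt)) break
    seen <- c(seen, nxt)
    frontier <- nxt
    depth <- depth + 1
  }
  sort(seen)
}

# exhaustive two-constraint filter: for every entity, walk every subject's
# ancestor chain and every sameAs/type edge by raw subsetting
oracle_two_constraint <- function(graph, entity_iris, seeds, allowed) {
  out <- list()
  for (ent in entity_iris) {
    subjects <- unique(graph$o[graph$s == ent & graph$p == kgemr:::kg_iri$subject])
    qual <- character()
    for (su in subjects) {
      anc <- c(su, oracle_reachable(graph, su, kgemr:::kg_iri$broader))
      if (length(intersect(anc, seeds))) qual <- c(qual, su)
    }
    if (!length(qual)) next
    same <- graph$o[graph$s == ent & graph$p == kgemr:::kg_iri$sameas]
    ok <- FALSE
    for (sa in same) {
      types <- graph$o[graph$s == sa & graph$p == kgemr:::kg_iri$rdftype]
      if (length(intersect(types, allowed))) ok <- TRUE
    }
    if (ok) out[[ent]] <- sort(qual)
  }
  out
}

# random DAG over n nodes (edges only from lower to higher index)
random_dag <- function(n, p_edge = 0.15, seed = 1) {
  set.seed(seed)
  s <- character(); o <- character()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (runif(1) < p_edge) {
      s <- c(s, paste0("urn:n", i)); o <- c(o, paste0("urn:n", j))
    }
  }
  rdf_graph(s, rep("urn:rel", length(s)), o)
}

# random DBpedia-like fixture for the two-constraint fuzz: categories with a
# random broader forest, entities with 1-3 subjects, optional sameAs + type
random_db_fixture <- function(n_entities = 30, n_cats = 20, seed = 1) {
  set.seed(seed)
  seeds <- paste0("urn:seed", 1:3)
  cats <- paste0("urn:cat", seq_len(n_cats))
  s <- character(); p <- character(); o <- character()
  for (ct in cats) {
    # each category points at a seed, another category, or nothing
    r <- runif(1)
    tgt <- if (r < 0.4) sample(seeds, 1) else if (r < 0.7) sample(cats, 1) else NULL
    if (!is.null(tgt) && !identical(tgt, ct)) {
      s <- c(s, ct); p <- c(p, kgemr:::kg_iri$broader); o <- c(o, tgt)
    }
  }
  allowed <- "urn:classA"
  ents <- paste0("urn:ent", seq_len(n_entities))
  for (e in ents) {
    for (su in sample(cats, sample(1:3, 1))) {
      s <- c(s, e); p <- c(p, kgemr:::kg_iri$subject); o <- c(o, su)
    }
    if (runif(1) < 0.7) {
      en <- sub("ent", "en", e)
      s <- c(s, e); p <- c(p, kgemr:::kg_iri$sameas); o <- c(o, en)
      if (runif(1) < 0.7) {
        s <- c(s, en); p <- c(p, kgemr:::kg_iri$rdftype)
        o <- c(o, sample(c(allowed, "urn:classB"), 1))
      }
    }
  }
  list(graph = rdf_graph(s, p, o), entities = ents, seeds = seeds,
       allowed = allowed, cats = cats)
}

# two-pass mean / sample-variance oracle
oracle_mean_sd <- function(x) {
  m <- sum(x) / length(x)
  list(mean = m, sd = sqrt(sum((x - m)^2) / (length(x) - 1)))
}

# nominal Krippendorff alpha by direct pair counting (independent coding)
oracle_alpha <- function(m) {
  pairs_o <- 0; tot <- 0
  vals <- sort(unique(na.omit(as.vector(m))))
  marg <- setNames(numeric(length(vals)), vals)
  for (u in seq_len(ncol(m))) {
    col <- na.omit(m[, u]); mu <- length(col)
    if (mu < 2) next
    for (i in seq_len(mu)) {
      marg[as.character(col[i])] <- marg[as.character(col[i])] + 1
      for (j in seq_len(mu)) if (i != j && col[i] != col[j])
        pairs_o <- pairs_o + 1 / (mu - 1)
    }
    tot <- tot + mu
  }
  d_o <- pairs_o / tot
  d_e <- (sum(outer(marg, marg)) - sum(marg^2)) / (tot * (tot - 1))
  1 - d_o / d_e
}
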