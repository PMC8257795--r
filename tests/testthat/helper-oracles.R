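# Independent oracles used by the property and acceptance tests. These are
# deliberately written with different data structures / algorithms than the
# package implementations they check.

# --- collinear chaining -----------------------------------------------------

# exhaustive enumeration of every valid chain (both orientations) by DFS;
# returns the maximum chain length. Only feasible for small anchor sets.
oracle_max_chain_exhaustive <- function(q, t, max_gap) {
  n <- length(q)
  best <- 0L
  compat <- function(i, j, dir) {
    dq <- q[j] - q[i]; dt <- dir * (t[j] - t[i])
    dq >= 1 && dq <= max_gap && dt >= 0 && dt <= max_gap
  }
  for (dir in c(1, -1)) {
    dfs <- function(last, len) {
      best <<- max(best, len)
      for (j in seq_len(n)) {
        if (compat(last, j, dir)) dfs(j, len + 1L)
      }
    }
    for (s in seq_len(n)) dfs(s, 1L)
  }
  best
}

# DAG longest-path oracle via igraph topological order (used at n ~ 40
# where exhaustive DFS is infeasible)
oracle_max_chain_dag <- function(q, t, max_gap) {
  n <- length(q)
  best <- 1L
  for (dir in c(1, -1)) {
    edges <- list()
    for (i in seq_len(n)) for (j in seq_len(n)) {
      dq <- q[j] - q[i]; dt <- dir * (t[j] - t[i])
      if (dq >= 1 && dq <= max_gap && dt >= 0 && dt <= max_gap)
        edges[[length(edges) + 1L]] <- c(i, j)
    }
    if (!length(edges)) next
    g <- igraph::graph_from_edgelist(do.call(rbind, edges), directed = TRUE)
    g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
    ord <- as.integer(igraph::topo_sort(g))
    len <- rep(1L, n)
    for (v in ord) {
      for (u in as.integer(igraph::neighbors(g, v, mode = "in")))
        len[v] <- max(len[v], len[u] + 1L)
    }
    best <- max(best, max(len))
  }
  best
}

# --- NG86 -------------------------------------------------------------------

# independent Nei-Gojobori implementation: plain loops over codon strings,
# no caching, same conventions (stop targets non-synonymous for site counts,
# stop-free minimal pathways, Jukes-Cantor correction)
oracle_ng86 <- function(codons_a, codons_b) {
  gcode <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  syn_sites_one <- function(cod) {
    ch <- strsplit(cod, "")[[1]]
    s <- 0
    for (p in 1:3) for (b in bases[bases != ch[p]]) {
      alt <- ch; alt[p] <- b
      ac <- paste(alt, collapse = "")
      if (gcode[[ac]] != "*" && gcode[[ac]] == gcode[[cod]]) s <- s + 1 / 3
    }
    s
  }
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    res <- list()
    for (i in seq_along(v)) for (p in perms(v[-i]))
      res[[length(res) + 1L]] <- c(v[i], p)
    res
  }
  pair_diffs <- function(c1, c2) {
    if (c1 == c2) return(c(0, 0))
    a <- strsplit(c1, "")[[1]]; b <- strsplit(c2, "")[[1]]
    dpos <- which(a != b)
    paths_ok <- list(); paths_all <- list()
    for (ord in perms(dpos)) {
      cur <- a; sd <- 0; nd <- 0; blocked <- FALSE
      for (p in ord) {
        nxt <- cur; nxt[p] <- b[p]
        cs <- paste(cur, collapse = ""); ns <- paste(nxt, collapse = "")
        if (gcode[[ns]] == "*" || gcode[[cs]] == "*") {
          blocked <- TRUE
          nd <- nd + 1
        } else if (gcode[[cs]] == gcode[[ns]]) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      paths_all[[length(paths_all) + 1L]] <- c(sd, nd)
      if (!blocked) paths_ok[[length(paths_ok) + 1L]] <- c(sd, nd)
    }
    use <- if (length(paths_ok)) paths_ok else paths_all
    colMeans(do.call(rbind, use))
  }
  S <- 0; Sd <- 0; Nd <- 0
  for (i in seq_along(codons_a)) {
    S <- S + (syn_sites_one(codons_a[i]) + syn_sites_one(codons_b[i])) / 2
    d <- pair_diffs(codons_a[i], codons_b[i])
    Sd <- Sd + d[1]; Nd <- Nd + d[2]
  }
  N <- 3 * length(codons_a) - S
  ps <- Sd / S; pn <- Nd / N
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(Ka = jc(pn), Ks = jc(ps), N = N, S = S, Sd = Sd, Nd = Nd)
}

# --- forward-backward -------------------------------------------------------

# exact posterior by vectorised path-sum enumeration over all K^T state
# sequences
oracle_posterior_pathsum <- function(init, trans, emiss) {
  T_ <- nrow(emiss); K <- ncol(emiss)
  get_tr <- function(t) if (is.list(trans)) trans[[t]] else trans
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
  w <- init[paths[, 1]] * emiss[cbind(1, paths[, 1])]
  if (T_ > 1) for (t in 2:T_) {
    tr <- get_tr(t - 1)
    w <- w * tr[cbind(paths[, t - 1], paths[, t])] * emiss[cbind(t, paths[, t])]
  }
  post <- matrix(0, T_, K)
  for (t in seq_len(T_)) for (k in seq_len(K))
    post[t, k] <- sum(w[paths[, t] == k])
  post / rowSums(post)
}

# --- run culling ------------------------------------------------------------

# independent culling recurrence operating on explicit (value, length) run
# lists instead of call vectors
oracle_cull <- function(calls, min_block) {
  runs_of <- function(x) {
    r <- rle(x); Map(list, value = r$values, len = r$lengths)
  }
  runs <- runs_of(calls)
  for (L in 2:min_block) {
    repeat {
      lens <- vapply(runs, function(r) r$len, numeric(1))
      if (length(runs) <= 1 || all(lens >= L)) break
      i <- which(lens < L)[1]
      left <- if (i > 1) lens[i - 1] else -1
      right <- if (i < length(runs)) lens[i + 1] else -1
      if (left >= right) {
        runs[[i - 1]]$len <- runs[[i - 1]]$len + runs[[i]]$len
      } else {
        runs[[i + 1]]$len <- runs[[i + 1]]$len + runs[[i]]$len
      }
      runs[[i]] <- NULL
      # merge adjacent equal-valued runs
      j <- 1
      while (j < length(runs)) {
        if (identical(runs[[j]]$value, runs[[j + 1]]$value)) {
          runs[[j]]$len <- runs[[j]]$len + runs[[j + 1]]$len
          runs[[j + 1]] <- NULL
        } else j <- j + 1
      }
    }
    if (length(runs) == 1) break
  }
  unlist(lapply(runs, function(r) rep(r$value, r$len)))
}

# --- hypergeometric ---------------------------------------------------------

oracle_fisher_p <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  ks <- max(0, k - n):min(k, m)
  pr <- choose(m, ks) * choose(n, k - ks) / choose(m + n, k)
  obs <- pr[ks == a]
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# --- Bayes interval ---------------------------------------------------------

# brute force: every contiguous interval containing the peak; minimal width
# with mass >= prob
oracle_bayes <- function(lod, prob) {
  w <- 10^lod; w <- w / sum(w)
  peak <- which.max(lod)
  best <- NULL
  for (i in 1:peak) for (j in peak:length(lod)) {
    mass <- sum(w[i:j])
    if (mass >= prob - 1e-12) {
      wd <- j - i
      if (is.null(best) || wd < best$width)
        best <- list(i = i, j = j, width = wd, mass = mass)
    }
  }
  best
}

# --- sliding quantiles ------------------------------------------------------

oracle_sliding_quantile <- function(values, window) {
  n <- length(values)
  q <- (rank(values, ties.method = "average") - 0.5) / n
  out <- numeric(0)
  i <- 1
  while (i + window - 1 <= n) {
    out <- c(out, mean(q[i:(i + window - 1)]))
    i <- i + 1
  }
  out
}

# --- DBSCAN -----------------------------------------------------------------

# brute-force pairwise-distance clustering: core points and their
# transitive-closure components
oracle_dbscan_cores <- function(anchors, radius, min_hits) {
  n <- nrow(anchors)
  d <- as.matrix(stats::dist(anchors))
  core <- vapply(seq_len(n), function(i) sum(d[i, ] <= radius) >= min_hits,
                 logical(1))
  adj <- d <= radius & outer(core, core, "&")
  comp <- rep(0L, n); cl <- 0L
  for (i in which(core)) {
    if (comp[i] != 0L) next
    cl <- cl + 1L
    stack <- i
    while (length(stack)) {
      v <- stack[1]; stack <- stack[-1]
      if (comp[v] != 0L) next
      comp[v] <- cl
      stack <- c(stack, which(adj[v, ] & comp == 0L))
    }
  }
  list(core = core, components = comp)
}
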