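# Shared fixtures, built once per test run and cached. Each fixture is a
# deterministic function of its fixed seed; seeds were fixed when the fixture
# was written.
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# small book + single planted edge, used by estimation-chain tests
tiny_study <- function() fixture("tiny_study", function() {
  book <- make_parcel_book(12, seed = 1, locality = 0.03)
  des <- coupling_design(
    data.frame(i = 1, j = 7, freq = 12, lag = pi / 2, kappa = 8, amp = 1,
               conditions = "Shape", windows = "early,late"),
    subject_gain = 1)
  st <- simulate_dataset(book, des, n_subjects = 1, n_trials = 30, seed = 2)
  raw <- get_epochs(st, 1)
  list(book = book, design = des, study = st, raw = raw,
       nb = filter_epochs(raw, 12))
})

# direct estimator access: wrap phase matrices in a minimal narrowband object
# (parcels x samples, one trial, all samples valid, inside the early window)
nb_from_phases <- function(phi) {
  z <- array(0i, dim = c(1, nrow(phi), ncol(phi)))
  z[1, , ] <- exp(1i * phi)
  structure(list(z = z, f0 = 10, fs_out = 50, m = 5,
                 t = seq(0.6, 1.2 - 1e-9, length.out = ncol(phi)),
                 valid = rep(TRUE, ncol(phi)),
                 condition = "Shape", load = 2L, subject = 1L),
            class = "narrowband_epochs")
}

# exhaustive edge-betweenness oracle: enumerate all shortest paths between
# all node pairs by BFS layer expansion, crediting each edge fractionally
brute_edge_betweenness <- function(adj) {
  p <- nrow(adj)
  pr <- which(upper.tri(adj) & adj, arr.ind = TRUE)
  eb <- numeric(nrow(pr))
  ekey <- paste(pr[, 1], pr[, 2])
  all_shortest <- function(s, t) {
    # BFS distances from s
    dist <- rep(Inf, p); dist[s] <- 0
    frontier <- s
    while (length(frontier) > 0 && !is.finite(dist[t])) {
      nxt <- integer(0)
      for (v in frontier) {
        nb <- which(adj[v, ] & !is.finite(dist))
        dist[nb] <- dist[v] + 1
        nxt <- c(nxt, nb)
      }
      frontier <- unique(nxt)
    }
    if (!is.finite(dist[t])) return(list())
    # enumerate paths backwards from t along strictly decreasing distance
    paths <- list(t)
    for (d in seq(dist[t], 1)) {
      nxt_paths <- list()
      for (pa in paths) {
        head <- pa[1]
        preds <- which(adj[head, ] & dist == d - 1)
        for (q in preds) nxt_paths[[length(nxt_paths) + 1]] <- c(q, pa)
      }
      paths <- nxt_paths
    }
    paths
  }
  for (s in 1:(p - 1)) for (t in (s + 1):p) {
    paths <- all_shortest(s, t)
    np <- length(paths)
    if (np == 0) next
    for (pa in paths) {
      for (k in seq_len(length(pa) - 1)) {
        a <- min(pa[k], pa[k + 1]); b <- max(pa[k], pa[k + 1])
        idx <- match(paste(a, b), ekey)
        eb[idx] <- eb[idx] + 1 / np
      }
    }
  }
  data.frame(i = pr[, 1], j = pr[, 2], betweenness = eb)
}

# random stat_graph on p nodes with given edge probability
random_stat_graph <- function(p, prob, seed) {
  set.seed(seed)
  w <- matrix(0, p, p)
  ut <- which(upper.tri(w))
  on <- ut[runif(length(ut)) < prob]
  w[on] <- runif(length(on), 0.05, 0.5) * sample(c(-1, 1), length(on), TRUE)
  w <- w + t(w)
  stat_graph(weights = w, sign = sign(w),
             p = ifelse(w != 0, 0.01, NA) * 1,
             tested = matrix(TRUE, p, p) & !diag(p),
             n_subjects = 12)
}
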