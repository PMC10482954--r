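# Independent oracles used by unit and acceptance tests.

# Reference DBSCAN: neighbour graph, core points with >= min_samples
# neighbours (self included), connected components of the core subgraph
# (igraph), borders assigned to the first core neighbour in input order.
brute_dbscan <- function(P, eps, min_samples) {
  D <- as.matrix(stats::dist(P))
  n <- nrow(P)
  adj <- D <= eps
  core <- rowSums(adj) >= min_samples
  lab <- integer(n)
  if (any(core)) {
    g <- igraph::graph_from_adjacency_matrix(adj[core, core, drop = FALSE],
                                             mode = "undirected",
                                             diag = FALSE)
    comp <- igraph::components(g)$membership
    first <- tapply(seq_along(comp), comp, min)
    lab[core] <- as.integer(rank(first)[comp])
  }
  for (p in which(!core)) {
    cn <- which(adj[p, ] & core)
    if (length(cn)) lab[p] <- lab[cn[1]]
  }
  lab
}

# Exact big-integer/rational evaluation of the hypergeometric enrichment
# sum, via Python's arbitrary-precision integers and Fraction (the result
# is the correctly rounded double of an exact rational). cases: data.frame
# with columns n_exp, nps, npd, nns, nnd, L. Returns numeric vector.
python_hypergeom_oracle <- function(cases) {
  f_in <- tempfile(fileext = ".csv")
  f_out <- tempfile(fileext = ".txt")
  utils::write.csv(cases, f_in, row.names = FALSE)
  script <- c(
    "import csv, sys",
    "from fractions import Fraction",
    "from math import comb",
    "inp, outp = sys.argv[1], sys.argv[2]",
    "rows = list(csv.DictReader(open(inp)))",
    "res = []",
    "for r in rows:",
    "    n_exp, nps, npd = int(r['n_exp']), int(r['nps']), int(r['npd'])",
    "    nns, nnd, L = int(r['nns']), int(r['nnd']), int(r['L'])",
    "    n_noise = L * L - n_exp",
    "    A = n_exp - nps",
    "    B = n_noise - nns",
    "    D = (n_exp - nps) + (n_noise - nns)",
    "    k = npd + nnd",
    "    den = comb(D, k)",
    "    s = Fraction(0)",
    "    for i in range(nnd + 1):",
    "        a, b = npd + i, nnd - i",
    "        if a < 0 or b < 0 or a > A or b > B:",
    "            continue",
    "        s += Fraction(comb(A, a) * comb(B, b), den)",
    "    res.append(min(float(s), 1.0))",
    "open(outp, 'w').write('\\n'.join(repr(x) for x in res) + '\\n')")
  f_py <- tempfile(fileext = ".py")
  writeLines(script, f_py)
  status <- system2("python", c(f_py, f_in, f_out))
  stopifnot(status == 0)
  as.numeric(readLines(f_out))
}

# brute-force divergent-window scan (independent of the package loop
# structure): marks positions covered by any qualifying window
brute_divergence_positions <- function(ss_a, ss_b, min_len, min_frac) {
  a <- strsplit(ss_a, "")[[1]]
  b <- strsplit(ss_b, "")[[1]]
  d <- (a == "H" & b == "E") | (a == "E" & b == "H")
  n <- length(d)
  mark <- logical(n)
  if (n >= min_len) {
    for (s in 1:(n - min_len + 1)) {
      for (e in (s + min_len - 1):n) {
        if (mean(d[s:e]) >= min_frac) mark[s:e] <- TRUE
      }
    }
  }
  which(mark)
}

# independent span construction: runs of marked positions, each trimmed
# to its outermost difference
brute_divergence_spans <- function(ss_a, ss_b, min_len, min_frac) {
  a <- strsplit(ss_a, "")[[1]]
  b <- strsplit(ss_b, "")[[1]]
  d <- (a == "H" & b == "E") | (a == "E" & b == "H")
  marked <- brute_divergence_positions(ss_a, ss_b, min_len, min_frac)
  if (!length(marked)) return(data.frame(start = integer(0),
                                         end = integer(0)))
  grp <- cumsum(c(1L, diff(marked) > 1L))
  out <- do.call(rbind, lapply(split(marked, grp), function(run) {
    dd <- run[d[run]]
    data.frame(start = min(dd), end = max(dd))
  }))
  rownames(out) <- NULL
  out
}
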