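# Shared fixtures and independent oracles. Heavy objects (the default
# synthetic run) are computed once per test session and cached.

.cache <- new.env(parent = emptyenv())

# Full pipeline on the default study conditions (200 MCI + 140 CN, 164
# features, two planted 10-feature modules, seed 1).
cachedRun <- function() {
  if (is.null(.cache$run))
    .cache$run <- suppressWarnings(suppressMessages(
      runConsensusAnalysis(seed = 1)))
  .cache$run
}

# Small cohort for I/O round trips.
cachedSmallSim <- function() {
  if (is.null(.cache$smallSim))
    .cache$smallSim <- simulateCohort(simConfig(n_cn = 15, n_mci = 15,
                                                seed = 3))
  .cache$smallSim
}

# Minimal schema of p thickness features for unit tests that need a
# CohortMatrix without the full 164-feature catalog.
toySchema <- function(p = 4, volumes = 0) {
  entries <- data.frame(
    feature_id = c(sprintf("thick%02d", seq_len(p)),
                   if (volumes > 0) sprintf("vol%02d", seq_len(volumes))),
    region = "toy",
    hemisphere = "none",
    measure = c(rep("thickness", p), rep("volume", volumes)),
    tissue = c(rep("cortical_gm", p), rep("subcortical", volumes)),
    source_table = "aseg", excluded = FALSE, stringsAsFactors = FALSE)
  methods::new("FeatureSchema", entries = entries)
}

toyCohort <- function(values, cohort, icv = NULL, schema = NULL,
                      timepoint = "baseline") {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("S%03d", seq_len(nrow(values)))
  if (is.null(schema)) {
    p <- sum(grepl("^thick", colnames(values)))
    v <- sum(grepl("^vol", colnames(values)))
    schema <- toySchema(p, v)
  }
  if (is.null(icv)) icv <- rep(1.5e6, nrow(values))
  methods::new("CohortMatrix", values = values, cohort = cohort,
               timepoint = timepoint, icv = icv, schema = schema,
               volumeUnit = "mm3")
}

toyZ <- function(values, tag = "baseline") {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("S%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("f%02d", seq_len(ncol(values)))
  methods::new("ZMatrix", values = values, datasetTag = tag,
               constant = 1.3489, degenerate = character(0))
}

# ---- independent oracles -------------------------------------------------

# TOM by literal triple loop over the definition.
bruteTOM <- function(a) {
  n <- nrow(a)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { out[i, j] <- 1; next }
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    ki <- sum(a[i, -i]); kj <- sum(a[j, -j])
    out[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
  }
  out
}

# Step-up BH straight from the definition: adj_i = min_{j>=i} p_(j)*m/j.
bruteBH <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m))
    adj[i] <- min(pmin(ps[i:m] * m / (i:m), 1))
  out <- numeric(m)
  out[o] <- adj
  out
}

# AUC by counting all between-class pairs (ties count 1/2).
bruteAUC <- function(x, cls) {
  pos <- x[cls]; neg <- x[!cls]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# Random symmetric adjacency with unit diagonal.
randomAdjacency <- function(n) {
  a <- matrix(stats::runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  a
}
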